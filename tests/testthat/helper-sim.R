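# Shared fixture builders: small simulated populations used across tests.

# Down-scaled population: few lines, short genome, one season, one
# treatment, few blocks -- keeps per-test runtime low while preserving the
# structure of the full design.
small_config <- function(...) {
  defaults <- list(
    n_ril = 40, n_chrom = 2, markers_per_chrom = 6, chrom_length_cm = 50,
    years = 2012, treatments = "UN", blocks_per_env = c("2012" = 3),
    points_range = c(6, 10), seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# A config with every stochastic effect switched off: each plant then
# traces the population-mean logistic curve exactly.
null_config <- function(...) {
  zero <- c(r = 0, Lmax = 0, L0 = 0)
  small_config(
    qtl_effect_sizes = list(r = numeric(0), Lmax = numeric(0)),
    n_qtl_per_trait = 0,
    year_sd = zero, gxe_sd = zero, block_sd = zero, plant_sd = zero,
    residual_sd = 0, amax_beta = zero, ...)
}

# Simulate phenotype data for a single-genotype hierarchical fit.
one_genotype_data <- function(r = 0.08, Lmax = 60, L0 = 3, n_plants = 8,
                              n_points = 12, noise_sd = 0.1, seed = 1,
                              t_max = NULL) {
  set.seed(seed)
  if (is.null(t_max)) t_max <- 1.3 * duration_to_fraction(
    logistic_params(r, Lmax, L0), 0.95)
  out <- lapply(seq_len(n_plants), function(p) {
    tt <- sort(stats::runif(n_points, 0.02 * t_max, t_max))
    data.frame(plant_id = sprintf("P%02d", p), genotype = "G1",
               t_dd = tt,
               value = logistic_size_vec(r, Lmax, L0, tt) +
                 stats::rnorm(n_points, 0, noise_sd))
  })
  do.call(rbind, out)
}
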