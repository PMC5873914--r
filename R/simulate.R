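# Synthetic-data generator: RIL genotypes on a linkage map, additive QTL
# architectures, environment structure (years x density treatments x
# blocks), longitudinal leaf measurements on a degree-day axis, daily
# temperatures, and reflectance spectra.  Every stage returns the injected
# truth so downstream estimators can be validated against it.

#' Haldane recombination fraction
#'
#' Map-function conversion from genetic distance to recombination
#' fraction, \eqn{r = (1 - e^{-2d/100})/2} with `d` in centimorgans.
#' Distances are interpreted on the RIL (expansion-corrected) scale.
#'
#' @param d_cm Genetic distance in cM (vector).
#' @return Recombination fraction in [0, 0.5).
#' @export
haldane_rf <- function(d_cm) (1 - exp(-2 * d_cm / 100)) / 2

#' Simulation configuration
#'
#' Defaults emulate the mapping population and field design the pipeline
#' is aimed at: 119 recombinant inbred lines plus the two parents, fully
#' homozygous marker genotypes on 10 chromosomes, two density treatments
#' (UN/CR) across two growing seasons with randomized blocks, and 5-16
#' sequential leaf measurements per plant on a degree-day axis.
#'
#' @param n_ril Number of recombinant inbred lines (default 119).
#' @param n_chrom Number of chromosomes (default 10).
#' @param markers_per_chrom Evenly spaced markers per chromosome.
#' @param chrom_length_cm Chromosome map length in cM.
#' @param missing_rate Fraction of marker genotypes set to missing.
#' @param trait Measurement label (default `"LW"`, leaf width in mm).
#' @param pop_mean Named population-mean logistic parameters
#'   (`r` in 1/DD, `Lmax` and `L0` in mm).
#' @param n_qtl_per_trait QTL count per curve parameter (default 3).
#' @param qtl_effect_sizes Named list of per-locus additive effect
#'   magnitudes for `r` and `Lmax` (length `n_qtl_per_trait` each).  An
#'   effect is the difference between the two homozygote class means at
#'   the locus; lines deviate by half the effect either side of the
#'   population mean.
#' @param year_sd Named SDs of growing-season (year) main effects.
#' @param gxe_sd Named SDs of genotype-by-year deviations.
#' @param block_sd Named SDs of block effects on plant-level parameters.
#' @param plant_sd Named SDs of within-genotype plant deviations.
#' @param residual_sd Measurement noise SD in mm.
#' @param amax_mean,amax_sd Genotypic photosynthetic capacity
#'   (\eqn{A_{max}}, umol m-2 s-1) distribution.
#' @param amax_beta Named slopes of plant-level parameter means on the
#'   centered genotypic \eqn{A_{max}}.
#' @param years Growing seasons simulated.
#' @param treatments Density treatments (`UN` uncrowded, `CR` crowded).
#' @param blocks_per_env Blocks per treatment within each year (named by
#'   year; each block holds one replicate of every line).
#' @param points_range Minimum/maximum sequential measurements per plant.
#' @param seed RNG seed stored with the configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_ril = 119,
                       n_chrom = 10,
                       markers_per_chrom = 15,
                       chrom_length_cm = 100,
                       missing_rate = 0,
                       trait = "LW",
                       pop_mean = c(r = 0.012, Lmax = 40, L0 = 2),
                       n_qtl_per_trait = 3,
                       qtl_effect_sizes = list(
                         r = c(0.0012, 0.0009, 0.0006),
                         Lmax = c(2.5, 1.8, 1.2)),
                       year_sd = c(r = 0.0012, Lmax = 0.8, L0 = 0),
                       gxe_sd = c(r = 0.0008, Lmax = 0.8, L0 = 0),
                       block_sd = c(r = 0.0004, Lmax = 1.0, L0 = 0.1),
                       plant_sd = c(r = 0.0006, Lmax = 1.2, L0 = 0.2),
                       residual_sd = 1.5,
                       amax_mean = 25, amax_sd = 4,
                       amax_beta = c(r = 0, Lmax = 0.2, L0 = 0),
                       years = c(2011, 2012),
                       treatments = c("UN", "CR"),
                       blocks_per_env = c("2011" = 6, "2012" = 8),
                       points_range = c(5, 16),
                       seed = 1L) {
  if (n_ril < 2) stop("'n_ril' must be at least 2", call. = FALSE)
  if (markers_per_chrom < 1) stop("at least one marker per chromosome",
                                  call. = FALSE)
  sds <- c(year_sd, gxe_sd, block_sd, plant_sd, residual_sd)
  if (any(sds < 0)) stop("all SDs must be non-negative", call. = FALSE)
  if (points_range[1] < 5 || points_range[2] > 16 ||
      points_range[1] > points_range[2])
    stop("'points_range' must lie within [5, 16]", call. = FALSE)
  stopifnot(all(c("r", "Lmax", "L0") %in% names(pop_mean)))
  cfg <- list(n_ril = n_ril, n_chrom = n_chrom,
              markers_per_chrom = markers_per_chrom,
              chrom_length_cm = chrom_length_cm,
              missing_rate = missing_rate, trait = trait,
              pop_mean = pop_mean, n_qtl_per_trait = n_qtl_per_trait,
              qtl_effect_sizes = qtl_effect_sizes,
              year_sd = year_sd, gxe_sd = gxe_sd, block_sd = block_sd,
              plant_sd = plant_sd, residual_sd = residual_sd,
              amax_mean = amax_mean, amax_sd = amax_sd,
              amax_beta = amax_beta,
              years = years, treatments = treatments,
              blocks_per_env = blocks_per_env,
              points_range = points_range, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

sd_of <- function(v, p) if (p %in% names(v)) unname(v[[p]]) else 0

#' Simulate a genetic map and RIL marker genotypes
#'
#' Markers are evenly spaced along each chromosome; each fully homozygous
#' line is generated by a two-state Markov walk whose switch probability
#' between adjacent markers is the Haldane recombination fraction of
#' their distance.  Codes are `AA` (first parent, IMB211-like) and `BB`
#' (second parent, R500-like); an optional missingness rate blanks codes
#' at random.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return List with `map` (data.frame: marker, chrom, pos_cm) and
#'   `genotypes` (character matrix, lines x markers).
#' @export
simulate_map_genotypes <- function(config, seed = config$seed) {
  set.seed(seed)
  stopifnot(inherits(config, "sim_config"))
  pos <- seq(0, config$chrom_length_cm, length.out = config$markers_per_chrom)
  map <- do.call(rbind, lapply(seq_len(config$n_chrom), function(ch)
    data.frame(marker = sprintf("A%02d_m%02d", ch, seq_along(pos)),
               chrom = ch, pos_cm = pos)))
  rownames(map) <- NULL
  n <- config$n_ril
  rf <- haldane_rf(diff(pos))
  genos <- matrix(NA_character_, n, nrow(map),
                  dimnames = list(sprintf("RIL_%03d", seq_len(n)), map$marker))
  for (ch in seq_len(config$n_chrom)) {
    idx <- which(map$chrom == ch)
    state <- matrix(0L, n, length(idx))
    state[, 1] <- stats::rbinom(n, 1, 0.5)
    if (length(idx) > 1) for (j in 2:length(idx)) {
      switch_ <- stats::rbinom(n, 1, rf[j - 1])
      state[, j] <- (state[, j - 1] + switch_) %% 2L
    }
    genos[, idx] <- ifelse(state == 0L, "AA", "BB")
  }
  if (config$missing_rate > 0) {
    drop <- which(stats::runif(length(genos)) < config$missing_rate)
    genos[drop] <- NA_character_
  }
  list(map = map, genotypes = genos)
}

# Signed allele dosage: +1 for AA (IMB211-like), -1 for BB, NA for missing.
signed_dosage <- function(genotypes) {
  d <- matrix(NA_real_, nrow(genotypes), ncol(genotypes),
              dimnames = dimnames(genotypes))
  d[genotypes == "AA"] <- 1
  d[genotypes == "BB"] <- -1
  d
}

#' Simulate daily temperatures for one growing season
#'
#' Seasonal sinusoid plus day-to-day noise, returned as a data.frame
#' with `date`, `tmin_c`, `tmax_c` columns for a `n_days`-day season.
#'
#' @param n_days Season length in days.
#' @param seed RNG seed.
#' @return data.frame with daily `tmin_c` and `tmax_c`.
#' @export
simulate_temperatures <- function(n_days = 90, seed = 1L) {
  set.seed(seed)
  day <- seq_len(n_days)
  mean_t <- 14 + 6 * sin(pi * day / n_days) + stats::rnorm(n_days, 0, 1.5)
  range_t <- stats::runif(n_days, 8, 14)
  data.frame(date = day, tmin_c = mean_t - range_t / 2,
             tmax_c = mean_t + range_t / 2)
}

#' Simulate longitudinal leaf measurements with known truth
#'
#' Builds genotype-by-environment logistic growth parameters from an
#' additive QTL architecture (per-genotype value = population mean +
#' year effect + sum of signed QTL effects + genotype-by-year deviation),
#' adds block and plant-level deviations plus an \eqn{A_{max}} covariate
#' contribution at the plant level, and emits noisy logistic measurements
#' at a 2-3 visits/week schedule converted to degree days (5-16 points
#' per plant).
#'
#' @param mapgen Output of [simulate_map_genotypes()].
#' @param config A [sim_config()].
#' @param seed RNG seed (defaults to `config$seed + 1`).
#' @return List with `phenotypes` (long data.frame: plant_id, genotype,
#'   treatment, year, block, t_dd, value, trait), `amax` (per-genotype
#'   covariate table), and `truth` (QTL table, per genotype-by-year
#'   parameters, plant parameters, and the generating config).
#' @export
simulate_phenotypes <- function(mapgen, config, seed = config$seed + 1L) {
  set.seed(seed)
  stopifnot(inherits(config, "sim_config"))
  map <- mapgen$map; genos <- mapgen$genotypes
  n <- nrow(genos)
  lines <- rownames(genos)
  dos <- signed_dosage(genos)
  dos[is.na(dos)] <- 0   # missing marker contributes no QTL effect

  # --- QTL architecture ------------------------------------------------
  qtl <- NULL
  for (param in c("r", "Lmax")) {
    eff <- config$qtl_effect_sizes[[param]]
    k <- min(config$n_qtl_per_trait, length(eff), nrow(map))
    if (k > 0) {
      # spread loci over distinct chromosomes where possible
      chroms <- sample(unique(map$chrom), min(k, config$n_chrom))
      picks <- vapply(seq_len(k), function(j) {
        ch <- chroms[((j - 1) %% length(chroms)) + 1]
        sample(which(map$chrom == ch), 1)
      }, integer(1))
      qtl <- rbind(qtl, data.frame(
        param = param, marker = map$marker[picks],
        chrom = map$chrom[picks], pos_cm = map$pos_cm[picks],
        effect = eff[seq_len(k)],
        direction = sample(c(-1, 1), k, replace = TRUE)))
    }
  }

  # --- genotype-level parameters --------------------------------------
  amax <- data.frame(genotype = c(lines, "IMB211", "R500"),
                     amax = stats::rnorm(n + 2, config$amax_mean,
                                         config$amax_sd))
  amax_c <- amax$amax - mean(amax$amax)
  names(amax_c) <- amax$genotype

  # parents carry fixed allele dosages (+1 / -1 at every locus)
  all_lines <- c(lines, "IMB211", "R500")
  dos_at <- function(marker) {
    c(dos[, marker], IMB211 = 1, R500 = -1)
  }
  geno_value <- function(param) {
    base <- rep(unname(config$pop_mean[[param]]), n + 2)
    qp <- qtl[qtl$param == param, , drop = FALSE]
    # 'effect' is the difference between homozygote class means, so each
    # line deviates by +/- effect/2 around the population mean
    if (!is.null(qtl) && nrow(qp)) for (j in seq_len(nrow(qp)))
      base <- base + qp$direction[j] * qp$effect[j] * dos_at(qp$marker[j]) / 2
    base
  }

  env_grid <- expand.grid(year = config$years, treatment = config$treatments,
                          stringsAsFactors = FALSE)
  geno_params <- NULL
  year_eff <- lapply(c("r", "Lmax", "L0"), function(p)
    stats::setNames(stats::rnorm(length(config$years), 0,
                                 sd_of(config$year_sd, p)),
                    as.character(config$years)))
  names(year_eff) <- c("r", "Lmax", "L0")
  gxe <- lapply(c("r", "Lmax", "L0"), function(p)
    matrix(stats::rnorm((n + 2) * length(config$years), 0,
                        sd_of(config$gxe_sd, p)),
           n + 2, length(config$years),
           dimnames = list(all_lines, as.character(config$years))))
  names(gxe) <- c("r", "Lmax", "L0")

  base_r <- geno_value("r"); base_L <- geno_value("Lmax")
  for (y in as.character(config$years)) {
    geno_params <- rbind(geno_params, data.frame(
      genotype = all_lines, year = as.integer(y),
      r = pmax(base_r + year_eff$r[y] + gxe$r[, y], 1e-4),
      Lmax = pmax(base_L + year_eff$Lmax[y] + gxe$Lmax[, y],
                  config$pop_mean[["L0"]] + 1),
      L0 = rep(unname(config$pop_mean[["L0"]]), n + 2)))
  }

  # --- thermal-time visit schedules per environment --------------------
  season <- lapply(as.character(config$years), function(y)
    simulate_temperatures(90, seed = seed + as.integer(y) %% 1000))
  names(season) <- as.character(config$years)
  visit_dd <- lapply(season, function(tt) {
    cum <- accumulate_degree_days(tt$tmin_c, tt$tmax_c)$cumulative_dd
    days <- sort(unique(pmin(90, cumsum(sample(2:4, 30, replace = TRUE)))))
    germ <- cum[5]                  # germination ~ day 5
    dd <- cum[days] - germ
    dd[dd > 0]
  })

  # --- plant-level parameters and observations ------------------------
  rows <- list(); plants <- list(); pid <- 0L
  for (e in seq_len(nrow(env_grid))) {
    y <- as.character(env_grid$year[e]); trt <- env_grid$treatment[e]
    nb <- unname(config$blocks_per_env[y])
    if (is.na(nb)) nb <- 4
    gp <- geno_params[geno_params$year == as.integer(y), ]
    rownames(gp) <- gp$genotype
    for (b in seq_len(nb)) {
      block_id <- sprintf("%s_%s_B%02d", y, trt, b)
      beff <- vapply(c("r", "Lmax", "L0"), function(p)
        stats::rnorm(1, 0, sd_of(config$block_sd, p)), numeric(1))
      for (g in all_lines) {
        pid <- pid + 1L
        pr <- max(gp[g, "r"] + beff["r"] +
                    stats::rnorm(1, 0, sd_of(config$plant_sd, "r")) +
                    config$amax_beta[["r"]] * amax_c[g], 1e-4)
        pL <- max(gp[g, "Lmax"] + beff["Lmax"] +
                    stats::rnorm(1, 0, sd_of(config$plant_sd, "Lmax")) +
                    config$amax_beta[["Lmax"]] * amax_c[g],
                  gp[g, "L0"] + 0.5)
        p0 <- max(gp[g, "L0"] + beff["L0"] +
                    stats::rnorm(1, 0, sd_of(config$plant_sd, "L0")) +
                    config$amax_beta[["L0"]] * amax_c[g], 0.2)
        k <- sample(seq(config$points_range[1], config$points_range[2]), 1)
        dd <- visit_dd[[y]]
        # each plant is scored at a per-plant subset of the season's
        # visits, spread over the whole growth period
        tsel <- sort(sample(dd, min(k, length(dd))))
        val <- pmax(logistic_size_vec(pr, pL, p0, tsel) +
                      stats::rnorm(length(tsel), 0, config$residual_sd),
                    0.1)   # sizes are physical measurements, floored > 0
        plant_id <- sprintf("P%05d", pid)
        plants[[pid]] <- data.frame(plant_id = plant_id, genotype = g,
                                    year = as.integer(y), treatment = trt,
                                    block = block_id,
                                    r = pr, Lmax = pL, L0 = p0)
        rows[[pid]] <- data.frame(plant_id = plant_id, genotype = g,
                                  treatment = trt, year = as.integer(y),
                                  block = block_id, t_dd = tsel,
                                  value = val, trait = config$trait)
      }
    }
  }
  phen <- do.call(rbind, rows); rownames(phen) <- NULL
  plant_params <- do.call(rbind, plants); rownames(plant_params) <- NULL

  list(phenotypes = phen, amax = amax,
       truth = list(qtl = qtl, geno_params = geno_params,
                    plant_params = plant_params,
                    year_effects = year_eff, config = config,
                    seasons = season))
}

#' Simulate plant reflectance spectra
#'
#' Vegetation-like smooth baseline (green peak, red edge, NIR plateau,
#' water-absorption dips) with a genotype-linked red-edge feature, sampled
#' on the instrument's native grid (1.4 nm up to 1000 nm, 2 nm beyond),
#' interpolated to a 1-nm grid over 350-2500 nm (2151 points), with the
#' mean of `n_sweeps` noisy sweeps per plant.
#'
#' @param n_plants Number of plants.
#' @param geno_effect Per-plant scalar shifting the red-edge feature
#'   (length `n_plants`, default 0).
#' @param noise_sd Per-sweep reflectance noise SD.
#' @param n_sweeps Replicate sweeps averaged per plant (default 10).
#' @param baseline Optional function of wavelength giving the noise-free
#'   baseline reflectance; default is the built-in vegetation shape.
#' @param seed RNG seed.
#' @return List with `wavelength` (350:2500) and `reflectance`
#'   (matrix, plants x wavelengths).
#' @export
simulate_spectra <- function(n_plants, geno_effect = rep(0, n_plants),
                             noise_sd = 0.01, n_sweeps = 10,
                             baseline = NULL, seed = 1L) {
  set.seed(seed)
  native <- c(seq(350, 1000, by = 1.4), seq(1002, 2500, by = 2))
  grid <- 350:2500
  if (is.null(baseline)) {
    baseline <- function(wl, shift = 0) {
      0.05 +
        0.08 * exp(-((wl - 550) / 40)^2) +                  # green peak
        0.42 / (1 + exp(-(wl - (715 + shift)) / 18)) *      # red edge -> NIR
          exp(-pmax(wl - 1100, 0) / 1800) -
        0.12 * exp(-((wl - 1450) / 60)^2) -                 # water bands
        0.18 * exp(-((wl - 1940) / 80)^2)
    }
  }
  refl <- matrix(NA_real_, n_plants, length(grid),
                 dimnames = list(NULL, grid))
  for (i in seq_len(n_plants)) {
    clean <- baseline(native, geno_effect[i])
    sweeps <- matrix(stats::rnorm(length(native) * n_sweeps, clean, noise_sd),
                     length(native), n_sweeps)
    avg <- rowMeans(sweeps)
    refl[i, ] <- stats::approx(native, avg, xout = grid, rule = 2)$y
  }
  list(wavelength = grid, reflectance = refl)
}

#' Write simulated data as CSV files
#'
#' Writes the genotype matrix (lines x markers, codes AA/BB/NA), the map,
#' the long phenotype table, per-season temperatures, and the
#' \eqn{A_{max}} covariate table into a directory.
#'
#' @param mapgen Output of [simulate_map_genotypes()].
#' @param sim Output of [simulate_phenotypes()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_sim_csvs <- function(mapgen, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(map = file.path(dir, "map.csv"),
             genotypes = file.path(dir, "genotypes.csv"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             amax = file.path(dir, "amax.csv"))
  utils::write.csv(mapgen$map, paths["map"], row.names = FALSE)
  gdf <- data.frame(line = rownames(mapgen$genotypes), mapgen$genotypes,
                    check.names = FALSE)
  utils::write.csv(gdf, paths["genotypes"], row.names = FALSE)
  utils::write.csv(sim$phenotypes, paths["phenotypes"], row.names = FALSE)
  utils::write.csv(sim$amax, paths["amax"], row.names = FALSE)
  for (y in names(sim$truth$seasons)) {
    p <- file.path(dir, sprintf("temperature_%s.csv", y))
    utils::write.csv(sim$truth$seasons[[y]], p, row.names = FALSE)
    paths[paste0("temperature_", y)] <- p
  }
  invisible(paths)
}
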