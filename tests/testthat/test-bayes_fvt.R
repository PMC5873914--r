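# Hierarchical Bayesian FVT fitting: bookkeeping, parameter recovery,
# shrinkage, envelopes, diagnostics.

test_that("retained sample count follows the iteration/burn-in/thin arithmetic", {
  expect_identical(retained_sample_count(mcmc_config(500000, 440000, 20)),
                   3000L)
  expect_identical(retained_sample_count(mcmc_config(100, 0, 1)), 100L)
  expect_identical(retained_sample_count(mcmc_config(1000, 500, 10)), 50L)
  expect_error(mcmc_config(100, 100, 1), "burn_in")
  expect_identical(retained_sample_count(mcmc_preset("paper")), 3000L)
  # every stored chain has exactly the retained length
  d <- one_genotype_data(n_plants = 3, n_points = 6, seed = 2)
  fit <- fit_hierarchical(d, config = mcmc_config(600, 200, 4, seed = 1))
  expect_identical(fit$n_retained, 100L)
  expect_identical(nrow(fit$samples$mu0), 100L)
  expect_identical(length(fit$samples$sigma), 100L)
  expect_identical(dim(fit$samples$mu_g)[1], 100L)
})

test_that("single-genotype posterior recovers injected parameters within 5%", {
  d <- one_genotype_data(r = 0.08, Lmax = 60, L0 = 3, n_plants = 8,
                         n_points = 12, noise_sd = 0.1, seed = 1)
  fit <- fit_hierarchical(d, config = mcmc_preset("test"))
  s <- posterior_summary(fit)
  est <- setNames(s$mean, s$param)
  expect_lt(abs(est["r"] - 0.08) / 0.08, 0.05)
  expect_lt(abs(est["Lmax"] - 60) / 60, 0.05)
  expect_lt(abs(est["L0"] - 3) / 3, 0.10)
  expect_false(fit$diverged)
  # derived traits agree with the growth-model transforms at the means
  p <- logistic_params(est[["r"]], est[["Lmax"]], est[["L0"]])
  expect_equal(unname(est["iD"]), inflection_time(p), tolerance = 0.05)
  expect_equal(unname(est["d"]), duration_to_fraction(p, 0.95),
               tolerance = 0.05)
})

test_that("null A_max covariate slope concentrates near zero", {
  set.seed(4)
  d <- do.call(rbind, lapply(1:6, function(g)
    transform(one_genotype_data(r = 0.07, Lmax = 50 + 3 * (g %% 3), L0 = 2,
                                n_plants = 3, n_points = 8, noise_sd = 0.5,
                                seed = 100 + g),
              genotype = paste0("G", g),
              plant_id = sprintf("G%d_%s", g, plant_id))))
  am <- setNames(rnorm(6, 25, 4), paste0("G", 1:6))  # unrelated to traits
  fit <- fit_hierarchical(d, amax = am, config = mcmc_preset("test"))
  beta_lmax <- fit$samples$beta[, 2]
  expect_lt(abs(mean(beta_lmax)), 0.05)   # log-scale slope ~ 0
  expect_true(stats::sd(beta_lmax) > 0)   # actually sampled
})

test_that("genotypes with identical data get statistically indistinguishable posteriors", {
  base <- one_genotype_data(r = 0.06, Lmax = 45, L0 = 2.5, n_plants = 4,
                            n_points = 10, noise_sd = 0.4, seed = 6)
  d <- rbind(transform(base, genotype = "GA",
                       plant_id = paste0("A", plant_id)),
             transform(base, genotype = "GB",
                       plant_id = paste0("B", plant_id)))
  fit <- fit_hierarchical(d, config = mcmc_preset("test"))
  s <- posterior_summary(fit)
  for (p in c("r", "Lmax")) {
    a <- s[s$genotype == "GA" & s$param == p, ]
    b <- s[s$genotype == "GB" & s$param == p, ]
    expect_lt(max(a$q025, b$q025), min(a$q975, b$q975))  # intervals overlap
    expect_lt(abs(a$mean - b$mean) / a$mean, 0.05)
  }
})

test_that("data-poor genotypes shrink further toward the global mean", {
  set.seed(7)
  mk <- function(g, n_plants, Lmax, seed)
    transform(one_genotype_data(r = 0.07, Lmax = Lmax, L0 = 2,
                                n_plants = n_plants, n_points = 10,
                                noise_sd = 0.8, seed = seed),
              genotype = g, plant_id = paste0(g, "_", plant_id))
  d <- rbind(do.call(rbind, lapply(1:6, function(i)
    mk(paste0("BG", i), 4, 50, 200 + i))),
    mk("POOR", 1, 70, 300), mk("RICH", 8, 70, 301))
  fit <- fit_hierarchical(d, config = mcmc_preset("test"))
  mu0_lmax <- mean(fit$samples$mu0[, 2])
  poor <- mean(fit$samples$mu_g[, "POOR", 2])
  rich <- mean(fit$samples$mu_g[, "RICH", 2])
  expect_lt(abs(poor - mu0_lmax), abs(rich - mu0_lmax))
})

test_that("credible envelopes nest and collapse for degenerate posteriors", {
  d <- one_genotype_data(n_plants = 4, n_points = 8, seed = 8)
  fit <- fit_hierarchical(d, config = mcmc_config(2000, 1000, 2, seed = 2))
  grid <- seq(0, 120, by = 5)
  env <- credible_envelopes(fit, "G1", grid)
  expect_true(all(env$outer_lo <= env$inner_lo))   # outer contains inner
  expect_true(all(env$outer_hi >= env$inner_hi))
  expect_true(all(env$inner_lo <= env$inner_hi))
  expect_error(credible_envelopes(fit, "NOPE", grid), "genotype")

  # degenerate: identical draws and zero residual SD -> zero-width bands
  degen <- fit
  for (s in seq_len(degen$n_retained)) degen$samples$mu_g[s, 1, ] <-
    degen$samples$mu_g[1, 1, ]
  degen$samples$sigma[] <- 0
  env0 <- credible_envelopes(degen, "G1", grid)
  expect_equal(env0$inner_lo, env0$inner_hi, tolerance = 1e-12)
  expect_equal(env0$outer_lo, env0$outer_hi, tolerance = 1e-12)
})

test_that("chain diagnostics recover constructed autocorrelation structure", {
  set.seed(9)
  iid <- rnorm(4000)
  ar1 <- as.numeric(arima.sim(list(ar = 0.9), 4000))
  const <- rep(2.5, 4000)
  diag_tab <- chain_diagnostics(cbind(iid = iid, ar1 = ar1, const = const))
  expect_lt(abs(diag_tab$lag1[diag_tab$param == "iid"]), 0.06)
  expect_equal(diag_tab$lag1[diag_tab$param == "ar1"], 0.9, tolerance = 0.05)
  expect_identical(diag_tab$flag[diag_tab$param == "const"], "degenerate")
  expect_gt(diag_tab$ess[diag_tab$param == "iid"],
            diag_tab$ess[diag_tab$param == "ar1"])
})

test_that("convergence report summarizes a fitted chain and input is validated", {
  d <- one_genotype_data(n_plants = 3, n_points = 6, seed = 10)
  fit <- fit_hierarchical(d, config = mcmc_config(1500, 500, 2, seed = 3))
  rep_ <- convergence_report(fit)
  expect_true(all(c("mu0_logLmax", "sigma") %in% rep_$diagnostics$param))
  expect_type(rep_$flags, "character")

  bad <- d; bad$value[1] <- -1
  expect_error(fit_hierarchical(bad), "positive")
  one_pt <- d[!duplicated(d$plant_id), ]
  expect_error(fit_hierarchical(one_pt), "2 measurements")
})
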