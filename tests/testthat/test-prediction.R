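# Additive QTL prediction of FVT parameters, envelope scoring,
# leave-k-out evaluation and the proportion Z statistic.

test_that("additive prediction equation: mean plus direction x effect", {
  expect_equal(predict_parameter(30, data.frame(direction = numeric(0),
                                                effect = numeric(0))), 30)
  loci <- data.frame(direction = c(1, -1), effect = c(2.5, 1.0))
  expect_equal(predict_parameter(30, loci), 31.5)
  flipped <- transform(loci, direction = -direction)
  expect_equal(predict_parameter(30, flipped) - 30,
               -(predict_parameter(30, loci) - 30))   # reflection symmetry
  expect_error(predict_parameter(30, data.frame(direction = 2, effect = 1)),
               "direction")
})

test_that("predicted growth curves are consistent with the growth model", {
  grid <- seq(0, 150, by = 5)
  got <- predict_growth_curve(0.08, 60, 3, grid)
  expect_true(got$ok)
  expect_equal(got$curve,
               logistic_size(logistic_params(0.08, 60, 3), grid))
  iD <- inflection_time(logistic_params(0.08, 60, 3))
  at_iD <- predict_growth_curve(0.08, 60, 3, iD)
  expect_equal(at_iD$curve, 30, tolerance = 1e-10)     # Lmax / 2
  # invalid predictions are flagged failures, not errors
  expect_false(predict_growth_curve(-0.01, 60, 3, grid)$ok)
  expect_false(predict_growth_curve(0.08, 2, 3, grid)$ok)
})

make_envelope <- function(base, half_inner = 1, half_outer = 2,
                          grid = seq(0, 100, by = 4)) {
  f <- logistic_size_vec(base[1], base[2], base[3], grid)
  structure(data.frame(t_dd = grid,
                       inner_lo = f - half_inner, inner_hi = f + half_inner,
                       outer_lo = f - half_outer, outer_hi = f + half_outer),
            class = c("credible_envelope", "data.frame"))
}

test_that("envelope verdicts distinguish success, marginal and fail", {
  base <- c(r = 0.08, Lmax = 60, L0 = 3)
  env <- make_envelope(base)
  grid <- env$t_dd
  on_mean <- predict_growth_curve(0.08, 60, 3, grid)
  expect_identical(envelope_verdict(on_mean, env)$overall, "success")
  shifted_up <- list(ok = TRUE, curve = on_mean$curve + 5)
  expect_identical(envelope_verdict(shifted_up, env)$overall, "fail")
  # inside outer but poking outside inner at one point
  poke <- on_mean$curve; poke[10] <- poke[10] + 1.5
  expect_identical(envelope_verdict(list(ok = TRUE, curve = poke),
                                    env)$overall, "marginal")
  # cross-environment mode uses the outer band only
  expect_identical(envelope_verdict(list(ok = TRUE, curve = poke), env,
                                    mode = "cross")$overall, "success")
  expect_identical(envelope_verdict(list(ok = FALSE,
                                         curve = rep(NA_real_, length(grid))),
                                    env)$overall, "fail")
})

test_that("containment failures are attributed to the right parameter by phase", {
  base <- c(r = 0.08, Lmax = 60, L0 = 3)
  env <- make_envelope(base)
  grid <- env$t_dd
  d95 <- duration_to_fraction(logistic_params(0.08, 60, 3), 0.95)
  iD <- inflection_time(logistic_params(0.08, 60, 3))
  # wrong asymptote: fails only after the predicted 95% duration
  f <- logistic_size_vec(0.08, 60, 3, grid)
  late_off <- f; late_off[grid > d95] <- late_off[grid > d95] + 3
  v <- envelope_verdict(list(ok = TRUE, curve = late_off), env,
                        r = 0.08, Lmax = 60, L0 = 3)
  expect_identical(v$Lmax, "fail")
  expect_identical(v$r, "success")
  # wrong rate: fails only before the predicted inflection
  early_off <- f; early_off[grid <= iD & grid > 0] <-
    early_off[grid <= iD & grid > 0] + 3
  v2 <- envelope_verdict(list(ok = TRUE, curve = early_off), env,
                         r = 0.08, Lmax = 60, L0 = 3)
  expect_identical(v2$r, "fail")
  expect_identical(v2$Lmax, "success")
  # failures in both phases count against both parameters
  both_off <- f + 3
  v3 <- envelope_verdict(list(ok = TRUE, curve = both_off), env,
                         r = 0.08, Lmax = 60, L0 = 3)
  expect_identical(v3$r, "fail")
  expect_identical(v3$Lmax, "fail")
})

test_that("grid mismatch interpolates with a warning", {
  env <- make_envelope(c(0.08, 60, 3))
  fine <- seq(0, 120, by = 3)    # extends beyond the envelope grid
  curve <- predict_growth_curve(0.08, 60, 3, fine)
  expect_warning(v <- envelope_verdict(curve, env, grid = fine), "beyond")
  expect_identical(v$overall, "success")
})

test_that("proportion Z statistic matches its formula", {
  expect_equal(proportion_z(10, 20)$z, 0)
  got <- proportion_z(17.4, 20)     # p_hat = 0.87
  expect_equal(got$z, 3.31, tolerance = 0.005)
  expect_equal(proportion_z(20, 20)$z, 4.47, tolerance = 0.005)
  expect_equal(proportion_z(20, 20)$p_value,
               pnorm(4.4721, lower.tail = FALSE), tolerance = 1e-4)
  expect_error(proportion_z(5, 0), "'n'")
  expect_error(proportion_z(21, 20), "successes")
})

test_that("leave-k-out rounds are reproducible and never train on held-out genotypes", {
  cfg <- small_config(n_ril = 18, n_chrom = 2, markers_per_chrom = 5,
                      chrom_length_cm = 40, blocks_per_env = c("2012" = 2),
                      points_range = c(6, 8),
                      qtl_effect_sizes = list(r = numeric(0), Lmax = numeric(0)),
                      n_qtl_per_trait = 0, residual_sd = 0.8, seed = 55)
  mg <- simulate_map_genotypes(cfg)
  sim <- simulate_phenotypes(mg, cfg)
  tiny <- mcmc_config(800, 400, 4)
  run <- function() leave_k_out_evaluate(
    sim$phenotypes, mg$map, mg$genotypes, k = 3, rounds = 2,
    n_perm = 100, train_config = tiny, holdout_config = tiny, seed = 99)
  a <- run(); b <- run()
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$training_log, b$training_log)
  expect_false(any(a$training_log$in_training))   # audit: no leakage
  # null architecture: no QTL pass, predictions collapse to the mean
  expect_true(all(a$predictions$pred_Lmax ==
                    ave(a$predictions$pred_Lmax, a$predictions$round)))
})
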