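# Genotype-to-phenotype prediction: FVT parameters for held-out genotypes
# from additive QTL effects (population mean plus the sum of direction x
# effect over the genotype's alleles), whole-curve prediction, scoring
# against Bayesian credible envelopes, and the leave-k-out resampling
# evaluation with proportion Z tests.

#' Predict a trait parameter from additive QTL effects
#'
#' `prediction = population_mean + sum(direction_j * effect_j)` over the
#' genotype's loci, where each direction is +1 or -1 according to which
#' allele the genotype carries and the sign of the locus effect.
#'
#' @param population_mean Population mean of the parameter.
#' @param loci data.frame with columns `direction` (+1/-1) and `effect`
#'   (non-negative additive effect); zero rows give the null model.
#' @return Predicted parameter value.
#' @export
predict_parameter <- function(population_mean, loci) {
  if (!nrow(loci)) return(population_mean)
  if (!all(loci$direction %in% c(-1, 1)))
    stop("directions must be +1 or -1", call. = FALSE)
  population_mean + sum(loci$direction * loci$effect)
}

#' Per-genotype QTL predictions from a fitted model
#'
#' For every requested line, combines the line's expected signed allele
#' dosage at each model locus with the locus effect and direction to
#' predict the trait parameter.  Loci where the line carries no genotype
#' information (expected dosage 0) contribute nothing.
#'
#' @param model A `qtl_model` from [stepwise_qtl_search()].
#' @param probs The `geno_probs` object used for mapping.
#' @param lines Character vector of line names to predict.
#' @return data.frame: `genotype`, `predicted`, `n_loci_used`.
#' @export
predict_from_model <- function(model, probs, lines) {
  mu <- attr(model, "mean")
  D <- expected_dosage(probs)
  pos_key <- paste0("c", model$chrom, "_", model$pos_cm)
  out <- lapply(lines, function(ln) {
    if (!ln %in% rownames(D))
      return(data.frame(genotype = ln, predicted = NA_real_,
                        n_loci_used = 0L))
    if (!nrow(model))
      return(data.frame(genotype = ln, predicted = mu, n_loci_used = 0L))
    s <- D[ln, pos_key]
    loci <- data.frame(direction = model$direction * sign(s),
                       effect = model$effect * abs(s))
    loci <- loci[loci$direction != 0, , drop = FALSE]
    data.frame(genotype = ln,
               predicted = predict_parameter(mu, loci),
               n_loci_used = nrow(loci))
  })
  do.call(rbind, out)
}

#' Predicted growth curve from QTL-predicted parameters
#'
#' Evaluates the logistic curve with the predicted growth rate and final
#' size plus the supplied `L0` constant.  Invalid predictions
#' (non-positive `r` or `Lmax`, or `Lmax <= L0`) are flagged failed
#' rather than raising an error: a prediction that is biologically
#' impossible counts as unsuccessful.
#'
#' @param r,Lmax Predicted parameters.
#' @param L0 Initial-size constant (population-level).
#' @param grid Degree-day evaluation grid.
#' @return List with `ok` (logical) and `curve` (numeric, NA when not
#'   `ok`).
#' @export
predict_growth_curve <- function(r, Lmax, L0, grid) {
  if (!is.finite(r) || !is.finite(Lmax) || r <= 0 || Lmax <= L0 || L0 <= 0)
    return(list(ok = FALSE, curve = rep(NA_real_, length(grid))))
  list(ok = TRUE, curve = logistic_size_vec(r, Lmax, L0, grid))
}

# classify grid times into early / middle / late growth phases relative
# to the predicted curve's inflection (iD) and 95% duration (d)
phase_of <- function(grid, r, Lmax, L0) {
  p <- logistic_params(r, Lmax, L0)
  iD <- inflection_time(p)
  d <- duration_to_fraction(p, 0.95)
  ifelse(grid <= iD, "early", ifelse(grid > d, "late", "middle"))
}

#' Score a predicted curve against credible envelopes
#'
#' Within-environment mode: `"success"` when the curve lies inside the
#' inner (genotype-mean) band at every grid point, `"marginal"` when it
#' stays inside the outer (posterior-predictive) band, `"fail"`
#' otherwise.  Cross-environment mode uses only the outer band
#' (success/fail).  Per-parameter verdicts attribute containment
#' failures to the growth rate when they occur only in the early phase
#' (before the predicted inflection), to the final size when only in the
#' late phase (after the predicted 95% duration), and to both otherwise.
#'
#' @param curve Predicted curve (list from [predict_growth_curve()] or a
#'   numeric vector on the envelope grid).
#' @param envelope A `credible_envelope` whose grid covers the curve's;
#'   mismatched grids are linearly interpolated with a warning.
#' @param grid Grid of the predicted curve (defaults to the envelope's).
#' @param mode `"within"` or `"cross"`.
#' @param r,Lmax,L0 Predicted parameters for phase attribution; when
#'   omitted, both parameters share the overall verdict.
#' @return List with `overall` verdict and per-parameter verdicts `r`
#'   and `Lmax`.
#' @export
envelope_verdict <- function(curve, envelope, grid = envelope$t_dd,
                             mode = c("within", "cross"),
                             r = NULL, Lmax = NULL, L0 = NULL) {
  mode <- match.arg(mode)
  if (is.list(curve)) {
    if (!curve$ok)
      return(list(overall = "fail", r = "fail", Lmax = "fail"))
    curve <- curve$curve
  }
  env <- envelope
  if (!isTRUE(all.equal(grid, envelope$t_dd))) {
    if (min(grid) < min(envelope$t_dd) || max(grid) > max(envelope$t_dd))
      warning("curve grid extends beyond the envelope; interpolating with ",
              "boundary extension")
    env <- data.frame(t_dd = grid)
    for (b in c("inner_lo", "inner_hi", "outer_lo", "outer_hi"))
      env[[b]] <- stats::approx(envelope$t_dd, envelope[[b]], xout = grid,
                                rule = 2)$y
  }
  in_inner <- curve >= env$inner_lo & curve <= env$inner_hi
  in_outer <- curve >= env$outer_lo & curve <= env$outer_hi
  overall <- if (mode == "cross") {
    if (all(in_outer)) "success" else "fail"
  } else if (all(in_inner)) "success" else if (all(in_outer)) "marginal"
    else "fail"

  if (is.null(r) || is.null(Lmax) || is.null(L0))
    return(list(overall = overall, r = overall, Lmax = overall))

  phase <- phase_of(grid, r, Lmax, L0)
  verdict_for <- function(fails) {
    implicate <- function(bad) {
      if (!any(bad)) return(c(r = FALSE, Lmax = FALSE))
      ph <- unique(phase[bad])
      only_early <- all(ph == "early"); only_late <- all(ph == "late")
      c(r = !only_late, Lmax = !only_early)
    }
    implicate(fails)
  }
  imp_inner <- verdict_for(!in_inner)
  imp_outer <- if (mode == "cross") imp_inner else verdict_for(!in_outer)
  per_param <- function(p) {
    if (mode == "cross") {
      if (!imp_outer[[p]]) "success" else "fail"
    } else if (!imp_inner[[p]]) "success"
      else if (!imp_outer[[p]]) "marginal" else "fail"
  }
  list(overall = overall, r = per_param("r"), Lmax = per_param("Lmax"))
}

#' Proportion Z test against chance
#'
#' `Z = (p_hat - p0) / sqrt(p0 (1 - p0) / n)` with a one-sided
#' upper-tail normal p-value; the chance level defaults to 0.5.
#'
#' @param successes Success count.
#' @param n Number of scored predictions (>= 1).
#' @param p0 Null proportion (default 0.5).
#' @return List with `p_hat`, `z`, `p_value`.
#' @export
proportion_z <- function(successes, n, p0 = 0.5) {
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  if (successes < 0 || successes > n)
    stop("'successes' must lie in [0, n]", call. = FALSE)
  p_hat <- successes / n
  z <- (p_hat - p0) / sqrt(p0 * (1 - p0) / n)
  list(p_hat = p_hat, z = z,
       p_value = stats::pnorm(z, lower.tail = FALSE))
}

#' Leave-k-out genotype-to-phenotype prediction assessment
#'
#' Repeats, `rounds` times: exclude `k` mapped genotypes at random;
#' refit the hierarchical Bayesian FVT model, shrinkage genotype means
#' and the multi-QTL model (at the relaxed `alpha_map` permutation
#' threshold) on the remaining genotypes only; predict the excluded
#' genotypes' growth rate and final size from the additive QTL effects;
#' and score each predicted growth curve against credible envelopes
#' fitted to the held-out genotypes' own observed plants.  Predictions
#' use genotype data only -- no phenotype of a held-out genotype enters
#' model building (the training genotype set is logged per round so this
#' can be audited).
#'
#' @param phenotypes Long measurement table (one trait / treatment /
#'   season): `plant_id`, `genotype`, `block`, `t_dd`, `value`.
#' @param map Genetic map data.frame.
#' @param genotypes Marker genotype matrix (lines x markers); lines
#'   absent from it (e.g. parents) are never selected for exclusion.
#' @param k Genotypes excluded per round (default 5).
#' @param rounds Resampling rounds (default 20).
#' @param alpha_map Permutation quantile for QTL detection (default
#'   0.90).
#' @param n_perm Permutations per round.
#' @param train_config,holdout_config [mcmc_config()]s for the training
#'   fit and the held-out envelope fit.
#' @param step,error_rate Interval-mapping grid step and genotyping
#'   error rate.
#' @param seed Seed controlling round membership and all refits.
#' @return A `prediction_assessment`: `predictions` (per round x
#'   genotype), `proportions`, `z_tests`, `correlations`, and
#'   `training_log`.
#' @export
leave_k_out_evaluate <- function(phenotypes, map, genotypes, k = 5,
                                 rounds = 20, alpha_map = 0.90,
                                 n_perm = 200,
                                 train_config = mcmc_config(6000, 3000, 3),
                                 holdout_config = mcmc_config(6000, 3000, 3),
                                 step = 2, error_rate = 0.001, seed = 1L) {
  eligible <- intersect(unique(phenotypes$genotype), rownames(genotypes))
  if (length(eligible) < k + 10)
    stop("need at least k + 10 mappable genotypes", call. = FALSE)
  probs <- genotype_probabilities(map, genotypes, step = step,
                                  error_rate = error_rate)
  set.seed(seed)
  round_seeds <- sample.int(1e6, rounds)
  preds <- list(); logs <- list()
  for (rd in seq_len(rounds)) {
    set.seed(round_seeds[rd])
    held <- sample(eligible, k)
    train <- phenotypes[!phenotypes$genotype %in% held, , drop = FALSE]
    test <- phenotypes[phenotypes$genotype %in% held, , drop = FALSE]
    logs[[rd]] <- data.frame(round = rd, genotype = held,
                             in_training = held %in% train$genotype)

    cfg_t <- train_config; cfg_t$seed <- round_seeds[rd] + 1L
    fit_train <- fit_hierarchical(train, config = cfg_t)

    # shrinkage genotype means of the plant-level parameter estimates
    pm <- fit_train$plant_means
    blocks <- phenotypes$block[match(rownames(pm), phenotypes$plant_id)]
    geno_of <- fit_train$plant_genotype[rownames(pm)]
    mean_of <- function(param) {
      d <- data.frame(genotype = geno_of, block = blocks,
                      value = pm[, param])
      est <- estimate_genotype_means(d)
      stats::setNames(est$means$shrunken_mean, est$means$genotype)
    }
    models <- list(); predicted <- list()
    for (param in c("r", "Lmax")) {
      ym <- mean_of(param)
      ym <- ym[names(ym) %in% rownames(genotypes)]
      thr <- permutation_threshold(probs, ym, n_perm = n_perm,
                                   quantile = alpha_map,
                                   seed = round_seeds[rd] + 2L)
      models[[param]] <- stepwise_qtl_search(probs, ym, thr)
      predicted[[param]] <- predict_from_model(models[[param]], probs, held)
    }
    L0_const <- stats::median(exp(colMeans(
      fit_train$samples$mu_g[, , 3, drop = FALSE]))[1, ])

    # envelopes from the held-out genotypes' own observed plants
    cfg_h <- holdout_config; cfg_h$seed <- round_seeds[rd] + 3L
    fit_held <- fit_hierarchical(test, config = cfg_h)
    sum_held <- posterior_summary(fit_held)

    for (g in held) {
      pr <- predicted$r$predicted[predicted$r$genotype == g]
      pL <- predicted$Lmax$predicted[predicted$Lmax$genotype == g]
      tg <- test$t_dd[test$genotype == g]
      grid <- seq(0, max(tg), length.out = 25)
      env <- credible_envelopes(fit_held, g, grid)
      curve <- predict_growth_curve(pr, pL, L0_const, grid)
      v <- if (curve$ok)
        envelope_verdict(curve, env, grid, mode = "within",
                         r = pr, Lmax = pL, L0 = L0_const)
      else list(overall = "fail", r = "fail", Lmax = "fail")
      obs <- sum_held[sum_held$genotype == g, ]
      preds[[length(preds) + 1L]] <- data.frame(
        round = rd, genotype = g, pred_r = pr, pred_Lmax = pL,
        L0_const = L0_const,
        obs_r = obs$mean[obs$param == "r"],
        obs_Lmax = obs$mean[obs$param == "Lmax"],
        verdict_overall = v$overall, verdict_r = v$r,
        verdict_Lmax = v$Lmax)
    }
  }
  tab <- do.call(rbind, preds)
  prop <- function(col, lev) mean(tab[[col]] %in% lev)
  n_sc <- nrow(tab)
  zs <- list(
    r = proportion_z(sum(tab$verdict_r == "success"), n_sc),
    Lmax = proportion_z(sum(tab$verdict_Lmax == "success"), n_sc))
  out <- list(
    predictions = tab,
    proportions = c(
      success_r = prop("verdict_r", "success"),
      marginal_r = prop("verdict_r", c("success", "marginal")),
      success_Lmax = prop("verdict_Lmax", "success"),
      marginal_Lmax = prop("verdict_Lmax", c("success", "marginal"))),
    z_tests = zs,
    correlations = c(
      r = stats::cor(tab$pred_r, tab$obs_r),
      Lmax = stats::cor(tab$pred_Lmax, tab$obs_Lmax)),
    training_log = do.call(rbind, logs),
    k = k, rounds = rounds, alpha_map = alpha_map, seed = seed)
  class(out) <- "prediction_assessment"
  out
}

#' @export
print.prediction_assessment <- function(x, ...) {
  cat(sprintf("Leave-%d-out prediction assessment, %d rounds (%d scored)\n",
              x$k, x$rounds, nrow(x$predictions)))
  cat(sprintf("  success (inner band): r %.0f%%, Lmax %.0f%%\n",
              100 * x$proportions["success_r"],
              100 * x$proportions["success_Lmax"]))
  cat(sprintf("  within outer band:    r %.0f%%, Lmax %.0f%%\n",
              100 * x$proportions["marginal_r"],
              100 * x$proportions["marginal_Lmax"]))
  cat(sprintf("  predicted-vs-observed correlation: r %.2f, Lmax %.2f\n",
              x$correlations["r"], x$correlations["Lmax"]))
  cat(sprintf("  Z vs chance 0.5: r %.2f (p=%.2g), Lmax %.2f (p=%.2g)\n",
              x$z_tests$r$z, x$z_tests$r$p_value,
              x$z_tests$Lmax$z, x$z_tests$Lmax$p_value))
  invisible(x)
}
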