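# Three-level hierarchical Bayesian estimation of logistic growth-curve
# parameters from longitudinal measurements: plant-level (r, Lmax, L0)
# with a genotype-level mean layer and global hyperparameters, sampled by
# Metropolis-within-Gibbs.  Curve parameters are sampled on the log scale
# (a Gaussian hierarchy there guarantees positivity); genotype and global
# means, hierarchy SDs, the residual SD and the optional A_max covariate
# slope all have conjugate updates, so only the plant-level parameters
# need random-walk Metropolis steps.

#' MCMC configuration
#'
#' @param iterations Total MCMC draws.
#' @param burn_in Discarded initial draws (`< iterations`).
#' @param thin Keep one draw in `thin`.
#' @param proposal_scale Initial random-walk SD for plant-level log
#'   parameters (adapted during burn-in only).
#' @param seed RNG seed.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(iterations = 500000, burn_in = 440000, thin = 20,
                        proposal_scale = 0.08, seed = 1L) {
  if (burn_in >= iterations)
    stop("'burn_in' must be smaller than 'iterations'", call. = FALSE)
  if (thin < 1) stop("'thin' must be at least 1", call. = FALSE)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 proposal_scale = proposal_scale, seed = as.integer(seed)),
            class = "mcmc_config")
}

#' MCMC presets
#'
#' `"paper"` is the full single-chain protocol (500,000 iterations,
#' 440,000 burn-in, thinning 1-in-20, hence 3,000 retained samples);
#' `"test"` is a short-chain preset for simulation studies and test
#' suites.
#'
#' @param preset `"paper"` or `"test"`.
#' @param seed RNG seed.
#' @return An [mcmc_config()].
#' @export
mcmc_preset <- function(preset = c("paper", "test"), seed = 1L) {
  switch(match.arg(preset),
         paper = mcmc_config(500000, 440000, 20, seed = seed),
         test = mcmc_config(12000, 6000, 3, seed = seed))
}

#' Retained sample count
#'
#' `(iterations - burn_in) / thin`, integer division (remainder
#' discarded).
#'
#' @param config An [mcmc_config()].
#' @return Integer number of retained posterior samples per parameter.
#' @export
retained_sample_count <- function(config) {
  if (config$burn_in >= config$iterations)
    stop("'burn_in' must be smaller than 'iterations'", call. = FALSE)
  as.integer((config$iterations - config$burn_in) %/% config$thin)
}

# crude per-plant initial values on the log scale
init_plant_theta <- function(y, t) {
  Lmax0 <- 1.05 * max(y) + 1e-6
  L00 <- max(min(y) * 0.9, 0.05 * Lmax0, 1e-3)
  z <- log(pmin(pmax(y / Lmax0, 1e-3), 1 - 1e-3))
  z <- z - log(1 - exp(z))                       # logit of y/Lmax
  r0 <- if (length(unique(t)) > 1 && stats::sd(t) > 0)
    max(min(stats::coef(stats::lm(z ~ t))[2], 2), 1e-3) else 0.05
  c(log(r0), log(Lmax0), log(L00))
}

#' Fit the hierarchical Bayesian FVT model
#'
#' One trait / treatment / season combination is fitted at a time (the
#' combinations are modeled independently).  The model:
#' observations `y ~ N(L(t; r_p, Lmax_p, L0_p), sigma^2)` per plant `p`;
#' plant log parameters `theta_p ~ N(mu_g(p) + beta * a_g(p), omega^2)`
#' where `a_g` is the centered genotypic photosynthetic capacity
#' (`A_max`) when supplied; genotype means `mu_g ~ N(mu0, tau^2)`; and
#' weakly-informative hyperpriors scaled to the data range (the global
#' `Lmax` prior is centered on the maximum observed size).  Proposal
#' scales adapt during burn-in only, preserving detailed balance in the
#' retained chain.
#'
#' @param measurements data.frame with columns `plant_id`, `genotype`,
#'   `t_dd`, `value` (positive sizes, >= 2 measurements per plant).
#' @param amax Optional named vector of genotypic `A_max` values
#'   (centered internally).
#' @param config An [mcmc_config()]; see [mcmc_preset()].
#' @return An `fvt_posterior` object: retained samples for the global
#'   mean, genotype means, hierarchy SDs, residual SD and covariate
#'   slope; plant-level posterior means; acceptance rates and lookup
#'   tables.
#' @export
fit_hierarchical <- function(measurements, amax = NULL,
                             config = mcmc_preset("test")) {
  need <- c("plant_id", "genotype", "t_dd", "value")
  if (!all(need %in% names(measurements)))
    stop("measurements must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(measurements$value)) || any(measurements$value <= 0))
    stop("measurements must be positive and finite", call. = FALSE)
  counts <- table(measurements$plant_id)
  if (any(counts < 2))
    stop("every plant needs at least 2 measurements", call. = FALSE)

  set.seed(config$seed)
  y <- measurements$value
  tt <- measurements$t_dd
  plant_ids <- sort(unique(measurements$plant_id))
  pidx <- match(measurements$plant_id, plant_ids)
  P <- length(plant_ids)
  plant_geno <- vapply(split(as.character(measurements$genotype), pidx),
                       `[`, character(1), 1)
  genos <- sort(unique(plant_geno))
  G <- length(genos)
  gidx <- match(plant_geno, genos)               # genotype of each plant
  N <- length(y)

  use_amax <- !is.null(amax)
  a_g <- if (use_amax) {
    av <- amax[genos]
    if (anyNA(av)) stop("amax missing for some genotypes", call. = FALSE)
    av - mean(av)
  } else rep(0, G)
  a_p <- a_g[gidx]

  # --- initial values --------------------------------------------------
  theta <- t(vapply(seq_len(P), function(p) {
    sel <- pidx == p
    init_plant_theta(y[sel], tt[sel])
  }, numeric(3)))
  mu_g <- apply(theta, 2, function(col) tapply(col, gidx, mean))
  mu_g <- matrix(mu_g, G, 3)
  mu0 <- colMeans(mu_g)
  tau <- rep(0.2, 3); omega <- rep(0.2, 3)
  beta <- rep(0, 3)
  sigma <- max(0.05 * stats::sd(y), 1e-3)

  # hyperpriors
  m0 <- c(mu0[1], log(max(y)), mu0[3])           # Lmax centered on max size
  s0 <- rep(2, 3)
  a_v <- 1; b_v <- 0.01                          # weak InvGamma on tau^2, omega^2
  a_s <- 2; b_s <- (0.1 * stats::sd(y))^2        # InvGamma on sigma^2
  beta_prior_sd <- 1

  fitted <- logistic_size_vec(exp(theta[pidx, 1]), exp(theta[pidx, 2]),
                              exp(theta[pidx, 3]), tt)
  rss_p <- as.numeric(rowsum((y - fitted)^2, pidx))

  scales <- rep(config$proposal_scale, P)
  acc_count <- integer(P); acc_window <- integer(P); window_n <- 0L

  S <- retained_sample_count(config)
  keep <- list(mu0 = matrix(NA_real_, S, 3),
               mu_g = array(NA_real_, c(S, G, 3),
                            dimnames = list(NULL, genos, c("r", "Lmax", "L0"))),
               sigma = numeric(S), tau = matrix(NA_real_, S, 3),
               omega = matrix(NA_real_, S, 3),
               beta = matrix(NA_real_, S, 3))
  plant_accum <- matrix(0, P, 3)
  s_out <- 0L
  comp_scale <- c(1, 0.35, 0.8)                  # r moves more than Lmax

  for (it in seq_len(config$iterations)) {
    ## 1. plant-level Metropolis (vectorized over plants)
    prior_mean <- mu_g[gidx, , drop = FALSE] +
      a_p %o% beta                               # P x 3
    prop <- theta + (matrix(stats::rnorm(P * 3), P, 3) *
                       rep(comp_scale, each = P)) * scales
    prop_fitted <- logistic_size_vec(exp(prop[pidx, 1]), exp(prop[pidx, 2]),
                                     exp(prop[pidx, 3]), tt)
    prop_rss <- as.numeric(rowsum((y - prop_fitted)^2, pidx))
    d_lik <- (rss_p - prop_rss) / (2 * sigma^2)
    d_pri <- rowSums(((theta - prior_mean)^2 - (prop - prior_mean)^2) /
                       (2 * rep(omega^2, each = P)))
    acc <- log(stats::runif(P)) < d_lik + d_pri
    if (any(acc)) {
      theta[acc, ] <- prop[acc, ]
      rss_p[acc] <- prop_rss[acc]
      accobs <- acc[pidx]
      fitted[accobs] <- prop_fitted[accobs]
    }
    acc_count <- acc_count + acc; acc_window <- acc_window + acc
    window_n <- window_n + 1L
    if (it <= config$burn_in && window_n == 50L) {   # adapt during burn-in
      rate <- acc_window / 50
      scales <- pmin(pmax(scales * exp(0.6 * (rate - 0.3)), 1e-4), 2)
      acc_window <- integer(P); window_n <- 0L
    }

    ## 2. genotype means (conjugate per component)
    resid_ga <- theta - a_p %o% beta
    for (j in 1:3) {
      sums <- as.numeric(rowsum(resid_ga[, j], gidx))
      n_g <- tabulate(gidx, G)
      prec <- n_g / omega[j]^2 + 1 / tau[j]^2
      mean_ <- (sums / omega[j]^2 + mu0[j] / tau[j]^2) / prec
      mu_g[, j] <- stats::rnorm(G, mean_, sqrt(1 / prec))
    }

    ## 3. global means
    for (j in 1:3) {
      prec <- G / tau[j]^2 + 1 / s0[j]^2
      mean_ <- (sum(mu_g[, j]) / tau[j]^2 + m0[j] / s0[j]^2) / prec
      mu0[j] <- stats::rnorm(1, mean_, sqrt(1 / prec))
    }

    ## 4. hierarchy SDs (conjugate inverse-gamma)
    for (j in 1:3) {
      tau[j] <- sqrt(1 / stats::rgamma(1, a_v + G / 2,
                                       b_v + sum((mu_g[, j] - mu0[j])^2) / 2))
      dev <- theta[, j] - mu_g[gidx, j] - beta[j] * a_p
      omega[j] <- sqrt(1 / stats::rgamma(1, a_v + P / 2,
                                         b_v + sum(dev^2) / 2))
    }

    ## 5. covariate slope (conjugate; only with amax)
    if (use_amax && sum(a_p^2) > 0) for (j in 1:3) {
      e <- theta[, j] - mu_g[gidx, j]
      prec <- sum(a_p^2) / omega[j]^2 + 1 / beta_prior_sd^2
      mean_ <- (sum(a_p * e) / omega[j]^2) / prec
      beta[j] <- stats::rnorm(1, mean_, sqrt(1 / prec))
    }

    ## 6. residual SD (conjugate inverse-gamma)
    sigma <- sqrt(1 / stats::rgamma(1, a_s + N / 2, b_s + sum(rss_p) / 2))

    ## record
    if (it > config$burn_in &&
        (it - config$burn_in) %% config$thin == 0L) {
      s_out <- s_out + 1L
      keep$mu0[s_out, ] <- mu0
      keep$mu_g[s_out, , ] <- mu_g
      keep$sigma[s_out] <- sigma
      keep$tau[s_out, ] <- tau
      keep$omega[s_out, ] <- omega
      keep$beta[s_out, ] <- beta
      plant_accum <- plant_accum + exp(theta)
    }
  }

  acc_rate <- acc_count / config$iterations
  structure(list(
    samples = keep,
    n_retained = S,
    genotypes = genos,
    plant_ids = plant_ids,
    plant_genotype = stats::setNames(plant_geno, plant_ids),
    plant_means = {
      pm <- plant_accum / S
      dimnames(pm) <- list(plant_ids, c("r", "Lmax", "L0")); pm
    },
    acceptance = stats::setNames(acc_rate, plant_ids),
    used_amax = use_amax,
    diverged = mean(acc_rate) < 0.01,
    config = config), class = "fvt_posterior")
}

#' @export
print.fvt_posterior <- function(x, ...) {
  cat(sprintf("Hierarchical FVT posterior: %d genotypes, %d plants, %d samples\n",
              length(x$genotypes), length(x$plant_ids), x$n_retained))
  cat(sprintf("  mean plant acceptance rate %.2f%s\n",
              mean(x$acceptance), if (x$diverged) "  [DIVERGENCE FLAG]" else ""))
  invisible(x)
}

#' Posterior summaries of genotype-level FVT parameters
#'
#' Per genotype: posterior mean, median, and 2.5/97.5 percentiles of
#' `r`, `Lmax`, `L0` (natural scale) and the derived traits `d` (time to
#' 95% of final size) and `iD` (inflection time), each computed per
#' retained draw.
#'
#' @param posterior An `fvt_posterior`.
#' @return data.frame, one row per genotype x parameter.
#' @export
posterior_summary <- function(posterior) {
  qs <- function(v) c(mean = mean(v), median = stats::median(v),
                      q025 = unname(stats::quantile(v, 0.025)),
                      q975 = unname(stats::quantile(v, 0.975)))
  rows <- list()
  for (g in posterior$genotypes) {
    th <- exp(posterior$samples$mu_g[, g, ])     # S x 3, natural scale
    A <- (th[, 2] - th[, 3]) / th[, 3]           # (Lmax - L0) / L0
    A <- pmax(A, 1e-12)
    d <- log(A * 0.95 / 0.05) / th[, 1]
    iD <- pmax(log(A), 0) / th[, 1]
    vals <- cbind(r = th[, 1], Lmax = th[, 2], L0 = th[, 3], d = d, iD = iD)
    for (p in colnames(vals))
      rows[[paste(g, p)]] <- data.frame(genotype = g, param = p,
                                        t(qs(vals[, p])))
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

#' Dual 95% credible envelopes for a genotype's growth curve
#'
#' The inner envelope is the pointwise 95% credible band of the genotype
#' mean curve (logistic curve evaluated over the genotype-level parameter
#' draws); the outer envelope is the posterior-predictive band for a
#' future observation (the same draws with residual noise added), i.e.
#' the band within which a new measurement of this genotype in this
#' environment is expected to fall.  The outer band contains the inner
#' band pointwise by construction.
#'
#' @param posterior An `fvt_posterior` containing the genotype.
#' @param genotype Genotype label.
#' @param grid Degree-day evaluation grid.
#' @param level Credible level (default 0.95).
#' @return A `credible_envelope`: data.frame with `t_dd`, `inner_lo`,
#'   `inner_hi`, `outer_lo`, `outer_hi`, plus attributes `genotype` and
#'   `level`.
#' @export
credible_envelopes <- function(posterior, genotype, grid, level = 0.95) {
  if (!genotype %in% posterior$genotypes)
    stop("genotype not in posterior: ", genotype, call. = FALSE)
  th <- exp(posterior$samples$mu_g[, genotype, ])  # S x 3
  S <- nrow(th)
  curves <- vapply(grid, function(t0)
    logistic_size_vec(th[, 1], th[, 2], th[, 3], t0), numeric(S))
  alpha <- (1 - level) / 2
  inner <- apply(curves, 2, stats::quantile, probs = c(alpha, 1 - alpha))
  noisy <- curves + stats::rnorm(length(curves), 0,
                                 posterior$samples$sigma)
  outer <- apply(noisy, 2, stats::quantile, probs = c(alpha, 1 - alpha))
  out <- data.frame(t_dd = grid,
                    inner_lo = inner[1, ], inner_hi = inner[2, ],
                    outer_lo = pmin(outer[1, ], inner[1, ]),
                    outer_hi = pmax(outer[2, ], inner[2, ]))
  attr(out, "genotype") <- genotype
  attr(out, "level") <- level
  class(out) <- c("credible_envelope", "data.frame")
  out
}

#' Chain diagnostics for a sample matrix
#'
#' Lag-1 autocorrelation, effective sample size (initial-positive-
#' sequence estimate), and degeneracy flags per column of a matrix of
#' retained samples.
#'
#' @param samples Numeric matrix, iterations x parameters.
#' @param max_lag Largest lag entering the ESS sum.
#' @return data.frame: `param`, `mean`, `sd`, `lag1`, `ess`, `flag`.
#' @export
chain_diagnostics <- function(samples, max_lag = 50) {
  samples <- as.matrix(samples)
  if (is.null(colnames(samples)))
    colnames(samples) <- paste0("par", seq_len(ncol(samples)))
  S <- nrow(samples)
  rows <- lapply(colnames(samples), function(nm) {
    v <- samples[, nm]
    if (stats::sd(v) == 0)
      return(data.frame(param = nm, mean = mean(v), sd = 0,
                        lag1 = NA_real_, ess = 0, flag = "degenerate"))
    ac <- stats::acf(v, lag.max = min(max_lag, S - 1), plot = FALSE)$acf[-1]
    pos <- which(ac < 0.05)
    cut <- if (length(pos)) pos[1] - 1 else length(ac)
    ess <- S / (1 + 2 * sum(ac[seq_len(cut)]))
    flag <- if (ess < 0.01 * S) "low_ess" else "ok"
    data.frame(param = nm, mean = mean(v), sd = stats::sd(v),
               lag1 = ac[1], ess = ess, flag = flag)
  })
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

#' Convergence report for a fitted posterior
#'
#' Runs [chain_diagnostics()] on the global-mean, residual-SD and
#' hierarchy-SD chains and summarizes plant-level Metropolis acceptance.
#'
#' @param posterior An `fvt_posterior`.
#' @return List with `diagnostics` (data.frame), `acceptance` summary,
#'   and `flags` (character vector of parameters failing checks).
#' @export
convergence_report <- function(posterior) {
  mat <- cbind(mu0_logr = posterior$samples$mu0[, 1],
               mu0_logLmax = posterior$samples$mu0[, 2],
               mu0_logL0 = posterior$samples$mu0[, 3],
               sigma = posterior$samples$sigma,
               tau_logr = posterior$samples$tau[, 1],
               omega_logr = posterior$samples$omega[, 1])
  diag_tab <- chain_diagnostics(mat)
  flags <- diag_tab$param[diag_tab$flag != "ok"]
  if (posterior$diverged) flags <- c(flags, "plant_acceptance")
  list(diagnostics = diag_tab,
       acceptance = summary(posterior$acceptance),
       flags = flags)
}

#' Write posterior genotype summaries to CSV
#'
#' @param posterior An `fvt_posterior`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_posterior_csv <- function(posterior, path) {
  utils::write.csv(posterior_summary(posterior), path, row.names = FALSE)
  invisible(path)
}
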