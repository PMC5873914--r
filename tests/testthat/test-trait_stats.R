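# Outlier rule, shrinkage genotype means, random-effect LRTs.

test_that("3-SD outlier rule removes only extreme points, single pass", {
  x <- c(rep(0, 30), 10)
  # oracle: z of the 10 under full-sample mean/SD is 5.39
  z <- (10 - mean(x)) / sd(x)
  expect_equal(z, 5.39, tolerance = 1e-3)
  res <- filter_outliers(x)
  expect_identical(res$removed_idx, 31L)
  expect_identical(res$retained, rep(0, 30))

  expect_identical(filter_outliers(1:5)$retained, 1:5)     # all within 3 SD
  expect_identical(filter_outliers(c(7, 7, 7))$removed_idx, integer(0))

  # exactly one pass: re-running on the retained values can remove more
  y <- c(rep(0, 50), 3.2, 40)
  first <- filter_outliers(y)
  expect_identical(first$removed, 40)
  second <- filter_outliers(first$retained)
  expect_identical(second$removed, 3.2)
})

test_that("balanced-case shrinkage matches the closed-form oracle", {
  # engineered one-way data with exact ANOVA variance components:
  # MSW = 4, MSB = 20, m = 4 reps -> sigma2_g = 4, sigma2_e = 4,
  # lambda = 4 / (4 + 4/4) = 0.8
  eff <- c(2, -2, sqrt(6), -sqrt(6), 0)
  dev <- c(1, -1, 1, -1) * sqrt(3)
  df <- expand.grid(rep = 1:4, genotype = paste0("G", 1:5))
  df$value <- 8 + eff[as.integer(df$genotype)] + dev[df$rep]
  est <- estimate_genotype_means(df)
  expect_equal(unname(est$varcomp["genotype"]), 4, tolerance = 1e-6)
  expect_equal(unname(est$varcomp["Residual"]), 4, tolerance = 1e-6)
  expect_equal(est$grand_mean, 8, tolerance = 1e-8)
  g1 <- est$means[est$means$genotype == "G1", ]
  expect_equal(g1$raw_mean, 10)
  expect_equal(g1$shrunken_mean, 9.6, tolerance = 1e-6)    # 8 + 0.8 * 2
})

test_that("shrinkage limits: lambda -> 1 with no residual noise, -> 0 with no genetic signal", {
  df <- expand.grid(rep = 1:4, genotype = paste0("G", 1:6))
  df$value <- c(10, 12, 14, 16, 18, 20)[as.integer(df$genotype)]
  est <- estimate_genotype_means(df)
  expect_equal(est$means$shrunken_mean, est$means$raw_mean, tolerance = 1e-3)

  set.seed(3)
  df2 <- expand.grid(rep = 1:6, genotype = paste0("G", 1:50))
  df2$value <- rnorm(nrow(df2))
  est2 <- estimate_genotype_means(df2)
  dev_shrunk <- est2$means$shrunken_mean - est2$grand_mean
  dev_raw <- est2$means$raw_mean - est2$grand_mean
  # shrunken means sit between raw means and the grand mean
  expect_true(all(abs(dev_shrunk) <= abs(dev_raw) + 1e-9))
  expect_lt(sd(est2$means$shrunken_mean), 0.5 * sd(est2$means$raw_mean))
})

test_that("genotype means adjust for block effects", {
  set.seed(4)
  df <- expand.grid(block = paste0("B", 1:4), genotype = paste0("G", 1:20))
  block_eff <- c(B1 = 5, B2 = -5, B3 = 2, B4 = -2)
  geno_eff <- rnorm(20, 0, 2)
  df$value <- 10 + geno_eff[as.integer(df$genotype)] +
    block_eff[df$block] + rnorm(nrow(df), 0, 0.5)
  est <- estimate_genotype_means(df)
  expect_true("block" %in% names(est$varcomp))
  expect_gt(est$varcomp["block"], est$varcomp["Residual"])
  expect_gt(cor(est$means$shrunken_mean - est$grand_mean, geno_eff), 0.9)
  expect_error(estimate_genotype_means(df[df$genotype == "G1", ]),
               "2 genotypes")
})

test_that("random-effect chi-square matches a brute-force REML likelihood oracle", {
  # direct multivariate-normal REML log-likelihood, maximized by optim --
  # fully independent of lme4's representation
  reml_loglik <- function(y, Z_list, s2, s2e) {
    n <- length(y)
    V <- diag(s2e, n)
    for (k in seq_along(Z_list)) V <- V + s2[k] * tcrossprod(Z_list[[k]])
    Vi <- solve(V)
    X <- matrix(1, n, 1)
    XtViX <- crossprod(X, Vi %*% X)
    beta <- solve(XtViX, crossprod(X, Vi %*% y))
    r <- y - X %*% beta
    as.numeric(-0.5 * (determinant(V)$modulus +
                         determinant(XtViX)$modulus +
                         crossprod(r, Vi %*% r) + (n - 1) * log(2 * pi)))
  }
  max_reml <- function(y, Z_list) {
    obj <- function(lv) -reml_loglik(y, Z_list,
                                     exp(lv[seq_along(Z_list)]),
                                     exp(lv[length(lv)]))
    best <- optim(rep(0, length(Z_list) + 1), obj, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-12))
    -best$value
  }
  set.seed(8)
  toy <- expand.grid(genotype = paste0("G", 1:4), block = c("B1", "B2"))
  toy$value <- 3 + c(1.2, -0.8, 0.5, -0.9)[as.integer(toy$genotype)] +
    c(0.4, -0.4)[as.integer(toy$block)] + rnorm(8, 0, 0.3)
  Zg <- outer(toy$genotype, levels(toy$genotype), "==") * 1
  Zb <- outer(toy$block, levels(toy$block), "==") * 1

  got <- test_random_effect(toy, c("genotype", "block"), "genotype")
  ll_full <- max_reml(toy$value, list(Zg, Zb))
  ll_red <- max_reml(toy$value, list(Zb))
  expect_equal(got$chisq, max(0, 2 * (ll_full - ll_red)), tolerance = 1e-4)
  expect_identical(got$df, 1L)
})

test_that("LRT is null-calibrated and powered against injected G x Y variance", {
  set.seed(12)
  # null: no genotype variance at all
  pvals <- replicate(8, {
    d <- expand.grid(rep = 1:3, genotype = paste0("G", 1:25),
                     block = paste0("B", 1:2))
    d$value <- rnorm(nrow(d)) + c(0.5, -0.5)[as.integer(d$block)]
    test_random_effect(d, c("genotype", "block"), "genotype")$p_value
  })
  expect_gt(median(pvals), 0.4)

  # power: genotype-by-year SD equal to residual SD
  hits <- replicate(8, {
    d <- expand.grid(rep = 1:4, genotype = paste0("G", 1:100),
                     year = c("Y1", "Y2"))
    gxe <- matrix(rnorm(200), 100, 2)
    g <- rnorm(100, 0, 0.5)
    d$value <- g[as.integer(d$genotype)] +
      gxe[cbind(as.integer(d$genotype), as.integer(d$year))] +
      rnorm(nrow(d))
    test_random_effect(d, c("genotype", "year", "genotype:year"),
                       "genotype:year")$p_value < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("plasticity test table has the full-model structure", {
  cfg <- small_config(n_ril = 25, years = c(2011, 2012),
                      treatments = c("UN", "CR"),
                      blocks_per_env = c("2011" = 2, "2012" = 2), seed = 15)
  sim <- simulate_phenotypes(simulate_map_genotypes(cfg), cfg)
  # per-plant Lmax point estimates stand in for fitted FVT parameters
  d <- sim$truth$plant_params
  d$value <- d$Lmax
  tab <- plasticity_test_table(d)
  expect_identical(nrow(tab), 8L)
  expect_true(all(tab$chisq >= 0))
  expect_true(all(c("genotype", "genotype:treatment:year") %in% tab$effect))
  expect_true(all(levels(tab$signif) == c("***", "**", "*", ".", "NS")))
})
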