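# HMM genotype probabilities, Haley-Knott scans, permutation thresholds,
# stepwise multi-QTL search, PVE and support intervals.

# Brute-force forward-backward oracle for a 3-marker chain: enumerate the
# 8 hidden state paths directly.
brute_force_middle_prob <- function(obs, d12, d23, err) {
  states <- c("AA", "BB")
  emis <- function(o, s) if (is.na(o)) 1 else if (o == s) 1 - err else err
  trans <- function(s1, s2, d) {
    r <- haldane_rf(d); if (s1 == s2) 1 - r else r
  }
  joint <- 0; mid_aa <- 0
  for (s1 in states) for (s2 in states) for (s3 in states) {
    p <- 0.5 * trans(s1, s2, d12) * trans(s2, s3, d23) *
      emis(obs[1], s1) * emis(obs[2], s2) * emis(obs[3], s3)
    joint <- joint + p
    if (s2 == "AA") mid_aa <- mid_aa + p
  }
  mid_aa / joint
}

three_marker_fixture <- function(obs, positions = c(0, 10, 20)) {
  map <- data.frame(marker = c("m1", "m2", "m3"), chrom = 1,
                    pos_cm = positions)
  g <- matrix(obs, 1, 3, dimnames = list("L1", map$marker))
  list(map = map, genotypes = g)
}

test_that("HMM probabilities match the forward-backward oracle on 3-point chains", {
  cases <- list(c("AA", "BB", "AA"), c("AA", NA, "BB"), c("BB", "BB", "AA"))
  for (obs in cases) {
    fx <- three_marker_fixture(obs)
    gp <- genotype_probabilities(fx$map, fx$genotypes, step = 10,
                                 error_rate = 0.01)
    got <- gp$probAA[1, gp$grid$pos_cm == 10]
    want <- brute_force_middle_prob(obs, 10, 10, 0.01)
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("HMM limits: observed markers certain, interval midpoint as derived", {
  fx <- three_marker_fixture(c("AA", NA, "AA"), positions = c(0, 10, 20))
  gp <- genotype_probabilities(fx$map, fx$genotypes, step = 1, error_rate = 0)
  # at an observed marker with zero error the state is certain
  expect_equal(unname(gp$probAA[1, gp$grid$pos_cm == 0]), 1)
  # midpoint of a 20 cM AA--AA interval: (1-r)^2 / ((1-r)^2 + r^2), r = Haldane(10)
  r <- haldane_rf(10)
  want <- (1 - r)^2 / ((1 - r)^2 + r^2)
  expect_equal(unname(gp$probAA[1, gp$grid$pos_cm == 10]), want,
               tolerance = 1e-12)
  expect_equal(round(want, 3), 0.990)
  # probabilities are proper at every position
  expect_true(all(gp$probAA >= 0 & gp$probAA <= 1))
})

test_that("Haley-Knott LOD reproduces explicit least-squares arithmetic", {
  map <- data.frame(marker = c("m1", "m2"), chrom = 1, pos_cm = c(0, 50))
  g <- matrix(c("AA", "AA", "BB", "BB",
                "AA", "BB", "AA", "BB"), 4, 2,
              dimnames = list(paste0("L", 1:4), map$marker))
  gp <- genotype_probabilities(map, g, step = 1, error_rate = 0)
  y <- c(L1 = 1.0, L2 = 1.2, L3 = 3.0, L4 = 2.8)
  sc <- scan_hk(gp, y)
  # RSS0 = 3.28 (about the mean 2), RSS1 = 0.04 (class means 1.1 / 2.9)
  expect_equal(sc$lod[sc$pos_cm == 0], 2 * log10(3.28 / 0.04),
               tolerance = 1e-10)
  expect_equal(round(sc$lod[sc$pos_cm == 0], 2), 3.83)
  expect_true(all(sc$lod >= 0))
})

test_that("scan at fully informative markers equals single-marker regression", {
  cfg <- small_config(n_ril = 60, seed = 21)
  mg <- simulate_map_genotypes(cfg)
  gp <- genotype_probabilities(mg$map, mg$genotypes, step = 2,
                               error_rate = 0)
  set.seed(1)
  y <- stats::setNames(rnorm(60, 20, 3), rownames(mg$genotypes))
  sc <- scan_hk(gp, y)
  for (mk in sample(mg$map$marker, 5)) {
    x <- ifelse(mg$genotypes[, mk] == "AA", 1, -1)
    rss1 <- sum(stats::lm.fit(cbind(1, x), unname(y))$residuals^2)
    rss0 <- sum((y - mean(y))^2)
    want <- (60 / 2) * log10(rss0 / rss1)
    expect_equal(sc$lod[match(mk, sc$marker)], want, tolerance = 1e-10)
  }
})

test_that("permutation thresholds are monotone in quantile and reproducible", {
  cfg <- small_config(n_ril = 40, seed = 31)
  mg <- simulate_map_genotypes(cfg)
  gp <- genotype_probabilities(mg$map, mg$genotypes)
  set.seed(2)
  y <- stats::setNames(rnorm(40), rownames(mg$genotypes))
  t95 <- permutation_threshold(gp, y, n_perm = 200, quantile = 0.95, seed = 5)
  t90 <- permutation_threshold(gp, y, n_perm = 200, quantile = 0.90, seed = 5)
  expect_gte(t95, t90)
  t95b <- permutation_threshold(gp, y, n_perm = 200, quantile = 0.95, seed = 5)
  expect_identical(as.numeric(t95), as.numeric(t95b))
  # a null scan rarely beats its own 0.95 threshold
  sc <- scan_hk(gp, y)
  expect_lt(max(sc$lod), t95 + 2)   # sanity bound, calibration tested elsewhere
})

test_that("PVE formula and its inverse round-trip", {
  expect_equal(pve_from_lod(0, 119), 0)
  expect_equal(pve_from_lod(3, 100), 12.90, tolerance = 5e-3)
  for (lod in c(0.5, 3, 10)) {
    expect_equal(lod_from_pve(pve_from_lod(lod, 119), 119), lod,
                 tolerance = 1e-10)
  }
  expect_error(pve_from_lod(3, 0), "'n'")
  expect_error(pve_from_lod(-1, 10), "'lod'")
})

test_that("1.5-LOD support interval matches constructed curves", {
  tri <- data.frame(chrom = 1, pos_cm = 30:70, marker = NA,
                    lod = pmax(6 - 0.3 * abs(30:70 - 50), 0))
  ci <- lod_support_interval(tri, 1, 50, drop = 1.5)
  expect_equal(unname(ci), c(45, 55))
  expect_true(ci["lo"] <= 50 && 50 <= ci["hi"])
  flat <- data.frame(chrom = 1, pos_cm = 0:100, marker = NA, lod = 4)
  expect_equal(unname(lod_support_interval(flat, 1, 50)), c(0, 100))
})

test_that("stepwise search recovers an injected two-QTL architecture", {
  cfg <- sim_config(n_ril = 200, n_chrom = 2, markers_per_chrom = 11,
                    chrom_length_cm = 100, seed = 77)
  mg <- simulate_map_genotypes(cfg)
  dos <- ifelse(mg$genotypes == "AA", 1, -1)
  m1 <- "A01_m04"; m2 <- "A02_m08"
  set.seed(7)
  y <- stats::setNames(30 + 1.5 * dos[, m1] + 1.2 * dos[, m2] +
                         rnorm(200, 0, 0.8), rownames(mg$genotypes))
  gp <- genotype_probabilities(mg$map, mg$genotypes)
  thr <- permutation_threshold(gp, y, n_perm = 200, seed = 3)
  model <- stepwise_qtl_search(gp, y, thr)
  expect_identical(nrow(model), 2L)
  true_pos <- mg$map[match(c(m1, m2), mg$map$marker), ]
  for (i in 1:2) {
    row <- model[model$chrom == true_pos$chrom[i], ]
    expect_identical(nrow(row), 1L)
    expect_true(row$ci_lo <= true_pos$pos_cm[i] &&
                  true_pos$pos_cm[i] <= row$ci_hi)
    expect_identical(row$direction, 1)         # AA allele increases trait
  }
  expect_equal(sort(model$effect), c(1.2, 1.5), tolerance = 0.15)
  expect_true(all(model$pve > 0 & model$pve < 100))
  expect_true(all(model$lod > thr / 2))
})

test_that("stepwise search returns an empty model for null phenotypes and the scan peak for one QTL", {
  cfg <- small_config(n_ril = 80, seed = 91)
  mg <- simulate_map_genotypes(cfg)
  gp <- genotype_probabilities(mg$map, mg$genotypes)
  set.seed(9)
  ynull <- stats::setNames(rnorm(80), rownames(mg$genotypes))
  thr <- permutation_threshold(gp, ynull, n_perm = 200, seed = 4)
  expect_identical(nrow(stepwise_qtl_search(gp, ynull, thr)), 0L)

  dos <- ifelse(mg$genotypes == "AA", 1, -1)
  y1 <- stats::setNames(10 - 2 * dos[, "A02_m03"] + rnorm(80, 0, 1),
                        rownames(mg$genotypes))
  sc <- scan_hk(gp, y1)
  thr1 <- permutation_threshold(gp, y1, n_perm = 200, seed = 4)
  model <- stepwise_qtl_search(gp, y1, thr1)
  expect_identical(nrow(model), 1L)
  peak <- sc[which.max(sc$lod), ]
  expect_identical(model$chrom, peak$chrom)
  expect_identical(model$pos_cm, peak$pos_cm)
  expect_identical(model$direction, -1)        # AA allele decreases trait
})

test_that("colocalization collapse merges same-direction overlapping QTL only", {
  tab <- data.frame(chrom = c(1, 1, 1, 2),
                    pos_cm = c(20, 25, 60, 10),
                    lod = c(5, 4, 6, 3), direction = c(1, 1, -1, 1),
                    ci_lo = c(15, 18, 50, 5), ci_hi = c(28, 30, 70, 15))
  out <- collapse_colocalized(tab)
  expect_identical(nrow(out), 3L)
  merged <- out[out$chrom == 1 & out$direction == 1, ]
  expect_identical(merged$lod, 5)              # keeps the stronger peak
  expect_identical(merged$n_colocalized, 2L)
  # opposite-direction overlap does not merge
  tab2 <- tab[1:2, ]; tab2$direction <- c(1, -1)
  expect_identical(nrow(collapse_colocalized(tab2)), 2L)
})
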