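# Interval mapping for fully inbred (RIL) populations: hidden-Markov
# genotype probabilities on a cM grid, Haley-Knott regression scans,
# permutation-based genome-wide LOD thresholds, iterative multi-QTL model
# search, percent variance explained, and LOD support intervals.

#' Read a genetic map CSV
#'
#' Expects columns `marker`, `chrom`, `pos_cm`; positions must be strictly
#' increasing within each chromosome and marker names unique.
#'
#' @param path CSV path.
#' @return data.frame with columns `marker`, `chrom`, `pos_cm`.
#' @export
read_genetic_map <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_map(map)
  map
}

validate_map <- function(map) {
  need <- c("marker", "chrom", "pos_cm")
  if (!all(need %in% names(map)))
    stop("map must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(map$marker))
    stop("duplicate marker names in map", call. = FALSE)
  bad <- tapply(map$pos_cm, map$chrom, function(p) any(diff(p) <= 0))
  if (any(unlist(bad)))
    stop("marker positions must be strictly increasing within chromosome",
         call. = FALSE)
  invisible(map)
}

#' Read a RIL genotype matrix CSV
#'
#' Rows are lines, first column `line`, remaining columns markers with
#' codes `AA`/`BB` (missing values allowed).  Heterozygote codes are not
#' expected in a fully inbred population and are treated as missing with
#' a warning.
#'
#' @param path CSV path.
#' @return Character matrix, lines x markers.
#' @export
read_ril_genotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  g <- as.matrix(df[, -1, drop = FALSE])
  rownames(g) <- df[[1]]
  bad <- !(g %in% c("AA", "BB") | is.na(g))
  if (any(bad)) {
    warning(sum(bad), " non-homozygote genotype codes treated as missing")
    g[bad] <- NA_character_
  }
  g
}

#' Genotype probabilities along a cM grid
#'
#' Two-state (homozygote classes only) hidden Markov chain along each
#' chromosome, with Haldane transition probabilities between consecutive
#' evaluation positions and a symmetric genotyping-error emission model:
#' an observed marker code equals the true state with probability
#' `1 - error_rate`.  Evaluation positions are the marker positions plus a
#' `step`-cM grid (the classical interval-mapping grid).
#'
#' @param map Genetic map data.frame (`marker`, `chrom`, `pos_cm`).
#' @param genotypes Character matrix lines x markers, codes `AA`/`BB`/NA.
#' @param step Grid step in cM (default 1).
#' @param error_rate Genotyping error probability (default 0.001).
#' @return A `geno_probs` object: list with `grid` (chrom, pos_cm, marker),
#'   `probAA` (lines x positions matrix of P(AA)), `lines`, `step`,
#'   `error_rate`.
#' @export
genotype_probabilities <- function(map, genotypes, step = 1,
                                   error_rate = 0.001) {
  validate_map(map)
  if (!all(map$marker %in% colnames(genotypes)))
    stop("genotype matrix lacks some mapped markers", call. = FALSE)
  lines <- rownames(genotypes)
  n <- nrow(genotypes)
  grids <- list(); probs <- list()
  for (ch in unique(map$chrom)) {
    mch <- map[map$chrom == ch, , drop = FALSE]
    pos <- sort(unique(c(mch$pos_cm,
                         seq(min(mch$pos_cm), max(mch$pos_cm), by = step))))
    mk <- mch$marker[match(pos, mch$pos_cm)]
    P <- length(pos)
    # emission likelihoods per position: n x 2 (AA, BB), 1 where no marker
    emitAA <- matrix(1, n, P); emitBB <- matrix(1, n, P)
    for (j in which(!is.na(mk))) {
      obs <- genotypes[, mk[j]]
      eAA <- ifelse(is.na(obs), 1, ifelse(obs == "AA", 1 - error_rate,
                                          error_rate))
      eBB <- ifelse(is.na(obs), 1, ifelse(obs == "BB", 1 - error_rate,
                                          error_rate))
      emitAA[, j] <- eAA; emitBB[, j] <- eBB
    }
    rf <- haldane_rf(diff(pos))
    # forward-backward, vectorized over lines
    fAA <- matrix(NA_real_, n, P); fBB <- matrix(NA_real_, n, P)
    fAA[, 1] <- 0.5 * emitAA[, 1]; fBB[, 1] <- 0.5 * emitBB[, 1]
    sc <- fAA[, 1] + fBB[, 1]
    fAA[, 1] <- fAA[, 1] / sc; fBB[, 1] <- fBB[, 1] / sc
    if (P > 1) for (j in 2:P) {
      r <- rf[j - 1]
      aa <- (fAA[, j - 1] * (1 - r) + fBB[, j - 1] * r) * emitAA[, j]
      bb <- (fAA[, j - 1] * r + fBB[, j - 1] * (1 - r)) * emitBB[, j]
      sc <- aa + bb
      fAA[, j] <- aa / sc; fBB[, j] <- bb / sc
    }
    bAA <- matrix(1, n, P); bBB <- matrix(1, n, P)
    if (P > 1) for (j in (P - 1):1) {
      r <- rf[j]
      nAA <- bAA[, j + 1] * emitAA[, j + 1]
      nBB <- bBB[, j + 1] * emitBB[, j + 1]
      aa <- (1 - r) * nAA + r * nBB
      bb <- r * nAA + (1 - r) * nBB
      sc <- aa + bb
      bAA[, j] <- aa / sc; bBB[, j] <- bb / sc
    }
    pAA <- fAA * bAA / (fAA * bAA + fBB * bBB)
    grids[[as.character(ch)]] <- data.frame(chrom = ch, pos_cm = pos,
                                            marker = mk)
    probs[[as.character(ch)]] <- pAA
  }
  grid <- do.call(rbind, grids); rownames(grid) <- NULL
  probAA <- do.call(cbind, probs)
  dimnames(probAA) <- list(lines, paste0("c", grid$chrom, "_", grid$pos_cm))
  structure(list(grid = grid, probAA = probAA, lines = lines, step = step,
                 error_rate = error_rate),
            class = "geno_probs")
}

#' Expected signed allele dosage
#'
#' Per line and evaluation position, `P(AA) - P(BB)` in `[-1, 1]`
#' (+1 = homozygous for the first-parent, IMB211-like allele).
#'
#' @param probs A `geno_probs` object.
#' @return Numeric matrix, lines x positions.
#' @export
expected_dosage <- function(probs) 2 * probs$probAA - 1

# Core LOD machinery: residualize a phenotype matrix and dosage matrix on
# covariates (Frisch-Waugh), then LOD = -(n/2) log10(1 - r^2) per
# position/phenotype pair.
lod_matrix <- function(D, Y, X = NULL) {
  n <- nrow(D)
  if (!is.null(X)) {
    qr_x <- qr(cbind(1, X))
    D <- qr.resid(qr_x, D)
    Y <- qr.resid(qr_x, Y)
  } else {
    D <- sweep(D, 2, colMeans(D))
    Y <- sweep(Y, 2, colMeans(Y))
  }
  dn <- sqrt(colSums(D^2)); yn <- sqrt(colSums(Y^2))
  r2 <- (crossprod(D, Y) / outer(dn, yn))^2
  r2[!is.finite(r2)] <- 0           # monomorphic position: no information
  r2 <- pmin(r2, 1 - 1e-12)
  -(n / 2) * log10(1 - r2)
}

align_phenotype <- function(probs, phenotypes) {
  if (is.null(names(phenotypes)))
    stop("'phenotypes' must be named by line", call. = FALSE)
  common <- intersect(probs$lines, names(phenotypes)[!is.na(phenotypes)])
  if (length(common) < 3)
    stop("fewer than 3 informative lines", call. = FALSE)
  list(idx = match(common, probs$lines), y = unname(phenotypes[common]))
}

#' Haley-Knott genome scan
#'
#' At every evaluation position, regresses the phenotype on the expected
#' signed allele dosage; `LOD = (n/2) log10(RSS0 / RSS1)` against the
#' intercept-only null (or the covariate model when `covariates` are
#' given, yielding a conditional scan).
#'
#' @param probs A `geno_probs` object from [genotype_probabilities()].
#' @param phenotypes Named numeric vector of line (genotype) means.
#' @param covariates Optional numeric matrix of covariates (rows aligned
#'   with `probs$lines`), e.g. dosages of already-modeled QTL.
#' @return A `qtl_scan` data.frame: `chrom`, `pos_cm`, `marker`, `lod`;
#'   the number of lines used is attached as attribute `n`.
#' @export
scan_hk <- function(probs, phenotypes, covariates = NULL) {
  al <- align_phenotype(probs, phenotypes)
  D <- expected_dosage(probs)[al$idx, , drop = FALSE]
  X <- if (!is.null(covariates)) covariates[al$idx, , drop = FALSE]
  lod <- lod_matrix(D, matrix(al$y), X)[, 1]
  out <- cbind(probs$grid, lod = pmax(lod, 0))
  attr(out, "n") <- length(al$y)
  class(out) <- c("qtl_scan", "data.frame")
  out
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the phenotype-to-line assignment, records the genome-wide
#' maximum Haley-Knott LOD for each permutation, and returns the requested
#' quantile of that null distribution.
#'
#' @inheritParams scan_hk
#' @param n_perm Number of permutations (>= 100).
#' @param quantile Null-quantile defining the threshold (0.95 for mapping,
#'   0.90 for the prediction pipeline).
#' @param seed RNG seed for reproducible permutations.
#' @return Threshold LOD (numeric scalar); the vector of permutation
#'   maxima is attached as attribute `max_lods`.
#' @export
permutation_threshold <- function(probs, phenotypes, n_perm = 1000,
                                  quantile = 0.95, seed = 1L,
                                  covariates = NULL) {
  if (n_perm < 100) stop("'n_perm' must be at least 100", call. = FALSE)
  al <- align_phenotype(probs, phenotypes)
  D <- expected_dosage(probs)[al$idx, , drop = FALSE]
  X <- if (!is.null(covariates)) covariates[al$idx, , drop = FALSE]
  set.seed(seed)
  Y <- replicate(n_perm, sample(al$y))
  maxima <- apply(lod_matrix(D, Y, X), 2, max)
  out <- unname(stats::quantile(maxima, quantile))
  attr(out, "max_lods") <- maxima
  out
}

#' Percent variance explained from a LOD score
#'
#' `PVE = 100 * (1 - 10^(-2 * LOD / n))` where `n` is the number of
#' genotypes in the mapping population.
#'
#' @param lod LOD score (>= 0).
#' @param n Number of genotypes (>= 1).
#' @return Percent variance explained, in `[0, 100)`.
#' @export
pve_from_lod <- function(lod, n) {
  if (any(n < 1)) stop("'n' must be at least 1", call. = FALSE)
  if (any(lod < 0)) stop("'lod' must be non-negative", call. = FALSE)
  100 * (1 - 10^(-2 * lod / n))
}

#' Inverse of [pve_from_lod()]
#'
#' @param pve Percent variance explained, in `[0, 100)`.
#' @param n Number of genotypes.
#' @return LOD score.
#' @export
lod_from_pve <- function(pve, n) -(n / 2) * log10(1 - pve / 100)

#' LOD support interval around a peak
#'
#' The widest contiguous run of evaluated positions around the peak whose
#' LOD stays within `drop` of the peak LOD; the interval endpoints are the
#' outermost evaluated positions meeting that criterion.
#'
#' @param scan A `qtl_scan` data.frame (possibly restricted to one
#'   chromosome).
#' @param chrom Chromosome holding the peak.
#' @param peak_pos Peak position in cM.
#' @param drop LOD drop defining the support interval (default 1.5).
#' @return Numeric vector `c(lo, hi)` in cM.
#' @export
lod_support_interval <- function(scan, chrom, peak_pos, drop = 1.5) {
  s <- scan[scan$chrom == chrom, , drop = FALSE]
  s <- s[order(s$pos_cm), ]
  ip <- which.min(abs(s$pos_cm - peak_pos))
  thresh <- s$lod[ip] - drop
  ok <- s$lod >= thresh
  lo <- ip; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- ip; while (hi < nrow(s) && ok[hi + 1]) hi <- hi + 1
  c(lo = s$pos_cm[lo], hi = s$pos_cm[hi])
}

#' Iterative multi-QTL model search
#'
#' Forward search in the spirit of iterative `scanone`/`addqtl`/
#' `refineqtl` model building: starting from the genome scan, repeatedly
#' add the highest peak exceeding the threshold in a scan conditional on
#' the dosages of the QTL already in the model (conditioning by
#' residualization, keeping the Haley-Knott regression approximation
#' throughout), refine each locus position by maximizing the conditional
#' LOD on its chromosome holding the others fixed, and stop when no new
#' peak passes.  Ties at equal LOD break to the lowest chromosome, then
#' lowest cM.
#'
#' The final multi-locus fit reports, per locus: the drop-one-term LOD,
#' the additive effect (half the difference between homozygote class
#' means), its direction (+1 when the first-parent, IMB211-like allele
#' increases the trait), the percent variance explained from the drop-one
#' LOD, and the 1.5-LOD support interval from the locus's conditional
#' scan.
#'
#' @inheritParams scan_hk
#' @param threshold LOD threshold a new peak must exceed.
#' @param drop LOD drop for support intervals (default 1.5).
#' @param max_qtl Safety cap on model size.
#' @return A `qtl_model` object: data.frame of loci (`chrom`, `pos_cm`,
#'   `marker`, `lod`, `effect`, `direction`, `pve`, `ci_lo`, `ci_hi`)
#'   with attributes `model_lod` (full-model LOD), `n`, `threshold`, and
#'   `mean` (fitted population mean).
#' @export
stepwise_qtl_search <- function(probs, phenotypes, threshold, drop = 1.5,
                                max_qtl = 10) {
  al <- align_phenotype(probs, phenotypes)
  D <- expected_dosage(probs)[al$idx, , drop = FALSE]
  y <- al$y
  grid <- probs$grid
  n <- length(y)

  pick_peak <- function(lod) {
    best <- max(lod)
    cand <- which(lod >= best - 1e-9)
    cand[order(grid$chrom[cand], grid$pos_cm[cand])][1]
  }

  sel <- integer(0)
  repeat {
    X <- if (length(sel)) D[, sel, drop = FALSE]
    lod <- lod_matrix(D, matrix(y), X)[, 1]
    if (length(sel)) lod[sel] <- 0
    peak <- pick_peak(lod)
    if (lod[peak] <= threshold || length(sel) >= max_qtl) break
    sel <- c(sel, peak)
    # refine each locus holding the others fixed (up to 3 sweeps)
    for (sweep_i in 1:3) {
      moved <- FALSE
      for (k in seq_along(sel)) {
        others <- sel[-k]
        X <- if (length(others)) D[, others, drop = FALSE]
        ch <- grid$chrom[sel[k]]
        on_ch <- which(grid$chrom == ch)
        lod_ch <- lod_matrix(D[, on_ch, drop = FALSE], matrix(y), X)[, 1]
        new_pos <- on_ch[pick_peak_local(lod_ch, grid[on_ch, ])]
        if (new_pos != sel[k]) { sel[k] <- new_pos; moved <- TRUE }
      }
      if (!moved) break
    }
  }

  if (!length(sel)) {
    out <- data.frame(chrom = integer(0), pos_cm = numeric(0),
                      marker = character(0), lod = numeric(0),
                      effect = numeric(0), direction = numeric(0),
                      pve = numeric(0), ci_lo = numeric(0),
                      ci_hi = numeric(0))
    attr(out, "model_lod") <- 0
    attr(out, "n") <- n
    attr(out, "threshold") <- threshold
    attr(out, "mean") <- mean(y)
    class(out) <- c("qtl_model", "data.frame")
    return(out)
  }

  sel <- sel[order(grid$chrom[sel], grid$pos_cm[sel])]
  Dm <- D[, sel, drop = FALSE]
  fit_full <- stats::lm.fit(cbind(1, Dm), y)
  rss_full <- sum(fit_full$residuals^2)
  rss_null <- sum((y - mean(y))^2)
  model_lod <- (n / 2) * log10(rss_null / rss_full)
  betas <- fit_full$coefficients[-1]

  loci <- lapply(seq_along(sel), function(k) {
    others <- Dm[, -k, drop = FALSE]
    rss_wo <- sum(stats::lm.fit(cbind(1, others), y)$residuals^2)
    lod_k <- (n / 2) * log10(rss_wo / rss_full)
    X <- if (ncol(others)) others
    ch <- grid$chrom[sel[k]]
    on_ch <- which(grid$chrom == ch)
    cond <- cbind(grid[on_ch, c("chrom", "pos_cm")],
                  lod = lod_matrix(D[, on_ch, drop = FALSE],
                                   matrix(y), X)[, 1])
    ci <- lod_support_interval(cond, ch, grid$pos_cm[sel[k]], drop)
    nearest <- grid$marker[on_ch][
      which.min(abs(grid$pos_cm[on_ch] - grid$pos_cm[sel[k]]) +
                  ifelse(is.na(grid$marker[on_ch]), 1e6, 0))]
    data.frame(chrom = ch, pos_cm = grid$pos_cm[sel[k]], marker = nearest,
               lod = lod_k, effect = abs(betas[k]),
               direction = sign(betas[k]),
               pve = pve_from_lod(lod_k, n),
               ci_lo = unname(ci["lo"]), ci_hi = unname(ci["hi"]))
  })
  out <- do.call(rbind, loci); rownames(out) <- NULL
  attr(out, "model_lod") <- model_lod
  attr(out, "n") <- n
  attr(out, "threshold") <- threshold
  attr(out, "mean") <- unname(fit_full$coefficients[1])
  class(out) <- c("qtl_model", "data.frame")
  out
}

pick_peak_local <- function(lod, grid_ch) {
  best <- max(lod)
  cand <- which(lod >= best - 1e-9)
  cand[order(grid_ch$pos_cm[cand])][1]
}

#' Collapse colocalizing QTL
#'
#' Reporting rule for QTL mapped for the same trait across environments:
#' loci whose 1.5-LOD support intervals overlap on the same chromosome and
#' whose effects have the same direction are collapsed to a single
#' reported QTL (the one with the highest LOD).
#'
#' @param qtl_table data.frame with at least `chrom`, `pos_cm`, `lod`,
#'   `direction`, `ci_lo`, `ci_hi` (rows may come from different scans).
#' @return The collapsed data.frame, one row per reported QTL, with a
#'   `n_colocalized` count column.
#' @export
collapse_colocalized <- function(qtl_table) {
  if (!nrow(qtl_table)) return(cbind(qtl_table, n_colocalized = integer(0)))
  qtl_table <- qtl_table[order(qtl_table$chrom, qtl_table$ci_lo), ]
  grp <- integer(nrow(qtl_table)); g <- 0L
  for (i in seq_len(nrow(qtl_table))) {
    assigned <- FALSE
    if (i > 1) for (j in which(grp[seq_len(i - 1)] > 0)) {
      same <- qtl_table$chrom[j] == qtl_table$chrom[i] &&
        qtl_table$direction[j] == qtl_table$direction[i] &&
        qtl_table$ci_lo[i] <= qtl_table$ci_hi[j] &&
        qtl_table$ci_hi[i] >= qtl_table$ci_lo[j]
      if (same) { grp[i] <- grp[j]; assigned <- TRUE; break }
    }
    if (!assigned) { g <- g + 1L; grp[i] <- g }
  }
  keep <- vapply(split(seq_len(nrow(qtl_table)), grp), function(ix)
    ix[which.max(qtl_table$lod[ix])], integer(1))
  out <- qtl_table[keep, , drop = FALSE]
  out$n_colocalized <- as.integer(table(grp))
  rownames(out) <- NULL
  out
}

#' Write a QTL scan or model to CSV
#'
#' @param x A `qtl_scan` or `qtl_model` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_qtl_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
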