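# Trait-level statistics ahead of QTL mapping: the 3-SD outlier rule,
# shrinkage (BLUP) genotype means controlling for block, and
# likelihood-ratio chi-square tests for random effects (the variance-
# partitioning analysis behind the plasticity tables).

#' Single-pass 3-SD outlier filter
#'
#' Removes observations more than `k` standard deviations from the mean,
#' with mean and SD computed once from the full input (a single pass; the
#' filter is deliberately not iterated).  With zero SD nothing is removed.
#'
#' @param values Numeric trait vector (length >= 2; NAs are kept).
#' @param k SD multiple defining an outlier (default 3).
#' @return List with `retained` (values with outliers dropped),
#'   `removed_idx` (integer indices into the input) and `removed`
#'   (the dropped values).
#' @export
filter_outliers <- function(values, k = 3) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(values, na.rm = TRUE)
  s <- stats::sd(values, na.rm = TRUE)
  out <- if (is.na(s) || s == 0) logical(length(values)) else
    !is.na(values) & abs(values - m) > k * s
  list(retained = values[!out], removed_idx = which(out),
       removed = values[out])
}

#' Shrinkage genotype means (BLUPs) controlling for block
#'
#' Fits the two-random-factor intercept model
#' `trait ~ 1 + (1 | genotype) + (1 | block)` by REML (through lme4) and
#' returns per-genotype shrinkage means: the fitted grand mean plus the
#' genotype's conditional mode.  In the balanced case the shrinkage
#' factor is \eqn{\lambda_i = \sigma^2_g / (\sigma^2_g + \sigma^2_e /
#' m_i)} toward the grand mean.
#'
#' @param data data.frame with columns named by `trait_col`, `genotype`
#'   and (optionally) `block`.
#' @param trait_col Name of the trait column (default `"value"`).
#' @return List with `means` (data.frame: genotype, shrunken_mean,
#'   raw_mean, n_rep), `varcomp` (named variance components) and
#'   `grand_mean`.
#' @export
estimate_genotype_means <- function(data, trait_col = "value") {
  if (!all(c("genotype", trait_col) %in% names(data)))
    stop("data must have 'genotype' and '", trait_col, "' columns",
         call. = FALSE)
  if (length(unique(data$genotype)) < 2)
    stop("need at least 2 genotypes", call. = FALSE)
  data$.y <- data[[trait_col]]
  has_block <- "block" %in% names(data) && length(unique(data$block)) >= 2
  form <- if (has_block) .y ~ 1 + (1 | genotype) + (1 | block)
          else .y ~ 1 + (1 | genotype)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = data, REML = TRUE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- stats::setNames(vc$vcov, vc$grp)
  grand <- unname(lme4::fixef(fit)[1])
  blup <- lme4::ranef(fit)$genotype
  raw <- tapply(data$.y, data$genotype, mean, na.rm = TRUE)
  nrep <- tapply(!is.na(data$.y), data$genotype, sum)
  genos <- rownames(blup)
  means <- data.frame(genotype = genos,
                      shrunken_mean = grand + blup[, 1],
                      raw_mean = as.numeric(raw[genos]),
                      n_rep = as.integer(nrep[genos]))
  rownames(means) <- NULL
  list(means = means, varcomp = varcomp, grand_mean = grand)
}

# Build an lmer formula from random-effect term labels such as
# "genotype", "genotype:year", "block".
re_formula <- function(terms, response = ".y") {
  rhs <- paste(sprintf("(1 | %s)", terms), collapse = " + ")
  stats::as.formula(paste(response, "~ 1 +", rhs))
}

#' Likelihood-ratio test for a random effect
#'
#' Compares REML fits of a random-intercept model with and without one
#' random term: `chi-square = 2 (logLik_full - logLik_reduced)` with one
#' degree of freedom per dropped variance component, and an upper-tail
#' chi-square p-value.  (The boundary-at-zero null makes this
#' conservative; the df convention matches standard random-effect
#' likelihood-ratio reporting.)
#'
#' @param data data.frame containing the response and grouping columns.
#' @param full_terms Character vector of random-term labels for the full
#'   model, e.g. `c("genotype", "block", "genotype:year")`.
#' @param drop_term The term to remove (must be in `full_terms`).
#' @param trait_col Response column name (default `"value"`).
#' @return data.frame with `effect`, `chisq`, `df`, `p_value`.
#' @export
test_random_effect <- function(data, full_terms, drop_term,
                               trait_col = "value") {
  if (!drop_term %in% full_terms)
    stop("'drop_term' must be one of 'full_terms' (nested models required)",
         call. = FALSE)
  data$.y <- data[[trait_col]]
  for (v in unique(unlist(strsplit(full_terms, ":", fixed = TRUE))))
    data[[v]] <- factor(data[[v]])
  reduced_terms <- setdiff(full_terms, drop_term)
  if (!length(reduced_terms))
    stop("cannot drop the only random term", call. = FALSE)
  fit_full <- suppressMessages(suppressWarnings(
    lme4::lmer(re_formula(full_terms), data = data, REML = TRUE)))
  fit_red <- suppressMessages(suppressWarnings(
    lme4::lmer(re_formula(reduced_terms), data = data, REML = TRUE)))
  chisq <- max(0, 2 * (as.numeric(stats::logLik(fit_full)) -
                         as.numeric(stats::logLik(fit_red))))
  df <- 1L
  data.frame(effect = drop_term, chisq = chisq, df = df,
             p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Random-effect test report for the full plasticity model
#'
#' Runs [test_random_effect()] for every random term of the crossed
#' design (block nested in year x treatment; genotype, treatment, year
#' and their interactions), producing the familiar effect / chi-square /
#' df / significance-code table.
#'
#' @param data data.frame with `value`, `genotype`, `treatment`, `year`,
#'   `block` columns.
#' @param terms Random-term labels of the full model; the default is the
#'   7-term crossed/nested layout.
#' @param trait_col Response column name.
#' @return data.frame with one row per tested term plus a `signif` code
#'   column (`***`, `**`, `*`, `.`, `NS`).
#' @export
plasticity_test_table <- function(data,
                                  terms = c("block", "treatment", "year",
                                            "genotype", "treatment:year",
                                            "genotype:treatment",
                                            "genotype:year",
                                            "genotype:treatment:year"),
                                  trait_col = "value") {
  rows <- lapply(terms, function(tm)
    test_random_effect(data, terms, tm, trait_col = trait_col))
  out <- do.call(rbind, rows)
  out$signif <- cut(out$p_value, c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
                    labels = c("***", "**", "*", ".", "NS"))
  out
}
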