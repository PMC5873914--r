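# QTL-by-environment interaction tests: fixed-effect linear models of a
# trait on marker genotype, density treatment, growing season and their
# interactions, with Type III (marginal) F statistics.  Sum-to-zero
# contrasts are enforced -- Type III tests are not meaningful under
# treatment contrasts.

#' Type III F tests for a fixed-effect model
#'
#' Fits the full crossed model under sum-to-zero contrasts and computes,
#' for each requested term, the marginal (Type III) F statistic
#' \deqn{F = ((RSS_{-term} - RSS_{full}) / \Delta df) /
#'       (RSS_{full} / df_{resid})}
#' where the reduced model removes only that term's model-matrix columns
#' while keeping every other term, including higher-order interactions.
#'
#' Terms whose columns are aliased in the full fit (empty design cells)
#' are flagged `estimable = FALSE` and skipped.
#'
#' @param formula Model formula, e.g. `value ~ qtl * treatment * year`.
#' @param data data.frame with the response and factor columns.
#' @param terms Character vector of term labels to test; default all
#'   terms in the formula.
#' @return data.frame: `term`, `F`, `df1`, `df2`, `p_value`, `estimable`.
#' @export
type3_tests <- function(formula, data, terms = NULL) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  # sum-to-zero contrasts for every factor, enforced (characters coerced)
  for (j in seq_along(mf)) if (is.character(mf[[j]])) mf[[j]] <- factor(mf[[j]])
  contr <- lapply(Filter(is.factor, mf), function(f) "contr.sum")
  mm <- stats::model.matrix(formula, mf, contrasts.arg = contr)
  asgn <- attr(mm, "assign")
  labels <- attr(stats::terms(formula, data = data), "term.labels")
  if (is.null(terms)) terms <- labels

  fit_full <- stats::lm.fit(mm, y)
  aliased <- is.na(fit_full$coefficients)
  rss_full <- sum(fit_full$residuals^2)
  df_resid <- length(y) - sum(!aliased)

  rows <- lapply(terms, function(tm) {
    ti <- match(tm, labels)
    if (is.na(ti)) stop("term not in model: ", tm, call. = FALSE)
    cols <- which(asgn == ti)
    if (!length(cols) || any(aliased[cols]))
      return(data.frame(term = tm, F = NA_real_, df1 = NA_integer_,
                        df2 = df_resid, p_value = NA_real_,
                        estimable = FALSE))
    fit_red <- stats::lm.fit(mm[, -cols, drop = FALSE], y)
    rss_red <- sum(fit_red$residuals^2)
    df1 <- length(cols)
    Fval <- ((rss_red - rss_full) / df1) / (rss_full / df_resid)
    data.frame(term = tm, F = Fval, df1 = df1, df2 = df_resid,
               p_value = stats::pf(Fval, df1, df_resid, lower.tail = FALSE),
               estimable = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' QTL-by-environment interaction ANOVA at one marker
#'
#' Fits the full crossed fixed-effect model of the trait on the marker
#' genotype and the environmental factors present in the data (density
#' treatment and/or year), and reports Type III F tests for the
#' interaction terms involving the marker: treatment x QTL, year x QTL
#' and, when both factors are present, treatment x year x QTL.  Markers
#' are tested one at a time (one detected QTL per call).
#'
#' @param data data.frame with a trait column, a marker-genotype column,
#'   and `treatment` and/or `year` factor columns (>= 2 levels each for
#'   the terms involving them).
#' @param marker_col Name of the marker genotype column.
#' @param trait_col Name of the trait column (default `"value"`).
#' @return data.frame of `interaction_test` rows: `marker`, `term`, `F`,
#'   `df1`, `df2`, `p_value`, `signif`, `estimable`.
#' @export
marker_env_anova <- function(data, marker_col, trait_col = "value") {
  if (!marker_col %in% names(data))
    stop("no column '", marker_col, "' in data", call. = FALSE)
  d <- data.frame(value = data[[trait_col]],
                  qtl = factor(data[[marker_col]]))
  env <- intersect(c("treatment", "year"), names(data))
  env <- env[vapply(env, function(v)
    length(unique(data[[v]])) >= 2, logical(1))]
  if (!length(env))
    stop("need at least one environmental factor with 2+ levels",
         call. = FALSE)
  for (v in env) d[[v]] <- factor(data[[v]])
  rhs <- paste(c("qtl", env), collapse = " * ")
  form <- stats::as.formula(paste("value ~", rhs))
  want <- c(if ("treatment" %in% env) "qtl:treatment",
            if ("year" %in% env) "qtl:year",
            if (all(c("treatment", "year") %in% env)) "qtl:treatment:year")
  out <- type3_tests(form, d, terms = want)
  out$signif <- cut(out$p_value, c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
                    labels = c("***", "**", "*", ".", "NS"))
  term_names <- c("qtl:treatment" = "treat_x_qtl", "qtl:year" = "year_x_qtl",
                  "qtl:treatment:year" = "year_x_qtl_x_treat")
  out$term <- unname(term_names[out$term])
  cbind(marker = marker_col, out)
}

#' QTL-by-environment report across a QTL table
#'
#' Runs [marker_env_anova()] for every locus in a QTL model table (using
#' the genotype codes at each locus's nearest marker), producing the
#' trait / marker / term / F / p report shape used for interaction
#' summaries.
#'
#' @param data Plant- or genotype-level trait table with `genotype`,
#'   `treatment`/`year` and trait columns.
#' @param qtl_table data.frame with a `marker` column (e.g. a
#'   `qtl_model`).
#' @param genotypes Marker genotype matrix (lines x markers).
#' @param trait_col Trait column in `data`.
#' @param trait Label copied into the report.
#' @return Combined data.frame of interaction tests, one block per
#'   marker.
#' @export
qtl_env_report <- function(data, qtl_table, genotypes,
                           trait_col = "value", trait = trait_col) {
  rows <- lapply(unique(qtl_table$marker), function(mk) {
    d <- data[as.character(data$genotype) %in% rownames(genotypes), ,
              drop = FALSE]   # parents / unmapped lines carry no genotype
    d$.marker_geno <- genotypes[as.character(d$genotype), mk]
    d <- d[!is.na(d$.marker_geno), , drop = FALSE]
    out <- marker_env_anova(d, ".marker_geno", trait_col = trait_col)
    out$marker <- mk
    out
  })
  cbind(trait = trait, do.call(rbind, rows))
}
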