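#!/usr/bin/env Rscript
# Stage 3: trait-level statistics on the fitted FVT parameters --
# 3-SD outlier screening, shrinkage (BLUP) genotype means per
# environment controlling for block, and the random-effects
# likelihood-ratio table testing genotype, environment and their
# interactions (the phenotypic-plasticity analysis).

suppressPackageStartupMessages(library(fvtqtl))

fvt_dir <- "results/fvt"
out_dir <- "results/traits"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

files <- list.files(fvt_dir, "^plant_params_.*csv$", full.names = TRUE)
plants <- do.call(rbind, lapply(files, read.csv))
plants$block <- {
  # recover block labels from the simulated phenotype table
  ph <- read.csv("results/sim/phenotypes.csv")
  ph$block[match(plants$plant_id, ph$plant_id)]
}

params <- c("r", "Lmax", "L0")

## outlier screen (per trait x environment), single pass
kept <- list()
for (p in params) {
  for (yr in unique(plants$year)) for (trt in unique(plants$treatment)) {
    sel <- plants$year == yr & plants$treatment == trt
    f <- filter_outliers(plants[[p]][sel])
    if (length(f$removed_idx))
      cat(sprintf("outliers removed for %s %s %s: %d\n", p, trt, yr,
                  length(f$removed_idx)))
    d <- plants[sel, ][setdiff(seq_len(sum(sel)), f$removed_idx), ]
    kept[[paste(p, yr, trt)]] <- d
  }
}

## BLUP genotype means per environment
blup_rows <- list()
for (p in params) for (yr in unique(plants$year))
  for (trt in unique(plants$treatment)) {
    d <- kept[[paste(p, yr, trt)]]
    d$value <- d[[p]]
    est <- estimate_genotype_means(d)
    blup_rows[[paste(p, yr, trt)]] <- data.frame(
      param = p, year = yr, treatment = trt, est$means)
  }
blups <- do.call(rbind, blup_rows)
write.csv(blups, file.path(out_dir, "genotype_means.csv"), row.names = FALSE)
cat(sprintf("wrote BLUP genotype means: %d rows\n", nrow(blups)))

## random-effect likelihood-ratio tests (plasticity table shape)
tabs <- list()
for (p in c("r", "Lmax")) {
  d <- plants
  d$value <- d[[p]]
  tab <- plasticity_test_table(d)
  tab$param <- p
  tabs[[p]] <- tab
  cat(sprintf("\n%s random-effect tests:\n", p))
  print(tab[, c("effect", "chisq", "df", "p_value", "signif")],
        row.names = FALSE)
}
write.csv(do.call(rbind, tabs), file.path(out_dir, "plasticity_tests.csv"),
          row.names = FALSE)
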