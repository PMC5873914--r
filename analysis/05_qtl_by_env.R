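#!/usr/bin/env Rscript
# Stage 5: QTL-by-environment interactions -- for each mapped locus,
# Type III F tests of treatment x QTL, year x QTL and the three-way
# interaction on plant-level parameter estimates (sum-to-zero
# contrasts, marker fitted one locus at a time).

suppressPackageStartupMessages(library(fvtqtl))

out_dir <- "results/qtl_env"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

genos <- read_ril_genotypes("results/sim/genotypes.csv")
qtl_tab <- read.csv("results/qtl/qtl_table.csv")
files <- list.files("results/fvt", "^plant_params_.*csv$", full.names = TRUE)
plants <- do.call(rbind, lapply(files, read.csv))

reports <- list()
for (p in c("r", "Lmax")) {
  sub <- qtl_tab[grepl(paste0("_", p, "$"), qtl_tab$trait), ]
  if (!nrow(sub)) next
  d <- plants
  d$value <- d[[p]]
  rep_p <- qtl_env_report(d, sub, genos, trait = p)
  reports[[p]] <- rep_p
  cat(sprintf("\n%s QTL x environment (Type III):\n", p))
  print(rep_p[, c("marker", "term", "F", "df1", "df2", "p_value", "signif")],
        row.names = FALSE)
}

out <- do.call(rbind, reports)
write.csv(out, file.path(out_dir, "qtl_env_tests.csv"), row.names = FALSE)
sig <- out[!is.na(out$p_value) & out$p_value < 0.05, ]
cat(sprintf("\n%d of %d interaction tests significant at 0.05\n",
            nrow(sig), sum(!is.na(out$p_value))))
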