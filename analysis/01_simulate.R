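#!/usr/bin/env Rscript
# Stage 1: generate the synthetic RIL study used by the downstream
# analysis scripts -- a biparental RIL population with an additive QTL
# architecture on the logistic leaf-growth parameters, measured in two
# density treatments across two seasons with randomized blocks on a
# degree-day axis.
#
# Scale: 40 lines, 5 chromosomes, 2-3 blocks per environment.  This is a
# deliberately reduced rendition of the full design (119 lines, 10
# chromosomes) chosen so the whole analysis chain reruns in minutes;
# every downstream script consumes these tables.

suppressPackageStartupMessages(library(fvtqtl))

out_dir <- "results/sim"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(
  n_ril = 40, n_chrom = 5, markers_per_chrom = 10, chrom_length_cm = 80,
  years = c(2011, 2012), treatments = c("UN", "CR"),
  blocks_per_env = c("2011" = 2, "2012" = 3),
  seed = 2012)

mg <- simulate_map_genotypes(cfg)
sim <- simulate_phenotypes(mg, cfg)
paths <- write_sim_csvs(mg, sim, out_dir)

# persist the injected truth for later comparison
write.csv(sim$truth$qtl, file.path(out_dir, "truth_qtl.csv"),
          row.names = FALSE)
write.csv(sim$truth$geno_params, file.path(out_dir, "truth_geno_params.csv"),
          row.names = FALSE)
write.csv(sim$truth$plant_params, file.path(out_dir, "truth_plant_params.csv"),
          row.names = FALSE)

ph <- sim$phenotypes
cat("Simulated population written to", out_dir, "\n")
cat(sprintf("  %d lines x %d markers on %d chromosomes\n",
            nrow(mg$genotypes), ncol(mg$genotypes), cfg$n_chrom))
cat(sprintf("  %d plants, %d measurements (%.1f per plant)\n",
            length(unique(ph$plant_id)), nrow(ph),
            nrow(ph) / length(unique(ph$plant_id))))
cat("  injected QTL:\n")
print(sim$truth$qtl[, c("param", "marker", "chrom", "pos_cm",
                        "effect", "direction")])
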