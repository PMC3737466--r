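#!/usr/bin/env Rscript
# Stage 1: simulate the study's raw material.
#
# Three treatment-vs-control two-colour microarray comparisons whose
# responsive gene sets overlap through a shared latent pathway (emulating
# three inhibitors that converge on the same signalling route), plus a
# promoter set with a planted CRT/DRE core (CCGAC) in the up-regulated
# genes' promoters, and an expression compendium containing a few
# experiments correlated with the first treatment's response.

suppressPackageStartupMessages(library(crossarray))

out <- "results/simulation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- generator_config(
  n_probes = 4000, n_blocks = 8, n_bio_reps = 2, dye_swap = TRUE,
  treatments = c("plc_inhibitor", "pi4k_inhibitor", "dgk_inhibitor"),
  frac_regulated = 0.05, frac_shared = 0.7,
  effect_size_log2 = 2, noise_sd_log2 = 0.3, seed = 2026L)

message("simulating ", cfg$n_probes, " probes x ", length(cfg$treatments),
        " comparisons (4 hybridisations each)...")
sim <- simulate_experiment(cfg)
for (tr in names(sim$spots))
  write_spot_table(sim$spots[[tr]], file.path(out, paste0("spots_", tr, ".tsv")))
write.table(sim$truth, file.path(out, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

n_reg <- vapply(split(sim$truth$class != "NC", sim$truth$treatment),
                sum, integer(1))
message("truly regulated probes per treatment: ",
        paste(names(n_reg), n_reg, sep = "=", collapse = ", "))

message("simulating promoter sets (planted CCGAC at rate 0.5)...")
pro <- simulate_promoters(100, 5000, length = 1000, motif = "CCGAC",
                          plant_rate_fg = 0.5, plant_rate_bg = 0,
                          seed = 2027L)
Biostrings::writeXStringSet(pro$fg, file.path(out, "promoters_fg.fasta"))
Biostrings::writeXStringSet(pro$bg, file.path(out, "promoters_bg.fasta"))
write.table(pro$truth, file.path(out, "promoter_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("simulating a 50-experiment compendium (10% aligned columns)...")
eff <- setNames(sim$truth$effect[sim$truth$treatment == "plc_inhibitor"],
                sim$truth$probe[sim$truth$treatment == "plc_inhibitor"])
comp <- simulate_compendium(50, eff, correlated_fraction = 0.1,
                            noise_sd = 0.5, seed = 2028L)
write_compendium(comp, file.path(out, "compendium.tsv"))
writeLines(colnames(comp)[attr(comp, "correlated")],
           file.path(out, "compendium_planted_columns.txt"))

message("done; wrote ", out)
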