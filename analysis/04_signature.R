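#!/usr/bin/env Rscript
# Stage 4: transcriptome signature similarity ranking.
#
# Builds the top-200-up + top-200-down signature from the first treatment's
# differential calls and ranks every compendium experiment by Pearson
# correlation with the signature's log-ratios, checking that the planted
# correlated experiments surface at the top.

suppressPackageStartupMessages(library(crossarray))

out <- "results/signature"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

calls <- read.delim("results/de/de_plc_inhibitor.tsv")
comp <- read_compendium("results/simulation/compendium.tsv")
planted <- readLines("results/simulation/compendium_planted_columns.txt")

rk <- signature_rank(calls, comp, k = 200)
write.table(as.data.frame(rk), file.path(out, "signature_ranking.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

top <- rk$experiment[seq_along(planted)]
message("planted experiments: ", paste(sort(planted), collapse = ", "))
message("top-ranked experiments: ", paste(sort(top), collapse = ", "))
message("all planted experiments in the top ranks: ",
        setequal(top, planted))
print(head(as.data.frame(rk)[, c("experiment", "correlation", "rank")], 10))
message("done; wrote ", out)
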