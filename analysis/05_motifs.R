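#!/usr/bin/env Rscript
# Stage 5: promoter cis-element over-representation.
#
# Two parts. First, a demonstration of promoter extraction on a simulated
# genome + GFF annotation (up to 1000 bp upstream, truncated at neighbour
# genes and contig edges, 5'UTRs excluded). Second, the k-mer
# over-representation scan on the simulated promoter sets: every 4-10 bp
# word occurring in the foreground is tested by 2x2 chi-squared against
# the background, significant words are clustered into IUPAC consensus
# modules and matched against the packaged cis-element catalogue.

suppressPackageStartupMessages(library(crossarray))

out <- "results/motifs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("extracting promoters from a simulated genome + annotation...")
ga <- simulate_genome_annotation(n_genes = 60, contig_length = 120000,
                                 seed = 2029L)
ps <- extract_promoters(ga$genome, ga$annotation)
write.table(ps$info, file.path(out, "extracted_promoters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("extracted ", length(ps$sequences), " promoters; truncation: ",
        paste(names(table(ps$info$truncation)), table(ps$info$truncation),
              sep = "=", collapse = ", "))

message("scanning 4-10 bp words in the planted promoter sets...")
fg <- Biostrings::readDNAStringSet("results/simulation/promoters_fg.fasta")
bg <- Biostrings::readDNAStringSet("results/simulation/promoters_bg.fasta")
enr <- enumerate_and_test(fg, bg)
write.table(head(as.data.frame(enr), 2000),
            file.path(out, "motif_enrichment_top2000.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
sig <- enr[enr$significant, ]
message(nrow(enr), " candidate words tested; ", nrow(sig),
        " significant at p < 1e-5")
print(sig[, c("word", "fg_present", "bg_present", "chi2", "p")])

if (nrow(sig) > 0) {
  cl <- cluster_motifs(enr)
  mt <- match_catalogue(cl)
  modules <- merge(cl$clusters, mt, by = "consensus")
  write.table(cl$members, file.path(out, "motif_clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(modules, file.path(out, "motif_modules.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message("modules and closest catalogue entries:")
  print(modules[, c("cluster", "n_words", "consensus", "best_match",
                    "score")])
}
message("done; wrote ", out)
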