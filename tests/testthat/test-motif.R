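test_that("identical foreground and background yield no significant word", {
  pro <- simulate_promoters(40, 40, length = 300, plant_rate_fg = 0,
                            plant_rate_bg = 0, seed = 3)
  enr <- enumerate_and_test(pro$fg, pro$fg, lengths = 4:6)
  expect_false(any(enr$significant))
  expect_true(all(enr$fg_present == enr$bg_present))
  expect_true(all(enr$chi2 == 0))
})

test_that("2x2 chi-squared matches a hand-computed Pearson value", {
  ct <- crossarray:::chisq_2x2(50, 50, 500, 9500)
  expect_equal(ct$chi2, oracle_chisq_2x2(50, 50, 500, 9500),
               tolerance = 1e-12)
  # explicit arithmetic for the same table
  e11 <- 100 * 550 / 10100
  expect_gt(ct$chi2, (50 - e11)^2 / e11)
  expect_equal(ct$p, pchisq(ct$chi2, 1, lower.tail = FALSE))
})

test_that("a planted motif is recovered and all chi2 match the oracle", {
  pro <- simulate_promoters(60, 1500, length = 600, motif = "CCGAC",
                            plant_rate_fg = 0.7, plant_rate_bg = 0, seed = 5)
  enr <- enumerate_and_test(pro$fg, pro$bg, lengths = 4:7)
  cc <- enr[enr$word == "CCGAC", ]
  expect_equal(nrow(cc), 1L)
  expect_true(cc$significant)
  expect_lt(cc$p, 1e-5)
  # presence counts equal an exhaustive scan
  expect_equal(cc$fg_present,
               sum(oracle_presence(as.character(pro$fg), "CCGAC")))
  expect_equal(cc$bg_present,
               sum(oracle_presence(as.character(pro$bg), "CCGAC")))
  # chi-squared equals direct summation for every candidate word
  orc <- mapply(oracle_chisq_2x2, enr$fg_present, enr$fg_absent,
                enr$bg_present, enr$bg_absent)
  expect_lt(max(abs(enr$chi2 - orc)), 1e-9)
  # marginals are consistent
  expect_true(all(enr$fg_present + enr$fg_absent == 60))
  expect_true(all(enr$bg_present + enr$bg_absent == 1500))
})

test_that("word statistics are invariant under reverse-complementing inputs", {
  pro <- simulate_promoters(20, 50, length = 300, motif = "CCGAC",
                            plant_rate_fg = 0.5, seed = 7)
  enr1 <- enumerate_and_test(pro$fg, pro$bg, lengths = 4:5)
  rc <- function(x) Biostrings::reverseComplement(x)
  enr2 <- enumerate_and_test(rc(pro$fg), rc(pro$bg), lengths = 4:5)
  o1 <- enr1[order(enr1$word), ]
  o2 <- enr2[order(enr2$word), ]
  expect_identical(o1$word, o2$word)
  expect_identical(o1$fg_present, o2$fg_present)
  expect_identical(o1$bg_present, o2$bg_present)
  expect_equal(o1$chi2, o2$chi2, tolerance = 1e-12)
})

test_that("words with N never match and short promoters count as absent", {
  fg <- c(s1 = "ACGTNACGT", s2 = "AAAAAAAAA")
  bg <- c(b1 = "ACG")  # shorter than any 4-mer
  enr <- enumerate_and_test(fg, bg, lengths = 4, min_expected = 0)
  expect_false(any(grepl("N", enr$word)))
  expect_true(all(enr$bg_present == 0))
  # ACGTN...: only ACGT windows without N are candidates
  expect_true("AAAA" %in% enr$word)
  expect_false("GTNA" %in% enr$word)
})

test_that("null foreground draws stay within the test multiplicity", {
  false_pos <- integer(10)
  for (s in 1:10) {
    pro <- simulate_promoters(60, 1200, length = 500, motif = "CCGAC",
                              plant_rate_fg = 0, plant_rate_bg = 0,
                              seed = 300 + s)
    enr <- enumerate_and_test(pro$fg, pro$bg, lengths = 4:8)
    false_pos[s] <- sum(enr$significant)
  }
  # expectation under multiplicity: ~n_words x 1e-5 per seed
  expect_lte(mean(false_pos), 1.5)
})

test_that("similar words cluster into one module with a sensible consensus", {
  cl <- cluster_motifs(c("CCGAC", "CCGACA", "ACCGAC"))
  expect_equal(nrow(cl$clusters), 1L)
  expect_match(cl$clusters$consensus, "CCGAC")
  cl2 <- cluster_motifs(c("AAAAA", "CGCGT"))
  expect_equal(nrow(cl2$clusters), 2L)
  expect_equal(cl2$clusters$n_words, c(1L, 1L))
})

test_that("similarity is the best-offset match fraction over the overlap", {
  expect_equal(word_similarity("CCGAC", "CCGAC"), 1)
  expect_equal(word_similarity("CCGAC", "GTCGG"), 1)  # reverse complement
  expect_equal(word_similarity("CCGAC", "CCGAC", both_strands = FALSE), 1)
  # best admissible offset aligns the two AAA blocks plus one mismatch
  expect_equal(word_similarity("AAAAAA", "AAATTT"), 3 / 4)
  expect_equal(word_similarity("AAAA", "TTTT", both_strands = FALSE), 0)
})

test_that("greedy clustering equals an exhaustive-linkage oracle", {
  set.seed(19)
  words <- unique(vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), sample(5:8, 1), TRUE),
          collapse = ""), character(1)))
  cl <- cluster_motifs(words, threshold = 0.75)
  k <- length(words)
  adj <- matrix(FALSE, k, k)
  for (i in 1:k) for (j in 1:k) {
    adj[i, j] <- word_similarity(words[i], words[j]) >= 0.75
  }
  # transitive closure by repeated boolean multiplication
  reach <- adj | diag(TRUE, k)
  for (step in 1:k) reach <- reach | (reach %*% reach > 0)
  oracle_part <- apply(reach, 1, function(r) min(which(r)))
  got <- cl$members$cluster[match(words, cl$members$word)]
  expect_equal(length(unique(got)), length(unique(oracle_part)))
  expect_true(all(tapply(got, oracle_part, function(x)
    length(unique(x))) == 1))
})

test_that("cluster consensus uses IUPAC codes over aligned columns", {
  cl <- cluster_motifs(c("CACGTG", "CACGTT"))
  expect_equal(nrow(cl$clusters), 1L)
  expect_match(cl$clusters$consensus, "CACGT[KGT]")
})

test_that("catalogue matching is IUPAC-aware with alphabetical tie-breaks", {
  out <- match_catalogue("CCGAC")
  expect_true(out$matched)
  expect_identical(out$best_match, "CRT/DRE-like motif")
  out2 <- match_catalogue("CACGTG")
  expect_identical(out2$best_match, "ACGT element, G-box")
  expect_equal(out2$score, 1)
  # no admissible overlap -> unmatched
  out3 <- match_catalogue("TTT", catalogue = data.frame(
    name = "x", pattern = "GGGGGG"))
  expect_false(out3$matched)
  out4 <- match_catalogue("CCGAC", catalogue = data.frame(
    name = character(0), pattern = character(0)))
  expect_false(out4$matched)
  # ties flagged, first name alphabetically wins
  out5 <- match_catalogue("CACGTG", catalogue = data.frame(
    name = c("b-entry", "a-entry"), pattern = c("CACGTG", "CACGTG")))
  expect_true(out5$tie)
  expect_identical(out5$best_match, "a-entry")
})

test_that("promoters follow the upstream/truncation/strand rules", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep("ACGT", 2000), collapse = "")))
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1000, 2001, 2500, 4001), c(1500, 2400, 3000, 5000)),
    strand = c("+", "+", "-", "+"))
  gr$type <- "gene"
  gr$ID <- c("gA", "gB", "gC", "gD")
  ps <- extract_promoters(genome, gr, upstream = 1000)
  # gB starts at 2001 with gA ending at 1500: promoter 1501..2000
  b <- ps$info[ps$info$gene == "gB", ]
  expect_equal(c(b$start, b$end, b$length), c(1501, 2000, 500))
  expect_identical(b$truncation, "neighbor_overlap")
  # gC is minus-strand ending at 3000, next gene starts 4001:
  # promoter = reverse complement of 3001..4000
  cc <- ps$info[ps$info$gene == "gC", ]
  expect_equal(c(cc$start, cc$end, cc$length), c(3001, 4000, 1000))
  raw <- as.character(Biostrings::subseq(genome[[1]], 3001, 4000))
  expect_identical(as.character(ps$sequences[["gC"]]), revcomp(raw))
  # gA: upstream hits the contig start
  a <- ps$info[ps$info$gene == "gA", ]
  expect_equal(c(a$start, a$end, a$length), c(1, 999, 999))
  expect_identical(a$truncation, "contig_start")
})

test_that("annotated 5'UTRs shift the promoter anchor upstream", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep("ACGT", 1000), collapse = "")))
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(2001, 2001, 2001), c(3000, 3000, 2100)),
    strand = "+")
  gr$type <- c("gene", "mRNA", "five_prime_UTR")
  gr$ID <- c("g1", "g1.1", "g1.1.utr")
  gr$Parent <- IRanges::CharacterList(list(character(0), "g1", "g1.1"))
  ps <- extract_promoters(genome, gr, upstream = 500)
  info <- ps$info[ps$info$gene == "g1", ]
  # anchor stays at the 5'UTR's upstream edge (= gene start here)
  expect_equal(c(info$start, info$end), c(1501, 2000))
})

test_that("extracted promoter lengths match an exhaustive distance oracle", {
  ga <- simulate_genome_annotation(n_genes = 50, contig_length = 80000,
                                   seed = 3)
  gff <- tempfile(fileext = ".gff3")
  fa <- tempfile(fileext = ".fa")
  rtracklayer::export(ga$annotation, gff, format = "gff3")
  Biostrings::writeXStringSet(ga$genome, fa)
  ps <- extract_promoters(fa, gff)
  genes <- ga$annotation[ga$annotation$type == "gene"]
  utrs <- ga$annotation[ga$annotation$type == "five_prime_UTR"]
  starts <- GenomicRanges::start(genes)
  ends <- GenomicRanges::end(genes)
  for (i in seq_along(genes)) {
    gid <- genes$ID[i]
    if (!gid %in% ps$info$gene) next
    st <- as.character(GenomicRanges::strand(genes[i]))
    u <- utrs[grepl(paste0("^", gid, "\\."), unlist(utrs$Parent))]
    if (st == "+") {
      anchor <- min(starts[i],
                    if (length(u)) min(GenomicRanges::start(u)) else Inf)
      lim <- max(1, max(c(0, ends[-i][ends[-i] < anchor]) + 1),
                 anchor - 1000)
      expected_len <- anchor - lim
    } else {
      anchor <- max(ends[i],
                    if (length(u)) max(GenomicRanges::end(u)) else -Inf)
      lim <- min(80000, min(c(Inf, starts[-i][starts[-i] > anchor]) - 1),
                 anchor + 1000)
      expected_len <- lim - anchor
    }
    expect_equal(ps$info$length[ps$info$gene == gid], expected_len)
  }
  # every sequence is uppercase A/C/G/T and at least the minimum length
  expect_false(any(grepl("[^ACGT]", as.character(ps$sequences))))
  expect_true(all(ps$info$length >= 20))
})
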