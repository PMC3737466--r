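#' Reverse complement of plain character sequences
#'
#' Vectorised over a character vector of A/C/G/T/N (and IUPAC ambiguity
#' code) strings.
#'
#' @param x Character vector of sequences.
#' @return Reverse-complemented character vector.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x))
}

canonical_word <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

as_char_seqs <- function(x) {
  if (inherits(x, "promoter_set")) x <- x$sequences
  if (inherits(x, "promoter_simulation"))
    stop("pass the $fg or $bg component of a promoter simulation",
         call. = FALSE)
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x)) stop("sequences must be a character vector, ",
                             "DNAStringSet or promoter_set", call. = FALSE)
  toupper(x)
}

#' Exhaustive k-mer over-representation test of promoter sets
#'
#' Enumerates every exact word of the requested lengths occurring in at
#' least one foreground promoter (on either strand when
#' `both_strands = TRUE`; each word is identified with its reverse
#' complement and reported as the lexicographically smaller of the pair),
#' counts for each word the number of foreground and background promoters
#' containing at least one occurrence, and tests each 2x2
#' presence/absence-by-set table with an uncorrected Pearson chi-squared
#' test. Words are flagged significant when the p-value falls below the
#' threshold *and* the foreground presence rate exceeds the background rate
#' (over-representation only) *and* the table is eligible for the
#' chi-squared approximation — every expected cell at least `min_expected`
#' (Cochran's rule; without it, words seen in a couple of foreground
#' promoters and absent from the background receive astronomically small
#' chi-squared p-values that the asymptotic approximation cannot support,
#' and the null false-positive rate explodes). Words containing non-ACGT
#' characters are never candidates, and an N in a promoter never matches; a
#' word longer than a promoter counts as absent from it.
#'
#' Background scanning uses an Aho-Corasick dictionary
#' ([Biostrings::PDict]) per word length.
#'
#' @param fg,bg Foreground and background promoter sets (character vector,
#'   [Biostrings::DNAStringSet] or `promoter_set`). The foreground need not
#'   be excluded from the background.
#' @param lengths Word lengths to enumerate (default 4 to 10 bp).
#' @param p_threshold Significance threshold (default 1e-5).
#' @param both_strands Search both strands and identify each word with its
#'   reverse complement (default `TRUE`).
#' @param min_expected Minimal expected cell count for a word's chi-squared
#'   test to be considered reliable (default 5).
#' @return Data frame of class `"motif_enrichment"`, one row per candidate
#'   word, ordered by p-value: `word`, `length`, `fg_present`, `fg_absent`,
#'   `bg_present`, `bg_absent`, `chi2`, `p`, `eligible`, `significant`.
#' @export
enumerate_and_test <- function(fg, bg, lengths = 4:10, p_threshold = 1e-5,
                               both_strands = TRUE, min_expected = 5) {
  fg <- as_char_seqs(fg)
  bg <- as_char_seqs(bg)
  if (length(fg) == 0) stop("empty foreground", call. = FALSE)
  if (length(bg) == 0) stop("empty background", call. = FALSE)
  bg_dna <- Biostrings::DNAStringSet(bg)
  fg_dna <- Biostrings::DNAStringSet(fg)
  res <- lapply(lengths, function(L) {
    cand <- candidate_words(fg, L, both_strands)
    if (length(cand) == 0) return(NULL)
    fg_present <- presence_counts(cand, fg_dna, both_strands)
    bg_present <- presence_counts(cand, bg_dna, both_strands)
    data.frame(word = cand, length = L,
               fg_present = fg_present, fg_absent = length(fg) - fg_present,
               bg_present = bg_present, bg_absent = length(bg) - bg_present,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no candidate words", call. = FALSE)
  ct <- chisq_2x2(out$fg_present, out$fg_absent, out$bg_present, out$bg_absent)
  out$chi2 <- ct$chi2
  out$p <- ct$p
  out$eligible <- ct$min_expected >= min_expected
  out$significant <- out$eligible & out$p < p_threshold &
    out$fg_present / length(fg) > out$bg_present / length(bg)
  out <- out[order(out$p, out$word), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_fg") <- length(fg)
  attr(out, "n_bg") <- length(bg)
  attr(out, "p_threshold") <- p_threshold
  attr(out, "both_strands") <- both_strands
  class(out) <- c("motif_enrichment", "data.frame")
  out
}

# All distinct (canonical) L-mers occurring in at least one sequence.
candidate_words <- function(seqs, L, both_strands) {
  words <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < L) return(character(0))
    unique.default(substring(s, 1:(n - L + 1), L:n))
  }), use.names = FALSE)
  words <- unique.default(words)
  words <- words[!grepl("[^ACGT]", words)]
  if (both_strands) words <- unique.default(canonical_word(words))
  sort(words)
}

# Number of sequences containing >= 1 occurrence of each canonical word.
presence_counts <- function(cand, seqs_dna, both_strands) {
  patterns <- if (both_strands) unique.default(c(cand, revcomp(cand))) else cand
  canon_id <- match(if (both_strands) canonical_word(patterns) else patterns,
                    cand)
  pd <- Biostrings::PDict(patterns)
  hits <- Biostrings::vwhichPDict(pd, seqs_dna)
  ids <- unlist(lapply(hits, function(ix) unique.default(canon_id[ix])),
                use.names = FALSE)
  tabulate(ids, nbins = length(cand))
}

# Vectorised Pearson chi-squared on 2x2 tables (no continuity correction).
chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  e11 <- (a + b) * (a + c) / n
  e12 <- (a + b) * (b + d) / n
  e21 <- (c + d) * (a + c) / n
  e22 <- (c + d) * (b + d) / n
  term <- function(o, e) ifelse(e > 0, (o - e)^2 / e, 0)
  chi2 <- term(a, e11) + term(b, e12) + term(c, e21) + term(d, e22)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       min_expected = pmin(e11, e12, e21, e22))
}

#' Best ungapped similarity between two words
#'
#' Slides one word against the other (both orientations when
#' `both_strands`) and returns the maximal fraction of matching positions
#' over the overlap, considering only offsets with an overlap of at least
#' `min_overlap` positions.
#'
#' @param a,b Words (A/C/G/T strings).
#' @param min_overlap Minimal overlap length considered (default 4).
#' @param both_strands Also consider the reverse complement of `b`.
#' @return Similarity in `[0, 1]` (0 if no admissible overlap).
#' @export
word_similarity <- function(a, b, min_overlap = 4, both_strands = TRUE) {
  ca <- strsplit(a, "")[[1]]
  variants <- if (both_strands) unique(c(b, revcomp(b))) else b
  best <- 0
  na <- length(ca)
  for (bv in variants) {
    cb <- strsplit(bv, "")[[1]]
    nb <- length(cb)
    for (off in (-(nb - min_overlap)):(na - min_overlap)) {
      ia <- max(1, off + 1):min(na, off + nb)
      ib <- ia - off
      if (length(ia) < min_overlap) next
      best <- max(best, mean(ca[ia] == cb[ib]))
    }
  }
  best
}

#' Cluster significant words into consensus motifs
#'
#' Greedy single-linkage clustering of words by their best-offset ungapped
#' similarity (see [word_similarity()]): two words are linked when their
#' similarity reaches the threshold, and clusters are the connected
#' components. Each cluster's members are then aligned to the cluster's
#' longest word at their best offset and orientation, and a position-wise
#' IUPAC consensus over the aligned columns is reported.
#'
#' @param x A `"motif_enrichment"` table (the significant rows are used) or
#'   a character vector of words.
#' @param threshold Similarity threshold for linkage (default 0.75).
#' @param min_overlap Minimal overlap for a similarity to count (default 4).
#' @param both_strands Consider reverse complements when aligning.
#' @return List of class `"motif_clusters"`: `members` (data frame `word`,
#'   `cluster`) and `clusters` (data frame `cluster`, `n_words`,
#'   `consensus`).
#' @export
cluster_motifs <- function(x, threshold = 0.75, min_overlap = 4,
                           both_strands = TRUE) {
  words <- if (is.data.frame(x)) x$word[x$significant] else as.character(x)
  words <- unique(words)
  if (length(words) == 0) stop("no significant words to cluster",
                               call. = FALSE)
  k <- length(words)
  sim <- diag(1, k)
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      sim[i, j] <- sim[j, i] <-
        word_similarity(words[i], words[j], min_overlap, both_strands)
    }
  }
  cluster <- connected_components(sim >= threshold)
  members <- data.frame(word = words, cluster = cluster,
                        stringsAsFactors = FALSE)
  clusters <- do.call(rbind, lapply(sort(unique(cluster)), function(cl) {
    w <- words[cluster == cl]
    data.frame(cluster = cl, n_words = length(w),
               consensus = consensus_iupac(w, min_overlap, both_strands),
               stringsAsFactors = FALSE)
  }))
  structure(list(members = members, clusters = clusters),
            class = "motif_clusters")
}

connected_components <- function(adj) {
  k <- nrow(adj)
  comp <- integer(k)
  cur <- 0L
  for (s in seq_len(k)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# Position-wise IUPAC consensus of words aligned to the longest member.
consensus_iupac <- function(words, min_overlap = 4, both_strands = TRUE) {
  seed <- words[order(-nchar(words), words)][1]
  cs <- strsplit(seed, "")[[1]]
  placed <- list(data.frame(pos = seq_along(cs), base = cs))
  for (w in setdiff(words, seed)) {
    best <- list(score = -1, off = 0, chars = NULL)
    variants <- if (both_strands) unique(c(w, revcomp(w))) else w
    for (wv in variants) {
      cw <- strsplit(wv, "")[[1]]
      nw <- length(cw); ns <- length(cs)
      for (off in (-(nw - min_overlap)):(ns - min_overlap)) {
        ia <- max(1, off + 1):min(ns, off + nw)
        if (length(ia) < min_overlap) next
        score <- mean(cs[ia] == cw[ia - off])
        if (score > best$score) best <- list(score = score, off = off,
                                             chars = cw)
      }
    }
    if (!is.null(best$chars))
      placed <- c(placed, list(data.frame(
        pos = best$off + seq_along(best$chars), base = best$chars)))
  }
  all_pos <- do.call(rbind, placed)
  cols <- sort(unique(all_pos$pos))
  code <- vapply(cols, function(p) {
    iupac_code(unique(all_pos$base[all_pos$pos == p]))
  }, character(1))
  paste(code, collapse = "")
}

iupac_code <- function(bases) {
  map <- Biostrings::IUPAC_CODE_MAP
  key <- paste(sort(unique(unlist(strsplit(bases, "")))), collapse = "")
  hit <- names(map)[vapply(map, function(b)
    paste(sort(strsplit(b, "")[[1]]), collapse = "") == key, logical(1))]
  if (length(hit) == 0) "N" else hit[1]
}

#' Match motif clusters against a catalogue of named cis-elements
#'
#' Compares each cluster consensus with every catalogue pattern using an
#' IUPAC-aware best-offset score: two positions are compatible when their
#' base sets intersect, and the score is the maximal fraction of compatible
#' positions over the overlap (both orientations, overlap at least
#' `min_overlap`). The best-scoring catalogue entry is reported per
#' cluster; score ties are broken alphabetically by entry name and flagged.
#' Clusters whose best score falls below `threshold` (or with no admissible
#' overlap) are reported unmatched, as is everything when the catalogue is
#' empty.
#'
#' @param clusters A `"motif_clusters"` object or character vector of
#'   consensus strings.
#' @param catalogue Data frame with `name` and `pattern` columns, or path
#'   to a tab-separated file with those columns; defaults to the small
#'   editable plant cis-element catalogue shipped with the package.
#' @param min_overlap Minimal overlap (default 4).
#' @param threshold Minimal score to call a match (default 0.8).
#' @return Data frame: `consensus`, `best_match`, `pattern`, `score`,
#'   `tie`, `matched`.
#' @export
match_catalogue <- function(clusters, catalogue = crossarray_catalogue(),
                            min_overlap = 4, threshold = 0.8) {
  cons <- if (inherits(clusters, "motif_clusters"))
    clusters$clusters$consensus else as.character(clusters)
  if (is.character(catalogue) && length(catalogue) == 1)
    catalogue <- read.delim(catalogue, stringsAsFactors = FALSE)
  if (!is.data.frame(catalogue) ||
      !all(c("name", "pattern") %in% names(catalogue)))
    stop("catalogue must have 'name' and 'pattern' columns", call. = FALSE)
  out <- lapply(cons, function(cx) {
    if (nrow(catalogue) == 0)
      return(data.frame(consensus = cx, best_match = NA_character_,
                        pattern = NA_character_, score = NA_real_,
                        tie = FALSE, matched = FALSE))
    sc <- lapply(catalogue$pattern, function(p)
      iupac_match(cx, p, min_overlap))
    scores <- vapply(sc, `[[`, numeric(1), "score")
    overlaps <- vapply(sc, `[[`, numeric(1), "overlap")
    best <- max(scores)
    hits <- which(scores == best)
    # equal compatibility fractions: prefer the longer overlap, then the
    # alphabetically first name (flagged as a tie)
    best_ov <- max(overlaps[hits])
    hits <- hits[overlaps[hits] == best_ov]
    hits <- hits[order(catalogue$name[hits])]
    matched <- is.finite(best) && best >= threshold
    data.frame(consensus = cx,
               best_match = if (matched) catalogue$name[hits[1]] else
                 NA_character_,
               pattern = if (matched) catalogue$pattern[hits[1]] else
                 NA_character_,
               score = best, tie = matched && length(hits) > 1,
               matched = matched, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' IUPAC-aware best-offset compatibility score between two patterns
#'
#' @param a,b IUPAC pattern strings.
#' @param min_overlap Minimal overlap length (default 4).
#' @return Maximal fraction of compatible positions over the overlap, over
#'   both orientations of `b`; 0 if no admissible overlap.
#' @export
iupac_similarity <- function(a, b, min_overlap = 4) {
  iupac_match(a, b, min_overlap)$score
}

# Best IUPAC-compatible alignment: fraction of compatible positions and the
# overlap length achieving it (longer overlaps win among equal fractions).
iupac_match <- function(a, b, min_overlap = 4) {
  expand <- function(p) {
    map <- Biostrings::IUPAC_CODE_MAP
    lapply(strsplit(toupper(p), "")[[1]], function(ch) {
      if (ch %in% names(map)) strsplit(map[[ch]], "")[[1]] else character(0)
    })
  }
  ea <- expand(a)
  best <- 0
  best_ov <- 0
  na <- length(ea)
  for (bv in unique(c(b, revcomp(toupper(b))))) {
    eb <- expand(bv)
    nb <- length(eb)
    for (off in (-(nb - min_overlap)):(na - min_overlap)) {
      ia <- max(1, off + 1):min(na, off + nb)
      if (length(ia) < min_overlap) next
      compat <- vapply(seq_along(ia), function(t)
        length(intersect(ea[[ia[t]]], eb[[ia[t] - off]])) > 0, logical(1))
      score <- mean(compat)
      if (score > best || (score == best && length(ia) > best_ov)) {
        best <- score
        best_ov <- length(ia)
      }
    }
  }
  list(score = best, overlap = best_ov)
}

#' The small plant cis-element catalogue shipped with the package
#'
#' @return Path to the tab-separated catalogue file (columns `name`,
#'   `pattern`, `reference`), which users can copy and edit.
#' @export
crossarray_catalogue <- function() {
  system.file("extdata", "motif_catalogue.tsv", package = "crossarray",
              mustWork = TRUE)
}
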