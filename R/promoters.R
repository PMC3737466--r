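#' Extract promoter sequences from a genome and annotation
#'
#' For each annotated gene, takes up to `upstream` bp upstream of the
#' transcription start — the gene's 5'-most coordinate after including any
#' annotated 5'UTR, so the promoter never contains 5'UTR sequence — and
#' truncates the region at the nearest boundary of any other annotated gene
#' (either strand) and at the contig edge. Minus-strand promoters are
#' reverse-complemented so every output sequence reads 5' to 3' towards its
#' gene. Genes whose promoter ends up shorter than `min_length` are dropped
#' and recorded.
#'
#' 5'UTR features (`five_prime_UTR`) are associated with genes through the
#' GFF `Parent` chain (UTR to mRNA to gene) or directly.
#'
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file;
#'   sequence names are matched to annotation seqnames by their first
#'   whitespace-separated token.
#' @param annotation A [GenomicRanges::GRanges] (with a `type` metadata
#'   column, GFF-style, 1-based inclusive coordinates) or path to a GFF
#'   file read with [rtracklayer::import].
#' @param upstream Maximal promoter length in bp (default 1000).
#' @param min_length Minimal retained promoter length (default 20).
#' @return List of class `"promoter_set"`:
#'   \describe{
#'     \item{sequences}{[Biostrings::DNAStringSet] named by gene, uppercase.}
#'     \item{info}{data frame `gene`, `seqname`, `strand`, `start`, `end`
#'       (genomic, 1-based inclusive), `length`, `truncation`
#'       (`none`/`neighbor_overlap`/`contig_start`).}
#'     \item{dropped}{data frame `gene`, `reason` for genes without a
#'       usable promoter.}
#'   }
#' @export
extract_promoters <- function(genome, annotation, upstream = 1000,
                              min_length = 20) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  if (is.character(annotation)) annotation <- rtracklayer::import(annotation)
  if (!methods::is(annotation, "GRanges") || is.null(annotation$type))
    stop("annotation must be a GRanges with a 'type' column or a GFF file",
         call. = FALSE)
  genes <- annotation[annotation$type == "gene"]
  if (length(genes) == 0) stop("no gene features in annotation",
                               call. = FALSE)
  gene_ids <- gene_identifiers(genes)
  utr_gene <- five_prime_utr_genes(annotation, genes, gene_ids)

  info <- list(); dropped <- list(); seqs <- character(0)
  for (i in seq_along(genes)) {
    gid <- gene_ids[i]
    chrom <- as.character(GenomicRanges::seqnames(genes[i]))
    if (!chrom %in% names(genome)) {
      warning("gene ", gid, " on sequence absent from genome; skipped",
              call. = FALSE)
      dropped[[length(dropped) + 1L]] <-
        data.frame(gene = gid, reason = "missing_sequence")
      next
    }
    chrom_len <- length(genome[[chrom]])
    strand <- as.character(GenomicRanges::strand(genes[i]))
    utrs <- utr_gene[[gid]]
    others <- genes[-i]
    others <- others[as.character(GenomicRanges::seqnames(others)) == chrom]

    if (strand == "-") {
      anchor <- max(GenomicRanges::end(genes[i]),
                    if (length(utrs)) max(GenomicRanges::end(utrs)) else -Inf)
      p_start <- anchor + 1
      p_end_full <- anchor + upstream
      p_end <- min(p_end_full, chrom_len)
      trunc <- if (p_end < p_end_full) "contig_start" else "none"
      if (length(others)) {
        ov <- GenomicRanges::start(others) <= p_end &
          GenomicRanges::end(others) >= p_start
        if (any(ov)) {
          limit <- min(GenomicRanges::start(others)[ov]) - 1
          if (limit < p_end) { p_end <- limit; trunc <- "neighbor_overlap" }
        }
      }
    } else {
      anchor <- min(GenomicRanges::start(genes[i]),
                    if (length(utrs)) min(GenomicRanges::start(utrs)) else Inf)
      p_end <- anchor - 1
      p_start_full <- anchor - upstream
      p_start <- max(p_start_full, 1)
      trunc <- if (p_start > p_start_full) "contig_start" else "none"
      if (length(others)) {
        ov <- GenomicRanges::start(others) <= p_end &
          GenomicRanges::end(others) >= p_start
        if (any(ov)) {
          limit <- max(GenomicRanges::end(others)[ov]) + 1
          if (limit > p_start) { p_start <- limit; trunc <- "neighbor_overlap" }
        }
      }
    }
    len <- p_end - p_start + 1
    if (len < min_length) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(gene = gid, reason = "too_short")
      next
    }
    s <- toupper(as.character(Biostrings::subseq(genome[[chrom]],
                                                 p_start, p_end)))
    if (strand == "-") s <- revcomp(s)
    seqs[gid] <- s
    info[[length(info) + 1L]] <-
      data.frame(gene = gid, seqname = chrom, strand = strand,
                 start = p_start, end = p_end, length = len,
                 truncation = trunc, stringsAsFactors = FALSE)
  }
  if (length(seqs) == 0) stop("no promoters extracted", call. = FALSE)
  structure(list(sequences = Biostrings::DNAStringSet(seqs),
                 info = do.call(rbind, info),
                 dropped = if (length(dropped)) do.call(rbind, dropped) else
                   data.frame(gene = character(0), reason = character(0))),
            class = "promoter_set")
}

gene_identifiers <- function(genes) {
  ids <- genes$ID
  if (is.null(ids)) ids <- genes$Name
  if (is.null(ids)) ids <- paste0("gene", seq_along(genes))
  ids[is.na(ids)] <- paste0("gene", which(is.na(ids)))
  as.character(ids)
}

# Map gene id -> GRanges of its five_prime_UTR features (Parent chain).
five_prime_utr_genes <- function(annotation, genes, gene_ids) {
  utrs <- annotation[annotation$type == "five_prime_UTR"]
  out <- setNames(vector("list", length(gene_ids)), gene_ids)
  if (length(utrs) == 0) return(out)
  id2parent <- list()
  has_id <- !is.null(annotation$ID) & !is.na(annotation$ID)
  if (!is.null(annotation$Parent)) {
    par <- vapply(as.list(annotation$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
    id2parent <- setNames(par, annotation$ID)
  }
  resolve <- function(x) {
    for (step in 1:3) {
      if (is.na(x)) return(NA_character_)
      if (x %in% gene_ids) return(x)
      x <- if (x %in% names(id2parent)) id2parent[[x]] else NA_character_
    }
    NA_character_
  }
  upar <- vapply(as.list(utrs$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  owner <- vapply(upar, resolve, character(1))
  for (g in unique(owner[!is.na(owner)])) {
    out[[g]] <- utrs[!is.na(owner) & owner == g]
  }
  out
}

#' Simulate a toy genome with a GFF-style gene annotation
#'
#' Generates a single random contig with non-overlapping genes (uniform
#' random residues), each optionally carrying an mRNA and a 5'UTR at its
#' 5' end, for exercising promoter extraction.
#'
#' @param n_genes Number of genes.
#' @param contig_length Contig length in bp.
#' @param gene_length Range of gene lengths (bp), sampled uniformly.
#' @param utr_prob Probability that a gene carries an annotated 5'UTR.
#' @param utr_length Range of 5'UTR lengths (bp).
#' @param seed Integer seed.
#' @return List: `genome` ([Biostrings::DNAStringSet], one contig named
#'   `chr1`) and `annotation` ([GenomicRanges::GRanges] with gene, mRNA and
#'   five_prime_UTR features, ID/Parent attributes set).
#' @export
simulate_genome_annotation <- function(n_genes = 50, contig_length = 100000,
                                       gene_length = c(500, 2000),
                                       utr_prob = 0.5,
                                       utr_length = c(30, 150), seed = 1L) {
  set.seed(seed)
  genome <- paste(sample(c("A", "C", "G", "T"), contig_length,
                         replace = TRUE), collapse = "")
  lens <- sample(gene_length[1]:gene_length[2], n_genes, replace = TRUE)
  # place genes left to right with random gaps, without overlap
  gaps <- sample(50:3000, n_genes, replace = TRUE)
  starts <- cumsum(gaps + c(0, lens[-n_genes]))
  keep <- starts + lens - 1 <= contig_length
  starts <- starts[keep]; lens <- lens[keep]
  n <- length(starts)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  ids <- sprintf("G%03d", seq_len(n))

  rows <- list()
  for (i in seq_len(n)) {
    g_start <- starts[i]; g_end <- starts[i] + lens[i] - 1
    rows[[length(rows) + 1L]] <- data.frame(
      start = g_start, end = g_end, strand = strands[i], type = "gene",
      ID = ids[i], Parent = NA_character_)
    mid <- paste0(ids[i], ".1")
    rows[[length(rows) + 1L]] <- data.frame(
      start = g_start, end = g_end, strand = strands[i], type = "mRNA",
      ID = mid, Parent = ids[i])
    if (runif(1) < utr_prob) {
      ul <- sample(utr_length[1]:utr_length[2], 1)
      ul <- min(ul, lens[i] - 10)
      ur <- if (strands[i] == "+") c(g_start, g_start + ul - 1) else
        c(g_end - ul + 1, g_end)
      rows[[length(rows) + 1L]] <- data.frame(
        start = ur[1], end = ur[2], strand = strands[i],
        type = "five_prime_UTR", ID = paste0(mid, ".utr5"), Parent = mid)
    }
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(tab$start, tab$end),
    strand = tab$strand)
  gr$type <- tab$type
  gr$ID <- tab$ID
  gr$Parent <- IRanges::CharacterList(lapply(tab$Parent, function(p)
    if (is.na(p)) character(0) else p))
  list(genome = Biostrings::DNAStringSet(c(chr1 = genome)),
       annotation = gr)
}
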