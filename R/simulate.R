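#' Simulate a set of two-colour microarray comparisons with known truth
#'
#' Generates spot-level channel intensities for one treatment-vs-control
#' comparison per treatment label in the configuration, together with the
#' per-probe ground truth. Intensities are built multiplicatively on the
#' log2 scale: for each spot the two channels are
#' `2^(A + M/2)` and `2^(A - M/2)` where `A` is the spot's log2 abundance
#' and the raw log-ratio `M` is the sum of the signed true effect (sign
#' flipped on dye-swapped arrays), the intensity-dependent dye bias, the
#' print-tip block offset, and Gaussian spot noise (log-normal on the
#' intensity scale).
#'
#' @param config A [generator_config()].
#' @return A list of class `"ma_simulation"` with elements
#'   \describe{
#'     \item{spots}{named list (one per treatment) of spot tables: columns
#'       `probe`, `array`, `block`, `bio_rep`, `orientation`
#'       (`"forward"`/`"swapped"`), `ch1` (red, 635 nm), `ch2` (green,
#'       532 nm), `valid`.}
#'     \item{truth}{data frame with one row per probe and treatment:
#'       `probe`, `treatment`, `class` (`UP`/`NC`/`DOWN`) and `effect`
#'       (signed true log2 ratio; `class` is `UP` iff `effect > 0`,
#'       `DOWN` iff `effect < 0`, `NC` iff exactly 0).}
#'     \item{config}{the configuration, echoed.}
#'   }
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_probes
  probes <- sprintf("P%05d", seq_len(n))
  block_of <- block_assignment(n, config$n_blocks)

  block_off <- config$block_offsets
  if (is.null(block_off)) {
    block_off <- rnorm(config$n_blocks, 0, 0.1)
  } else {
    block_off <- rep_len(block_off, config$n_blocks)
  }

  a_base <- rnorm(n, config$a_mean, config$a_sd)
  truth <- simulate_truth(probes, config)

  n_arrays <- config$n_bio_reps * (if (config$dye_swap) 2L else 1L)
  array_seeds <- sample.int(.Machine$integer.max - 1L,
                            n_arrays * length(config$treatments))
  spots <- vector("list", length(config$treatments))
  names(spots) <- config$treatments
  k <- 0L
  for (tr in config$treatments) {
    eff <- truth$effect[truth$treatment == tr]
    tabs <- vector("list", n_arrays)
    a <- 0L
    for (rep_i in seq_len(config$n_bio_reps)) {
      orients <- if (config$dye_swap) c("forward", "swapped") else "forward"
      for (ori in orients) {
        a <- a + 1L; k <- k + 1L
        set.seed(array_seeds[k])
        sign_ori <- if (ori == "swapped") -1 else 1
        A <- a_base + rnorm(n, 0, 0.1)
        Ac <- A - config$a_mean
        bias <- config$dye_bias_coefs[1] + config$dye_bias_coefs[2] * Ac +
          config$dye_bias_coefs[3] * Ac^2
        M <- sign_ori * eff + bias + block_off[block_of] +
          rnorm(n, 0, config$noise_sd_log2)
        tabs[[a]] <- data.frame(
          probe = probes,
          array = sprintf("%s_rep%d_%s", tr, rep_i, ori),
          block = block_of,
          bio_rep = rep_i,
          orientation = ori,
          ch1 = 2^(A + M / 2),
          ch2 = 2^(A - M / 2),
          valid = runif(n) >= config$invalid_rate,
          stringsAsFactors = FALSE)
      }
    }
    spots[[tr]] <- do.call(rbind, tabs)
    rownames(spots[[tr]]) <- NULL
  }
  structure(list(spots = spots, truth = truth, config = config),
            class = "ma_simulation")
}

block_assignment <- function(n_probes, n_blocks) {
  as.integer(ceiling(seq_len(n_probes) / ceiling(n_probes / n_blocks)))
}

simulate_truth <- function(probes, config) {
  n <- length(probes)
  n_reg <- round(config$frac_regulated * n)
  pool <- sample(probes, n_reg)              # latent shared pathway set
  pool_sign <- setNames(sample(c(-1, 1), n_reg, replace = TRUE), pool)
  n_shared <- round(config$frac_shared * n_reg)
  out <- lapply(config$treatments, function(tr) {
    shared <- pool[seq_len(n_shared)]
    own <- sample(setdiff(probes, pool), n_reg - n_shared)
    eff <- setNames(numeric(n), probes)
    eff[shared] <- pool_sign[shared] * config$effect_size_log2
    eff[own] <- sample(c(-1, 1), length(own), replace = TRUE) *
      config$effect_size_log2
    data.frame(probe = probes, treatment = tr,
               class = ifelse(eff > 0, "UP", ifelse(eff < 0, "DOWN", "NC")),
               effect = unname(eff), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Extract one treatment's true regulation classes as a named vector
#'
#' @param truth The `truth` data frame of an [simulate_experiment()] result.
#' @param treatment Treatment label to extract.
#' @return Named character vector probe -> class (`UP`/`NC`/`DOWN`).
#' @export
truth_classes <- function(truth, treatment) {
  t1 <- truth[truth$treatment == treatment, ]
  if (nrow(t1) == 0) stop("unknown treatment: ", treatment)
  setNames(t1$class, t1$probe)
}

#' Simulate promoter sequence sets with a planted motif
#'
#' Emits a foreground and a background set of random promoter sequences
#' (i.i.d. residues with a configurable, AT-rich base composition typical of
#' plant promoters) and plants one copy of an exact motif into a stated
#' fraction of each set, at a uniform random position on a uniformly chosen
#' strand.
#'
#' @param n_fg,n_bg Number of foreground / background promoters.
#' @param length Promoter length in bp.
#' @param motif Motif to plant (A/C/G/T only; degenerate bases unsupported).
#' @param plant_rate_fg,plant_rate_bg Fraction of sequences (foreground /
#'   background) receiving one planted copy.
#' @param base_comp Named base probabilities for A, C, G, T.
#' @param seed Integer seed.
#' @return List of class `"promoter_simulation"`: `fg` and `bg`
#'   ([Biostrings::DNAStringSet]), and `truth`, a data frame with the set,
#'   sequence name, planting flag, position and strand of each planted copy.
#' @export
simulate_promoters <- function(n_fg, n_bg, length = 1000, motif = "CCGAC",
                               plant_rate_fg = 0.5, plant_rate_bg = 0,
                               base_comp = c(A = 0.34, C = 0.16,
                                             G = 0.16, T = 0.34),
                               seed = 1L) {
  if (grepl("[^ACGT]", motif))
    stop("motif must contain only A/C/G/T (degenerate planting not supported)",
         call. = FALSE)
  if (nchar(motif) > length) stop("motif longer than promoter", call. = FALSE)
  if (plant_rate_fg < 0 || plant_rate_fg > 1 ||
      plant_rate_bg < 0 || plant_rate_bg > 1)
    stop("plant rates must lie in [0, 1]", call. = FALSE)
  stopifnot(identical(sort(names(base_comp)), c("A", "C", "G", "T")))
  set.seed(seed)
  emit <- function(n_seq, rate, prefix) {
    bases <- sample(names(base_comp), n_seq * length, replace = TRUE,
                    prob = base_comp[c("A", "C", "G", "T")])
    seqs <- vapply(seq_len(n_seq), function(i) {
      paste(bases[((i - 1) * length + 1):(i * length)], collapse = "")
    }, character(1))
    names(seqs) <- sprintf("%s%04d", prefix, seq_len(n_seq))
    planted <- runif(n_seq) < rate
    pos <- rep(NA_integer_, n_seq)
    strand <- rep(NA_character_, n_seq)
    k <- nchar(motif)
    for (i in which(planted)) {
      pos[i] <- sample.int(length - k + 1L, 1L)
      strand[i] <- sample(c("+", "-"), 1L)
      ins <- if (strand[i] == "+") motif else revcomp(motif)
      substr(seqs[i], pos[i], pos[i] + k - 1L) <- ins
    }
    list(seqs = seqs,
         truth = data.frame(seq = names(seqs), planted = planted,
                            position = pos, strand = strand,
                            stringsAsFactors = FALSE))
  }
  fg <- emit(n_fg, plant_rate_fg, "fg")
  bg <- emit(n_bg, plant_rate_bg, "bg")
  truth <- rbind(cbind(set = "fg", fg$truth), cbind(set = "bg", bg$truth))
  structure(list(fg = Biostrings::DNAStringSet(fg$seqs),
                 bg = Biostrings::DNAStringSet(bg$seqs),
                 truth = truth),
            class = "promoter_simulation")
}

#' Simulate an expression compendium around a known signature
#'
#' Builds a gene-by-experiment matrix of log-ratios in which a stated subset
#' of experiments share the regulation pattern of the supplied truth (the
#' true effect vector plus Gaussian noise) while the remaining experiments
#' are independent noise of comparable spread.
#'
#' @param n_experiments Number of compendium experiments (columns).
#' @param effects Named numeric vector of true per-gene log2 effects (the
#'   signature-generating pattern; typically `truth$effect` for one
#'   treatment).
#' @param correlated_fraction Fraction of experiments aligned to `effects`.
#' @param noise_sd Noise SD added to aligned experiments (and the scale of
#'   unaligned columns beyond the effect spread).
#' @param seed Integer seed.
#' @return Numeric matrix (genes x experiments) with attributes
#'   `"correlated"` (column indices of aligned experiments).
#' @export
simulate_compendium <- function(n_experiments, effects,
                                correlated_fraction = 0.1,
                                noise_sd = 0.3, seed = 1L) {
  if (is.null(names(effects))) stop("effects must be a named vector",
                                    call. = FALSE)
  if (correlated_fraction < 0 || correlated_fraction > 1)
    stop("correlated_fraction must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  n_genes <- length(effects)
  n_cor <- round(correlated_fraction * n_experiments)
  idx_cor <- if (n_cor > 0) sort(sample.int(n_experiments, n_cor)) else integer()
  sd_null <- sqrt(var(effects) + noise_sd^2)
  mat <- matrix(rnorm(n_genes * n_experiments, 0, sd_null),
                nrow = n_genes,
                dimnames = list(names(effects),
                                sprintf("experiment_%03d", seq_len(n_experiments))))
  for (j in idx_cor) {
    mat[, j] <- effects + rnorm(n_genes, 0, noise_sd)
  }
  attr(mat, "correlated") <- idx_cor
  mat
}
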