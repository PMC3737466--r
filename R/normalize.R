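#' Exclude badly formed and non-positive spots
#'
#' Keeps only spots flagged valid whose two channel intensities are both
#' strictly positive (the log-ratio is undefined otherwise).
#'
#' @param spots Spot table (see [simulate_experiment()]).
#' @return The filtered spot table.
#' @export
filter_spots <- function(spots) {
  keep <- spots$valid & is.finite(spots$ch1) & is.finite(spots$ch2) &
    spots$ch1 > 0 & spots$ch2 > 0
  keep[is.na(keep)] <- FALSE
  out <- spots[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("no usable spots after filtering", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Compute per-spot M and A values
#'
#' `M = log2(ch1/ch2)` (red over green) and `A = (log2 ch1 + log2 ch2)/2`.
#'
#' @param spots Filtered spot table.
#' @return The table with `M` and `A` columns appended.
#' @export
spot_ma <- function(spots) {
  spots$M <- log2(spots$ch1) - log2(spots$ch2)
  spots$A <- (log2(spots$ch1) + log2(spots$ch2)) / 2
  spots
}

#' Intensity-dependent loess normalization of one array
#'
#' Fits a robust loess curve of M on A (via [limma::loessFit]; with equal
#' weights this is exactly `stats::lowess`) and subtracts the fit, removing
#' the smooth intensity-dependent dye bias.
#'
#' @param array_spots Spot table of a single array with `M` and `A` columns
#'   (see [spot_ma()]).
#' @param span Loess span (default 0.3).
#' @param iterations Number of robustifying iterations passed to
#'   [limma::loessFit] (default 4, i.e. 3 re-weighting passes).
#' @param min_spots Minimum number of spots required to fit the smoother.
#' @return The table with `M` replaced by the loess-corrected values.
#' @export
loess_normalize_array <- function(array_spots, span = 0.3, iterations = 4L,
                                  min_spots = 100L) {
  if (nrow(array_spots) < min_spots)
    stop("too few spots to fit the loess smoother (", nrow(array_spots),
         " < ", min_spots, ")", call. = FALSE)
  if (any(!is.finite(array_spots$M)) || any(!is.finite(array_spots$A)))
    stop("non-finite intensities in array", call. = FALSE)
  fit <- limma::loessFit(array_spots$M, array_spots$A, span = span,
                         iterations = iterations)
  array_spots$M <- array_spots$M - fit$fitted
  array_spots
}

#' Print-tip correction by per-block median centering
#'
#' Subtracts from each log-ratio the median log-ratio of its print-tip
#' block, so that after correction every block's median M is zero.
#'
#' @param array_spots Spot table of a single array with `M` and `block`
#'   columns.
#' @return The table with block-centered `M`.
#' @export
block_median_center <- function(array_spots) {
  med <- tapply(array_spots$M, array_spots$block, median)
  array_spots$M <- array_spots$M -
    as.numeric(med[as.character(array_spots$block)])
  array_spots
}

#' Average dye-swap technical replicates into per-replicate log-ratios
#'
#' Re-expresses every spot's log-ratio on the treatment/control scale (the
#' sign of dye-swapped measurements is flipped) and averages the technical
#' replicates of each probe within each biological replicate. Probes
#' measured in only one member of a dye-swap pair use the available
#' measurement; the number of contributing spots is recorded.
#'
#' @param spots Normalized spot table of one comparison with `M`, `A`,
#'   `probe`, `bio_rep` and `orientation` columns.
#' @return Data frame with one row per probe and biological replicate:
#'   `probe`, `bio_rep`, `M` (mean treatment/control log2 ratio), `A`
#'   (mean intensity) and `n_spots`.
#' @export
average_dye_swap <- function(spots) {
  m_tc <- ifelse(spots$orientation == "swapped", -spots$M, spots$M)
  key <- interaction(spots$probe, spots$bio_rep, drop = TRUE)
  out <- data.frame(
    probe = tapply(spots$probe, key, `[`, 1L),
    bio_rep = as.integer(tapply(spots$bio_rep, key, `[`, 1L)),
    M = as.numeric(tapply(m_tc, key, mean)),
    A = as.numeric(tapply(spots$A, key, mean)),
    n_spots = as.integer(tapply(m_tc, key, length)),
    stringsAsFactors = FALSE)
  out <- out[order(out$probe, out$bio_rep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full normalization chain for one treatment-vs-control comparison
#'
#' Filters spots, computes M/A values, loess-normalizes and block-centers
#' each array, sign-corrects and averages the dye-swap pairs, and assembles
#' the per-probe, per-replicate log-ratio matrix. "Signal" probes are those
#' with at least one valid spot in every biological replicate.
#'
#' @param spots Raw spot table of one comparison.
#' @inheritParams loess_normalize_array
#' @return List of class `"normalized_matrix"`:
#'   \describe{
#'     \item{M, A}{probe x biological-replicate matrices (NA where a probe
#'       had no valid spot in that replicate).}
#'     \item{n_spots}{matrix of contributing spot counts.}
#'     \item{signal}{logical vector; `TRUE` for signal probes.}
#'   }
#' @export
normalize_comparison <- function(spots, span = 0.3, iterations = 4L,
                                 min_spots = 100L) {
  spots <- spot_ma(filter_spots(spots))
  parts <- split(spots, spots$array)
  parts <- lapply(parts, function(a) {
    block_median_center(
      loess_normalize_array(a, span = span, iterations = iterations,
                            min_spots = min_spots))
  })
  spots <- do.call(rbind, parts)
  per_rep <- average_dye_swap(spots)

  probes <- sort(unique(per_rep$probe))
  reps <- sort(unique(per_rep$bio_rep))
  shape <- function(col, fill = NA_real_) {
    m <- matrix(fill, length(probes), length(reps),
                dimnames = list(probes, paste0("rep", reps)))
    m[cbind(match(per_rep$probe, probes), match(per_rep$bio_rep, reps))] <-
      per_rep[[col]]
    m
  }
  M <- shape("M"); A <- shape("A"); n_spots <- shape("n_spots", 0)
  structure(list(M = M, A = A, n_spots = n_spots,
                 signal = rowSums(n_spots > 0) == length(reps)),
            class = "normalized_matrix")
}
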