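#' Rank compendium experiments by signature correlation
#'
#' Builds a transcriptome signature from a differential call table — the K
#' probes with the largest mean log-ratios (most up-regulated) and the K
#' with the smallest (most down-regulated), carrying their mean log-ratios
#' as the reference vector — and ranks every experiment of an expression
#' compendium by the Pearson correlation between its log-ratios and the
#' reference over the signature genes.
#'
#' Signature genes absent from the compendium are dropped with a warning.
#' An experiment with zero variance over the signature genes has an
#' undefined correlation; it is flagged and ranked last.
#'
#' @param de_table A `"differential_calls"` table (or any data frame with
#'   `probe` and `mean_M` columns).
#' @param compendium Numeric matrix genes x experiments of log-ratios.
#' @param k Number of genes per direction (default 200).
#' @return Data frame of class `"signature_ranking"`, one row per
#'   experiment sorted by decreasing correlation: `experiment`,
#'   `correlation` (NA if undefined), `rank`, `undefined`. The signature
#'   (named reference vector) is attached as attribute `"signature"`.
#' @export
signature_rank <- function(de_table, compendium, k = 200) {
  stopifnot(all(c("probe", "mean_M") %in% names(de_table)))
  n_probes <- nrow(de_table)
  if (2 * k > n_probes)
    stop("k exceeds the number of probes per direction", call. = FALSE)
  ord <- order(de_table$mean_M, decreasing = TRUE)
  sig_probes <- c(de_table$probe[head(ord, k)],
                  de_table$probe[tail(ord, k)])
  reference <- setNames(de_table$mean_M[match(sig_probes, de_table$probe)],
                        sig_probes)
  present <- sig_probes %in% rownames(compendium)
  if (!all(present)) {
    warning(sum(!present), " signature gene(s) absent from the compendium; ",
            "dropped", call. = FALSE)
    reference <- reference[present]
  }
  if (length(reference) < 3)
    stop("fewer than 3 signature genes present in the compendium",
         call. = FALSE)
  sub <- compendium[names(reference), , drop = FALSE]
  sds <- apply(sub, 2, function(x) sd(x))
  correlation <- rep(NA_real_, ncol(sub))
  ok <- sds > 0 & is.finite(sds)
  correlation[ok] <- as.numeric(cor(reference, sub[, ok, drop = FALSE]))
  out <- data.frame(experiment = colnames(compendium),
                    correlation = correlation,
                    undefined = !ok,
                    stringsAsFactors = FALSE)
  out <- out[order(-ifelse(is.na(out$correlation), -Inf, out$correlation),
                   out$undefined), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "signature") <- reference
  class(out) <- c("signature_ranking", "data.frame")
  out
}

#' @importFrom stats sd
NULL
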