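#' Configuration for the synthetic microarray generator
#'
#' Bundles and validates every knob of the spot-level two-colour microarray
#' simulator. The defaults emulate a CATMA-style dye-swap design: two
#' biological replicates, each hybridised twice with fluorochrome reversal
#' (four hybridisations per treatment-vs-control comparison), probes grouped
#' into print-tip blocks, a smooth intensity-dependent dye bias, and
#' per-block additive log-ratio offsets.
#'
#' Treatment-responsive probes are drawn partly from a common latent
#' "pathway" set so that the regulation calls of different treatments are
#' statistically dependent: `frac_shared` of each treatment's regulated
#' probes come from that shared pool (with a shared direction of
#' regulation), the rest are treatment-specific with random direction.
#' `frac_shared = 0` makes the regulated sets independent across
#' treatments; `frac_shared = 1` makes them identical.
#'
#' @param n_probes Number of probes on the array.
#' @param n_blocks Number of print-tip blocks (probes are assigned to
#'   blocks in contiguous chunks).
#' @param n_bio_reps Number of independent biological replicates (default 2).
#' @param dye_swap If `TRUE` (default) each biological replicate is
#'   hybridised twice with fluorochrome reversal.
#' @param treatments Character vector of treatment labels; one
#'   treatment-vs-control comparison is simulated per label.
#' @param frac_regulated Proportion of probes truly regulated per treatment.
#' @param frac_shared Proportion of each treatment's regulated probes drawn
#'   from the shared pathway pool (in `[0, 1]`).
#' @param effect_size_log2 Mean absolute true log2 ratio of regulated probes.
#' @param noise_sd_log2 Spot-level log2-ratio noise standard deviation.
#' @param dye_bias_coefs Coefficients `c(b0, b1, b2)` of the dye-bias curve
#'   `b0 + b1*(A - a_mean) + b2*(A - a_mean)^2` added to every raw log-ratio,
#'   the classic banana-shaped M-A artifact that loess normalization removes.
#' @param block_offsets Per-block additive log-ratio shifts; a single value
#'   is recycled, `NULL` draws them from `N(0, 0.1)`.
#' @param a_mean,a_sd Mean and SD of the per-probe base abundance on the
#'   log2-intensity (A) scale; intensities are log-normal.
#' @param invalid_rate Probability that a spot is flagged as a badly formed
#'   feature (default 0.01).
#' @param seed Integer seed; every downstream draw derives from it.
#'
#' @return A validated list of class `"generator_config"`.
#' @seealso [simulate_experiment()]
#' @export
generator_config <- function(n_probes = 2000,
                             n_blocks = 8,
                             n_bio_reps = 2,
                             dye_swap = TRUE,
                             treatments = c("treatmentA", "treatmentB"),
                             frac_regulated = 0.05,
                             frac_shared = 0.5,
                             effect_size_log2 = 1.5,
                             noise_sd_log2 = 0.3,
                             dye_bias_coefs = c(0.3, -0.1, 0.03),
                             block_offsets = NULL,
                             a_mean = 10,
                             a_sd = 1.5,
                             invalid_rate = 0.01,
                             seed = 1L) {
  stop_cfg <- function(msg) stop("invalid generator configuration: ", msg,
                                 call. = FALSE)
  if (n_probes < 1 || n_blocks < 1 || n_bio_reps < 1)
    stop_cfg("counts must be positive")
  if (n_blocks > n_probes) stop_cfg("more blocks than probes")
  for (p in c(frac_regulated = frac_regulated, frac_shared = frac_shared,
              invalid_rate = invalid_rate)) {
    if (is.na(p) || p < 0 || p > 1)
      stop_cfg("proportions must lie in [0, 1]")
  }
  if (length(treatments) < 1 || anyDuplicated(treatments))
    stop_cfg("treatments must be distinct labels")
  if (effect_size_log2 < 0 || noise_sd_log2 < 0 || a_sd < 0)
    stop_cfg("scale parameters must be non-negative")
  if (!length(dye_bias_coefs) %in% 1:3)
    stop_cfg("dye_bias_coefs must have 1 to 3 coefficients")
  if (!is.null(block_offsets) && !length(block_offsets) %in% c(1L, n_blocks))
    stop_cfg("block_offsets must be scalar or one value per block")
  cfg <- list(n_probes = as.integer(n_probes),
              n_blocks = as.integer(n_blocks),
              n_bio_reps = as.integer(n_bio_reps),
              dye_swap = isTRUE(dye_swap),
              treatments = as.character(treatments),
              frac_regulated = frac_regulated,
              frac_shared = frac_shared,
              effect_size_log2 = effect_size_log2,
              noise_sd_log2 = noise_sd_log2,
              dye_bias_coefs = c(dye_bias_coefs, 0, 0)[1:3],
              block_offsets = block_offsets,
              a_mean = a_mean,
              a_sd = a_sd,
              invalid_rate = invalid_rate,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}
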