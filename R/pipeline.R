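#' Configuration of an end-to-end pipeline run
#'
#' Collects the generator configuration and every stage parameter, each
#' defaulting to the value used throughout the package (loess span 0.3,
#' variance trim band [0.025, 0.975], Bonferroni alpha 0.05, signature size
#' 200 per direction, motif lengths 4-10 bp with threshold 1e-5).
#'
#' @param generator A [generator_config()].
#' @param stages Character vector of enabled stages, in dependency order:
#'   `"simulate"`, `"de"`, `"xtab"`, `"signature"`, `"motif"`.
#' @param alpha Bonferroni family-wise significance level.
#' @param span,iterations,min_spots Loess normalization parameters.
#' @param trim Variance trim band.
#' @param k_signature Signature genes per direction.
#' @param n_experiments,correlated_fraction,compendium_noise_sd Compendium
#'   simulation parameters for the signature stage.
#' @param n_fg,n_bg,promoter_length,motif,plant_rate_fg,plant_rate_bg
#'   Promoter simulation parameters for the motif stage.
#' @param motif_lengths,motif_p_threshold Motif enumeration parameters.
#' @param out_dir Directory for persisted intermediates (`NULL` = none).
#' @param force Overwrite existing intermediates (default `FALSE`).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(generator = generator_config(),
                       stages = c("simulate", "de", "xtab", "signature",
                                  "motif"),
                       alpha = 0.05, span = 0.3, iterations = 4L,
                       min_spots = 100L, trim = c(0.025, 0.975),
                       k_signature = 200, n_experiments = 50,
                       correlated_fraction = 0.1,
                       compendium_noise_sd = 0.3,
                       n_fg = 100, n_bg = 1000, promoter_length = 1000,
                       motif = "CCGAC", plant_rate_fg = 0.5,
                       plant_rate_bg = 0, motif_lengths = 4:10,
                       motif_p_threshold = 1e-5,
                       out_dir = NULL, force = FALSE) {
  stopifnot(inherits(generator, "generator_config"))
  stages <- match.arg(stages, c("simulate", "de", "xtab", "signature",
                                "motif"), several.ok = TRUE)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the enabled stages in dependency order: spot-level simulation,
#' normalization + differential calls per treatment, cross-treatment
#' contingency enrichment (plus triple overlap and Venn counts when three
#' or more treatments are simulated), signature correlation ranking against
#' a simulated compendium, and promoter motif over-representation on
#' simulated promoter sets. A disabled stage is absent from the report and
#' any enabled stage missing its prerequisite fails fast, naming the stage.
#' Intermediates are persisted as TSV/FASTA under `config$out_dir` when
#' set; existing files are only overwritten with `force = TRUE`. Reports
#' are bit-identical across runs with the same configuration and seed.
#'
#' @param config A [run_config()].
#' @return List of class `"run_report"` with one element per executed
#'   stage, plus `config` (echo) and `version`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  st <- config$stages
  need <- function(stage, dep) {
    if (stage %in% st && !dep %in% st)
      stop("stage '", stage, "' requires stage '", dep, "'", call. = FALSE)
  }
  need("de", "simulate"); need("xtab", "de"); need("signature", "de")
  report <- list()
  out_dir <- config$out_dir
  persist <- function(x, name, writer = write.table) {
    if (is.null(out_dir)) return(invisible())
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    path <- file.path(out_dir, name)
    if (file.exists(path) && !isTRUE(config$force))
      stop("refusing to overwrite ", path, " without force = TRUE",
           call. = FALSE)
    if (identical(writer, write.table)) {
      write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else writer(x, path)
    invisible(path)
  }

  sim <- NULL; calls <- NULL; classes <- NULL
  if ("simulate" %in% st) {
    message("stage simulate: ", config$generator$n_probes, " probes, ",
            length(config$generator$treatments), " treatment(s)")
    sim <- simulate_experiment(config$generator)
    for (tr in names(sim$spots))
      persist(sim$spots[[tr]], paste0("spots_", tr, ".tsv"))
    persist(sim$truth, "truth.tsv")
    report$simulate <- list(
      n_probes = config$generator$n_probes,
      treatments = config$generator$treatments,
      n_regulated = vapply(split(sim$truth$class != "NC", sim$truth$treatment),
                           sum, integer(1)))
  }
  if ("de" %in% st) {
    message("stage de: normalization and differential calls")
    calls <- lapply(sim$spots, differential_calls,
                    span = config$span, iterations = config$iterations,
                    min_spots = config$min_spots, trim = config$trim,
                    alpha = config$alpha)
    classes <- lapply(calls, classify_probes)
    for (tr in names(calls)) {
      persist(as.data.frame(calls[[tr]]), paste0("de_", tr, ".tsv"))
    }
    report$de <- list(
      n_signal = vapply(calls, function(x) attr(x, "m"), integer(1)),
      n_up = vapply(classes, function(v) sum(v == "UP"), integer(1)),
      n_down = vapply(classes, function(v) sum(v == "DOWN"), integer(1)))
  }
  if ("xtab" %in% st) {
    message("stage xtab: cross-treatment contingency enrichment")
    trs <- names(classes)
    pairs <- utils::combn(trs, 2, simplify = FALSE)
    xt <- lapply(pairs, function(p)
      build_contingency(classes[[p[1]]], classes[[p[2]]], treatments = p))
    names(xt) <- vapply(pairs, paste, character(1), collapse = "_vs_")
    report$xtab <- lapply(xt, function(x)
      list(report = enrichment_report(x), chi2 = x$chi2, df = x$df,
           p_string = x$p_string))
    if (length(trs) >= 3) {
      report$triple <- triple_overlap(classes[[1]], classes[[2]],
                                      classes[[3]])[
        c("n", "cell", "observed", "expected", "fold")]
      report$venn_up <- venn_counts(classes[1:3], class = "UP")
    }
  }
  if ("signature" %in% st) {
    message("stage signature: compendium correlation ranking")
    tr1 <- config$generator$treatments[1]
    eff <- setNames(sim$truth$effect[sim$truth$treatment == tr1],
                    sim$truth$probe[sim$truth$treatment == tr1])
    comp <- simulate_compendium(config$n_experiments, eff,
                                config$correlated_fraction,
                                config$compendium_noise_sd,
                                seed = config$generator$seed + 1L)
    k <- min(config$k_signature, floor(nrow(calls[[tr1]]) / 2))
    rk <- signature_rank(calls[[tr1]], comp, k = k)
    persist(as.data.frame(rk), "signature_ranking.tsv")
    report$signature <- list(k = k,
                             top10 = head(as.data.frame(rk), 10),
                             planted = attr(comp, "correlated"))
  }
  if ("motif" %in% st) {
    message("stage motif: promoter k-mer over-representation")
    pro <- simulate_promoters(config$n_fg, config$n_bg,
                              length = config$promoter_length,
                              motif = config$motif,
                              plant_rate_fg = config$plant_rate_fg,
                              plant_rate_bg = config$plant_rate_bg,
                              seed = config$generator$seed + 2L)
    if (!is.null(out_dir)) {
      persist(pro$fg, "promoters_fg.fasta", Biostrings::writeXStringSet)
      persist(pro$bg, "promoters_bg.fasta", Biostrings::writeXStringSet)
    }
    enr <- enumerate_and_test(pro$fg, pro$bg,
                              lengths = config$motif_lengths,
                              p_threshold = config$motif_p_threshold)
    persist(as.data.frame(enr), "motif_enrichment.tsv")
    sig <- enr[enr$significant, , drop = FALSE]
    report$motif <- list(n_candidates = nrow(enr),
                         n_significant = nrow(sig))
    if (nrow(sig) > 0) {
      cl <- cluster_motifs(enr)
      report$motif$clusters <- cl$clusters
      report$motif$catalogue <- match_catalogue(cl)
    }
  }
  report$config <- config
  report$version <- as.character(packageVersion("crossarray"))
  class(report) <- "run_report"
  report
}

#' Recompute the packaged printed contingency tables
#'
#' The package ships, as plain-text fixtures, the observed counts and the
#' printed theoretical counts and enrichment ratios of the published
#' cross-treatment contingency tables. This function recomputes the
#' theoretical counts and ratios from the observed counts alone and emits a
#' cell-by-cell diff against the printed values, flagging every printed
#' cell that is not internally consistent with its own observed counts.
#'
#' A printed theoretical count is consistent when the recomputed value
#' agrees to 2 decimals; a printed ratio is consistent when the recomputed
#' ratio agrees to the number of decimals actually printed.
#'
#' @param files Paths to fixture files (tab-separated, columns `row_class`,
#'   `col_class`, `observed`, `printed_theoretical`, `printed_ratio`);
#'   defaults to all fixtures shipped under `extdata/printed_tables`.
#' @return Named list (one element per table) of class
#'   `"printed_table_check"` elements, each a list with `analysis` (the
#'   recomputed [contingency_from_counts()]) and `cells`, a data frame with
#'   observed, printed and recomputed values plus consistency flags.
#' @export
reproduce_printed_tables <- function(files = NULL) {
  if (is.null(files)) {
    dir <- system.file("extdata", "printed_tables", package = "crossarray",
                       mustWork = TRUE)
    files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  }
  out <- lapply(files, function(f) {
    tab <- read.delim(f, colClasses = c("character", "character", "integer",
                                        "numeric", "character"))
    obs <- matrix(0L, 3, 3, dimnames = list(regulation_levels,
                                            regulation_levels))
    obs[cbind(tab$row_class, tab$col_class)] <- tab$observed
    an <- contingency_from_counts(obs, treatments = strsplit(
      sub("\\.tsv$", "", basename(f)), "_vs_")[[1]])
    idx <- cbind(tab$row_class, tab$col_class)
    computed_theo <- an$theoretical[idx]
    computed_ratio <- an$ratio[idx]
    rendered <- format_ratio(tab$observed, computed_theo)
    printed_dec <- ifelse(grepl("\\.", tab$printed_ratio),
                          nchar(sub(".*\\.", "", tab$printed_ratio)), 0)
    cells <- data.frame(
      row_class = tab$row_class, col_class = tab$col_class,
      observed = tab$observed,
      printed_theoretical = tab$printed_theoretical,
      computed_theoretical = computed_theo,
      theoretical_consistent =
        abs(computed_theo - tab$printed_theoretical) <= 0.005 + 1e-9,
      printed_ratio = tab$printed_ratio,
      computed_ratio = computed_ratio,
      rendered_ratio = rendered,
      ratio_consistent =
        abs(computed_ratio - as.numeric(tab$printed_ratio)) <=
        0.5 * 10^(-printed_dec) + 1e-9,
      stringsAsFactors = FALSE)
    structure(list(analysis = an, cells = cells),
              class = "printed_table_check")
  })
  names(out) <- sub("\\.tsv$", "", basename(files))
  out
}
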