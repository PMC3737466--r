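regulation_levels <- c("UP", "NC", "DOWN")
regulation_symbols <- c(UP = ">", NC = "<>", DOWN = "<")

#' Cross-classify two regulation-call vectors
#'
#' Restricts both vectors to their common probes (probes with a signal in
#' both experiments), tabulates the 3x3 cross-classification of regulation
#' classes (rows: first vector; order UP, NC, DOWN), and computes the
#' theoretical counts expected under independence, the observed/theoretical
#' enrichment ratio per cell, and a Pearson chi-squared test of
#' independence.
#'
#' @param v1,v2 Named character vectors probe -> class (`UP`/`NC`/`DOWN`),
#'   e.g. from [classify_probes()].
#' @param treatments Labels of the two experiments (for reports).
#' @return See [contingency_from_counts()].
#' @export
build_contingency <- function(v1, v2, treatments = c("experiment1",
                                                     "experiment2")) {
  if (anyDuplicated(names(v1)) || anyDuplicated(names(v2)))
    stop("duplicate probes in a class vector", call. = FALSE)
  common <- intersect(names(v1), names(v2))
  if (length(common) == 0) stop("no common probes", call. = FALSE)
  obs <- table(factor(v1[common], levels = regulation_levels),
               factor(v2[common], levels = regulation_levels))
  obs <- matrix(as.integer(obs), 3, 3,
                dimnames = list(regulation_levels, regulation_levels))
  contingency_from_counts(obs, treatments = treatments)
}

#' Contingency analysis from an observed count matrix
#'
#' Computes, from a square table of observed counts, the theoretical counts
#' under independence (`row_i * col_j / N`), the per-cell enrichment ratios
#' `observed/theoretical`, and the Pearson chi-squared statistic
#' `sum (O - T)^2 / T` over cells with positive theoretical count. With a
#' zero row or column marginal the affected ratios are undefined (NA) and
#' the degrees of freedom are reduced to
#' `(non-empty rows - 1) * (non-empty cols - 1)`.
#'
#' @param observed Square integer matrix of observed counts (rows/columns
#'   in class order UP, NC, DOWN for 3x3 regulation tables).
#' @param treatments Labels of the two classifications.
#' @return List of class `"contingency_analysis"`: `treatments`, `n`,
#'   `observed`, `theoretical`, `ratio`, `row_marginals`, `col_marginals`,
#'   `chi2`, `df`, `p`, `p_string` (the p-value, or `"< 2.2e-16"` below
#'   that), `degenerate` (flag for zero marginals).
#' @export
contingency_from_counts <- function(observed,
                                    treatments = c("experiment1",
                                                   "experiment2")) {
  observed <- as.matrix(observed)
  if (nrow(observed) != ncol(observed))
    stop("observed counts must form a square table", call. = FALSE)
  if (any(observed < 0)) stop("negative counts", call. = FALSE)
  n <- sum(observed)
  if (n == 0) stop("empty table", call. = FALSE)
  rowm <- rowSums(observed)
  colm <- colSums(observed)
  theoretical <- outer(rowm, colm) / n
  ratio <- ifelse(theoretical > 0, observed / theoretical, NA_real_)
  keep <- theoretical > 0
  chi2 <- sum(((observed - theoretical)^2 / theoretical)[keep])
  degenerate <- any(rowm == 0) || any(colm == 0)
  df <- (sum(rowm > 0) - 1L) * (sum(colm > 0) - 1L)
  if (df < 1) stop("table has fewer than 2 non-empty rows or columns",
                   call. = FALSE)
  if (any(theoretical[keep] < 5))
    warning("some cells have theoretical count < 5; ",
            "the chi-squared approximation may be poor", call. = FALSE)
  p <- pchisq(chi2, df = df, lower.tail = FALSE)
  structure(list(treatments = treatments, n = n, observed = observed,
                 theoretical = theoretical, ratio = ratio,
                 row_marginals = rowm, col_marginals = colm,
                 chi2 = chi2, df = df, p = p,
                 p_string = if (p < 2.2e-16) "< 2.2e-16" else
                   format(p, digits = 4),
                 degenerate = degenerate),
            class = "contingency_analysis")
}

#' Render an enrichment ratio at display precision
#'
#' Ratios are shown with 2 decimals, except values of 10 or more which get
#' 1 decimal; a cell with zero observed count renders as `"0"`; an
#' undefined ratio (zero theoretical count) renders as `"NA"`.
#'
#' @param observed,theoretical Observed and theoretical counts (vectorised).
#' @return Character vector of rendered ratios.
#' @export
format_ratio <- function(observed, theoretical) {
  r <- observed / theoretical
  out <- ifelse(observed == 0, "0",
                ifelse(r >= 10, formatC(r, digits = 1, format = "f"),
                       formatC(r, digits = 2, format = "f")))
  out[!is.finite(r) & observed != 0] <- "NA"
  out
}

#' Render a contingency analysis in the observed/(theoretical)/ratio layout
#'
#' Produces a character matrix with, for each row class, three lines:
#' observed counts, theoretical counts in parentheses (2 decimals), and the
#' enrichment ratio at display precision (see [format_ratio()]), plus
#' marginal totals.
#'
#' @param analysis A `"contingency_analysis"`.
#' @param decimals Decimals for theoretical counts (default 2).
#' @return Character matrix; rows interleave observed, theoretical and
#'   ratio lines per class, columns are the second experiment's classes
#'   plus `Total`.
#' @export
enrichment_report <- function(analysis, decimals = 2) {
  stopifnot(inherits(analysis, "contingency_analysis"))
  obs <- analysis$observed
  theo <- analysis$theoretical
  k <- nrow(obs)
  rows <- character(0)
  out <- NULL
  for (i in seq_len(k)) {
    out <- rbind(out,
                 c(format(obs[i, ]), format(analysis$row_marginals[i])),
                 c(sprintf("(%s)", formatC(theo[i, ], digits = decimals,
                                           format = "f")), ""),
                 c(format_ratio(obs[i, ], theo[i, ]), ""))
    rows <- c(rows, paste0(rownames(obs)[i],
                           c("|observed", "|theoretical", "|ratio")))
  }
  out <- rbind(out, c(format(analysis$col_marginals), format(analysis$n)))
  rownames(out) <- c(rows, "Total")
  colnames(out) <- c(colnames(obs), "Total")
  out
}

#' @export
print.contingency_analysis <- function(x, ...) {
  cat(sprintf("Contingency analysis: %s vs %s (N = %d common probes)\n",
              x$treatments[1], x$treatments[2], x$n))
  print(enrichment_report(x), quote = FALSE)
  cat(sprintf("Pearson chi-squared = %.4g, df = %d, p %s\n",
              x$chi2, x$df,
              if (startsWith(x$p_string, "<")) x$p_string else
                paste("=", x$p_string)))
  invisible(x)
}

#' Observed and expected counts of a joint three-way regulation cell
#'
#' On the probes common to three experiments, counts how many fall in a
#' given joint class cell (for instance induced by all three treatments)
#' and compares with the count expected under mutual independence,
#' `N * p1 * p2 * p3`, from the marginal class proportions of each
#' experiment on the common set. The full 3x3x3 observed and expected
#' arrays are returned as well; the expected counts sum to N by
#' construction.
#'
#' @param v1,v2,v3 Named class vectors probe -> class.
#' @param cell Joint class cell of interest, e.g. `c("UP","UP","UP")`.
#' @return List of class `"triple_overlap"`: `n`, `cell`, `observed`,
#'   `expected`, `fold`, plus the full `observed_array` and
#'   `expected_array`.
#' @export
triple_overlap <- function(v1, v2, v3, cell = c("UP", "UP", "UP")) {
  common <- Reduce(intersect, list(names(v1), names(v2), names(v3)))
  if (length(common) == 0) stop("no common probes", call. = FALSE)
  f <- lapply(list(v1, v2, v3), function(v)
    factor(v[common], levels = regulation_levels))
  n <- length(common)
  obs_arr <- table(f[[1]], f[[2]], f[[3]])
  # expected = N * p1 * p2 * p3, computed as integer products / N^2 so
  # that exactly representable cases stay exact
  cnts <- lapply(f, table)
  exp_arr <- outer(outer(as.numeric(cnts[[1]]), as.numeric(cnts[[2]])),
                   as.numeric(cnts[[3]])) / n^2
  dimnames(exp_arr) <- list(names(cnts[[1]]), names(cnts[[2]]),
                            names(cnts[[3]]))
  cell <- match.arg(cell, regulation_levels, several.ok = TRUE)
  observed <- obs_arr[cell[1], cell[2], cell[3]]
  expected <- exp_arr[cell[1], cell[2], cell[3]]
  structure(list(n = n, cell = cell,
                 observed = as.integer(observed),
                 expected = as.numeric(expected),
                 fold = as.numeric(observed / expected),
                 observed_array = obs_arr, expected_array = exp_arr),
            class = "triple_overlap")
}

#' Exclusive Venn region counts for class-positive gene sets
#'
#' Takes two or three regulation-call vectors, extracts the probes carrying
#' a given class (e.g. `UP`), and counts every exclusive region of the Venn
#' diagram. Region counts sum to the size of the union.
#'
#' @param v_list List of 2 or 3 named class vectors (list names label the
#'   sets; defaults to `A`, `B`, `C`).
#' @param class Class defining set membership (`"UP"` or `"DOWN"`).
#' @return Named integer vector of exclusive region counts (`A`, `B`,
#'   `AB`, ... where a name lists the sets containing the region).
#' @export
venn_counts <- function(v_list, class = c("UP", "DOWN")) {
  class <- match.arg(class)
  k <- length(v_list)
  if (k < 2 || k > 3) stop("venn_counts supports 2 or 3 sets", call. = FALSE)
  labels <- names(v_list)
  if (is.null(labels)) labels <- LETTERS[seq_len(k)]
  sets <- lapply(v_list, function(v) names(v)[v == class])
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  pattern <- apply(membership, 1, function(b) paste(labels[b], collapse = ""))
  region_names <- unlist(lapply(seq_len(k), function(m)
    apply(utils::combn(labels, m), 2, paste, collapse = "")))
  counts <- setNames(integer(length(region_names)), region_names)
  tab <- table(pattern)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Overlap of two gene lists against a finite universe
#'
#' Counts the observed overlap of two lists, the overlap expected by chance
#' (`|A| * |B| / U`), and the upper-tail hypergeometric probability of an
#' overlap at least as large.
#'
#' @param list_a,list_b Character vectors of gene identifiers.
#' @param universe_size Size of the gene universe both lists are drawn from.
#' @return List of class `"set_overlap"`: `n_a`, `n_b`, `universe`,
#'   `observed`, `expected`, `p`.
#' @export
set_overlap <- function(list_a, list_b, universe_size) {
  a <- unique(list_a); b <- unique(list_b)
  if (length(a) > universe_size || length(b) > universe_size)
    stop("list larger than the universe", call. = FALSE)
  obs <- length(intersect(a, b))
  structure(list(n_a = length(a), n_b = length(b),
                 universe = universe_size, observed = obs,
                 expected = length(a) * length(b) / universe_size,
                 p = phyper(obs - 1, length(a), universe_size - length(a),
                            length(b), lower.tail = FALSE)),
            class = "set_overlap")
}
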