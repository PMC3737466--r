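#' Read and write the package's tab-separated tables
#'
#' Spot tables, truth tables, class-call tables and compendium matrices are
#' exchanged as plain tab-separated text with a header line.
#'
#' @param x Object to write (see details of each function).
#' @param path File path.
#' @return `read_*` functions return the parsed object; `write_*` functions
#'   return `path` invisibly.
#' @name crossarray_io
NULL

#' @rdname crossarray_io
#' @export
write_spot_table <- function(x, path) {
  stopifnot(all(c("probe", "array", "block", "bio_rep", "orientation",
                  "ch1", "ch2", "valid") %in% names(x)))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname crossarray_io
#' @export
read_spot_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  x$valid <- as.logical(x$valid)
  x
}

#' @rdname crossarray_io
#' @export
write_class_vector <- function(x, path) {
  write.table(data.frame(probe = names(x), class = unname(x)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname crossarray_io
#' @export
read_class_vector <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  setNames(x$class, x$probe)
}

#' @rdname crossarray_io
#' @export
write_compendium <- function(x, path) {
  write.table(data.frame(gene = rownames(x), x, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname crossarray_io
#' @export
read_compendium <- function(path) {
  x <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  m
}
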