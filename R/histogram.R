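#' Discrete count histogram
#'
#' Container for a discrete frequency distribution: non-negative integer
#' occurrence counts \eqn{n_j} over \eqn{k} labelled bins.  This is the
#' distribution \eqn{P = \{n_j/n\}} underlying the Renyi entropy and all
#' point divergence gain computations.  Zero-count bins are legitimate and
#' are kept: they can serve as targets of an exchange (an intensity that
#' appears in the second frame but not in the first).
#'
#' @param counts numeric vector of non-negative integer-valued counts, one
#'   per bin.  At least one count must be positive.
#' @param labels optional vector of unique bin labels (intensity values).
#'   Defaults to the names of `counts`, or to `0, 1, ..., k-1`.
#' @return an object of class `count_histogram` with fields `counts`,
#'   `labels`, `n` (total count) and `k` (number of bins).
#' @examples
#' h <- count_histogram(c(3, 1))
#' renyi_entropy(h, alpha = 2)
#' @export
count_histogram <- function(counts, labels = NULL) {
  if (length(counts) < 1L) stop("histogram needs at least one bin")
  if (!.is_count_vector(counts)) {
    stop("counts must be finite, non-negative and integer-valued")
  }
  counts <- round(as.numeric(counts))
  if (is.null(labels)) {
    labels <- if (!is.null(names(counts))) names(counts) else seq_along(counts) - 1
  }
  if (length(labels) != length(counts)) stop("labels and counts lengths differ")
  if (anyDuplicated(labels)) stop("bin labels must be unique")
  n <- sum(counts)
  if (n < 1) stop("empty distribution")
  structure(list(counts = counts, labels = labels, n = n, k = length(counts)),
            class = "count_histogram")
}

#' @export
print.count_histogram <- function(x, ...) {
  cat(sprintf("<count_histogram: %d bins (%d occupied), n = %s>\n",
              x$k, sum(x$counts > 0), format(x$n, scientific = FALSE)))
  invisible(x)
}

# index of a bin label, with a clear error if absent
.bin_index <- function(hist, label, what = "bin") {
  i <- match(label, hist$labels)
  if (is.na(i)) stop(sprintf("%s label '%s' not present in histogram", what, label))
  i
}

#' Read / write a histogram as two-column CSV
#'
#' The on-disk format is `bin_label,count` with a header row, one row per
#' bin (zero-count bins included).
#'
#' @param hist a [count_histogram()].
#' @param path file path.
#' @return `write_histogram_csv` returns `path` invisibly;
#'   `read_histogram_csv` returns a `count_histogram`.
#' @export
write_histogram_csv <- function(hist, path) {
  stopifnot(inherits(hist, "count_histogram"))
  utils::write.csv(
    data.frame(bin_label = hist$labels, count = hist$counts),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_histogram_csv
#' @export
read_histogram_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("bin_label", "count") %in% names(d))) {
    stop("expected columns bin_label, count")
  }
  count_histogram(d$count, labels = d$bin_label)
}

#' Alpha grids for spectra
#'
#' Named grids of the Renyi order alpha used throughout: `"default13"` is
#' the 13-point working grid `{0.1, 0.3, 0.5, 0.7, 0.99, 1.3, 1.5, 1.7,
#' 2.0, 2.5, 3.0, 3.5, 4.0}`; `"grid40"` is the denser 40-point grid
#' `{0.1, ..., 0.9, 0.99, 1.1, ..., 4.0}` (step 0.1, with 0.99 replacing
#' 1.0).  A numeric vector is validated and returned as-is.
#'
#' @param x grid name or strictly increasing numeric vector of
#'   non-negative alpha values.
#' @return numeric vector of alpha values.
#' @export
alpha_grid <- function(x = "default13") {
  if (is.character(x)) {
    x <- match.arg(x, c("default13", "grid40"))
    vals <- switch(x,
      default13 = c(0.1, 0.3, 0.5, 0.7, 0.99, 1.3, 1.5, 1.7, 2.0, 2.5, 3.0, 3.5, 4.0),
      grid40 = c(seq(0.1, 0.9, by = 0.1), 0.99, seq(1.1, 4.0, by = 0.1)))
    return(vals)
  }
  if (!is.numeric(x) || length(x) < 1L || anyNA(x)) stop("invalid alpha grid")
  if (any(x < 0)) stop("alpha values must be non-negative")
  if (any(diff(x) <= 0)) stop("alpha grid must be strictly increasing (no duplicates)")
  as.numeric(x)
}
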