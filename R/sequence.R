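# Frame sequences, pixel transition tables, per-pixel PDG maps and the
# macroscopic PDGE / PDGED alpha spectra.

#' Ordered sequence of grayscale frames
#'
#' @param frames list of 2-D integer-valued matrices, all of the same
#'   shape.
#' @param bit_depth 8, 12 or 16; inferred from the maximum intensity when
#'   omitted (<= 255: 8; <= 4095: 12; else 16).
#' @return an object of class `frame_sequence` with fields `frames`,
#'   `bit_depth` and `shape`.
#' @export
frame_sequence <- function(frames, bit_depth = NULL) {
  if (!is.list(frames) || length(frames) < 1L) stop("need at least one frame")
  shp <- dim(frames[[1]])
  if (is.null(shp) || length(shp) != 2L) stop("frames must be 2-D matrices")
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!identical(dim(f), shp)) stop(sprintf("frame %d has a different shape", i))
    if (!.is_count_vector(as.vector(f))) {
      stop(sprintf("frame %d has non-integer or negative intensities", i))
    }
    storage.mode(f) <- "integer"       # canonical storage for raster data
    frames[[i]] <- f
  }
  maxv <- max(vapply(frames, max, numeric(1)))
  if (is.null(bit_depth)) {
    bit_depth <- if (maxv <= 255) 8L else if (maxv <= 4095) 12L else 16L
  }
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 12L, 16L)) stop("bit_depth must be 8, 12 or 16")
  if (maxv > 2^bit_depth - 1) stop("intensities exceed the stated bit depth")
  structure(list(frames = frames, bit_depth = bit_depth, shape = shp),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence: %d frames, %d x %d, %d-bit>\n",
              length(x$frames), x$shape[1], x$shape[2], x$bit_depth))
  invisible(x)
}

#' Intensity histogram of one frame
#'
#' Counts over the full native intensity range `0 .. 2^bit_depth - 1`
#' (empty levels kept), so that any intensity of a companion frame is a
#' valid exchange target.
#'
#' @param frame integer matrix.
#' @param bit_depth 8, 12 or 16.
#' @return a [count_histogram()] labelled by intensity.
#' @export
frame_hist <- function(frame, bit_depth = 8L) {
  nlev <- 2L^as.integer(bit_depth)
  count_histogram(tabulate(as.vector(frame) + 1L, nbins = nlev),
                  labels = 0:(nlev - 1L))
}

# pooled intensity histogram of two frames (alternative PDG basis)
.pooled_hist <- function(a, b, bit_depth) {
  nlev <- 2L^as.integer(bit_depth)
  count_histogram(tabulate(c(as.vector(a), as.vector(b)) + 1L, nbins = nlev),
                  labels = 0:(nlev - 1L))
}

#' Pixel transition table of a frame pair
#'
#' Tallies \eqn{n_{lm}}, the number of pixel positions whose intensity is
#' `l` in `frame_a` and `m` in `frame_b`.  The marginal over m is
#' `frame_a`'s intensity histogram; the marginal over l is `frame_b`'s.
#'
#' @param frame_a,frame_b integer matrices of the same shape.
#' @return an object of class `transition_table` with fields `l`, `m`,
#'   `n_lm` (parallel vectors over the realized transitions), `total`
#'   (pixel count) and `encode_base`.
#' @export
transition_table <- function(frame_a, frame_b) {
  if (!identical(dim(frame_a), dim(frame_b))) stop("frames differ in shape")
  L <- max(frame_a, frame_b) + 1
  code <- as.vector(frame_a) * L + as.vector(frame_b)
  tab <- table(code)
  codes <- as.numeric(names(tab))
  structure(list(l = codes %/% L, m = codes %% L, n_lm = as.numeric(tab),
                 total = length(code), encode_base = L),
            class = "transition_table")
}

# omega per realized transition of a table, given the basis histogram
.omega_table <- function(tt, base_hist, alpha, log_base) {
  il <- match(tt$l, base_hist$labels)
  im <- match(tt$m, base_hist$labels)
  if (anyNA(il) || anyNA(im)) {
    stop("transition intensity outside the basis histogram's bins")
  }
  nl <- base_hist$counts[il]
  nm <- base_hist$counts[im]
  if (any(nl < 1)) {
    stop("basis histogram has zero count for a realized source intensity")
  }
  .omega_counts(nl, nm, same = (tt$l == tt$m), alpha = alpha,
                core = .hist_core(base_hist$counts), log_base = log_base)
}

#' Per-pixel point divergence gain map
#'
#' For each pixel position i the value \eqn{\Omega_\alpha(a_i \to b_i)}:
#' the information gained or lost when the first frame's intensity is
#' exchanged for the second frame's at that position, relative to the
#' basis histogram.  By default the basis is the first frame's whole-image
#' histogram, so every exchange removes from an occupied bin; `"pooled"`
#' uses the combined histogram of both frames.  Each distinct transition
#' (a_i, b_i) is evaluated once and broadcast to all pixels realizing it.
#'
#' @inheritParams transition_table
#' @param alpha non-negative Renyi order.
#' @param log_base 2 (bits, default) or `"e"`.
#' @param basis `"first"` (default) or `"pooled"`.
#' @param bit_depth native depth; inferred from the pair when omitted.
#' @return an object of class `pdg_map` with fields `values` (numeric
#'   matrix), `alpha`, `log_base`, `basis`.
#' @export
pdg_map <- function(frame_a, frame_b, alpha, log_base = 2,
                    basis = c("first", "pooled"), bit_depth = NULL) {
  basis <- match.arg(basis)
  .check_scalar_alpha(alpha)
  if (!identical(dim(frame_a), dim(frame_b))) stop("frames differ in shape")
  if (is.null(bit_depth)) {
    maxv <- max(frame_a, frame_b)
    bit_depth <- if (maxv <= 255) 8L else if (maxv <= 4095) 12L else 16L
  }
  bh <- if (basis == "first") frame_hist(frame_a, bit_depth)
        else .pooled_hist(frame_a, frame_b, bit_depth)
  tt <- transition_table(frame_a, frame_b)
  om <- .omega_table(tt, bh, alpha, log_base)
  L <- tt$encode_base
  code <- as.vector(frame_a) * L + as.vector(frame_b)
  vals <- om[match(code, tt$l * L + tt$m)]
  structure(list(values = matrix(vals, nrow(frame_a), ncol(frame_a)),
                 alpha = alpha, log_base = log_base, basis = basis),
            class = "pdg_map")
}

#' @export
print.pdg_map <- function(x, ...) {
  cat(sprintf("<pdg_map: %d x %d, alpha = %g, basis = %s, range [%.4g, %.4g]>\n",
              nrow(x$values), ncol(x$values), x$alpha, x$basis,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Point divergence gain entropy (PDGE) of a frame pair
#'
#' \eqn{I_\alpha = \sum_i |\Omega_\alpha(a_i \to b_i)| = \sum_{l,m} n_{lm}
#' |\Omega_\alpha(l \to m)|}: the absolute information change summed over
#' all pixels.  Absolute values keep gains and losses from cancelling.
#'
#' @param tt a [transition_table()].
#' @param base_hist the basis histogram (normally the first frame's, from
#'   [frame_hist()]).
#' @inheritParams pdg_map
#' @return non-negative scalar.
#' @export
pdge <- function(tt, base_hist, alpha, log_base = 2) {
  stopifnot(inherits(tt, "transition_table"), inherits(base_hist, "count_histogram"))
  .check_scalar_alpha(alpha)
  om <- .omega_table(tt, base_hist, alpha, log_base)
  sum(tt$n_lm * abs(om))
}

#' Point divergence gain entropy density (PDGED) of a frame pair
#'
#' \eqn{P_\alpha = \sum_{l,m} \chi_{lm} |\Omega_\alpha(l \to m)|} with
#' \eqn{\chi_{lm} = 1} iff the transition l -> m is realized at least
#' once.  Each realized intensity pair contributes once regardless of its
#' multiplicity (distinct pairs contribute separately even if their omega
#' values coincide numerically), which makes \eqn{P_\alpha} more sensitive
#' to rare phenomena.  Always \eqn{0 \le P_\alpha \le I_\alpha}.
#'
#' @inheritParams pdge
#' @return non-negative scalar.
#' @export
pdged <- function(tt, base_hist, alpha, log_base = 2) {
  stopifnot(inherits(tt, "transition_table"), inherits(base_hist, "count_histogram"))
  .check_scalar_alpha(alpha)
  om <- .omega_table(tt, base_hist, alpha, log_base)
  sum(abs(om))
}

#' PDGE / PDGED alpha spectra of a frame sequence
#'
#' For every frame pair (t, t+lag) and every alpha of the grid, the
#' macroscopic values \eqn{I_\alpha(t)} and \eqn{P_\alpha(t)}.  Pair t is
#' attributed to image index t (a series of N frames yields N - lag rows
#' per alpha).
#'
#' @param seq a [frame_sequence()].
#' @param alphas alpha grid (see [alpha_grid()]).
#' @param lag time lag s between the paired frames; default 1
#'   (consecutive frames).
#' @inheritParams pdg_map
#' @return a data frame of class `pdg_spectra` with columns `pair_index`,
#'   `alpha`, `I_alpha`, `P_alpha` and attributes `alphas`, `lag`,
#'   `log_base`, `basis`.
#' @export
pdg_spectra <- function(seq, alphas = alpha_grid("default13"), lag = 1L,
                        log_base = 2, basis = c("first", "pooled")) {
  stopifnot(inherits(seq, "frame_sequence"))
  basis <- match.arg(basis)
  alphas <- alpha_grid(alphas)
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be a positive integer")
  N <- length(seq)
  if (lag >= N) stop("lag must be smaller than the sequence length")
  out <- vector("list", N - lag)
  for (t in seq_len(N - lag)) {
    a <- seq$frames[[t]]
    b <- seq$frames[[t + lag]]
    bh <- if (basis == "first") frame_hist(a, seq$bit_depth)
          else .pooled_hist(a, b, seq$bit_depth)
    tt <- transition_table(a, b)
    I <- P <- numeric(length(alphas))
    for (j in seq_along(alphas)) {
      om <- .omega_table(tt, bh, alphas[j], log_base)
      I[j] <- sum(tt$n_lm * abs(om))
      P[j] <- sum(abs(om))
    }
    out[[t]] <- data.frame(pair_index = t, alpha = alphas,
                           I_alpha = I, P_alpha = P)
  }
  res <- do.call(rbind, out)
  attr(res, "alphas") <- alphas
  attr(res, "lag") <- lag
  attr(res, "log_base") <- log_base
  attr(res, "basis") <- basis
  class(res) <- c("pdg_spectra", "data.frame")
  res
}

#' Peak-vs-monotone classification of an alpha spectrum
#'
#' A spectrum \eqn{I_\alpha = f(\alpha)} (or \eqn{P_\alpha}) with an
#' interior maximum indicates multifractal image content; a monotone
#' spectrum indicates unifractal / Euclidean content.  The maximum counts
#' as interior only if it strictly exceeds both grid endpoints (beyond a
#' tiny relative guard against floating-point noise).
#'
#' @param alphas alpha grid.
#' @param values spectrum values on that grid.
#' @return list with elements `multifractal` (logical) and `alpha_peak`
#'   (the argmax alpha).
#' @export
classify_spectrum <- function(alphas, values) {
  stopifnot(length(alphas) == length(values), length(values) >= 3L)
  i <- which.max(values)
  G <- length(values)
  edge <- max(values[1], values[G])
  interior <- i > 1L && i < G && values[i] > edge * (1 + 1e-12) + 1e-300
  list(multifractal = interior, alpha_peak = alphas[i])
}

#' Read / write spectra as long-form CSV
#'
#' Columns `pair_index, alpha, I_alpha, P_alpha`; a leading `#` comment
#' line records the lag and log base.
#'
#' @param spectra a [pdg_spectra()] result.
#' @param path file path.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(inherits(spectra, "pdg_spectra"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pdgain spectra lag=%d log_base=%s basis=%s",
                     attr(spectra, "lag"), format(attr(spectra, "log_base")),
                     attr(spectra, "basis")), con)
  utils::write.csv(as.data.frame(spectra), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  need <- c("pair_index", "alpha", "I_alpha", "P_alpha")
  if (!all(need %in% names(d))) stop("not a spectra CSV")
  attr(d, "alphas") <- sort(unique(d$alpha))
  class(d) <- c("pdg_spectra", "data.frame")
  d
}
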