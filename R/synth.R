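# Synthetic fixture sequences with known ground truth, standing in for
# camera / microscopy series: a translating square, a symmetric focus
# stack, and a seeded noise pair.

# separable Gaussian blur with edge-replicating padding; sigma 0 = identity
.gauss_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  kk <- stats::dnorm(-r:r, sd = sigma)
  kk <- kk / sum(kk)
  blur1d <- function(m) {                        # along rows of m
    nr <- nrow(m)
    idx <- pmin(pmax(outer(seq_len(nr), -r:r, `+`), 1L), nr)
    out <- matrix(0, nr, ncol(m))
    for (j in seq_along(kk)) out <- out + kk[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(blur1d(t(blur1d(mat))))
}

.square_frame <- function(shape, top_left, side, bg, fg) {
  f <- matrix(bg, shape[1], shape[2])
  r <- top_left[1] + seq_len(side) - 1L
  c <- top_left[2] + seq_len(side) - 1L
  if (min(r, c) < 1L || max(r) > shape[1] || max(c) > shape[2]) {
    stop("object out of bounds")
  }
  f[r, c] <- fg
  f
}

#' Synthetic test sequences
#'
#' Three deterministic (seeded) fixture kinds:
#' \describe{
#'   \item{`moving_square`}{a `side`-pixel square of intensity `fg` on a
#'     constant `bg` background, translating by `step` (rows, cols) each
#'     frame.  The changed-pixel set of each pair is the symmetric
#'     difference of the two square positions; the square's top-left
#'     corners are returned in the `positions` attribute.}
#'   \item{`focus_stack`}{a fixed high-contrast object (bright disk with
#'     a dark inner square) blurred with a Gaussian whose width grows
#'     linearly with the distance from the central frame — a symmetric
#'     defocus series, sharpest at the middle.  The `focal_index`
#'     attribute holds the ground-truth in-focus frame.}
#'   \item{`noise_pair`}{two frames: a smooth gradient plus seeded
#'     Gaussian texture, and a copy with a fraction `noise_rate` of its
#'     pixels replaced by uniform random intensities (`changed`
#'     attribute: logical matrix of replaced pixels).}
#' }
#'
#' @param kind fixture kind.
#' @param frames number of frames (default 10; 21 for `focus_stack`;
#'   `noise_pair` always has 2).
#' @param shape `c(rows, cols)`, default 64 x 64.
#' @param bg,fg background / object intensity (8-bit defaults 32 / 224).
#' @param side square side in pixels (default 12).
#' @param step per-frame displacement `c(rows, cols)` of the square.
#' @param start top-left corner of the square in frame 1.
#' @param blur_max Gaussian sigma at the stack ends (default 10: the blur
#'   width grows by one pixel per frame on the default 21-frame stack).
#' @param noise_rate fraction of replaced pixels in `noise_pair`.
#' @param seed RNG seed; identical specs give identical sequences.
#' @param bit_depth intensity depth of the fixture (default 8).
#' @return a [frame_sequence()] with ground-truth attributes as above.
#' @export
synth_sequence <- function(kind = c("moving_square", "focus_stack", "noise_pair"),
                           frames = NULL, shape = c(64L, 64L), bg = 32L,
                           fg = 224L, side = 12L, step = c(2L, 0L),
                           start = c(9L, 9L), blur_max = 10, noise_rate = 0.05,
                           seed = 1L, bit_depth = 8L) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  top <- 2L^as.integer(bit_depth) - 1L
  if (kind == "moving_square") {
    if (is.null(frames)) frames <- 10L
    positions <- lapply(seq_len(frames) - 1L, function(t) start + t * step)
    fr <- lapply(positions, .square_frame, shape = shape, side = side,
                 bg = bg, fg = fg)
    out <- frame_sequence(fr, bit_depth)
    attr(out, "positions") <- positions
    out
  } else if (kind == "focus_stack") {
    if (is.null(frames)) frames <- 21L
    if (frames %% 2L == 0L) stop("focus_stack needs an odd frame count")
    mid <- (frames + 1L) %/% 2L
    rr <- row(matrix(0, shape[1], shape[2]))
    cc <- col(matrix(0, shape[1], shape[2]))
    ctr <- (shape + 1) / 2
    obj <- matrix(bg, shape[1], shape[2])
    obj[(rr - ctr[1])^2 + (cc - ctr[2])^2 <= (min(shape) / 5)^2] <- fg
    inner <- abs(rr - ctr[1]) <= min(shape) / 12 &
             abs(cc - ctr[2]) <= min(shape) / 12
    obj[inner] <- bg %/% 2L
    fr <- lapply(seq_len(frames), function(t) {
      sigma <- blur_max * abs(t - mid) / (mid - 1L)
      b <- .round_half_away(.gauss_blur(obj, sigma))
      matrix(pmin(pmax(b, 0), top), shape[1], shape[2])
    })
    out <- frame_sequence(fr, bit_depth)
    attr(out, "focal_index") <- mid
    out
  } else {
    .with_seed(seed, {
      grad <- .round_half_away(
        (row(matrix(0, shape[1], shape[2])) + col(matrix(0, shape[1], shape[2]))) /
          sum(shape) * top * 0.5)
      tex <- matrix(.round_half_away(stats::rnorm(prod(shape), 0, top / 32)),
                    shape[1], shape[2])
      f1 <- pmin(pmax(grad + tex + bg, 0), top)
      changed <- matrix(stats::runif(prod(shape)) < noise_rate,
                        shape[1], shape[2])
      f2 <- f1
      f2[changed] <- sample(0:top, sum(changed), replace = TRUE)
      out <- frame_sequence(list(f1, f2), bit_depth)
      attr(out, "changed") <- changed
      out
    })
  }
}
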