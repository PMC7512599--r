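# Segmentation on PDG maps: time-stable zero masks, extreme-value
# tracking masks, 8-bit rendering, and Least Information Loss bit-depth
# reduction.

.new_mask <- function(mask, rule, param) {
  structure(mask, rule = rule, param = param, class = c("segmentation_mask", "matrix"))
}

#' Zero-stability segmentation mask
#'
#' Marks pixels whose PDG magnitude is at most `tol`.  With the default
#' `tol = 0` these are the exact zeros of the map: unchanged pixels
#' (a_i = b_i) and balanced exchanges (n_l = n_m + 1) — the time-stable
#' content of the frame pair.  Joining such masks across a stack traces
#' time-stable objects in 3-D.
#'
#' @param map a [pdg_map()].
#' @param tol non-negative tolerance on |Omega| (default 0, exact zeros).
#' @return logical matrix of class `segmentation_mask`.
#' @export
stability_mask <- function(map, tol = 0) {
  stopifnot(inherits(map, "pdg_map"), tol >= 0)
  .new_mask(abs(map$values) <= tol, "zero_stability", tol)
}

#' Extreme-value segmentation mask
#'
#' Marks the `fraction` of pixels with the most positive (`side = "top"`)
#' or most negative (`side = "bottom"`) PDG values; on a frame pair with
#' a moving object the top mask covers the object's new position and the
#' bottom mask its old one.  Ties at the cut value are all included, so
#' the mask may exceed the nominal fraction.  A constant map has no
#' strict extremes and yields an empty mask.  Alternatively an absolute
#' cutoff may be given via `threshold` (top: Omega >= threshold; bottom:
#' Omega <= threshold).
#'
#' @param map a [pdg_map()].
#' @param fraction pixel fraction in (0, 1].
#' @param side `"top"` or `"bottom"`.
#' @param threshold optional absolute Omega cutoff overriding `fraction`.
#' @return logical matrix of class `segmentation_mask`.
#' @export
extreme_mask <- function(map, fraction = NULL, side = c("top", "bottom"),
                         threshold = NULL) {
  stopifnot(inherits(map, "pdg_map"))
  side <- match.arg(side)
  v <- map$values
  if (!is.null(threshold)) {
    mask <- if (side == "top") v >= threshold else v <= threshold
    return(.new_mask(mask, paste0(side, "_extreme"), threshold))
  }
  if (is.null(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  if (max(v) == min(v)) {
    return(.new_mask(matrix(FALSE, nrow(v), ncol(v)),
                     paste0(side, "_extreme"), fraction))
  }
  kth <- ceiling(fraction * length(v))
  mask <- if (side == "top") v >= sort(v, decreasing = TRUE)[kth]
          else v <= sort(v)[kth]
  .new_mask(mask, paste0(side, "_extreme"), fraction)
}

#' Render a PDG map as an 8-bit raster
#'
#' Symmetric linear mapping of [-M, +M] (M = max |Omega|) to 0..255:
#' `floor((v + M) / (2M) * 256)` clipped to 255, so zero maps to the 128
#' midpoint, -M to 0 and +M to 255.  Invariant under multiplication of
#' the map by a positive scalar.  An all-zero map renders uniform
#' mid-gray (128).
#'
#' @param map a [pdg_map()].
#' @return integer matrix with values in 0..255.
#' @export
render_map <- function(map) {
  stopifnot(inherits(map, "pdg_map"))
  v <- map$values
  if (any(!is.finite(v))) stop("map contains non-finite values")
  M <- max(abs(v))
  if (M == 0) {
    px <- matrix(128L, nrow(v), ncol(v))
  } else {
    px <- floor((v + M) / (2 * M) * 256)
    px[px > 255] <- 255
    storage.mode(px) <- "integer"
  }
  px
}

#' Diverging color preview of a PDG map
#'
#' Blue (negative) - gray (zero) - red (positive) rendering, returned as
#' an rows x cols x 3 integer array of 8-bit RGB values.
#'
#' @param map a [pdg_map()].
#' @return integer array `c(rows, cols, 3)`.
#' @export
render_map_rgb <- function(map) {
  px <- render_map(map)            # 0..255, 128 = zero
  s <- (px - 128L) / 127.5         # approx -1..1
  r <- ifelse(s > 0, 128 + 127 * s, 128 * (1 + s) * 0.85)
  b <- ifelse(s < 0, 128 - 127 * s, 128 * (1 - s) * 0.85)
  g <- 128 * (1 - abs(s)) * 0.9
  out <- array(0L, c(nrow(px), ncol(px), 3L))
  out[, , 1] <- as.integer(pmin(pmax(round(r), 0), 255))
  out[, , 2] <- as.integer(pmin(pmax(round(g), 0), 255))
  out[, , 3] <- as.integer(pmin(pmax(round(b), 0), 255))
  out
}

#' Least Information Loss bit-depth reduction
#'
#' Builds the pooled intensity histogram of the whole series, drops the
#' empty bins (shifting the occupied levels up to consecutive ranks) and
#' linearly rescales the ranks to the full target range
#' `0 .. 2^target_depth - 1`.  Intensity order is preserved exactly, and
#' no occupied level collides with another unless the target range is
#' smaller than the number of occupied levels.
#'
#' @param seq a [frame_sequence()] of depth greater than `target_depth`.
#' @param target_depth target bit depth (default 8).
#' @return a [frame_sequence()] of the target depth.
#' @export
lil_convert <- function(seq, target_depth = 8L) {
  stopifnot(inherits(seq, "frame_sequence"))
  target_depth <- as.integer(target_depth)
  if (seq$bit_depth <= target_depth) {
    stop("input bit depth must exceed the target depth")
  }
  levels <- sort(unique(unlist(lapply(seq$frames, as.vector))))
  R <- length(levels)
  if (R < 2L) stop("fewer than 2 occupied intensity levels")
  newval <- .round_half_away((seq_along(levels) - 1) / (R - 1) *
                               (2^target_depth - 1))
  frames <- lapply(seq$frames, function(f) {
    matrix(newval[match(as.vector(f), levels)], nrow(f), ncol(f))
  })
  frame_sequence(frames, bit_depth = target_depth)
}
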