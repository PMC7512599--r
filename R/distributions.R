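# Discretized reference distributions (Cauchy, Gauss, Levy, Rayleigh)
# used to study the PDG matrix on typical unimodal histograms.

# canonical (family, parameter, support) combinations
.dist_canonical <- list(
  levy = list(list(c = 5, support = c(1, 256)),
              list(c = 7, support = c(1, 256)),
              list(c = 3, support = c(1, 85))),
  cauchy = list(list(c = 7, support = c(-127, 127)),
                list(c = 3.5, support = c(-44, 44))),
  gauss = list(list(c = 4, sigma = 1, support = c(-4, 4)),
               list(c = 3, sigma = 10, support = c(-29, 29)),
               list(c = 4, sigma = 10, support = c(-36, 36)),
               list(c = 10, sigma = 10, support = c(-64, 64))),
  rayleigh = list(list(c = 10, b = 16, support = c(1, 108)))
)

#' Specification of a discretized test distribution
#'
#' Describes one of the four reference densities, a count magnitude
#' exponent `c` (counts scale as \eqn{10^c}) and an integer support.  The
#' densities are, with x integer:
#' \itemize{
#'   \item Levy (unit scale): \eqn{e^{-1/(2x)} / \sqrt{2\pi x^3}}, x >= 1
#'   \item Cauchy: \eqn{1 / (\pi (1 + x^2))}
#'   \item Gauss: \eqn{e^{-x^2/(2\sigma^2)} / (\sigma\sqrt{2\pi})}
#'   \item Rayleigh: \eqn{(x/b^2)\, e^{-x^2/(2b^2)}}, x >= 1
#' }
#' Only the canonical parameter/support combinations (see
#' [generate_histogram()]) are accepted silently; other combinations
#' require an explicit `support` and raise a warning.
#'
#' @param family one of `"levy"`, `"cauchy"`, `"gauss"`, `"rayleigh"`.
#' @param c magnitude exponent; bin counts are `round(10^c * f(x))`.
#' @param sigma Gauss width (gauss only).
#' @param b Rayleigh scale (rayleigh only).
#' @param support integer interval `c(x_min, x_max)`; defaults to the
#'   canonical support for the given parameters.
#' @return an object of class `dist_spec`.
#' @export
dist_spec <- function(family = c("levy", "cauchy", "gauss", "rayleigh"),
                      c, sigma = NULL, b = NULL, support = NULL) {
  family <- match.arg(family)
  if (family == "gauss" && is.null(sigma)) stop("gauss requires sigma")
  if (family == "rayleigh" && is.null(b)) stop("rayleigh requires b")
  canon <- NULL
  for (combo in .dist_canonical[[family]]) {
    ok <- isTRUE(all.equal(combo$c, c)) &&
      (is.null(combo$sigma) || isTRUE(all.equal(combo$sigma, sigma))) &&
      (is.null(combo$b) || isTRUE(all.equal(combo$b, b)))
    if (ok) { canon <- combo; break }
  }
  if (is.null(support)) {
    if (is.null(canon)) {
      stop("no canonical support for this parameter combination; supply `support`")
    }
    support <- canon$support
  } else if (is.null(canon) || !identical(as.numeric(support),
                                          as.numeric(canon$support))) {
    warning("non-canonical distribution parameters or support")
  }
  if (length(support) != 2L || support[1] > support[2]) stop("empty support")
  if (family %in% c("levy", "rayleigh") && support[1] < 1) {
    stop("levy/rayleigh support must start at x >= 1")
  }
  structure(list(family = family, c = c, sigma = sigma, b = b,
                 support = as.integer(support)),
            class = "dist_spec")
}

.dist_density <- function(spec, x) {
  switch(spec$family,
    levy = exp(-1 / (2 * x)) / sqrt(2 * pi * x^3),
    cauchy = 1 / (pi * (1 + x^2)),
    gauss = exp(-x^2 / (2 * spec$sigma^2)) / (spec$sigma * sqrt(2 * pi)),
    rayleigh = (x / spec$b^2) * exp(-x^2 / (2 * spec$b^2)))
}

#' Generate a discretized reference histogram
#'
#' Bin count at integer x equals `round(10^c * f(x))` with `f` the family
#' density and rounding half-away-from-zero (Matlab semantics).  Zero
#' counts arising in the tails are kept as empty bins; they are valid
#' exchange targets for [pdg()].  Generation is fully deterministic.
#'
#' @param spec a [dist_spec()].
#' @return a [count_histogram()] with the support integers as bin labels.
#' @examples
#' generate_histogram(dist_spec("gauss", c = 4, sigma = 1))
#' @export
generate_histogram <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  x <- seq(spec$support[1], spec$support[2])
  counts <- .round_half_away(10^spec$c * .dist_density(spec, x))
  count_histogram(counts, labels = x)
}
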