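# Core Renyi-entropy machinery: entropy, point information gain (PIG),
# point divergence gain (PDG) and the histogram-level PDG matrix.

# Precomputed per-histogram quantities reused across many exchanges.
.hist_core <- function(counts) {
  occ <- counts[counts > 0]
  list(counts = counts, n = sum(counts), k_occ = length(occ), M = max(occ))
}

# Vectorized PDG over count pairs (nl, nm) of a single base histogram.
#
# Grouping matters for exactness: the two differences are paired so that
# the exchange nl = nm + 1 (a permutation of the count multiset) yields a
# floating-point-exact zero, and so that at alpha = 2 the value depends on
# (nm - nl) only, bit-for-bit.  Counts are rescaled by the maximum count
# only when the raw powers would overflow; for ordinary image histograms
# the powers stay exact integers well below 2^53.
.omega_counts <- function(nl, nm, same, alpha, core, log_base = 2) {
  ld <- .logdiv(log_base)
  if (alpha == 0) {
    # support-size semantics: H0 = log(#occupied bins)
    k0 <- core$k_occ
    knew <- k0 - (nl == 1) + (nm == 0)
    val <- (log(knew) - log(k0)) / ld
  } else if (alpha == 1) {
    # Shannon limit, per-exchange closed form with 0*log(0) = 0
    val <- ((.xlogx(nm) - .xlogx(nl - 1)) + (.xlogx(nl) - .xlogx(nm + 1))) /
      (core$n * ld)
  } else {
    M <- if (alpha * log(core$M + 1) < 600) 1 else core$M
    occ <- core$counts[core$counts > 0] / M
    cs <- sum(occ^alpha)
    d1 <- ((nl - 1) / M)^alpha - (nm / M)^alpha
    d2 <- ((nm + 1) / M)^alpha - (nl / M)^alpha
    val <- log1p((d1 + d2) / cs) / ((1 - alpha) * ld)
  }
  val[same] <- 0
  val
}

#' Renyi entropy of a count histogram
#'
#' \eqn{H_\alpha(P) = \frac{1}{1-\alpha}\log\sum_j p_j^\alpha} over the
#' occupied bins, with the Shannon entropy at \eqn{\alpha = 1} and the
#' support-size entropy \eqn{\log(\#\{j : n_j > 0\})} at \eqn{\alpha = 0}.
#' Zero-count bins never contribute (the \eqn{0^\alpha} terms, including
#' \eqn{0^0}, are excluded).
#'
#' @param hist a [count_histogram()].
#' @param alpha non-negative Renyi order.
#' @param log_base 2 (bits, default) or `"e"` (nats).
#' @return entropy in units of `log_base`.
#' @examples
#' renyi_entropy(count_histogram(rep(1, 8)), 2)   # log2(8) = 3 bits
#' @export
renyi_entropy <- function(hist, alpha, log_base = 2) {
  stopifnot(inherits(hist, "count_histogram"))
  .check_scalar_alpha(alpha)
  ld <- .logdiv(log_base)
  p <- hist$counts[hist$counts > 0] / hist$n
  if (alpha == 1) {
    -sum(p * log(p)) / ld
  } else if (alpha == 0) {
    log(length(p)) / ld
  } else {
    log(sum(p^alpha)) / ((1 - alpha) * ld)
  }
}

#' Point information gain
#'
#' Entropy change caused by removing one occurrence of phenomenon `i`:
#' \eqn{\Gamma_\alpha(i) = H_\alpha(P^{(i)}) - H_\alpha(P)}, where
#' \eqn{P^{(i)}} has count \eqn{n_i - 1} in bin `i` and total \eqn{n - 1}.
#'
#' @inheritParams renyi_entropy
#' @param i bin label of the removed occurrence (`n_i >= 1` required).
#' @return the gain in units of `log_base`.
#' @export
pig <- function(hist, i, alpha, log_base = 2) {
  stopifnot(inherits(hist, "count_histogram"))
  .check_scalar_alpha(alpha)
  ii <- .bin_index(hist, i, "phenomenon")
  if (hist$counts[ii] < 1) stop("phenomenon absent")
  if (hist$n < 2) stop("resulting distribution empty")
  counts2 <- hist$counts
  counts2[ii] <- counts2[ii] - 1
  h2 <- count_histogram(counts2, labels = hist$labels)
  renyi_entropy(h2, alpha, log_base) - renyi_entropy(hist, alpha, log_base)
}

#' Point divergence gain
#'
#' Entropy change caused by exchanging one occurrence of bin `l` for one of
#' bin `m`: \eqn{\Omega_\alpha(l \to m) = H_\alpha(P^{(l \to m)}) -
#' H_\alpha(P)}, where \eqn{P^{(l \to m)}} decrements \eqn{n_l} and
#' increments \eqn{n_m} (total unchanged).  For \eqn{\alpha \ne 0, 1} the
#' closed form
#' \deqn{\Omega_\alpha = \frac{1}{1-\alpha}\log\left(
#'   \frac{(n_l-1)^\alpha - n_l^\alpha + (n_m+1)^\alpha - n_m^\alpha}
#'        {C_\alpha} + 1\right), \quad C_\alpha = \sum_j n_j^\alpha,}
#' is used (evaluated log1p-style, since the shift is often tiny).  At
#' \eqn{\alpha = 1} the Shannon per-exchange closed form applies, at
#' \eqn{\alpha = 0} the change in support size.  `l == m` returns exactly
#' 0, as does any exchange with \eqn{n_l = n_m + 1} (a permutation of the
#' count multiset).  The value is positive when a frequent point replaces a
#' rare one (\eqn{n_l \gg n_m}) and negative in the opposite direction.
#'
#' @inheritParams renyi_entropy
#' @param l bin label the occurrence is removed from (`n_l >= 1`).
#' @param m bin label the occurrence is added to (`n_m >= 0`).
#' @return the gain in units of `log_base`.
#' @examples
#' h <- count_histogram(c(3, 1), labels = c("a", "b"))
#' pdg(h, "a", "b", alpha = 2)   # +0.3219 bits
#' @export
pdg <- function(hist, l, m, alpha, log_base = 2) {
  stopifnot(inherits(hist, "count_histogram"))
  .check_scalar_alpha(alpha)
  il <- .bin_index(hist, l, "source bin")
  im <- .bin_index(hist, m, "target bin")
  nl <- hist$counts[il]
  if (nl < 1) stop("cannot remove from empty bin")
  nm <- hist$counts[im]
  .omega_counts(nl, nm, same = (il == im), alpha = alpha,
                core = .hist_core(hist$counts), log_base = log_base)
}

#' Collision-entropy (alpha = 2) special case of the point divergence gain
#'
#' Direct evaluation of the simplification
#' \eqn{\Omega_2(l \to m) = -\log\left(\frac{2}{C_2}(n_m - n_l + 1) +
#' 1\right)} with \eqn{C_2 = \sum_j n_j^2}.  Agrees with
#' `pdg(hist, l, m, 2)` to floating-point accuracy; the value depends on
#' the count difference \eqn{n_m - n_l} only.
#'
#' @inheritParams pdg
#' @export
pdg_alpha2 <- function(hist, l, m, log_base = 2) {
  stopifnot(inherits(hist, "count_histogram"))
  il <- .bin_index(hist, l, "source bin")
  im <- .bin_index(hist, m, "target bin")
  nl <- hist$counts[il]
  if (nl < 1) stop("cannot remove from empty bin")
  if (il == im) return(0)
  nm <- hist$counts[im]
  c2 <- sum(hist$counts^2)
  -log1p(2 * (nm - nl + 1) / c2) / .logdiv(log_base)
}

#' Point divergence gain matrix of a histogram
#'
#' The k-by-k table with entry (l, m) equal to
#' \eqn{\Omega_\alpha(l \to m)} for the given base histogram.  Rows
#' correspond to the source bin l, columns to the target bin m.  Rows with
#' \eqn{n_l = 0} are undefined (one cannot remove an occurrence from an
#' empty bin) and are stored as `NA`; the diagonal of defined rows is
#' exactly 0.
#'
#' @inheritParams renyi_entropy
#' @return an object of class `pdg_matrix` with fields `values` (k x k
#'   numeric matrix with bin labels as dimnames), `alpha`, `log_base`,
#'   `c_alpha` (\eqn{C_\alpha = \sum_j n_j^\alpha} over occupied bins) and
#'   `base` (the histogram).
#' @export
pdg_matrix <- function(hist, alpha, log_base = 2) {
  stopifnot(inherits(hist, "count_histogram"))
  .check_scalar_alpha(alpha)
  k <- hist$k
  cnt <- hist$counts
  core <- .hist_core(cnt)
  nl <- matrix(cnt, k, k)                # rows: source bin l
  nm <- matrix(cnt, k, k, byrow = TRUE)  # cols: target bin m
  same <- diag(k) == 1
  vals <- .omega_counts(as.vector(nl), as.vector(nm), as.vector(same),
                        alpha, core, log_base)
  vals <- matrix(vals, k, k)
  vals[cnt == 0, ] <- NA_real_
  dimnames(vals) <- list(l = hist$labels, m = hist$labels)
  occ <- cnt[cnt > 0]
  c_alpha <- if (alpha == 0) length(occ) else sum(occ^alpha)
  structure(list(values = vals, alpha = alpha, log_base = log_base,
                 c_alpha = c_alpha, base = hist),
            class = "pdg_matrix")
}

#' @export
print.pdg_matrix <- function(x, ...) {
  cat(sprintf("<pdg_matrix: %d x %d, alpha = %g, C_alpha = %g>\n",
              nrow(x$values), ncol(x$values), x$alpha, x$c_alpha))
  invisible(x)
}

#' Read / write a PDG matrix as CSV
#'
#' The CSV carries the k-by-k table (rows = source bin l, columns = target
#' bin m, bin labels as row/column names) preceded by a `#`-comment line
#' with the metadata `alpha`, `log_base` and `c_alpha`.
#'
#' @param pm a [pdg_matrix()].
#' @param path file path.
#' @export
write_pdg_matrix_csv <- function(pm, path) {
  stopifnot(inherits(pm, "pdg_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# alpha=%.17g log_base=%s c_alpha=%.17g",
                     pm$alpha, format(pm$log_base), pm$c_alpha), con)
  utils::write.csv(as.data.frame(pm$values), con, row.names = TRUE)
  invisible(path)
}
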