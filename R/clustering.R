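# Clustering of an image series by its [I_alpha, P_alpha] spectra:
# feature assembly, z-score standardization, PCA projection, k-means++
# and consecutive relabeling along the series.

#' Feature matrix of a spectra table
#'
#' One row per frame pair (attributed image index t), columns
#' `[I_alpha1 .. I_alphaG, P_alpha1 .. P_alphaG]` — 26 features on the
#' default 13-point grid.  All pairs must share the same alpha grid.
#'
#' @param spectra a [pdg_spectra()] result (or the data frame read back
#'   from its CSV).
#' @return numeric matrix with `pair_index` row names and an `alphas`
#'   attribute.
#' @export
feature_matrix <- function(spectra) {
  d <- as.data.frame(spectra)
  need <- c("pair_index", "alpha", "I_alpha", "P_alpha")
  if (!all(need %in% names(d))) stop("not a spectra table")
  if (anyNA(d[need])) stop("spectra contain missing values")
  alphas <- sort(unique(d$alpha))
  pairs <- sort(unique(d$pair_index))
  d <- d[order(d$pair_index, d$alpha), ]
  if (nrow(d) != length(pairs) * length(alphas) ||
      !all(d$alpha == rep(alphas, length(pairs)))) {
    stop("inconsistent alpha grids across pairs")
  }
  G <- length(alphas)
  I <- matrix(d$I_alpha, ncol = G, byrow = TRUE)
  P <- matrix(d$P_alpha, ncol = G, byrow = TRUE)
  fm <- cbind(I, P)
  dimnames(fm) <- list(pairs, c(paste0("I_", alphas), paste0("P_", alphas)))
  attr(fm, "alphas") <- alphas
  fm
}

#' Column-wise z-score standardization
#'
#' Centers each feature column and scales it to unit standard deviation;
#' constant columns map to all-zero instead of dividing by zero.
#' Idempotent up to floating-point noise.
#'
#' @param fm numeric feature matrix with at least two rows.
#' @return matrix of the same shape.
#' @export
standardize_features <- function(fm) {
  fm <- as.matrix(fm)
  if (nrow(fm) < 2L) stop("standardization needs at least two rows")
  mu <- colMeans(fm)
  sd <- apply(fm, 2, stats::sd)
  out <- sweep(fm, 2, mu)
  nz <- sd > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, sd[nz], "/")
  out[, !nz] <- 0
  attr(out, "alphas") <- attr(fm, "alphas")
  out
}

# k-means++ seeding: indices of k distinct starting centers
.kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2, X[idx[1], ])^2)
  for (j in seq_len(k)[-1]) {
    cand <- which(d2 > 0)
    if (length(cand) == 0L) stop("fewer distinct rows than clusters")
    idx[j] <- if (length(cand) == 1L) cand else
      cand[sample.int(length(cand), 1L, prob = d2[cand])]
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[j], ])^2))
  }
  idx
}

#' Cluster an image series by its spectral features
#'
#' Pipeline: optional z-score standardization, projection onto the
#' principal components explaining at least `var_explained` of the
#' variance (or the raw feature space with `pca = FALSE`), then k-means
#' with k-means++ seeding and squared Euclidean distance (Lloyd
#' iterations).  `nstart` seeded restarts are run and the labeling with
#' the lowest within-cluster sum of squares is kept (ties: earliest
#' restart).  Fixed `seed` makes the result reproducible.
#'
#' If the matrix holds fewer distinct rows than `k`, the clustering is
#' degenerate: a warning is raised and the distinct rows become the
#' clusters (fewer than `k` non-empty groups).
#'
#' @param fm feature matrix from [feature_matrix()].
#' @param k requested number of clusters (2..6 in typical use).
#' @param seed integer RNG seed.
#' @param standardize apply [standardize_features()] first (default
#'   FALSE).
#' @param pca project onto principal components first (default TRUE).
#' @param var_explained cumulative variance ratio retained by the PCA
#'   projection (default 0.95).
#' @param nstart number of k-means++ restarts (default 10).
#' @return object of class `cluster_labels`: list with `labels` (one
#'   integer per row), `k`, `seed`.
#' @export
cluster_frames <- function(fm, k, seed = 1L, standardize = FALSE, pca = TRUE,
                           var_explained = 0.95, nstart = 10L) {
  X <- as.matrix(fm)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k > nrow(X)) stop("k exceeds the number of rows")
  if (standardize) X <- standardize_features(X)
  ndistinct <- nrow(unique(X))
  if (ndistinct < k) {
    warning("fewer distinct feature rows than clusters; degenerate clustering")
    u <- unique(X)
    labels <- match(apply(X, 1, paste, collapse = "\r"),
                    apply(u, 1, paste, collapse = "\r"))
    return(structure(list(labels = as.integer(labels), k = k, seed = seed),
                     class = "cluster_labels"))
  }
  if (pca) {
    pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    v <- pr$sdev^2
    if (sum(v) > 0) {
      ncomp <- which(cumsum(v) / sum(v) >= var_explained)[1]
      X <- pr$x[, seq_len(max(ncomp, 1L)), drop = FALSE]
    }
  }
  labels <- .with_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      km <- tryCatch({
        ctr <- X[.kmeanspp_centers(X, k), , drop = FALSE]
        suppressWarnings(stats::kmeans(X, centers = ctr, iter.max = 100L,
                                       algorithm = "Lloyd"))
      }, error = function(e) NULL)
      if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss)) {
        best <- km
      }
    }
    if (is.null(best)) stop("k-means failed on every restart")
    as.integer(best$cluster)
  })
  structure(list(labels = labels, k = k, seed = seed), class = "cluster_labels")
}

#' @export
print.cluster_labels <- function(x, ...) {
  cat(sprintf("<cluster_labels: %d rows, k = %d, seed = %d>\n",
              length(x$labels), x$k, x$seed))
  invisible(x)
}

#' Relabel clusters consecutively along the series
#'
#' Renames cluster labels by order of first appearance, so the first row
#' carries label 1 and each label j > 1 first appears after the first
#' appearance of j - 1.  The partition itself is unchanged.
#'
#' @param labels a `cluster_labels` object or plain integer vector.
#' @return same type as the input, with renamed labels.
#' @examples
#' relabel_consecutive(c(3, 3, 1, 1, 2))  # 1 1 2 2 3
#' @export
relabel_consecutive <- function(labels) {
  if (inherits(labels, "cluster_labels")) {
    labels$labels <- as.integer(match(labels$labels, unique(labels$labels)))
    return(labels)
  }
  as.integer(match(labels, unique(labels)))
}

#' Write cluster labels as CSV
#'
#' @param labels a `cluster_labels` object.
#' @param path file path.
#' @param image_index optional image indices (defaults to 1..N).
#' @export
write_labels_csv <- function(labels, path, image_index = NULL) {
  stopifnot(inherits(labels, "cluster_labels"))
  if (is.null(image_index)) image_index <- seq_along(labels$labels)
  utils::write.csv(data.frame(image_index = image_index,
                              cluster = labels$labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
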