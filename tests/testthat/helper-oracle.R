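# Independent brute-force oracles: Renyi entropies evaluated from explicit
# probability vectors, and PDG / PIG as direct entropy differences.  These
# never touch the package's closed-form code paths.

oracle_entropy <- function(counts, alpha, base = 2) {
  p <- counts[counts > 0] / sum(counts)
  ld <- log(base)
  if (alpha == 0) {
    log(length(p)) / ld
  } else if (alpha == 1) {
    -sum(p * log(p)) / ld
  } else {
    log(sum(p^alpha)) / ((1 - alpha) * ld)
  }
}

# PDG oracle by explicit count editing (l, m are bin indices)
oracle_pdg <- function(counts, l, m, alpha, base = 2) {
  if (l == m) return(0)
  c2 <- counts
  c2[l] <- c2[l] - 1
  c2[m] <- c2[m] + 1
  oracle_entropy(c2, alpha, base) - oracle_entropy(counts, alpha, base)
}

oracle_pig <- function(counts, i, alpha, base = 2) {
  c2 <- counts
  c2[i] <- c2[i] - 1
  oracle_entropy(c2, alpha, base) - oracle_entropy(counts, alpha, base)
}

# Row-wise entropies of a histogram matrix (histograms in rows), for
# vectorized exhaustive comparisons.
oracle_entropy_rows <- function(cm, alpha, base = 2) {
  n <- rowSums(cm)
  p <- cm / n
  ld <- log(base)
  if (alpha == 0) {
    log(rowSums(cm > 0)) / ld
  } else if (alpha == 1) {
    x <- p * log(p)
    x[cm == 0] <- 0
    -rowSums(x) / ld
  } else {
    log(rowSums(p^alpha)) / ((1 - alpha) * ld)
  }
}

# all histograms over k bins with counts in 0..maxcount, total >= 1
enum_histograms <- function(k, maxcount) {
  cm <- as.matrix(do.call(expand.grid, rep(list(0:maxcount), k)))
  dimnames(cm) <- NULL
  cm[rowSums(cm) >= 1, , drop = FALSE]
}

# random small histogram for property tests
random_histogram <- function(k = 6, maxcount = 20) {
  repeat {
    cnt <- sample(0:maxcount, k, replace = TRUE)
    if (sum(cnt) >= 2) return(cnt)
  }
}

expect_close <- function(actual, expected, rel = 1e-10, abs = 1e-12) {
  expect_true(all(abs(actual - expected) <= rel * abs(expected) + abs),
              label = sprintf("max deviation %.3g",
                              max(abs(actual - expected))))
}
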