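# core_pdg: Renyi entropy, PIG, PDG, alpha=2 special case, PDG matrix.

test_that("renyi_entropy matches hand values and the oracle", {
  expect_equal(renyi_entropy(count_histogram(rep(3, 8)), 2), 3)       # uniform
  expect_equal(renyi_entropy(count_histogram(rep(2, 8)), 0.5), 3)
  expect_equal(renyi_entropy(count_histogram(c(0, 7, 0)), 4), 0)      # degenerate
  expect_equal(renyi_entropy(count_histogram(c(3, 1)), 2),
               -log2(10 / 16))                                        # 0.6781 bits
  expect_equal(renyi_entropy(count_histogram(c(3, 1)), 2, "e"),
               -log(10 / 16))
  set.seed(7)
  for (r in 1:20) {
    cnt <- random_histogram()
    a <- sample(c(0, 0.3, 1, 1.7, 2, 5), 1)
    expect_equal(renyi_entropy(count_histogram(cnt), a), oracle_entropy(cnt, a))
  }
})

test_that("renyi_entropy rejects bad input", {
  expect_error(count_histogram(c(0, 0)), "empty")
  expect_error(renyi_entropy(count_histogram(c(1, 2)), -1), "non-negative")
})

test_that("pig matches hand values and direct evaluation", {
  expect_equal(pig(count_histogram(c(2, 2)), 0, 1),
               -(1 / 3) * log2(1 / 3) - (2 / 3) * log2(2 / 3) - 1)    # -0.0817
  expect_equal(pig(count_histogram(rep(4, 5)), 0, 0), 0)              # support kept
  expect_equal(pig(count_histogram(c(1, 5)), 0, 0), -1)               # support 2 -> 1
  expect_error(pig(count_histogram(c(0, 3)), 0, 1), "absent")
  expect_error(pig(count_histogram(c(1, 0)), 0, 1), "empty")
  set.seed(11)
  for (r in 1:20) {
    cnt <- random_histogram()
    i <- sample(which(cnt > 0), 1)
    a <- sample(c(0, 0.5, 1, 2, 4), 1)
    expect_equal(pig(count_histogram(cnt), i - 1, a), oracle_pig(cnt, i, a))
  }
})

test_that("pdg reproduces frozen example values", {
  h31 <- count_histogram(c(3, 1))
  expect_equal(pdg(h31, 0, 1, 2), log2(2) - log2(1.6))                # +0.3219
  expect_equal(pdg(h31, 0, 1, 2), -log2(0.2 * (1 - 3 + 1) + 1))      # alpha=2 form
  expect_equal(pdg(h31, 0, 1, 1),
               (1 * log(1 / 2) + 3 * log(3 / 2) + log(2 / 2)) / (4 * log(2)))
  h32 <- count_histogram(c(3, 2))
  for (a in c(0, 0.5, 0.99, 1, 2, 4)) {
    expect_identical(pdg(h32, 0, 1, a), 0)        # n_l = n_m + 1 permutes counts
    expect_identical(pdg(h32, 0, 0, a), 0)        # l = m leaves P unchanged
  }
  expect_error(pdg(count_histogram(c(0, 4)), 0, 1, 2), "empty bin")
  expect_error(pdg(h31, 0, 1, -0.5), "non-negative")
})

test_that("pdg agrees with the brute-force oracle on random histograms", {
  set.seed(23)
  for (r in 1:60) {
    cnt <- random_histogram()
    occ <- which(cnt > 0)
    l <- sample(occ, 1)
    m <- sample(seq_along(cnt), 1)
    h <- count_histogram(cnt)
    for (a in c(0, 0.5, 0.99, 1, 2, 4)) {
      expect_close(pdg(h, l - 1, m - 1, a), oracle_pdg(cnt, l, m, a))
    }
  }
})

test_that("pdg decomposes into two point information gains", {
  # Omega(l->m)(P) = Gamma(l)(P) - Gamma(m)(P^(l->m))
  set.seed(31)
  for (r in 1:40) {
    cnt <- random_histogram()
    occ <- which(cnt > 0)
    l <- sample(occ, 1)
    m <- sample(seq_along(cnt), 1)
    cnt2 <- cnt; cnt2[l] <- cnt2[l] - 1; cnt2[m] <- cnt2[m] + 1
    h <- count_histogram(cnt)
    h2 <- count_histogram(cnt2)
    for (a in c(0, 0.5, 1, 2, 4)) {
      expect_equal(pdg(h, l - 1, m - 1, a),
                   pig(h, l - 1, a) - pig(h2, m - 1, a),
                   tolerance = 1e-10)
    }
  }
})

test_that("pdg sign follows the count imbalance", {
  h <- count_histogram(c(100, 5, 1000))
  for (a in c(0.5, 0.99, 1, 2, 4)) {
    expect_lt(pdg(h, 1, 2, a), 0)   # rare -> frequent: negative
    expect_gt(pdg(h, 2, 1, a), 0)   # frequent -> rare: positive
    expect_lt(pdg(h, 0, 2, a), 0)
    expect_gt(pdg(h, 2, 0, a), 0)
  }
})

test_that("pdg is continuous through alpha = 1", {
  set.seed(41)
  for (r in 1:25) {
    cnt <- random_histogram()
    l <- sample(which(cnt > 0), 1)
    m <- sample(seq_along(cnt), 1)
    h <- count_histogram(cnt)
    expect_lt(abs(pdg(h, l - 1, m - 1, 0.999) - pdg(h, l - 1, m - 1, 1)), 1e-3)
  }
})

test_that("pdg magnitude decays as alpha grows, for non-maximal bins", {
  g <- generate_histogram(dist_spec("gauss", c = 4, sigma = 1))
  cnt <- g$counts
  nonmax <- which(cnt > 0 & cnt < max(cnt))
  for (l in nonmax) {
    for (m in setdiff(nonmax, l)) {
      expect_lte(abs(pdg(g, g$labels[l], g$labels[m], 50)),
                 abs(pdg(g, g$labels[l], g$labels[m], 4)) + 1e-15)
    }
  }
})

test_that("pdg is small for large-n histograms", {
  g <- generate_histogram(dist_spec("gauss", c = 4, sigma = 1))
  expect_gte(g$n, 9999)   # n is 9999: large-n regime
  big <- which(g$counts >= 10)
  for (a in c(0.5, 0.99, 1, 2, 4)) {
    vals <- vapply(big, function(l) {
      max(abs(vapply(big, function(m) pdg(g, g$labels[l], g$labels[m], a),
                     numeric(1))))
    }, numeric(1))
    expect_lt(max(vals), 0.01)
  }
})

test_that("pdg_alpha2 agrees with the generic path and the oracle", {
  expect_equal(pdg_alpha2(count_histogram(c(3, 1)), 0, 1), -log2(0.8))
  expect_identical(pdg_alpha2(count_histogram(c(7, 6)), 0, 1), 0)  # n_m = n_l - 1
  set.seed(51)
  for (r in 1:30) {
    cnt <- random_histogram()
    l <- sample(which(cnt > 0), 1)
    m <- sample(seq_along(cnt), 1)
    h <- count_histogram(cnt)
    expect_equal(pdg_alpha2(h, l - 1, m - 1), pdg(h, l - 1, m - 1, 2),
                 tolerance = 1e-12)
    expect_close(pdg_alpha2(h, l - 1, m - 1), oracle_pdg(cnt, l, m, 2))
  }
  # two equal bins: n_m - n_l + 1 = 1, small negative value
  h55 <- count_histogram(c(5, 5))
  expect_equal(pdg_alpha2(h55, 0, 1), oracle_pdg(c(5, 5), 1, 2, 2))
  expect_lt(pdg_alpha2(h55, 0, 1), 0)
})

test_that("pdg_matrix tabulates all exchanges with the right structure", {
  h <- count_histogram(c(1, 1, 1))
  pm <- pdg_matrix(h, 2)
  expect_identical(dim(pm$values), c(3L, 3L))
  expect_identical(unname(diag(pm$values)), rep(0, 3))
  off <- pm$values[row(pm$values) != col(pm$values)]
  for (v in off) expect_equal(v, oracle_pdg(c(1, 1, 1), 1, 2, 2))
  expect_equal(pm$c_alpha, 3)

  # alpha = 0: every defined exchange that keeps the support is exactly 0
  g <- generate_histogram(dist_spec("gauss", c = 4, sigma = 1))
  m0 <- pdg_matrix(g, 0)
  keeps <- outer(g$counts >= 2, g$counts >= 1, `&`)
  expect_true(all(m0$values[keeps] == 0))
  expect_true(all(is.na(m0$values[g$counts == 0, ])))

  # alpha = 2: equal count difference implies equal cell value
  m2 <- pdg_matrix(g, 2)$values
  d <- outer(g$counts, g$counts, function(a, b) b - a)
  ok <- !is.na(m2) & row(m2) != col(m2)
  for (dd in unique(d[ok])[1:20]) {
    expect_length(unique(m2[ok & d == dd]), 1L)
  }
})

test_that("histogram and PDG matrix CSV round-trips preserve content", {
  h <- count_histogram(c(4, 0, 2, 9), labels = c(10, 11, 12, 13))
  f <- tempfile(fileext = ".csv")
  write_histogram_csv(h, f)
  h2 <- read_histogram_csv(f)
  expect_equal(h2$counts, h$counts)
  expect_equal(h2$labels, h$labels)

  pm <- pdg_matrix(h, 1.5)
  f2 <- tempfile(fileext = ".csv")
  write_pdg_matrix_csv(pm, f2)
  expect_match(readLines(f2, n = 1), "alpha=1.5")
  back <- as.matrix(utils::read.csv(f2, comment.char = "#", row.names = 1))
  expect_equal(unname(back), unname(pm$values))
})

test_that("alpha_grid returns the named grids and validates input", {
  expect_length(alpha_grid("default13"), 13L)
  expect_length(alpha_grid("grid40"), 40L)
  expect_equal(alpha_grid("default13")[5], 0.99)
  expect_false(1.0 %in% alpha_grid("grid40"))
  expect_error(alpha_grid(c(1, 1)), "increasing")
  expect_error(alpha_grid(c(2, 1)), "increasing")
  expect_error(alpha_grid(c(-1, 2)), "non-negative")
})
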