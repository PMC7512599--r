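# sequence_transform: transition tables, per-pixel PDG maps, PDGE/PDGED
# and the alpha spectra.

fix_a <- matrix(c(0, 0, 0, 1), 2, 2, byrow = TRUE)   # one bright pixel
fix_b <- matrix(0, 2, 2)

test_that("transition_table tallies positionwise intensity pairs", {
  tt <- transition_table(fix_a, fix_b)
  expect_equal(tt$total, 4L)
  d <- data.frame(l = tt$l, m = tt$m, n = tt$n_lm)
  expect_equal(d$n[d$l == 0 & d$m == 0], 3)
  expect_equal(d$n[d$l == 1 & d$m == 0], 1)
  expect_equal(nrow(d), 2L)

  same <- transition_table(fix_a, fix_a)
  expect_true(all(same$l == same$m))
  expect_equal(sum(same$n_lm), 4)
  expect_error(transition_table(fix_a, matrix(0, 2, 3)), "shape")
})

test_that("transition marginals equal the two frames' histograms", {
  set.seed(5)
  for (r in 1:10) {
    a <- matrix(sample(0:15, 64, TRUE), 8, 8)
    b <- matrix(sample(0:15, 64, TRUE), 8, 8)
    tt <- transition_table(a, b)
    ml <- tapply(tt$n_lm, tt$l, sum)
    expect_equal(unname(ml[order(as.numeric(names(ml)))]),
                 unname(table(a)[order(as.numeric(names(table(a))))]),
                 ignore_attr = TRUE)
    mm <- tapply(tt$n_lm, tt$m, sum)
    expect_equal(unname(mm[order(as.numeric(names(mm)))]),
                 unname(table(b)[order(as.numeric(names(table(b))))]),
                 ignore_attr = TRUE)
  }
})

test_that("pdg_map computes per-pixel gains against the first frame's histogram", {
  m <- pdg_map(fix_a, fix_b, alpha = 2)
  # histogram of a: n0 = 3, n1 = 1; exchange 1 -> 0: collision form -log2(1.6)
  expect_equal(m$values[2, 2], -log2(1.6))
  expect_equal(sum(m$values != 0), 1L)
  expect_identical(pdg_map(fix_a, fix_a, 2)$values, matrix(0, 2, 2))

  # every pixel must match a scalar pdg() call on the same basis histogram
  set.seed(9)
  a <- matrix(sample(0:7, 36, TRUE), 6, 6)
  b <- matrix(sample(0:7, 36, TRUE), 6, 6)
  bh <- frame_hist(a, 8)
  for (al in c(0, 0.99, 2, 4)) {
    mp <- pdg_map(a, b, al)$values
    ref <- matrix(mapply(function(x, y) pdg(bh, x, y, al), a, b), 6, 6)
    expect_identical(mp, ref)            # cache transparency: bit-identical
  }
})

test_that("pdg_map honors the pooled basis and equal-pair pixels agree", {
  a <- matrix(c(2, 2, 5, 5), 2, 2)     # [2 5; 2 5]
  b <- matrix(c(5, 5, 2, 9), 2, 2)     # [5 2; 5 9]
  m <- pdg_map(a, b, 2, basis = "pooled")
  ph <- pdgain:::.pooled_hist(a, b, 8L)
  expect_identical(m$values[1, 1], pdg(ph, 2, 5, 2))
  expect_identical(m$values[1, 1], m$values[2, 1])  # same (2 -> 5) transition
  expect_identical(m$values[2, 2], pdg(ph, 5, 9, 2))
  # first-frame basis also handles targets absent from frame a (n_m = 0)
  m1 <- pdg_map(a, b, 2, basis = "first")
  expect_identical(m1$values[2, 2], pdg(frame_hist(a, 8), 5, 9, 2))
  expect_gt(m1$values[2, 2], 0)
})

test_that("pdge and pdged match their definitions", {
  tt <- transition_table(fix_a, fix_b)
  bh <- frame_hist(fix_a, 8)
  expect_equal(pdge(tt, bh, 2), log2(1.6))
  expect_equal(pdged(tt, bh, 2), log2(1.6))   # pairs (0,0) -> 0 and (1,0)
  ttid <- transition_table(fix_a, fix_a)
  expect_equal(pdge(ttid, bh, 2), 0)
  expect_equal(pdged(ttid, bh, 2), 0)

  # multiplicity: n_lm-fold in I, once in P
  a <- matrix(5, 10, 10); a[1, 1] <- 9
  b <- matrix(9, 10, 10); b[1, 1] <- 9
  tt2 <- transition_table(a, b)          # 5 -> 9 occurs 99x, 9 -> 9 once
  bh2 <- frame_hist(a, 8)
  w <- abs(pdg(bh2, 5, 9, 2))
  expect_equal(pdge(tt2, bh2, 2), 99 * w)
  expect_equal(pdged(tt2, bh2, 2), w)
})

test_that("pdge equals the per-pixel sum of the map", {
  set.seed(13)
  for (r in 1:5) {
    a <- matrix(sample(0:31, 256, TRUE), 16, 16)
    b <- matrix(sample(0:31, 256, TRUE), 16, 16)
    tt <- transition_table(a, b)
    bh <- frame_hist(a, 8)
    for (al in c(0.5, 1, 2)) {
      expect_equal(pdge(tt, bh, al), sum(abs(pdg_map(a, b, al)$values)),
                   tolerance = 1e-10)
    }
  }
})

test_that("pdg_spectra has the contracted shape and degenerate behavior", {
  ms <- synth_sequence("moving_square", frames = 6, seed = 2)
  sp <- pdg_spectra(ms)
  expect_s3_class(sp, "pdg_spectra")
  expect_equal(nrow(sp), 5L * 13L)
  expect_setequal(unique(sp$pair_index), 1:5)
  expect_true(all(sp$I_alpha > 0))       # motion in every pair
  expect_true(all(sp$P_alpha <= sp$I_alpha + 1e-12))
  expect_true(all(sp$P_alpha >= 0))

  const <- frame_sequence(rep(list(matrix(7, 4, 4)), 3))
  spc <- pdg_spectra(const, alphas = c(0.5, 2))
  expect_true(all(spc$I_alpha == 0))
  expect_true(all(spc$P_alpha == 0))

  expect_error(pdg_spectra(const, lag = 3), "lag")
  sp2 <- pdg_spectra(ms, lag = 2, alphas = c(1, 2))
  expect_equal(nrow(sp2), 4L * 2L)
})

test_that("spectra CSV round-trips through feature_matrix identically", {
  ms <- synth_sequence("moving_square", frames = 5, seed = 3)
  sp <- pdg_spectra(ms, alphas = alpha_grid("default13"))
  f <- tempfile(fileext = ".csv")
  write_spectra_csv(sp, f)
  back <- read_spectra_csv(f)
  expect_equal(feature_matrix(back), feature_matrix(sp), tolerance = 1e-12)
})

test_that("spectrum classification flags interior peaks only", {
  al <- alpha_grid("default13")
  rising <- seq_along(al)
  expect_false(classify_spectrum(al, rising)$multifractal)
  falling <- rev(rising)
  expect_false(classify_spectrum(al, falling)$multifractal)
  peaked <- dnorm(al, mean = 1.5, sd = 0.5)
  cs <- classify_spectrum(al, peaked)
  expect_true(cs$multifractal)
  expect_equal(cs$alpha_peak, 1.5)
  expect_false(classify_spectrum(al, rep(0, 13))$multifractal)
})

test_that("fixture spectra have the shapes the theory dictates", {
  # noise pair: rare-count transitions dominate; monotone decreasing in alpha
  np <- synth_sequence("noise_pair", seed = 3)
  sp <- pdg_spectra(np)
  expect_true(all(diff(sp$I_alpha) < 0))
  expect_false(classify_spectrum(attr(sp, "alphas"), sp$I_alpha)$multifractal)

  # two-intensity moving square: all transitions sit in high-count bins, so
  # Omega -> 0 at both alpha extremes forces an interior peak
  ms <- synth_sequence("moving_square", seed = 1)
  s1 <- pdg_spectra(ms)
  v <- s1$I_alpha[s1$pair_index == 1]
  expect_true(classify_spectrum(attr(s1, "alphas"), v)$multifractal)
  expect_lt(v[1], max(v) / 2)            # vanishing low-alpha limit
  expect_lt(v[13], max(v))
})
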