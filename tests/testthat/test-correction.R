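test_that("monoisotopic elements give an identity correction matrix", {
  iso <- mono_isotopes()
  frag <- tiny_fragment(iso)
  M <- build_correction_matrix(frag, iso)
  expect_equal(M, diag(4), tolerance = 1e-15)
})

test_that("a pure-carbon fragment has binomial natural-abundance columns", {
  a <- 0.011
  iso <- carbon_isotopes(a)
  frag <- fragment_spec("c2", c(C = 2), n_carbons = 2, mz_low = 24, mz_high = 26,
                        isotopes = iso)
  M <- build_correction_matrix(frag, iso)
  expect_equal(M[, 1], c((1 - a)^2, 2 * a * (1 - a), a^2))
  # one tracer carbon left: single natural binomial, shifted by 1
  expect_equal(M[, 2], c(0, (1 - a), a))
  expect_equal(M[, 3], c(0, 0, 1))
})

test_that("correction matrix matches exhaustive isotope-placement enumeration", {
  iso <- load_isotopes()
  frag <- tiny_fragment(iso)
  M <- build_correction_matrix(frag, iso)
  for (j in 0:3) {
    oracle <- oracle_correction_column(as.list(frag$formula), iso, j, 4L)
    expect_equal(M[, j + 1], oracle, tolerance = 1e-12)
  }
  # registered ribose fragment: column sums below 1 (window truncation) and
  # decreasing in the tracer count
  reg <- load_fragments()
  Mr <- build_correction_matrix(reg$ribose, iso)
  cs <- colSums(Mr)
  expect_true(all(cs < 1))
  expect_true(all(diff(cs) < 0))
})

test_that("correct_mid inverts the forward convolution for every registered fragment", {
  iso <- load_isotopes()
  reg <- load_fragments()
  set.seed(11)
  for (frag in reg) {
    M <- build_correction_matrix(frag, iso)
    for (i in 1:25) {
      x <- stats::rgamma(n_channels(frag), 0.8)
      x <- x / sum(x)
      raw <- mid(convolve_mid(x, M), frag)
      rec <- suppressWarnings(correct_mid(raw, M))
      expect_lt(max(abs(rec$fractions - x)), 1e-8)
      expect_equal(sum(rec$fractions), 1, tolerance = 1e-9)
      expect_true(all(rec$fractions >= 0))
    }
  }
})

test_that("column 0 of the matrix corrects to a pure unlabeled MID", {
  reg <- load_fragments()
  M <- build_correction_matrix(reg$lactate)
  raw <- mid(M[, 1], reg$lactate)
  rec <- correct_mid(raw, M)
  expect_equal(rec$fractions, c(1, 0, 0, 0, 0, 0), tolerance = 1e-10)
  expect_true(rec$corrected)
})

test_that("known MIDs survive channel noise within 0.01 per channel", {
  reg <- load_fragments()
  M <- build_correction_matrix(reg$ribose)
  truth <- c(0.55, 0.2, 0.25, 0, 0, 0)
  set.seed(7)
  worst <- 0
  for (i in 1:100) {
    raw <- convolve_mid(truth, M) + stats::rnorm(6, 0, 0.002)
    raw[raw < 0] <- 0
    rec <- suppressWarnings(correct_mid(mid(raw, reg$ribose), M))
    worst <- max(worst, max(abs(rec$fractions - truth)))
  }
  expect_lt(worst, 0.01)
})

test_that("degenerate matrices and formulas are rejected with named errors", {
  # unknown element is named in the error
  expect_error(fragment_spec("xq", c(C = 2, Q = 1), 2, 24, 60, carbon_isotopes()),
               "Q", class = "midflux_config_error")
  reg <- load_fragments()
  singular <- matrix(1, 6, 6)
  raw <- mid(rep(1 / 6, 6), reg$ribose)
  expect_error(correct_mid(raw, singular), class = "midflux_conditioning_error")
})

test_that("tracer purity below 1 spreads tracer columns downward", {
  iso <- carbon_isotopes(0)
  frag <- fragment_spec("c2", c(C = 2), 2, 24, 26, isotopes = iso)
  M <- build_correction_matrix(frag, iso, purity = 0.99)
  # one nominally-labeled carbon: m1 w.p. 0.99, m0 w.p. 0.01
  expect_equal(M[, 2], c(0.01, 0.99, 0))
  expect_equal(M[, 3], c(0.0001, 2 * 0.99 * 0.01, 0.99^2))
})
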