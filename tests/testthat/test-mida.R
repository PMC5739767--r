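test_that("fa_mid_model reproduces the binomial precursor-product pattern", {
  expect_equal(fa_mid_model(0, 0.7, 8), c(1, rep(0, 16)))
  m <- fa_mid_model(1, 1, 8)
  expect_equal(m[17], 1)
  expect_equal(sum(m[-17]), 0)
  # m4/m2 ratio closed form at p = 0.2: (7/2) * (0.2/0.8)
  m <- fa_mid_model(0.2, 1, 8)
  expect_equal(m[5] / m[3], 0.875, tolerance = 1e-12)
  expect_error(fa_mid_model(0.2, 0.5, 7), class = "midflux_input_error")
  expect_error(fa_mid_model(-0.1, 0.5, 8), class = "midflux_input_error")
})

test_that("fa_mid_model lands on the simplex for a full (p, g) grid", {
  grid <- seq(0, 1, length.out = 21)
  for (p in grid) for (g in grid) {
    v <- fa_mid_model(p, g, 9)
    expect_equal(sum(v), 1, tolerance = 1e-12)
    expect_true(all(v >= 0))
    expect_true(all(v[seq(2, 18, by = 2)] == 0))  # odd channels empty
  }
})

test_that("fa_enrichment is 1 - m0, linear in g, and monotone in p and g", {
  expect_equal(fa_enrichment(fa_mid_model(0.25, 0, 8)), 0)
  expect_equal(fa_enrichment(fa_mid_model(0.25, 1, 8)), 1 - 0.75^8, tolerance = 1e-12)
  expect_equal(fa_enrichment(fa_mid_model(0.25, 0.5, 8)), 0.5 * (1 - 0.75^8),
               tolerance = 1e-12)
  ps <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(sapply(ps, function(p) fa_enrichment(fa_mid_model(p, 0.6, 8)))) > 0))
  expect_true(all(diff(sapply(ps, function(g) fa_enrichment(fa_mid_model(0.3, g, 8)))) > 0))
})

test_that("fit_mida recovers noiseless parameters exactly over a grid", {
  for (n in c(8L, 9L)) {
    win <- if (n == 8L) 10L else 11L
    for (p in c(0.1, 0.25, 0.4)) for (g in c(0.3, 0.6, 0.9)) {
      obs <- fa_mid_model(p, g, n)[seq_len(win)]
      fit <- suppressWarnings(fit_mida(obs, n, tracer_fraction = 1))
      expect_equal(fit$p, p, tolerance = 1e-6)
      expect_equal(fit$g, g, tolerance = 1e-6)
      # ratio initialization and refined estimate coincide on clean data
      expect_lt(abs(fit$p - fit$p_ratio), 1e-9)
      expect_true(fit$ratio_consistent)
      expect_lt(fit$fit_residual, 1e-20)
    }
  }
})

test_that("pct_glucose_to_acetyl saturates at p = 0.5 * T", {
  obs <- fa_mid_model(0.25, 0.6, 8)[1:10]
  fit <- fit_mida(obs, 8, tracer_fraction = 0.5)
  expect_equal(fit$pct_glucose_to_acetyl, 100, tolerance = 1e-6)
})

test_that("fit_mida flags insufficient labeling and bound hits", {
  unlabeled <- c(1, rep(0, 9))
  expect_error(fit_mida(unlabeled, 8), class = "midflux_insufficient_labeling")
})

test_that("fit_mida has small bias under channel noise", {
  set.seed(23)
  p_true <- 0.25; g_true <- 0.6
  base <- fa_mid_model(p_true, g_true, 8)[1:10]
  base <- base / sum(base)
  fits <- replicate(60, {
    obs <- base + stats::rnorm(10, 0, 0.002)
    obs[obs < 0] <- 0
    f <- suppressWarnings(fit_mida(obs / sum(obs), 8, tracer_fraction = 1))
    c(f$p, f$g)
  })
  expect_lt(abs(mean(fits[1, ]) - p_true), 0.01)
  expect_lt(abs(mean(fits[2, ]) - g_true), 0.03)
})
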