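test_that("product-limit estimates match hand calculation", {
  km <- km_estimate(5, 1)
  expect_equal(km$table$surv, 0)
  expect_equal(km$table$time, 5)
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$table$surv, c(2 / 3, 1 / 3, 0))
  # censored subject at an event time stays at risk for that time
  km <- km_estimate(c(2, 2, 4), c(1, 0, 1))
  expect_equal(km$table$surv[km$table$time == 2], 2 / 3)
  expect_error(km_estimate(numeric(0), numeric(0)), class = "midflux_input_error")
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(5)
  t <- stats::rexp(80, 0.1)
  km <- km_estimate(t, rep(1, 80))
  emp <- vapply(km$table$time, function(x) mean(t > x), numeric(1))
  expect_equal(km$table$surv, emp, tolerance = 1e-12)
  expect_true(all(diff(km$table$surv) <= 0))
})

test_that("log-rank statistic equals hand hypergeometric sums and is symmetric", {
  ta <- c(2, 4, 6, 8); ea <- c(1, 1, 1, 0)
  tb <- c(1, 2, 3, 4); eb <- c(1, 1, 1, 1)
  res <- logrank_test(ta, ea, tb, eb)
  expect_equal(res$statistic, oracle_logrank_chisq(ta, ea, tb, eb), tolerance = 1e-12)
  # symmetry in group order
  expect_equal(res$statistic, logrank_test(tb, eb, ta, ea)$statistic)
  # invariance to time-unit rescaling
  expect_equal(res$statistic, logrank_test(ta * 30.44, ea, tb * 30.44, eb)$statistic)
  # identical groups: no signal
  same <- logrank_test(ta, ea, ta, ea)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  expect_error(logrank_test(ta, rep(0, 4), tb, rep(0, 4)),
               class = "midflux_degenerate_test")
  expect_error(logrank_test(numeric(0), numeric(0), tb, eb),
               class = "midflux_input_error")
})

test_that("best_cutoff minimizes p over the quartile scan and flags the bias", {
  set.seed(31)
  n <- 120
  expr <- stats::rnorm(n)
  high <- expr > stats::quantile(expr, 0.4)
  time <- stats::rexp(n, 0.02 * ifelse(high, 3, 1))
  bc <- best_cutoff(time, rep(1, n), expr)
  expect_true(bc$p_selection_biased)
  expect_gte(bc$percentile, 25)
  expect_lte(bc$percentile, 75)
  ok <- !bc$scan$skipped
  expect_equal(bc$p, min(bc$scan$p[ok]))
  expect_true(all(bc$p <= bc$scan$p[ok]))
  # ties at the cutoff go to the low group
  expr_t <- rep(c(1, 2), each = n / 2)
  bc_t <- best_cutoff(time, rep(1, n), expr_t)
  expect_equal(bc_t$scan$n_high[bc_t$scan$cutoff == 1], rep(n / 2, sum(bc_t$scan$cutoff == 1)))
  # degenerate inputs
  expect_error(best_cutoff(time, rep(1, n), rep(3, n)), class = "midflux_degenerate_input")
  expect_error(best_cutoff(time[1:10], rep(1, 10), expr[1:10]),
               class = "midflux_degenerate_input")
})

test_that("permutation-adjusted p is calibrated-ish relative to the biased p", {
  set.seed(77)
  n <- 60
  time <- stats::rexp(n, 0.02)
  bc <- best_cutoff(time, rep(1, n), stats::rnorm(n), permutations = 60)
  expect_gte(bc$p_permutation, bc$p)  # selection bias removed, p can only grow
})

test_that("pearson_correlation matches cor.test and rejects degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  set.seed(3)
  a <- stats::rnorm(50); b <- a + stats::rnorm(50)
  res <- pearson_correlation(a, b)
  ct <- stats::cor.test(a, b)
  expect_equal(res$r, unname(ct$estimate))
  expect_equal(res$p, ct$p.value)
  expect_error(pearson_correlation(x, rep(1, 5)), class = "midflux_degenerate_input")
  expect_error(pearson_correlation(1:2, 1:2), class = "midflux_input_error")
})
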