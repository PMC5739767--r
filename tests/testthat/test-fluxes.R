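reg <- load_fragments()
lac_mid <- function(m2, m1 = 0) {
  mid(c(1 - m1 - m2, m1, m2, 0, 0, 0), reg$lactate, corrected = TRUE)
}

test_that("glycolytic flux scales lactate release by the m2-derived fraction", {
  # no m2 lactate: nothing glycolytic
  res <- glycolytic_flux(lac_mid(0), lac_rate = 100, tracer_fraction = 0.5)
  expect_equal(res$f_lac_from_glc, 0)
  expect_equal(res$glycolytic_flux, 0)
  # saturation: m2 = 0.5 * T means all lactate is glycolytic
  res <- glycolytic_flux(lac_mid(0.25), lac_rate = 100, tracer_fraction = 0.5,
                         glc_rate = 100)
  expect_equal(res$f_lac_from_glc, 1)
  expect_equal(res$glycolytic_flux, 100)
  # 2 lactate per glucose in the share denominator
  expect_equal(res$glucose_to_lactate_share, 0.5)
  expect_equal(res$other_uses_share, 0.5)
  # m1 lactate reported but excluded from f
  res <- glycolytic_flux(lac_mid(0.2, m1 = 0.05), 100, 0.5)
  expect_equal(res$f_lac_from_glc, 0.8)
  expect_equal(res$m1_lactate, 0.05)
})

test_that("model violations warn rather than fail silently", {
  expect_warning(glycolytic_flux(lac_mid(0.3), 100, 0.5),
                 class = "midflux_model_violation")
  expect_error(glycolytic_flux(lac_mid(0.1), 100, 0),
               class = "midflux_input_error")
  expect_error(glycolytic_flux(mid(c(0.9, 0, 0.1, 0, 0, 0), reg$lactate), 100, 0.5),
               class = "midflux_input_error")
})

test_that("ppp_split reports m1, m2 and a floored ratio", {
  rib <- mid(c(0.8, 0.1, 0.1, 0, 0, 0), reg$ribose, corrected = TRUE)
  sp <- ppp_split(rib)
  expect_equal(sp$ox_nonox_ratio, 1.0)
  expect_true(sp$ratio_defined)
  # m2 below the floor: undefined, not infinite
  rib0 <- mid(c(0.9, 0.1, 5e-5, 0, 0, 0), reg$ribose, corrected = TRUE)
  sp0 <- ppp_split(rib0)
  expect_false(sp0$ratio_defined)
  expect_true(is.na(sp0$ox_nonox_ratio))
})

test_that("m2 alanine tracks the pyruvate pool label", {
  expect_equal(m2_alanine(mid(c(1, 0, 0, 0, 0, 0), reg$alanine, corrected = TRUE)), 0)
  expect_equal(m2_alanine(mid(c(0.7, 0.05, 0.25, 0, 0, 0), reg$alanine,
                              corrected = TRUE)), 0.25)
})

test_that("delta-delta-Ct fold changes follow 2^-ddCt", {
  expect_equal(fold_change_ddct(20, 18, 20, 18), 1)
  expect_equal(fold_change_ddct(21, 18, 20, 18), 0.5)
  expect_equal(fold_change_ddct(18, 18, 20, 18), 4)
  expect_error(fold_change_ddct(46, 18, 20, 18), class = "midflux_input_error")
  expect_error(fold_change_ddct(0, 18, 20, 18), class = "midflux_input_error")
})

test_that("f estimates recover simulator truth through correction", {
  iso <- load_isotopes()
  M <- build_correction_matrix(reg$lactate, iso)
  set.seed(19)
  for (f_true in c(0.4, 0.9)) {
    errs <- replicate(30, {
      truth <- c(1 - 0.25 * f_true, 0, 0.25 * f_true, 0, 0, 0)
      raw <- convolve_mid(truth, M) + stats::rnorm(6, 0, 0.002)
      raw[raw < 0] <- 0
      corr <- suppressWarnings(correct_mid(mid(raw, reg$lactate), M))
      res <- suppressWarnings(glycolytic_flux(corr, 100, 0.5))
      res$f_lac_from_glc - f_true
    })
    expect_lt(abs(mean(errs)), 0.02)
    expect_lt(max(abs(errs)), 0.05)
  }
})
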