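test_that("configuration enforces partitions and mass balance", {
  expect_error(sim_config(), class = "midflux_config_error")
  expect_error(sim_config(seed = 1, glycolysis_share = 0.8, oxppp_share = 0.1),
               class = "midflux_config_error")
  expect_error(sim_config(seed = 1, pyruvate_fate = c(lactate = 0.5, alanine = 0.5,
                                                      acetyl = 0.5)),
               class = "midflux_config_error")
  expect_error(sim_config(seed = 1, rho_nonox = 1.2), class = "midflux_config_error")
  expect_error(sim_config(seed = 1, glucose_uptake = 100, lactate_release = 250),
               class = "midflux_config_error")
})

test_that("an unlabeled experiment yields unlabeled MIDs everywhere", {
  st <- simulate_label_state(sim_config(seed = 1, tracer_fraction = 0))
  for (m in st$mids) {
    expect_equal(m$fractions[1], 1)
    expect_equal(sum(m$fractions[-1]), 0)
  }
})

test_that("carbon bookkeeping follows the tracer design rules", {
  frags <- load_fragments()
  # pure oxidative PPP at T = 1: all labeled ribose is m1
  st <- simulate_label_state(sim_config(seed = 1, tracer_fraction = 1, rho_nonox = 0),
                             frags)
  expect_equal(mid_fraction(st$mids$ribose, 1), 1)
  expect_equal(mid_fraction(st$mids$ribose, 2), 0)
  # default config: lactate m2 = 0.5 * T * f, inherited by alanine
  cfg <- sim_config(seed = 1)
  st <- simulate_label_state(cfg, frags)
  expect_equal(mid_fraction(st$mids$lactate, 2), 0.5 * 0.5 * cfg$f_lac_from_glc)
  expect_equal(mid_fraction(st$mids$alanine, 2), mid_fraction(st$mids$lactate, 2))
  # fatty-acid MIDs are the binomial model evaluated at the true (p, g)
  p_true <- 0.5 * cfg$tracer_fraction * (1 - cfg$acetyl_dilution)
  expected <- fa_mid_model(p_true, cfg$fa_new_synthesis, 8)[1:10]
  expect_equal(st$mids$palmitate$fractions, expected / sum(expected), tolerance = 1e-12)
  # ground truth is consistent with its own MIDs
  expect_equal(st$truth$m2_alanine, mid_fraction(st$mids$alanine, 2))
  expect_equal(st$truth$ox_nonox_ratio,
               mid_fraction(st$mids$ribose, 1) / mid_fraction(st$mids$ribose, 2))
})

test_that("emitted bundles are deterministic and round-trip through the readers", {
  cfg <- sim_config(seed = 42)
  d1 <- tempfile("sim"); d2 <- tempfile("sim")
  p1 <- simulate_bundle(cfg, d1)
  p2 <- simulate_bundle(cfg, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
  # different seed, different noise
  p3 <- simulate_bundle(sim_config(seed = 43), tempfile("sim"))
  expect_false(identical(readLines(p1[["mids"]]), readLines(p3[["mids"]])))
  # readers accept everything emitted
  tab <- read_mid_table(p1[["mids"]])
  mids <- mids_from_table(tab)
  expect_equal(length(mids), cfg$n_reps)
  expect_setequal(names(mids[[1]]),
                  c("glucose", "lactate", "alanine", "ribose", "palmitate", "stearate"))
  media <- read_media_table(p1[["media"]])
  expect_equal(nrow(media), cfg$n_reps * 4)
  surv <- read_survival_table(p1[["survival"]])
  expect_equal(nrow(surv), cfg$n_patients)
  truth <- jsonlite::read_json(p1[["truth"]])
  expect_equal(truth$f_lac_from_glc, cfg$f_lac_from_glc)
})

test_that("emitted media concentrations respect carbon mass balance", {
  cfg <- sim_config(seed = 9, sigma_conc_rel = 0)
  paths <- simulate_bundle(cfg, tempfile("sim"))
  media <- read_media_table(paths[["media"]])
  one <- media[media$sample_id == "S01", ]
  glc <- one[one$metabolite == "glucose", ]
  lac <- one[one$metabolite == "lactate", ]
  consumed <- (glc$conc_start - glc$conc_end)
  released <- (lac$conc_end - lac$conc_start)
  expect_lte(released, 2 * consumed + 1e-9)
})
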