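#' Configuration for the label-propagation simulator
#'
#' Defines a complete in-silico [1,2-13C2]-glucose tracing experiment with
#' known ground truth: tracer design, pathway partitions, CORE rates, growth,
#' measurement noise and a survival cohort. Defaults emulate a 24 h labeling
#' window on an adherent breast cancer culture (see the package vignette for
#' the reasoning behind each value).
#'
#' @param seed Mandatory RNG seed.
#' @param tracer_fraction Molar fraction of medium glucose that is
#'   [1,2-13C2]-glucose. Default 0.5.
#' @param glucose_uptake,lactate_release,glutamine_uptake,glutamate_release
#'   True CORE rates, nmol per 1e6 cells per hour.
#' @param glycolysis_share,oxppp_share Partition of glucose-6-phosphate
#'   between glycolysis and the oxidative PPP; must sum to 1.
#' @param pyruvate_fate Named fractions `lactate`, `alanine`, `acetyl` of
#'   pyruvate fate; must sum to 1.
#' @param f_lac_from_glc Fraction of the pyruvate/lactate pool derived from
#'   glucose via glycolysis (the estimand of the glycolytic-flux stage).
#' @param rho_nonox Fraction of ribose synthesized through the
#'   non-oxidative PPP branch (m2 ribose); the remainder comes through the
#'   oxidative branch (m1 ribose).
#' @param acetyl_dilution Fraction of lipogenic acetyl-CoA from unlabeled,
#'   non-glucose sources; acetyl m2 enrichment is
#'   `0.5 * tracer_fraction * (1 - acetyl_dilution)`.
#' @param fa_new_synthesis Fractional new synthesis `g` of the fatty-acid
#'   pools during the labeling window.
#' @param lactate_m1 Optional fixed m1 contamination of lactate (PPP
#'   recycling) to stress the estimator; default 0.
#' @param growth_rate Exponential growth rate (per hour).
#' @param cells_initial Initial cell count.
#' @param duration Labeling window (hours).
#' @param volume_ml Medium volume (mL).
#' @param conc_start Named start concentrations (mM) for glucose, lactate,
#'   glutamine, glutamate.
#' @param sigma_mid Gaussian noise SD added to each observed MID channel.
#' @param sigma_conc_rel Relative Gaussian noise on measured concentrations.
#' @param n_reps Replicate samples per condition.
#' @param n_patients,baseline_hazard,hazard_ratio,censoring_rate,
#'   effect_percentile,gene_correlation,max_followup Survival cohort block:
#'   cohort size, exponential baseline hazard (per month), hazard ratio for
#'   patients above the `effect_percentile` of gene-1 expression, fraction
#'   of subjects censored uniformly before their event, Pearson correlation
#'   of gene-2 with gene-1, and administrative follow-up cap (months).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       tracer_fraction = 0.5,
                       glucose_uptake = 200,
                       lactate_release = 280,
                       glutamine_uptake = 30,
                       glutamate_release = 15,
                       glycolysis_share = 0.9,
                       oxppp_share = 0.1,
                       pyruvate_fate = c(lactate = 0.75, alanine = 0.05, acetyl = 0.20),
                       f_lac_from_glc = 0.8,
                       rho_nonox = 0.8,
                       acetyl_dilution = 0.2,
                       fa_new_synthesis = 0.6,
                       lactate_m1 = 0,
                       growth_rate = log(2) / 36,
                       cells_initial = 5e5,
                       duration = 24,
                       volume_ml = 2,
                       conc_start = c(glucose = 10, lactate = 0, glutamine = 2, glutamate = 0),
                       sigma_mid = 0.002,
                       sigma_conc_rel = 0.02,
                       n_reps = 3,
                       n_patients = 300,
                       baseline_hazard = 0.02,
                       hazard_ratio = 2,
                       censoring_rate = 0.3,
                       effect_percentile = 50,
                       gene_correlation = 0.6,
                       max_followup = 120) {
  if (missing(seed)) mf_stop("sim_config requires an explicit seed", "midflux_config_error")
  cfg <- as.list(environment())
  fracs <- c(tracer_fraction, glycolysis_share, oxppp_share, pyruvate_fate,
             f_lac_from_glc, rho_nonox, acetyl_dilution, fa_new_synthesis,
             lactate_m1, censoring_rate)
  if (any(fracs < 0 | fracs > 1)) {
    mf_stop("all fractions must lie in [0, 1]", "midflux_config_error")
  }
  if (abs(glycolysis_share + oxppp_share - 1) > 1e-9) {
    mf_stop("glycolysis_share + oxppp_share must sum to 1", "midflux_config_error")
  }
  if (abs(sum(pyruvate_fate) - 1) > 1e-9) {
    mf_stop("pyruvate_fate fractions must sum to 1", "midflux_config_error")
  }
  # T = 0 is allowed here (an unlabeled control experiment); the flux
  # estimators themselves require T > 0
  if (lactate_release > 2 * glucose_uptake) {
    mf_stop("mass balance violated: lactate release exceeds 2 x glucose uptake",
            "midflux_config_error")
  }
  if (0.5 * tracer_fraction * f_lac_from_glc + lactate_m1 > 1) {
    mf_stop("lactate labeling fractions exceed 1", "midflux_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' Ground-truth labeling state implied by a simulator configuration
#'
#' Deterministic isotopologue bookkeeping at metabolic and isotopic steady
#' state: the glycolytic pyruvate pool is m2 with probability
#' `0.5 * T * f_lac_from_glc` (each labeled glucose split by aldolase yields
#' one m2 and one m0 triose), lactate and alanine inherit the pyruvate
#' distribution, ribose is m1 via the oxidative branch (C1 lost as CO2) and
#' m2 via the non-oxidative branch, and the fatty-acid MIDs follow
#' [fa_mid_model()] with acetyl enrichment
#' `p = 0.5 * T * (1 - acetyl_dilution)`.
#'
#' @param cfg A `sim_config`.
#' @param fragments Fragment registry (defines the SIM window lengths).
#' @return List with `mids` (tracer-only `mid` per metabolite, truncated to
#'   each SIM window), `rates` (true CORE rates) and `truth` (named list of
#'   every downstream estimand).
#' @export
simulate_label_state <- function(cfg, fragments = load_fragments()) {
  stopifnot(inherits(cfg, "sim_config"))
  T <- cfg$tracer_fraction
  windowed <- function(full, frag) {
    v <- full[seq_len(n_channels(frag))]
    mid(v / sum(v), frag, corrected = TRUE)
  }
  place <- function(frag, at, val) {
    v <- numeric(n_channels(frag))
    v[at + 1L] <- val
    v[1L] <- 1 - sum(val)
    mid(v, frag, corrected = TRUE)
  }
  pyr_m2 <- 0.5 * T * cfg$f_lac_from_glc
  p_true <- 0.5 * T * (1 - cfg$acetyl_dilution)
  mids <- list(
    glucose = place(fragments$glucose, 2L, T),
    lactate = place(fragments$lactate, c(1L, 2L), c(cfg$lactate_m1, pyr_m2)),
    alanine = place(fragments$alanine, 2L, pyr_m2),
    ribose = place(fragments$ribose, c(1L, 2L),
                   c((1 - cfg$rho_nonox) * T, cfg$rho_nonox * T)),
    palmitate = windowed(fa_mid_model(p_true, cfg$fa_new_synthesis, 8L), fragments$palmitate),
    stearate = windowed(fa_mid_model(p_true, cfg$fa_new_synthesis, 9L), fragments$stearate)
  )
  rates <- c(glucose = cfg$glucose_uptake, lactate = cfg$lactate_release,
             glutamine = cfg$glutamine_uptake, glutamate = cfg$glutamate_release)
  flux <- cfg$f_lac_from_glc * cfg$lactate_release
  truth <- list(
    tracer_fraction = T,
    core_rates = as.list(rates),
    f_lac_from_glc = cfg$f_lac_from_glc,
    glycolytic_flux = flux,
    glucose_to_lactate_share = flux / (2 * cfg$glucose_uptake),
    m2_alanine = pyr_m2,
    ribose_m1 = (1 - cfg$rho_nonox) * T,
    ribose_m2 = cfg$rho_nonox * T,
    ox_nonox_ratio = if (cfg$rho_nonox > 0) (1 - cfg$rho_nonox) / cfg$rho_nonox else NA_real_,
    ribose_enrichment = T,
    acetyl_p = p_true,
    fa_new_synthesis = cfg$fa_new_synthesis,
    pct_glucose_to_acetyl = (1 - cfg$acetyl_dilution) * 100,
    palmitate_enrichment = enrichment(mids$palmitate),
    stearate_enrichment = enrichment(mids$stearate),
    survival = list(n_patients = cfg$n_patients, baseline_hazard = cfg$baseline_hazard,
                    hazard_ratio = cfg$hazard_ratio, censoring_rate = cfg$censoring_rate,
                    effect_percentile = cfg$effect_percentile,
                    gene_correlation = cfg$gene_correlation,
                    median_baseline = log(2) / cfg$baseline_hazard)
  )
  list(mids = mids, rates = rates, truth = truth)
}

#' Emit observable CSVs (and ground truth) for a simulated experiment
#'
#' Converts the ground-truth state into the files the pipeline consumes:
#' raw MID tables (true MIDs convolved with natural abundance via the
#' correction matrix, plus seeded Gaussian channel noise), media
#' measurements (exact integral of consumption against exponential growth,
#' plus relative concentration noise), a survival cohort (exponential event
#' times, hazard multiplied for patients above the effect percentile of
#' gene-1 expression, uniform censoring, correlated gene-2), and a
#' ground-truth JSON. Identical seed and config give byte-identical files.
#'
#' @param state Output of [simulate_label_state()].
#' @param cfg The `sim_config` used to build it.
#' @param outdir Output directory (created if needed).
#' @param fragments,isotopes Registry and isotope table for the forward
#'   convolution.
#' @return Invisibly, named paths of the four files written:
#'   `mids`, `media`, `survival`, `truth`.
#' @export
emit_observables <- function(state, cfg, outdir,
                             fragments = load_fragments(),
                             isotopes = load_isotopes()) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  # --- raw MID table -------------------------------------------------------
  rows <- list()
  for (rep in seq_len(cfg$n_reps)) {
    sample_id <- sprintf("S%02d", rep)
    for (met in names(state$mids)) {
      frag <- fragments[[met]]
      M <- build_correction_matrix(frag, isotopes)
      raw <- convolve_mid(state$mids[[met]], M)
      if (cfg$sigma_mid > 0) {
        raw <- raw + stats::rnorm(length(raw), 0, cfg$sigma_mid)
        raw[raw < 0] <- 0
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, metabolite = met,
        channel_index = seq_along(raw) - 1L, abundance = raw,
        stringsAsFactors = FALSE)
    }
  }
  mid_df <- do.call(rbind, rows)
  # --- media table ---------------------------------------------------------
  k <- cfg$growth_rate
  dt <- cfg$duration
  n0 <- cfg$cells_initial
  n1 <- n0 * exp(k * dt)
  cell_hours_1e6 <- if (k == 0) (n0 / 1e6) * dt else (n0 / 1e6) * (exp(k * dt) - 1) / k
  media_rows <- list()
  for (rep in seq_len(cfg$n_reps)) {
    sample_id <- sprintf("S%02d", rep)
    for (met in names(state$rates)) {
      # nmol/1e6/h * 1e6 cell-hours -> nmol; /1000 -> umol; /mL -> mM
      delta_mM <- state$rates[[met]] * cell_hours_1e6 / 1000 / cfg$volume_ml
      c0 <- cfg$conc_start[[met]]
      c1 <- c0 - core_sign[[met]] * delta_mM
      if (c1 < 0) mf_stop(sprintf("simulated %s depleted below zero", met),
                          "midflux_config_error")
      if (cfg$sigma_conc_rel > 0) {
        c0 <- max(0, c0 * (1 + stats::rnorm(1, 0, cfg$sigma_conc_rel)))
        c1 <- max(0, c1 * (1 + stats::rnorm(1, 0, cfg$sigma_conc_rel)))
      }
      media_rows[[length(media_rows) + 1L]] <- data.frame(
        sample_id = sample_id, metabolite = met,
        conc_start = c0, conc_end = c1, volume_ml = cfg$volume_ml,
        t_start = 0, t_end = dt, cells_start = n0, cells_end = n1,
        stringsAsFactors = FALSE)
    }
  }
  media_df <- do.call(rbind, media_rows)
  # --- survival cohort -----------------------------------------------------
  np <- cfg$n_patients
  gene1 <- stats::rnorm(np)
  high <- gene1 > stats::quantile(gene1, cfg$effect_percentile / 100, names = FALSE)
  haz <- cfg$baseline_hazard * ifelse(high, cfg$hazard_ratio, 1)
  t_event <- stats::rexp(np, haz)
  # non-informative censoring: a fraction of subjects draws a censoring time
  # uniform on [0, max_followup], independent of the event process
  censor_draw <- stats::runif(np) < cfg$censoring_rate
  t_cens <- ifelse(censor_draw, stats::runif(np) * cfg$max_followup, Inf)
  time <- pmin(t_event, t_cens, cfg$max_followup)
  event <- as.integer(t_event <= pmin(t_cens, cfg$max_followup))
  rho <- cfg$gene_correlation
  gene2 <- rho * gene1 + sqrt(1 - rho^2) * stats::rnorm(np)
  surv_df <- data.frame(patient_id = sprintf("P%04d", seq_len(np)),
                        time_months = time, event = event,
                        expr_gene1 = gene1, expr_gene2 = gene2,
                        stringsAsFactors = FALSE)
  # --- write ---------------------------------------------------------------
  paths <- c(mids = file.path(outdir, "mids_raw.csv"),
             media = file.path(outdir, "media.csv"),
             survival = file.path(outdir, "survival.csv"),
             truth = file.path(outdir, "ground_truth.json"))
  utils::write.csv(mid_df, paths[["mids"]], row.names = FALSE)
  utils::write.csv(media_df, paths[["media"]], row.names = FALSE)
  utils::write.csv(surv_df, paths[["survival"]], row.names = FALSE)
  jsonlite::write_json(state$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Simulate a complete input bundle
#'
#' Convenience wrapper: [simulate_label_state()] then [emit_observables()].
#'
#' @inheritParams emit_observables
#' @param cfg A `sim_config`.
#' @param outdir Output directory.
#' @return Invisibly, the named file paths.
#' @examples
#' \donttest{
#' paths <- simulate_bundle(sim_config(seed = 1), tempfile("sim"))
#' }
#' @export
simulate_bundle <- function(cfg, outdir,
                            fragments = load_fragments(),
                            isotopes = load_isotopes()) {
  state <- simulate_label_state(cfg, fragments)
  emit_observables(state, cfg, outdir, fragments, isotopes)
}
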