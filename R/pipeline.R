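#' Assemble a pipeline configuration
#'
#' @param mid_csv,media_csv,survival_csv Input paths; `survival_csv` (and
#'   any other) may be `NULL`, which disables the corresponding stage.
#' @param outdir Output directory.
#' @param tracer_fraction Molar fraction of [1,2-13C2]-glucose in the
#'   medium glucose.
#' @param fragments_yaml,isotopes_yaml Optional registry overrides; `NULL`
#'   uses the bundled defaults.
#' @param m2_floor Floor for the ribose m1/m2 ratio denominator.
#' @param noise_floor MIDA channel noise floor.
#' @param cond_cap Correction-matrix condition-number cap.
#' @param tracer_purity Tracer isotopic purity (default 1).
#' @param permutations Permutations for the adjusted best-cutoff p (0 = off).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mid_csv = NULL, media_csv = NULL, survival_csv = NULL,
                            outdir = ".", tracer_fraction = 0.5,
                            fragments_yaml = NULL, isotopes_yaml = NULL,
                            m2_floor = 1e-4, noise_floor = 1e-3,
                            cond_cap = 1e8, tracer_purity = 1,
                            permutations = 0) {
  if (tracer_fraction <= 0 || tracer_fraction > 1) {
    mf_stop("tracer_fraction must be in (0, 1]", "midflux_config_error")
  }
  cfg <- mget(names(formals()))
  for (p in c(mid_csv, media_csv, survival_csv, fragments_yaml, isotopes_yaml)) {
    if (!is.null(p) && !file.exists(p)) {
      mf_stop(sprintf("input file does not exist: %s", p), "midflux_config_error")
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the tracer analysis pipeline end to end
#'
#' Executes correction -> CORE rates -> glycolytic flux -> PPP split ->
#' MIDA -> survival/correlation, writing one tidy CSV per stage plus a JSON
#' summary and a run log into `cfg$outdir`. A stage whose inputs are absent
#' is skipped with a logged warning; the others still run. Re-running on
#' identical inputs is byte-identical except for the log timestamp.
#'
#' @param cfg A `pipeline_config` (or path to a YAML file with the same
#'   fields).
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- do.call(pipeline_config, yaml::read_yaml(cfg))
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(fmt, ...) {
    log_lines[[length(log_lines) + 1L]] <<- sprintf(fmt, ...)
  }
  cfg_hash <- config_fingerprint(cfg)
  note("midflux %s | config %s", as.character(utils::packageVersion("midflux")), cfg_hash)
  summary <- list(package_version = as.character(utils::packageVersion("midflux")),
                  config_hash = cfg_hash,
                  tracer_fraction = cfg$tracer_fraction)
  isotopes <- load_isotopes(cfg$isotopes_yaml)
  fragments <- load_fragments(cfg$fragments_yaml, isotopes)

  corrected <- NULL
  if (!is.null(cfg$mid_csv)) {
    corrected <- stage_correct(cfg, fragments, isotopes, note)
    summary$n_samples <- length(unique(corrected$sample_id))
  } else {
    note("stage correct: skipped (no MID table)")
  }

  core <- NULL
  if (!is.null(cfg$media_csv)) {
    core <- core_flux_profile(read_media_table(cfg$media_csv))
    write_stage_csv(core$rates, cfg, "core_rates.csv", cfg_hash)
    for (i in seq_len(nrow(core$profile))) {
      summary$core_rates[[core$profile$metabolite[i]]] <- core$profile$mean[i]
    }
    note("stage core_rates: %d metabolites", nrow(core$profile))
  } else {
    note("stage core_rates: skipped (no media table)")
  }

  if (!is.null(corrected)) {
    summary <- stage_fluxes(cfg, corrected, core, fragments, summary, note)
    summary <- stage_mida(cfg, corrected, summary, note)
  }

  if (!is.null(cfg$survival_csv)) {
    summary <- stage_survival(cfg, summary, cfg_hash, note)
  } else {
    note("stage survival: skipped (no survival table)")
  }

  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(sprintf("# run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")), log_lines),
             file.path(cfg$outdir, "run_log.txt"))
  invisible(summary)
}

# fingerprint of the analytical configuration (output location excluded, so
# identical analyses stamp identical hashes wherever they are written)
config_fingerprint <- function(cfg) {
  keep <- sort(setdiff(names(cfg), "outdir"))
  fnv1a_hash(jsonlite::toJSON(unclass(cfg)[keep], auto_unbox = TRUE,
                              digits = NA, null = "null"))
}

write_stage_csv <- function(df, cfg, name, cfg_hash) {
  path <- file.path(cfg$outdir, name)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# midflux config %s", cfg_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  path
}

stage_correct <- function(cfg, fragments, isotopes, note) {
  tab <- read_mid_table(cfg$mid_csv)
  mids <- mids_from_table(tab, fragments)
  matrices <- lapply(fragments, build_correction_matrix, isotopes = isotopes,
                     purity = cfg$tracer_purity)
  rows <- list()
  for (s in names(mids)) {
    for (met in names(mids[[s]])) {
      corr <- tryCatch(
        correct_mid(mids[[s]][[met]], matrices[[met]], cond_cap = cfg$cond_cap),
        midflux_error = function(e) {
          mf_stop(sprintf("stage correct failed for sample '%s', metabolite '%s': %s",
                          s, met, conditionMessage(e)), "midflux_stage_error")
        })
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, metabolite = met,
        channel_index = seq_along(corr$fractions) - 1L,
        fraction = corr$fractions, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  write_stage_csv(out, cfg, "corrected_mids.csv", config_fingerprint(cfg))
  note("stage correct: %d samples x metabolites", length(rows))
  out
}

# mean corrected MID across samples for one metabolite, as a corrected `mid`
mean_corrected_mid <- function(corrected, met, fragments) {
  sub <- corrected[corrected$metabolite == met, , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  m <- tapply(sub$fraction, sub$channel_index, mean)
  mid(as.numeric(m[order(as.integer(names(m)))]), fragments[[met]], corrected = TRUE)
}

stage_fluxes <- function(cfg, corrected, core, fragments, summary, note) {
  rate_of <- function(met) {
    if (is.null(core)) return(NULL)
    i <- core$profile$metabolite == met
    if (!any(i)) NULL else core$profile$mean[i]
  }
  flux_rows <- list()
  lac <- mean_corrected_mid(corrected, "lactate", fragments)
  lac_rate <- rate_of("lactate")
  if (!is.null(lac) && !is.null(lac_rate) && lac_rate > 0) {
    res <- glycolytic_flux(lac, lac_rate, cfg$tracer_fraction, glc_rate = rate_of("glucose"))
    summary$f_lac_from_glc <- res$f_lac_from_glc
    summary$glycolytic_flux <- res$glycolytic_flux
    summary$glucose_to_lactate_share <- res$glucose_to_lactate_share
    summary$other_uses_share <- res$other_uses_share
    summary$m1_lactate <- res$m1_lactate
    flux_rows[[length(flux_rows) + 1L]] <- data.frame(
      quantity = c("f_lac_from_glc", "glycolytic_flux", "glucose_to_lactate_share"),
      value = c(res$f_lac_from_glc, res$glycolytic_flux, res$glucose_to_lactate_share))
    note("stage glycolysis: f = %.3f", res$f_lac_from_glc)
  } else {
    note("stage glycolysis: skipped (missing lactate MID or release rate)")
  }
  rib <- mean_corrected_mid(corrected, "ribose", fragments)
  if (!is.null(rib)) {
    pp <- ppp_split(rib, m2_floor = cfg$m2_floor)
    summary$ribose_m1 <- pp$m1_ribose
    summary$ribose_m2 <- pp$m2_ribose
    summary$ox_nonox_ratio <- pp$ox_nonox_ratio
    summary$ribose_enrichment <- enrichment(rib)
    flux_rows[[length(flux_rows) + 1L]] <- data.frame(
      quantity = c("ribose_m1", "ribose_m2", "ox_nonox_ratio", "ribose_enrichment"),
      value = c(pp$m1_ribose, pp$m2_ribose, pp$ox_nonox_ratio, enrichment(rib)))
    note("stage ppp: m1/m2 = %s", format(pp$ox_nonox_ratio))
  } else {
    note("stage ppp: skipped (missing ribose MID)")
  }
  ala <- mean_corrected_mid(corrected, "alanine", fragments)
  if (!is.null(ala)) {
    summary$m2_alanine <- m2_alanine(ala)
    flux_rows[[length(flux_rows) + 1L]] <- data.frame(
      quantity = "m2_alanine", value = summary$m2_alanine)
  } else {
    note("stage m2_alanine: skipped (missing alanine MID)")
  }
  if (length(flux_rows)) {
    cfg_hash <- summary$config_hash
    write_stage_csv(do.call(rbind, flux_rows), cfg, "fluxes.csv", cfg_hash)
  }
  summary
}

stage_mida <- function(cfg, corrected, summary, note) {
  units <- c(palmitate = 8L, stearate = 9L)
  rows <- list()
  fragments <- load_fragments(cfg$fragments_yaml)
  for (met in names(units)) {
    m <- mean_corrected_mid(corrected, met, fragments)
    if (is.null(m)) {
      note("stage mida (%s): skipped (no MID)", met)
      next
    }
    fit <- tryCatch(fit_mida(m, units[[met]], cfg$tracer_fraction, cfg$noise_floor),
                    midflux_insufficient_labeling = function(e) NULL)
    if (is.null(fit)) {
      note("stage mida (%s): skipped (insufficient labeling)", met)
      next
    }
    summary[[paste0(met, "_enrichment")]] <- fa_enrichment(m)
    summary[[paste0(met, "_p")]] <- fit$p
    summary[[paste0(met, "_g")]] <- fit$g
    summary[[paste0(met, "_pct_glucose_to_acetyl")]] <- fit$pct_glucose_to_acetyl
    rows[[length(rows) + 1L]] <- data.frame(
      metabolite = met, n_units = fit$n_units, p = fit$p, p_ratio = fit$p_ratio,
      g = fit$g, pct_glucose_to_acetyl = fit$pct_glucose_to_acetyl,
      enrichment = fa_enrichment(m), fit_residual = fit$fit_residual)
    note("stage mida (%s): p = %.4f, g = %.4f", met, fit$p, fit$g)
  }
  if (length(rows)) {
    write_stage_csv(do.call(rbind, rows), cfg, "mida.csv", summary$config_hash)
    if (!is.null(summary$palmitate_p)) {
      summary$acetyl_p <- summary$palmitate_p
      summary$pct_glucose_to_acetyl <- summary$palmitate_pct_glucose_to_acetyl
      summary$fa_new_synthesis <- summary$palmitate_g
    }
  }
  summary
}

stage_survival <- function(cfg, summary, cfg_hash, note) {
  df <- read_survival_table(cfg$survival_csv)
  genes <- grep("^expr_", names(df), value = TRUE)
  if (!length(genes)) {
    note("stage survival: skipped (no expr_* columns)")
    return(summary)
  }
  scans <- list()
  for (g in genes) {
    bc <- best_cutoff(df$time_months, df$event, df[[g]],
                      permutations = cfg$permutations)
    gene <- sub("^expr_", "", g)
    summary$survival[[gene]] <- list(
      best_percentile = bc$percentile, cutoff = bc$cutoff,
      logrank_statistic = bc$statistic, logrank_p = bc$p,
      p_selection_biased = TRUE, p_permutation = bc$p_permutation)
    sc <- bc$scan
    sc$gene <- gene
    scans[[gene]] <- sc
    km_high <- km_estimate(df$time_months[df[[g]] > bc$cutoff], df$event[df[[g]] > bc$cutoff])
    km_low <- km_estimate(df$time_months[df[[g]] <= bc$cutoff], df$event[df[[g]] <= bc$cutoff])
    km_tab <- rbind(cbind(gene = gene, group = "high", km_high$table),
                    cbind(gene = gene, group = "low", km_low$table))
    write_stage_csv(km_tab, cfg, sprintf("km_%s.csv", gene), cfg_hash)
    summary$survival[[gene]]$km_median_high <- km_high$median
    summary$survival[[gene]]$km_median_low <- km_low$median
    note("stage survival (%s): best percentile %d, p = %.3g", gene, bc$percentile, bc$p)
  }
  write_stage_csv(do.call(rbind, scans), cfg, "survival_scan.csv", cfg_hash)
  if (length(genes) >= 2L) {
    pc <- pearson_correlation(df[[genes[1L]]], df[[genes[2L]]])
    summary$expression_correlation <- list(
      genes = sub("^expr_", "", genes[1:2]), r = pc$r, p = pc$p, n = pc$n)
    note("stage correlation: r = %.3f", pc$r)
  }
  summary
}
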