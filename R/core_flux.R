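core_sign <- c(glucose = +1, glutamine = +1, lactate = -1, glutamate = -1)

#' Consumption/release rate of one medium metabolite
#'
#' Computes the CORE (consumption and release) rate from start/end medium
#' concentrations, normalized to cell exposure. Between the two cell counts
#' exponential growth is assumed, so the cell-time integral is the log-mean
#' count times the interval, `((N1 - N0) / ln(N1/N0)) * dt` (exact under
#' exponential growth); when the counts are equal the arithmetic limit
#' `N * dt` is used. The sign convention is consumption-positive for glucose
#' and glutamine, release-positive for lactate and glutamate.
#'
#' @param metabolite One of `"glucose"`, `"glutamine"`, `"lactate"`,
#'   `"glutamate"`.
#' @param conc_start,conc_end Medium concentrations (mM).
#' @param volume_ml Medium volume (mL).
#' @param t_start,t_end Sampling times (hours).
#' @param cells_start,cells_end Cell counts at the two times.
#' @return Rate in nmol per 1e6 cells per hour, signed per convention.
#' @examples
#' # constant 1e6 cells, 2 mM drop in 2 mL over 24 h
#' core_rate("glucose", 10, 8, 2, 0, 24, 1e6, 1e6)
#' @export
core_rate <- function(metabolite, conc_start, conc_end, volume_ml,
                      t_start, t_end, cells_start, cells_end) {
  if (!metabolite %in% names(core_sign)) {
    mf_stop(sprintf("unknown CORE metabolite '%s'", metabolite), "midflux_input_error")
  }
  if (cells_start <= 0 || cells_end <= 0) {
    mf_stop("cell counts must be positive", "midflux_input_error")
  }
  if (t_end <= t_start) mf_stop("t_end must exceed t_start", "midflux_input_error")
  nbar <- if (cells_end == cells_start) {
    cells_start
  } else {
    (cells_end - cells_start) / log(cells_end / cells_start)
  }
  dt <- t_end - t_start
  # mM * mL = umol; *1000 -> nmol; normalize to 1e6 cell-hours
  delta_nmol <- (conc_start - conc_end) * volume_ml * 1000
  core_sign[[metabolite]] * delta_nmol / ((nbar / 1e6) * dt)
}

#' CORE flux profile for a media table
#'
#' Applies [core_rate()] row-wise and summarizes per metabolite across
#' samples. A metabolite reported as consumption whose mean rate is negative
#' beyond 5% of its magnitude is flagged (apparent net release where
#' consumption was expected).
#'
#' @param media Data frame from [read_media_table()].
#' @return List with `rates` (per-sample data frame: `sample_id`,
#'   `metabolite`, `rate`) and `profile` (per-metabolite `mean`, `sd`, `n`,
#'   `flagged`). Rates in nmol per 1e6 cells per hour.
#' @export
core_flux_profile <- function(media) {
  rates <- data.frame(
    sample_id = media$sample_id,
    metabolite = media$metabolite,
    rate = vapply(seq_len(nrow(media)), function(i) {
      core_rate(media$metabolite[i], media$conc_start[i], media$conc_end[i],
                media$volume_ml[i], media$t_start[i], media$t_end[i],
                media$cells_start[i], media$cells_end[i])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  mets <- unique(rates$metabolite)
  profile <- data.frame(
    metabolite = mets,
    mean = vapply(mets, function(m) mean(rates$rate[rates$metabolite == m]), numeric(1)),
    sd = vapply(mets, function(m) stats::sd(rates$rate[rates$metabolite == m]), numeric(1)),
    n = vapply(mets, function(m) sum(rates$metabolite == m), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  profile$flagged <- core_sign[profile$metabolite] > 0 &
    profile$mean < -0.05 * abs(profile$mean)
  if (any(profile$flagged)) {
    mf_warn(sprintf("apparent net release of %s despite consumption convention",
                    paste(profile$metabolite[profile$flagged], collapse = ", ")),
            "midflux_core_sign")
  }
  list(rates = rates, profile = profile)
}
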