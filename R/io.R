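#' Read a long-format MID table
#'
#' Expects a CSV with columns `sample_id`, `metabolite`, `channel_index`
#' (0-based), `abundance` (raw ion abundances, any scale). Abundances are
#' normalized to fractions within each (sample, metabolite) pair.
#'
#' @param path CSV path.
#' @return A data frame with columns `sample_id`, `metabolite`,
#'   `channel_index`, `abundance`, `fraction`.
#' @export
read_mid_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "metabolite", "channel_index", "abundance")
  if (!all(need %in% names(df))) {
    mf_stop(sprintf("MID table must have columns: %s", paste(need, collapse = ", ")),
            "midflux_input_error")
  }
  if (any(df$abundance < 0)) mf_stop("negative abundances in MID table", "midflux_input_error")
  df <- df[order(df$sample_id, df$metabolite, df$channel_index), , drop = FALSE]
  key <- interaction(df$sample_id, df$metabolite, drop = TRUE)
  totals <- tapply(df$abundance, key, sum)
  if (any(totals <= 0)) mf_stop("a (sample, metabolite) block sums to zero", "midflux_input_error")
  df$fraction <- df$abundance / as.numeric(totals[key])
  rownames(df) <- NULL
  df
}

#' Build `mid` objects from a long MID table
#'
#' @param table Data frame from [read_mid_table()].
#' @param fragments Fragment registry from [load_fragments()]; metabolites
#'   absent from the registry are dropped with a warning.
#' @return Nested list: `mids[[sample_id]][[metabolite]]`, each a raw `mid`.
#' @export
mids_from_table <- function(table, fragments = load_fragments()) {
  unknown <- setdiff(unique(table$metabolite), names(fragments))
  if (length(unknown)) {
    mf_warn(sprintf("dropping metabolites absent from the fragment registry: %s",
                    paste(unknown, collapse = ", ")), "midflux_unknown_metabolite")
    table <- table[table$metabolite %in% names(fragments), , drop = FALSE]
  }
  out <- list()
  for (s in unique(table$sample_id)) {
    sub <- table[table$sample_id == s, , drop = FALSE]
    out[[s]] <- list()
    for (met in unique(sub$metabolite)) {
      block <- sub[sub$metabolite == met, , drop = FALSE]
      block <- block[order(block$channel_index), , drop = FALSE]
      frag <- fragments[[met]]
      if (nrow(block) != n_channels(frag)) {
        mf_stop(sprintf("sample '%s', metabolite '%s': %d channels recorded, registry expects %d",
                        s, met, nrow(block), n_channels(frag)), "midflux_input_error")
      }
      out[[s]][[met]] <- mid(block$fraction, frag, corrected = FALSE)
    }
  }
  out
}

#' Read a media measurement table
#'
#' CSV with one row per (sample, metabolite): `sample_id`, `metabolite`,
#' `conc_start`, `conc_end` (mM), `volume_ml`, `t_start`, `t_end` (hours),
#' `cells_start`, `cells_end` (counts).
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_media_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "metabolite", "conc_start", "conc_end", "volume_ml",
            "t_start", "t_end", "cells_start", "cells_end")
  if (!all(need %in% names(df))) {
    mf_stop(sprintf("media table must have columns: %s", paste(need, collapse = ", ")),
            "midflux_input_error")
  }
  if (any(df$t_end <= df$t_start)) mf_stop("t_end must exceed t_start", "midflux_input_error")
  if (any(df$cells_start <= 0 | df$cells_end <= 0)) {
    mf_stop("cell counts must be positive", "midflux_input_error")
  }
  if (any(df$conc_start < 0 | df$conc_end < 0)) {
    mf_stop("concentrations must be non-negative", "midflux_input_error")
  }
  df
}

#' Read a survival table
#'
#' CSV with columns `patient_id`, `time_months`, `event` (1 = event,
#' 0 = censored) and one or more expression columns (`expr_*`).
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_survival_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_months", "event")
  if (!all(need %in% names(df))) {
    mf_stop("survival table must have columns patient_id, time_months, event",
            "midflux_input_error")
  }
  if (any(df$time_months <= 0)) mf_stop("survival times must be positive", "midflux_input_error")
  if (!all(df$event %in% c(0, 1))) mf_stop("event must be 0 or 1", "midflux_input_error")
  df
}
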