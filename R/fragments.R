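#' Define a SIM fragment
#'
#' A fragment specification ties a metabolite to the derivatized ion actually
#' recorded by the mass spectrometer: its elemental composition, the number of
#' biological backbone carbons it carries (the carbons a tracer can label),
#' and the selected-ion-monitoring (SIM) m/z window.
#'
#' @param metabolite Metabolite name (e.g. `"ribose"`).
#' @param formula Named integer vector or list of element counts for the
#'   derivatized fragment ion, e.g. `c(C = 11, H = 14, N = 1, O = 6)`.
#' @param n_carbons Number of backbone carbons of the biological molecule
#'   carried by the fragment (labelable positions).
#' @param mz_low,mz_high Integer bounds of the recorded SIM window; the
#'   number of recorded isotopologue channels is `mz_high - mz_low + 1`.
#' @param isotopes Isotope table used for the mass sanity check; the
#'   monoisotopic mass of `formula` must lie within `[mz_low - 1, mz_high]`
#'   (1 Da tolerance absorbs the proton transfer of chemical ionization).
#' @return An object of class `fragment_spec`.
#' @examples
#' fragment_spec("ribose", c(C = 11, H = 14, N = 1, O = 6), 5, 256, 261)
#' @export
fragment_spec <- function(metabolite, formula, n_carbons, mz_low, mz_high,
                          isotopes = load_isotopes()) {
  formula <- unlist(formula)
  names(formula) <- fix_element_names(names(formula))
  if (any(formula < 0)) mf_stop("formula element counts must be >= 0", "midflux_config_error")
  if (n_carbons < 1) mf_stop("n_carbons must be >= 1", "midflux_config_error")
  if (mz_high <= mz_low) mf_stop("mz_high must exceed mz_low", "midflux_config_error")
  if (is.null(formula[["C"]]) || formula[["C"]] < n_carbons) {
    mf_stop(sprintf("fragment '%s': formula carries fewer carbons than the backbone", metabolite),
            "midflux_config_error")
  }
  mono <- monoisotopic_mass(as.list(formula), isotopes)
  if (mono < mz_low - 1 || mono > mz_high) {
    mf_stop(sprintf(
      "fragment '%s': monoisotopic mass %.3f falls outside the SIM window sanity range [%d, %d]",
      metabolite, mono, mz_low - 1L, mz_high), "midflux_config_error")
  }
  structure(list(metabolite = metabolite, formula = formula,
                 n_carbons = as.integer(n_carbons),
                 mz_low = as.integer(mz_low), mz_high = as.integer(mz_high),
                 monoisotopic_mass = mono),
            class = "fragment_spec")
}

#' Number of recorded isotopologue channels of a fragment
#' @param fragment A `fragment_spec`.
#' @return Integer channel count (`mz_high - mz_low + 1`).
#' @export
n_channels <- function(fragment) {
  stopifnot(inherits(fragment, "fragment_spec"))
  fragment$mz_high - fragment$mz_low + 1L
}

#' @export
print.fragment_spec <- function(x, ...) {
  f <- paste0(names(x$formula), ifelse(x$formula > 1, x$formula, ""), collapse = "")
  cat(sprintf("<fragment_spec> %s: %s (%.3f Da), %d backbone C, SIM %d-%d (%d channels)\n",
              x$metabolite, f, x$monoisotopic_mass, x$n_carbons,
              x$mz_low, x$mz_high, n_channels(x)))
  invisible(x)
}

#' Load a fragment registry
#'
#' Reads a YAML registry keyed by metabolite name, each entry holding
#' `formula`, `n_carbons`, `mz_low`, `mz_high`. The bundled default registry
#' covers the six fragments of the [1,2-13C2]-glucose workflow: glucose
#' (327-336 m/z), lactate (327-332), alanine (241-246), ribose (256-261),
#' palmitate (269-278) and stearate (297-307), with elemental compositions
#' implied by the derivatization chemistry (aldononitrile acetates,
#' heptafluorobutyryl propylamide, N-TFA butyl ester, methyl esters).
#'
#' @param path Path to a YAML registry; defaults to the bundled registry.
#' @param isotopes Isotope table used for validation.
#' @return Named list of `fragment_spec` objects.
#' @examples
#' reg <- load_fragments()
#' names(reg)
#' @export
load_fragments <- function(path = NULL, isotopes = load_isotopes()) {
  path <- path %||% system.file("extdata", "fragments.yaml", package = "midflux")
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(met) {
    e <- raw[[met]]
    fragment_spec(met, e$formula, e$n_carbons, e$mz_low, e$mz_high, isotopes)
  })
  names(out) <- names(raw)
  out
}
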