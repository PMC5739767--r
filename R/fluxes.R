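#' Glycolytic flux from lactate labeling
#'
#' Under a medium in which a molar fraction `T` of glucose is
#' [1,2-13C2]-glucose, every labeled glucose processed by glycolysis yields
#' one m2 lactate (from carbons 1-3) and one m0 lactate (carbons 4-6), so a
#' fully glycolytic lactate pool shows `m2 = 0.5 * T`. The fraction of
#' released lactate that came from glucose via glycolysis is therefore
#' `f = m2 / (0.5 * T)`, and the glycolytic flux is `f` times the lactate
#' release rate. Lactate m1 (pentose-phosphate recycling) is deliberately
#' excluded from `f` and reported as a diagnostic.
#'
#' @param lac_mid Corrected lactate `mid`.
#' @param lac_rate Lactate release rate (nmol per 1e6 cells per hour), > 0.
#' @param tracer_fraction Molar fraction `T` of medium glucose that is
#'   [1,2-13C2]-glucose, in (0, 1].
#' @param glc_rate Optional glucose consumption rate (same units); when
#'   given, the share of consumed glucose accounted for by lactate release
#'   is computed with the 2-lactate-per-glucose stoichiometry:
#'   `share = glycolytic_flux / (2 * glc_rate)`.
#' @return List of class `glycolysis_result`: `f_lac_from_glc`,
#'   `glycolytic_flux`, `glucose_to_lactate_share`, `other_uses_share`,
#'   `m1_lactate` (diagnostic), `flagged` (TRUE when `f > 1.05`, a model
#'   violation).
#' @examples
#' reg <- load_fragments()
#' lac <- mid(c(0.825, 0, 0.175, 0, 0, 0), reg$lactate, corrected = TRUE)
#' glycolytic_flux(lac, lac_rate = 280, tracer_fraction = 0.5, glc_rate = 200)
#' @export
glycolytic_flux <- function(lac_mid, lac_rate, tracer_fraction, glc_rate = NULL) {
  stopifnot(inherits(lac_mid, "mid"))
  if (!lac_mid$corrected) mf_stop("lactate MID must be corrected", "midflux_input_error")
  if (tracer_fraction <= 0 || tracer_fraction > 1) {
    mf_stop("tracer_fraction must be in (0, 1]", "midflux_input_error")
  }
  if (lac_rate <= 0) mf_stop("lactate release rate must be positive", "midflux_input_error")
  m2 <- mid_fraction(lac_mid, 2)
  f <- m2 / (0.5 * tracer_fraction)
  flagged <- f > 1.05
  if (flagged) {
    mf_warn(sprintf("f_lac_from_glc = %.3f exceeds 1: labeling model violation", f),
            "midflux_model_violation")
  }
  flux <- f * lac_rate
  share <- other <- NA_real_
  if (!is.null(glc_rate)) {
    if (glc_rate <= 0) mf_stop("glucose consumption rate must be positive", "midflux_input_error")
    share <- flux / (2 * glc_rate)
    if (share > 1.05) {
      mf_warn(sprintf("glucose_to_lactate_share = %.3f exceeds 1", share),
              "midflux_model_violation")
    }
    other <- 1 - share
  }
  structure(list(f_lac_from_glc = f, glycolytic_flux = flux,
                 glucose_to_lactate_share = share, other_uses_share = other,
                 m1_lactate = mid_fraction(lac_mid, 1), flagged = flagged),
            class = "glycolysis_result")
}

#' Oxidative vs non-oxidative pentose phosphate pathway split
#'
#' With [1,2-13C2]-glucose, ribose made through the oxidative branch loses
#' the labeled C1 as CO2 and appears as m1, while the non-oxidative branch
#' retains both labels and yields m2 ribose. The m1/m2 ratio therefore
#' tracks relative oxidative vs non-oxidative activity.
#'
#' @param ribose_mid Corrected 6-channel ribose `mid`.
#' @param m2_floor Smallest m2 for which the ratio is reported; below it the
#'   ratio is returned as `NA` with `ratio_defined = FALSE` rather than a
#'   blown-up value. Default 1e-4 (below realistic MID precision).
#' @return List of class `ppp_split`: `m1_ribose`, `m2_ribose`,
#'   `ox_nonox_ratio` (`NA` when undefined), `ratio_defined`.
#' @examples
#' reg <- load_fragments()
#' ppp_split(mid(c(0.8, 0.1, 0.1, 0, 0, 0), reg$ribose, corrected = TRUE))
#' @export
ppp_split <- function(ribose_mid, m2_floor = 1e-4) {
  stopifnot(inherits(ribose_mid, "mid"))
  if (!ribose_mid$corrected) mf_stop("ribose MID must be corrected", "midflux_input_error")
  m1 <- mid_fraction(ribose_mid, 1)
  m2 <- mid_fraction(ribose_mid, 2)
  defined <- m2 >= m2_floor
  structure(list(m1_ribose = m1, m2_ribose = m2,
                 ox_nonox_ratio = if (defined) m1 / m2 else NA_real_,
                 ratio_defined = defined),
            class = "ppp_split")
}

#' m2 alanine fraction
#'
#' Alanine exchanges with pyruvate, so its m2 fraction is a proxy for
#' labeling of the pyruvate pool feeding transamination.
#'
#' @param ala_mid Corrected alanine `mid`.
#' @return The m2 fraction.
#' @export
m2_alanine <- function(ala_mid) {
  stopifnot(inherits(ala_mid, "mid"))
  if (!ala_mid$corrected) mf_stop("alanine MID must be corrected", "midflux_input_error")
  mid_fraction(ala_mid, 2)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Fold change of a target gene in condition A relative to condition B,
#' each normalized to a reference gene:
#' `2^-((ct_target_a - ct_ref_a) - (ct_target_b - ct_ref_b))`.
#'
#' @param ct_target_a,ct_ref_a Target and reference Ct in condition A.
#' @param ct_target_b,ct_ref_b Target and reference Ct in condition B
#'   (the baseline).
#' @return Fold change (1 = no change, 0.5 = one cycle less template).
#' @examples
#' fold_change_ddct(26, 20, 25, 20)  # one extra cycle -> 0.5
#' @export
fold_change_ddct <- function(ct_target_a, ct_ref_a, ct_target_b, ct_ref_b) {
  cts <- c(ct_target_a, ct_ref_a, ct_target_b, ct_ref_b)
  if (any(!is.finite(cts)) || any(cts <= 0) || any(cts >= 45)) {
    mf_stop("Ct values must lie in (0, 45)", "midflux_input_error")
  }
  ddct <- (ct_target_a - ct_ref_a) - (ct_target_b - ct_ref_b)
  2^(-ddct)
}
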