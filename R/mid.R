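#' Construct a mass isotopologue distribution (MID)
#'
#' A MID is the vector of fractions of molecules of one fragment whose mass
#' exceeds the monoisotopic species by 0, 1, ..., K mass units (m0..mK),
#' where K + 1 is the number of recorded SIM channels. Fractions are
#' normalized to sum to 1.
#'
#' @param fractions Non-negative numeric vector m0..mK; normalized on input.
#' @param fragment The `fragment_spec` the vector belongs to; when supplied,
#'   the length must equal the fragment's channel count.
#' @param corrected Logical: has natural isotope abundance been removed?
#' @return An object of class `mid`.
#' @examples
#' mid(c(0.5, 0, 0.5, 0, 0, 0))
#' @export
mid <- function(fractions, fragment = NULL, corrected = FALSE) {
  fractions <- as.numeric(fractions)
  if (any(!is.finite(fractions)) || any(fractions < 0)) {
    mf_stop("MID fractions must be finite and non-negative", "midflux_input_error")
  }
  s <- sum(fractions)
  if (s <= 0) mf_stop("MID fractions sum to zero", "midflux_input_error")
  fractions <- fractions / s
  if (!is.null(fragment)) {
    stopifnot(inherits(fragment, "fragment_spec"))
    if (length(fractions) != n_channels(fragment)) {
      mf_stop(sprintf("MID for '%s' has %d channels; fragment records %d",
                      fragment$metabolite, length(fractions), n_channels(fragment)),
              "midflux_input_error")
    }
  }
  structure(list(fractions = fractions, fragment = fragment,
                 corrected = isTRUE(corrected)),
            class = "mid")
}

#' @export
print.mid <- function(x, digits = 4, ...) {
  met <- if (!is.null(x$fragment)) x$fragment$metabolite else "?"
  cat(sprintf("<mid> %s (%s), %d channels\n", met,
              if (x$corrected) "corrected" else "raw", length(x$fractions)))
  v <- round(x$fractions, digits)
  names(v) <- paste0("m", seq_along(v) - 1L)
  print(v)
  invisible(x)
}

#' Extract one isotopologue fraction
#' @param x A `mid`.
#' @param k Isotopologue index (0 for m0).
#' @return The mk fraction.
#' @export
mid_fraction <- function(x, k) {
  stopifnot(inherits(x, "mid"))
  if (k < 0 || k >= length(x$fractions)) {
    mf_stop(sprintf("channel m%d outside the recorded window", k), "midflux_input_error")
  }
  x$fractions[k + 1L]
}

#' Fraction of molecules carrying at least one tracer carbon
#'
#' For a corrected MID this is the total labeled fraction, `1 - m0`; it is
#' the "total 13C-labeled" summary commonly reported for ribose from RNA and
#' for fatty acids.
#'
#' @param x A corrected `mid`.
#' @return `1 - m0`.
#' @seealso [mean_label()] for the average number of labeled carbons per
#'   carbon, a distinct summary.
#' @export
enrichment <- function(x) {
  stopifnot(inherits(x, "mid"))
  if (!x$corrected) mf_warn("enrichment() on an uncorrected MID", "midflux_uncorrected")
  1 - x$fractions[1L]
}

#' Mean label per carbon
#'
#' The average number of tracer carbons per backbone carbon,
#' `sum(i * mi) / n_carbons`. This weights multiply-labeled species more than
#' [enrichment()], which only asks whether a molecule carries any label.
#'
#' @param x A corrected `mid` with an attached fragment (for `n_carbons`).
#' @return Mean label per carbon, in `[0, 1]`.
#' @export
mean_label <- function(x) {
  stopifnot(inherits(x, "mid"))
  if (is.null(x$fragment)) mf_stop("mean_label() needs a fragment to supply n_carbons",
                                   "midflux_input_error")
  if (!x$corrected) mf_warn("mean_label() on an uncorrected MID", "midflux_uncorrected")
  k <- seq_along(x$fractions) - 1
  sum(k * x$fractions) / x$fragment$n_carbons
}
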