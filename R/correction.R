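#' Build the natural-abundance correction matrix for a fragment
#'
#' Column j (0-based) of the returned matrix is the mass-shift distribution,
#' over the recorded SIM channels, of a fragment molecule already carrying j
#' tracer 13C atoms: those j backbone carbons are excluded from the natural
#' 13C binomial, every other atom contributes its natural isotope
#' distribution, and the whole column is shifted up by j channels. Columns
#' are truncated to the window and deliberately NOT renormalized — mass
#' leaving the SIM window is real signal loss and is absorbed by the
#' non-negative least-squares solve in [correct_mid()], which keeps the
#' forward model linear.
#'
#' @param fragment A `fragment_spec`.
#' @param isotopes An `isotope_table`.
#' @param purity Tracer isotopic purity: probability that a nominally
#'   labeled position actually carries 13C. Default 1.
#' @return A `channels x channels` lower-triangular (in mass shift) matrix.
#'   Multiplying it by a tracer-only MID gives the MID the instrument
#'   observes.
#' @examples
#' reg <- load_fragments()
#' M <- build_correction_matrix(reg$ribose, load_isotopes())
#' colSums(M)  # < 1: window truncation loss
#' @export
build_correction_matrix <- function(fragment, isotopes = load_isotopes(), purity = 1) {
  stopifnot(inherits(fragment, "fragment_spec"))
  if (purity <= 0 || purity > 1) mf_stop("purity must be in (0, 1]", "midflux_config_error")
  channels <- n_channels(fragment)
  formula <- fragment$formula
  nC <- formula[["C"]]
  M <- matrix(0, channels, channels)
  for (j in 0:(channels - 1L)) {
    # tracer positions cannot exceed the backbone; columns beyond it exist
    # only to keep the matrix square and should attract no weight
    j_trac <- min(j, fragment$n_carbons)
    # tracer positions shift mass by the number that truly carry 13C
    shift <- if (purity < 1 && j > 0) {
      base <- numeric(channels)
      base[1L + (0:j)] <- stats::dbinom(0:j, j, purity)
      base
    } else {
      base <- numeric(channels)
      base[j + 1L] <- 1
      base
    }
    dist <- shift
    dist <- conv_trunc(dist, natural_binom(isotopes, "C", nC - j_trac, channels), channels)
    for (el in setdiff(names(formula), "C")) {
      dist <- conv_trunc(dist, natural_binom(isotopes, el, formula[[el]], channels), channels)
    }
    M[, j + 1L] <- dist
  }
  M
}

# mass-shift distribution of `count` atoms of one element at natural
# abundance, truncated to `len` channels
natural_binom <- function(isotopes, element, count, len) {
  if (count == 0) return(1)
  atom <- atom_shift_dist(isotopes, element)
  out <- 1
  for (i in seq_len(count)) out <- conv_trunc(out, atom, len)
  out
}

#' Convolve a tracer-only MID with natural abundance
#'
#' The forward model: given the MID a fragment would show if only tracer
#' carbons added mass, returns the abundance pattern the instrument records
#' over the SIM window (column-truncated, so the result may sum to less
#' than 1). Used by the simulator and by round-trip tests.
#'
#' @param x A `mid` (or bare numeric vector of channel fractions).
#' @param matrix Correction matrix from [build_correction_matrix()].
#' @return Numeric vector of observed channel abundances.
#' @export
convolve_mid <- function(x, matrix) {
  v <- if (inherits(x, "mid")) x$fractions else as.numeric(x)
  if (length(v) != ncol(matrix)) {
    mf_stop("MID length does not match correction matrix", "midflux_input_error")
  }
  as.numeric(matrix %*% v)
}

#' Remove natural isotope abundance from a raw MID
#'
#' Solves `matrix %*% x = raw` by non-negative least squares, clips any
#' residual negatives at zero and renormalizes to the simplex, so the result
#' reflects tracer-derived labeling only. With the un-renormalized matrix of
#' [build_correction_matrix()], mass lost off the end of the SIM window is
#' absorbed by the solve rather than biasing the low channels.
#'
#' @param raw A raw `mid` for the same fragment the matrix was built for.
#' @param matrix Correction matrix from [build_correction_matrix()].
#' @param cond_cap Condition-number cap; a matrix above it aborts with a
#'   conditioning error. Default 1e8.
#' @param residual_tol Corrected signal allowed in channels beyond the
#'   backbone carbon count before a warning is raised. Default 0.005.
#' @return A corrected `mid` (`corrected = TRUE`).
#' @examples
#' reg <- load_fragments()
#' M <- build_correction_matrix(reg$ribose)
#' truth <- c(0.6, 0.15, 0.25, 0, 0, 0)
#' raw <- mid(convolve_mid(truth, M), reg$ribose)
#' correct_mid(raw, M)$fractions  # recovers `truth`
#' @export
correct_mid <- function(raw, matrix, cond_cap = 1e8, residual_tol = 0.005) {
  stopifnot(inherits(raw, "mid"))
  if (kappa(matrix, exact = TRUE) > cond_cap) {
    mf_stop(sprintf("correction matrix condition number exceeds %g", cond_cap),
            "midflux_conditioning_error")
  }
  x <- pracma::lsqnonneg(matrix, raw$fractions)$x
  clipped <- x < 0
  if (any(x[clipped] < -0.01)) {
    mf_warn(sprintf("clipped %d channel(s) with negative weight below -0.01",
                    sum(x[clipped] < -0.01)), "midflux_clip")
  }
  x[clipped] <- 0
  if (sum(x) <= 0) mf_stop("correction annihilated the MID", "midflux_input_error")
  x <- x / sum(x)
  frag <- raw$fragment
  if (!is.null(frag) && length(x) > frag$n_carbons + 1L) {
    beyond <- x[(frag$n_carbons + 2L):length(x)]
    if (any(beyond > residual_tol)) {
      mf_warn(sprintf("corrected MID for '%s' has %.4f signal beyond the %d-carbon backbone",
                      frag$metabolite, max(beyond), frag$n_carbons), "midflux_residual")
    }
  }
  mid(x, frag, corrected = TRUE)
}
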