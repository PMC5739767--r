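#' Load a natural-abundance isotope table
#'
#' Reads a YAML table mapping each element to its stable isotopes, given as
#' `(offset, mass, abundance)` entries where `offset` is the nominal mass
#' shift relative to the lightest (most abundant) isotope. Abundances per
#' element must sum to 1 within 1e-12.
#'
#' @param path Path to a YAML isotope table. Defaults to the bundled table
#'   of IUPAC representative natural abundances.
#' @return An object of class `isotope_table`: a named list, one entry per
#'   element, each a data frame with columns `offset`, `mass`, `abundance`.
#' @examples
#' iso <- load_isotopes()
#' iso$C
#' @export
load_isotopes <- function(path = NULL) {
  path <- path %||% system.file("extdata", "isotopes.yaml", package = "midflux")
  raw <- yaml::read_yaml(path)
  names(raw) <- fix_element_names(names(raw))
  tab <- lapply(raw, function(entries) {
    df <- do.call(rbind, lapply(entries, as.data.frame))
    df[order(df$offset), , drop = FALSE]
  })
  for (el in names(tab)) {
    s <- sum(tab[[el]]$abundance)
    if (abs(s - 1) > 1e-12) {
      mf_stop(sprintf("isotope abundances for element '%s' sum to %.15f, not 1", el, s),
              "midflux_config_error")
    }
    if (any(tab[[el]]$abundance < 0)) {
      mf_stop(sprintf("negative isotope abundance for element '%s'", el),
              "midflux_config_error")
    }
  }
  structure(tab, class = "isotope_table")
}

#' @export
print.isotope_table <- function(x, ...) {
  cat("<isotope_table> elements:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

# YAML 1.1 parses a bare N (or Y) key as a boolean; map it back to the element
fix_element_names <- function(x) {
  x[x == "FALSE"] <- "N"
  x[x == "TRUE"] <- "Y"
  x
}

# single-atom mass-shift distribution for one element, as a numeric vector
# over offsets 0..max(offset)
atom_shift_dist <- function(iso, element) {
  entry <- iso[[element]]
  if (is.null(entry)) {
    mf_stop(sprintf("unknown element '%s' in fragment formula", element),
            "midflux_config_error")
  }
  d <- numeric(max(entry$offset) + 1L)
  d[entry$offset + 1L] <- entry$abundance
  d
}

monoisotopic_mass <- function(formula, iso) {
  m <- 0
  for (el in names(formula)) {
    entry <- iso[[el]]
    if (is.null(entry)) {
      mf_stop(sprintf("unknown element '%s' in fragment formula", el),
              "midflux_config_error")
    }
    m <- m + formula[[el]] * entry$mass[which.min(entry$offset)]
  }
  m
}
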