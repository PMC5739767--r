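# Independent oracles used across tests.

# Brute-force natural-abundance column: enumerate the isotope choice of every
# individual atom (j tracer carbons excluded), accumulate probability by total
# mass shift. Exponential in atom count -- keep formulas tiny.
oracle_correction_column <- function(formula, iso, j, channels) {
  atoms <- list()
  for (el in names(formula)) {
    cnt <- formula[[el]] - if (el == "C") j else 0L
    if (cnt < 0) stop("more tracer carbons than formula carbons")
    for (i in seq_len(cnt)) {
      atoms[[length(atoms) + 1L]] <- list(offsets = iso[[el]]$offset,
                                          probs = iso[[el]]$abundance)
    }
  }
  col <- numeric(channels)
  if (!length(atoms)) {
    if (j < channels) col[j + 1L] <- 1
    return(col)
  }
  grid <- do.call(expand.grid, lapply(atoms, function(a) seq_along(a$offsets)))
  for (r in seq_len(nrow(grid))) {
    shift <- j
    prob <- 1
    for (i in seq_along(atoms)) {
      idx <- grid[r, i]
      shift <- shift + atoms[[i]]$offsets[idx]
      prob <- prob * atoms[[i]]$probs[idx]
    }
    if (shift < channels) col[shift + 1L] <- col[shift + 1L] + prob
  }
  col
}

# Hand log-rank: hypergeometric expected events and variance summed over
# distinct event times, independent of survival::survdiff.
oracle_logrank_chisq <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  in_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  o_minus_e <- 0
  vsum <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & in_a)
    d <- sum(event == 1 & time == t)
    d_a <- sum(event == 1 & time == t & in_a)
    e_a <- d * n_a / n
    v <- if (n > 1) d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1) else 0
    o_minus_e <- o_minus_e + (d_a - e_a)
    vsum <- vsum + v
  }
  (o_minus_e)^2 / vsum
}

# monoisotopic-only isotope table (no natural abundance at all)
mono_isotopes <- function(elements = c("C", "H", "O")) {
  masses <- c(C = 12, H = 1.007825, N = 14.003074, O = 15.994915)
  tab <- lapply(elements, function(el) {
    data.frame(offset = 0L, mass = masses[[el]], abundance = 1)
  })
  names(tab) <- elements
  structure(tab, class = "isotope_table")
}

# single-element carbon table with adjustable 13C abundance
carbon_isotopes <- function(a13 = 0.011) {
  structure(list(C = data.frame(offset = c(0L, 1L), mass = c(12, 13.003355),
                                abundance = c(1 - a13, a13))),
            class = "isotope_table")
}

# a small fragment whose atoms are few enough for exhaustive enumeration
tiny_fragment <- function(iso) {
  fragment_spec("tinyol", c(C = 3, H = 2, O = 1), n_carbons = 3,
                mz_low = 54, mz_high = 57, isotopes = iso)
}
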