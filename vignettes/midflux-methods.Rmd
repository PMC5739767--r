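---
title: "Models and methods behind midflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind midflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midflux)
```

midflux analyzes [1,2-¹³C₂]-glucose tracing experiments in cultured cells.
This vignette explains each model the package implements, the assumptions it
rests on, the defaults and why they were chosen, the numerical choices, and
what the synthetic-data generator does and does not establish about real
data.

## Natural-abundance correction

A measured MID mixes tracer labeling with naturally occurring heavy isotopes
(¹³C, ²H, ¹⁵N, ¹⁷/¹⁸O, ²⁹/³⁰Si) of the whole derivatized fragment. For a
fragment with elemental formula F and a SIM window of $c$ channels we build a
$c \times c$ matrix $M$ whose column $j$ is the mass-shift distribution of a
molecule already carrying $j$ tracer ¹³C atoms: those $j$ backbone carbons
are excluded from the natural-¹³C binomial, every remaining atom contributes
its natural isotope distribution (computed by polynomial convolution), and
the column is shifted up by $j$.

Two deliberate choices:

- **Columns are truncated to the SIM window and not renormalized.** Mass
  that shifts past the top recorded m/z is signal the detector genuinely
  never sees; renormalizing would smear that loss back into the window and
  bias the low channels. The non-negative least-squares (NNLS) inversion
  absorbs the loss instead, keeping the forward model linear.
- **Correction solves $M x = \text{raw}$ by NNLS** (`pracma::lsqnonneg`)
  rather than a plain matrix inverse, then clips and renormalizes onto the
  simplex. NNLS keeps corrected MIDs non-negative without the oscillating
  artifacts a direct solve produces at low signal. A condition-number cap
  (default $10^8$) aborts on degenerate matrices rather than returning
  noise.

Fragments whose window covers the full backbone (glucose, lactate, alanine,
ribose) get a post-correction check: corrected signal beyond the backbone
carbon count above 0.005 raises a warning, since no tracer arrangement can
put mass there. The fatty-acid windows (10 channels for palmitate, 11 for
stearate) are shorter than their 16/18-carbon backbones, so there the matrix
is simply built at window size and tracer columns are capped at the window.

The fragment registry ships editable defaults whose elemental formulas
follow the derivatization chemistry (aldononitrile acetates for glucose and
ribose, heptafluorobutyryl propylamide for lactate, N-TFA butyl ester for
alanine, methyl esters for the fatty acids); each formula is validated only
by requiring its monoisotopic mass to fall within `[mz_low - 1, mz_high]`
(the 1 Da slack absorbs the proton transfer of chemical ionization). If your
instrument records a different adduct, edit the YAML registry — the
validation will tell you if the formula and window disagree. Tracer isotopic
purity is assumed 1.0 by default and is configurable; at purities ≥ 0.99 the
effect on the estimators is well below measurement noise.

## CORE rates

Consumption/release rates are
$r = \Delta C \cdot V / \left( \bar N \cdot \Delta t \right)$ in
nmol·(10⁶ cells)⁻¹·h⁻¹, where $\bar N$ is the log-mean of the two cell
counts, $(N_1 - N_0)/\ln(N_1/N_0)$ — the exact time-average under
exponential growth, falling back to $N$ when the counts are equal. The sign
convention is consumption-positive for glucose and glutamine,
release-positive for lactate and glutamate; an apparently negative
consumption is flagged, never silently reported. Only two medium samples
(start and end of the labeling window) are assumed, so any departure from
exponential growth between the counts biases $\bar N$; with a 24 h window
and doubling times of 30–40 h the bias is negligible.

## Glycolytic flux and glucose fate

Aldolase splits [1,2-¹³C₂]-glucose into one labeled and one unlabeled
triose, so a fully glucose-derived lactate pool shows $m2 = 0.5\,T$.
The estimator $f = m2_{\text{lac}} / (0.5\,T)$ uses **m2 only**: m1 lactate
(generated when label cycles through the PPP before glycolysis) is excluded
from the "via glycolysis" flux and reported separately as a diagnostic.
The glycolytic flux is $f$ times the lactate release rate, and the share of
consumed glucose accounted for by lactate divides by twice the glucose
consumption rate (two lactate per glucose, molecule stoichiometry; a
carbon-mole convention would give the same number for this pair since both
trioses carry three carbons). $f > 1.05$ warns of a model violation.

## PPP split from ribose

The oxidative branch decarboxylates C1 — the labeled ribose it makes from
[1,2-¹³C₂]-glucose is m1 — while non-oxidative rearrangements keep both
labels, giving m2. The m1/m2 ratio is reported as the ox/nonox activity
index. When m2 falls below a floor (default $10^{-4}$, one part in ten
thousand, below realistic MID precision) the ratio is returned as undefined
(`NA` with a flag) rather than a numerically explosive value.

## Binomial MIDA of fatty acids

Palmitate and stearate are treated as polymers of 8 and 9 acetyl units
drawn independently from a lipogenic acetyl-CoA pool with m2 fraction $p$
(acetyl units from [1,2-¹³C₂]-glucose via pyruvate dehydrogenase are m0 or
m2; no m1 acetyl — a design assumption of the tracer). With fractional new
synthesis $g$,
$$ m_{2k} = g \binom{n}{k} p^k (1-p)^{n-k} \; (k \ge 1), \qquad
   m_0 = (1-g) + g(1-p)^n . $$
The map $(p, g) \mapsto$ even-channel MID is injective for $p \in (0,1)$,
$g \in (0,1]$, so both parameters are identifiable from one spectrum.

Numerics: $p$ is initialized from $m4/m2 = \frac{n-1}{2}\frac{p}{1-p}$,
which is invariant to window truncation and renormalization; $g$ follows in
closed form from $m2$ with a window-sum correction. This closed-form pair is
kept as a candidate alongside three L-BFGS-B refinements (bounds
$[10^{-6}, 1-10^{-6}]$, multi-start to guard the shallow valley at small
$g$), and the lowest even-channel SSE wins — on noiseless data the
closed-form candidate is exact, so ratio-based and refined $p$ coincide.
Because the SIM windows truncate the binomial support, the model prediction
is renormalized over the recorded window before comparison. An m2 below the
noise floor (default $10^{-3}$) aborts with an "insufficient labeling"
error; estimates at a box bound are flagged. Stearate is fit as 9
independent units; elongation of pre-existing palmitate into stearate
(old-core/new-unit hybrids) is ignored and surfaces in `fit_residual`.

The percentage of lipogenic acetyl-CoA from glucose is $p / (0.5\,T) \times
100$: one labeled acetyl per labeled glucose through glycolysis sets the
theoretical maximum $p_{\max} = 0.5\,T$.

## Survival stage

Kaplan–Meier curves and the two-group log-rank test are delegated to the
`survival` package (product-limit with simultaneous-tie convention;
hypergeometric expected events, $\chi^2_1$). The best-cutoff scan
dichotomizes at every integer percentile from the 25th through the 75th
inclusive (endpoints included), with the high group defined strictly above
the cutoff so ties go low, and keeps the minimal log-rank p. "Best
performing" is interpreted as minimal p; maximizing the hazard ratio is a
noted alternative that is not implemented. The selected p is optimized over
~51 correlated tests and is **anti-conservative**; it is always returned
with `p_selection_biased = TRUE`, no multiple-testing correction is applied
by default, and an optional permutation adjustment (expression labels
permuted, min-p re-selected per permutation) is available off by default.
Pearson correlation with the $t$-transform p-value links two genes'
expression.

## The synthetic-data generator

The simulator does deterministic isotopologue bookkeeping at metabolic and
isotopic steady state over the labeling window — no isotopomer ODEs — which
matches a single-endpoint 24 h design and keeps every oracle analytic:

- pyruvate (hence lactate and alanine) is m2 with probability
  $0.5\,T\,f$, where $f$ is the glucose-derived fraction of the pool;
- ribose is m1 with probability $(1-\rho_{\text{nonox}})T$ and m2 with
  probability $\rho_{\text{nonox}} T$;
- lipogenic acetyl-CoA is m2 with probability $p = 0.5\,T(1-d)$, $d$ the
  dilution by unlabeled carbon sources, and fatty-acid MIDs follow the
  binomial model exactly;
- observed MIDs are the true MIDs convolved with the natural-abundance
  matrix plus Gaussian channel noise (σ = 0.002 by default, typical of
  SIM peak-area reproducibility);
- media concentrations integrate consumption against exponential growth
  exactly, with 2% relative measurement noise;
- the survival cohort draws exponential event times, multiplies the hazard
  above a chosen expression percentile, censors a fraction of subjects
  uniformly on [0, max follow-up] (non-informative), and draws the second
  gene with fixed correlation to the first.

Default conditions are one 24 h labeling window with 50% [1,2-¹³C₂]-glucose
and three replicate samples; 5×10⁵ starting cells in 2 mL with a 36 h
doubling time; glucose consumption 200 and lactate release 280
nmol·(10⁶ cells)⁻¹·h⁻¹ (a glycolytic tumor-line phenotype that keeps lactate
under the 2-per-glucose carbon ceiling), glutamine 30 and glutamate 15;
$f = 0.8$, $\rho_{\text{nonox}} = 0.8$ (most ribose non-oxidative in rapidly
proliferating cells), $d = 0.2$, $g = 0.6$; survival block of 300 patients,
baseline hazard 0.02 month⁻¹, hazard ratio 2 at the median, 30% censoring,
120-month follow-up, inter-gene correlation 0.6. Start concentrations (10 mM
glucose, 2 mM glutamine) match common culture media. Identical seed and
configuration give byte-identical output files.

What passing recovery tests does **not** show about real data: the simulator
has no PPP-derived m1 lactate by default (a config switch injects it to
stress the estimator), no compartmentation beyond the single dilution
parameter $d$, no isotopic non-steady state, no chromatographic peak-shape
or detector-saturation artifacts, and survival times are exactly
exponential. Estimator behavior under those violations must be judged from
the diagnostics (m1 lactate, `fit_residual`, warnings), not from the test
suite.

## Problem sizes and runtime

The validation suite runs at the study's own scales: 1,000 random MIDs for
the correction round trip, exhaustive isotope-placement enumeration on
three-atom-scale formulas, 200 replicates per (p, g) grid point for MIDA
recovery, 100 replicates per glycolytic-fraction setting, five-seed
monotonicity sweeps for the PPP ratio, 500 replicates for log-rank
calibration and power at n = 150/arm, 100 cohorts for the KM closed-form
check, and 200 + 100 cohorts (n = 300) for best-cutoff recovery and null
behavior. The full suite completes in about a minute on one CPU.

## Known limitations

- Single-tracer design: only [1,2-¹³C₂]-glucose rules are implemented.
- No full ¹³C-MFA network fitting (EMU/cumomer systems) and no TCA-cycle
  flux resolution; the estimators are deliberately local and analytic.
- Fragment formulas are chemistry-derived defaults validated only by the
  m/z-window mass check, not by measured spectra.
- The best-cutoff p-value is selection-biased by construction; use the
  permutation option when an honest error rate is needed.
- Group comparison across conditions (ANOVA-style testing of replicate
  fluxes) is out of scope; the pipeline exports per-sample values and
  means ± SD for downstream testing.
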