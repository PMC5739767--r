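# midflux

Analysis of [1,2-¹³C₂]-glucose stable-isotope tracing experiments in
cultured cells, from GC-MS mass isotopologue distributions (MIDs) to
pathway-level flux readouts, plus the survival/co-expression analysis used
to relate metabolic gene expression to patient outcome.

## Who it is for

Labs running ¹³C-assisted metabolomics on cell cultures: cells grown in
medium in which a known molar fraction *T* of glucose is [1,2-¹³C₂]-glucose,
with selected-ion-monitoring GC-MS measurement of glucose, lactate, alanine,
ribose (from RNA), palmitate and stearate, and spectrophotometric
consumption/release (CORE) assays of the medium. The package turns those raw
measurements into:

- **Natural-abundance-corrected MIDs.** The correction matrix for each
  derivatized fragment is built from its elemental formula; column *j* is
  the natural mass-shift distribution of a molecule already carrying *j*
  tracer ¹³C atoms, truncated to the recorded SIM window and *not*
  renormalized (window loss is real signal loss). Raw vectors are inverted
  by non-negative least squares.
- **CORE rates** in nmol·(10⁶ cells)⁻¹·h⁻¹, normalized to the cell-time
  integral under exponential growth (log-mean of the two cell counts).
- **Glycolytic flux.** Each labeled glucose passing glycolysis yields one m2
  and one m0 lactate, so the glucose-derived fraction of released lactate is
  *f* = m2 / (0.5 *T*); the glycolytic flux is *f* × lactate release, and
  the share of consumed glucose going to lactate uses the 2-lactate-per-
  glucose stoichiometry.
- **Oxidative vs non-oxidative PPP.** Ribose made through the oxidative
  branch loses the labeled C1 as CO₂ (m1); the non-oxidative branch keeps
  both labels (m2). The m1/m2 ratio indexes ox/nonox activity.
- **Binomial MIDA of fatty acids.** Palmitate (8 acetyl units) and stearate
  (9) are modeled as polymers of acetyl-CoA units that are m2 with
  probability *p*: m₂ₖ = *g*·C(n,k)·*p*ᵏ(1−*p*)ⁿ⁻ᵏ with fractional new
  synthesis *g*. *p* is initialized from the closed-form m4/m2 ratio and
  refined by bounded least squares; *p* / (0.5 *T*) × 100 is the percentage
  of lipogenic acetyl-CoA derived from glucose.
- **Best-cutoff Kaplan–Meier analysis.** For each integer expression
  percentile between the quartiles, the cohort is dichotomized and log-rank
  tested; the minimal-p cutoff is reported with an explicit selection-bias
  flag (and an optional permutation-adjusted p). Pearson correlation relates
  two genes' expression.
- **A label-propagation simulator** that forward-generates every input with
  known ground truth, so all estimators are validated by parameter recovery.

## Worked example

Simulate a complete experiment at the default conditions (T = 0.5, 24 h,
three replicates, 300-patient survival cohort) and run the pipeline:

```r
library(midflux)

cfg   <- sim_config(seed = 1)
paths <- simulate_bundle(cfg, "sim")
s <- run_pipeline(pipeline_config(
  mid_csv      = paths[["mids"]],
  media_csv    = paths[["media"]],
  survival_csv = paths[["survival"]],
  outdir       = "out", tracer_fraction = 0.5))

s$f_lac_from_glc        # 0.7899  fraction of lactate from glucose (truth 0.8)
s$glycolytic_flux       # 219.4   nmol/1e6 cells/h (truth 224)
s$ox_nonox_ratio        # 0.2505  ribose m1/m2 (truth 0.25)
s$pct_glucose_to_acetyl # 79.76   % lipogenic acetyl-CoA from glucose (truth 80)
s$expression_correlation$r  # 0.627 co-expression r (truth 0.6)
```

Correcting a single MID by hand:

```r
reg  <- load_fragments()                      # six SIM fragments
M    <- build_correction_matrix(reg$ribose)   # 6 x 6, from C11H14NO6
raw  <- mid(convolve_mid(c(0.55, 0.2, 0.25, 0, 0, 0), M), reg$ribose)
corr <- correct_mid(raw, M)
corr$fractions        # 0.55 0.20 0.25 0 0 0  (round trip)
ppp_split(corr)$ox_nonox_ratio   # 0.8
```

Outputs land in `outdir` as tidy CSVs (`corrected_mids.csv`,
`core_rates.csv`, `fluxes.csv`, `mida.csv`, `survival_scan.csv`,
`km_<gene>.csv`), a `summary.json`, and a `run_log.txt`; every file is
stamped with a hash of the analytical configuration. A thin CLI wrapper
lives at `inst/scripts/midflux-cli.R` (`simulate` / `run` subcommands).

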