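# scfluor

Single-cell fluorescence analysis for bistable gene-expression systems:
subpopulation sizing from cumulative intensity distributions, dual-reporter
intrinsic/extrinsic noise decomposition, and a generative
threshold-activation simulator.

## What it is for

In clonal bacterial populations, mobile genetic elements such as
integrative and conjugative elements (ICEs) activate in only a small
minority of cells — a bistable decision. In the *Pseudomonas knackmussii*
B13 system this fraction is ~3% in stationary phase, gated by the per-cell
level of the sigma factor RpoS: only cells in the upper tail of the RpoS
distribution are permissive, and doubling the *rpoS* gene dose (doubling
the mean level) expands the ON subpopulation to ~18%.

`scfluor` is for microbiologists quantifying such systems from single-cell
epifluorescence data. It implements:

- **Image quantification** — Otsu-based segmentation (log-domain by
  default) and background-subtracted average gray values (AGVs) per cell
  object (`segmentObjects()`, `measureAGV()`).
- **ON-subpopulation estimation** — automated breakpoint detection on the
  cumulative ranked AGV curve by exhaustive two-segment least squares
  (`cumulativeCurve()`, `findBreakpoint()`): the ON fraction is
  `100 − breakpoint percentile`.
- **Noise decomposition** — the two-reporter moment estimators
  `η²_int = ⟨(g−c)²⟩ / 2⟨g⟩⟨c⟩`,
  `η²_ext = (⟨gc⟩ − ⟨g⟩⟨c⟩) / ⟨g⟩⟨c⟩`,
  `η²_tot = η²_int + η²_ext` (exact identity), with seeded bootstrap
  uncertainty (`noiseDecomposition()`, `bootstrapNoise()`), after
  per-channel normalization and breakpoint gating
  (`scaleAndNormalize()`, `selectActive()`).
- **Association statistics** — quadrant-conditioned activation
  (`quadrantActivation()`), reporter correlation, conjugative transfer
  frequency, and ANOVA/Tukey group comparison with compact letter display
  (`compareGroups()`).
- **Synthetic data with known truth** — `simulatePopulation()` (RpoS
  threshold gate + Bernoulli "factor X" + lognormal extrinsic/intrinsic
  reporter noise + camera background and saturation),
  `simulateDualReporter()` (closed-form noise truths),
  `renderImages()` (synthetic micrographs with ground-truth masks),
  `simulateTransferAssay()`.

Everything is reproducible: every stochastic function takes a seed, and
`runPipeline()` produces byte-identical outputs for identical
config + seed.

## Worked example

```r
library(scfluor)

## a wild-type population: 20,000 cells, RpoS threshold mu + 1.881 sigma
cells <- simulatePopulation(simulationParams("wildtype",
    n_cells = 20000, seed = 11))

findBreakpoint(cumulativeCurve(agv(cells, "egfp")))
#> BreakpointResult
#>   breakpoint: percentile 97.135, AGV 35.997
#>   ON subpopulation: 2.865% of 20000 cells, mean AGV 158.896
```

The breakpoint estimator recovers the ~3% ON subpopulation (the Gaussian
upper-tail probability Φ(−1.881) = 3.0% built into the preset) and its
mean expression (~159 gray values) directly from the cumulative curve.

```r
## dual-reporter noise on the gated ON cells
nz <- scaleAndNormalize(agv(cells, "egfp"), agv(cells, "echerry"), 10, 10)
bp_g <- findBreakpoint(cumulativeCurve(nz$g))
bp_c <- findBreakpoint(cumulativeCurve(nz$c))
gated <- selectActive(nz$g, nz$c, bp_g, bp_c,
    saturated = cells$saturated_egfp | cells$saturated_echerry)
bootstrapNoise(gated$g, gated$c, n_boot = 1000, seed = 12)
#> NoiseEstimate (n = 485 cells)
#>   eta_int 0.2572  eta_ext 0.1900  eta_tot 0.3198
#>   bootstrap (1000 resamples, seed 12):
#>     eta_int: 0.2569 +/- 0.0092
#>     eta_ext: 0.1897 +/- 0.0129
#>     eta_tot: 0.3197 +/- 0.0070
```

Within the ON subpopulation, channel-specific (intrinsic) and shared
(extrinsic) variability are of comparable size here, and
`eta_tot² = eta_int² + eta_ext²` holds exactly.

```r
## is activation conditioned on the RpoS level?
quadrantActivation(cells$R, agv(cells, "egfp"))
#> QuadrantResult (reporter threshold 35.997 )
#>   Q1st: 3193 cells, activation fraction 0.0003132
#>   Q2nd: 6771 cells, activation fraction 0
#>   Q3rd: 6828 cells, activation fraction 0
#>   Q4th: 3208 cells, activation fraction 0.1786
```

Only the top RpoS quadrant (above mean + SD) shows appreciable activation
— the signature of threshold gating.

See `vignette source in vignettes/bistable-subpopulation-noise.Rmd` for
the model, parameter defaults, numerical choices and limitations.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package: the ON-subpopulation
percentages estimated by the breakpoint procedure on 100,000-cell
simulations gated at RpoS thresholds μ + 1.881σ and μ + 0.915σ, and the
intrinsic/extrinsic noise estimates on a 50,000-cell dual-reporter sample
with extrinsic lognormal shape 0.5164 and intrinsic shape 0.4542. Results
are written as JSON (`t4`, `t5`, `t6`, `t7`), each with the value and the
problem size used.
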