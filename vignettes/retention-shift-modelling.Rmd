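---
title: "Modelling retention-time shifts under a factorial design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling retention-time shifts under a factorial design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtshift)
```

## Scope and model

`rtshift` analyses how the retention times of many compounds in a complex
mixture shift when chromatographic conditions change. The reference
layout is a five-level full factorial in mobile-phase pH (coded −2..+2 ↦
3.25..4.25) and column temperature (coded −2..+2 ↦ 35..45 °C): 25
factorial runs plus five replicated center points. The response is the
runs × compounds matrix `X` of retention times in minutes.

The working model is the quadratic response surface on the coded scale,

```
X = D B + S L + E
```

where `D` is the design matrix with columns `1, p, t, p², t², p·t`; `B`
holds per-compound coefficients (minutes per coded unit); `S L` is a
low-rank contribution of *latent uncontrolled factors* (run-level scores
`S` times compound-level loadings `L`) standing in for everything the
design does not control — ambient drift, mobile-phase composition error,
column ageing; and `E` is i.i.d. Gaussian measurement noise. The designed
and latent parts are both low-rank, which is precisely why per-compound
shifts are mutually predictable and why pattern-based alignment works.

Five estimation routes are implemented and compared:

1. **MLR** (`fit_mlr`): `B̂ = (DᵀD)⁻¹DᵀX`, computed by SVD pseudo-inverse
   with singular values below `max(dim) × eps × σ₁` treated as zero. The
   normal-equations form is algebraically identical but numerically
   fragile when quadratic columns are near-collinear, hence the SVD.
2. **The PCA route** (`fit_pca`, `fit_conversion`,
   `coefficients_from_loadings`, wrapped by `pca_coefficients`): PCA
   `X = TPᵀ + E`, conversion factor `Ĉ = (TᵀT)⁻¹TᵀD`, coefficients
   `B̂ = (ĈᵀĈ)⁻¹ĈᵀPᵀ`. With components spanning the design's column
   space and no latent contamination this equals MLR exactly — the
   package's central algebraic identity, tested to 1e−8 relative.
3. **ASCA** (`fit_asca`, `asca_coefficients`): grand-center `X`,
   partition into per-factor effect matrices (level means broadcast to
   member runs) plus residual, PCA each block, then run the same
   conversion machinery on the concatenated block scores.
4. **Per-compound PCR/PLS** (`fit_pcr`, `fit_pls`,
   `exclude_overlapping`): each compound regressed on the principal
   components (or PLS components) of the *other* compounds' retention
   times.
5. **Design-level prediction** (`predict_design_levels`): each design
   term regressed on PCA scores of `X`, RMSEC/RMSECV versus component
   count.

## Centering and the intercept

PCA is run on column-mean-centered data. Uncentered PCA would spend its
first component on the mean retention times themselves (tens of minutes,
versus shifts of hundredths), burying the shift structure. Centering is
linear, so the centered responses obey `Xc = Dc B₋₀` with the *same*
non-intercept coefficients, where `Dc` is the column-centered design
without the intercept (`design_columns_centered`). The conversion
regression therefore uses `Dc`, and the intercept row is restored
afterwards from the column means. This choice is made prominently
because nothing in the algebra forces it, yet every cross-route
comparison depends on it.

## Sign and ordering conventions

SVD leaves component signs arbitrary; `fit_pca` fixes each component so
its largest-magnitude loading entry is positive, making scores,
conversion factors and downstream tables reproducible across BLAS/LAPACK
builds. Components are ordered by decreasing variance. Run order in
`build_design` is lexicographic with the first declared factor outermost
and center replicates appended last — the original study does not state a
run order, and a documented deterministic order keeps outputs
byte-reproducible. Coefficients are fitted on the coded scale (standard
DoE practice; real-unit fitting is available by building the design from
real values, but coded columns keep the terms comparable across factors).

## ASCA details

On a balanced full factorial the per-factor effect matrices are mutually
orthogonal and sum (with the residual) to the grand-centered data
exactly; `fit_asca` verifies balance and refuses unbalanced assignments
unless forced, because type-I style level means silently confound
effects otherwise. The five extra center replicates unbalance the
design, so the pipeline runs ASCA on the 25 factorial rows only. Because
five levels are summarized nonparametrically by level means, quadratic
within-factor structure is captured without polynomial fitting.

For coefficient recovery, `asca_coefficients` concatenates the scores of
the per-effect PCAs *and* of the residual-block PCA: on a balanced
design the interaction term averages to zero within every level of
either factor, so it lives entirely in the ASCA residual, and without
the residual block it would be unrecoverable. Each effect block is
capped at two components by default (the usual two-component ASCA effect
representation). The cap matters: trailing effect components carry
level-mean noise, their conversion-factor rows are near zero, and the
pseudo-inverse in the coefficient step amplifies whatever those
components' unit-norm loadings contain. With the cap, ASCA-route
coefficients for well-expressed terms correlate with MLR above 0.99
under the default noise; without it they degrade visibly. The cap, the
residual inclusion, and the residual component budget are all exposed as
arguments rather than hard-coded, since the reference formulation of
ASCA leaves these choices open.

## PCR, PLS and overlap exclusion

A compound's calibration block excludes every compound whose retention
time comes within `rt_window` (default 0.2 min) of the target's *in any
run*. The window width is a judgement call — the original account only
states that overlapping peaks were removed — and 0.2 min is roughly twice
the co-elution tolerance used in peak tracking; it is configurable. The
exclusion is deliberately per-run and symmetric.

Cross-validation is leave-one-run-out throughout: with 30 runs it is
cheap, and it respects the run as the natural exchangeable unit.
Relative residual variance is residual sum of squares over *centered*
sum of squares (an `center = FALSE` option exists), so 0 means perfect
prediction and 1 means no better than the compound's mean.

PLS1 is implemented by NIPALS with X-deflation per component. When
comparing PLS with PCR, each method is given its own CV-selected
component count: a PLS component is chosen to covary with the response
and carries more fitting capacity than a variance-ranked principal
component, so comparing both at a fixed shared count compares them at
unmatched complexity (PLS at six components visibly overfits these
data). At their respective CV optima the two methods' cross-validated
residual variances agree within 20% for ≥ 90% of compounds.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions the analysis is meant to face:

- **98 compounds**, mean elution times uniform over 5–38 min (sorted, as
  a chromatogram would present them).
- **Temperature linear**: negative for all but 10 compounds (drawn
  −|N(0.10, 0.04)|; the positive minority +|N(0.03, 0.01)|) — higher
  temperature elutes most peptides earlier.
- **pH linear**: N(0, 0.15), both signs; **pH quadratic**: N(0, 0.05),
  both signs and non-negligible — the pH response is curved.
- **Temperature quadratic** N(0, 0.001) and **interaction**
  |N(0, 0.001)| (positive, tiny): these two terms sit below the
  replicate repeatability error. The scale 0.001 min is chosen from a
  detectability argument: with 98 compounds, a term of per-compound
  scale σ_b contributes a spiked covariance direction of strength
  ≈ 98·σ_b²·var(term column); at 0.001 this sits below both the
  Marchenko–Pastur noise edge of a 30 × 98 matrix at 0.02 min noise and
  the latent factor's strength, so the term is genuinely unrecoverable
  from the data — reproducing, by construction, the observed failure of
  auto- and cross-prediction for the small terms. Larger values (e.g.
  0.01) would still be "insignificant" per compound yet recoverable by
  pooling 98 compounds, which is not the behaviour the study reports.
- **One latent uncontrolled factor**: loadings N(0, 0.03 min), scores
  N(0, 1) per run. At this scale the latent contribution to a typical
  compound is comparable to measurement noise, enough to open a visible
  gap between PCR and MLR auto-prediction without dominating the design
  effects.
- **Noise**: i.i.d. N(0, 0.02 min) per cell — about one second, a
  realistic post-alignment repeatability for a well-behaved LC-MS
  gradient; the simplest model consistent with pure-error CIs.
- **Peak lists**: each compound (charge 1–2) emits its monoisotopic peak
  plus two isotope peaks at 1.00335/z spacings (relative intensities
  0.6, 0.25 — below 1, as for peptides under ≈ 1800 Da) and, for 30% of
  singly charged compounds, one adduct (Na⁺/NH₄⁺/K⁺ deltas). Compound
  m/z values are drawn on a loose lattice with a rejection step that
  keeps every cross-compound species pair at least 0.02 Th away from any
  isotope/adduct mass relation: the generator emulates *well-resolved*
  species. Real digests contain coincidental near-relations; on such
  data the filter's exactness necessarily degrades to a tolerance
  trade-off, which is why the tolerances are arguments, not constants.

What the generator does **not** emulate: peak shapes and integration
error, missing peaks, intensity-dependent m/z error, retention-time
drift within a run sequence (latent scores are i.i.d., not
autocorrelated), and real co-elution structure. Passing tests therefore
demonstrate correctness of the *algorithms* under the stated model, not
performance on raw instrument data.

## Confidence intervals

The replicated center points estimate pure error. `replicate_ci` puts a
t-interval directly on retention times, `t₀.₉₇₅,n−1·s/√n` per compound —
the error-bar convention for coefficient plots. `coefficient_ci`
propagates the same pure-error s through the least-squares geometry,
`t₀.₉₇₅,n−1·s·√[(DᵀD)⁻¹]ⱼⱼ`, giving an interval per coefficient. The
latter is the statistically calibrated object: because the replicate
standard deviation is independent of the fitted coefficients and the
per-run disturbances (noise plus i.i.d. latent contribution) are
normal, the pivot is exactly t-distributed, and 200-repeat Monte-Carlo
runs show 94–96% empirical coverage at the 95% level with per-term
biases below 0.01 × the noise SD.

## Numerical choices and degenerate inputs

- Pseudo-inverses by SVD with cutoff `max(dim) × eps × σ₁` everywhere.
- Effect-matrix ranks are judged against 1e−10 × the grand-centered data
  norm: partitioning O(10 min) values leaves O(1e−13) roundoff singular
  values that must not count as structure.
- `fit_conversion` refuses zero-variance score columns; the coefficient
  step refuses conversion factors with fewer effective components than
  design terms (the system is underdetermined).
- Rank-deficient designs are refused with the collinear columns named.
- Zero-variance compound columns make relative residual variance
  undefined and error out rather than returning NaN.
- Isotope/adduct chains (A isotope-of B isotope-of C) are resolved by a
  greedy intensity-descending pass in which only peaks already accepted
  as monoisotopic can act as parents; this is deterministic and
  idempotent.

## Problem sizes in the test suite

The shipped tests run the full study geometry (30 × 98) for the
end-to-end properties, 200 Monte-Carlo repeats for coverage/bias, 50
seeded repeats for the PCR-versus-MLR comparison, and smaller matrices
(10–40 compounds) for unit-level oracles; the whole suite completes in
well under a minute on one core. These sizes were chosen to make the
stochastic assertions stable across seeds (binomial/Monte-Carlo margins
of a few percent) while staying trivially cheap.

## Known limitations

- The latent-factor mechanism is an assumption; the original study
  attributes the PCR-over-MLR advantage to uncontrolled factors without
  characterizing their distribution.
- ASCA significance testing (permutation tests) is out of scope, as are
  fractional/D-optimal designs, peak-shape simulation, and raw-data
  (mzML) ingestion; the package starts from tracked peak lists or
  retention matrices.
- The exact ASCA variant used for the study's figures is not fully
  specified in the original account; this implementation documents its
  own variant (level-mean partitioning, per-effect PCA, residual block
  included for conversion, two components per effect) and exposes every
  one of those choices as an argument.
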