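---
title: "Wavelength selection and calibration transfer for NIR spectra: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelength selection and calibration transfer for NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vipboruta)
```

This vignette is the package's own account of the statistical machinery:
the models it fits, the assumptions they lean on, the tunable parameters
and their defaults, what the synthetic data generator does and does not
emulate, and the numerical decisions made where more than one
defensible choice existed.

## The calibration problem

A near-infrared absorbance spectrum of an aqueous culture medium is a
vector of a few hundred to a few thousand wavenumber channels
(4000–12000 cm⁻¹) dominated by two broad water bands near 7000 and
5100 cm⁻¹. The analytes of interest — glucose consumed and lactate
produced during a batch cultivation — absorb weakly (overtone and
combination bands of C–H and O–H groups), their bands overlap each
other and the other medium components, and no analyte peak is visible
in a raw spectrum. Calibration therefore runs through three stages:
derivative preprocessing to strip additive baselines, wavelength
selection to discard the channels that carry no analyte information,
and a latent-variable regression that tolerates the collinearity of the
survivors.

Two further facts shape the design. Culture samples are scarce (a
seven-day batch yields one spectrum per day), so the training set is
tiny and the strong mutual correlation of glucose, lactate and the
other metabolites — all driven by the same cultivation clock — invites
models that predict glucose from, say, the ammonia bands. Pseudo media
(lab blends of fresh medium, spent medium and glucose powder) are cheap
and abundant, and because glucose is spiked independently, its
correlation with the remaining components is broken there. The
transfer-learning design lets a model exploit the pseudo samples
without pretending they are culture samples.

## PLS, latent-variable selection and VIP

`fit_pls()` implements NIPALS for a univariate response. With a
centered (and by default variance-scaled) design `X` and response `y`,
each component takes the closed-form step `w = X'y/‖X'y‖`, `t = Xw`,
`p = X't/t't`, `q = y't/t't`, followed by deflation of `X` and `y`; no
inner iteration is needed for a single response. Weights are unit-norm
and score vectors mutually orthogonal — both are asserted by property
tests. Autoscaling is the default because the variable importance in
projection statistic is derived under it; `scaling = "center"` is
available. Zero-variance columns — which the transfer-learning design
*guarantees* (entire blocks of zeros) — are centered and given scale 1,
so autoscaling never divides by zero and the columns contribute
nothing.

The component count `a` is chosen by `optimize_lv()`: k-fold
cross-validation (default 5 folds, seeded shuffle) over the grid 1–20,
maximizing `r²_CV = 1 − PRESS/TSS`, with centering and scaling
re-estimated inside every training fold to avoid leakage. Ties break
toward the smallest `a` (parsimony). One model with the largest
candidate count is fitted per fold and all smaller counts are scored
from its leading components, which is exact for NIPALS and makes the
grid search cost one fit per fold. If deflation exhausts the response
before the requested count (rank-deficient designs), the fit truncates
and the remaining candidates inherit the last prediction.

`vip()` computes, for predictor *i*,

$$\mathrm{VIP}_i = \sqrt{\,n\;\frac{\sum_{j=1}^{a} SS_j\,(w_{ij}/\lVert w_j\rVert)^2}{\sum_{j=1}^{a} SS_j}}, \qquad SS_j = q_j^2\, t_j^\top t_j,$$

where `SS_j` is the response variance captured by component *j*. Under
the square-root convention `Σᵢ VIPᵢ² = n`, which is the normalization
the tests assert; scores above 1 mark above-average predictors. The
literature occasionally typesets the statistic without the root; the
`sqrt = FALSE` flag returns the squared variant, and because the square
is monotone the induced variable ordering — all that the selection
engine consumes — is identical.

## The shadow-feature selection engine

`run_boruta()` is importance-agnostic. Per iteration it (1) permutes
every active column independently (`make_shadow()`), producing shadow
features with the exact marginal distribution of their originals but no
association with the response; (2) calls the importance provider on
`[X | shadows]`; (3) sets the threshold at the `p`-percentile of the
shadow importances — the default `p = 100` takes the maximum, and
"exceeds" is strict (`>`), the literal reading of the hit rule; (4)
increments hits for originals above the threshold; and (5) re-judges
every feature still under test with an exact two-tailed binomial test
against hit probability ½. The p-value convention is the doubled
one-tailed exact tail, capped at 1; with α = 0.05 a feature that hits
every time is confirmed at trial 6 (2·0.5⁶ = 0.031), the earliest
possible decision, and a feature that never hits is rejected on the
same schedule. Decisions are final; rejected features leave the active
set, so the design matrix shrinks monotonically and later iterations
are cheap. Iteration stops when nothing is tentative or after
`max_iter` rounds (default 100, the convention of the reference Boruta
implementations, since the procedure itself does not prescribe one).

Two deliberate defaults differ from some Boruta implementations and are
exposed as configuration. No multiplicity correction is applied to the
per-feature tests (`correction = "none"`; Bonferroni is available),
matching the plain per-feature test description rather than the extra
layers some packages add. And features still tentative at termination
are *excluded* from the selection (`tentative_policy = "exclude"`),
since only confirmed variables have positive evidence; `"include"` is
available.

Providers: `rf_importance_provider()` returns impurity importance from
`randomForest` (clipped at zero, seeded per call, so repeated calls are
reproducible); `vip_importance_provider()` re-optimizes the
latent-variable count by cross-validation *inside every iteration* —
the count that suits the current active set, not the initial one — then
fits PLS on the combined matrix and returns VIP for originals and
shadows alike. A `reuse_lv` mode freezes the count after the first
iteration; it is an approximation for quick experiments and is not used
by the package defaults or the shipped analyses.

## Transfer learning as a design-matrix layout

`tl_training_design()` builds the three-block augmented matrix: rows
are all culture samples followed by all pseudo samples; columns are
three copies of the wavenumber axis. Block 1 holds both domains'
spectra, block 2 culture spectra (zero for pseudo rows), block 3 pseudo
spectra (zero for culture rows). A linear model on this design is
algebraically a sum of a shared predictor and two domain corrections.
Prediction for new culture samples uses `[X | X | 0]`
(`tl_prediction_design()`). Two consequences are worth stating:

- With no pseudo samples the design degenerates to `[X | X | 0]`, and
  NIPALS on duplicated blocks predicts *identically* to plain PLS at
  equal component count — a sharp correctness check the tests run on
  twenty random datasets (tolerance 1e-8).
- When selection is combined with transfer learning, Boruta runs on the
  full 3n-column design and prediction subsets the `[X | X | 0]` matrix
  to the surviving columns; `tl_map_selection()` maps any selected column back
  to (block, wavenumber) for reporting, and reports print cm⁻¹ ranges,
  never raw indices.

All index bookkeeping is 1-based, the R convention.

## The synthetic data generator

Real culture/pseudo NIR datasets of this kind are not publicly
available, so `simulate_culture()` / `simulate_pseudo()` generate data
with the statistical structure the method is designed for, via
Beer–Lambert mixing `A = C·E + baseline + noise`:

- **Component profiles** (`component_spectra()`): sums of Gaussian
  bands. Water: two broad bands (7000, 5150 cm⁻¹, amplitudes 0.55 and
  1.0 AU). Glucose: bands at 8710, 5807, 4762, 4393, 4295 and 4252
  cm⁻¹ — the saccharide C–H/O–H overtone and combination positions —
  with amplitudes of order 10⁻³ AU per g/L, three orders below water,
  so raw spectra show no analyte peaks. Lactate bands sit at 5830 and
  4355 cm⁻¹; true lactate band positions and all absolute amplitudes
  are not recoverable from public sources, so these are explicitly
  synthetic choices placed in the combination regions where lactate
  selection is expected. Glutamine, ammonia and a serum-protein
  background overlap the analyte regions.
- **Culture trajectories**: 5 batches × 9 daily samples. Initial
  glucose is uniform on 5–7 g/L and decays exponentially with a
  per-batch rate (0.25–0.35/day); lactate rises proportionally to the
  consumed glucose (per-batch yield 0.40–0.55 g/g); glutamine falls,
  ammonia and the protein drift follow the same depletion clock with
  per-batch random slopes. This produces the strong within-domain
  correlation structure (glucose–lactate correlation below −0.8) and
  batch-to-batch variation in the confounding, which is exactly what
  punishes a culture-only model on held-out batches.
- **Pseudo media**: 102 samples, each a random convex blend of a fresh
  and an end-of-culture composition (keeping lactate and interferents
  mutually correlated) with glucose replaced by an independent uniform
  draw on 0.87–8.0 g/L — the spiking mechanism that decorrelates
  glucose; lactate is clipped to 0.12–3.1 g/L.
- **Noise model**: iid Gaussian absorbance noise (1e-4 AU, a clean
  FT-NIR level), a per-sample random quadratic baseline (3e-4 AU scale)
  that the first derivative largely removes — the motivation for the
  preprocessing stage — and ~0.2% pathlength/water variation.
- **Split**: 22 train / 23 test culture samples assigned by batch
  (whole early batches train; one batch is split by alternating days so
  both sides see a full trajectory; later batches test). The real
  study's split criterion is unknown; this is a labeled convention, not
  a reconstruction.

The default grid is 4000–12000 cm⁻¹ at 16 cm⁻¹ (501 points), a
deliberate scale-down that keeps a full 10-seed, 7-method study in the
test suite's budget of a few minutes; the step is configurable (4 cm⁻¹
reproduces instrument resolution) and all results in the package's
checks are stated at the 501-point scale. What the generator does *not*
emulate: temperature-driven water-band shifts, scattering and
multiplicative pathlength effects, instrument drift, serum lot
variation, and non-Gaussian band shapes. Passing tests therefore show
that the machinery recovers planted structure under realistic
correlation and signal-to-background conditions — not that it meets any
particular accuracy on real instruments.

`truth_mask()` returns the grid indices within ±2 band widths of an
analyte's bands (the recovery targets); `noise_mask()` returns indices
carrying no band signal at all. Its `guard` argument matters when
scoring a selector that runs on derivative spectra: a Savitzky–Golay
filter of window 21 spreads band information up to half a window
(10 grid points, 160 cm⁻¹) beyond the band support, so columns inside
that margin genuinely carry smeared analyte signal and are excluded
from the "flat noise" set when false selections are counted.

## Preprocessing

`savitzky_golay()` delegates to `signal::sgolayfilt`. Defaults: window
21 points, second-order polynomial, first derivative — second
derivatives are supported but amplify noise enough that they are not
the default. Two conventions are the package's own, stated because the
field is not uniform: the derivative is taken with respect to
wavenumber (units AU·cm), by passing the grid spacing to the filter, so
results are invariant to resampling; and edges are handled by
evaluating the terminal-window polynomial fit, which keeps the channel
count unchanged (no wavenumber bookkeeping offsets) and is exact for
polynomial spectra up to the filter order — verified to 1e-8 by
randomized tests. A uniform grid is required (relative tolerance 1e-6
on the spacing).

## Numerical choices and degenerate inputs

- Binomial p-values: doubled exact one-tailed tails, capped at 1 (not
  the minimum-likelihood two-tailed convention); the decision function
  is tested against exhaustive enumeration for all hit counts up to 20
  trials.
- Shadow threshold at `p = 100` uses the sample maximum
  (`quantile(..., type = 7)` for interior percentiles); hits require
  strictly greater importance.
- `optimize_lv` drops grid candidates infeasible for a fold
  (`a > min(m_fold − 1, n)`) rather than erroring, and errors only when
  no candidate survives.
- `fit_pls` refuses `a > min(m − 1, n)`, constant designs, and a
  constant response under autoscaling; a response exhausted mid-fit
  truncates with a warning rather than producing degenerate components.
- Seeds: every stochastic step (fold shuffles, shadow permutations,
  forest fits, the generator) takes an explicit seed and restores the
  caller's RNG state, so identical configurations reproduce bit-identical
  results and independent steps do not share streams.
- CSV round trips write doubles at 17 significant digits, so
  write-then-read is the identity on values, including negative
  derivative absorbances.

## Known limitations

Selection on 22 training samples cannot distinguish a genuinely
informative channel from one whose spurious sample correlation with the
response happens to persist across iterations — the shadow threshold is
redrawn each round, but the original's correlation is fixed. A few such
channels typically survive; on synthetic runs they are on the order of
0–3% of the signal-free channels. The transfer-learning design triples
the column count, which makes its selection runs the slowest component,
and with very small pseudo sets the domain-specific blocks are weakly
determined. The pooled and transferred variants assume the pseudo
domain shares the analyte's spectral signature with culture media —
true here by construction; with real media, matrix effects could break
it, and nothing in the package would detect that automatically.
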