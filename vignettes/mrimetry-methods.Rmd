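---
title: "Quantitative relaxometry, volumetry and iron histomorphometry: models and methods"
author: "MRImetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative relaxometry, volumetry and iron histomorphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MRImetry)
```

MRImetry implements the quantitative analysis chain of a longitudinal
small-animal abdominal MRI monitoring study: relaxometry of an inversion-recovery
(Look-Locker) T1 series and a multi-echo T2 decay, organ and tumor volumetry
from segmentation label masks, iron quantification from stained histology, and
the cohort-level statistics that compare genotypes and sexes over time. A
synthetic-data layer generates every input with known ground truth, so the
whole chain can be exercised, validated and re-run without any scanner data.

## Relaxation models

**T1 (inversion recovery, Look-Locker).** A Look-Locker readout samples the
recovery of longitudinal magnetization after an inversion pulse with repeated
low-flip excitations. The sampled signal follows the three-parameter model

$$S(TI) = a - b\,e^{-TI/T1^*},$$

where $TI$ is the time after inversion (ms) and $T1^*$ is the *apparent*
relaxation time, shortened by the readout-induced saturation. The corrected
relaxation time is obtained from the fitted parameters as

$$T1 = T1^*\left(\frac{b}{a} - 1\right).$$

`fitT1LookLocker()` applies this correction identically; the `T1Fit` object
stores both $T1^*$ and $T1$. Ideal inversion corresponds to $b = 2a$, in which
case $T1 = T1^*$. A fitted $b/a \le 1$ implies a non-positive $T1$; such fits
are returned with their parameters intact but flagged `converged = FALSE` —
never silently clamped — so downstream code can decide what to do with them.

**Polarity restoration.** Reconstructed magnitude images lose the sign of the
still-inverted early samples. Rather than guessing the zero crossing, the
fitter tries every candidate flip index $j$ from 0 to (index of the signal
minimum + 1), negates the first $j$ samples, fits, and keeps the lowest-RMS
solution. The candidate set is small, so the search is exhaustive and
deterministic. Input that already contains negative values is treated as
signed and fitted directly.

**T2 (multi-echo spin echo).** The transverse decay is modelled
mono-exponentially with an additive offset,

$$S(TE) = M_0\,e^{-TE/T2} + c,$$

where $c$ absorbs the Rician noise floor of magnitude images. The first echo
of a multi-echo train is biased by stimulated-echo contributions, so
`fitT2MonoExp()` **always** excludes echo 1, regardless of the caller's
exclusion flags; the tests assert that arbitrary corruption of echo 1 cannot
change the fit. Whether the offset should be constrained non-negative is
genuinely open; we fit it unconstrained so that the residual diagnostics stay
honest, and report it.

## Robust fitting (IRLS)

Both fits run through `irlsFit()`, which alternates a weighted nonlinear
least-squares solve (Levenberg–Marquardt, via minpack.lm) with Huber
reweighting:

* robust scale $s = 1.4826 \cdot \mathrm{MAD}$ of the current residuals;
* weights $w_i = \min(1,\, 1.345\,s / |r_i|)$;
* convergence when the relative parameter change drops below `tol`
  (default $10^{-8}$), at most `maxIter = 50` iterations.

Three numerical details matter in practice:

1. **Weights precede the first solve.** The first weights are computed from
   the residuals of the *starting* parameters. With a robust start this
   downweights a gross outlier immediately; solving once with unit weights
   first can jump into the outlier's basin, after which reweighting converges
   to the wrong solution.
2. **Robust, deterministic starts.** For the decay model the start is
   derivative-free and outlier-resistant: $c_0$ just below the late-echo
   floor, $T2_0$ from the *median of pairwise slopes* of the log-amplitude
   (a Theil–Sen estimate), $M_0$ from the median intercept. A least-squares
   log-linear start was evaluated first and discarded: a single 10x outlier
   corrupts it badly enough that the subsequent robust fit can diverge. The
   IR start uses $a_0 = \max S$, $b_0 = a_0 + |\min S|$, and $T1^*_0$ from
   the zero-crossing time divided by $\ln 2$ (schedule midpoint if the series
   never crosses zero).
3. **Exactness guards.** When the residual scale is negligible relative to
   the signal ($s \le 10^{-10}\,\mathrm{rms}(S)$), reweighting is skipped —
   reweighting on rounding noise would only perturb an already exact fit. The
   decay fit adds a profiled polish: given $T2$, $(M_0, c)$ enter linearly,
   so a 1-D refinement over $T2$ with the linear pair solved exactly, followed
   by a Levenberg–Marquardt restart, finishes off ill-conditioned cases
   (e.g. $T2$ comparable to the schedule length) to solver precision.

Huber's estimator is monotone, not redescending: a large leverage outlier at
the earliest fitted echo can still degrade the fit (it degrades the
unweighted fit at least as much). The validated property is comparative —
on instances with a single 10x outlier the robust fit beats the unit-weight
fit in well over 95% of cases — not absolute immunity.

With `weightsRule = "unit"` the routine is ordinary least squares; the test
suite checks this against an independent brute-force reference
(`gridFitT1()` / `gridFitT2()`: dense grid with the linear sub-parameters
profiled out, then Nelder–Mead refinement) to within 0.5% in $T1$/$T2$.

Exclusion flags are input data, mirroring a manual motion-rejection
workflow; an optional automated flagger (`autoExclude = TRUE`: residual
beyond 4 robust standard deviations, one refit) is provided but off by
default.

## ROI extraction and longitudinal stability

`roiMeanSeries()` averages voxels inside an ROI across an ordered volume
stack, one sample per time. A `"background"` ROI in air yields a noise-scale
estimate from the Rayleigh mean of pure-noise magnitude data,
$\hat\sigma = \bar S / \sqrt{\pi/2}$.

`stabilityReport()` quantifies serial stability against an internal reference
tissue: per-timepoint percent deviation from the animal's mean value, and the
coefficient of variation $100\,\mathrm{sd}/\mathrm{mean}$. At a
signal-to-noise ratio of 50 on the default TI schedule, the T1 estimator's
CoV across noise realizations sits near 1.3% with bias well under 1% — the
order of magnitude expected for a stable serial relaxometry protocol.

## Volumetry

Volumes are labelled-voxel counts times the voxel volume, with no
partial-volume weighting — exactly what semi-automatic segmentation tools
report, and exactly testable: a grid-aligned box phantom is recovered to
machine precision, and ellipsoid voxelisation error decreases strictly over
refining spacings (0.4 → 0.2 → 0.1 mm for a 3 mm-radius sphere, ending below
0.01%). A label touching the grid boundary sets a `truncated` flag, since the
organ may extend beyond the field of view. Trajectories report per-interval
percent change $100\,(V_t - V_{t-1})/V_{t-1}$; a step out of zero volume is
flagged `"onset"` instead of dividing by zero. The onset-detection threshold
(mm^3) is a user parameter — the minimum volume considered visible on the
anatomical images — because no principled universal value exists.

Voxel conventions: indices are 1-based in R, voxel centres sit at
`origin + (index - 0.5) * spacing`, and phantom membership is evaluated at
voxel centres with box faces half-open on the max side. This makes voxel
counts reproducible across machines.

## Iron histomorphometry

Stained-slide quantification mimics an interactive pixel-classifier
workflow, with the human-in-the-loop replaced by ground-truth-driven
validation. Features per pixel: raw RGB, two stain-separation channels
(optical density projected on fixed Prussian-blue / nuclear-red unit
vectors — stain intensity is the discriminative signal), and Gaussian-smoothed
copies of all of these at configurable scales (default sigmas 1 and 2 px). The
classifier is a seedable random forest (100 trees), with a linear-discriminant
fallback below 200 labelled pixels, where a forest's bootstrap variance is not
worth its cost. Training rows are canonically ordered first so predictions do
not depend on the order in which annotations were supplied.

Iron load is the percentage of stain-positive pixels among *tissue* pixels;
tissue is everything darker than a luminance threshold (default 0.95), which
excludes bare glass. Across synthetic slides with true positive fractions of
5–40% and colour jitter up to 0.05, the estimated fraction tracks the truth
with mean absolute error far below 1.5 percentage points and is strictly
monotone in the truth.

## Cohort statistics

The statistical chain reproduces a common preclinical reporting convention:

1. **Normality gate**: Kolmogorov–Smirnov against a normal with estimated
   mean and sd, per group. Because estimating the parameters makes the plain
   KS test anticonservative, the default applies the Lilliefors correction
   (`method = "ks"` gives the uncorrected variant; the Lilliefors tables
   require n ≥ 5, smaller samples fall back to the uncorrected test).
   Zero-variance samples are classified non-normal.
2. **Two-group test**: unpaired two-tailed t test (equal variances) when both
   groups pass the gate, two-tailed Mann–Whitney otherwise. Groups too small
   to gate (n < 3) route to Mann–Whitney, as do zero-variance groups where t
   is undefined. Overlapping animal ids between groups are an error: the
   design is unpaired.
3. **Mann–Whitney p values** are computed by full enumeration of all group
   assignments of the pooled values when both groups have at most 8
   observations (ties handled via midranks, exactly), and by a normal
   approximation with tie and continuity correction otherwise. The
   enumeration is cross-checked against `wilcox.test`'s exact p on tie-free
   instances for every group-size combination up to 7.
4. **Stars**: `*` p ≤ 0.05, `**` p ≤ 0.01, `***` p ≤ 0.001. No
   multiple-testing correction by default (matching per-comparison
   reporting); `mtc = "bh"` adds Benjamini–Hochberg adjusted values.

Whether the gate should be applied per group or pooled is not standardised;
it is applied per group here, and the choice is confined to one function so
it can be switched. Under the null (two groups of 7 Gaussian samples), the
gated procedure's empirical type-I error over 2000 simulations stays within
[0.03, 0.07].

## The synthetic-data layer

The generators define the study conditions and report their ground truth:

* **Signal series**: the IR and decay models above, sampled on a default TI
  schedule of 50 points from 7 ms in 80 ms steps (~4 s span, several times a
  rodent-tissue T1; the schedule is always explicit, never inferred) and a
  default TE schedule of 14 echoes at 6 ms spacing (6–84 ms). Noise is
  Rician — magnitude of a complex Gaussian with the true signal on the real
  axis, sd `noiseSigma` per component — or plain Gaussian for signed data. An
  optional multiplicative first-echo bias emulates the artifact that
  motivates the first-echo rule.
* **Phantoms**: boxes, ellipsoids and tubes on a configurable grid with
  analytic volumes reported alongside; later shapes overwrite earlier ones
  and duplicate labels are an error.
* **Slides**: exactly `round(fraction * n)` randomly placed positive pixels,
  class colours with per-channel Gaussian jitter. Identical class colours
  with zero jitter and both classes present is rejected as unlearnable.
* **Cohorts**: a 2 sex x 2 genotype factorial with 7 animals per cell by
  default, measured at months 2–12 (relaxometry from month 4), generated as
  baseline(timepoint) + genotype effect + sex effect + Gaussian residual.
  Default effect sizes sketch the phenotype pattern of a KIT-mutant
  GIST-model study — late marrow-T1 shortening in mutants, female-shorter
  splenic T2 (higher iron), an early cecal volume decrease turning into a
  late increase, several-fold more Peyer's patches in mutants, and a tumor
  model with per-timepoint onset hazards concentrated in mutant females,
  sub-mm^3 initial volume (0.5 mm^3) and a geometric growth factor of 4 per
  two-month interval.

What the generators deliberately do **not** emulate: spatial structure inside
ROIs (partial-volume mixtures, B1 inhomogeneity), imaging artifacts other
than a first-echo bias and frame-level corruption, multi-exponential decay,
spatially clustered stain morphology, within-animal correlation beyond the
per-measurement residual, and dropout/censoring. Passing tests therefore
validate the estimators and their arithmetic under the stated noise models,
not robustness to every property of real scanner data.

## Pipeline and reproducibility

`runPipeline()` executes inputs → relaxometry → morphometry →
histomorphometry → statistics from one declarative config
(`defaultRunConfig()`, or YAML/JSON via `readRunConfig()`). All stage outputs
are plain CSV/Markdown; `manifest.json` records a config hash (the output
path is excluded from the hash, so identical analyses share a manifest),
package version, per-stage file checksums and record counts, and a warnings
log that mirrors exclusion footnotes (excluded records, truncated masks,
non-converged fits). Identical config and seed give byte-identical outputs;
a failing stage aborts after writing the manifest of completed stages.

Problem sizes: validation runs use 100-combination noiseless grids, 200-seed
noise and outlier ensembles, 20 oracle instances, 20 synthetic slides at
100 x 100 px, 2000 null cohorts, and a default pipeline cohort of 28 animals
— sizes at which every Monte-Carlo bound in the tests has comfortable slack
while the whole suite runs in well under a minute.

## Known limitations

* Voxelwise T1/T2 mapping is out of scope; fits operate on ROI-mean series.
* No B1/inversion-efficiency correction; the IR model absorbs imperfect
  inversion into $b/a$.
* Huber IRLS protects against isolated outliers, not against structured
  artifacts affecting many echoes.
* The pixel classifier assumes colour separates the classes; stains whose
  discrimination is textural would need richer features.
* The statistics module implements two-group comparisons only — no
  mixed-effects longitudinal modelling, by design.
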