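# MRImetry

Quantitative analysis for longitudinal small-animal MRI tumor-monitoring
studies, written for imaging scientists who track organ phenotypes and tumor
progression in mouse cohorts and need the full chain — relaxometry, organ
volumetry, stain-based iron quantification and cohort statistics — in one
tested, reproducible package. A synthetic-data module generates every input
with known ground truth, so the entire pipeline runs and validates itself
without any scanner data.

## What it computes

**T1 relaxometry (Look-Locker inversion recovery).** The ROI-mean signal is
fitted with

&nbsp;&nbsp;&nbsp;&nbsp;S(TI) = a − b·e^(−TI/T1\*),&nbsp;&nbsp;&nbsp;
T1 = T1\*·(b/a − 1),

where T1\* is the apparent relaxation time under the readout-induced
saturation and the second relation is the Look-Locker correction. Magnitude
data get exhaustive polarity restoration before fitting.

**T2 relaxometry (multi-echo spin echo).** The decay is fitted with

&nbsp;&nbsp;&nbsp;&nbsp;S(TE) = M0·e^(−TE/T2) + c,

where c absorbs the magnitude-image noise floor; the first echo is always
excluded (stimulated-echo bias). Both fits run through a robust iteratively
reweighted least-squares engine (Huber weights, tuning constant 1.345,
Levenberg–Marquardt inner solves) validated against an independent
grid-search reference.

**Volumetry.** Organ/tumor volume = labelled voxel count x voxel volume,
with longitudinal trajectories (percent change per interval), onset
detection against a visibility threshold, and truncation flags for labels
touching the field-of-view boundary.

**Iron histomorphometry.** A seedable per-pixel classifier (random forest on
RGB + stain-separation + multiscale-smoothed features) trained from sparse
annotations; iron load is reported as percent stain-positive area over
tissue pixels.

**Cohort statistics.** Per measurement and timepoint: Kolmogorov–Smirnov
normality gate (Lilliefors-corrected), then an unpaired two-tailed t test or
a two-tailed Mann–Whitney test (exact by enumeration for small groups),
stars at p ≤ 0.05 / 0.01 / 0.001, genotype-within-sex and
sex-within-genotype comparisons, mean ± sd summaries with exclusion logging.

## Worked example

```r
library(MRImetry)

# a noisy magnitude Look-Locker series with known truth (T1* = 600 ms,
# b/a = 1.96, so true T1 = 576 ms), at SNR 50
series <- simulateIRSeries(a = 1000, b = 1960, t1Star = 600,
                           noiseSigma = 20, seed = 7)
fitT1LookLocker(series)
#> T1Fit: T1 = 574.22 ms (T1* = 581.47, a = 999.2, b = 1986)
#>   50 points, rms 19.69, flip index 5, converged: TRUE
```

The fit restored the sign of the first 5 magnitude samples, recovered the
residual scale (rms 19.7 against a true noise sd of 20) and estimated T1
within 0.3% of the true 576 ms.

```r
decay <- simulateDecaySeries(m0 = 1000, t2 = 16, c0 = 30,
                             noiseSigma = 20, seed = 7)
fitT2MonoExp(decay)
#> T2Fit: T2 = 13.126 ms (M0 = 1044, c = 66.35)
#>   13 points (echo 1 excluded), rms 15.81, converged: TRUE

# cohort-level report: genotype comparison of marrow T1 at month 12
coh <- simulateCohort(seed = 7)   # 7 animals per sex x genotype
rep <- longitudinalReport(coh, measurements = "marrow_T1")
#> marrow_T1 @ 12 months [genotype_within_sex f, mutant_vs_control]:
#>   t test, statistic -3.322, p = 0.006093 **
#> marrow_T1 @ 12 months [genotype_within_sex m, mutant_vs_control]:
#>   t test, statistic -5.947, p = 6.743e-05 ***
```

The default synthetic cohort builds in a late-age marrow-T1 shortening in
mutants; the report recovers it as significant genotype differences at
month 12 in both sexes.

```r
volumeTrajectory(c(100, 145), c(10, 12))$pctChange
#> [1] NA 45
```

An end-to-end run (`runPipeline(defaultRunConfig(seed = 1))`) writes the
cohort table, relaxometry fits, stability report, phantom and tumor
volumetry, iron quantification and the statistics report into one output
directory, together with a `manifest.json` recording checksums, record
counts and warnings. A thin command-line wrapper over these functions is
included at `inst/cli/mrimetry.R`.

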