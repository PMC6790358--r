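---
title: "plantmet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plantmet: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical models, the tunable parameters
and the design decisions behind `plantmet`, in the order the pipeline
runs. It also states precisely what the synthetic benchmark does and does
not demonstrate about real data.

## The measurement model

A centroided UPLC-HRMS run is a sequence of scans; each scan is a set of
(m/z, intensity) centroids at one retention time. The package assumes:

* **centroid mode** — profile-mode input is rejected at read time; the
  density-clustering EIC builder relies on one centroid per ion per scan;
* **m/z stability** — a given ion's centroid m/z wanders by far less
  than the 0.01 Da tolerance between scans (high-resolution instruments
  achieve ~1 mDa at the masses considered here);
* **bilinear responses** — the height of ion *i* of metabolite *m* in
  sample *s* factorizes as (abundance of *m* in *s*) x (response factor
  of *i*) x noise. This bilinearity is what makes peak-height correlation
  across samples evidence of a shared metabolite origin;
* **shared elution** — all ions of one metabolite (isotopologues,
  adducts, in-source fragments) elute with the same profile, because
  they originate from the same molecules passing the column.

## Stage 1: EIC extraction and peak detection

**Ion density clustering.** All centroids of a run are pooled, sorted by
m/z and split wherever the gap between neighbours exceeds `mz_tol`
(0.01 Da). Clusters with fewer than `min_points` members are discarded
as background. The default is `min_points = 10`: a genuine
chromatographic peak of width sigma = 0.02–0.05 min sampled at 0.01-min
intervals contributes roughly 30–60 centroids above the detection floor,
so 10 points separates real traces from scattered noise without
penalising narrow peaks; fractions of total scan count are not a usable
scale here, because a metabolite occupies only a small part of a
gradient. A cluster's m/z span can slightly exceed 2 x `mz_tol` when
centroids chain; with realistic jitter (~1 mDa) this is rare and
harmless.

**Baseline correction.** The trace is tiled into `baseline_window_min`
(2 min) windows; each window's minimum point anchors a piecewise-linear
baseline (constant beyond the outer anchors), which is subtracted with
clipping at zero, twice. Two iterations remove most of the residual left
when a first-pass anchor sat on a peak flank. A flat trace maps exactly
to zero, so constant column bleed yields no peaks.

**Scale-space ridge detection.** The corrected trace is smoothed with
Gaussian kernels of sigma in `sigmas` (1–10 scan steps). Local maxima
are linked across successive scales (drift window +/-(sigma + 2) steps);
a ridge persisting `min_ridge_length` (3) scales is a peak candidate.
Boundaries are the flanking local minima of the lightest smoothing;
height is the corrected intensity at the apex and area the summed
corrected intensity over the window — both exactly, which tests assert
as an identity.

**Signal-to-noise.** Noise is the median absolute deviation of first
differences of the corrected trace outside candidate peak windows
(scaled to a standard deviation); for short traces fully occupied by a
peak it falls back to the high-frequency residual against the lightly
smoothed trace. The *signal* is the apex of the trace smoothed at the
ridge-persistence scale, measured above that smoothed trace's median.
Both choices matter: white noise produces sharp raw apexes several
noise-sigma above a minima-anchored baseline, but dies under smoothing,
while an imperfectly removed baseline contributes a DC offset that must
not count as signal. With `min_snr = 3` a pure-noise trace yields no
peaks in well over 95% of random draws, which the tests check by
Monte-Carlo.

## Stage 2: time-shift correction

The sample with the most detected peaks becomes the reference — the
richest peak list gives the most anchors. Candidate pairs must agree
within `align_mz_tol` (0.01 Da) and `align_rt_tol` (0.5 min). Pair
similarity is the Pearson correlation of the two elution profiles, each
resampled to `resample_points` (50) points over +/-2 half-widths around
its own apex; this deliberately normalises width so that a moderately
broadened copy of a peak in another sample still matches (cross-sample
width variation is a nuisance here, unlike in stage 5). Constant
profiles get similarity 0.

The dynamic program maximizes accumulated similarity over monotone
matchings, with unmatched peaks free and invalid pairs unmatchable;
matched pairs scoring at least `min_match` (0.5) become warp anchors.
Monotonicity means two identical-shape peaks present in both runs are
matched in elution order, never crossed. Exhaustive enumeration on small
matrices confirms optimality in the tests.

Two anchor-quality safeguards reflect physical assumptions rather than
tuning: only peaks with SNR >= `anchor_min_snr` (10) may serve as
anchors, because the apex of a feature near the noise floor is too
poorly localised to be a time reference; and since retention drift is
smooth, anchors whose implied shift jumps from the running median of
their neighbours by more than 4 robust standard deviations (floor
0.02 min, allowing for apex discretisation) are discarded. The warp is
linear interpolation through the surviving anchors; beyond the anchor
range the edge shift is held constant, avoiding wild extrapolation.
Raw scans are never resampled — only peak retention-time fields are
remapped.

## Stage 3: registration (NNC)

Candidates of a peak are peaks of other groups within `reg_mz_tol`
(0.01 Da) and `reg_rt_tol` (0.1 min), ordered by retention-time
difference (ties by m/z difference). One scanning round finds every
mutual-first-candidate pair over the current group means and merges the
sample-disjoint ones simultaneously; rounds repeat to fixpoint, with an
iteration cap at the peak count guaranteeing termination. Batch rounds
(rather than one merge at a time) make the result independent of input
order, which a shuffle test asserts. After a merge the group is
represented by its member means. A pair whose merge would put two peaks
of one sample into a group is skipped, not an error; the surplus peak
ends as its own component.

## Stage 4: screening and Meta IDs

**ANOVA.** Heights (not areas — the apex is less sensitive to boundary
errors; areas remain available via `response = "area"`) are tested per
component with a fixed-effects one-way ANOVA. Missing cells are dropped
(unbalanced design, never imputed); a component is testable only with
two or more observed samples in each of two or more groups. Degenerate
variances are resolved explicitly (zero between-group variance: F = 0,
p = 1; zero within-group variance with a real difference: F = Inf,
p = 0). No multiple-testing correction is applied by default — the
screen is a filter, not an inference endpoint — but Benjamini–Hochberg
is available via `p_adjust = "BH"`.

**Robust correlation.** The correlation of two components' heights
across samples uses the minimum covariance determinant: the MCD scatter
of the bivariate sample (support fraction `mcd_support` = 0.75) defines
robust distances, and the Pearson correlation of the retained points is
returned. Distances are median-scaled against the chi-square reference
because the raw MCD scatter is not consistency-calibrated, and a point
is excluded only if it lies beyond the chi-square 0.9999 bound *and*
30x the h-th smallest distance. The two-sided rule matters: any fixed
chi-square cutoff occasionally rejects a legitimate extreme of a clean
sample, biasing the estimate, whereas gross outliers sit orders of
magnitude out. On clean data the estimator reproduces plain Pearson
exactly in the package's tests; contaminating a perfectly correlated
pair with 20% gross outliers moves it by less than 0.02. Below 10
paired observations plain Pearson is used (the MCD is unstable there);
below `min_pairs` (5) the correlation is undefined and the pair cannot
form an edge. Exact collinearity, which the subset search cannot
handle, is broken by an infinitesimal seeded jitter used for the search
only. The subset search is seeded from the configuration (`mcd_seed`),
so pipelines are exactly reproducible.

**Meta IDs.** Significant components are nodes; edges require robust
correlation >= `corr_threshold` (0.9) *and* co-elution of the component
mean retention times within `coelution_rt_tol` (0.1 min). Connected
components of this graph share a Meta ID (transitive merging — two ions
each strongly correlated with a third are claimed by the same
metabolite even if their mutual estimate is weaker). The co-elution gate
is a deliberate design choice the correlation alone cannot replace:
biosynthetically coupled but chromatographically separated metabolites
correlate strongly across samples yet are certainly not one compound.
It can be disabled by setting the tolerance to infinity.

## Stage 5: ion-clustering annotation

Within each sample, isotope pairs are seeded: a partner at
+1.00336 Da (the 13C–12C mass difference) within `iso_mz_tol`
(0.005 Da), co-eluting within `anno_rt_tol` (0.02 min), with shape
similarity >= `shape_cutoff0` (0.9) and *lower* intensity than the
monoisotopic ion (true below ~90 carbons; prevents reversed
assignments). Shape similarity here is computed on a common
absolute-time grid over the union of the two peaks' supports, zero
outside each support — the opposite convention from stage 2, because
width and asymmetry differences between co-eluting peaks are exactly
the deconvolution signal and must not be normalised away.

The observed isotope-pair similarity sets each ion's adaptive cut-off,
`max(cutoff_floor, min(shape_cutoff0, similarity - margin))` with
margin 0.02 and floor 0.8: a clean peak keeps 0.9, a noisy one relaxes
gracefully, and the threshold never exceeds the initialized value.
Satellites ([M+2+H]+ at +2.00671, [M+3+H]+ at +3.01007, and the adduct
table NH4+ +17.02655, Na+ +21.98194, K+ +37.95588 relative to [M+H]+,
extendable via `adduct_table`) are recognized under the per-ion
threshold; a contested satellite goes to the more similar parent.

[M+H]+ ions then cluster bottom-up (agglomerative, average-linkage)
under hard gates — every cross pair must co-elute within `anno_rt_tol`
and satisfy both ions' adaptive thresholds — and unannotated co-eluting
peaks join a cluster as in-source fragments when they pass every MH
member's threshold. Finally, reconciliation: components are confirmed
as one metabolite only if their ions co-cluster in at least `min_votes`
samples (default: a majority) *and* they share a Meta ID. Pairs with
only one kind of evidence are reported as partial evidence rather than
merged; this two-channel AND rule is what separates co-eluting
same-width metabolites whose abundances are uncorrelated, a case shape
alone provably cannot resolve (two clean Gaussians with width ratio
1.5 still correlate ~0.96 on a common grid). The derived spectrum is
taken from the single sample where the [M+H]+ ion is tallest —
averaging across warped time axes is ill-defined — and lists every
member peak's apex m/z, height and role in ascending m/z.

## The synthetic benchmark: what it emulates, and what it does not

`generate_dataset()` draws a metabolite catalogue (apex positions,
widths, carbon counts, [M+H]+ masses, base abundances), expands it to
an ion catalogue (isotopologues from a binomial 13C model, one adduct,
0–2 fragments), and renders centroided scans with: an irregular scan
grid (0.01 min +/- 10% jitter), smooth sinusoidal per-sample retention
warps (amplitude 0.05 min by default, strictly monotone, with the
analytic form stored for scoring), multiplicative per-centroid shape
noise (2%), an additive detector noise floor (sd 8 counts), m/z jitter
(sd 1 mDa), a 20-count emission floor, slow baseline drift under 30% of
true traces (expressed in warped time, as drift rides the same flow
fluctuations as retention), and 5x as many low-intensity noise ions as
true ions. Abundances are bilinear with per-sample biological variation
(log-sd 0.25), per-ion noise (log-sd 0.1) and a 4-fold group effect in
a random direction for every metabolite — the benchmark exists to
exercise screening and confirmation, and only screened components can
be confirmed; null calibrations set `effect_fraction = 0` explicitly.

Two generator choices keep the benchmark's ground truth identifiable.
Metabolite apexes are placed with at least 0.15 min separation, because
a co-eluting same-width pair with same-direction effects is provably
unresolvable by any shape- or correlation-based method; deliberate
co-elution is instead exercised by `generate_coelution_pair()`, which
pins two metabolites to one apex (the tailed profile's mode shift is
compensated) with shape-distinct profiles — one Gaussian, one
exponentially tailed, correlation ~0.6 — and uncorrelated abundances.
And all metabolites carry group effects, as noted above.

What passing the benchmark does **not** show about real data: vendor
noise is not i.i.d. and centroiders produce artefacts near saturation
and in fused peaks; real retention drift can be locally non-smooth
(pressure events); real isotope patterns include S/Cl/K signatures the
binomial carbon model ignores; fragments of co-eluting metabolites can
share exact masses; and matrix effects violate bilinearity for
strongly suppressed ions. The benchmark demonstrates algorithmic
correctness under a controlled model, not instrument-grade robustness.

## Calibration and problem sizes

The test-suite and acceptance-script sizes were chosen to characterise
behaviour well while keeping a full run in the minutes range: oracle
equivalence on 1000 pooled centroids, 100 random similarity matrices up
to 6x6 (exhaustive enumeration), 100 random registration sets up to 30
peaks, 50 random ANOVA tables; warp recovery with 40 anchors at
amplitude 0.25 min; screening power over 100 replicate tables (5
effect + 45 null components) and type-I rate pooled over 200 null
tables; and the end-to-end benchmark at its default size (20
metabolites, ~95 ions, 6 samples, ~570 true ion observations, ~2800
detected peaks). Screening calibrations run on tables simulated
directly from the abundance model (`simulate_component_table()`) — the
raw-scan path adds nothing to a calibration of the screening stage.

## Known limitations

* Positive ionisation only; the adduct table is user-extendable but no
  negative-mode chemistry ships by default.
* No gap-filling: a component missing in a sample stays missing (an
  empty cell, never zero) rather than being re-integrated from the raw
  trace.
* Single-reference alignment; a sample sharing no peaks with the
  reference keeps its own time axis (with a warning) rather than
  failing.
* Compound identification (matching derived spectra against libraries)
  is out of scope; the MSP export exists to hand spectra to such tools.
* The MCD path needs >= 10 paired samples; small studies fall back to
  plain Pearson, which one gross outlier can distort.
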