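---
title: "Methods: inter-subject correlation and its companion tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inter-subject correlation and its companion tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natisc)
```

This vignette explains the models and procedures the package
implements, the assumptions behind them, the defaults and why they were
chosen, and what the synthetic-data tests do and do not establish about
real data.

## The scientific problem

In a naturalistic design every subject watches the same film, possibly
under different instructions or beliefs. Classical GLM analysis needs a
trial structure; a film has none. The inter-subject correlation (ISC)
framework instead asks, per voxel, how *similar* two subjects' BOLD
time courses are, on the premise that stimulus-driven processing is
time-locked across brains while idiosyncratic activity is not. A belief
manipulation that changes how the film is processed should then change
cross-subject synchrony even when mean activation does not.

## Pairwise ISC and the Fisher-z scale

For runs of T TRs, the voxelwise similarity of a subject pair is the
Pearson correlation r of their time series, stored as z = atanh(r).
Averages of correlations are always formed on the z scale and reported
as tanh(mean z); the transform approximately stabilises the variance of
r so that pooling across pairs with different true values is less
biased. Correlations within floating-point distance of |r| = 1 (they
arise only from degenerate inputs such as duplicated runs) are clamped
to 1 − 1e−7 before atanh so all z values are finite. Zero-variance
voxel-pairs are recorded as *missing*, never as zero: a flat time
series carries no similarity information, and imputing 0 would bias
pooled means toward the null.

With two viewings per condition, every viewing of subject i is paired
with every viewing of subject j (i ≠ j), so the same-condition pool has
2·2·N(N−1)/2 pairs — the within-subject test–retest cells are kept out
of all inference and appear only in the full run-by-run similarity
matrix (120 × 120 for N = 30, 4 runs each). Pooling all four
cross-viewing combinations, rather than averaging a subject's two
viewings first, is what the pair-count formula implies and is what the
package implements.

## The condition contrast and its permutation null

Let z_A and z_B be the pooled pair tensors of the two belief conditions
with the matched indexing (i, j, viewing a, viewing b). The observed
statistic per voxel is the one-sample t of Δz = z_A − z_B over matched
pairs. Pairs sharing a subject are not independent, so the parametric
t reference is invalid; significance comes from permutation.

The exchangeable unit under the null "belief does not matter" is the
*subject*: each subject's sessions may be swapped between conditions.
Swapping subjects independently with probability 1/2 and re-pooling
yields the null distribution. Re-pooling is exact only if the
mixed-condition pair cells are available — if subject i is swapped and
j is not, the permuted "condition A" pair (i, j) correlates i's
condition-B runs with j's condition-A runs. The package therefore
computes the Fisher-z tensor over **all** cross-subject session pairs
once and re-indexes columns per permutation. Relabelling at the pair
level instead would break exchangeability (pairs share subjects) and
was rejected.

Permutation p-values use p = (1 + #{|t*| ≥ |t|}) / (1 + B), which can
never be zero. Note the resolution limit of subject-level exchange: the
two-sided null has at most 2^(N−1) distinct relabellings, so with very
small groups (N ≤ 8) the attainable p is bounded below by 2^−(N−1)
regardless of B. Voxelwise correction is Benjamini–Hochberg FDR at
q = 0.05 within the analysis mask; the t-threshold corresponding to the
adaptive BH cutoff is a *data-dependent output* reported alongside the
mask, not a constant of the method. For display, masks can be
cluster-filtered at a minimum extent of 64 voxels (4 × 4 × 4);
connectivity is 6-neighbour by default (26 available) — the choice is a
convention, stated rather than hidden. Joint significance across two
analyses uses the intersection–union test: the voxelwise maximum of the
two p-maps, BH-corrected.

The one-group ISC test destroys temporal alignment instead: each run is
circularly shifted by an independent random offset of at least 10 TRs
and the mean pairwise z-map recomputed. Circular shifting preserves
each run's autocorrelation and amplitude spectrum while removing
stimulus locking, which is exactly the null of interest; the offset
floor keeps surrogate series from being nearly aligned with the
original.

## Nuisance cleaning

Runs are cleaned by a single joint least-squares projection on an
intercept, the user's confound columns, and a discrete-cosine drift
basis containing all frequencies below the high-pass cutoff (0.01 Hz
default for the ISC path). Joint projection rather than sequential
filtering guarantees residuals exactly orthogonal to every regressor;
with sequential steps the second projection partially reintroduces
components removed by the first. The 24-column motion expansion is the
conventional one — the six rigid-body parameters, their backward
differences (first row zero), and the squares of both. Tissue-signal
confounds (white matter, CSF) are accepted as extra columns; computing
them from atlases is out of scope. A rank-deficient regressor matrix
degrades to a pseudoinverse fit with a warning rather than an error,
since duplicated confound columns are common and harmless to residuals.

## GLM localizer

The decision regressor is a boxcar spanning identity-revelation to
button press, convolved with the canonical double-gamma HRF (response
gamma peaking at 6 s, undershoot at 16 s, ratio 6, 32 s support) on a
20× oversampled grid and sampled at TR times. The baseline is implicit:
all non-decision time constitutes the reference, so no second regressor
is needed — an explicit "non-decision" regressor would be collinear
with the intercept. Drift columns cover periods above 128 s. The
second level is a one-sample t over subjects' contrast volumes,
enhanced with TFCE (per voxel, the integral over thresholds h of
extent^0.5 · h² · dh with dh = max|t|/100, 26-connectivity, negative
lobes enhanced on the negated map), with family-wise correction from
the max-TFCE distribution under random sign flips of whole subject
maps. TFCE and component labelling run in compiled code; the R test
suite checks them against an independent threshold-sweep oracle and the
single-voxel closed form (∫₀ʰ x² dx = h³/3).

## Eye-gaze ISC

Saccade samples are those exceeding 30°/s velocity or 4000°/s²
acceleration; maximal clean runs between saccades/blinks become
fixations at their centroid. Because no online drift correction is
assumed, each recording's fixation cloud is rigidly translated so its
mean coincides with the grand mean across recordings (the mean of
per-recording means, so unbalanced recording lengths do not reweight
subjects).

Heatmaps are built in 2 s windows (matching the TR): each fixation
overlapping a window contributes a Gaussian of σ = 1° truncated at 3σ.
The discretised kernel is renormalised to unit sum, so heatmap mass
equals the number of contributing fixations exactly; a continuous
truncated Gaussian would silently lose ~1 % of its mass at the 3σ
radius. Grid resolution defaults to 0.25°/cell — σ is the binding
spatial scale, and the only requirement is resolution ≤ σ/2. Windowed
pairwise Pearson correlations are stored on the z scale; the group
statistic is the difference between the back-transformed mean of
both-in-A pairs and both-in-B pairs (mixed pairs are computed but
excluded, matching the contrast of interest), with recordings' group
labels permuted for the null.

One property worth stating explicitly: a gaze displacement shared by
*every* recording of a group leaves that group's internal similarity —
and hence this statistic — unchanged. Only manipulations that reduce
within-group coherence (for example, each subject's attention diverging
in its own direction) are detectable, and that is what the synthetic
planted-effect scenario implements.

Recording-level QC mirrors standard practice: reject when blink time
exceeds 10 % of the recording or when the majority of blink/saccade
events last 1 s or more.

## Behavioural and physiological controls

*Framewise displacement* is Σ|Δtranslations| + 50 mm · Σ|Δrotations|
per TR (first value 0), with the 0.5 mm threshold and the
90 %-of-volumes rule as the QC summary. *Similarity permutation tests*
convert recordings to pairwise similarities — negative absolute
difference for scalars such as mean FD, Fisher-z correlation for
traces such as heart rate — and contrast same-condition-A against
same-condition-B pair values with a two-sample t whose reference comes
from relabelling recordings. *TOST* uses the one-sample/paired form
t_upper = (d − Δ)√n, t_lower = (d + Δ)√n on n − 1 degrees of freedom;
this form reproduces the printed worked examples of the design it
targets, and raw-score input is converted through the sample SD.
*Mantel tests* correlate off-diagonal upper triangles under joint
row/column permutation of one matrix. *Time-point-wise rating tests*
permute whole traces between groups and BH-correct across time points;
5 Hz rating traces are block-averaged to the 2 s grid before group
tests (the resampling choice is ours and documented here).

All permutation p-values in the package respect the (1 + k)/(1 + B)
floor, and every stochastic routine takes an explicit seed.

## The synthetic cohort generator

The generator is a first-class module, not a fixture: it defines the
study conditions under which the pipeline is validated.

* **BOLD.** Each voxel in an effect region carries w·s_v(t) + ε, where
  s_v is a per-voxel stimulus course shared across subjects (one
  independent draw per condition) and ε is i.i.d. Gaussian subject
  noise. Courses are unit-variance low-pass-filtered Gaussian noise
  (0.1 Hz cutoff), mimicking the autocorrelation of stimulus-driven
  BOLD; the true ISC is then c = w²/(w² + σ²) analytically, which is
  the oracle for all recovery tests. A region may also be driven by a
  single course shared across *both* conditions ("both"), emulating the
  null in which belief does not alter processing while synchrony is
  nonzero. Note that with condition-specific courses, equal-but-nonzero
  coupling in both conditions is *not* a null for the subject-exchange
  contrast (mixed-condition pairs would decorrelate), so calibration
  nulls use zero coupling or shared courses.
* **Design sizes.** Defaults mirror the target acquisition: 712 TRs of
  2 s, two viewings per condition, 2 × 2 within-subject. The phantom
  grid is 16 × 16 × 8 so full-design runs fit in memory and seconds,
  not hours; all sizes are configurable.
* **Gaze.** Fixations cluster around a scripted sequence of spatial
  attractors with gamma-distributed dwell times, separated by fast
  saccadic jumps; in-fixation jitter steps are bounded so neither
  saccade threshold can fire inside a fixation by construction.
  Constant per-recording drift and the divergent-attention displacement
  described above are available as planted effects.
* **Ancillaries.** Motion as smooth random walks with optional
  sustained spikes; positive smooth heart/breathing rate traces;
  bounded 5 Hz valence/arousal traces.

Equal seeds give bit-identical cohorts.

### What the synthetic tests do not show

The generator omits scanner drift and spike artefacts, spatial
autocorrelation of noise, haemodynamic variability across subjects,
aliased physiology, and any registration error — the cleaning and QC
stages are therefore validated only for their *algebra* (orthogonality,
formulas, thresholds), not for their adequacy on real scanners.
Likewise, effect sizes for belief-driven ISC differences in real data
are unknown; the planted couplings (ISC 0.5 vs 0.1) are calibration
choices demonstrating recovery under favourable but plausible
conditions, not claims about the magnitude of real effects.

## Numerical choices and degenerate inputs

* Correlation clamp 1 − 1e−7 before atanh; round trips are exact to
  1e−12 for |z| ≤ 5.
* Voxel indices are 1-based R conventions internally; world geometry
  travels only through the NIfTI affine, and no template space is
  assumed.
* BH-FDR is computed on non-missing p-values only; voxels with no
  valid pairs stay missing through every downstream map.
* TFCE uses an integer threshold grid h = k·dh to make the sweep
  reproducible across platforms; dh defaults to max|stat|/100, and the
  suite checks the result against a fine-step oracle within 1 %.
* Rank-deficient cleaning designs warn and use the pseudoinverse;
  rank-deficient GLM designs *error* naming the collinear columns,
  because a mis-specified task model should not be silently repaired.
* Sizes used by the validation suites: null calibration runs 200
  cohorts of N = 8, T = 150 at 200 permutations on a 6 × 6 × 4 grid
  (the grid is our choice; the exchangeability being tested does not
  depend on it); recovery uses N = 12, T = 300, 1000 permutations on
  10 × 10 × 6. With BH control the false-discovery *proportion* of a
  single run fluctuates around its controlled expectation, so
  single-run FDP near q is expected behaviour.

## Interfaces

Functions take data frames or plain matrices first and return tibbles;
fitted objects have `tidy()`, `glance()` and `autoplot()` methods. Runs
and maps read and write NIfTI (via RNifti, affine passed through),
tables are tab-separated with headers, and ground truth and stat-map
metadata travel as JSON sidecars. The pipeline is driven from R or
Rscript; `scripts/acceptance.R` is the reproducibility entry point.

## Known limitations

No parametric ISC inference, no spatial-autocorrelation-aware cluster
p-values, no mixed-effects ISC models, no within-subject (test–retest)
inference, no slice-timing/registration/smoothing (expected upstream),
no pupillometry or smooth pursuit, and no scoring of implicit-bias
reaction-time tasks. The eye-gaze module expects pre-exported sample
tables in degrees; pixel-to-degree conversion is the caller's
responsibility.
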