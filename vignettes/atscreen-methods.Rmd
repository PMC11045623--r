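---
title: "Methods: unsupervised target screening of HRMS ion chromatograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unsupervised target screening of HRMS ion chromatograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

atscreen screens and quantifies target analytes in batches of centroided
LC- or GC-HRMS runs without manual peak review. This vignette explains the
model behind each stage, the tunable parameters, the numerical choices
made where the design was genuinely open, and what the synthetic test bed
does and does not demonstrate.

## The screening problem

A targeted batch consists of solvent blanks, reference standards
(constant-concentration controls and/or a calibration series), optional
matrix-matched QC standards, an optional internal-standard-only control,
and unknown samples. Every target is defined by a quantifier m/z, an
expected retention time, optionally a confirming ion with an expected
intensity ratio, and an assigned internal standard (IS). Three features of
real data defeat naive peak picking: noisy or elevated baselines, batch-
and compound-dependent retention-time drift, and multi-peak patterns from
co-eluting isomers sharing one m/z. Each pipeline stage addresses one of
these.

## Extracted ion chromatograms and the background trace

`extract_eic()` sums, per scan, all centroid intensities within the m/z
tolerance (5 ppm by default; absolute Da via `mz_tol_unit`). Scans without
a matching centroid contribute an explicit zero so point counts reflect
the acquisition rate. Summing rather than taking the maximum makes the
trace robust to centroid splitting.

Baseline and noise are never estimated on the analyte window itself: a
peak can occupy most of a narrow window and would inflate both. Instead a
*background EIC* spans the search window widened by
`background_extension_factor` (1.5). The baseline is normally the 25%
intensity quantile (linear interpolation between order statistics,
type-7; the convention shifts the baseline by under one count on
realistic traces). Three triggers guard that choice:

* **zigzag** — the fraction of the background covered by alternating
  high/low spikes must stay below `zigzag_trigger_threshold` (0.25);
* **spread** — the RMSE of the baseline-defining intensities about the
  baseline, relative to the baseline, must stay below
  `background_rmse_threshold` (0.10);
* **dynamic range** — the maximum over the 25% quantile must exceed
  `minimum_background_ratio` (3).

If any trigger fails the stricter `higher_background_quantile` (0.80)
defines an elevated baseline. Noise is the standard deviation of the
baseline-defining intensities; baseline + 3x noise and + 10x noise act as
in-sample LOD and LOQ. These are intensity gates for annotation
confidence only — they make no concentration claim. Degenerate cases: an
all-zero trace reports baseline 0 / noise 0 and is flagged; a zero
baseline fails the ratio trigger rather than dividing by zero, and fails
the spread trigger whenever the defining set has any spread (a relative
criterion has no reference at zero).

The zigzag pattern itself needed an operational definition (the source
idea is verbal): a run of at least `zigzag_min_run` (4) consecutive
points strictly alternating between "high" (above baseline + 3x noise)
and "low" (at most baseline + noise). Because the triggers need a
baseline before one exists, the triggers are evaluated against the
provisional 25%-quantile baseline.

## Shape layer: SAX at point resolution

Every EIC can be rendered as a symbolic (SAX) sequence: z-normalise the
intensities and map each point to the letter of its standard-normal bin
(`sax_alphabet_size` = 7). One letter per raw point — no word
compression — because the workflow edits letters at specific indices:
`zero_out_bounds()` writes the lowest letter at peak starts, ends, and
enforced split points so that shape comparison sees separated segments.
A constant trace maps to the middle letter (no variance to normalise).

`mindist()` is the standard SAX lower bound on the Euclidean distance of
the z-normalised sources: letters at most one bin apart contribute
nothing; otherwise the gap between the nearer breakpoints. Sequences of
unequal length are compared after linearly index-resampling the shorter
onto the longer (peaks differ in point count across samples). Two
consequences matter in practice: the distance is a *lower* bound, so a
noisy copy of the consensus shape scores 0 (never falsely flagged), and
only shapes differing by two or more bins at matched positions score at
all — the gate is deliberately coarse. The screening ceiling
(`mindist_ceiling`, 2.0) and the switch (`use_MINDIST`, off by default,
matching how the workflow is normally run) are both exposed; the source
never quantifies the ceiling, so the default was chosen as roughly one
two-bin disagreement across a third of a typical peak and documented
here.

## The peak walker

Detection is a bespoke local-maxima walk, not a model fit, because the
shapes it must admit (plateaus, shoulder bumps, tailing, partial zigzag)
defeat parametric deconvolution. Seeds are taken at the highest
unassigned intensity in the window, walking both flanks independently:

* strictly decreasing values are assigned to the peak;
* a non-decreasing stretch is tolerated up to `density_factor` (5) times
  the data density (median points per 0.1 min); the stretch is absorbed
  as soon as a value drops more than `intensity_factor_decrease` (40%)
  below the last assigned intensity — this is what lets a small shoulder
  bump live inside one peak;
* if the budget runs out first, the flank ends at the plateau start;
* a rise of more than `intensity_factor_increase` (40%) above the last
  assigned intensity starts a second counter; if the rise outlives
  `increase_density_fraction` (1/4) of the data density, the flank ends —
  the rise belongs to another peak.

Two numerical choices are ours. First, the walk stops when the intensity
reaches baseline + max(noise, 0.1% of the seed height above baseline):
on noiseless traces an exponential tail decreases forever and two distant
peaks' flanks would otherwise meet mid-baseline; on real traces the floor
is simply the noise band. Second, both flanks are walked independently —
a peak has two bounds.

Where two walks' bounds meet or overlap, `split_merged()` places an
enforced boundary at the intensity minimum between the apexes and
re-integrates both areas. Peaks below the intensity cutoff
(`minimum_cutoff_intensity_factor` = 0.001 of the tallest reference peak)
bypass splitting entirely: below that level fluctuating patterns are
tolerated rather than dissected. One geometric fact worth recording: two
equal Gaussians closer than two standard deviations sum to a unimodal
envelope, so "merged but bimodal" starts at roughly 3 sigma separation;
the splitter is validated there and at wider gaps.

Quantities are always computed on the raw trace — `integrate_area()`
(trapezoidal, inclusive bounds) refuses a smoothed EIC by contract.
Smoothing (`smooth_for_shape()`: linear interpolation to half the native
spacing, then a 5-point centred moving average) exists only for the
shape layer.

## Retention-time drift, three levels

1. **Batch-global.** Every IS is located in every sample over the full
   run; the mean apex displacement from the listed IS retention time is
   the global shift, and the largest absolute displacement becomes the
   search half-width — never below 0.5 min (LC) or 0.1 min (GC). The
   mean is applied as a centre offset during annotation; the maximum
   sizes the window. (The source leaves this combination open; using the
   mean as offset plus the maximum as half-width covers both the robust
   and the fully shifted cases.) The GC floor presumes GC-narrow peaks:
   the window floor must exceed the peak width, or the background window
   collapses onto the peak itself and the baseline quantile lands on the
   flank.
2. **Intensity-dependent.** Column overload makes high loads elute
   early. Apex retention time is regressed on log10 apex height over the
   calibration levels (log-response rather than concentration: the
   displacement scales with what the column sees). The trend is accepted
   only if the slope is negative, significant at p < 0.05, and no peak
   above LOD sits in the IS-only control inside the analyte window (the
   unspecific-peak veto); without a control the veto is unavailable and
   p < 0.01 is required.
3. **Per-sample.** The displacement of the assigned IS in that sample,
   measured against the IS's own consensus position over the annotation
   samples — not against the listed value, which would double-count the
   global shift. A missing IS falls back to zero shift.

The resolved window centres on the consensus retention time plus the
per-sample shift (plus the trend prediction once a height is measured)
and is trimmed to the reference-observed range extended by the
half-width. One override: a valid peak sitting exactly at the
*uncorrected* expected retention time (within one scan spacing,
`shift_exact_match_scans`) wins over the IS-derived shift — a
high-resolution match at the expected position outranks an inferred
correction.

## Screening decisions

Per analyte and sample, `screen_sample()` selects among detected peaks
the one nearest the shift-resolved expectation (ties to the taller) that
clears both the intensity cutoff and the in-sample LOD. No such peak
means NOT_DETECTED. A selected peak is DETECTED unless a gate fires, in
which case the area is still integrated but the hit is tagged CHECK:

* residual shift beyond max(consensus width, mode floor);
* MINDIST above the ceiling (only when enabled, and never when
  intensities at or above LOD sit within one consensus width of the
  expected position — near-expected signal tolerates bad shapes);
* `min_peak_points` or fewer points (7);
* an expected confirming ion missing: the confirmer is demanded only
  when quantifier height x expected ratio exceeds the confirmer's own
  LOD; it must then co-elute (apex inside the quantifier bounds) with a
  measured ratio within `confirming_ratio_tolerance` (20%).

CHECK counts as negative in fully unsupervised evaluation; a flag flips
it for supervised re-evaluation. All decisions are deterministic.

## Quantification

Responses (areas by default, heights by option) are divided by the
assigned IS response of the same sample; analytes without an IS fall
back to raw responses with a batch warning. The order of corrections is
blank subtraction, then matrix correction, then calibration — each
defined on what the previous step outputs.

* **Blanks.** If more than `blank_fraction_threshold` (1/3) of solvent
  blanks show a response, the blank mean is subtracted everywhere and
  samples not exceeding `blank_multiplier` (3) times the blank mean are
  masked-by-background.
* **Matrix.** The factor median(solvent)/median(matrix QC) multiplies
  sample ratios.
* **References.** Constant-concentration controls outside
  Q1 − 1.5 IQR … Q3 + 1.5 IQR are removed from recovery calculations
  (the 1.5 fence is the conventional choice; the source names only the
  IQR).
* **Calibration.** Six linear variants — through-origin or free
  intercept, each unweighted, weighted by x, or by 1/x, where x is the
  nominal concentration — are fitted and auto-trimmed: the level with
  the largest Cook's distance (computed from the variant's own hat
  matrix, including the no-intercept case) is dropped while the median
  quantification error falls *and* R² rises, never below
  `min_cal_points` (4) levels. The error is the median absolute percent
  deviation of back-predicted concentrations, recomputed on the retained
  levels at every step. Variants with R² ≥ `min_r2` (0.95) and error
  below `max_error_quant` (30%) compete on lowest error, then widest
  retained concentration range, then highest R². R² is computed about
  the mean for all variants so they compete on one scale. The retained
  extremes define the linear-range cutoffs; sample ratios outside them
  are reported as below/above calibration rather than extrapolated.
* **Recovery.** 100 x sample ratio / median ratio of the valid
  references.

One statistical fact documented rather than hidden: with multiplicative
response noise the top calibration level dominates every one of the six
weightings, so a single batch's slope estimate inherits roughly the full
noise SD. Slope recovery claims are therefore statistical — bias under
2% and median absolute deviation under 5% across seeded batches at 5%
noise — not per-batch guarantees.

## The synthetic test bed

`make_batch()` realises a declared batch: Gaussian or exponentially
modified Gaussian peaks (tailing exercises the plateau rules) on an
additive baseline with truncated Gaussian noise, optional zigzag
segments, co-eluting isomers on a shared channel, linear
response–concentration relations with optional saturation and blank
contamination, and batch-global, per-sample, per-compound, and
per-observation retention-time displacements. Defaults emulate the
screening conditions the workflow targets: calibration from 0.1 to
1000 ng/mL, LC-like peaks (sigma 0.04 min) sampled at 0.02 min (about
12 points across a peak — deliberately not oversampled, since apex
localisation in scan units is only meaningful at realistic sampling),
baseline 20 counts with noise SD 2, 5% multiplicative response noise.
Everything is seeded; identical seeds give identical batches.

What passing the synthetic suite shows: the walker, splitter, shift
model, gates, and calibration chain recover planted truth under noise,
drift, and interference of the declared kinds. What it does not show:
behaviour under real matrix chemistry — correlated noise, baseline
drift within a run, ionisation suppression varying with co-elution,
centroiding artefacts, or detector saturation beyond the simple
saturation law. Results on real batches remain parameter-dependent, and
the most influential parameter is the intensity cutoff factor, which
decides which intensity regime faces the splitter at all.

Problem sizes used throughout the tests (chosen as the smallest that
make the statistical claims meaningful): 200 traces for walker
recovery, 50 seeded batches for calibration statistics, and a
40-analyte x 8-sample batch (plus blanks, 8 calibration levels, 3
references, and an IS-only control) for the end-to-end screening and
quantification checks.

## Known limitations

* The GC window floor (0.1 min) is only sensible for GC-narrow peaks;
  wide peaks under a narrow floor corrupt the background quantile (see
  above).
* MINDIST is a coarse lower bound; it can only flag shapes differing by
  two or more bins and is off by default.
* Only linear calibration is implemented; strongly bent responses are
  trimmed to their linear range rather than modelled.
* Profile-mode mzML is rejected, not centroided.
* The walker's plateau budget is expressed in raw points, so extreme
  changes in acquisition rate within a batch would change its tolerance.
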