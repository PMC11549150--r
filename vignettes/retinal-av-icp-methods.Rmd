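---
title: "Methods: retinal A/V-ratio measurement and ICP analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retinal A/V-ratio measurement and ICP analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinaicp)
```

## The problem and the model

Invasive intracranial pressure (ICP) monitoring — an external ventricular
drain or an intraparenchymal probe — is accurate but carries surgical risk.
A candidate non-invasive surrogate is the retinal arteriole/venule (A/V)
ratio seen on fundoscopy: rising ICP impedes venous outflow, the venule
distends, and the A/V ratio falls. `retinaicp` implements the full analysis
chain for this idea on monochrome fundus video (nominally 1280 x 1024 pixels
at 15 frames/s): frame triage, optic-disc anchored quality scoring, vessel
segmentation, sub-pixel width measurement, time-matching to ICP, and a
hierarchical statistical analysis.

The measurement target is the **A/V area ratio**. With vessel cross-sections
treated as circular,

$$\mathrm{Area}_{vessel} = \pi\left(\frac{\mathrm{width}}{2}\right)^2,
\qquad
AV_{area} = \frac{(\mathrm{artery\ width}/2)^2}{(\mathrm{vein\ width}/2)^2}
          = \left(\frac{\mathrm{artery\ width}}{\mathrm{vein\ width}}\right)^2 .$$

Being a ratio of same-frame widths, $AV_{area}$ is dimensionless and needs no
millimetre calibration; all widths are reported in pixels.

The statistical model is a random-intercept linear mixed model. Patient $i$
contributes a baseline $b_i \sim N(\mu_b, \sigma_b^2)$ (patients differ in
their resting A/V ratio), and the population relation between A/V ratio and
ICP is piecewise linear with a knot at 15 mmHg — flat below, declining above:

$$AV_{ij} = b_i + \beta_{\le}\min(ICP_{ij}, 15) +
  \beta_{>}\max(ICP_{ij} - 15, 0) + \varepsilon_{ij},
  \qquad \varepsilon_{ij} \sim N(0, \sigma_w^2).$$

Stratified fits (ICP above/below 15 mmHg, ICP above/below the intraocular
pressure IOP) estimate the slope separately per stratum; two slopes are
compared with a two-sample z (Wald) test using the pooled standard error
$\sqrt{se_1^2 + se_2^2}$ and normal 95% intervals ($\pm 1.96\,se$). The
intraclass correlation $\mathrm{ICC} = \sigma_b^2/(\sigma_b^2+\sigma_w^2)$
quantifies how much variance is between-patient; a sensitivity analysis
treats "A/V ratio < 0.75" as a screening call for "ICP > 15 mmHg".

## Pipeline stages and their parameters

**Frame triage** (`classify_frame()`): a frame is a usable fundus view iff a
bright, circularly symmetric optic disc is detected (`detect_disc()`:
Gaussian smoothing at sigma 5 px, peak prominence at least 0.08 above the
median intensity, half-prominence region fully inside the frame) and the
Frangi vesselness response covers at least 2% of the disc crop. Constant or
pure-noise frames classify as `no_fundus`, never as errors.

**Quality scoring** (`tenengrad_score()`): mean squared Sobel gradient
magnitude over a square crop of side 1.5x the disc bounding box. The crop
factor 1.5 follows the source convention of scoring a disc-anchored
neighbourhood; we read "1.5 x height/width" as a square crop of 1.5x the
disc diameter, the most literal interpretation, and expose the factor as a
parameter. The score is offset-invariant and strictly decreasing under
defocus, so the argmax frame is the best-focused one; ties break to the
earliest timestamp.

**Alignment** (`align_to_reference()`): translation-only registration by the
FFT cross-correlation peak of mean-subtracted frames, gated by the Pearson
correlation of the shifted overlap (default minimum 0.3). Handheld-camera
jitter at 15 frames/s is dominated by translation; rotation/scale are out of
scope but the gate simply excludes frames they would corrupt. The returned
`(dx, dy)` is the shift *applied to the frame* to match the reference (the
negative of the underlying motion).

**Segmentation** (`segment_vessels()`): multiscale Frangi vesselness for
dark tubes (scales 1.5/2.5/4 px, beta 0.5, structureness constant at half
the per-scale maximum), hysteresis thresholding at 25%/8% of the maximum
response, a darkness gate (vessel pixels must sit at least 0.02 below the
median intensity — this suppresses the filter's ring response on the dark
side of the bright disc rim), disc-interior exclusion out to 1.3 disc radii,
and removal of components under 30 px. The trained segmentation networks of
clinical deployments are deliberately replaced by this classical operator:
the package's subject is the measurement geometry and statistics, which are
validated against phantom ground truth, not learned weights. Precomputed
binary masks can be supplied instead at every entry point.

**Width measurement** (`centerline()`, `perpendicular_widths()`,
`reject_outliers()`): each measurement point is cropped to a 128 x 128
patch; the mask patch is thinned to a 1-px skeleton (Zhang-Suen, implemented
here because no installed package provides thinning) and the longest
end-to-end path through the skeleton graph is taken as the centreline —
short side-spurs are bypassed by construction, and 5 px are trimmed from
each end where thinning artefacts concentrate. At each interior path pixel
the local tangent is estimated over +/-2 path points (after a 5-point running
mean irons out the staircase of the pixel skeleton), and an intensity
profile is sampled by bilinear interpolation along the perpendicular at
0.1 px steps over +/-32 px. The line width is the **full width at half
depth** of the profile (half-minimum for dark vessels; the mask-edge
half-crossing when measuring on masks) — the standard sub-pixel convention
when no width definition is otherwise fixed. Lines whose profile leaves the
patch are dropped. Outlier widths are flagged by the modified z-score
(|w - median| > 3 x 1.4826 MAD); when the MAD degenerates to zero the scaled
mean absolute deviation takes its place (the Iglewicz-Hoaglin fallback), so
a single wild width among ties is still caught, and all-equal widths flag
nothing. The mean over retained lines is the vessel width.

**Artery/vein labelling**: with phantom ground truth, by proximity to the
true centrelines; without it, by calibre — the wider vessel is the vein, the
standard anatomical rule for monochrome imagery. This is a documented
limitation: calibre can mislabel atypical anatomy, and a monochrome sensor
offers no colour cue.

**ICP matching** (`window_mean_icp()`): the reference ICP of a frame is the
arithmetic mean of all recorded samples in the closed window of 5 s each
side of the frame timestamp. "From 5 s before and after" is read inclusively;
boundary behaviour is unit-tested. No interpolation — only observed samples
are averaged, and an empty window excludes the observation rather than
imputing. IOP is a per-session scalar; rows without IOP drop out of the IOP
strata only.

**Statistics** (`fit_stratum()`, `compare_slopes()`, `model_summary()`,
`diagnostics()`, `implied_npv()`): strata are fit as separate
random-intercept models on subsets (not one interaction model), because the
published per-group table and the two-sample z test both assume independent
standard errors. Intervals are normal ($\pm1.96\,se$) throughout — that is
the arithmetic the published tables satisfy exactly. "ICP > 15" is strict,
"<= 15" inclusive, and likewise for the IOP split. The pooled summary fits
the piecewise (linear-spline) fixed-effect structure rather than a single
linear term: the stratified analysis asserts a flat-below/declining-above
relation, and a straight-line fixed effect would push the kink into the
residual and bias the ICC down. R-squared is the squared Pearson correlation
of conditional fitted values with observations — one of several mixed-model
conventions, chosen to match "variance explained by the predicted values" —
and the ICC standard error uses Fisher's large-sample formula with the mean
cluster size. The ROC AUC is the midrank (Wilcoxon) statistic, computed via
pROC and cross-checked in the tests against a brute-force pairwise oracle;
`implied_npv()` inverts Bayes' rule to check that printed sensitivity,
specificity and PPV are mutually consistent with an NPV at a solvable
prevalence. Random slopes are available behind the random-intercept default;
no multiplicity correction is applied, matching the analysis this package
reproduces.

## What the synthetic generators emulate

**Fundus phantoms** (`frame_phantom_spec()`, `render_frames()`): a bright
disc (soft 3 px edge) and one arteriole/venule pair drawn as constant-width
quadratic curves leaving the disc rim at +/-28 degrees, on a mid-grey
background; per-frame integer rigid shifts up to `motion_amplitude`; optional
Gaussian defocus and sensor noise; a configurable fraction of pure-noise
(non-fundus) frames. Vessel edges are linear ramps whose half-depth point
sits exactly at width/2 from the centreline, so the drawn full width at half
depth *is* the nominal width and blur (symmetric, narrow relative to the
vessel) moves it only negligibly. The phantom deliberately omits
photorealism: no vascular tree, no papilledema, no pulsatility or
cardiac-cycle variation, no reflectance structure. Passing phantom tests
therefore validates the measurement geometry — not robustness to real-world
contrast, glare, or miosis-degraded optics.

**Synthetic cohorts** (`cohort_spec()`, `generate_cohort()`): the generator
realises exactly the random-intercept piecewise model above, so the
statistical layer can be scored on parameter recovery. Defaults are
calibrated once to the published cohort summaries and kept fixed:
ICP ~ N(10.9, 5.7^2) clipped to [-1, 31] mmHg (ICP may be negative; there is
no floor at zero), IOP ~ N(7.4, 2.1^2) clipped to [4, 13] mmHg drawn once
per session, above-knot slope -0.0659 A/V units per mmHg and 0 below,
15 patients x 2 sessions x 250 points (echoing 32 sessions and ~7.8k points
over 15 patients). Variance components default to sigma_b = 0.08,
sigma_w = 0.10, giving ICC = 0.39 to match the published intraclass
correlation. The baseline A/V mean is 1.2: at the published slope, an ICP of
31 mmHg lowers A/V by ~1.05, so a baseline near the 0.75 diagnostic cut-off
would pin much of the range against the positivity clip and distort every
slope; 1.2 keeps the piecewise relation linear across the whole calibrated
ICP range. Range enforcement is by clipping, not resampling, so the seeded
random stream stays aligned between specs that differ only in ranges.

Session counts and points per vessel are free parameters — the source
analysis does not state how its ~7.8k points distribute over sessions and
measurement points, so the defaults above are one realistic choice, not an
inference.

## Numerical choices and degenerate inputs

* Pixel coordinates are 1-based `(x = column, y = row)`, origin top-left —
  the idiomatic R convention for matrices (a deliberate departure from
  0-based conventions common elsewhere).
* Patch crops clamp at borders and record their origin; frames smaller than
  the patch are errors.
* Reference-frame ties break to the earliest timestamp; registration shifts
  are integer pixels with constant fill; sub-threshold correlation marks a
  frame unaligned instead of guessing.
* Profile background is the median of the outer quarters of each profile;
  dips shallower than 0.05 are not measured; polarity (dark vessel vs bright
  mask bar) is auto-detected per profile.
* `reject_outliers()` needs at least 3 lines; `fit_stratum()` needs at least
  2 patients and 3 observations and errors naming the stratum otherwise
  (one patient leaves the random intercept unidentifiable); zero-variance
  noise-free cohorts are fit to machine precision but may emit singular-fit
  warnings.
* `diagnostics()` requires both ICP classes; `implied_npv()` errors when no
  prevalence in (0, 1) is consistent with its inputs.
* Seeds: every generator consumes a single integer seed; identical spec +
  seed is bit-identical output.

## Problem sizes used in the tests

The suite renders phantoms of 320 x 256 to 720 x 600 pixels with vessel
widths 4-20 px, and simulates cohorts of 6-20 patients with up to 10,000
observations; the slope-recovery experiment runs 100 seeded replicates of
the default 15 x 500 cohort and the ICC recovery averages 50. These sizes
were chosen so the whole suite exercises every stage end to end in well
under typical package-check budgets while keeping Monte-Carlo error small
relative to the tolerances tested.

## Known limitations

* The classical disc detector and segmenter are tuned to phantom-like
  contrast; real NICU fundus video (miosis, glare, defocus) would need the
  learned components they stand in for, or manual masks.
* Artery/vein disambiguation by calibre fails for atypical anatomy.
* Translation-only alignment ignores rotation and scale changes.
* The ICC standard error is a balanced-design approximation using the mean
  cluster size.
* The clinical headline numbers of the source analysis (its regression
  table, ICC, R-squared, F, AUC, sensitivity/specificity on ~7.8k real
  points) depend on undeposited patient data; this package demonstrates
  *recovery of generating parameters* under its own calibrated simulator and
  *arithmetic consistency* of the published tables, which is all a
  desk-scale reimplementation can honestly claim.

```{r, eval = FALSE}
# End-to-end example at the default calibration
coh <- generate_cohort(cohort_spec(seed = 1))
fit_all_strata(coh)
model_summary(coh)
diagnostics(coh)
```
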