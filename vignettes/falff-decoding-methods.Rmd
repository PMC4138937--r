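---
title: "Decoding resting states from fALFF patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding resting states from fALFF patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Whether a subject is resting with eyes closed (EC) or eyes open (EO) changes
the spatial pattern of spontaneous low-frequency BOLD fluctuations. This
package implements an analysis that asks whether the two states can be
*decoded* from that pattern: per-region fALFF values are computed for both
conditions, regions whose fALFF differs between conditions are selected with
a paired Wilcoxon signed-rank test, and a linear support-vector classifier
is trained to predict the state of held-out recordings. Because the original
cohort data were never deposited, the package also ships a seeded synthetic
resting-state generator so that every stage runs against data with known
ground truth.

# The amplitude metric

For a detrended series $x_t$ sampled at interval $TR$, the one-sided FFT
amplitude at frequency $f_k = k/(N \cdot TR)$ is the square root of the
spectral power, scaled so the squared amplitudes sum to the time-domain sum
of squares (Parseval). ALFF is the amplitude sum over the low band
(0.01–0.08 Hz); fALFF is that sum divided by the amplitude sum over the
entire measurable range (up to the Nyquist frequency $1/(2 \cdot TR)$,
0.25 Hz at $TR = 2$ s), excluding the DC bin.

Numerical conventions, fixed so results are bit-stable:

* **Sum, not mean, over bins.** The numerator and denominator aggregate
  amplitudes by summation, which makes fALFF a fraction in $[0, 1]$; the
  ratio-of-means convention is available via `method = "mean"` and differs
  exactly by the bin-count ratio.
* **DC excluded.** Series are detrended (hence demeaned), so the 0 Hz bin
  carries no information; excluding it from the denominator makes the
  $[0,1]$ bound exact.
* **Half-open band edges.** A bin belongs to the low band iff
  $0.01 \le f_k < 0.08$; the full band runs over $0 < f_k \le$ Nyquist.
  At $TR = 2$ s and 230 analysed volumes this is 32 in-band bins of 115.
* **No tapering.** The FFT is taken on the raw detrended series.
* **Degenerate input.** A series that is identically zero after detrending
  has no defined fraction; fALFF is `NA` (flagged missing), never $0/0$.

For Gaussian white noise the expected fALFF is approximately the in-band
bin fraction $32/115 \approx 0.278$; the exact amplitude-weighted
expectation (Rayleigh-mean interior bins, half-normal Nyquist bin) is
$\approx 0.279$, which the test suite verifies by Monte Carlo.

In volumetric mode, fALFF maps are smoothed (6 mm FWHM Gaussian, separable
convolution with border renormalisation so constant maps are preserved),
normalised by the within-mask global mean (masked mean exactly 1
afterwards), and averaged over 5 mm ROI spheres (the source analyses never
state a radius; 5 mm is configurable). The order — fALFF, then smoothing,
then global-mean normalisation — follows the original processing
description. The ROI-level path, which the classifier actually consumes, is
the default.

# Feature selection

Per region, the per-subject paired differences (EC − EO, pairing strictly
by subject id) enter a Wilcoxon signed-rank test: exact zero differences
are dropped, tied magnitudes receive midranks, and the positive rank sum
$W^+$ is standardised as

$$Z = \frac{W^+ - n(n+1)/4}{\sqrt{n(n+1)(2n+1)/24 - \sum_g (t_g^3 - t_g)/48}}$$

with no continuity correction; positive $Z$ means higher fALFF with eyes
closed. The published description calls this a "two-sample" test, but the
design is within-subject and only the paired reading yields one Z per
region from 24 paired observations, so the paired test is what is
implemented. Fewer than 5 non-zero pairs is an error (the normal
approximation is meaningless there); all-zero differences give a flagged
$Z = 0$. Against exact enumeration of all sign assignments, the
normal-approximation two-sided p agrees with the exact mid-p within 0.037
at $n = 5$–$6$ and within 0.03 from $n = 7$ up (for $|Z| \le 2.5$) —
bounds frozen from the enumeration oracle itself.

Four selection criteria define the discriminative patterns: $|Z| > 1.96$,
$Z > 1.96$, $Z > 2.25$, $Z < -1.96$, all strict inequalities. Patterns are
ordered by descending $|Z|$ with ties broken by template order, so feature
vectors are deterministic. Applied to the bundled 28-region published
reference pattern, the criteria select 28, 21, 13 and 7 regions, and the
$Z > 1.96$ pattern is 18/21 ≈ 86% sensorimotor. No multiple-testing
correction is applied (matching the source procedure); an FDR flag is a
deliberate non-feature at this stage. Two reference rows carry coordinates
that duplicate earlier rows — an apparent typographical defect in the
source table — and are reproduced verbatim with a `note` flag rather than
silently corrected.

# Classification

Samples (one per subject per condition, EC = +1, EO = −1) are randomly
halved *per condition*, reproducing the original scheme even though it can
place one subject's EC in training and EO in test; `split_by_subject()`
provides the leak-free alternative. The classifier is a linear soft-margin
SVM (LIBSVM via e1071) at $C = 1$ — the toolbox default, declared since the
source names no value — without feature standardisation. The primal weight
vector is extracted so the decision function $d(x) = w \cdot x + b$ is
explicit; ties at $d = 0$ predict EC. Accuracy is the percentage of correct
test labels; the ROC curve is swept over the observed decision values (tied
values form one step) and AUC is its trapezoidal area, which equals the
Mann–Whitney statistic of the decision values (tested).

## Circularity of whole-cohort selection

The original procedure selects features using *all* subjects before the
train/test split. This is statistically circular: under pure-noise cohorts
(effect size 0) the procedure still decodes at roughly 70% mean accuracy,
because the chance regions that pass $|Z| > 1.96$ on the full cohort carry
the same chance signal into the test half. The package reproduces the
procedure by default because fidelity comes first, but it makes the bias
measurable: `decode_nested()` performs selection inside the training half
only (with a subject-stratified split, since nested selection needs paired
training subjects) and is calibrated at 50% under the null. Calibration
claims in the tests and in the acceptance report therefore use the nested
route; the circular null accuracy is reported alongside it as a measured
quantity, not asserted to be chance.

# The synthetic cohort generator

The generator emulates the study geometry: 24 subjects × 2 conditions,
$TR = 2$ s, 240 volumes with the first 10 discarded downstream (the
generator is a pure acquisition model; trimming is a pipeline step). Each
region's series is

$$x(t) = a_s \, g_{rc} \, \frac{1}{\sqrt{K}}\sum_{k=1}^{K}
\sin(2\pi f_k t + \phi_k) \; + \; \text{pink}(t) + \varepsilon(t)$$

* $K = 5$ oscillation frequencies are drawn uniformly **from the DFT grid
  of the trimmed window** within 0.01–0.08 Hz. Drawing from the continuum
  would leak up to half of an edge tone's power outside the band and make a
  clean band-limitation property unattainable; on-grid tones stay exactly
  in band, and remain on-grid after trimming because dropping leading
  samples only shifts their phase.
* $g_{rc} = 1 + $ `effect_size` in effect regions under EC, else 1 — the
  EC > EO direction that dominates the sensorimotor findings.
* $a_s$ is a lognormal per-subject amplitude factor (sdlog 0.2) shared by
  both of a subject's recordings, so the paired design is meaningfully
  easier than an unpaired one, and between-subject variance is realistic.
* pink noise is white noise whose spectrum is shaped by $f^{-\beta/2}$
  ($\beta = 1$) and inverted, unit variance by construction; white noise
  has sd `noise_sigma`.

Noise levels (`noise_sigma = 1`, `pink_sigma = 1`, oscillation amplitude 1)
were calibrated once by Monte Carlo so that an `effect_size` of 1.0 planted
in 10 regions is recovered ($\ge 8$ of 10 at $|Z| > 1.96$) in well over 90%
of replicates at $n = 24$, then frozen. Under the null the $|Z| > 1.96$
selection rate is ≈5%, as it should be.

What the generator does *not* emulate: hemodynamic response shape, head
motion, physiological noise regressors, spatial autocorrelation between
regions, or non-stationarity. Passing tests therefore demonstrate that the
pipeline is correct and calibrated on band-limited signals in stationary
noise — not that real scanner data would yield the published accuracies,
which are in any case unreproducible without the undeposited cohort.

The bundled 160-region template is likewise *synthetic*: the original
meta-analytic coordinate table is not redistributable here, so
`synthetic_template_160()` generates a deterministic stand-in with
realistic module sizes (default 34, fronto-parietal 21, cingulo-opercular
32, sensorimotor 33, occipital 22, cerebellum 18). Real coordinate tables
load through `read_roi_template()`.

# Problem sizes in the tests

The test suite and the acceptance script regenerate everything from seeds:
white-noise calibration uses 10,000 (tests) / 4,000 (script) draws of
230-sample series; the null and effect studies use 100 (tests) / 25
(script) replicate cohorts of 24 subjects over the 160-region template.
These sizes give Monte-Carlo standard errors comfortably inside the
asserted bands while keeping a full run in a few minutes.

One consequence of global-mean normalisation is worth knowing when reading
synthetic results: it couples regions. Planting positive EC > EO effects in
a few regions raises the EC global mean, which *depresses* the normalised
fALFF of every other region under EC — so some negative-direction
selections on effect cohorts are induced signal, not pure chance, and the
$Z < -1.96$ pattern decodes above chance there. The same mechanism operates
in real normalised data.

# Known limitations

* The published per-criterion accuracies (85/84/88/63%) are not targets:
  they came from one undeposited cohort and a single random split, and the
  whole-cohort selection inflates them by an amount the nested audit can
  only estimate on synthetic data.
* The reference table's repeated Z values (2.92 ×6, 2.50 ×6, 2.09 ×8) have
  a granularity a continuous paired signed-rank on $n = 24$ would not
  naturally produce; the package treats them as given inputs for the
  worked example and does not attempt to regenerate them from simulation.
* Volumetric mode paints ideal spheres on a regular grid; there is no
  partial-volume handling or anatomical masking beyond the sphere union.
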