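---
title: "Methods: metrics, pre-processing and the synthetic evaluation study"
author: "moqam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metrics, pre-processing and the synthetic evaluation study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(moqam)
```

`moqam` evaluates how well scalar image quality metrics (IQMs) computed on
motion-corrupted brain MR volumes agree with observer quality scores, and how
sensitive that agreement is to the pre-processing surrounding the metric
computation. This vignette documents the models and procedures, the choices
that were genuinely open and how they were resolved, the numerical edge
cases, and what the synthetic study can and cannot show.

## The evaluation pipeline

A volume is evaluated slice-wise along a configurable axis (default the
third array axis; the toolbox deliberately does not guess an anatomical
orientation). The pipeline for one image under one `pipeline_config()` is:

1. **Slice selection.** Only slices whose fraction of brain-mask-positive
   pixels (over all pixels in the slice) reaches `brain_fraction_threshold`
   (default 0.10) enter the analysis. This excludes peripheral slices whose
   near-empty content would otherwise dominate worst-slice reductions. The
   denominator is the total pixel count of the slice, not the total brain
   volume — the reading under which "10 % brain voxels" is a per-slice
   coverage statement.
2. **Normalization** (volume-wise): `none`, `minmax`
   (`(x − min)/(max − min)`), `meanstd` (z-score `(x − mean)/sd`), or
   `percentile` (`(x − p1)/(p99.9 − p1)`, clipped to `[0, 1]`).
3. **Mask mode:** `none` (mask ignored), `multiply` (image and reference
   multiplied by the binary mask, zeroing the background), or `mask`
   (intensities untouched, but metric aggregation restricted to
   mask-positive pixels).
4. **Per-metric range rescaling** (`[0, 1]` mapped affinely onto the
   metric's required input range, e.g. `[−1, 1]` for the perceptual
   distance), per-slice metric computation, and
5. **Reduction** across slices: `mean`, or `worst` — the minimum for
   higher-is-better metrics and the maximum for lower-is-better ones, i.e.
   the most degraded slice, which matches how radiologists are typically
   instructed to score a volume.

Three open points were resolved as follows, and are exposed as parameters:

- *"Mean divided by standard deviation"* is implemented as the z-score
  `(x − mean)/sd`, the conventional reading; a literal `mean(x)/sd(x)` would
  collapse each volume to a constant and could not produce matched
  image/reference histograms.
- *Normalization domain.* Statistics are computed over the evaluation domain
  implied by the mask mode: mask-positive voxels for `mask`/`multiply`, the
  full volume for `none`. In brain images the background often exceeds 60 %
  of the voxels, so computing a minimum or percentile over the full volume
  would let the background dictate the scaling — exactly the failure mode
  the grid is meant to expose, and still observable by choosing
  `mask_mode = "none"`.
- *Percentile clipping.* Values outside `[p1, p99.9]` are clipped to
  `[0, 1]` after rescaling, because downstream range contracts (FSIM/VIF
  require `[0, 1]` or `[0, 255]`) are hard constraints.

### Availability contract

FSIM, VIF and the perceptual distance require inputs on a fixed range, which
only min-max and percentile normalization produce, and they operate on whole
2D slices (frequency-domain filtering, pyramid decompositions, convolutional
features), which is incompatible with restricting computation to an
irregular mask-positive pixel set. They are therefore *available* only for
`norm_mode ∈ {minmax, percentile}` and `mask_mode ∈ {none, multiply}`. An
unavailable cell yields a structured result with a machine-readable reason
("range requirement" / "mask-mode requirement"), never a number, and never a
silently dropped row. Degenerate slices (no edges, zero gradient energy)
yield missing per-slice values that are skipped by both reductions, with the
number of slices actually used reported alongside every result.

## Metric implementations

- **SSIM**: 11×11 Gaussian windows (σ = 1.5), `c1 = (0.01 L)²`,
  `c2 = (0.03 L)²`. Local statistics are computed on fully interior windows
  (no padding), so border pixels never contribute half-windows. Within the
  pipeline, the dynamic range `L` is the intensity range of the normalized
  reference over the evaluation domain (≈ 1 after min-max/percentile).
- **PSNR**: `10 log10(max(x̂)²/MSE)` with the peak taken from the reference
  slice over the evaluation domain, not a fixed nominal range. Identical
  slices return `+Inf` with a warning rather than an error, so severity
  ladders that include an exact copy remain usable.
- **FSIM**: phase congruency from a log-Gabor filter bank (4 scales, 4
  orientations, minimum wavelength 6, multiplier 2, σ_onf = 0.55, angular
  spread σ = π/4/1.2) with phase-deviation energy, a Rayleigh-model noise
  threshold estimated from the smallest-scale amplitude, and a sigmoid
  frequency-spread weight; gradients from the Scharr operator; stability
  constants T1 = 0.85 and T2 = 160 on the `[0, 255]` convention (inputs on
  `[0, 1]` are rescaled internally; images are average-pooled so the
  shorter side is at most ~256 pixels, matching common practice).
- **VIF**: the multi-scale *pixel-domain* variant — a 4-level Gaussian
  pyramid, window size `2^(5−scale)+1`, Gaussian-scale-mixture source with
  an additive-noise channel, visual-noise variance `sigma_nsq = 2` on the
  `[0, 255]` convention. The pixel-domain variant reproduces the
  wavelet-domain original closely while avoiding a wavelet dependency.
  Note that VIF exceeds 1 only when the test image *amplifies* information
  relative to the reference (e.g. contrast enhancement, `g > 1` in the
  channel model); a test image that is merely cleaner than a noisy
  reference still yields VIF < 1, because the reference is the modelled
  source — the toolbox implements the original definition rather than the
  folk reading.
- **Perceptual feature distance**: LPIPS-style — multi-layer feature maps,
  per-pixel channel unit-normalization, squared differences averaged over
  pixels and channels, summed over layers. The bundled extractor is a
  3-layer random-weight CNN (He-scaled Gaussian weights drawn from a seed,
  ReLU, 2×2 mean pooling, channels 8/16/32), fully reproducible and
  requiring no download; pretrained backbones can be plugged in through
  the same `feature_extractor` interface. Distances are comparable only
  within one extractor; they are *not* comparable to published LPIPS
  numbers. Slices must be at least ~24 pixels on a side for three layers.
- **Reference-free metrics**: gradient magnitudes use the normalized Sobel
  operator (unit response to a unit ramp; central differences available);
  edges for AES use a Canny-style detector (Gaussian σ = 1, non-maximum
  suppression, hysteresis thresholds at the 70th/90th percentiles of the
  positive gradient magnitudes) — the detector is configurable because no
  standard choice exists. IE and GE use root-energy normalization
  (`y = x/sqrt(Σx²)`), with `0·ln 0 = 0`; since mean-std normalization
  creates negative intensities, IE uses `|x|` so it remains defined on
  every grid cell.

## Agreement statistics

Observer scores (1–5 Likert; 5 = artifact-free) are fused per image as a
weighted mean over non-missing raters, with a double weight on radiologists
relative to radiographers by default. Inter-rater reliability is
Krippendorff's alpha from the coincidence matrix of pairable values, with
nominal/ordinal/interval distance functions; the **ordinal** level is the
default, being the appropriate choice for Likert data (the level is a flag,
since reliability coefficients are routinely reported at several levels).
Missing cells are excluded pairwise; items with fewer than two ratings do
not contribute; if every pairable value is identical the expected
disagreement is zero and alpha is defined as 1 with an explanatory note.

Metric–observer agreement is the Spearman rank correlation (average ranks on
ties) between metric values and fused scores, per metric and optionally per
group (MR sequence). P-values come from `stats::cor.test` (exact for small
samples without ties, t-approximation otherwise); the `significant` flag
uses a two-sided α = 0.05 with no multiple-testing correction, matching
per-cell reporting practice (a Holm correction can be applied downstream
from the returned p-values). Lower-is-better metrics are expected to
correlate *negatively* with scores; signs are preserved in all outputs, and
the league table ranks metrics within each group by descending |rho|
(average ranks on ties) and reports the median rank across groups.

## The synthetic study

`generate_study()` makes the full evaluation reproducible with no external
data. Per subject it builds an ellipsoidal head phantom (bright skull rim,
brain compartment defining the mask, ventricles and deep-gray structures,
smooth Gaussian-filtered texture, exactly zero background; the brain
occupies well under 40 % of the voxels so the background dominates, as in
real skull-stripped acquisitions), then corrupts it at each severity of the
ladder and simulates a rater panel.

- **Motion model.** Discrete rigid movement events assign contiguous
  phase-encode segments (first in-plane axis) of each slice's k-space the
  signal of an in-plane rotated/translated object, producing the
  ghosting/ringing characteristic of head motion; the DC line always
  belongs to the unmoved object, and the output is the magnitude image.
  Severity scales the *amplitude* of a fixed per-subject trajectory
  (3 events, up to 3° rotation and 3 mm translation per unit severity),
  so a subject's ladder is strictly comparable and severity 0 reproduces
  the input bit-exactly. Distinct motion types (nodding vs. shaking) are
  not modelled — the artifact class the metrics see is ghosting either way.
- **Raters.** Latent quality `q = 5 − 2·severity` clipped to `[1, 5]` (the
  slope 2 makes the default ladder {0, 0.5, 1, 2} span the full score
  range), plus zero-mean Gaussian noise per rater (default SD 0.35 for the
  two radiologists, doubled for the two radiographers, reflecting reading
  experience), rounded to the Likert grid. Radiologists carry fusion
  weight 2, radiographers 1.
- **Determinism.** All randomness flows from one master seed via sub-seeds
  drawn once (`sample.int` after `set.seed(master)`); regeneration is
  byte-identical, and the study exercises every cell of the
  mask × normalization availability grid in the test suite.

**Default problem sizes.** Phantoms are 64×64×32 voxels (32³ in most unit
tests) and the default study is 10 subjects × severities {0, 0.5, 1, 2} —
40 volumes. These sizes give stable rank correlations (|rho| ≈ 0.9 for the
reference-based metrics against simulated scores) while keeping a full
study run in the order of half a minute on one CPU.

**What the synthetic study does not show.** The phantom has no coil
profiles, relaxation contrast, sequence-specific artifacts, anatomical
variability or registration error; rater noise is unbiased and
uncorrelated across raters, unlike real panels. Passing the synthetic suite
therefore demonstrates that the *machinery* (pipeline contracts, metric
definitions, statistics) is correct and that metric responses propagate
with the right signs under a controlled corruption — it does not certify
how any metric ranks on real acquisitions. One instructive example: image
entropy's response to in-brain ghosting after masking and percentile
normalization is content-dependent and can move opposite to its nominal
direction, echoing the weak and inconsistent correlations reference-free
metrics show on real data; the tests therefore assert its direction only
where the construction guarantees it (additive noise on raw slices).

## Numerical notes

- 2D convolutions use exact shift-and-add summation (no FFT round-off), so
  SSIM agrees with a literal windowed-formula evaluation to 1e-10 and the
  entropies with pixel-loop evaluation to 1e-12.
- Masks are binarized at 0.5 to tolerate interpolated masks from upstream
  registration; binarization is idempotent.
- Array indexing is 1-based throughout, as in R; slice indices in outputs
  refer to positions along the configured slice axis.
- Degenerate inputs fail loudly and specifically: constant volumes under
  scaling normalizations, empty masks, empty slice selections, all-zero
  PSNR references, and zero-variance VIF references each raise a classed
  error; degenerate *slices* inside a batch become missing values instead,
  so one flat slice cannot sink a volume.
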