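---
title: "Methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

furatrack implements the quantitative analysis of a correlative imaging
assay on primary T cell–macrophage co-cultures: dual-excitation (340/380 nm)
Fura-2 time-lapse imaging of T cells perfused over antigen-presenting
macrophages, single-cell calcium signature classification, motility
analysis around the calcium maximum, multivariate separation of responder
phenotypes, quantification of marker accumulation at the cell–cell
interface, and flow-cytometry conjugate readouts. This vignette documents
the models, every tunable parameter that matters, and the design decisions
taken where the published description leaves the operational details open.

## 1. The ratio stack and trace extraction

The 340:380 intensity ratio increases monotonically with cytoplasmic free
calcium and is independent of dye loading, which is why the ratio — not
either channel — is the measured signal. `compute_ratio_stack()` divides
the channels pixel-wise and masks pixels whose 380 nm intensity does not
exceed `bg_threshold`.

Numerical choices:

* **The 0.5/2.0 clip is display-only.** Measured maxima exceed 2.0 (the
  'high' class is partly defined by exceeding 2), so clipping the measured
  ratio would destroy the signal the classifier needs. `render_display()`
  maps ratio 0.5 to 0 and 2.0 to 65535 linearly with clamping, then applies
  a 16-entry false-color look-up table; measurements always use the raw
  ratio.
* **Background masking is opt-in** (`bg_threshold = 0` by default, so only
  zero-denominator pixels are masked): no background subtraction is part of
  the published processing, and masking should never silently change a
  measurement.
* **Pixel convention:** 0-based indices, pixel centres at integer
  coordinates, x right / y down; micrometre positions are converted with
  `pixel_size_um` and rounded to the nearest pixel centre.
* **Circular ROI membership:** a pixel belongs to the extraction ROI iff
  its centre lies within `roi_diameter_px / 2` of the ROI centre — no area
  weighting, so the pixel set is deterministic and matches an integer
  enumeration oracle exactly. The manual tracker's 20-pixel "point size" is
  read as a **diameter**; it is exposed as `roi_diameter_px` for anyone who
  prefers the radius reading.
* Samples whose ROI is entirely masked or out of bounds are flagged
  `dropped`, never errors: a track walking off the field is data, not a
  bug.

## 2. The thirteen per-cell measures

Tracks shorter than 5 minutes are excluded (inclusive boundary: exactly
300 s is kept). The baseline is the median of the pooled samples of the ten
tracks with the smallest ratio range; "median value of ten tracks" could
also be read as a median of per-track medians, so that variant is exposed
(`method = "per_track_median"`) but pooling is the default as the most
literal reading.

* **R2B (returns to baseline)** counts downward crossings of the
  `(1 + 0.20) × baseline` level. "Within 20% of the baseline" is read
  one-sided (from above): calcium excursions are positive, and a ±20% band
  would count noise dips below baseline as returns.
* **AUC** is the trapezoidal integral of `max(r(t) − baseline, 0)` divided
  by track duration. The positive part is used because an "area between
  curve and baseline" for a signal that can dip below baseline should not
  let dips cancel rises; a signed variant is available (`signed_auc`).
* **t_max** is the *first* sample attaining the maximum (onset semantics on
  plateaus).
* **Mobile fraction** uses a 2 µm/min speed threshold on per-step speeds.
* **Pre/post ratios** split the track at t_max with the t_max sample
  terminating the pre segment and starting the post segment. A zero
  denominator yields `NA`, never infinity. Tracks with fewer than three
  samples on either side are flagged `excluded_few_points`; the flag
  applies only to the four ratio measures — the other nine are still
  reported, matching the scope of the original exclusion.
* **Matched controls:** each acute cell (max ratio ≥ 1) is paired to the
  unused basal cell (max ratio ≤ 1) with the closest t_max, processing
  acute cells in ascending t_max, ties resolved to the lower track id.
  Basal cells are split at their **own** t_max (each cell is its own
  flow-history control); splitting the basal cell at its partner's t_max is
  available via the feature table if wanted, but the own-maximum reading is
  the default because the measure is defined per cell. Note the greedy
  pairing is not globally optimal — it beats random pairing on aggregate
  (and in ~94% of random instances) but not on every draw.

## 3. Signature classification

The published classification was visual and blinded; the classifier makes
it operational with declared thresholds (`classifier_params()`):

| parameter | default | meaning |
|---|---|---|
| `responder_threshold` | 1.0 | population responder cut on max ratio |
| `high_onset` | 1.5 | onset level of the sustained 'high' rule |
| `high_sustain` | 1.0 | level that must be held after onset |
| `high_absolute` | 2.0 | max ratio that is 'high' outright |
| `rise_band` | +20% of baseline | what counts as a rise / a return |
| `spike_max_frames` | 2 | longest excursion still called a spike |
| `sustain_tolerance_frames` | 0 | dips tolerated by the sustained rule |

Rule order: flat (no rise) → high (absolute or sustained) → transient
(rise with a return) → low (everything else). Two declared choices:
"no rise or sharp spikes" is operationalized by treating excursions of at
most `spike_max_frames` frames as spikes that do *not* disqualify flatness
(otherwise the definition contradicts itself), and rise detection is tied
to the baseline (relative band) rather than to the absolute responder
threshold because baselines vary between fields of view. "Sustained above 1
for the duration of the experiment" is evaluated strictly from the first
crossing of 1.5 to the end of the track; the tolerance parameter exists
because real traces blink.

Population statistics use Fisher's exact test (two-sided,
minimum-likelihood method) and the Mann–Whitney U test (midrank ties; exact
p for ≤ 8 per group without ties, tie-corrected normal approximation
otherwise), with no multiple-testing correction, matching the original
analysis.

## 4. PCA and LDA

Both run on column-wise z-scored measures (`scale_features()`; sample sd,
zero-variance columns dropped with a warning). `run_lda()` solves the
generalized eigenproblem on between/within scatter directly, giving at most
3 discriminants for 4 classes, scaled to unit within-class variance.

* **Priors are proportional** to class frequencies by default — the classes
  are highly imbalanced (most cells are flat) and equal priors would
  misstate the base rates; equal priors are one argument away.
* **Accuracy is resubstitution** (predict the training data), since the
  original class-prediction plots mention no cross-validation. Both overall
  and per-class agreement are reported, because "97.6% correctly
  classified" can be read as either the 'high'-class agreement or the
  overall rate — the result object contains both so either comparison can
  be made against an externally supplied measures table
  (`read_calcium_measures()`).
* A ridge of `1e-8 × mean(diag(W))` is added to the within-class scatter
  only when it is numerically singular, and the result records that it
  happened.
* Loadings/scalings are oriented so the largest-magnitude element is
  positive; eigen-solver rank tolerance is 1e-10.
* 95% confidence ellipses use the chi-square(2 df) quantile on the group
  mean and covariance; collinear groups are flagged degenerate.

## 5. Interface quantification

`membrane_profile_mfi()` measures the mean of pixels whose centres lie
within half the trace width (perpendicular distance) of the annotated
polyline — a deterministic analogue of a 10-pixel-wide manual membrane
trace, with each pixel counted once at self-overlaps. The accumulation
ratio assigns overlap pixels to the interface band and excludes them from
the rest band. MFI is the arithmetic mean of raw pixel values with no
background subtraction by default; adding a uniform offset provably pulls
the ratio toward 1, which is why background handling is the user's explicit
decision.

For permeabilized staining, four square ROIs (default 50 px = 3.37 µm) are
placed at the interface, away, and both sides. The original description
fixes neither the centre-to-ROI distance nor the sign convention of the
polarity axes, so these are declared: the offset defaults to one ROI size;
`front_back = %interface − %away`; `side_side = %side1 − %side2` with side1
at +90° from the interface direction. ROI membership is evaluated in the
rotated frame, so axis-aligned cases are exact and 90° rotations of image
plus annotation leave all outputs unchanged.

## 6. Flow cytometry

Gates nest: live (DAPI−) ⊇ conjugate (PKH26+DiD+) ⊇ signal (pulse width
> 100, excluding small double-positive debris from dye transfer). Conjugate
frequency is the double-positive share of live events. Relative calcium is
the Fluo-2 MFI of gated events in the first acquisition as a percentage of
the same gate in the tandem post-ionomycin acquisition; the original text
names the DiD+ gate for run one but gates its headline figure on the
conjugate/pulse-width selection, so the gate is selectable
(`gate = "signal"` default, `"conjugate"` alternative). MFI is the
arithmetic mean ("mean fluorescence intensity"), with a geometric option.
Quadrant thresholds are explicit configuration — the original gates were
set from compensation controls and never reported numerically — and inputs
are assumed compensated.

## 7. The synthetic world

The generator's defaults state the assay the pipeline was built for:
470 × 470 µm fields imaged every 10 s for 121 frames (~20 min), 107 T cells
(198 macrophages nominally present as unlabeled context), signature mixture
63% flat / 15% transient / 12% low / 10% high — the flat share is the
published +sAgs figure; the split of the remaining 37% is chosen once,
weighted toward transients as in the untreated condition, and not
revisited. Onset times are uniform on 60–600 s (clamped so every template
can still express its class before the movie ends). Trace templates: baseline
0.8; transient peak 1.3 decaying back with τ = 60 s; low sustained at 1.35
(below both 'high' criteria); high peak 2.2 decaying to a 1.4 plateau
(satisfying both). Gaussian ratio noise of sd 0.02 is the "default low
noise" condition; rendering noise (Poisson + read) is off by default so
unit fixtures are exact.

Motility is a persistent random walk: basal speed 15 µm/min (perfusion
pushes cells faster than autonomous crawling), per-frame heading change sd
0.5 rad, per-step speed CV 0.4. All 'high' cells and half the 'low' cells
arrest at onset. **Arrest is modelled as pure confinement** — the cell
keeps its step lengths but is re-aimed whenever it strays more than 4 µm
from the onset position. This deviates from a speed-drop-plus-confinement
model deliberately: the motility-ratio analysis this generator feeds found
*reduced Euclidean displacement with preserved track length and speed*
("corralling"), and a default speed drop would contradict the phenomenon
the pipeline is designed to detect. A speed drop remains available via
`arrest_speed_um_min`.

Rendering uses the forward model `E340 = B(x, y) · (0.5 + 0.5 c)`,
`E380 = E340 / c`, with `B` a Gaussian blob (σ = 2.5 µm, truncated at 3σ)
and `c` the true ratio: the 340 channel rises and the 380 channel falls
monotonically with calcium, and the pixel-wise ratio equals `c` exactly, so
ROI means reproduce the ground truth to machine precision without noise.
(An additive-pair model in which the two channels sum to a constant does
not satisfy the exact-ratio requirement, which is why this invertible form
is used.) Overlapping cells add in both channels and are located with
`collision_flags()`; extraction fidelity is guaranteed only on
collision-free samples, exactly as for a manual tracker facing touching
cells. Default pixel size is 0.92 µm (a 512 × 512 field), a compromise
between the camera sampling of the original assay and desk-scale memory.

The synthetic flow tables allocate event classes deterministically from the
configured fractions (8% conjugates by default, the published frequency;
relative calcium level 0.25, consistent with the published peak of roughly
a quarter of the ionomycin maximum) so that frequency readouts are exact
and only intensities are random.

**What the generator does not emulate** — and what a green test therefore
does not establish: photobleaching, focus drift, flow-speed gradients
across the chamber, cell division, shape changes and segmentation error,
spectral spillover, and any biology of real donor variation. The published
donor-dependent percentages (8 ± 3% conjugates, 63%/72% flat, and the
97.6% 'high'-class LDA agreement on n = 1391 real cells) are properties of
primary human cells; the synthetic suites check the *machinery* that
produced them (round-trip classification, oracle-exact measures, the
arrest signature, flat/high separability), not the numbers themselves. The
LDA route for the real measures table ships as
`read_calcium_measures()` + `run_lda()` for anyone holding that file.

## 8. Known limitations

* The TIFF codec is a minimal baseline implementation (uncompressed,
  little-endian, grayscale 8/16-bit and 8-bit RGB) — sufficient for this
  package's own files and typical microscope exports saved uncompressed,
  not a general TIFF library.
* Tracks are inputs: there is no segmentation, tracking, gap closing or
  drift correction here.
* Interface quantification works on single sections or user-chosen
  projections; no 3-D quantification or en-face ring analysis.
* Flow compensation/spillover correction is out of scope; event tables are
  assumed compensated.

## Worked example

```{r example}
library(furatrack)

cfg <- sim_config(n_tcells = 300, seed = 42)
sim <- simulate_tracks(cfg)
features <- compute_features(sim$tracks)
labels <- classify_traces(sim$tracks, attr(features, "baseline"))
signature_frequencies(labels$label)

acute <- features[features$max_ratio >= 1 & !features$excluded_short, ]
basal <- features[features$max_ratio <= 1 & !features$excluded_short, ]
pairs <- match_controls(acute, basal)

sx <- scale_features(as.matrix(features[!features$excluded_short &
        !features$excluded_few_points, c("mobile_fraction", "t_max_s",
        "pct_track_length_at_max", "r2b", "min_ratio", "max_ratio",
        "median_ratio", "auc_ratio", "length_ratio", "speed_ratio",
        "mi_ratio", "euclid_ratio")]))
run_lda(sx, sim$truth$label[match(rownames(sx), sim$truth$track_id)])
```
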