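---
title: "Methods: synthetic multi-scale navigation and photoacoustic sensing for pedicle drilling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic multi-scale navigation and photoacoustic sensing for pedicle drilling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padrill)
```

`padrill` models a two-scale guidance pipeline for pedicle screw drilling —
ultrasound-based global navigation plus in-situ photoacoustic tissue
sensing — entirely on synthetic data. This vignette documents the models,
the parameters that matter, the numerical choices, and what the passing
test suite does and does not demonstrate about real data.

## The spine phantom

Each vertebra is an analytic union of three solids in a right-handed mm
frame (x lateral, y anterior = drilling direction, z axial):

* an ellipsoidal **body** (semi-axes 18 x 14 x 11 mm at the top level),
* two cylindrical **pedicles** (outer diameter 3.5 mm, length 12 mm,
  centred 9 mm lateral of the midline), and
* box-like **posterior elements** (10 x 8 x 10 mm per side).

Every solid carries a cortical shell (default 0.25 mm) over a cancellous
core; the pedicle core is extended 2.5 mm into the body so the
pedicle-body junction is a continuous cancellous corridor rather than an
internal wall, which is what the anatomy looks like. The 3.5 mm pedicle
diameter is the tightest clinically relevant corridor; with the 1.44 mm
safe distance to cortical bone this fixes the shell thickness budget: a
core radius of 1.75 - 0.25 = 1.50 mm leaves a drill on the pedicle axis
0.06 mm of margin. That thin margin is deliberate — it is exactly the
regime the sensing component has to resolve.

Caudal levels grow by 8% per level and their posterior surface deepens by
1.6 mm per level, mirroring lumbar anatomy. This also matters technically:
it is the only cue by which a 2D ultrasound frame carries information about
which level it shows, so the level-classification head of the detector has
signal to learn from.

Surface point sampling, tissue-label rasterisation (background / muscle /
cortical / cancellous; voxel centres at `origin + (index - 1) * spacing`)
and every simulator are pure functions of their parameters and a seed.

## Drilling trajectories

`make_trajectory()` builds the three canonical paths through a pedicle, all
starting on the posterior bone surface:

* **CP** runs down the pedicle axis at 0.12 mm/s: clearance to cortical is
  the full 1.50 mm core radius, above the 1.44 mm threshold at every frame.
* **LMP** enters 0.55 mm lateral and tilts 1.5 degrees laterally at
  0.12 mm/s: during pedicle transit the lateral wall comes within
  0.4-0.7 mm (warnings), after which the wide vertebral body restores
  clearance — warning followed by recovery, without a breach.
* **MMP** tilts 5 degrees medially at 0.09 mm/s: the medial wall approaches
  through the warning band, is crossed, and the probe exits into the spinal
  canal where all photoacoustic contact is lost.

Speeds are paced so that, at the 30 s frame interval, each phase of each
path is represented within an 8-frame timeline (the shape of the reported
experiments). The zone ground truth for scoring the classifier is computed
in the plane perpendicular to the drill axis — what an ideal sideways
sensor could know — not in 3D: a wall a millimetre ahead of the tip is
invisible to a side-viewing probe and would be an unfair truth label.

Seeded repetitions of a timeline vary the noise stream and an axial entry
offset of up to 1 mm. Lateral targeting is deliberately not jittered: the
lateral offset is what distinguishes the three path classes in the first
place, and it is the quantity the navigation stage fixes.

## Ultrasound simulation, compounding and detection

Spinal sonography shows little more than the first bone interface, so the
frame model is minimal: per scanline, a Gaussian ridge (sigma 1 px) at the
first ray-surface intersection, hard shadow beyond it with an additive
noise floor, and multiplicative Rayleigh speckle (scale 0.05) in soft
tissue. First hits are computed analytically (quadratics for ellipsoids and
cylinders, slab tests for boxes); the test suite checks them against dense
marching over the label function.

Compounding is forward pixel-splatting with mean fusion: order-invariant by
construction, `hit_count` marks empty voxels as `NA` rather than zero. No
hole filling is attempted.

The classical detector marks, per column, the shallowest sample above 0.5 x
the column maximum whose trailing mean (at least 8 samples) stays below
0.18 x the column peak. The two thresholds encode the physics: bone ridges
are followed by near-zero shadow (trailing mean a few percent of the peak),
while speckle columns have a trailing mean near the Rayleigh mean (about
40% of the column peak), so the rule separates the two with a wide margin.

The learned detector is a per-scanline encoder-decoder (column in, heatmap
column out; default 48 hidden units) with a frame-pooled softmax head for
the spine level, trained full-batch with Adam. The heatmap target is
`exp(-d^2 / 2 sigma^2)` of the Euclidean distance field of the surface mask
(computed by `EBImage::distmap`; the closed form was chosen over an
explicit Gaussian convolution because it is exact and cheap to re-render
when sigma changes). Sigma anneals down the schedule (default 8, 4, 2 px)
whenever the epoch loss falls below 0.5 x the loss at the start of the
current stage — the annealing trigger had to be pinned somewhere, and a
fixed ratio keeps it scale-free. The level prediction is used to label
extracted points per frame; it does not gate detection at inference (the
alternative reading — per-image sigma selection at inference — changes
nothing about the extracted mask under per-column argmax, so the
training-time reading was implemented). Training on 64 synthetic 64 x 64
frames takes seconds on one CPU; the full-scale U-Net this miniaturises is
out of scope.

## Registration

Coarse alignment matches centroids and PCA axes; the four proper-rotation
sign assignments are scored by symmetric nearest-neighbour MSE. Clouds with
a largest/smallest eigenvalue ratio under 1.1 are flagged ambiguous.
Refinement is point-to-point ICP (Kabsch update via SVD, tolerance 1e-6
mm^2, at most 100 iterations, correspondence gate off by default) with an
optional trimmed variant (keep the best fraction of correspondences) for
partial-overlap, outlier-contaminated detections. The radius-selective
stage crops the ultrasound cloud to candidate radii (default 15, 25, 35,
50 mm) around the target level centre — the stated selection criterion is
the final MSE, and the crop interpretation was chosen because the
literal iterative point-removal schedule is under-specified; the MSE argmin
is the part that is pinned down. Radii capturing fewer than 10 points are
skipped and flagged.

Two lessons from the end-to-end demo are encoded as pipeline choices rather
than library defaults. First, PCA frames of a thin posterior ultrasound
sheet and of a full vertebra model genuinely differ, so the coarse stage
runs against the model's posterior-visible subset (`posterior_visible()`),
and for a small posture update the identity (the previous registration) is
kept as a competing initialisation, scored by the same symmetric MSE.
Second, cropping around the centroid of the level's visible surface rather
than the body centre retains the pedicles and posterior elements, whose 3D
structure locks the remaining degrees of freedom that a thin body strip
leaves loose.

## Photoacoustic model

The packaged cancellous-bone absorption spectrum is a fixed sum of
log-normal-shaped components pinned at 406, 540 and 576 nm (the printed
peak positions; the underlying curve is not published, so component widths
and the gently decaying baseline are free choices verified only to preserve
the peak set on a 1 nm grid). 532 nm sits on the rising flank of the 540 nm
peak, which is the rationale for the source choice it emulates.

Tissue signatures are damped oscillation bursts: cancellous at 2 MHz centre
frequency, relative amplitude 1.0; cortical at 6 MHz, amplitude 0.8;
sampling 50 MHz; depth conversion at 1540 m/s. These numbers are free
parameters chosen to reproduce the two reported orderings (cancellous peak
amplitude above cortical; cortical spectrum concentrated at higher
frequency) — no published axis values exist to calibrate against, and tests
assert only the orderings. Signals scale exactly linearly with fluence
(noise included), so zero fluence gives a null trace.

A PAE scan casts one radial ray per angle through the label map. Rays whose
first sample is not bone produce nothing but the noise floor — acoustic
contact is lost — and a cortical signature is added only when the interface
appears before any background along the ray. This is what makes post-breach
frames go dark. The interface distance estimator band-passes each A-scan at
the cortical spatial frequency (analytic-signal envelope via FFT masking)
and takes the envelope peak with parabolic sub-sample interpolation; the
0.05 mm radial step and 0.1 mm label-map spacing keep the quantization
error below the 0.06 mm CP margin discussed above.

Zone classification works per sector (default 8): `none` below the noise
gate (0.25 envelope units), `interface` when a cortical echo sits inside
the warning threshold (1.44 mm), `cancellous` otherwise when the
low-frequency band is live. A frame is dangerous when at least 80% of
sectors are dead, warning when any sector sees a close interface, safe
otherwise. Sectors seeing cortical beyond the threshold deliberately count
as cancellous-safe: inside a 3.5 mm pedicle the wall is always within
sensing range, and flagging it would make every correct-path frame a
warning. Timeline segmentation calls the leading run of dead frames
`initial`, the trailing run `exited`.

gCNR estimates the PDF overlap with histograms on shared bin edges (64
bins): `OVL = sum min(p_i, p_o) dx`, `gCNR = 1 - OVL`. The summed-minimum
form reduces to the single optimal-threshold form when the PDFs cross once
and remains correct when they cross several times; the reported threshold
is the first crossing bin. Quantile ("rank-preserving") bins make the
statistic invariant to monotone remapping and are used for that property
test; equal-width bins are the default.

## What the generator does and does not emulate

The phantom reproduces the geometry that drives the method: a millimetre
corridor, a thin bright shell on sparse ultrasound, side-viewing
photoacoustic contrast between two bone types, signal loss after breach.
It does not model refraction, speed-of-sound aberration, reverberation or
anisotropic speckle in ultrasound; porous, blood-filled cancellous
micro-structure, optical fluence decay with depth, or transducer impulse
response in photoacoustics; nor soft-tissue deformation or tracking error
in the poses. Passing tests therefore demonstrate internal correctness and
the method's behaviour under its stated assumptions — not clinical
performance. In the same spirit, reported ex vivo gCNR tables cannot be
reproduced without the raw images; the demo's 3 x 8 gCNR table is analogous
in shape and qualitative pattern only, with ROIs fixed as a near annulus
(0.25-2.0 mm) against a far one (2.4-3.0 mm).

## Problem sizes and determinism

Default study sizes: 1 800 surface points per level (5 000 in the demo,
where registration benefits from a denser model), 36-frame sweeps of
96 x 96 px at 0.5 mm, label maps at 0.1 mm over the pedicle corridor,
32-angle PAE scans over a 3 mm range, 8-frame timelines, 100-seed
registration ensembles and 50-seed drilling ensembles per path, and a
64-frame detector training set. These sizes keep a full run on one CPU in
the minutes range while leaving every statistical margin (95/100 recovery,
90% classification success) comfortably measurable. All randomness flows
through explicit seeds; generators save and restore the global RNG state.

## Known limitations

* The PCA coarse stage is unreliable for near-symmetric partial views; the
  demo mitigates this with visibility matching and an identity candidate,
  but a global initialiser (e.g. branch-and-bound) is explicitly out of
  scope.
* MSE-based radius selection favours small crops when detections are noisy;
  trimmed ICP softens but does not remove this bias.
* Frames written as PNG quantize to 1/255 on first write (the installed
  PNG writer is 8-bit); poses and all other floating-point artifacts
  round-trip exactly, polar PAE images to float32.
* The per-scanline detector ignores lateral context by design; columns with
  grazing-incidence surfaces rely on the heatmap threshold to abstain.
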