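# padrill

Radiation-free, multi-scale navigation and in-situ sensing for pedicle screw
drilling, as a fully synthetic, testable R toolkit.

Pedicle screws must traverse a bony corridor a few millimetres wide; a breach
of the cortical wall risks the spinal cord, nerve roots and vessels. `padrill`
implements the two scales of a radiation-free guidance pipeline around that
problem:

* **Macroscopic navigation** — freehand 3D ultrasound (US) frames are
  compounded into a volume, bone surfaces are detected (a classical
  shadow-based rule, plus a small two-loss heatmap detector whose Gaussian
  target sigma anneals during training and whose auxiliary head classifies
  the spine level), and the resulting point cloud is registered to per-level
  vertebra models by PCA-initialised, radius-selective iterative closest
  point (ICP): the cloud is cropped to candidate radii around the target
  level and the radius with the smallest mean squared error (MSE) is kept.
* **Mesoscopic sensing** — a side-viewing photoacoustic endoscopy (PAE)
  probe inside the drill senses the tissue around the bit. Cancellous bone
  returns a strong low-frequency signature, cortical bone a weaker
  high-frequency one; per-sector band-pass energies and the estimated
  cortical-interface distance classify each frame as **safe** (cancellous
  all around), **warning** (interface inside the 1.44 mm safe distance) or
  **dangerous** (signal loss — the drill has left the bone).

Everything runs on a deterministic parametric spine phantom (ellipsoidal
bodies, cylindrical 3.5 mm pedicles, box-like posterior elements, cortical
shells over cancellous cores), with tissue-label maps, tracked US frames, PA
signals, PAE scans and the three canonical drilling paths — correct (CP),
lateral misplacement (LMP), medial misplacement (MMP) — generated in code.

Image quality is scored with the generalized contrast-to-noise ratio,

```
OVL = sum_bins min(p_i, p_o) * dx,     gCNR = 1 - OVL
```

where `p_i` and `p_o` are the intensity PDFs inside and outside a target;
`gCNR` is bounded in [0, 1] and invariant to monotone intensity remapping
when rank-preserving bins are used.

## Worked example

```r
library(padrill)

# packaged cancellous-bone absorption spectrum, 340-960 nm at 1 nm
sp <- cancellous_absorption_spectrum(seq(340, 960, by = 1))
find_peaks(sp)[1:3]
#> [1] 406 540 576            # strongest absorption, then the two secondary peaks

check_fluence(16)            # 532 nm source at 16 mJ/cm2 vs the 30 mJ/cm2 ANSI limit
#> $ok [1] TRUE   $margin [1] 14

man <- run_full_demo(default_run_config(seed = 1))
print(man)
#> run_manifest: 12 artifacts
#>   registration TRE 0.731 mm (rot 1.700 deg, trans 0.728 mm)
#>   CP: safe safe safe safe safe safe safe safe -> correct
#>   LMP: safe safe warning warning warning safe safe safe -> lateral-graze
#>   MMP: safe safe safe safe warning warning dangerous dangerous -> medial-breach
```

The demo simulates a tracked US sweep over anatomy displaced by a known
5 degree / 2 mm rigid motion, recovers that motion to a target registration
error (TRE) of 0.73 mm, then drills the three paths while classifying each
30-second PAE frame. The manifest also carries a 3 x 8 gCNR table (paths x
time points); in-bone frames score around 0.6-0.8 against the background
annulus, while the post-breach MMP frames collapse to about 0.1 because only
noise remains:

```
       a    b    c    d    e    f    g    h
CP  0.71 0.71 0.78 0.77 0.78 0.62 0.72 0.73
LMP 0.75 0.70 0.68 0.66 0.66 0.70 0.75 0.72
MMP 0.73 0.74 0.73 0.72 0.65 0.66 0.10 0.15
```

Transforms on disk follow one convention everywhere: a row-major 3 x 4
matrix `[R | t]` in mm that **maps points** (`y = R x + t`), not frames —
see `write_frames()` / `read_frames()`.

## Command line

```sh
inst/cli/padrill spectrum --out spectrum.csv
inst/cli/padrill register --us us_cloud.ply --model model_L3.ply \
    --center 0,24,0 --radii 15,25,35,50 --out result.json
inst/cli/padrill demo --seed 1 --out demo_out/
```
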