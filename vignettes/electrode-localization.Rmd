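---
title: "Localizing intracranial electrodes from post-implant CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing intracranial electrodes from post-implant CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieegloc)
```

## The problem

Patients evaluated for epilepsy surgery are implanted with intracranial
electrodes: sEEG shafts (linear arrays of contacts inserted through burr
holes) and/or ECoG grids and strips (subdural arrays placed on the cortical
surface through a craniotomy). Interpreting the recordings requires knowing
where every contact sits in the patient's brain. The raw evidence is a
post-implant CT, in which each metal contact appears as a bright, roughly
Gaussian density, viewed against the pre-implant MRI and its derived
surfaces and parcellation (the package assumes CT and MRI have already been
co-registered by external tools and consumes their outputs).

`ieegloc` is the headless engine for this workflow: seed-based contact
refinement, automatic shaft extrapolation/interpolation, anatomic labeling,
ECoG brain-shift correction, electrode-to-surface value mapping, and
BIDS-iEEG export, all scriptable and all testable against synthetic
fixtures with known ground truth.

## Contact refinement

A clicked or predicted coordinate is rarely the true contact center. The
refinement operator replaces it with the intensity-weighted centroid of the
above-threshold CT voxels within a radius (default 2.0 mm) of the current
estimate and iterates until the estimate moves less than 0.01 mm (at most
10 iterations — in practice convergence takes 2–3). Weights are the
intensity *excess* above the threshold, `w = I - thr`, clipped at zero, so
that background intensity never biases the centroid. Iterating (rather than
a single pass) makes the result independent of where inside the blob the
seed landed; the operator is then idempotent to within the 0.01 mm motion
tolerance.

The intensity threshold is either an absolute value or a percentile of the
volume's finite intensities (default 99.5). Metal contacts are the
brightest structures in a post-implant CT by a wide margin, so a high
percentile isolates them without Hounsfield calibration. A constant volume
has no meaningful percentile and is rejected.

The CT is always used at native resolution. `read_volume()` never
resamples, and the package deliberately demonstrates why in its test suite:
small research contacts that are cleanly above threshold at 0.5 mm voxels
are diluted below it after 2x block-mean down-sampling
(`downsample_volume()`, a test instrument emulating coarse acquisition) and
vanish from the candidate list.

## Shaft automation

Whole shafts are localized from two clicked contacts.

* **Extrapolation** (`extrapolate_shaft()`): the user supplies the first
  two contacts. The step between the two most recently placed contacts
  predicts the next one; the prediction is then *snapped* to the CT.
* **Interpolation** (`interpolate_shaft()`): the user supplies the two end
  contacts. The march starts at one end and re-aims at every step — the
  prediction is the current contact plus the remaining straight-line vector
  to the refined far endpoint divided by the number of gaps left. Because
  each step is corrected by the CT and the aim is continuously updated,
  bends accumulate no error; a strip turning 90 degrees around an
  occipital-pole-like arc is recovered with RMS error around 0.01 mm on
  clean fixtures. Marching from one end (rather than from both ends
  simultaneously) was chosen for simplicity; the far endpoint is pinned to
  its refined position either way.

Snapping (`snap_to_density()`) examines above-threshold voxels within the
search radius (default 2.0 mm) of the prediction, excludes voxels closer
than the exclusion radius (default 1.5 mm) to any already-selected contact
(preventing duplicate selection when contacts are 3–3.5 mm apart), picks
the brightest admissible voxel — ties broken by distance to the prediction,
then by lowest flat voxel index so results are deterministic — and refines
from there. If no admissible voxel exists the geometric prediction is kept,
flagged `geometric-fallback`, with a warning: one ambiguous CT region
should not discard a shaft, and the provenance column makes the fallback
auditable. The 1.5 mm exclusion default is about half the common contact
pitch; the search radius matches the refinement radius so the two stages
see the same neighbourhood.

## Anatomic labeling

Given an integer parcellation volume (e.g. FreeSurfer aparc+aseg exported
to NIfTI) and a color-LUT text file, each localized contact is labeled by
majority vote over the 3x3x3 cube of voxels centered on its voxel.
Voting makes the label robust to sub-voxel electrode displacement. On a
tie, the label of the cube's *center voxel* is used — applied literally,
i.e. the center label wins even when it is not among the tied maxima; the
alternative (restricting to the tied labels) differs only on contrived
fixtures, and the literal rule is simpler to reason about. At the volume
edge the cube is truncated rather than padded; electrodes outside the
volume entirely are labeled `unknown` with a warning.

## Brain-shift correction

A craniotomy lets the brain sag, sometimes by a centimetre, so subdural
contact positions in the post-implant CT can end up *inside* the
preoperative brain surface. Since ECoG contacts physically sit on the
cortex, the correction moves each interior ECoG contact back to the pial
envelope; sEEG contacts, inserted through burr holes, are never touched,
and both original and shifted coordinates are kept in the table.

Containment uses the generalized winding number (robust to glancing
intersections on coarse meshes; requires a closed envelope).
Correction is two-stage:

1. exact nearest-point projection (face interior, edge, or vertex — not
   nearest-vertex) of every interior contact;
2. topology regularization: minimize
   `sum_i ||s_i - proj_i||^2 + lambda * sum_(i,j) (||s_i - s_j|| - ||o_i - o_j||)^2`
   over the shifted positions `s`, where the second sum runs over adjacent
   contact pairs (4-neighbourhood in a grid, chain in a strip) and
   `o` are the original positions. The solver is coordinate-wise spring
   relaxation with re-projection onto the surface after every sweep, at
   most 100 sweeps or relative objective change below 1e-6.

`lambda` (`lambda_topo`, default 1.0, dimensionless) trades projection
fidelity against preservation of inter-contact spacing; at 0 the correction
is pure projection. The adjacency-distance penalty is this package's
concrete reading of "topology is preserved" — an approximation in the
spirit of the published projection methods, not a claim of bit-identity
with any of them. On a 2x4 grid pushed 8 mm into a 50 mm sphere, corrected
contacts sit on the mesh to machine precision and adjacent spacings change
by under 15%.

## Value mapping

Per-electrode scalars (power, stimulation-mapping categories, time series)
are mapped to surface vertices for visualization. For a vertex at distance
`d` from an electrode with value `v`:

```
vertexvalue = v * exp(-d * decay_factor / max_radius),   d <= max_radius
```

with defaults `decay_factor = 1.5` and `max_radius = 1` mm; vertices
farther than `max_radius` from every electrode stay unassigned. When
several electrodes are in range, the decayed values are averaged with
inverse-distance weights `1 / max(d, 1e-6)` — "weighted by distance" is
read as nearer-dominates, the only monotone reading consistent with the
discrete mode, which simply copies the nearest in-range electrode's value
(appropriate for categorical data, where averaging is meaningless).
Distances are Euclidean in world mm, electrode side taken from the shifted
coordinate when present (that is where the contact actually sits relative
to the preoperative surface); geodesic distances are out of scope since the
mapping radius is of the order of one vertex spacing. Time-series mapping
applies the same formula frame by frame.

## Synthetic fixtures

Every test runs on generated data with known ground truth:

* `make_trajectory()` — exact arc-length-spaced points on a line or
  circular arc;
* `render_ct()` — isotropic Gaussian blobs (default peak 1000, sigma
  0.6 mm on 0.5 mm voxels) over Gaussian background noise (default SD 20),
  bit-reproducible from its seed. Defaults emulate a clinical contact pitch
  of 3.5 mm with clean percentile separation between metal and background;
* `make_label_volume()` — half-space/box parcellations with generated LUT;
* `make_icosphere()` — closed pial-envelope stand-in;
* `make_grid_fixture()` — a geodesically spaced grid on a spherical cap,
  displaced inward to emulate post-craniotomy shift.

Gaussian blobs are a deliberate simplification: real contacts are
cylinders with metal blooming, streak artifacts, wires, and bone nearby.
The fixtures exercise the centroid/snap/vote/project logic exactly, but
passing on them does not demonstrate robustness to metal-artifact streaks,
touching contacts at sub-millimetre pitch, or mis-registration between CT
and MRI — those require real data and remain the user's responsibility to
verify (the provenance column and candidate exports exist for exactly that
audit).

## Numerical choices and problem sizes

* Voxel indices are 0-based everywhere internally and in the voxel-coordinate
  columns; all public coordinates are world mm RAS. sform is preferred over
  qform when both header codes are set.
* Refinement: move tolerance 0.01 mm, cap 10 iterations. Snapping
  tie-breaks: intensity, then distance, then flat voxel index.
* Shift solver: <= 100 sweeps, relative tolerance 1e-6, re-projection every
  sweep.
* Mapping: epsilon floor 1e-6 mm on inverse-distance weights.
* Test and acceptance runs use 96^3-voxel, 0.5 mm fixtures (50 random
  shafts, 100 refinement blobs, 1000 vote points, 200 projection points) —
  sizes chosen so the full suite completes in about a minute on one CPU
  while keeping every estimate comfortably away from its tolerance.

## Known limitations

* No DICOM ingestion, registration, resampling or MNI normalization — the
  package consumes co-registered NIfTI and caller-supplied template
  coordinates only.
* Fully automatic whole-CT segmentation without seeds is out of scope; two
  seed contacts per group are required.
* The brain-shift objective is a local relaxation; pathological initial
  configurations (e.g. a grid folded onto itself) may converge to a local
  minimum.
* Electrode "size" is exported as `n/a` in BIDS output; physical contact
  geometry is not modeled.
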