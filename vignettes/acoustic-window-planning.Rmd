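---
title: "Acoustic-window planning from CT: model and methods"
author: "AcousticWindow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic-window planning from CT: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AcousticWindow)
```

## The problem

Ultrasound image quality depends critically on where the probe is placed.
Organs such as the liver or the heart are partly hidden behind ribs and
gas-filled structures, so only narrow *acoustic windows* — for example the
intercostal spaces — give an unobstructed sound path. A robotic or assisted
acquisition system therefore needs a planner that, given previously acquired
tomographic data (CT) and a target point, proposes the probe pose expected to
produce the best image. `AcousticWindow` implements such a planner: a
geometric hard-constraint stage, a CT-derived acoustic transmission model
that scores each admissible pose, and an exhaustive two-stage optimiser, with
a naive geometric baseline and slice-based quality metrics for comparison.

## The transmission model

At an interface between media with acoustic impedances $Z_1$ and $Z_2$, the
transmitted intensity fraction is

$$t(Z_1, Z_2) = 1 - \left(\frac{Z_2 - Z_1}{Z_2 + Z_1}\right)^2 .$$

Acoustic impedance is the product of density and speed of sound; assuming a
constant speed of sound and the approximately linear relation between tissue
density and X-ray attenuation, CT intensity becomes a usable impedance
proxy. We map Hounsfield units to a dimensionless attenuation proxy

$$\mu = \max(1 + \mathrm{HU}/1000,\ \varepsilon),\qquad \varepsilon = 10^{-3},$$

so water sits at 1, cortical bone near 2, and air at the floor
$\varepsilon$. Only *ratios* of $\mu$ enter the model (the package verifies
scale invariance as a property test), and the floor makes every tissue/air
interface a near-total reflector — the physically expected behaviour — while
keeping the reflection-ratio denominator away from zero.

Along a scan-line the model accumulates squared reflection ratios at the
sample resolution: with samples $\mu_0, \mu_1, \dots$ the cumulative raw
transmission past sample $K$ is

$$t_K = \exp\!\Big(-\sum_{k<K} r_k^2\Big),\qquad
  r_k = \frac{|\mu_{k+1} - \mu_k|}{\mu_k + \mu_{k+1}},$$

and a log compression $\hat t = \log(1 + \nu t)/\log(1 + \nu)$ with
$\nu = 0.5$ mimics the dynamic-range mapping of ultrasound pipelines. For a
single sharp interface this construction contributes exactly $r^2$, which
agrees with the closed-form $1 - r^2$ to $O(r^4)$; for smooth media it
discretises the continuous attenuation integral.

The per-pose quality score is the mean compressed transmission over all
scan-lines of the curvilinear fan and all depth samples,

$$\bar t(s, R) = \frac{1}{N_{el}\,d_y}\sum_{i=1}^{N_{el}}
  \int_0^{d_y} \hat t\big(R(b_i + l v_i) + s\big)\, \mathrm{d}l,$$

evaluated with scan-line origins $b_i$ on the physical curved array and
uniform depth samples including the skin sample at $l = 0$.

### Numerical choices

* **Nearest-voxel sampling along rays.** Ray marching samples $\mu$ at the
  voxel containing each sample point rather than trilinearly. Sub-voxel
  interpolation would smear a sharp interface into a one-voxel ramp whose
  summed squared reflection *depends on the step size* (finer steps make a
  bone interface arbitrarily transparent); piecewise-constant sampling keeps
  the reflection sum step-size invariant on piecewise-constant media, which
  is the regime the planner must rank correctly (soft tissue vs bone vs
  air). The test suite checks invariance across steps of 0.25/0.5/1 mm to
  1e-6. Trilinear interpolation remains in use where it belongs: evaluating
  CT values on oblique slice planes.
* **Ray step.** Default half the minimum voxel spacing (configurable);
  depths run from 0 to $d_y$ inclusive.
* **Compression per depth sample.** The compression is applied to the
  cumulative transmission at every depth sample (the integrand of the score
  is the compressed value), not once at full depth.
* **Coupling penalty of the curved array.** Outer elements of a convex
  array lie behind the central element, so with the base point on the skin
  their rays start marginally in air and acquire an entry interface. This
  penalises poses in proportion to how much of the array face is off the
  skin, applies equally to all compared poses, and disappears in an
  unbounded constant medium (where $\bar t = 1$ exactly).

## Hard constraints and the optimiser

A surface point $s$ with outward normal $n_s$ is an admissible base point
for target $P_t$ iff

* $|P_t - s| < d_y$ (the target lies within the penetration depth), and
* the angle between the axial direction $d_a = (P_t - s)/|P_t - s|$ and the
  *inward* normal $-n_s$ is at most $\alpha = 30°$ (acoustic coupling and
  patient comfort limit the tilt of the probe against the skin).

Fixing $d_a$ to point at the target leaves one rotational degree of freedom,
the roll $\phi$ about $d_a$; the image plane is invariant under an in-plane
flip, so $\phi \in [0°, 180°)$ on a 5° grid by default. The optimiser is an
exhaustive two-stage search — per candidate the best roll, then the best
candidate — which by construction equals the joint argmax over the full
candidate-roll product set; ties break deterministically (lowest surface
index, then smallest roll). The test suite cross-checks the compiled batch
kernel against an independent R summation route and a brute-force joint
enumeration.

Multi-view trajectories share one base point admissible for *every* target
(the intersection of the per-target candidate sets) and maximise the product
of per-target scores; given the base point the product factorises, so each
roll is optimised independently and the base point maximises the sum of log
scores.

The naive baseline places the probe at the surface point nearest the target
with the lateral axis $(n \times d_a)/|n \times d_a|$; its multi-view
variant sets the elevational axis to the normalised rejection of the
trajectory direction from $d_a$, giving parallel image planes.

## Evaluation metrics

Planned poses are scored on CT by resampling the ultrasound-image-shaped
slice (the curvilinear fan spanned by the lateral and axial axes) and
computing, over in-fan pixels only:

* $r_{ct}$ — the fraction of pixels outside the soft-tissue window
  $[\beta_1, \beta_2] = [-100, 150]$ HU (bone and air that impair
  transmission; lower is better), and
* $r_{seg}$ — the fraction of pixels inside the target-organ label (image
  context; higher is better).

Ratios run over the fan rather than its bounding rectangle because the
ultrasound image of a convex probe *is* the fan; rectangle background would
dilute both ratios. CT is sampled trilinearly, labels nearest-neighbour
(categorical data), pixel pitch defaults to the minimum CT voxel spacing to
avoid aliasing thin ribs.

## The synthetic phantom

The generator emulates the structure the planner exploits without requiring
patient data: an elliptic soft-tissue body cylinder (40 HU) in air
(−1000 HU), four bone-density rib arcs (900 HU, tube radius 4 mm) in axial
planes with an 8 mm intercostal gap, a labelled soft-tissue organ ellipsoid
(60 HU) beneath the rib cage, and Gaussian HU noise (σ = 10). Rib planes are
symmetric about the organ centre so an intercostal window faces it. The HU
palette keeps body and organ inside the soft-tissue window with bone far
above it. Targets are drawn uniformly from organ voxels eroded by two voxels
(boundary targets have ambiguous coverage); everything is determined by the
seed.

What the phantom does *not* emulate: realistic CT texture, respiration,
multiple organs, gas pockets, or curved/oblique ribs. Passing tests
demonstrate the planner's contracts (constraint correctness, optimiser
optimality, rib avoidance in the intended geometry), not clinical
performance on patient CTs.

```{r phantom-demo, eval = FALSE}
ph <- generatePhantom(phantomConfig())
surf <- extractSurface(ph$ct, density = 0.03)
field <- huToMu(ph$ct)
plan <- planSingleView(field, surf, ph$targets[1, ], probeGeometry(),
                       plannerConfig())
planScores(plan)
```

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `depth` | 140 mm | penetration depth $d_y$ of the modelled abdominal probe |
| `nElements` | 64 | planning scan-lines (subsampled from a 128-element array) |
| `arrayRadius`, `fovAngle` | 40 mm, 70° | convex-array curvature and aperture |
| `alphaDeg` | 30° | probe-to-normal coupling-angle limit |
| `angleGridStepDeg` | 5° | roll grid over [0°, 180°) |
| `nu` | 0.5 | log-compression factor |
| `epsilon` | 1e-3 | attenuation-proxy floor (air) |
| `beta1`, `beta2` | −100, 150 HU | soft-tissue window of $r_{ct}$ |
| `thresholdHu` | −300 HU | air/tissue threshold for surface extraction |
| `density` | 0.25 pts/mm² | surface sampling density (see below) |

The surface density is a genuine knob: planning cost is linear in the number
of candidates. The package default of 0.25 points/mm² resolves fine
anatomy; the phantom studies in the tests and the acceptance script use
0.01–0.05 points/mm² (a 4–9 mm point pitch, still well below the 8 mm
intercostal gap), and the oracle-equivalence checks use a coarser 15° roll
grid so that brute-force joint enumeration stays exact and fast. The
acceptance study plans 10 targets on the default 96×96×64 phantom at
density 0.03; determinism is exercised end to end with 2 targets.

## Design decisions in open territory

* **Surface extraction** thresholds at −300 HU, keeps the largest
  6-connected component, closes one-voxel skin holes, then places points at
  boundary voxels projected onto the 0.5 iso-level of the Gaussian-smoothed
  (σ = 1 voxel) mask along normals taken from the smoothed-mask gradient,
  sign-fixed outward. Sub-voxel projection keeps sphere radii accurate to a
  voxel diagonal; smoothing uses edge replication so volume-truncation faces
  do not tilt normals. Subsampling bins points on a grid of pitch
  $\sqrt{1/\mathrm{density}}$ in volume-local coordinates, which makes the
  extraction exactly equivariant under rigid translation of the volume.
* **Admissibility sign convention.** The coupling test compares the probe
  axis with the inward normal, $\langle d_a, -n_s\rangle \ge \cos\alpha$:
  with outward normals and an axial axis pointing into the body this is the
  tilt limit the constraint intends.
* **Roll-zero convention.** $\phi = 0$ keys the lateral axis to the
  normalised rejection of a world reference "up" vector (default the volume
  z axis) from $d_a$, with a deterministic fallback when they are parallel —
  reproducibility demands a fixed convention.
* **Exhaustive rather than convexity-exploiting roll search.** The score is
  usually near-convex in the roll, but an exhaustive grid guarantees the
  optimiser equals the brute-force joint argmax, which is the property the
  tests pin down.
* **Tie-breaks** are part of the contract (lowest surface index, then
  smallest roll): without them determinism and oracle equality would be
  ill-posed on constant media.

## Limitations

Straight rays with a constant speed of sound: no refraction, focusing,
beam-width, element directivity or frequency-dependent absorption — the
model ranks acoustic windows, it does not synthesise images. Trajectories
use a single shared base point; sequences with moving base points are out of
scope. Planning quality on real patient CT depends on inputs this package
does not model (registration accuracy, respiratory state), and absolute
$\bar t$, $r_{ct}$, $r_{seg}$ values on the phantom are not comparable to
values reported on patient data.
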