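---
title: "From coronary CT angiography to computed FFR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From coronary CT angiography to computed FFR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autoffr)
```

`autoffr` computes fractional flow reserve from a coronary CT angiography
(CCTA) volume without manual intervention: unsupervised lumen segmentation,
centreline/radius geometry extraction, and an implicit coupled 1D-0D
pulsatile blood-flow model whose output of record is cFFR, the ratio of
cycle-mean distal to proximal coronary pressure. This vignette explains the
model and every consequential design choice; the README shows a worked
end-to-end run.

## Image filtering

Each axial slice passes through four stages.

* **Noise estimation.** The noise SD $\sigma$ is the median absolute
  diagonal Haar wavelet detail divided by 0.6745 — the standard robust
  estimator under the additive-Gaussian noise assumption. It is estimated
  per slice.
* **Non-local means de-noising** with filter strength $2\sigma$, 5 px
  template and 7 px search windows. NLM averages pixels whose local
  patches look alike, which removes noise from flat regions very
  effectively while refusing to average across edges. A consequence worth
  knowing: structures whose cross-section is comparable to the template
  window (a coronary lumen is 6–9 px at 0.458 mm spacing) have few
  self-similar patches in the search window, so the *interior* of a vessel
  is denoised much less than open background. When lumen-background
  contrast is large compared with the filter strength the lumen boundary
  survives sharply; when the contrast is only a few noise SDs the filter
  biases boundary pixels toward the majority (background) side.
* **Frangi vesselness**, the Hessian-eigenvalue measure of similarity to a
  bright tube, maximised over Gaussian scales of 1–6 px (covering coronary
  diameters at the stated pixel spacing) with $\beta = 0.5$ and
  $\gamma = 15$. The score is in $[0,1]$. Rather than replacing the grey
  image, the score *gates* it: a pixel is a vessel candidate when its
  vesselness exceeds a low cutoff (default 0.05) **and** its de-noised
  grey intensity exceeds the copy's threshold. The cutoff is deliberately
  permissive because vessels crossing the slice plane appear as small
  blobs, which the vesselness blob-suppression term scores around 0.1–0.3
  rather than near 1; a strict gate would erase them. Thresholding the
  grey values (not the vesselness) keeps the 125–145 threshold vocabulary
  meaningful.
* **Binary thresholding and contour-area removal.** Pixels above the
  grey threshold form components (8-connectivity); components *strictly
  larger* than 900 voxels are removed, which eliminates chambers and the
  aorta while sparing coronary-sized cross-sections.

## Aortic landmark

The ascending aorta is the one reliably circular bright structure on
superior slices, so a circular Hough transform over radii 25–60 px (Canny
edges, hysteresis 50/150; annulus matched filter per radius, votes
normalised by perimeter) is applied to the 5th–9th slices and the mean
detected centre becomes the spatial reference point. Slices are counted on
the processed stack. A detection must cover at least 30% of the circle
perimeter; if no slice in the range yields a circle the pipeline aborts
with "aorta not detected".

## Segmentation by density clustering

Candidate voxel centres are clustered with DBSCAN using a search radius of
$\varepsilon = 1.6$ voxels and a minimum of 2 points (the point itself
included). On an integer grid, the $\varepsilon$-neighbourhood is a fixed
offset stencil, so the implementation clusters in voxel-index space —
deliberately so, despite anisotropic spacing, because the parameters are
stated in voxels. Border points reachable from two clusters go to the
cluster discovered first in lexicographic scan order, making the partition
order-independent and deterministic.

The two clusters whose minimum point distance to the aortic reference is
smallest are the coronary arteries (look-alike pulmonary vessels lose this
test by an order of magnitude). The cluster at lower image columns is the
right coronary artery, matching the radiological axial convention.

Because lumen intensity decays distally, segmentation runs on five copies
thresholded at 125, 130, 135, 140 and 145 grey levels; the per-copy
selected clusters are unioned. Lower thresholds capture faint distal
segments, higher thresholds stay clean proximally, and the union is
monotone: adding a threshold never shrinks the mask.

## Geometry extraction

* **Cleaning.** Two DBSCAN passes on the selected voxels: clusters formed
  at $\varepsilon = 7$ voxels with at least 700 points in the radius are
  removed (only the aortic-root blob reaches that density — a
  coronary-calibre tube of radius 3 voxels holds roughly 400–600 voxels in
  any 7-voxel ball), then voxels not in any cluster at
  $\varepsilon = 1.5$, 3 points are removed (speckle).
* **Mask regularisation.** Before skeletonisation the binary mask is
  smoothed with a small Gaussian and re-thresholded at 0.5 (a
  majority-style filter), and interior cavities — background regions not
  connected to the volume border — are filled. A lumen is solid, so a
  cavity is always a thresholding dropout, and its spurious inner wall
  would corrupt both the medial axis and the radius estimate. The
  smoothing SD scales with the measured image noise,
  $\min(0.8, 0.08\,\hat\sigma)$ voxels, so a clean volume is not blurred
  at all.
* **Skeletonisation.** Topology-preserving 3D thinning: six directional
  sub-iterations per pass; each sub-iteration freezes the current border
  in that direction, then deletes candidates sequentially, re-checking at
  deletion time that the voxel is *simple* (removal changes neither the
  26-connected foreground component count in its neighbourhood nor the
  6-connected background structure) and not a curve end point. Freezing
  the border bounds erosion to one voxel layer per direction per pass and
  keeps the result centred; sequential re-checked deletion preserves
  topology exactly. Digital tubes shorten by about one radius at each open
  end — inherent to medial-axis thinning — which is one reason the first
  mesh nodes at the ostium are trimmed (below).
* **Branch splitting.** The skeleton's 26-adjacency graph is split at
  voxels of degree ≥ 3 into maximal junction-free paths; spurs shorter
  than 3 voxels are pruned; a purely cyclic component is broken at its
  lexicographically smallest voxel with a warning.
* **Surface and radii.** The lumen surface is an iso-surface (marching
  tetrahedra on the Kuhn 6-tet cube decomposition, watertight across
  cubes) of the Gaussian-smoothed mask at level 0.5, in mm world
  coordinates. The radius at a centreline point is the *shortest normal
  distance* to surface vertices: the minimum distance over vertices within
  a ±1-voxel slab around the plane normal to the local centreline tangent.
  The slab matters: without it, tube end caps and axially adjacent
  branches contaminate the minimum. The estimate still dips at
  bifurcations, where the nearest wall belongs to the sibling branch —
  accepted and documented, as the downstream 1D model assumes circular
  cross-sections anyway.
* **1D meshing.** Radius versus arc length is interpolated per branch with
  PCHIP (shape-preserving cubic Hermite; never overshoots local data, so
  a stenosis minimum survives resampling exactly) onto equidistant nodes
  at 0.01 cm — the fine mesh needed to resolve abrupt area changes.
  Branches with fewer than three knots fall back to linear interpolation.
  The tree is rooted at the branch end nearest the aortic reference and
  the first 5 nodes of the root branch are dropped (configurable 4–6):
  root cleaning erodes voxels at the ostium and under-sizes those radii.
  Two symmetrical guards apply at the distal ends: trailing nodes of
  terminal vessels whose estimated radius falls below 0.7 mm are trimmed
  (where the mask frays the estimate drops to the voxel scale and stops
  being a measurement, and an outlet below distal-coronary calibre makes
  the terminal characteristic impedance exceed any physiological bed
  resistance), and terminal twigs shorter than 2 mm — thinning artefacts
  at junctions — are pruned recursively. Interior radius minima
  (stenoses) are never touched by either guard.

## Haemodynamic model

Mass and momentum balance on each 1D vessel segment:

$$C_A \frac{\partial P}{\partial t} + \frac{\partial Q}{\partial x} = 0,
\qquad
\frac{\rho}{A}\frac{\partial Q}{\partial t}
 + \frac{\rho}{A}\frac{\partial (Q^2/A)}{\partial x}
 + \frac{\partial P}{\partial x} = -\,22 \mu \pi \frac{Q}{A^2},$$

with blood density $\rho = 1.06$ g/cm³ and viscosity $\mu = 0.04$ P. The
right-hand friction term sets the steady viscous drop
$\Delta P = 22\pi\mu Q L/A^2$, the main driver of FFR loss; the convective
term matters where the area changes across a stenosis. The system closes
with the elastic tube law

$$P - P_{ext} - P_0 =
  \frac{2\rho c_0^2}{b}\left[\left(\frac{A}{A_0}\right)^{b/2} - 1\right]
  + \frac{\Gamma}{A_0\sqrt{A_0}} \frac{\partial A}{\partial t},
\qquad
c_0 = \sqrt{\tfrac{2}{3\rho}\,(k_1 e^{k_2 r_0} + k_3)},$$

with $k_1 = 2\times10^7$ g cm⁻¹ s⁻², $k_2 = -22.53$ cm⁻¹,
$k_3 = 8.65\times10^5$ g cm⁻¹ s⁻². Defaults: $b = 2$ (the square-root
tube law; a collapse pressure may be supplied instead, making $b$
radius-dependent), $\Gamma = 0$ (purely elastic — the steady pressure
field that determines cFFR is independent of the viscoelastic term), and
$P_0$ equal to the mean arterial pressure so the imaged geometry is the
reference state near mean load. The $k_1$ unit is read as g/(cm·s²) for
dimensional consistency of $c_0$ in cm/s.

**Boundary conditions.** The inflow waveform is prescribed at each
coronary root: a two-phase shape with configurable mean (left coronary
flow predominantly diastolic, right more uniform), shipped as an editable
default standing in for subject-specific data. Mean inflows default to
hyperaemic values (2.5 and 1.2 cm³/s left/right) because FFR is defined at
maximal vasodilation. Each terminal vessel couples to a coronary
Windkessel bed: characteristic impedance $R_1 = \rho c_0/A_{0,end}$, then
arterial and venous micro-circulatory resistances
$R_2 = 0.79\,(R_{Tf}-R_1)$ and $R_3 = 0.21\,(R_{Tf}-R_1)$ so that
$R_1+R_2+R_3 = R_{Tf}$, compliances $C_1$ (arterial) and $C_2$
(intramyocardial, referenced to a scaled ventricular pressure so systole
impedes coronary inflow — scale 0.5 left, 0.2 right, uncalibrated and
configurable), and venous pressure 5 mmHg. The side's total resistance is
$R_{cor} = \mathrm{MAP}/Q_{cor}$ with
$\mathrm{MAP} = \tfrac{2}{3}\,80 + \tfrac{1}{3}\,120 = 93.3$ mmHg, and is
distributed over terminals by Murray's power law with exponent 2.27:
terminal flow fractions $f_i = r_i^{2.27}/\sum_j r_j^{2.27}$,
$R_{Tf,i} = R_{cor}/f_i$; bed compliances are distributed by the same
fractions (defaults $5\times10^{-7}$ and $5\times10^{-6}$ cm⁵/dyn per
side, chosen for sub-second bed time constants).

**Discretisation.** Space: sub-domain collocation — the equations are
integrated over each mesh cell with the composite trapezoidal rule, a
compact box scheme that is second-order and free of odd-even decoupling.
Time: second-order backward differences (BDF2), with a single
backward-Euler start step (one lower-order step does not degrade the
global order). Each step solves the full nonlinear system — all node
areas/flows, junction constraints (mass conservation and static-pressure
continuity), terminal couplings and bed states — by damped Newton
iteration with an analytic sparse Jacobian, equilibrated by row and column
scaling so the near-rigid wall limit (tube-law stiffness $\sim 10^{13}$)
remains solvable. Junction balances therefore hold to solver precision at
every step. Defaults: $\Delta t = 10^{-4}$ s, Newton tolerance $10^{-8}$
(relative step), at most 5 cycles with early exit once consecutive-cycle
inlet pressures agree within 0.5% in relative $L_2$. On Newton failure the
step is retried as backward-Euler micro-steps with up to 4 halvings. A
steady mode drops the time derivatives and solves directly for the
equilibrium — the initial condition of every pulsatile run (taken at
$Q(0)$ so the inflow is continuous), and sufficient on its own for steady
quantities such as cFFR under constant hyperaemic flow.

**cFFR** is the ratio of cycle-mean pressure at the query point to the
cycle-mean pressure at that side's inlet (for steady runs, the ratio of
steady pressures; in the zero-viscosity limit it is 1 everywhere). A mean
ratio rather than a fixed cycle phase is used because invasive FFR is a
mean-pressure ratio. Without clinical annotations the default query point
is the node of minimum lumen radius per side — a package convention.

## Phantoms and what the tests show

All tests run on digital phantoms with exact ground truth.

* The **tube phantom** is a straight tube along the slice axis with an
  optional cosine-tapered stenosis (`severity` = fractional diameter
  reduction; throat radius $r_0(1-\text{severity})$). Defaults: radius 4
  voxels, lumen grey 145 (top of the thresholdable band), dark
  epicardial-fat-like background (30), optional CT-like partial-volume
  edges, additive Gaussian noise clipped to $[0,255]$. Axis and throat
  are grid-aligned: an even-symmetric digital tube has no unique middle
  voxel and is degenerate for any thinning algorithm (the reference
  implementations annihilate it), a situation real masks never present.
* The **coronary phantom** (256×256×48 at 0.458/0.625 mm) adds an aorta
  cylinder detectable on slices 5–9, a bifurcating left tree and a right
  tree sprouting at the aortic wall, and a distant decoy vessel standing
  in for a pulmonary branch, with lumen intensity tapering 145→128
  distally — which is precisely what the multi-threshold union is for.
* The **stenosed 1D mesh** generator feeds the solver directly with known
  throat radius and location.

The coronary phantom's trees are deliberately minimal — two outlets per
side. When the pipeline runs on it, the configured mean inflows are
scaled to that reduced perfusion territory (1.0 / 0.5 cm³/s left/right
instead of the whole-tree hyperaemic defaults): the total coronary
resistance `MAP/Qcor` is distributed over the available outlets, and a
two-outlet tree fed a whole-tree flow would demand outlet bed resistances
below the vessels' own characteristic impedance. cFFR, a pressure ratio,
is insensitive to this territory scaling to first order.

What the phantoms do *not* emulate: beating-heart motion, beam hardening,
calcified plaque, myocardial bridging, anatomically realistic chamber
background. Passing tests demonstrate correctness of the algorithms under
the stated noise model, not clinical accuracy on real scans.

Problem sizes used by the test-suite and the acceptance script: solver
oracles on 10 cm / 1001-node vessels; pulsatile runs on 1.5–2 cm vessels
at $\Delta t$ of 0.4–2 ms for 1–2 cycles; the temporal-order measurement
against a 3200-step reference; geometry recovery on the default tube
phantom; segmentation and the end-to-end runs on the default coronary
phantom in steady mode.

## Numerical choices and degenerate inputs

* Threshold comparisons are strict (`> threshold`; components `>` 900
  voxels are removed), following the "larger than" wording.
* DBSCAN `minPts` counts the point itself; two voxels 3 apart at
  $\varepsilon=1.6$ are both noise.
* PCHIP deduplicates coincident arc-length knots; branches shorter than
  the mesh spacing collapse to two nodes with a warning.
* A centreline point lying exactly on a surface vertex (radius 0) is
  dropped with a warning, as are points outside the surface bounding box.
* Zero-area states abort the solver naming the vessel and node; the
  damped Newton update never steps into negative areas.
* The DICOM layer is deliberately minimal: explicit-VR little-endian
  single-frame slices with geometry tags — enough to round-trip the
  phantom writer and read standard uncompressed CT exports. Volumes are
  window-normalised to $[0,255]$ on input (default window is the identity
  for 8-bit data) because every grey threshold in the method lives on
  that scale; whether the original workflow operated on raw HU or 8-bit
  exports is not determinable, so the window is configurable and flagged
  to users.
* Configuration files are YAML with one section per stage; a single seed
  governs every stochastic element (phantom noise only — the pipeline
  itself is deterministic, which the tests verify bitwise).

## Known limitations

* The radius estimate inherits the voxel quantisation of the skeleton: on
  noisy masks the thinned centreline can sit a full voxel off-axis over
  extended stretches, and the min-distance radius then under-reads by
  about that amount. Under heavy noise ($\sigma = 10$ on a 115-grey
  contrast) worst-case radius errors of ~1–1.5 voxels occur at such
  stretches even though the throat location and skeleton deviation bounds
  hold. This scatter is of the same order as the automatic-vs-manual
  radius spread reported for comparable workflows; sub-voxel centreline
  refinement would remove it but is deliberately out of scope.
* Segmentation leaks near the aortic root on low-quality data are not
  repaired (a known failure mode of the approach); the per-threshold
  quality table attached to the segmentation output is the diagnostic
  handle.
* Coronary dominance is not modelled; boundary conditions are
  population-level defaults, so absolute cFFR values on real data carry
  the corresponding uncertainty.
* The elliptic-lumen case is out of scope (circular cross-sections are
  assumed throughout), as are 3D CFD, closed-loop heart models and
  hyperaemia pharmacology.
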