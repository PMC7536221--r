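---
title: "Multi-planar velocity encoding and 4D flow cine reconstruction"
author: "cineflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-planar velocity encoding and 4D flow cine reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cineflow)
```

## The measurement model

Balanced SSFP sequences accrue image phase proportional to spin velocity:
the net gradient first moment **m** of the sequence maps a velocity **v**
(cm/s) to a phase

$$\phi = \gamma\,\mathbf{m}\cdot\mathbf{v} = \mathbf{s}\cdot\mathbf{v},$$

where we only ever store the product $\mathbf{s} = \gamma\mathbf{m}$
(rad per cm/s) — the gyromagnetic ratio and the moment have no separately
observable effect.  The velocity-encoding limit is
$\mathrm{VENC} = \pi/|\mathbf{s}|$: the speed along $\mathbf{s}$ that
produces a phase of $\pi$.  Phases are stored wrapped to $(-\pi, \pi]$ and
the package assumes all speeds stay below VENC (with the default VENC of
159 cm/s, phantom speeds up to 100 cm/s and fetal speeds up to about
90 cm/s satisfy this); a wrap is a modelling-violation to be detected, not
unwrapped — no unwrapping algorithm is provided.

A single stack of parallel slices measures only the scalar projection
$\mathbf{s}\cdot\mathbf{v}$.  Because slice-to-volume reconstruction
requires stacks in several orientations anyway, and the bSSFP first moment
is fixed *relative to the slice*, every differently-oriented stack
delivers a differently-oriented projection.  Three non-coplanar stacks
with non-colinear sensitivities suffice to invert for the full vector;
five are used by default for redundancy under motion.  For bSSFP with
Cartesian sampling the net moment lies in the read/slice plane (the
phase-encode moment averages to zero over an acquisition); the angle
within that plane is not determined by first principles here and defaults
to 45 degrees between the read axis and the slice normal, configurable in
`defaultStackPlan()`.

When motion rotates a frame by the rigid transform $A_k$, the sensitivity
rotates with it: $\mathbf{s}^*_k = R_k \mathbf{s}_k$.  The rotated slice is
then still a valid projection of the velocity field along the rotated
direction — this equivariance (`phaseFromVelocity(Rv, Rs) ==
phaseFromVelocity(v, s)`) is the property that makes motion-corrected
velocity encoding possible at all, and it is tested directly.

## The inverse problem

Each kept frame pixel contributes one sample.  The forward model predicts
its phase from the cine velocity volume $V = \{v_{q,ih}\}$ (component
$q$, voxel $i$, cardiac phase $h$) as

$$\hat\phi_{jk} = \sum_h \tau_{hk} \sum_i w^{k}_{ij}\,
\mathbf{s}^*_k \cdot \mathbf{v}_{ih},$$

with $w$ anisotropic-Gaussian point-spread weights expressed in the
frame's slice coordinates (through-slice FWHM equal to the slice
thickness, in-plane FWHM 1.2 times the in-plane spacing, support radius 2
target voxels), normalized to sum 1 per sample, and $\tau$ a
wrapped-Gaussian kernel over cardiac phase distance, normalized over the
cine phases so that static problems ($N_h = 1$) reduce exactly to the
spatial model.  PSF entries below 1% of a sample's maximum weight are
dropped and the rest renormalized; this keeps about 95% of the kernel
mass while roughly halving the memory of the sparse system, whose
assembly is the dominant memory cost at full problem size.

The volume is estimated as

$$V = \arg\min_V \sum_k p_k \lVert \phi_k - \hat\phi_k(V)\rVert^2
+ \lambda\,\mathrm{Reg}(V),$$

with $p_k$ the per-frame outlier weights inherited from the magnitude
cine pipeline (consumed as inputs; frames with $p_k = 0$ are dropped).
$\mathrm{Reg}$ is a Charbonnier (smoothed-$L_1$) penalty on first
differences of each velocity component over the 6-neighborhood,
$\rho(t) = 2(\sqrt{1+t^2}-1)$ with $t = \Delta v/\delta$: quadratic for
differences below the scale $\delta$ (noise suppression) and linear above
it (edges such as vessel walls are preserved).  Components are
regularized independently; regularizing $|V|$ instead would couple the
components nonlinearly for no clear benefit.

The minimization starts from $V \equiv 0$ and uses Polak–Ribière
nonlinear conjugate gradient with Armijo backtracking, restarting every
10 iterations.  The data term is quadratic, so each line search costs one
forward application plus cheap regularizer evaluations; the objective is
non-increasing by construction and the solve is deterministic.

### Choice of lambda and delta

Neither the regularizer form nor its weights are prescribed by the
measurement physics, so they are package design choices, fixed as
defaults and configurable in `reconConfig()`:

* `delta = 30` cm/s.  On the default phantom, adjacent-voxel differences
  produced by noise alone are of the order of 3–10 cm/s while true
  transverse profile differences reach 20–25 cm/s near the walls of the
  fastest pipes; `delta` sits just above the steepest true gradients, so
  noise and the flow profiles themselves are smoothed in the
  near-quadratic regime while only genuinely sharp structure (several
  times the profile slope) would be treated as an edge.  Much smaller
  values (e.g. 5) penalize the flow profiles nearly linearly and visibly
  shrink peak velocities, hitting mid-speed pipes hardest.
* `lambda = 0.1`.  At the solution of the default noisy phantom problem
  this puts the data term and `lambda` times the regularizer within one
  order of magnitude of each other (the solver reports both), the point
  where the inversion stops amplifying sample noise without flattening
  the Gaussian flow profiles.

Because flow in a straight pipe is constant along the axis, the
regularizer mostly averages axially (differences near zero, fully
quadratic regime), which reduces noise without biasing the transverse
profile — one reason an edge-preserving penalty outperforms both no
regularization (noise amplified by the implicit deconvolution of the
PSF) and small-`delta` settings here.

### Encoding coverage

The per-voxel encoding matrix $\sum_k w\,p_k\,\mathbf{s}^*_k
\mathbf{s}^{*T}_k$ tells whether the three components are recoverable at
that voxel.  `coverageMap()` computes its rank and condition number
(closed-form symmetric 3x3 eigenvalues, vectorized over the volume; the
implementation is verified against `eigen()` in the tests).  Voxels with
rank below 3 or condition number above `conditionLimit` (default 100)
are still reconstructed — the regularizer propagates information into
them — but are flagged and must not be trusted quantitatively.  Removing
stacks over a sub-region reproduces exactly the failure mode this guards
against: a localized patch of wrong vectors co-located with the flags.

## Background phase and drift corrections

Hardware phase offsets (eddy currents, concomitant gradients) and slow
maternal/fetal motion add a spatially smooth background to every phase
image.  `backgroundCorrectStack()` fits one third-order polynomial per
stack over world coordinates — 20 monomials over coordinates centered on
the fitting-mask centroid and scaled by their radius of gyration, purely
for numerical conditioning — to the phase values inside a mask that must
exclude the heart and vessels, then subtracts the fitted field from
every frame and re-wraps.  Fitting is joint over all slices of the stack
(a single 3D polynomial), not per slice: the offsets vary smoothly in
3D and a joint fit is far better conditioned in the through-slice
direction.  On stacks whose background is exactly a degree-3 field the
correction is exact to numerical precision, and it is idempotent.

After reconstruction a residual, spatially smooth velocity offset can
remain.  `velocityDriftCorrect()` takes, per component, the per-voxel
median over cardiac frames restricted to non-blood voxels, fits the same
third-order spatial polynomial to those medians, and subtracts the
evaluated field from every frame globally.  The drift model adopted here
is spatial (one polynomial per component, constant in time); the
alternative temporal or spatio-temporal readings would require a drift
signal that the static phantom cannot exhibit, and the spatial reading is
the only one that a median *over frames* feeds naturally.  The non-blood
mask (`nonbloodMask()`) keeps voxels that stay below 50% of the
99th-percentile magnitude in *every* cardiac frame, so any voxel that
ever contains blood is excluded.

## The digital flow phantom

`defaultPhantom()` builds the validation object: six straight cylindrical
pipes in three antiparallel pairs along the three world axes, peak speeds
±25, ±80 and ±100 cm/s, radius 5 mm, truncated-Gaussian transverse
profile with sigma = radius/2 (a smooth stand-in for laminar flow), on a
96³ grid at 1 mm.  Geometry parameters without a physically mandated
value were fixed once as package defaults: pipe pairs are offset ±12 mm
from the volume center along one
perpendicular axis each (keeping all pipe axes 12 mm apart, so 5 mm-radius
pipes never overlap), and voxel centers are anchored on integer
millimetres so the pipe axes are sampled exactly and the discrete truth
attains the nominal peaks.  `defaultStackPlan()` supplies the five-stack
acquisition described above (three axis-aligned stacks, each orthogonal
to one pipe pair, plus two oblique stacks rotated 45° about z and about
x), all with VENC 159 cm/s.

`simulateStack()` samples the ground truth by trilinear interpolation at
each slice voxel's world center (after any injected per-frame rigid
transform), applies the encoding dot product with the rotated
sensitivity, adds Gaussian phase noise (default sigma 0.10 rad, a
moderate-SNR setting: 0.1 rad corresponds to about 5 cm/s of velocity
noise per projection at VENC 159 cm/s) and wraps.  The whole simulation
is driven by one integer seed and is bit-reproducible.

What the phantom does *not* emulate: bSSFP signal physics (banding,
off-resonance, transients), k-t undersampling artefacts, pulsatility
(flow is constant in time), partial-volume magnitude effects, or
registration errors (transforms are known exactly).  Tests passing on
the phantom therefore validate the geometry, encoding and inversion
machinery — not robustness to acquisition physics that the simulation
never generates.

## Problem sizes used in the validation suite

The end-to-end experiment (`validatePhantomExperiment()`) runs at the
full 96³/1 mm, five-stack scale for the headline parameter-recovery
check, about 4.4 million phase samples and 2.65 million unknowns.
Supporting experiments use reduced grids chosen as the smallest that
still exhibit the property under test: the per-voxel least-squares
equivalence runs at 32³, the motion and coverage experiments at 48–64³
(the phantom scales all pipe geometry with the grid), and the
property-style optimizer checks (objective monotonicity,
finite-difference gradients) on randomized ~6³ instances.

## Known limitations

* Speeds above VENC wrap and are reported as errors, never unwrapped.
* Flow quantification follows the |V| x area definition; for vessels not
  perpendicular to the ROI plane this overestimates through-plane flow,
  and an opt-in `normalComponent` mode integrates the signed v·n instead.
* The solver is single-scale; very large volumes rely on the sparse
  system fitting in memory (about 2–3 GB at the default scale).
* Cardiac phases and R-R intervals are consumed as inputs; heart-rate
  estimation, cardiac synchronization and registration live upstream.
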