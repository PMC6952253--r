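---
title: "Models and numerics behind kbsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind kbsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`kbsim` simulates an ultrasound-guided kidney biopsy: a deformable kidney,
a rigid needle exchanging forces with it, a haptic output channel, and the
ultrasound frame a trainee would watch. This vignette is the package's
account of the science: the models, their assumptions, the tunable
parameters, and the numerical choices that make the pipeline deterministic
and testable.

## Deformable kidney: corotational tetrahedral FEM

The kidney occupies a tetrahedral mesh with linear shape functions. Renal
parenchyma at procedure strain levels is modelled as isotropic linear
elastic with **E = 0.1 MPa** and **ν = 0.3**; density defaults to
**ρ = 1050 kg/m³**, a standard soft-tissue value. Pure linear FEM produces
spurious forces under large rigid rotations, so each element is evaluated
in a rotated frame (corotational formulation): with rest shape matrix
$D_m$ and current shape matrix $D_s$, the deformation gradient is
$F = D_s D_m^{-1}$ and the element rotation $R$ is the polar factor of
$F$, computed by SVD with determinant correction
($R = U\,\mathrm{diag}(1,1,\det(UV^\top))\,V^\top$). SVD was chosen over
faster iterative polar schemes because it stays well-behaved arbitrarily
close to element degeneracy. Whether to extract rotations per element or
per node is an open design choice in this class of simulator; the
element-based variant is implemented because it makes frame indifference
exact at the element level, which the tests exploit.

Elements whose four nodes sit bit-exactly at their rest positions are
assigned $R = I$ directly. This makes the rest configuration an exact zero
of the force — otherwise the floating-point residue of $D_m D_m^{-1}$
(~1e−16) leaks into displacements and, eventually, into rendered frames.

**Units.** Meshes are in mm (the clinical convention) while E is quoted in
Pa, so the model is assembled in the mm–N–s–tonne system: stiffness in
N/mm with E in MPa, lumped mass in tonnes (ρ·V/4 per tet node), forces in
N. Energies are reported in J.

## Time integration

One backward Euler step solves

$$(M + \Delta t\,C + \Delta t^2 \tilde K)\,\Delta v =
  \Delta t\,(f_{ext} + f_{int}(x) - C v) - \Delta t^2 \tilde K v,$$

with $\tilde K = \sum_e R_e K_e R_e^\top$ frozen at the step start (one
linearisation per step, no Newton loop — the real-time trade-off this
class of simulator makes), Rayleigh damping $C = \alpha M + \beta \tilde K$
(defaults α = 1 s⁻¹, β = 0.01 s, chosen for visibly damped, stable
interaction; both exposed in config), and Δt = 1/60 s, the visual
simulation rate. The $-\Delta t^2 \tilde K v$ term is part of the
consistent linearisation around $x + \Delta t\,(v + \Delta v)$; dropping
it makes the step inject energy, which the dissipativity test would catch.

**Constraints.** Zero-displacement (Dirichlet) conditions on the
renal-pelvis node set are enforced by projection inside the linear solve:
constrained rows of the right-hand side, residual and search direction are
zeroed, and the final state is overwritten with exact zeros, so the
constraint holds to the last bit. The solver is conjugate gradients with a
Jacobi (diagonal) preconditioner, relative tolerance 1e−8, at most 500
iterations; a step that fails to converge raises an error with the
residual rather than continuing silently.

**External attachments.** The needle's lateral springs and viscous shaft
friction act on nodes that are much softer than the springs themselves.
Treated explicitly they oscillate and can invert boundary elements within
a few steps, so their stiffness (per-node diagonal $k_\perp$) and
viscosity enter the implicit system matrix, while their step-start forces
enter $f_{ext}$. This changes no equilibrium, only the stability of the
path to it.

**Dissipativity in practice.** With damping on and no external force,
total mechanical energy decreases monotonically until it reaches the CG
noise floor (~1e−12 of the initial energy); tests assert monotonicity with
exactly that floor as slack.

## Needle-tissue interaction

The needle is a rigid segment (tip, unit direction, length) — biopsy
needles bend little over the short percutaneous path, and a segment rather
than an infinite line prevents spurious coupling behind the handle. Nodes
whose point-to-segment distance is below `d_thr` (default 4 mm) couple to
the shaft:

* lateral spring toward the closest axis point, `k_perp` = 0.3 N/mm;
* axial friction on the needle
  $-(\mu_v v_{rel} + f_c\,n\,\mathrm{sign}(v_{rel}))\,\hat d$ with
  $\mu_v$ = 0.05 N·s/mm and $f_c$ = 0.02 N per coupled node, where
  $v_{rel}$ is the tip's axial velocity relative to the mean coupled-node
  velocity. The tissue-side reaction is distributed equally over coupled
  nodes, so total momentum exchange is exactly zero.

Capsule puncture is a three-state machine driven by the signed tip-to-
surface gap (ray cast along the needle direction against the rest-pose
boundary triangles — deterministic, and surface motion at the entry point
is far below the force scale of interest): pressing on the surface builds
a membrane force `k_membrane`·depth (0.5 N/mm); at `f_puncture` (1.5 N)
the capsule breaks and resistance drops to `drop_factor`·`f_puncture`
(0.3); retracting above the surface frees the needle. None of these
numeric values is reported by the hardware trainer this emulates — they
sit in the range published for biopsy needle insertion and are exposed in
config as tuning knobs, not as reference values. Coincident ray crossings
(through a shared mesh vertex or edge) are collapsed before the
inside/outside parity test so the state machine cannot be confused by
exact-symmetry trajectories.

## Haptic force channel

The haptic loop runs an order of magnitude faster than the simulation, so
the device holds the last force it received (zeroth-order hold, inclusive
at sample instants: a query exactly at a sample time returns that sample).
The hold turns a ramp into a staircase whose steps a user can feel; a
causal moving average over the last K haptic-rate samples (default K = 1,
i.e. off) divides the maximum step by exactly K for that staircase. The
channel is modelled as deterministic post-hoc resampling of the per-step
force log — real-time threading is out of scope, and determinism is what
makes the closed-form tests possible.

## Ultrasound view

World convention: RAS, mm; volumes carry origin/spacing/direction with
voxel centres at half-integer continuous coordinates; the slice origin is
at the image centre. Reslicing samples the volume with trilinear
interpolation (constant 0 outside). Continuous coordinates within 1e−9 of
a lattice point are snapped so that voxel-aligned poses reproduce voxel
planes bit-exactly; trilinear interpolation is exact for affine intensity
fields, which the tests verify on oblique planes.

Deformation display uses backward warping of the 2D slice: each pixel's
world point $x$ is pulled back to $x - \hat u(x)$, with $\hat u$ the
barycentric interpolation of nodal displacements over the tet containing
$x$ in the *deformed* configuration, and zero outside the mesh (point-
location failure is "outside", never an error; ties at shared faces go to
the lowest element index). Whether the original hardware system warped the
3D volume or the extracted slice is ambiguous; per-slice warping is the
observably equivalent and much cheaper choice. The needle echo — Gaussian
transverse profile (amplitude 200, σ = 0.6 mm), linear out-of-plane
falloff inside the slab, additive and clamped to [0, 255] — is overlaid
*after* warping because the physical needle is rigid and its image should
not deform. Reverberation and comet-tail artefacts are not modelled.

## Synthetic phantom and trajectories

The phantom stands in for a patient acquisition plus expert segmentation:
a 128×128×96 volume at 0.8 mm with an ellipsoidal kidney (semi-axes
45×25×25 mm — renal long-axis proportions), bright one-voxel capsule rim,
mid-echogenic cortex, echogenic sinus at half the semi-axes, and
multiplicative speckle. Fully developed speckle is Rayleigh distributed,
but a Rayleigh factor scaled to unit mean has a *fixed* coefficient of
variation, so a strength parameter cannot scale it directly; the
implemented factor is $1 + \sigma_s\,(X/\mathbb E[X] - 1)$ with $X$
Rayleigh — unit mean, standard deviation proportional to $\sigma_s$
(default 0.5), exact identity at $\sigma_s = 0$. Clamping to [0, 255]
biases very bright voxels slightly; the cortex mean test budgets for it.

The matched mesh tetrahedralises the same ellipsoid on a body-centred
cubic lattice (12 tets of volume h³/12 per lattice cube): tets whose
centroid lies inside are kept, boundary nodes are snapped radially onto
the analytic surface, and any element flattened below 5% of its lattice
volume is repaired by relaxing its *interior* nodes back toward the
lattice — boundary nodes stay pinned on the surface so the mesh never
pokes past the voxel kidney. The default spacing targets ~2600 elements,
the scale of a decimated patient-specific kidney mesh; mesh volume
converges to the analytic ellipsoid volume as the lattice is refined.
General Delaunay meshing of arbitrary surfaces is deliberately not
implemented — users with segmented surfaces bring externally generated
TetGen or legacy-VTK meshes.

Scripted trajectories replace the electromagnetic tracker and the haptic
stylus. Positions interpolate linearly between keyframes; rotations use
normalised-linear quaternion interpolation (nlerp — monotone, cheap, and
exact at the midpoint where the tests pin it against slerp); needle tip
velocity is the analytic derivative of the interpolant. The canonical
session — scan 2.5 s, aim 1 s, insert 30 mm at 5 mm/s, retract — runs
10 s at 60 Hz and punctures the capsule exactly once.

## What the phantom does and does not show

Passing tests on the phantom demonstrate the *mechanics* of the pipeline:
geometric exactness of reslicing and warping, conservation and
dissipation properties of the FEM, closed-form behaviour of puncture and
haptic resampling, and bit-level reproducibility. They do not demonstrate
clinical realism: the phantom has no extrarenal tissue layers (so the
needle is less constrained than in vivo), no acoustic shadowing or
attenuation, a single organ, and an idealised ellipsoidal geometry. The
deformable body is the kidney alone; surrounding layers appear only
through the needle's friction parameters, which can be scheduled over
depth in config if layered resistance is wanted.

## Problem sizes and tolerances used in the checks

Unit-level oracles run on meshes of one to a few hundred elements; the
linear-FEM equivalence check uses a ≤300-node ellipsoid against a densely
assembled stiffness, with displacements ~1e−6 of the mesh size — the
corotational-vs-linear gap is first order in the displacement gradient,
so agreement to 1e−5 is only meaningful in that asymptotic regime.
Dissipativity runs 1000 unforced steps on the small mesh. Full-scale
checks (frame indifference, the canonical session run twice and compared
bit-for-bit) use the default ~2600-element phantom mesh and 601 frames at
128×96 px. These sizes keep a complete test run in a few minutes while
still exercising the element count the simulator is designed around.

## Known limitations

* One linearisation per step: very stiff materials or large steps trade
  accuracy for stability (backward Euler's numerical damping absorbs the
  error); there is no Newton loop.
* Element inversion aborts the step with a diagnostic; there is no
  inversion recovery.
* The coupling force law (springs + friction + membrane) is
  phenomenological; its constants are tuning knobs.
* Imaging is geometric, not acoustic: no speckle decorrelation under
  deformation, no refraction, no needle reverberation.
* Probe-tissue mechanical interaction is not simulated; the probe only
  selects the imaging plane.
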