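---
title: "Force inference from embryo cell shapes: models, calibration and benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force inference from embryo cell shapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the mechanical models implemented in `fides`, the
numerical choices behind them, the calibration of the discrete contact
model, what the synthetic benchmarks emulate, and the limitations a user
should keep in mind. Nothing here reports results beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The forward deformable cell model

Each cell is a closed triangle mesh whose nodes move overdamped,
`dx/dt = F / (c_i)`, with nodal drag `c_i = medium_drag * A_i` (`A_i` the
mixed-Voronoi node area). The forces are:

* **Cortical tension**: the exact negative gradient of the surface energy
  `gamma * A_total`. For a sphere this reproduces the Laplace traction
  `2 gamma H` per unit area, which is one of the model's acceptance
  oracles.
* **Volume conservation**: a pressure `P = K (V* - V) / V*` acting along
  outward node normals. The linear volumetric law is a choice; the
  emergent behavior that matters (and that is tested) is the Young-Laplace
  balance `P = 2 gamma H` of a relaxed cell. With the default `K = 50`
  (in units of `gamma0 / R0`), a free cell under unit tension loses about
  4% of its target volume at equilibrium.
* **Adhesive contact**: a Maugis-Dugdale-style traction between facing
  surfaces: linear repulsion on penetration plus a constant adhesive
  traction that persists under compression and tapers to zero over the
  outer 30% of the contact range. Its integral -- the work of separation --
  is the adhesive tension `omega` per unit area, which makes the
  interfacial tension `gamma_ij = gamma_i + gamma_j - omega_ij` and the
  Young-Dupre junction angles emerge. Tractions act along the
  closest-point direction (the gradient of a distance potential), blended
  into a smooth inter-normal axis at vanishing gap where that direction is
  undefined.
* **Eggshell**: a rigid convex polytope (a possibly shrunken convex hull
  of the embryo); nodes beyond a face plane feel a capped linear penalty.
* **Friction and viscosity**: tangential wet friction at contacts and a
  weak in-plane damping of edge-length rates. Inferences must not depend
  on their exact values; they shape transients only.

### Numerical stabilization of the discrete contact

A penalty-based adhesive contact between two explicit membranes is
delicate. Three ingredients proved necessary and are on by default:

1. **Smooth geometric queries.** The signed gap uses barycentric (Phong)
   interpolated normals and a blended contact axis; face-normal or
   closest-triangle switching otherwise flips the sign stochastically on
   rumpled surfaces and pumps a period-2 oscillation.
2. **Contact drag.** Nodes currently in contact get extra drag
   (`contact_extra_drag`, additive per contact partner). This models wet
   interface friction and damps the stiff normal dynamics without moving
   any equilibrium.
3. **Tangential mesh regularization.** Every step each node relaxes toward
   its neighbor average within its tangent plane (`mesh_smoothing`). This
   keeps the triangulation sliver-free at contact rims and furrows; to
   first order it does not change the shape. Without it, collapsed Voronoi
   areas make the cotangent tension stiffness explode on crumpled
   triangles.

### Calibration of the effective adhesion

At the default resolution (about 1,280 triangles per cell, edge length
~0.13 cell radii) the finite contact range (0.1 `R0`) makes the *emergent*
work of separation deviate from the nominal `omega`: short-range
attraction acts across shallow junction wedges (extra adhesion at small
`omega`), while discrete zipping resists junction advance (missing
adhesion at large `omega`). We therefore calibrate once, on relaxed
equal-tension doublets, the map from nominal to internal adhesion by
measuring the equilibrium junction angle and inverting the Young-Dupre
relation. The map (`fides:::.adhesion_calibration`) is monotone and is
applied in units of the mean tension of the contacting pair. It saturates
near `omega/gamma ~ 1`: very strong adhesion (contact angles beyond
~115 degrees) is not representable at this resolution, and the strongest
point of the doublet angle test retains a residual of several degrees.
Synthetic benchmarks therefore draw `omega` in [0.25, 0.65].

### Junction settling by adhesion annealing

Discrete contact lines pin: a junction must move node by node, so it
stalls anywhere within a hysteresis band of roughly ten degrees around its
equilibrium angle. `relax_annealed()` cycles all adhesive tensions around
their nominal values with a decaying amplitude (default six cycles,
amplitude 0.35, half-cycle duration 0.7, final quiet phase 5 time units),
driving each junction repeatedly through zip and peel until it settles.
The generators use this protocol; plain `relax()` is what the
shape-fitting evaluations use, since they only integrate short transients.

### Active models

The **cytokinetic ring** selects the node loop nearest the intersection of
the division plane (normal from spherical coordinates, offset `d` from the
cell center) with the mesh, connects consecutive nodes by zero-rest-length
springs of constant `k`, and smears each ring node's spring force over
nearby nodes with Gaussian weights (width two mean edge lengths) to keep
the furrow smooth. A proportional controller (`K_D`) stabilizes the
surface areas of the two sides against the reference captured at
attachment. The combined active force is projected to zero net force.

The **protrusion** distributes a total outward force `F_P` with a
difference-of-Gaussians weight `G_a - G_2a` in the angle between a node's
direction from the cell centroid and the protrusion axis, applied along
node normals (`G_s(b) = exp(-b^2 / 2 s^2) / s`, `a = alpha`); the DoG's
amplitude normalization and `sigma = alpha` are package choices, as only
relative magnitudes matter for inference. The residual net force is
inverted and redistributed over the protrusion so the total is exactly
zero. `F_P` is the sum of outward force magnitudes.

## Foam force inference

`ffi()` runs three stages:

1. **Interface classification**: a triangle belongs to the contact with
   the partner cell whose surface lies within the classification gap of
   its centroid, else to the exterior; the two facing patches of a contact
   form one interface.
2. **Junction measurement**: junction polylines are the edges where
   triangle labels change; samples are pooled over the polylines of every
   member mesh so per-mesh biases at two-sided interfaces cancel. At each
   sample, each of the three surfaces' tangents is estimated by fitting a
   sphere to interface triangles in a neighborhood that excludes a band of
   1.2 edge lengths around *any* junction (the junction cores are rounded
   by the finite contact range); the fit falls back to a linear
   extrapolation of the sign-aligned triangle normals in arc distance when
   it is inconsistent with it (saddle-shaped interfaces) or nearly flat.
   The three sector angles per sample close to 360 degrees by
   construction and are averaged along the junction. Interfaces with fewer
   than 50 triangles are excluded, as are junctions touching them.
3. **Least-squares solve**: two force-balance rows per junction (the
   Young-Dupre balance in the plane normal to the junction), one gauge row
   fixing the mean surface tension to 1, and -- in curved mode -- one
   Young-Laplace row `P_i - P_j = 2 H_ij gamma_ij` per measured interface
   curvature, with exterior pressure 0. Curvatures average per-node
   cotangent-Laplacian mean curvature over interface triangles at least
   two edge lengths from any junction, oriented from the
   lexicographically first region to the second. The pseudo-inverse
   (SVD) solves the stacked system; tensions are rescaled afterwards so
   the mean surface tension is exactly 1 (all non-gauge rows are
   homogeneous, so this is exact).

The unweighted mean over junction samples is used (whether the original
procedure weights by arc length is unknown; at our junction lengths the
difference is below the sampling noise).

## Shape-fitting inference (the inverse problem)

`fides_fit()` fits per-cell surface tensions, per-contact adhesive
tensions, per-cell target volumes and four parameters per scheduled ring
or protrusion. Each evaluation instantiates the forward model on the
observed meshes, integrates for dimensionless time 2.5, and computes the
deformation error `E_D = sum_i A_i d_i` (area-weighted normal-raycast
distances from the observed to the simulated surfaces) plus small linear
penalties on total adhesion energy, ring spring constants, and protrusive
forces (default weight: `1e-3` of the initial `E_D` per unit), so active
forces survive only where they clearly help. The optimizer perturbs each
parameter independently with a Gaussian step (5% of the tension scale for
tensions, 2% of the cell volume for targets, 0.05 rad for orientations, 5%
for magnitudes), evaluates each candidate against the same baseline,
applies all improving changes jointly, renormalizes the mean surface
tension to 1 (rescaling adhesions with it), and stops after 15 iterations
without improvement or at the iteration cap of 150. Divergent evaluations
score infinity. Because candidate evaluations within an iteration are
independent, execution order cannot affect accept decisions.

## Synthetic benchmarks

`make_simple_embryo()` builds a four-cell rhombus with five contacts:
radii drawn in [0.9, 1.15], tensions uniform within the spread
(default 0.3) and normalized to mean 1, adhesions in [0.25, 0.65]
(redrawn if an interfacial tension would be non-positive), placed tangent,
relaxed and annealed. `make_advanced_embryo()` places seven cells in a
schematic 7-cell arrangement (anterior AB quartet with the posterior pair
skewed to one side, MS and E ventral, P2 posterior) chosen so the 15
parametrized contacts all form; options add a hull eggshell shrunk to
0.965 (pressing every cell against the shell while keeping exterior
surfaces clearly curved) and the active set (one ring on P2 with a
pronounced but incomplete furrow, three protrusions on ABpl, one on ABpr).
All randomness is drawn before simulation, so a seed fully determines the
embryo.

What the generator does *not* emulate: segmentation noise, irregular
triangulations, anisotropic cortical tension, temporal dynamics. Passing
benchmarks therefore show method correctness under the model's own
assumptions, not robustness to imaging artifacts.

Problem sizes used by the shipped tests and the acceptance script (chosen
for a single-CPU run): benchmark embryos at 1,280 triangles per cell; the
shape-fitting checks run on 80-triangle-per-cell embryos with 30-60
iterations and a 2e-3 time step; benchmark statistics average 5 seeds in
the acceptance script and a single seed in the test suite.

## Ablation analysis

Recoil speeds follow `v(t) = v0 exp(-t / tau)` (Kelvin-Voigt cortex with
released active tension): `v0` is the tension proxy, `1/tau` the
stiffness proxy. Fits are nonlinear least squares on speeds. Because a
tracked speed is a displacement average over one frame reported at the
earlier frame time, `v0` is biased low for fast decays;
`calibrate_bias()` simulates ideal recoils through the frame window and
regresses the correction factor minus one on the fitted decay rate through
the origin. With 1-second frames the coefficient is about 0.66 s (and the
fitted decay rate itself is essentially unbiased), recovering the standard
correction `v_real = (1 + 0.66 / tau) * v_measured`; the window-center
timestamp convention would instead cancel the bias almost entirely, which
is how the reported coefficient pins down the convention.
`weighted_bootstrap()` resamples tracked points with weights equalizing
each cut's contribution, refits per replicate (2,000 by default), and
reports percentile intervals and one-sided p-values as the fraction of
replicates in which one condition's statistic does not exceed the other's.

## Known limitations

* The adhesion calibration is resolution-specific (measured at 1,280
  triangles per cell) and saturates near `omega/gamma ~ 1`; contact
  angles beyond ~115 degrees are out of reach, and the strongest-adhesion
  doublet check misses its 3-degree target by several degrees.
* Junction pinning is controlled, not eliminated: without annealing,
  junction angles can sit up to ~10 degrees from equilibrium.
* Confined, active embryos are genuinely hard for angle-based inference --
  that is the point of the benchmark -- but the *amount* of degradation
  depends on generator parameters (shell shrink, ring and protrusion
  strength) for which no published values exist; they were fixed once on
  geometric grounds.
* Absolute tensions and pressures are never produced; everything is
  relative to the mean surface tension.
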