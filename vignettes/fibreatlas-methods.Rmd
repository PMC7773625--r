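---
title: "Atrial fibre fields on surface meshes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atrial fibre fields on surface meshes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

Atrial myocytes have a preferential orientation (the *fibre* direction)
that steers electrical propagation, yet it cannot be imaged in vivo.
`fibreatlas` implements a complete desk-scale pipeline for working with
fibre fields on triangulated atrial surfaces:

1. a landmark-fixed two-coordinate system per chamber (two harmonic
   fields mapping each atrium to the unit square),
2. registration of per-element fibre fields between anatomies through
   that coordinate space,
3. circular-statistics averaging of co-registered fields into an atlas
   with per-element uncertainty,
4. streamline visualisation,
5. anisotropic monodomain simulation on single-surface and bilayer
   meshes (paced activation-time maps and their comparison metrics), and
6. spiral-wave arrhythmia runs post-processed into phase-singularity
   density maps compared by Pearson correlation.

Every stage is exercised end-to-end on synthetic anatomies generated by
the package itself, so the whole pipeline is testable without any
imaging data.

# The coordinate system

Each atrium is an open surface: an ellipsoid-like shell with rims at the
valve (mitral or tricuspid) and at the vessels (four pulmonary veins;
superior/inferior vena cava and coronary sinus). Two scalar fields
$\alpha,\beta : S \to [0,1]$ are computed as discrete harmonic functions
(cotangent-weight piecewise-linear FEM, no mass lumping; negative
cotangent weights from obtuse triangles are kept) with Dirichlet data on
landmark-derived boundary sets, so that $(\alpha, \beta)$ flattens the
chamber to the unit square.

The construction is driven entirely by the labelled rims plus one seed
point for the LA (a lateral mitral point) or two for the RA (posterior
and anterior tricuspid split points):

* A **cut chain** runs from one valve split vertex over the chamber dome
  (through the vertex farthest from the valve on the edge graph,
  avoiding every rim) to the other split vertex. Geodesics are edge-graph
  shortest paths (Dijkstra) — robust and sufficient, since the paths
  only seed Dirichlet boundaries.
* For the LA, $\beta$ (posterior MV $\to$ roof $\to$ anterior MV) is
  solved separately on the posterior and anterior sub-meshes produced by
  the cut: posterior-MV arc $=0$, anterior-MV arc $=1$, and the **roof
  segment** of the chain (between the superior PV rims) fixed at
  $\beta_{\text{roof}} = 0.5$ (configurable). The two solutions are
  rescaled to $[0, 0.5]$ and $[0.5, 1]$ and concatenated; continuity is
  verified on the roof. $\alpha$ (septal $\to$ lateral) is one full-mesh
  solve with $0$/$1$ on the septal/lateral chain halves.
* The RA mirrors this exactly with the chamber's own landmarks: $\alpha$
  (lateral TV $\to$ septal TV) is the two-region coordinate, split along
  the chain with the **inter-caval segment** fixed at $0.5$, and $\beta$
  (IVC $\to$ SVC) is the full-mesh coordinate driven by the chain
  halves, with the caval rims pinned (below).
* Along the non-interface part of the chain the two-region coordinate is
  genuinely double-valued — the **seam**. The package stores per-element
  corner coordinates, so all downstream geometry (bases, flattening,
  interpolation) uses region-consistent values; the seam vertices are
  reported and seam-adjacent elements get special treatment during
  mapping.

**Structure pinning.** Mapping fibres between anatomies requires that
the same anatomical structure sits at the same coordinates everywhere.
Each vessel rim is pinned by an *exact mean-coordinate constraint*
(a Lagrange multiplier on the reduced FEM system forcing the rim's
average $\alpha$ and $\beta$ to the atlas table) rather than by hard
per-vertex Dirichlet values. This fixes the structure's location while
letting the rim keep the shape and size the harmonic field prefers,
which empirically keeps the flattening fold-free; hard pinning of whole
rims to prescribed circles was tried and consistently folded the
one-ring. The shipped atlas table is the population average of the
unpinned rim centroids over the synthetic anatomy family — the same
averaging construction used to minimise distortion in data-driven
coordinate systems — and is plain editable data.

**Numerical safeguards.** Solves are checked to a relative residual of
$10^{-10}$. A local untangling pass then repairs any residual folds:
vertices of inverted triangles (and their one-ring) are relaxed toward
their neighbour average (Tutte-style uniform weights), Dirichlet nodes
never move, and after every sweep each pinned rim is shifted uniformly
back to its exact mean target. On the synthetic anatomies this converges
in $\le$ 20 sweeps and the flattening ends with zero inverted triangles
off the seam (`count_flipped_triangles`).

# Fibre representation and mapping

Fibres are sense-free unit tangent vectors per element ($v$ and $-v$
equivalent). The local basis is $e_\alpha$ (in-plane normalised gradient
of $\alpha$) and $e_\beta = n \times e_\alpha$. Angles are measured from
the chamber's reference axis — the $\alpha$ axis for the LA (so
$\theta \approx 0$ is lateral–septal and $\theta \approx \pi/2$
posterior–anterior) and the $\beta$ axis for the RA ($\theta \approx 0$
IVC–SVC) — and wrapped to $[0, \pi)$.

All interpolation and averaging of angles happens on the **doubled
angle** $(\cos 2\theta, \sin 2\theta)$, which respects the $0/\pi$
identification; raw $\theta$ interpolation would be discontinuous at the
wrap. To map a field from anatomy A to anatomy B, per-vertex doubled
resultants are built on A's flattened (seam-duplicated) triangulation,
each B element centroid is located there (grid-accelerated point
location with snapping), the doubled vector is barycentrically
interpolated and halved back to an angle, and the 3D tangent vector is
rebuilt through B's basis. Elements on the seam, or whose interpolation
is degenerate, take their nearest resolved neighbour's value. Mapping a
field onto its own anatomy is detected and returned exactly (the
vertex-smoothing interpolant cannot reproduce per-element noise, so the
identity is special-cased rather than approximated).

# Circular statistics and comparison metrics

Axial (period-$\pi$) statistics use the doubled-angle resultant:
$\mu = \tfrac12 \operatorname{atan2}(\overline{\sin 2\theta},
\overline{\cos 2\theta})$ and
$s = \tfrac12\sqrt{-2 \ln \bar R}$, matching the standard reference
implementation (`scipy` `circmean`/`circstd` with `low = 0`,
`high = pi`) to $10^{-9}$. A perfectly dispersed sample
($\bar R = 0$) is flagged and gets $\mu = 0$, $s = \infty$ by
convention. Note that this $\mu$ is exactly the minimiser of the
circular dispersion $\overline{1 - \cos 2(\theta - \mu)}$ — the circular
analogue of squared deviation — which is the property the test-suite
oracle verifies by brute force; the minimiser of literal squared wrapped
deviation differs at third order in the dispersion.

Two fields are compared per element by the folded acute angle
$E = \arccos(|F_1 \cdot F_2| / \lVert F_1\rVert \lVert F_2\rVert) \in
[0, \pi/2]$, the proportion $Q_{\pi/8}$ of elements with $E < \pi/8$
(strict, per-element counts, not area-weighted; area weighting is a
documented option left out of the default to mirror element-wise
treatment), and angle-class percentages splitting $[0,\pi)$ at $\pi/4$
and $5\pi/6$ (boundary values counted in the reference class, since the
published split uses strict inequalities on both sides and a tie rule
must be fixed). Named regions (posterior wall, roof, anterior wall,
appendage and vessel boxes) are axis-aligned boxes in coordinate space;
the shipped defaults match the package's own atlas layout and are
editable, which matters because any numeric reproduction of regional
percentages depends on the exact box extents.

# The synthetic anatomy family

`anatomy_spec()`/`make_anatomy()` generate idealised chambers: an
icosphere (subdivided icosahedron, near-equilateral triangles; the
target edge length is matched to the nearest subdivision level) opened
at circular caps for each rim, an appendage raised as a smooth radial
bump, and the result scaled to human-scale ellipsoid radii (LA default
22/20/18 mm). Case-to-case variability is a seeded jitter of radii
(±6%) and rim positions (±5°); the epicardial shell is a 0.5 mm normal
offset of the endocardial one (distinct from the 0.1 mm bilayer offset
used in simulation, which is a numerical device, not a wall thickness).
Cleanup guarantees manifold boundaries: stray components, boundary
pinches and same-loop boundary ears are removed (ears spanning two
loops are kept — removing them would merge neighbouring holes). The
default 1 mm setting yields roughly 2.2k vertices / 4.3k elements per
LA shell.

The default fibre pattern is a smooth angle surface
$\theta(\alpha,\beta)$ with posterior–anterior fibres over the roof and
lateral–septal fibres on the posterior and anterior walls, echoing the
dominant bundle layout of ex vivo fibre data. Perturbations are wrapped
normal on the doubled angle with standard deviation $1/\kappa$ radians;
$\kappa = 0$ disables the noise. (A von Mises *concentration* reading of
$\kappa$ is inconsistent with the requirement that $\kappa = 0$ mean "no
noise", so the inverse-scale convention was adopted; at the default
$\kappa = 8$ the per-element angular noise is $\approx 3.6^\circ$.) A
designated box gets $4\times$ the noise, emulating a locally unreliable
measurement; the atlas's standard-deviation field localises it. What
passing tests on these data do *not* show: real DT-MRI fields have
spatially correlated noise, discontinuous bundles and genuine
inter-subject disagreement far beyond jittered ellipsoids, so recovery
rates here are upper bounds on real-data behaviour.

`make_vector_cloud()` emulates voxel-grid fibre measurements (regular
grid at 0.4 mm pitch near the surface, nearest-element vectors) to test
`project_fibres_to_surface()`, which assigns each element the nearest
sample projected into the triangle plane.

# Streamlines

Streamlines are traced in the flattened square with fixed-step RK4
(defaults: step 0.005, 2000 steps, 10,000 random seeds), the direction
at each point being the interpolated doubled-angle halved back, with the
sign chosen to continue the previous step (the field has no sense);
seeds trace both directions. Integration deliberately ignores the metric
distortion of the flattening, as a 2D construction; trajectories stop at
the domain boundary, the seam, or where the angle is undefined. Thinning
is a greedy longest-first selection with a minimum point spacing — a
documented stand-in for any particular published selection rule. Lifted
3D polylines split where they cross the seam.

# Monodomain simulation

The reaction–diffusion substrate is P1 FEM with lumped mass on the
surface, with per-element in-plane conductivity tensors
$\sigma_t (I - n n^\top) + (\sigma_l - \sigma_t) f f^\top$; baseline
conductivities 0.4/0.1 S/m (4:1), the 10:1 variant 0.4/0.04 S/m;
surface-to-volume ratio 1400 cm$^{-1}$ and 1 µF/cm$^2$ capacitance
convert to diffusivities (0.286 mm$^2$/ms longitudinal at baseline).
Bilayer models duplicate the base surface offset 0.1 mm along vertex
normals (outward from the endocardial LA base, inward from the
epicardial RA base) and couple paired nodes linearly at rate
$\kappa_c$ (1/ms); the default $\kappa_c = 2$ gives sub-millisecond
transmural activation delay, and $\kappa_c = 0$ exactly decouples the
layers.

The membrane is pluggable; the required, tested default is a
two-variable normalised excitable model (Mitchell–Schaeffer form:
inward current $h v^2 (1-v)/\tau_{in}$ gated by a recovery variable,
linear outward current $v/\tau_{out}$; defaults $\tau_{in} = 0.3$,
$\tau_{out} = 6$, $\tau_{open} = 120$, $\tau_{close} = 80$ ms,
$v_{gate} = 0.13$, giving $\approx 150$ ms action potentials and
0.57 mm/ms longitudinal conduction at baseline). The `af = TRUE` preset
shortens $\tau_{close}$ to 30 ms and scales the inward current by 0.9 —
an excitability-reduction surrogate for the wavelength-shortening
electrical remodelling used to sustain fibrillation; a full ionic model
could be dropped in through the same interface, but the conclusions
exercised here depend on anisotropy and wavelength, which the surrogate
controls explicitly.

Time stepping is operator-split forward Euler at dt = 0.02 ms in
compiled code, guarded by a Gershgorin bound on the diffusion operator
(an explicit error, never silent instability); an implicit-diffusion
path (cached sparse LU, unconditionally stable) is available via
`method = "implicit"`. The explicit default was chosen because the
reaction-limited dt already satisfies the diffusion CFL at the mesh
scales the package targets and the compiled loop is an order of
magnitude faster.

Pacing sites are given in coordinates (portable across anatomies) and
stimulate a 2 mm ball for 2 ms; the amplitude auto-calibrates to 1.5×
the single-cell capture threshold times a diffusive-loading factor
(default 4, verified to capture on the shipped meshes). The protocol
default is the standard one (1 s lead-in, 5 beats at 700 ms cycle
length, activation read from the final beat); the examples and the
acceptance script use a scaled protocol (2 beats at 500 ms, 100 ms
lead-in) as their stated problem size. Activation time is the first
rising crossing of the midpoint between a node's extreme voltages,
linearly interpolated between samples; nodes without a 0.4 excursion
are reported missing. Map comparison returns the median absolute
difference and the maximum absolute difference as a percentage of the
reference map's total activation time.

# Arrhythmia metrics

Spiral-wave initial conditions place four Archimedean spirals (two
posterior, two anterior, equal spacing, alternating chirality for
adjacent cores) as a pseudo-activation-time field
$t_0 = (\text{cycle}/2\pi)(\chi \varphi + r/\text{pitch})$ about the
nearest core, realised by sampling membrane states from one steady paced
action potential; both layers get identical states. Phase is computed by
delay embedding, $\operatorname{atan2}(V(t) - \bar V, V(t-\tau) - \bar
V)$ with $\tau = 10$ ms — streaming-friendly and free of the edge
artefacts of transform-based phase, chosen because the upstream
phase-mapping method is not fully specified in print. Phase
singularities are triangles whose oriented wrapped phase differences sum
to $\pm 2\pi$ (the sign is the topological charge); locations are
element centroids in coordinate space, so different anatomies and layers
are directly comparable. Density maps are 32×32 histograms over the unit
square normalised by the analysed duration in seconds (so the map sums
to detections per second); snapshots default to every 5 ms; both are
configurable since no canonical values are published, and any smoothing
is left to the user. Termination is declared at the first snapshot with
no tissue above a small activity threshold, and analysis truncates
there.

# Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale: LA shells
at 1 mm (≈4.3k elements) and 2 mm (≈1.1k) settings, conduction-velocity
strips at 0.1 mm, 2 s arrhythmia runs on the coarse bilayer. All
randomness (anatomy jitter, fibre noise, streamline seeds, isotropic
control fields) flows through explicit integer seeds with the RNG state
restored afterwards (Mersenne-Twister), and repeated runs are
byte-identical.

# Known limitations

* Single-surface geometry: no transmural (third) coordinate and no
  volumetric fibre interpolation; four-PV topology is assumed.
* The coordinate recipe is the package's own (the published supplements
  it emulates are not printed in full); it makes no claim of
  bit-compatibility with any deposited coordinate data, and the atlas
  table must be re-pinned to reproduce specific published layouts.
* The membrane surrogate reproduces wavelength and restitution
  qualitatively, not ionic detail; no repolarisation heterogeneity or
  interatrial connections.
* Streamline tracing ignores flattening distortion; trajectories are
  faithful in coordinate space, not arc-length in 3D.
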