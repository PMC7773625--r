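# fibreatlas

Tools for building, registering, averaging, comparing and exercising
**atrial fibre fields** on triangulated surface meshes.

Atrial myocytes are arranged with a preferential orientation — the fibre
direction — that steers electrical propagation, but it cannot currently be
imaged in vivo, so computational models personalise fibres by mapping
measured or atlas fields onto patient geometry. `fibreatlas` provides the
full desk-scale toolchain for that problem, for modellers and
methodologists in computational cardiac electrophysiology:

* **Universal two-coordinate system per chamber.** Two discrete harmonic
  fields α, β (cotangent-FEM Laplace solves with landmark-derived
  Dirichlet data) flatten each atrium to the unit square; vessel rims are
  pinned by exact mean-coordinate constraints at shared atlas locations so
  structures coincide across anatomies.
* **Fibre registration and atlas construction.** Per-element sense-free
  fibre vectors are expressed as angles θ ∈ [0, π) in the local
  coordinate basis, mapped between anatomies by barycentric interpolation
  of the doubled angle (cos 2θ, sin 2θ), and averaged with axial circular
  statistics: μ = ½·atan2(mean sin 2θ, mean cos 2θ),
  s = ½·√(−2 ln R̄), giving a mean field plus per-element uncertainty.
* **Comparison metrics.** Folded acute angle
  E = arccos(|F₁·F₂|/‖F₁‖‖F₂‖) ∈ [0, π/2], the proportion Q_{π/8} of
  elements with E < π/8, and regional angle-class percentages.
* **Streamline visualisation** in coordinate space, thinned to regular
  coverage and lifted to 3D.
* **Anisotropic monodomain simulation** (compiled operator-split stepper,
  two-variable excitable membrane, conductivity tensors
  σ_t(I − nnᵀ) + (σ_l − σ_t)ffᵀ with baseline 0.4/0.1 S/m) on single
  surfaces and on endo/epi bilayers coupled node-to-node — paced
  activation-time maps, their median/max difference metrics, and
  spiral-wave arrhythmia runs post-processed into phase-singularity
  density maps compared by Pearson correlation.
* **Synthetic anatomy generator** (idealised LA/RA shells with labelled
  rims, appendage bump, seeded case-to-case jitter and smooth-plus-noise
  fibre patterns) so the entire pipeline runs and is tested with no
  external data.

## Worked example

```r
library(fibreatlas)

# two synthetic left atria (~4.3k elements each at the 1 mm setting)
a <- synth_case("LA", seed = 1)
b <- synth_case("LA", seed = 2)

# map anatomy A's fibre field onto anatomy B and back
ab  <- map_fibres(list(mesh = a$mesh, uac = a$uac, theta = a$theta),
                  list(mesh = b$mesh, uac = b$uac))
aba <- map_fibres(list(mesh = b$mesh, uac = b$uac, theta = attr(ab, "theta")),
                  list(mesh = a$mesh, uac = a$uac))
d <- abs(attr(aba, "theta") - a$theta) %% pi
median(pmin(d, pi - d)) * 180 / pi
#> [1] 2.402885
```

The printed number is the median angular error (degrees) of the
A→B→A registration round trip: about 2.4°, i.e. mapping through the
coordinate system is nearly lossless at the 1 mm mesh scale.

```r
# does the choice of fibre field matter for paced activation?
mapped <- map_fibres(list(mesh = b$mesh, uac = b$uac, theta = b$theta),
                     list(mesh = a$mesh, uac = a$uac))
prot <- pacing_protocol(c(0.75, 0.1), n_beats = 2, cycle_ms = 500,
                        lead_in_ms = 100)
m_nat <- build_bilayer(a$mesh, a$fibres, a$fibres)
m_map <- build_bilayer(a$mesh, mapped, mapped)
r_nat <- run_lat_protocol(m_nat, membrane_model(), prot, a$uac)
r_map <- run_lat_protocol(m_map, membrane_model(), prot, a$uac)
compare_lat(r_nat$lat, r_map$lat)$median_abs_ms
#> [1] 0.5574475
```

The median absolute activation-time difference between the native and
the mapped-in fibre field is ~0.56 ms at the baseline 4:1 anisotropy on
this anatomy — small relative to the ~142 ms total activation time, and
it grows when the anisotropy ratio is raised to 10:1.

A thin command-line wrapper is installed at
`system.file("exec", "fibreatlas", package = "fibreatlas")`
(`fibreatlas pipeline --config run.yaml` runs the whole two-anatomy
pipeline from one YAML file).

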