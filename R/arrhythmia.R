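#' Spiral-wave initial condition specification
#'
#' Archimedean-spiral pseudo-activation-time initial conditions: by
#' default four spiral cores (two posterior, two anterior) equally spaced
#' in coordinate space with opposite chirality for adjacent cores.
#'
#' @param cores K x 2 matrix of (alpha, beta) core locations.
#' @param chirality length-K vector of +-1.
#' @param pitch Archimedean pitch (coordinate units per radian of phase).
#' @param cycle_ms reentry cycle length used to scale the time field.
#' @return a `spiral_ic_spec`.
#' @export
spiral_ic_spec <- function(cores = rbind(c(0.3, 0.25), c(0.7, 0.25),
                                         c(0.3, 0.75), c(0.7, 0.75)),
                           chirality = c(1, -1, -1, 1),
                           pitch = 0.15, cycle_ms = 160) {
  cores <- as.matrix(cores)
  if (any(cores < 0 | cores > 1))
    stop("spiral cores must lie in the unit coordinate square")
  if (length(chirality) != nrow(cores))
    stop("one chirality per core required")
  if (!all(chirality %in% c(-1, 1))) stop("chirality must be +-1")
  # adjacent cores (mutual nearest neighbours) must alternate chirality
  if (nrow(cores) > 1) {
    d <- as.matrix(stats::dist(cores))
    diag(d) <- Inf
    nn <- apply(d, 1, which.min)
    if (any(chirality == chirality[nn]))
      stop("adjacent spirals must have opposite chirality")
  }
  structure(list(cores = cores, chirality = chirality, pitch = pitch,
                 cycle_ms = cycle_ms),
            class = "spiral_ic_spec")
}

# One steady action-potential template: (v, h) sampled from a paced
# space-clamped run, indexed by time since upstroke in [0, cycle).
ap_template <- function(membrane, cycle_ms, dt = 0.02) {
  nst <- round(3 * cycle_ms / dt)
  r <- cpp_membrane0d(0, 1, 0, dt, nst,
                      membrane$tau_in, membrane$tau_out, membrane$tau_open,
                      membrane$tau_close, membrane$v_gate,
                      membrane$excitability,
                      c(0, cycle_ms, 2 * cycle_ms), rep(2, 3), rep(1.5, 3))
  # last upstroke: first crossing of 0.5 after 2*cycle
  idx <- which(r$t >= 2 * cycle_ms)
  up <- idx[which(r$v[idx] >= 0.5)[1]]
  if (is.na(up)) stop("membrane template failed to capture")
  span <- up + seq_len(round(cycle_ms / dt)) - 1L
  span <- span[span <= length(r$v)]
  list(t = r$t[span] - r$t[up], v = r$v[span], h = r$h[span],
       dt = dt, cycle = cycle_ms)
}

#' Pseudo-activation-time field of the spiral initial condition
#'
#' `t0(alpha, beta) = (cycle / 2 pi) * (chi * phi + r / pitch)` around the
#' nearest core (polar angle phi, radius r), wrapped to the cycle.
#'
#' @param uac_points Q x 2 coordinate points.
#' @param spec a [spiral_ic_spec].
#' @return numeric vector of pseudo-activation times (ms) in `[0, cycle)`.
#' @export
spiral_time_field <- function(uac_points, spec) {
  P <- as.matrix(uac_points)
  d2 <- vapply(seq_len(nrow(spec$cores)), function(k)
    (P[, 1] - spec$cores[k, 1])^2 + (P[, 2] - spec$cores[k, 2])^2,
    numeric(nrow(P)))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  kmin <- max.col(-d2)
  dx <- P[, 1] - spec$cores[kmin, 1]
  dy <- P[, 2] - spec$cores[kmin, 2]
  phi <- atan2(dy, dx)
  r <- sqrt(dx^2 + dy^2)
  t0 <- (spec$cycle_ms / (2 * pi)) *
    (spec$chirality[kmin] * phi + r / spec$pitch)
  t0 %% spec$cycle_ms
}

#' Build node states realising a spiral-wave initial condition
#'
#' Maps the pseudo-activation-time field to membrane states sampled from
#' one steady action potential, identically on every layer of the model.
#'
#' @param model an `ep_model`.
#' @param membrane a [membrane_model].
#' @param uac `uac_field` of the base-layer mesh.
#' @param spec a [spiral_ic_spec].
#' @param dt template sampling step (ms).
#' @return list with `v`, `h` (length `model$n`) and `t0` (base layer).
#' @export
spiral_initial_state <- function(model, membrane, uac, spec, dt = 0.02) {
  tmpl <- ap_template(membrane, spec$cycle_ms, dt)
  pts <- cbind(uac$alpha, uac$beta)
  t0 <- spiral_time_field(pts, spec)
  # a node "activated at t0" is t0 ms into its action potential at t = 0
  phase_t <- t0 %% tmpl$cycle
  idx <- pmin(length(tmpl$v), 1L + round(phase_t / tmpl$dt))
  v1 <- tmpl$v[idx]; h1 <- tmpl$h[idx]
  layers <- model$n / model$n_per_layer
  list(v = rep(v1, layers), h = rep(h1, layers), t0 = t0)
}

#' Instantaneous phase from a voltage trace by delay embedding
#'
#' Per node: `phase(t) = atan2(V(t) - Vbar, V(t - tau) - Vbar)` with the
#' node's trace mean as origin. Nodes with negligible voltage excursion
#' get `NA` phase.
#'
#' @param trace a `monodomain_trace` (or list with `t`, `V`).
#' @param tau_ms embedding delay (default 10 ms).
#' @param min_amplitude excursion below which phase is undefined.
#' @return list with `t` (times of the phase frames) and `phase`
#'   (n x frames matrix in `(-pi, pi]`).
#' @export
compute_phase <- function(trace, tau_ms = 10, min_amplitude = 1e-3) {
  t <- trace$t; V <- trace$V
  if (length(t) < 3L) stop("trace too short for phase computation")
  dt <- stats::median(diff(t))
  lag <- max(1L, round(tau_ms / dt))
  if (lag >= length(t)) stop("embedding delay exceeds the trace")
  vb <- rowMeans(V)
  Vc <- V - vb
  amp <- apply(abs(Vc), 1, max)
  cols <- (lag + 1L):length(t)
  ph <- atan2(Vc[, cols, drop = FALSE], Vc[, cols - lag, drop = FALSE])
  ph[amp < min_amplitude, ] <- NA_real_
  list(t = t[cols], phase = ph)
}

#' Detect phase singularities on a mesh snapshot
#'
#' A triangle hosts a phase singularity when the oriented sum of wrapped
#' phase differences around its vertices is +-2 pi; the sign is the
#' topological charge and the location is the triangle centroid in
#' coordinate space.
#'
#' @param phase_snapshot per-vertex phase (one layer).
#' @param mesh the layer's [surface_mesh].
#' @param uac its `uac_field`.
#' @param tol winding tolerance (radians).
#' @return data frame with `alpha`, `beta`, `charge`, `element`.
#' @export
detect_ps <- function(phase_snapshot, mesh, uac, tol = pi) {
  tr <- mesh$triangles
  p1 <- phase_snapshot[tr[, 1]]
  p2 <- phase_snapshot[tr[, 2]]
  p3 <- phase_snapshot[tr[, 3]]
  wrap <- function(x) atan2(sin(x), cos(x))
  w <- wrap(p2 - p1) + wrap(p3 - p2) + wrap(p1 - p3)
  hit <- which(!is.na(w) & abs(w) > tol)
  eu <- element_uac(mesh, uac)
  data.frame(alpha = eu[hit, 1], beta = eu[hit, 2],
             charge = as.integer(sign(w[hit])), element = hit)
}

#' Phase-singularity density map over the coordinate square
#'
#' Time-normalised 2D histogram of detections: cell value = detections in
#' the cell per second of analysed arrhythmia, so the map integrates
#' (sums) to the total detection count divided by the duration.
#'
#' @param events data frame with `alpha`, `beta` (rbind of per-snapshot
#'   [detect_ps] results).
#' @param duration_ms analysed duration.
#' @param grid grid size G (G x G cells, default 32).
#' @return a `ps_density_map`: matrix (rows = alpha bins) with attributes.
#' @export
ps_density <- function(events, duration_ms, grid = 32) {
  if (duration_ms <= 0) stop("duration must be positive")
  brk <- seq(0, 1, length.out = grid + 1L)
  ia <- pmin(grid, pmax(1L, findInterval(events$alpha, brk,
                                         rightmost.closed = TRUE)))
  ib <- pmin(grid, pmax(1L, findInterval(events$beta, brk,
                                         rightmost.closed = TRUE)))
  m <- matrix(0, grid, grid)
  if (nrow(events)) {
    tab <- table(factor(ia, levels = 1:grid), factor(ib, levels = 1:grid))
    m <- matrix(as.numeric(tab), grid, grid)
  }
  structure(m / (duration_ms / 1000), class = "ps_density_map",
            duration_ms = duration_ms, n_events = nrow(events))
}

#' Mean simultaneous phase-singularity count
#'
#' @param events per-snapshot detections (data frame).
#' @param n_snapshots number of analysed snapshots.
#' @return average number of simultaneous phase singularities.
#' @export
mean_ps_count <- function(events, n_snapshots) {
  if (n_snapshots <= 0) stop("need at least one snapshot")
  nrow(events) / n_snapshots
}

#' Pearson correlation between two density maps
#'
#' @param map1,map2 `ps_density_map`s (or plain matrices) on the same grid.
#' @return correlation in `[-1, 1]`; `NA` (with a warning) if either map
#'   is constant.
#' @export
density_correlation <- function(map1, map2) {
  a <- as.numeric(map1); b <- as.numeric(map2)
  if (length(a) != length(b)) stop("density maps differ in size")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant density map: correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Run a spiral-wave arrhythmia experiment end to end
#'
#' Builds the spiral initial condition on a bilayer (or single-surface)
#' model, runs the monodomain simulation, computes phase by delay
#' embedding, detects phase singularities on the base layer at the
#' snapshot cadence, and aggregates the density map and mean count.
#' Termination (no tissue above the activity threshold) is recorded and
#' the analysis truncated there.
#'
#' @param model an `ep_model`.
#' @param membrane a [membrane_model] (typically `membrane_model(af = TRUE)`).
#' @param uac `uac_field` of the base-layer mesh.
#' @param spec a [spiral_ic_spec].
#' @param duration_ms simulated arrhythmia duration (<= 10 s).
#' @param dt time step (ms; `NULL` = 0.9x CFL bound capped at 0.02).
#' @param snapshot_dt_ms phase-singularity snapshot cadence (default 5).
#' @param grid density-map grid size.
#' @param tau_ms phase embedding delay.
#' @return list: `events`, `density`, `mean_count`, `n_snapshots`,
#'   `terminated`, `termination_ms`, `trace_t`.
#' @export
af_experiment <- function(model, membrane, uac, spec = spiral_ic_spec(),
                          duration_ms = 2000, dt = NULL,
                          snapshot_dt_ms = 5, grid = 32, tau_ms = 10) {
  if (is.null(dt)) dt <- min(0.02, 0.9 * cfl_max_dt(model))
  ic <- spiral_initial_state(model, membrane, uac, spec, dt = dt)
  tr <- run_monodomain(model, membrane, duration_ms, dt = dt,
                       initial_state = ic, record_dt = snapshot_dt_ms)
  ph <- compute_phase(tr, tau_ms = tau_ms)
  n1 <- model$n_per_layer
  # termination: first snapshot with no node above the activity threshold
  act <- apply(tr$V > 0.05, 2, any)
  termination_ms <- if (all(act)) NA_real_ else tr$t[which(!act)[1]]
  keep <- ph$t <= ifelse(is.na(termination_ms), Inf, termination_ms)
  events <- do.call(rbind, lapply(which(keep), function(k) {
    ev <- detect_ps(ph$phase[seq_len(n1), k], model$meshes[[1]], uac)
    if (nrow(ev)) cbind(time = ph$t[k], ev) else NULL
  }))
  if (is.null(events))
    events <- data.frame(time = numeric(), alpha = numeric(),
                         beta = numeric(), charge = integer(),
                         element = integer())
  dur <- if (is.na(termination_ms)) duration_ms else termination_ms
  dens <- ps_density(events, dur, grid)
  list(events = events, density = dens,
       mean_count = mean_ps_count(events, max(1L, sum(keep))),
       n_snapshots = sum(keep), terminated = !is.na(termination_ms),
       termination_ms = termination_ms, trace_t = tr$t)
}
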