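#' Tissue conductivity parameters
#'
#' Longitudinal/transverse monodomain conductivities with the
#' surface-to-volume ratio and membrane capacitance that convert them to
#' diffusivities. Baseline 0.4/0.1 S/m (4:1 anisotropy); the 10:1 variant
#' uses transverse 0.04 S/m.
#'
#' @param sigma_l longitudinal conductivity (S/m).
#' @param sigma_t transverse conductivity (S/m).
#' @param chi surface-to-volume ratio (1/m; default 1.4e5 = 1400/cm).
#' @param cm membrane capacitance (F/m^2; default 0.01 = 1 uF/cm^2).
#' @return `conductivity_params` list; `d_l`/`d_t` are the derived
#'   diffusivities in mm^2/ms.
#' @export
conductivity_params <- function(sigma_l = 0.4, sigma_t = 0.1,
                                chi = 1.4e5, cm = 0.01) {
  if (!(sigma_l >= sigma_t && sigma_t > 0))
    stop("need sigma_l >= sigma_t > 0")
  structure(list(sigma_l = sigma_l, sigma_t = sigma_t, chi = chi, cm = cm,
                 d_l = sigma_l / (chi * cm) * 1e3,
                 d_t = sigma_t / (chi * cm) * 1e3),
            class = "conductivity_params")
}

#' In-plane conductivity tensor of one element
#'
#' `sigma_t * (I - n n^T) + (sigma_l - sigma_t) * f f^T`: symmetric PSD
#' with in-plane eigenvalues `{sigma_l, sigma_t}` (principal axis = fibre)
#' and zero normal to the surface.
#'
#' @param fibre unit tangent 3-vector.
#' @param sigma_l,sigma_t conductivities.
#' @param normal unit triangle normal.
#' @return 3 x 3 matrix.
#' @export
element_conductivity_tensor <- function(fibre, sigma_l, sigma_t, normal) {
  f <- fibre / sqrt(sum(fibre^2))
  n <- normal / sqrt(sum(normal^2))
  sigma_t * (diag(3) - tcrossprod(n)) + (sigma_l - sigma_t) * tcrossprod(f)
}

# Anisotropic stiffness matrix (units: mm^2/ms after division by M) and
# lumped mass vector for one surface.
assemble_fem <- function(mesh, fibres, params) {
  v <- mesh$vertices; tr <- mesh$triangles
  nrm <- triangle_normals(mesh)
  ar <- triangle_areas(mesh)
  f <- unclass(fibres)
  dl <- params$d_l; dt_ <- params$d_t
  e1 <- v[tr[, 3], , drop = FALSE] - v[tr[, 2], , drop = FALSE]
  e2 <- v[tr[, 1], , drop = FALSE] - v[tr[, 3], , drop = FALSE]
  e3 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  g <- list(e1, e2, e3)
  for (k in 1:3) {
    ek <- g[[k]]
    g[[k]] <- cbind(nrm[, 2] * ek[, 3] - nrm[, 3] * ek[, 2],
                    nrm[, 3] * ek[, 1] - nrm[, 1] * ek[, 3],
                    nrm[, 1] * ek[, 2] - nrm[, 2] * ek[, 1]) / (2 * ar)
  }
  fg <- lapply(g, function(gk) rowSums(f * gk))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (a in 1:3) for (b in 1:3) {
    val <- ar * (dt_ * rowSums(g[[a]] * g[[b]]) +
                   (dl - dt_) * fg[[a]] * fg[[b]])
    ii <- c(ii, tr[, a]); jj <- c(jj, tr[, b]); xx <- c(xx, val)
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(v), nrow(v)))
  mass <- as.numeric(rowsum(rep(ar / 3, 3), as.integer(tr)))
  list(K = K, mass = mass)
}

#' Single-surface monodomain model
#'
#' @param mesh a [surface_mesh].
#' @param fibres a [fibre_field].
#' @param params [conductivity_params].
#' @return an `ep_model` (diffusion operator, mass, geometry).
#' @export
single_layer_model <- function(mesh, fibres, params = conductivity_params()) {
  fem <- assemble_fem(mesh, fibres, params)
  L <- -Matrix::Diagonal(x = 1 / fem$mass) %*% fem$K
  structure(list(type = "single", meshes = list(mesh), fibres = list(fibres),
                 params = params, L = methods::as(L, "CsparseMatrix"),
                 K = fem$K, mass = fem$mass,
                 vertices = mesh$vertices,
                 layer_of = rep(1L, nrow(mesh$vertices)),
                 n = nrow(mesh$vertices), n_per_layer = nrow(mesh$vertices)),
            class = "ep_model")
}

#' Bilayer monodomain model
#'
#' Couples two node-paired surfaces: the base surface is duplicated and
#' offset a small constant distance along its vertex normals (outward for
#' the LA, whose base layer is endocardial; inward for the RA, whose base
#' is epicardial), and paired nodes exchange current linearly with
#' coupling rate `kappa_c`. The offset is a numerical device, not the
#' wall thickness — transmural resistance is in `kappa_c` alone.
#'
#' @param mesh base [surface_mesh] (endo for LA, epi for RA).
#' @param fibres_base,fibres_other fibre fields for the two layers.
#' @param params [conductivity_params].
#' @param offset duplication offset in mm (default 0.1).
#' @param kappa_c interlayer coupling rate (1/ms).
#' @return an `ep_model` with `2 * n` nodes (base layer first).
#' @export
build_bilayer <- function(mesh, fibres_base, fibres_other,
                          params = conductivity_params(), offset = 0.1,
                          kappa_c = 2) {
  n1 <- nrow(mesh$vertices)
  sgn <- if (identical(mesh$chamber, "RA")) -1 else 1
  other <- mesh
  other$vertices <- mesh$vertices + sgn * offset * vertex_normals(mesh)
  other$layer <- if (identical(mesh$layer, "endo")) "epi" else "endo"
  fem1 <- assemble_fem(mesh, fibres_base, params)
  fem2 <- assemble_fem(other, fibres_other, params)
  K <- Matrix::bdiag(fem1$K, fem2$K)
  mass <- c(fem1$mass, fem2$mass)
  L <- -Matrix::Diagonal(x = 1 / mass) %*% K
  if (kappa_c > 0) {
    i <- c(seq_len(n1), seq_len(n1) + n1, seq_len(n1), seq_len(n1) + n1)
    j <- c(seq_len(n1), seq_len(n1) + n1, seq_len(n1) + n1, seq_len(n1))
    x <- c(rep(-kappa_c, 2 * n1), rep(kappa_c, 2 * n1))
    L <- L + Matrix::sparseMatrix(i = i, j = j, x = x,
                                  dims = c(2 * n1, 2 * n1))
  }
  structure(list(type = "bilayer", meshes = list(mesh, other),
                 fibres = list(fibres_base, fibres_other),
                 params = params, kappa_c = kappa_c, offset = offset,
                 L = methods::as(L, "CsparseMatrix"), K = K, mass = mass,
                 vertices = rbind(mesh$vertices, other$vertices),
                 layer_of = rep(1:2, each = n1),
                 n = 2L * n1, n_per_layer = n1),
            class = "ep_model")
}

#' Two-variable excitable membrane model
#'
#' The default reaction kinetics: a normalised two-current model with a
#' fast inward current gated by a recovery variable and a linear outward
#' current (Mitchell-Schaeffer form). `excitability` scales the inward
#' current; lowering it (together with the shorter `tau_close` of the
#' `af = TRUE` preset) stands in for the wavelength-shortening electrical
#' remodelling used in fibrillation studies.
#'
#' @param tau_in,tau_out,tau_open,tau_close time constants (ms).
#' @param v_gate gate threshold (normalised voltage).
#' @param excitability inward-current scale (1 = baseline).
#' @param af use the short-wavelength remodelled preset.
#' @return a `membrane_model` list.
#' @export
membrane_model <- function(tau_in = 0.3, tau_out = 6, tau_open = 120,
                           tau_close = 80, v_gate = 0.13,
                           excitability = 1, af = FALSE) {
  if (af) {
    tau_close <- 30; tau_open <- 60; excitability <- 0.9
  }
  structure(list(tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
                 tau_close = tau_close, v_gate = v_gate,
                 excitability = excitability),
            class = "membrane_model")
}

#' Largest explicit-Euler-stable time step for a model's diffusion operator
#'
#' Gershgorin bound on the spectral radius of the diffusion operator.
#'
#' @param model an `ep_model`.
#' @return dt bound in ms.
#' @export
cfl_max_dt <- function(model) {
  2 / max(Matrix::rowSums(abs(model$L)))
}

#' Run a monodomain simulation
#'
#' Operator-split reaction-diffusion stepping on an `ep_model`: explicit
#' (compiled, with a CFL guard) or implicit diffusion (cached sparse LU,
#' unconditionally stable). Voltage is recorded at `record_dt` from
#' `record_start` on.
#'
#' @param model an `ep_model`.
#' @param membrane a [membrane_model].
#' @param duration total simulated time (ms).
#' @param dt time step (ms, default 0.02).
#' @param stimuli list of stimuli: each a list with `nodes` (1-based),
#'   `onset`, `duration`, `amplitude` (1/ms), and optionally `cycle` +
#'   `count` for repeated pacing.
#' @param initial_state optional list with `v`, `h` (length n).
#' @param record_start,record_dt recording window control (ms).
#' @param method `"explicit"` or `"implicit"`.
#' @return a `monodomain_trace`: `t`, `V` (n x frames), `v_end`, `h_end`,
#'   `aborted`.
#' @export
run_monodomain <- function(model, membrane, duration, dt = 0.02,
                           stimuli = list(), initial_state = NULL,
                           record_start = 0, record_dt = 1,
                           method = c("explicit", "implicit")) {
  method <- match.arg(method)
  n <- model$n
  v0 <- if (is.null(initial_state)) rep(0, n) else initial_state$v
  h0 <- if (is.null(initial_state)) rep(1, n) else initial_state$h
  stopifnot(length(v0) == n, length(h0) == n)
  nsteps <- ceiling(duration / dt)
  rec_stride <- max(1L, round(record_dt / dt))
  if (method == "explicit") {
    dt_max <- cfl_max_dt(model)
    if (dt > dt_max)
      stop("dt = ", dt, " ms violates the explicit stability bound (",
           signif(dt_max, 3), " ms); reduce dt or use method = 'implicit'")
    Lc <- model$L
    res <- cpp_monodomain(
      Lc@p, Lc@i, Lc@x, v0, h0, 0, dt, nsteps,
      membrane$tau_in, membrane$tau_out, membrane$tau_open,
      membrane$tau_close, membrane$v_gate, membrane$excitability,
      lapply(stimuli, function(s) as.integer(s$nodes) - 1L),
      vapply(stimuli, function(s) s$onset, 0),
      vapply(stimuli, function(s) s$duration, 0),
      vapply(stimuli, function(s) if (is.null(s$cycle)) 0 else s$cycle, 0),
      vapply(stimuli, function(s)
        as.integer(if (is.null(s$count)) 1L else s$count), 1L),
      vapply(stimuli, function(s) s$amplitude, 0),
      record_start, rec_stride)
    if (res$aborted)
      stop("monodomain simulation unstable (|V| out of bounds at t = ",
           signif(res$t_end, 5), " ms)")
  } else {
    A <- Matrix::Diagonal(n) - dt * model$L
    fac <- Matrix::lu(A)
    V <- v0; H <- h0
    frames <- list(); tf <- numeric(0)
    for (k in seq_len(nsteps)) {
      t <- (k - 1) * dt
      ion <- membrane$excitability * H * V^2 * (1 - V) / membrane$tau_in -
        V / membrane$tau_out
      st <- numeric(n)
      for (s in stimuli) {
        rel <- t - s$onset
        if (rel < 0) next
        cyc <- if (is.null(s$cycle)) 0 else s$cycle
        cnt <- if (is.null(s$count)) 1L else s$count
        beat <- if (cyc > 0) floor(rel / cyc) else 0
        if (beat >= cnt) next
        if (rel - beat * cyc < s$duration) st[s$nodes] <- st[s$nodes] +
            s$amplitude
      }
      rhs <- V + dt * (ion + st)
      V <- as.numeric(Matrix::solve(fac, rhs))
      H <- H + dt * ifelse(V < membrane$v_gate,
                           (1 - H) / membrane$tau_open,
                           -H / membrane$tau_close)
      if (max(abs(V)) > 10)
        stop("monodomain simulation unstable at t = ", signif(t, 5), " ms")
      tk <- k * dt
      if (tk >= record_start - 1e-9 && (k %% rec_stride) == 0L) {
        frames[[length(frames) + 1L]] <- V
        tf <- c(tf, tk)
      }
    }
    res <- list(t = tf, V = do.call(cbind, frames), v_end = V, h_end = H,
                aborted = FALSE, t_end = nsteps * dt)
  }
  structure(list(t = as.numeric(res$t), V = res$V, v_end = res$v_end,
                 h_end = res$h_end, aborted = res$aborted, dt = dt,
                 model_n = n),
            class = "monodomain_trace")
}

#' Pacing protocol
#'
#' Trains of stimuli at a coordinate-defined site (portable across
#' anatomies): a quiescent lead-in, then `n_beats` at the given cycle
#' length; the activation map is read from the final beat.
#'
#' @param site_uac length-2 (alpha, beta) stimulus site.
#' @param radius stimulated ball radius in mm.
#' @param n_beats number of beats (default 5).
#' @param cycle_ms cycle length (default 700 ms).
#' @param lead_in_ms quiescent lead-in (default 1000 ms).
#' @param stim_dur_ms stimulus duration (default 2 ms).
#' @param amplitude stimulus amplitude (1/ms); `NULL` = auto-calibrate to
#'   1.5x the single-cell capture threshold times a diffusive-loading
#'   safety factor.
#' @export
pacing_protocol <- function(site_uac, radius = 2, n_beats = 5,
                            cycle_ms = 700, lead_in_ms = 1000,
                            stim_dur_ms = 2, amplitude = NULL) {
  structure(list(site_uac = site_uac, radius = radius, n_beats = n_beats,
                 cycle_ms = cycle_ms, lead_in_ms = lead_in_ms,
                 stim_dur_ms = stim_dur_ms, amplitude = amplitude),
            class = "pacing_protocol")
}

#' Single-cell capture threshold of a membrane model
#'
#' Bisects the amplitude of a rectangular current pulse that elicits an
#' action potential in the space-clamped membrane.
#'
#' @param membrane a [membrane_model].
#' @param dur_ms pulse duration.
#' @param dt time step.
#' @return threshold amplitude (1/ms).
#' @export
capture_threshold_0d <- function(membrane, dur_ms = 2, dt = 0.02) {
  fires <- function(amp) {
    r <- cpp_membrane0d(0, 1, 0, dt, round(60 / dt),
                        membrane$tau_in, membrane$tau_out,
                        membrane$tau_open, membrane$tau_close,
                        membrane$v_gate, membrane$excitability,
                        1, dur_ms, amp)
    max(r$v) > 0.8
  }
  lo <- 1e-3; hi <- 0.02
  while (!fires(hi)) {
    hi <- hi * 2
    if (hi > 100) stop("membrane cannot be captured")
  }
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

# Stimulated node set: centre = vertex nearest the site in coordinates
# (base layer), then a 3D ball across all layers.
stim_nodes_from_uac <- function(model, uac, site, radius) {
  d2 <- (uac$alpha - site[1])^2 + (uac$beta - site[2])^2
  ctr <- model$vertices[which.min(d2), ]
  which(sqrt(rowSums(sweep(model$vertices, 2, ctr)^2)) <= radius)
}

#' Run a pacing protocol and extract the final-beat activation map
#'
#' @param model an `ep_model`.
#' @param membrane a [membrane_model].
#' @param protocol a [pacing_protocol].
#' @param uac `uac_field` of the base-layer mesh (site lookup).
#' @param dt time step (ms).
#' @param record_dt sampling of the analysed beat (ms).
#' @param loading_factor multiplies the single-cell threshold when
#'   auto-calibrating the stimulus (accounts for diffusive loading).
#' @return list with `lat` (per-node ms, NA = no capture), `trace`
#'   (final-beat recording), `stim_nodes`.
#' @export
run_lat_protocol <- function(model, membrane, protocol, uac, dt = 0.02,
                             record_dt = 0.5, loading_factor = 4) {
  nodes <- stim_nodes_from_uac(model, uac, protocol$site_uac,
                               protocol$radius)
  amp <- protocol$amplitude
  if (is.null(amp))
    amp <- 1.5 * loading_factor *
      capture_threshold_0d(membrane, protocol$stim_dur_ms, dt)
  t_last <- protocol$lead_in_ms + (protocol$n_beats - 1) * protocol$cycle_ms
  duration <- protocol$lead_in_ms + protocol$n_beats * protocol$cycle_ms
  stim <- list(list(nodes = nodes, onset = protocol$lead_in_ms,
                    duration = protocol$stim_dur_ms, amplitude = amp,
                    cycle = protocol$cycle_ms, count = protocol$n_beats))
  tr <- run_monodomain(model, membrane, duration, dt = dt, stimuli = stim,
                       record_start = t_last, record_dt = record_dt)
  lat <- extract_lat(tr, window = c(t_last, duration))
  list(lat = lat - t_last, trace = tr, stim_nodes = nodes,
       amplitude = amp, beat_onset = t_last)
}

#' Extract local activation times from a voltage trace
#'
#' Per-node first rising crossing of the upstroke threshold (default: the
#' midpoint between the node's minimum and maximum voltage in the window),
#' linearly interpolated between stored samples. Nodes whose excursion is
#' below `min_amplitude` never activated and are returned as `NA`.
#'
#' @param trace a `monodomain_trace`.
#' @param window time window `c(t0, t1)` (ms; default the whole trace).
#' @param min_amplitude minimum voltage excursion for capture.
#' @return numeric LAT vector (ms) with attribute `n_missing`.
#' @export
extract_lat <- function(trace, window = NULL, min_amplitude = 0.4) {
  t <- trace$t; V <- trace$V
  if (is.null(window)) window <- range(t)
  sel <- which(t >= window[1] - 1e-9 & t <= window[2] + 1e-9)
  if (length(sel) < 2L) stop("trace does not cover the analysis window")
  t <- t[sel]; V <- V[, sel, drop = FALSE]
  vmin <- apply(V, 1, min); vmax <- apply(V, 1, max)
  thr <- (vmin + vmax) / 2
  captured <- (vmax - vmin) >= min_amplitude
  nt <- length(t)
  below <- V[, -nt, drop = FALSE] < thr
  above <- V[, -1, drop = FALSE] >= thr
  cross <- below & above
  first <- apply(cross, 1, function(r) {
    w <- which(r)
    if (length(w)) w[1] else NA_integer_
  })
  lat <- rep(NA_real_, nrow(V))
  ok <- captured & !is.na(first)
  k <- first[ok]
  v0 <- V[cbind(which(ok), k)]
  v1 <- V[cbind(which(ok), k + 1L)]
  frac <- (thr[ok] - v0) / (v1 - v0)
  lat[ok] <- t[k] + frac * (t[k + 1L] - t[k])
  attr(lat, "n_missing") <- sum(!ok)
  lat
}

#' Compare two activation maps
#'
#' @param lat_a reference LAT map (defines the total activation time).
#' @param lat_b comparison LAT map on the same nodes.
#' @return list: `median_abs_ms`, `max_abs_pct` (max |difference| as a
#'   percentage of the reference total activation time), `delta` field.
#' @export
compare_lat <- function(lat_a, lat_b) {
  if (length(lat_a) != length(lat_b)) stop("LAT maps differ in length")
  ok <- !is.na(lat_a) & !is.na(lat_b)
  if (!any(ok)) stop("no commonly activated nodes")
  d <- lat_b[ok] - lat_a[ok]
  tat <- diff(range(lat_a[ok]))
  delta <- rep(NA_real_, length(lat_a))
  delta[ok] <- d
  list(median_abs_ms = stats::median(abs(d)),
       max_abs_pct = 100 * max(abs(d)) / tat,
       total_activation_ms = tat, delta = delta)
}

#' Random in-plane fibre field (isotropic control)
#'
#' Uniformly random tangent direction per element, used to emulate the
#' isotropic case while keeping the anisotropic machinery unchanged.
#'
#' @param mesh a [surface_mesh].
#' @param seed RNG seed.
#' @return a [fibre_field].
#' @export
isotropic_control <- function(mesh, seed = 1L) {
  nrm <- triangle_normals(mesh)
  v <- mesh$vertices; tr <- mesh$triangles
  t1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  t1 <- t1 - nrm * rowSums(t1 * nrm)
  t1 <- t1 / sqrt(rowSums(t1^2))
  t2 <- cbind(nrm[, 2] * t1[, 3] - nrm[, 3] * t1[, 2],
              nrm[, 3] * t1[, 1] - nrm[, 1] * t1[, 3],
              nrm[, 1] * t1[, 2] - nrm[, 2] * t1[, 1])
  phi <- with_seed(seed, stats::runif(nrow(tr), 0, pi))
  fibre_field(mesh, cos(phi) * t1 + sin(phi) * t2)
}

#' Planar-wave conduction velocity on a strip
#'
#' Builds a thin rectangular sheet with fibres along x, paces one end with
#' a line stimulus, and regresses the activation time on distance over the
#' central band. With `direction = "cross"` the strip runs along y so
#' propagation is transverse to the fibres.
#'
#' @param params [conductivity_params].
#' @param membrane [membrane_model].
#' @param direction `"fibre"` or `"cross"`.
#' @param length_mm strip length along the propagation axis.
#' @param width_mm strip width.
#' @param h mesh edge (mm).
#' @param dt time step (ms; `NULL` = 0.9x the CFL bound, capped at 0.02).
#' @return conduction velocity in mm/ms.
#' @export
planar_wave_cv <- function(params = conductivity_params(),
                           membrane = membrane_model(),
                           direction = c("fibre", "cross"),
                           length_mm = 20, width_mm = 1, h = 0.1,
                           dt = NULL) {
  direction <- match.arg(direction)
  along_x <- direction == "fibre"
  mesh <- if (along_x) make_sheet(length_mm, width_mm, h) else
    make_sheet(width_mm, length_mm, h)
  fib <- fibre_field(mesh, matrix(rep(c(1, 0, 0), each = n_triangles(mesh)),
                                  ncol = 3))
  model <- single_layer_model(mesh, fib, params)
  axis <- if (along_x) mesh$vertices[, 1] else mesh$vertices[, 2]
  if (is.null(dt)) dt <- min(0.02, 0.9 * cfl_max_dt(model))
  amp <- 10 * capture_threshold_0d(membrane, 2, dt)
  stim <- list(list(nodes = which(axis <= max(1, 2 * h)), onset = 0,
                    duration = 2, amplitude = amp))
  cv_guess <- sqrt(if (along_x) params$d_l else params$d_t)
  duration <- length_mm / (0.3 * cv_guess) + 30
  tr <- run_monodomain(model, membrane, duration, dt = dt, stimuli = stim,
                       record_dt = 0.25)
  lat <- extract_lat(tr)
  band <- axis >= 0.25 * length_mm & axis <= 0.75 * length_mm & !is.na(lat)
  if (sum(band) < 10) stop("planar wave did not traverse the strip")
  fit <- stats::lm(lat[band] ~ axis[band])
  1 / unname(stats::coef(fit)[2])
}
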