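#' Trace fibre streamlines in coordinate space
#'
#' Integrates the sense-free fibre direction field in the flattened
#' coordinate square with a fixed-step RK4 scheme. The local direction at
#' any point is obtained by barycentric interpolation of the doubled-angle
#' unit vector, halved back to an angle; at each evaluation the direction
#' sign is chosen to continue the previous step (the field has no sense).
#' Each seed is traced in both directions and the halves concatenated.
#' Tracing terminates at the domain boundary (including rim holes and the
#' seam), when the local angle is undefined, or at `max_steps`.
#'
#' @param theta per-element angle field.
#' @param uac a `uac_field`.
#' @param mesh the [surface_mesh] carrying `theta`.
#' @param n_seeds number of random seed points in the unit square.
#' @param step RK4 step in coordinate units.
#' @param max_steps per-direction step budget.
#' @param seed RNG seed for the seed points.
#' @return list of `streamline` objects: matrices of 2D points with
#'   attribute `seed_id`.
#' @export
trace_streamlines <- function(theta, uac, mesh, n_seeds = 10000,
                              step = 0.005, max_steps = 2000, seed = 1L) {
  if (step <= 0) stop("step must be > 0")
  interp <- angle_interpolator(mesh, uac, theta)
  seeds <- with_seed(seed, cbind(stats::runif(n_seeds),
                                 stats::runif(n_seeds)))
  q0 <- interp(seeds)
  keep <- q0$distance <= step & q0$resultant > 1e-9
  seeds <- seeds[keep, , drop = FALSE]
  ids <- which(keep)
  ns <- nrow(seeds)
  # batched direction evaluation: rows of P, aligned against ref rows
  dir_at <- function(P, ref) {
    q <- interp(P)
    th <- 0.5 * atan2(q$s, q$c)
    D <- cbind(cos(th), sin(th))
    if (!is.null(ref)) {
      fl <- rowSums(D * ref) < 0
      D[fl, ] <- -D[fl, , drop = FALSE]
    }
    ok <- q$distance <= step & q$resultant > 1e-9
    list(D = D, ok = ok)
  }
  trace_half <- function(sgn) {
    # preallocated per-seed point storage
    X <- matrix(NA_real_, max_steps + 1L, ns)
    Y <- matrix(NA_real_, max_steps + 1L, ns)
    X[1, ] <- seeds[, 1]; Y[1, ] <- seeds[, 2]
    cnt <- rep(1L, ns)
    active <- seq_len(ns)
    P <- seeds
    d0 <- dir_at(P, NULL)
    ref <- sgn * d0$D
    active <- active[d0$ok]
    P <- P[d0$ok, , drop = FALSE]; ref <- ref[d0$ok, , drop = FALSE]
    for (k in seq_len(max_steps)) {
      if (!length(active)) break
      s1 <- dir_at(P, ref)
      s2 <- dir_at(P + step / 2 * s1$D, s1$D)
      s3 <- dir_at(P + step / 2 * s2$D, s1$D)
      s4 <- dir_at(P + step * s3$D, s1$D)
      D <- (s1$D + 2 * s2$D + 2 * s3$D + s4$D) / 6
      Pn <- P + step * D
      qn <- interp(Pn)
      ok <- s1$ok & s2$ok & s3$ok & s4$ok &
        Pn[, 1] >= 0 & Pn[, 1] <= 1 & Pn[, 2] >= 0 & Pn[, 2] <= 1 &
        qn$distance <= step & qn$resultant > 1e-9
      act_ok <- active[ok]
      cnt[act_ok] <- cnt[act_ok] + 1L
      X[cbind(cnt[act_ok], act_ok)] <- Pn[ok, 1]
      Y[cbind(cnt[act_ok], act_ok)] <- Pn[ok, 2]
      active <- act_ok
      P <- Pn[ok, , drop = FALSE]
      ref <- D[ok, , drop = FALSE]
    }
    list(X = X, Y = Y, cnt = cnt)
  }
  fwd <- trace_half(1)
  bwd <- trace_half(-1)
  out <- vector("list", ns)
  for (i in seq_len(ns)) {
    nb <- bwd$cnt[i]; nf <- fwd$cnt[i]
    sl <- rbind(
      if (nb > 1L) cbind(bwd$X[nb:2, i], bwd$Y[nb:2, i]) else NULL,
      cbind(fwd$X[seq_len(nf), i], fwd$Y[seq_len(nf), i]))
    attr(sl, "seed_id") <- ids[i]
    out[[i]] <- sl
  }
  out
}

#' Thin streamlines to a regular spatial coverage
#'
#' Greedy selection in descending length order: a candidate is kept iff
#' every one of its points is at least `spacing` (in coordinate units)
#' from every point of every already-kept streamline. Deterministic.
#'
#' @param streamlines list from [trace_streamlines].
#' @param spacing minimum coordinate-space separation.
#' @return the kept subset (same objects, original attributes).
#' @export
thin_streamlines <- function(streamlines, spacing) {
  if (spacing < 0) stop("spacing must be >= 0")
  if (spacing == 0 || !length(streamlines)) return(streamlines)
  lens <- vapply(streamlines, function(s) {
    if (nrow(s) < 2L) return(0)
    sum(sqrt(rowSums(diff(s)^2)))
  }, 0)
  ord <- order(lens, decreasing = TRUE)
  cell <- spacing
  occ <- new.env(hash = TRUE, parent = emptyenv())
  key_of <- function(p) paste(floor(p[, 1] / cell), floor(p[, 2] / cell))
  kept <- logical(length(streamlines))
  for (i in ord) {
    s <- streamlines[[i]]
    ok <- TRUE
    for (r in seq_len(nrow(s))) {
      p <- s[r, ]
      ci <- floor(p[1] / cell); cj <- floor(p[2] / cell)
      for (di in -1:1) for (dj in -1:1) {
        pts <- occ[[paste(ci + di, cj + dj)]]
        if (!is.null(pts) &&
            any((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 < spacing^2)) {
          ok <- FALSE; break
        }
      }
      if (!ok) break
    }
    if (ok) {
      kept[i] <- TRUE
      ks <- key_of(s)
      for (kk in unique(ks)) {
        occ[[kk]] <- rbind(occ[[kk]], s[ks == kk, , drop = FALSE])
      }
    }
  }
  streamlines[kept]
}

#' Lift coordinate-space streamlines onto the 3D surface
#'
#' Each 2D point is located in the flattened triangulation and lifted by
#' barycentric interpolation of the 3D vertex positions. Polylines are
#' split where they cross the seam (the flattening is discontinuous
#' there); unlocatable points are dropped and counted.
#'
#' @param streamlines list of 2D polylines.
#' @param mesh a [surface_mesh].
#' @param uac a `uac_field`.
#' @param snap_tol drop points farther than this from the flattened domain.
#' @return list of 3D polylines (k x 3 matrices); attributes `n_dropped`,
#'   `n_split`.
#' @export
streamlines_to_3d <- function(streamlines, mesh, uac, snap_tol = 0.02) {
  flat <- uac_flat_mesh(mesh, uac)
  v3 <- mesh$vertices[flat$orig_vertex, , drop = FALSE]
  n_dropped <- 0L; n_split <- 0L
  out <- list()
  for (s in streamlines) {
    if (!nrow(s)) next
    loc <- barycentric_locate(s, flat$vertices, flat$triangles)
    keep <- loc$distance <= snap_tol
    n_dropped <- n_dropped + sum(!keep)
    if (!any(keep)) next
    vi <- flat$triangles[loc$triangle, , drop = FALSE]
    p3 <- loc$weights[, 1] * v3[vi[, 1], , drop = FALSE] +
      loc$weights[, 2] * v3[vi[, 2], , drop = FALSE] +
      loc$weights[, 3] * v3[vi[, 3], , drop = FALSE]
    seam_hit <- flat$seam_triangles[loc$triangle]
    # segment break where a point is dropped or the path hits the seam
    grp <- cumsum(!keep | seam_hit)
    for (g in split(which(keep & !seam_hit), grp[keep & !seam_hit])) {
      if (length(g) < 2L) next
      out[[length(out) + 1L]] <- p3[g, , drop = FALSE]
    }
    n_split <- n_split + max(0L, length(unique(grp[keep])) - 1L)
  }
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_split") <- n_split
  out
}
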