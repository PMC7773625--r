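# Run code with a temporary RNG state seeded from `seed` (Mersenne-Twister),
# restoring the caller's state afterwards. All stochastic generator
# operations funnel through this so results are reproducible per seed.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

# Unit icosphere: icosahedron subdivided `level` times, projected to the
# sphere. 20 * 4^level near-equilateral triangles.
icosphere <- function(level) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    uk <- !duplicated(key)
    mid_id <- match(key, key[uk]) + nrow(v)
    mids <- (v[e[uk, 1], , drop = FALSE] + v[e[uk, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m <- nrow(f)
    m12 <- mid_id[1:m]; m23 <- mid_id[(m + 1):(2 * m)]
    m31 <- mid_id[(2 * m + 1):(3 * m)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  list(vertices = v, triangles = f)
}

# angular distance (radians) between unit vectors and one direction
ang_dist <- function(u, d) {
  d <- d / sqrt(sum(d^2))
  acos(pmin(1, pmax(-1, u %*% d)))
}

# unit direction from azimuth (from +x about +z) and elevation (from equator)
dir_sph <- function(az, el) {
  az <- az * pi / 180; el <- el * pi / 180
  c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
}

#' Specification of a synthetic atrial anatomy
#'
#' Describes an idealised atrial shell: an ellipsoid with circular openings
#' for the valve and vessel rims, an appendage bump, and seed-controlled
#' case-to-case variation (radii scaling and rim jitter). The default
#' layouts place four pulmonary-vein openings on the posterior left atrial
#' wall plus the mitral opening (LA), or SVC/IVC/tricuspid/coronary-sinus
#' openings (RA), with human-scale radii.
#'
#' @param chamber `"LA"` or `"RA"`.
#' @param radii ellipsoid semi-axes in mm.
#' @param edge_length target mesh edge length in mm (matched to the nearest
#'   icosphere subdivision level).
#' @param seed integer; drives the deterministic case-to-case jitter.
#' @param jitter relative amplitude of radii/rim-position variation.
#' @return an `anatomy_spec` list with per-rim directions and angular radii.
#' @export
anatomy_spec <- function(chamber = c("LA", "RA"), radii = NULL,
                         edge_length = 1.0, seed = 1L, jitter = 0.06) {
  chamber <- match.arg(chamber)
  if (edge_length <= 0) stop("edge_length must be > 0")
  if (is.null(radii))
    radii <- if (chamber == "LA") c(22, 20, 18) else c(23, 20, 19)
  base <- if (chamber == "LA") {
    list(
      rims = list(
        MV = list(dir = c(0, 0, -1), radius = 40),
        RSPV = list(dir = dir_sph(55, 45), radius = 12),
        RIPV = list(dir = dir_sph(50, 8), radius = 12),
        LSPV = list(dir = dir_sph(125, 45), radius = 12),
        LIPV = list(dir = dir_sph(130, 8), radius = 12)),
      bump = list(dir = dir_sph(215, 35), amp = 5, width = 14),
      seeds = list(mv_lateral = dir_sph(180, -55)))
  } else {
    list(
      rims = list(
        TV = list(dir = c(0, 0, -1), radius = 40),
        SVC = list(dir = dir_sph(45, 62), radius = 13),
        IVC = list(dir = dir_sph(90, -20), radius = 13),
        CS = list(dir = dir_sph(15, -32), radius = 6)),
      bump = list(dir = dir_sph(280, 30), amp = 5, width = 14),
      seeds = list(posterior = dir_sph(90, -55),
                   anterior = dir_sph(270, -55)))
  }
  jit <- with_seed(seed, {
    list(radii = stats::runif(3, 1 - jitter, 1 + jitter),
         az = stats::runif(length(base$rims) - 1L, -5, 5),
         el = stats::runif(length(base$rims) - 1L, -4, 4),
         amp = stats::runif(1, 1 - jitter, 1 + jitter))
  })
  radii <- radii * jit$radii
  rot_jitter <- function(d, daz, del) {
    az <- atan2(d[2], d[1]) * 180 / pi
    el <- asin(pmin(1, pmax(-1, d[3]))) * 180 / pi
    dir_sph(az + daz, el + del)
  }
  k <- 0L
  for (nm in names(base$rims)) {
    if (nm %in% c("MV", "TV")) next   # the valve stays put
    k <- k + 1L
    base$rims[[nm]]$dir <- rot_jitter(base$rims[[nm]]$dir, jit$az[k],
                                      jit$el[k])
  }
  base$bump$amp <- base$bump$amp * jit$amp
  structure(list(chamber = chamber, radii = radii,
                 edge_length = edge_length, rims = base$rims,
                 bump = base$bump, seeds = base$seeds, seed = seed),
            class = "anatomy_spec")
}

#' Generate an idealised atrial surface pair (endo + epi)
#'
#' Builds a trimmed, labelled ellipsoidal shell from an [anatomy_spec]:
#' an icosphere is opened at each rim (triangles inside the rim's angular
#' cap are removed), the appendage is raised as a smooth radial bump, the
#' surface is scaled to the ellipsoid radii, and the boundary loops are
#' detected and named from the rim directions. The epicardial surface is
#' the endocardial one offset 0.5 mm along outward vertex normals with
#' identical connectivity and labels. Deterministic for a fixed spec.
#'
#' @param spec an [anatomy_spec].
#' @param epi_offset epicardial normal offset in mm.
#' @return list with `endo`, `epi` ([surface_mesh]) and `landmarks`
#'   (named list of 3D seed points for rim naming and coordinate splits).
#' @export
make_anatomy <- function(spec, epi_offset = 0.5) {
  stopifnot(inherits(spec, "anatomy_spec"))
  # rim overlap check (angular)
  rn <- names(spec$rims)
  for (i in seq_along(rn)) for (j in seq_len(i - 1L)) {
    a <- spec$rims[[i]]; b <- spec$rims[[j]]
    sep <- acos(pmin(1, pmax(-1, sum(a$dir * b$dir)))) * 180 / pi
    if (sep < a$radius + b$radius + 4)
      stop("rims ", rn[i], " and ", rn[j], " overlap")
  }
  r_mean <- mean(spec$radii)
  level <- max(2L, min(6L, which.min(abs(
    1.05146 * r_mean / 2^(2:6) - spec$edge_length)) + 1L))
  ico <- icosphere(level)
  u <- ico$vertices
  f <- ico$triangles
  # remove triangles whose centroid direction lies inside any rim cap
  cen <- (u[f[, 1], ] + u[f[, 2], ] + u[f[, 3], ]) / 3
  cen <- cen / sqrt(rowSums(cen^2))
  drop <- rep(FALSE, nrow(f))
  for (rim in spec$rims) {
    d <- as.numeric(ang_dist(cen, rim$dir))
    inside <- d < rim$radius * pi / 180
    if (!any(inside)) inside[which.min(d)] <- TRUE  # coarse mesh: open at
    drop <- drop | inside                           # least one triangle
  }
  f <- f[!drop, , drop = FALSE]
  f <- clean_submesh(u, f)
  # appendage bump then ellipsoid scaling
  d_bump <- as.numeric(ang_dist(u, spec$bump$dir))
  mult <- 1 + (spec$bump$amp / r_mean) *
    exp(-d_bump^2 / (2 * (spec$bump$width * pi / 180)^2))
  pos <- u * mult
  pos <- sweep(pos, 2, spec$radii, `*`)
  used <- sort(unique(as.integer(f)))
  remap <- integer(nrow(u)); remap[used] <- seq_along(used)
  mesh <- surface_mesh(pos[used, , drop = FALSE],
                       matrix(remap[f], ncol = 3),
                       chamber = spec$chamber, layer = "endo")
  # rim naming from cap directions (projected to the ellipsoid surface)
  seeds <- lapply(spec$rims, function(r) r$dir * spec$radii)
  mesh$rim_labels <- detect_rims(mesh, seeds = seeds)
  if (length(mesh$rim_labels) != length(spec$rims) ||
      anyDuplicated(vapply(mesh$rim_labels, function(x) x[1], 0L)))
    stop("rim detection did not produce one loop per specified rim")

  epi <- mesh
  vn <- vertex_normals(mesh)
  epi$vertices <- mesh$vertices + epi_offset * vn
  epi$layer <- "epi"
  landmarks <- lapply(spec$seeds, function(d) as.numeric(d * spec$radii))
  list(endo = mesh, epi = epi, landmarks = landmarks)
}

# Drop stray components, non-manifold boundary pinches and boundary "ears"
# (triangles with all three vertices on the boundary) left by cap removal.
clean_submesh <- function(v, f) {
  repeat {
    # largest connected component
    g <- igraph::make_empty_graph(n = max(f), directed = FALSE)
    g <- igraph::add_edges(g, t(rbind(f[, c(1, 2)], f[, c(2, 3)],
                                      f[, c(3, 1)])))
    comp <- igraph::components(g)
    keep_v <- which(comp$membership == which.max(comp$csize))
    ink <- matrix(f %in% keep_v, ncol = 3)
    f <- f[rowSums(ink) == 3L, , drop = FALSE]
    # boundary vertices must have exactly 2 boundary neighbours
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    tab <- table(key)
    bnd <- names(tab)[tab == 1L]
    bv <- if (length(bnd)) as.integer(unlist(strsplit(bnd, " "))) else
      integer(0)
    cnt <- table(bv)
    pinch <- as.integer(names(cnt)[cnt != 2L])
    if (length(pinch)) {
      touch <- f[, 1] %in% pinch | f[, 2] %in% pinch | f[, 3] %in% pinch
      f <- f[!touch, , drop = FALSE]
      next
    }
    # boundary "ears": all three vertices on the same boundary loop (a
    # bridge between two different loops must be kept or the holes merge)
    bnd_pairs <- matrix(as.integer(unlist(strsplit(bnd, " "))),
                        ncol = 2, byrow = TRUE)
    gb <- igraph::make_empty_graph(n = max(f), directed = FALSE)
    gb <- igraph::add_edges(gb, t(bnd_pairs))
    loop_id <- igraph::components(gb)$membership
    on_bnd <- logical(max(f)); on_bnd[unique(bv)] <- TRUE
    ear <- on_bnd[f[, 1]] & on_bnd[f[, 2]] & on_bnd[f[, 3]] &
      loop_id[f[, 1]] == loop_id[f[, 2]] &
      loop_id[f[, 2]] == loop_id[f[, 3]]
    if (!any(ear)) return(f)
    f <- f[!ear, , drop = FALSE]
  }
}

#' Area-weighted outward vertex normals
#'
#' @param mesh a [surface_mesh].
#' @return N x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  tn <- triangle_normals(mesh)
  ar <- triangle_areas(mesh)
  tr <- mesh$triangles
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) {
    for (c in 1:3) {
      acc <- tapply(tn[, c] * ar, tr[, k], sum)
      idx <- as.integer(names(acc))
      n[idx, c] <- n[idx, c] + acc
    }
  }
  n / sqrt(rowSums(n^2))
}

#' Structured rectangular sheet mesh
#'
#' A flat strip/sheet in the xy-plane, triangulated as a regular grid:
#' the workhorse geometry for closed-form checks and planar-wave runs.
#'
#' @param lx,ly extents in mm.
#' @param h target edge length in mm.
#' @return a [surface_mesh] (with `x`/`y` columns also exposed via vertices).
#' @export
make_sheet <- function(lx, ly, h) {
  nx <- max(2L, round(lx / h) + 1L)
  ny <- max(2L, round(ly / h) + 1L)
  xs <- seq(0, lx, length.out = nx)
  ys <- seq(0, ly, length.out = ny)
  v <- cbind(rep(xs, ny), rep(ys, each = nx), 0)
  id <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  f <- rbind(cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
             cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
  surface_mesh(v, f, orient = FALSE)
}

#' Annulus mesh (two boundary loops), for rim-detection checks
#'
#' @param r_inner,r_outer radii (mm); @param n_theta,n_r grid resolution.
#' @export
make_annulus <- function(r_inner = 5, r_outer = 10, n_theta = 32, n_r = 4) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  rr <- seq(r_inner, r_outer, length.out = n_r)
  v <- do.call(rbind, lapply(rr, function(r) cbind(r * cos(th), r * sin(th), 0)))
  id <- function(i, j) (j - 1L) * n_theta + ((i - 1L) %% n_theta) + 1L
  i <- rep(seq_len(n_theta), n_r - 1L)
  j <- rep(seq_len(n_r - 1L), each = n_theta)
  f <- rbind(cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
             cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
  surface_mesh(v, f, orient = FALSE)
}

#' Specification of a smooth regional fibre pattern
#'
#' A target fibre angle surface theta(alpha, beta) over the unit square plus
#' a wrapped-normal perturbation model. The default LA-like pattern runs
#' lateral-septal (theta ~ 0) on the posterior wall and anterior wall and
#' posterior-anterior (theta ~ pi/2) over the roof, echoing the dominant
#' bundles seen in ex vivo fibre data. `kappa` is the inverse wrapped-normal
#' standard deviation of the noise on the doubled angle (rad^-1);
#' `kappa = 0` disables the perturbation. A designated `noisy_region` box
#' gets `kappa_noisy` (default `kappa / 4`), emulating a locally less
#' reliable fibre measurement.
#'
#' @param theta_fun function of (alpha, beta) returning angles in `[0, pi)`.
#' @param kappa inverse noise scale (rad^-1) on the doubled angle; `>= 0`.
#' @param noisy_region length-4 box `c(a0, a1, b0, b1)` or `NULL`.
#' @param kappa_noisy noise scale inside the box.
#' @param seed integer RNG seed for the perturbation.
#' @export
fibre_pattern_spec <- function(theta_fun = NULL, kappa = 8,
                               noisy_region = c(0.55, 0.9, 0.05, 0.35),
                               kappa_noisy = kappa / 4, seed = 1L) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (is.null(theta_fun))
    theta_fun <- function(alpha, beta) {
      (pi / 2) * exp(-(beta - 0.5)^2 / (2 * 0.13^2)) +
        0.25 * sin(pi * alpha) * exp(-(beta - 0.15)^2 / (2 * 0.2^2))
    }
  structure(list(theta_fun = theta_fun, kappa = kappa,
                 noisy_region = noisy_region, kappa_noisy = kappa_noisy,
                 seed = seed),
            class = "fibre_pattern_spec")
}

#' Generate a fibre field from a smooth pattern in coordinate space
#'
#' Evaluates the pattern angle at each element's coordinate centroid,
#' reconstructs the 3D tangent vector through the local coordinate basis
#' (so the recomputed coordinate angle equals the pattern exactly before
#' perturbation), then adds wrapped-normal noise on the doubled angle with
#' standard deviation `1/kappa`.
#'
#' @param mesh a [surface_mesh].
#' @param uac a `uac_field` on the mesh.
#' @param pattern a [fibre_pattern_spec].
#' @param basis optional precomputed [compute_uac_basis] result.
#' @return a [fibre_field] with attribute `theta` (the per-element angles).
#' @export
make_fibre_field <- function(mesh, uac, pattern = fibre_pattern_spec(),
                             basis = NULL) {
  if (is.null(basis)) basis <- compute_uac_basis(mesh, uac)
  eu <- element_uac(mesh, uac)
  theta <- pattern$theta_fun(eu[, 1], eu[, 2]) %% pi
  if (pattern$kappa > 0) {
    sd2 <- 1 / pattern$kappa
    sde <- rep(sd2, length(theta))
    if (!is.null(pattern$noisy_region)) {
      b <- pattern$noisy_region
      inb <- eu[, 1] >= b[1] & eu[, 1] <= b[2] &
        eu[, 2] >= b[3] & eu[, 2] <= b[4]
      sde[inb] <- 1 / pattern$kappa_noisy
    }
    noise <- with_seed(pattern$seed,
                       stats::rnorm(length(theta), 0, sde))
    theta <- (theta + noise / 2) %% pi
  }
  angle_to_fibre(theta, basis, mesh$chamber)
}

#' Sample a fibre field onto a regular 3D point grid
#'
#' Emulates a voxel-grid fibre measurement (e.g. the primary eigenvector of
#' diffusion-tensor imaging reconstructed at a stated voxel pitch): a
#' regular grid at spacing `pitch` is laid over the mesh bounding box and
#' grid points within half a pitch (plus half a local edge) of the surface
#' keep the fibre vector of their nearest element.
#'
#' @param mesh a [surface_mesh].
#' @param fibres a [fibre_field].
#' @param pitch grid spacing in mm (default 0.4).
#' @return a `vector_cloud`: list with `points` (S x 3) and `vectors`
#'   (S x 3 unit vectors).
#' @export
make_vector_cloud <- function(mesh, fibres, pitch = 0.4) {
  if (pitch <= 0) stop("pitch must be > 0")
  bb <- apply(mesh$vertices, 2, range)
  gx <- seq(bb[1, 1] - pitch / 2, bb[2, 1] + pitch / 2, by = pitch)
  gy <- seq(bb[1, 2] - pitch / 2, bb[2, 2] + pitch / 2, by = pitch)
  gz <- seq(bb[1, 3] - pitch / 2, bb[2, 3] + pitch / 2, by = pitch)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  cen <- triangle_centroids(mesh)
  nn <- cpp_nearest_3d(pts[, 1], pts[, 2], pts[, 3],
                       cen[, 1], cen[, 2], cen[, 3])
  d <- sqrt(rowSums((pts - cen[nn, , drop = FALSE])^2))
  med_edge <- stats::median(sqrt(rowSums(
    (mesh$vertices[mesh$triangles[, 1], ] -
       mesh$vertices[mesh$triangles[, 2], ])^2)))
  keep <- d <= 0.75 * pitch + 0.5 * med_edge
  if (!any(keep)) keep[which.min(d)] <- TRUE   # always >= 1 sample
  structure(list(points = pts[keep, , drop = FALSE],
                 vectors = unclass(fibres)[nn[keep], , drop = FALSE]),
            class = "vector_cloud")
}
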