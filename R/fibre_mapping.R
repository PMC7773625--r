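#' Per-element orthonormal coordinate basis from the coordinate gradients
#'
#' For each triangle, `e_alpha` is the in-plane normalised gradient of the
#' alpha coordinate and `e_beta = n x e_alpha`, giving an orthonormal
#' tangent pair tied to the coordinate system. Elements with a degenerate
#' alpha gradient inherit the basis of their nearest non-degenerate
#' neighbour (count reported as attribute `n_degenerate`).
#'
#' @param mesh a [surface_mesh].
#' @param uac a `uac_field`.
#' @return a `uac_basis`: list of M x 3 matrices `e_alpha`, `e_beta`,
#'   `normal`.
#' @export
compute_uac_basis <- function(mesh, uac) {
  v <- mesh$vertices; tr <- mesh$triangles
  nrm <- triangle_normals(mesh)
  ar <- triangle_areas(mesh)
  # gradient of a per-corner linear field u over each triangle:
  # grad u = (n x (u1 e1 + u2 e2 + u3 e3)) / (2A), e_i = edge opposite i
  e1 <- v[tr[, 3], , drop = FALSE] - v[tr[, 2], , drop = FALSE]
  e2 <- v[tr[, 1], , drop = FALSE] - v[tr[, 3], , drop = FALSE]
  e3 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  a <- uac$alpha_corner
  s <- a[, 1] * e1 + a[, 2] * e2 + a[, 3] * e3
  grad <- cbind(nrm[, 2] * s[, 3] - nrm[, 3] * s[, 2],
                nrm[, 3] * s[, 1] - nrm[, 1] * s[, 3],
                nrm[, 1] * s[, 2] - nrm[, 2] * s[, 1]) / (2 * ar)
  glen <- sqrt(rowSums(grad^2))
  degen <- which(glen < 1e-12)
  ok <- which(glen >= 1e-12)
  if (!length(ok)) stop("alpha gradient degenerate on every element")
  ea <- grad / pmax(glen, 1e-300)
  if (length(degen)) {
    cen <- triangle_centroids(mesh)
    nn <- cpp_nearest_3d(cen[degen, 1], cen[degen, 2], cen[degen, 3],
                         cen[ok, 1], cen[ok, 2], cen[ok, 3])
    src <- ok[nn]
    # re-project the neighbour's e_alpha into this element's plane
    borrowed <- ea[src, , drop = FALSE]
    nd <- nrm[degen, , drop = FALSE]
    borrowed <- borrowed - nd * rowSums(borrowed * nd)
    blen <- sqrt(rowSums(borrowed^2))
    ea[degen, ] <- borrowed / pmax(blen, 1e-300)
  }
  eb <- cbind(nrm[, 2] * ea[, 3] - nrm[, 3] * ea[, 2],
              nrm[, 3] * ea[, 1] - nrm[, 1] * ea[, 3],
              nrm[, 1] * ea[, 2] - nrm[, 2] * ea[, 1])
  structure(list(e_alpha = ea, e_beta = eb, normal = nrm),
            class = "uac_basis")
}

# Chamber convention for the angle reference axis: LA angles are measured
# from the alpha axis (lateral-septal direction ~ 0, posterior-anterior
# ~ pi/2); RA angles from the beta axis (IVC-SVC ~ 0, lateral-septal
# ~ pi/2). The orthogonal axis is n x ref, keeping the frame right-handed.
basis_frame <- function(basis, chamber) {
  if (identical(chamber, "RA")) {
    ref <- basis$e_beta
    nrm <- basis$normal
    orth <- cbind(nrm[, 2] * ref[, 3] - nrm[, 3] * ref[, 2],
                  nrm[, 3] * ref[, 1] - nrm[, 1] * ref[, 3],
                  nrm[, 1] * ref[, 2] - nrm[, 2] * ref[, 1])
    list(ref = ref, orth = orth)
  } else {
    list(ref = basis$e_alpha, orth = basis$e_beta)
  }
}

#' Convert between fibre vectors and coordinate angles
#'
#' `fibre_to_angle` expresses each element's fibre vector as an angle theta
#' in `[0, pi)` measured from the chamber's reference axis;
#' `angle_to_fibre` reconstructs the 3D unit tangent vector. The two are
#' inverse up to fibre sense (v and -v map to the same theta).
#'
#' @param fibres a [fibre_field].
#' @param basis a `uac_basis` from [compute_uac_basis].
#' @param chamber `"LA"` or `"RA"` (reference-axis convention).
#' @param theta numeric vector of angles.
#' @return `fibre_to_angle`: numeric vector in `[0, pi)`;
#'   `angle_to_fibre`: a [fibre_field].
#' @export
fibre_to_angle <- function(fibres, basis, chamber = "LA") {
  fr <- basis_frame(basis, chamber)
  f <- unclass(fibres)
  th <- atan2(rowSums(f * fr$orth), rowSums(f * fr$ref))
  th %% pi
}

#' @rdname fibre_to_angle
#' @param mesh optional mesh for validity checks (unused in reconstruction).
#' @export
angle_to_fibre <- function(theta, basis, chamber = "LA", mesh = NULL) {
  fr <- basis_frame(basis, chamber)
  v <- cos(theta) * fr$ref + sin(theta) * fr$orth
  structure(v, class = c("fibre_field", "matrix"), theta = theta %% pi)
}

#' Assign fibres to a surface from a vector sample cloud
#'
#' Each element takes the vector of the sample nearest its centroid,
#' projected into the triangle plane and renormalised — the standard way of
#' pulling a voxel-based fibre measurement onto a surface mesh. Samples
#' that project to (near) zero length are replaced by the nearest
#' neighbouring element's fibre; the replacement count is reported.
#'
#' @param mesh a [surface_mesh].
#' @param cloud a `vector_cloud` (see [make_vector_cloud]).
#' @return a [fibre_field] with attribute `n_replaced`.
#' @export
project_fibres_to_surface <- function(mesh, cloud) {
  if (!length(cloud$points) || nrow(cloud$points) == 0L)
    stop("empty vector cloud")
  cen <- triangle_centroids(mesh)
  nn <- cpp_nearest_3d(cen[, 1], cen[, 2], cen[, 3],
                       cloud$points[, 1], cloud$points[, 2],
                       cloud$points[, 3])
  raw <- cloud$vectors[nn, , drop = FALSE]
  nrm <- triangle_normals(mesh)
  v <- raw - nrm * rowSums(raw * nrm)
  len <- sqrt(rowSums(v^2))
  bad <- which(len < 1e-6)
  okv <- which(len >= 1e-6)
  v[okv, ] <- v[okv, , drop = FALSE] / len[okv]
  if (length(bad)) {
    if (!length(okv)) stop("all projected fibres degenerate")
    nb <- cpp_nearest_3d(cen[bad, 1], cen[bad, 2], cen[bad, 3],
                         cen[okv, 1], cen[okv, 2], cen[okv, 3])
    src <- okv[nb]
    b <- v[src, , drop = FALSE]
    nd <- nrm[bad, , drop = FALSE]
    b <- b - nd * rowSums(b * nd)
    v[bad, ] <- b / sqrt(rowSums(b^2))
  }
  structure(v, class = c("fibre_field", "matrix"),
            n_replaced = length(bad))
}

# Interpolator for a per-element angle field in coordinate space: builds the
# flattened (seam-duplicated) triangulation with per-vertex doubled-angle
# resultants, and returns a function mapping (alpha, beta) query points to
# interpolated (cos 2theta, sin 2theta) plus location metadata. Triangles
# touching the seam are excluded from vertex averaging; queries landing in
# them are flagged.
angle_interpolator <- function(mesh, uac, theta) {
  m <- n_triangles(mesh)
  stopifnot(length(theta) == m)
  flat <- uac_flat_mesh(mesh, uac)
  seam_tri <- flat$seam_triangles
  c2 <- cos(2 * theta); s2 <- sin(2 * theta)
  w <- triangle_areas(mesh)
  use <- !seam_tri
  if (!any(use)) use <- rep(TRUE, m)
  idx <- as.integer(flat$triangles[use, ])
  vc <- as.numeric(rowsum(rep(w[use] * c2[use], 3), idx))
  vs <- as.numeric(rowsum(rep(w[use] * s2[use], 3), idx))
  vid <- sort(unique(idx))
  cvert <- numeric(nrow(flat$vertices)); svert <- numeric(nrow(flat$vertices))
  cvert[vid] <- vc; svert[vid] <- vs
  len <- sqrt(cvert^2 + svert^2)
  nz <- len > 1e-12
  cvert[nz] <- cvert[nz] / len[nz]; svert[nz] <- svert[nz] / len[nz]
  covered <- logical(nrow(flat$vertices)); covered[vid] <- TRUE
  function(points) {
    loc <- barycentric_locate(points, flat$vertices, flat$triangles)
    tri <- loc$triangle
    wts <- loc$weights
    vi <- flat$triangles[tri, , drop = FALSE]
    cq <- rowSums(matrix(cvert[vi], ncol = 3) * wts)
    sq <- rowSums(matrix(svert[vi], ncol = 3) * wts)
    ok_cov <- matrix(covered[vi], ncol = 3)
    list(c = cq, s = sq, triangle = tri, snapped = loc$snapped,
         distance = loc$distance,
         on_seam = seam_tri[tri] | rowSums(ok_cov) < 3L,
         resultant = sqrt(cq^2 + sq^2))
  }
}

# Flattened 2D triangulation in coordinate space with seam vertices
# duplicated per region, so each triangle carries its own region's beta.
uac_flat_mesh <- function(mesh, uac) {
  tr <- mesh$triangles
  m <- nrow(tr)
  seam <- uac$seam
  on_seam_v <- logical(length(uac$alpha)); on_seam_v[seam] <- TRUE
  seam_tri <- matrix(on_seam_v[tr], ncol = 3)
  seam_any <- rowSums(seam_tri) > 0L
  # key: vertex id + (region for seam vertices)
  reg <- uac$partition
  key_m <- matrix(paste(as.integer(tr),
                        ifelse(matrix(on_seam_v[tr], ncol = 3),
                               rep(reg, 3), 0L)),
                  ncol = 3)
  keys <- unique(as.vector(key_m))
  idx <- matrix(match(key_m, keys), ncol = 3)
  av <- numeric(length(keys)); bv <- numeric(length(keys))
  av[as.vector(idx)] <- as.vector(uac$alpha_corner)
  bv[as.vector(idx)] <- as.vector(uac$beta_corner)
  list(vertices = cbind(av, bv), triangles = idx,
       seam_triangles = seam_any, orig_vertex = as.integer(
         vapply(strsplit(keys, " "), `[`, "", 1)))
}

#' Map a fibre field between anatomies through coordinate space
#'
#' The source field is expressed as angles in the source coordinate basis;
#' each target element centroid is located in the source's flattened
#' coordinate triangulation and the doubled-angle unit vector
#' `(cos 2theta, sin 2theta)` is barycentrically interpolated (never raw
#' theta, which is discontinuous at the 0/pi wrap) and halved back to an
#' angle; the 3D tangent vector is rebuilt through the target basis.
#' Target elements on the seam, or whose interpolation is degenerate, take
#' the value of their nearest resolved neighbour.
#'
#' @param source list with `mesh`, `uac`, and `fibres` or `theta`.
#' @param target list with `mesh`, `uac`.
#' @param snap_tol coordinate-space distance beyond which an unlocatable
#'   target centroid is an error.
#' @return a [fibre_field] on the target mesh, with attributes `theta` and
#'   `report` (snap/seam counts).
#' @export
map_fibres <- function(source, target, snap_tol = 0.1) {
  if (!identical(source$mesh$chamber, target$mesh$chamber))
    stop("source and target chambers differ")
  chamber <- source$mesh$chamber
  th_s <- source$theta
  if (is.null(th_s)) {
    sb <- compute_uac_basis(source$mesh, source$uac)
    th_s <- fibre_to_angle(source$fibres, sb, chamber)
  }
  # identity fast path: mapping a field onto its own anatomy is exact
  if (identical(source$mesh$vertices, target$mesh$vertices) &&
      identical(source$mesh$triangles, target$mesh$triangles) &&
      identical(source$uac$alpha, target$uac$alpha) &&
      identical(source$uac$beta, target$uac$beta)) {
    tb <- compute_uac_basis(target$mesh, target$uac)
    out <- angle_to_fibre(th_s %% pi, tb, chamber)
    attr(out, "report") <- list(n_snapped = 0L, n_seam_replaced = 0L,
                                max_snap_distance = 0)
    return(out)
  }
  interp <- angle_interpolator(source$mesh, source$uac, th_s)
  eu <- element_uac(target$mesh, target$uac)
  q <- interp(eu)
  far <- q$distance > snap_tol
  if (any(far))
    stop(sum(far), " target centroids unlocatable in source coordinate",
         " space (distance > ", snap_tol, ")")
  theta_t <- (0.5 * atan2(q$s, q$c)) %% pi
  # target elements on the target seam also get the neighbour rule
  sv <- logical(nrow(target$mesh$vertices)); sv[target$uac$seam] <- TRUE
  on_seam_t <- rowSums(matrix(sv[target$mesh$triangles], ncol = 3)) > 0L
  bad <- which(q$on_seam | q$resultant < 1e-9 | on_seam_t)
  good <- setdiff(seq_along(theta_t), bad)
  if (length(bad) && length(good)) {
    cen <- triangle_centroids(target$mesh)
    nb <- cpp_nearest_3d(cen[bad, 1], cen[bad, 2], cen[bad, 3],
                         cen[good, 1], cen[good, 2], cen[good, 3])
    theta_t[bad] <- theta_t[good[nb]]
  }
  tb <- compute_uac_basis(target$mesh, target$uac)
  out <- angle_to_fibre(theta_t, tb, chamber)
  attr(out, "report") <- list(n_snapped = sum(q$snapped),
                              n_seam_replaced = length(bad),
                              max_snap_distance = max(q$distance))
  out
}

#' Write a fibre-mapping report as JSON
#'
#' @param fibres a mapped [fibre_field] (from [map_fibres]).
#' @param path output path.
#' @export
write_mapping_report <- function(fibres, path) {
  rep <- attr(fibres, "report")
  if (is.null(rep)) rep <- list()
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
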