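#' Atlas coordinate table for anatomical structures
#'
#' Target (alpha, beta) locations at which vessel rims are pinned in the
#' coordinate system, so that the same structure lands at the same
#' coordinates on every anatomy. Pinning constrains each rim's mean
#' coordinates exactly while leaving the rim's shape free. The defaults
#' are the population averages of the unpinned rim centroids over the
#' synthetic anatomy family (the same construction the atlas idea
#' prescribes: fix structures at their average location to minimise
#' distortion); the table is plain data and can be edited to reproduce
#' any other layout.
#'
#' @param chamber `"LA"` or `"RA"`.
#' @return data frame with `structure`, `alpha`, `beta` and `box`
#'   (half-width of the acceptance box used by self-consistency checks).
#' @export
atlas_coordinates <- function(chamber = c("LA", "RA")) {
  chamber <- match.arg(chamber)
  if (chamber == "LA") {
    data.frame(
      structure = c("RSPV", "RIPV", "LSPV", "LIPV"),
      alpha = c(0.31, 0.27, 0.69, 0.77),
      beta = c(0.30, 0.14, 0.31, 0.15),
      box = 0.10)
  } else {
    data.frame(structure = c("IVC", "SVC", "CS"),
               alpha = c(0.31, 0.62, 0.87),
               beta = c(0.43, 0.85, 0.62),
               box = 0.10)
  }
}

# Rim-loop vertex nearest `point` that has at least one non-rim neighbour
# (so an interior path can start there).
connectable_loop_vertex <- function(mesh, loop, all_rim_v, point = NULL,
                                    opposite_of = NULL) {
  tr <- mesh$triangles
  is_rim <- logical(nrow(mesh$vertices)); is_rim[all_rim_v] <- TRUE
  deg <- integer(nrow(mesh$vertices))
  for (k in 1:3) {
    opp <- cbind(tr[, k], tr[, (k %% 3L) + 1L])
    ok <- !is_rim[opp[, 2]]
    acc <- rowsum(as.integer(ok), opp[, 1])
    deg[as.integer(rownames(acc))] <- deg[as.integer(rownames(acc))] +
      acc[, 1]
  }
  connectable <- deg[loop] > 0L
  if (!any(connectable)) stop("rim has no connectable vertices")
  if (!is.null(point)) {
    d <- sqrt(rowSums(sweep(mesh$vertices[loop, , drop = FALSE], 2,
                            as.numeric(point))^2))
    d[!connectable] <- Inf
    loop[which.min(d)]
  } else {
    k0 <- match(opposite_of, loop)
    off <- (seq_along(loop) - k0) %% length(loop)
    score <- abs(off - length(loop) / 2)
    score[!connectable] <- Inf
    loop[which.min(score)]
  }
}

# Cut chain over the chamber dome: valve split vertex -> apex (farthest
# non-rim vertex from the valve rim) -> other split vertex, avoiding every
# rim.
dome_cut_chain <- function(mesh, v_a, v_b, valve, all_rim_v) {
  g <- mesh_edge_graph(mesh)
  dv <- igraph::distances(g, v = as.character(valve))
  dmin <- stats::setNames(apply(dv, 2, min), igraph::V(g)$name)
  cand <- setdiff(seq_len(nrow(mesh$vertices)), all_rim_v)
  w <- cand[which.max(dmin[as.character(cand)])]
  ch1 <- geodesic_path(mesh, v_a, w, forbidden = all_rim_v)
  ch2 <- geodesic_path(mesh, v_b, w,
                       forbidden = c(all_rim_v, setdiff(ch1, w)))
  c(ch1, rev(ch2)[-1])
}

# Index range of the chain segment between the chain vertices nearest two
# reference rim loops.
chain_segment <- function(mesh, chain, loop_a, loop_b) {
  v <- mesh$vertices
  near_idx <- function(loop) {
    ctr <- colMeans(v[loop, , drop = FALSE])
    which.min(rowSums(sweep(v[chain, , drop = FALSE], 2, ctr)^2))
  }
  i <- near_idx(loop_a); j <- near_idx(loop_b)
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  if (i == j) j <- min(i + 1L, length(chain))
  c(i, j)
}

#' Build LA boundary conditions for the two coordinate solves
#'
#' From the five labelled rims and one user seed point (a point on the
#' lateral mitral valve) derives the whole Dirichlet set-up: a cut chain
#' from the septal MV over the atrial dome to the lateral MV; Dirichlet
#' 0/1 for the septal-to-lateral coordinate (alpha) on the septal/lateral
#' portions of the chain; Dirichlet 0/1 for the posterior-to-anterior
#' coordinate (beta) on the posterior/anterior MV arcs with the roof
#' segment of the chain (between the superior PV rims) fixed at the roof
#' value, solved separately on the posterior and anterior sub-meshes; and
#' mean-coordinate pinning of the four PV rims to the atlas table. Beta is
#' double-valued along the non-roof part of the chain, which becomes the
#' declared seam.
#'
#' @param mesh a [surface_mesh] with rims `MV`, `LSPV`, `LIPV`, `RSPV`,
#'   `RIPV` in `mesh$rim_labels`.
#' @param seed_point length-3 point near the lateral MV.
#' @param atlas atlas coordinate table (see [atlas_coordinates]).
#' @param beta_roof beta value assigned to the roof line (default 0.5).
#' @return a `uac_bcs` object (boundary condition set + partition).
#' @export
build_la_bcs <- function(mesh, seed_point, atlas = atlas_coordinates("LA"),
                         beta_roof = 0.5) {
  rims <- mesh$rim_labels
  need <- c("MV", "LSPV", "LIPV", "RSPV", "RIPV")
  miss <- setdiff(need, names(rims))
  if (length(miss)) stop("missing rim label(s): ", paste(miss, collapse = ", "))
  v <- mesh$vertices
  all_rim_v <- unlist(rims, use.names = FALSE)
  mv <- rims$MV

  v_lat_mv <- connectable_loop_vertex(mesh, mv, all_rim_v, point = seed_point)
  v_sep_mv <- connectable_loop_vertex(mesh, mv, all_rim_v,
                                      opposite_of = v_lat_mv)
  chain <- dome_cut_chain(mesh, v_sep_mv, v_lat_mv, mv, all_rim_v)
  seg <- chain_segment(mesh, chain, rims$RSPV, rims$LSPV)
  p_roof <- chain[seg[1]:seg[2]]
  p_sep <- chain[1:seg[1]]
  p_lat <- chain[seg[2]:length(chain)]

  part <- partition_by_cut(mesh, chain)
  if (part$n != 2L)
    stop("dome cut split the mesh into ", part$n, " components (expected 2)")
  comp_of_rim <- function(loop) {
    el <- incident_elements(mesh, loop)
    as.integer(names(which.max(table(part$component[el]))))
  }
  post_id <- comp_of_rim(rims$RIPV)
  if (comp_of_rim(rims$LIPV) != post_id)
    warning("inferior PV rims fall in different components; ",
            "using the RIPV side as posterior")

  arcs <- split_loop(mv, c(v_sep_mv, v_lat_mv))
  arc_side <- vapply(arcs, function(a) {
    el <- incident_elements(mesh, setdiff(a, c(v_sep_mv, v_lat_mv)))
    mean(part$component[el] == post_id)
  }, 0)
  mv_post <- arcs[[which.max(arc_side)]]
  mv_ant <- arcs[[which.min(arc_side)]]

  sep_nodes <- setdiff(p_sep, p_roof)
  lat_nodes <- setdiff(p_lat, p_roof)
  all_tris <- seq_len(n_triangles(mesh))
  coords <- list(
    alpha = list(
      regions = list(full = list(
        triangles = all_tris,
        bc = data.frame(node = c(sep_nodes, lat_nodes),
                        value = c(rep(0, length(sep_nodes)),
                                  rep(1, length(lat_nodes)))),
        range = c(0, 1), mean_constraints = list())),
      interface = integer(0)),
    beta = list(
      regions = list(
        posterior = list(
          triangles = which(part$component == post_id),
          bc = rbind(data.frame(node = mv_post, value = 0),
                     data.frame(node = p_roof, value = 1)),
          range = c(0, beta_roof), mean_constraints = list()),
        anterior = list(
          triangles = which(part$component != post_id),
          bc = rbind(data.frame(node = p_roof, value = 0),
                     data.frame(node = mv_ant, value = 1)),
          range = c(beta_roof, 1), mean_constraints = list())),
      interface = p_roof))

  for (i in seq_len(nrow(atlas))) {
    st <- atlas$structure[i]
    if (!st %in% names(rims)) next
    coords$alpha$regions$full$mean_constraints <- c(
      coords$alpha$regions$full$mean_constraints,
      list(list(nodes = rims[[st]], value = atlas$alpha[i],
                structure = st)))
    side <- if (comp_of_rim(rims[[st]]) == post_id) "posterior" else
      "anterior"
    rng <- coords$beta$regions[[side]]$range
    loc <- (atlas$beta[i] - rng[1]) / (rng[2] - rng[1])
    if (loc < 0 || loc > 1) {
      loc <- min(0.95, max(0.05, loc))
      warning("beta target for ", st, " clamped into its ", side,
              " sub-mesh")
    }
    coords$beta$regions[[side]]$mean_constraints <- c(
      coords$beta$regions[[side]]$mean_constraints,
      list(list(nodes = rims[[st]], value = loc, structure = st)))
  }

  structure(list(chamber = "LA", coords = coords,
                 roof = p_roof,
                 paths = list(septal = p_sep, lateral = p_lat,
                              roof = p_roof, mv_posterior = mv_post,
                              mv_anterior = mv_ant, chain = chain),
                 partition = part$component,
                 posterior_id = post_id),
            class = "uac_bcs")
}

#' Build RA boundary conditions for the two coordinate solves
#'
#' Mirrors the LA construction with the chamber's own landmarks: a cut
#' chain runs from the posterior tricuspid-valve split point over the dome
#' to the anterior split point (the two user seed points); the
#' lateral-to-septal coordinate (alpha) is solved separately on the
#' lateral and septal sub-meshes with Dirichlet 0/1 on the TV arcs and
#' the inter-caval segment of the chain fixed at 0.5; the IVC-to-SVC
#' coordinate (beta) is one full-mesh solve with Dirichlet 0 on the IVC
#' rim and 1 on the SVC rim. The CS rim is pinned (mean coordinates) to
#' the atlas table. Alpha is double-valued along the non-ridge part of
#' the chain (the declared seam).
#'
#' @param mesh a [surface_mesh] with rims `TV`, `SVC`, `IVC`, `CS`.
#' @param seed_points list with `posterior` and `anterior` length-3 points
#'   marking the TV split.
#' @param atlas atlas coordinate table.
#' @param alpha_ridge alpha value on the inter-caval ridge (default 0.5).
#' @return a `uac_bcs` object.
#' @export
build_ra_bcs <- function(mesh, seed_points, atlas = atlas_coordinates("RA"),
                         alpha_ridge = 0.5) {
  rims <- mesh$rim_labels
  need <- c("TV", "SVC", "IVC", "CS")
  miss <- setdiff(need, names(rims))
  if (length(miss)) stop("missing rim label(s): ", paste(miss, collapse = ", "))
  v <- mesh$vertices
  all_rim_v <- unlist(rims, use.names = FALSE)
  tv <- rims$TV

  v_post <- connectable_loop_vertex(mesh, tv, all_rim_v,
                                    point = seed_points$posterior)
  v_ant <- connectable_loop_vertex(mesh, tv, all_rim_v,
                                   point = seed_points$anterior)
  if (v_post == v_ant) stop("TV split points coincide")
  chain <- dome_cut_chain(mesh, v_post, v_ant, tv, all_rim_v)
  near_idx <- function(loop) {
    ctr <- colMeans(v[loop, , drop = FALSE])
    which.min(rowSums(sweep(v[chain, , drop = FALSE], 2, ctr)^2))
  }
  i_ivc <- near_idx(rims$IVC); i_svc <- near_idx(rims$SVC)
  lo <- min(i_ivc, i_svc); hi <- max(i_ivc, i_svc)
  if (lo == hi) hi <- min(lo + 1L, length(chain))
  p_ridge <- chain[lo:hi]
  # chain halves outside the inter-caval ridge drive the IVC-to-SVC
  # coordinate: 0 on the IVC-side half, 1 on the SVC-side half
  p_first <- setdiff(chain[1:lo], p_ridge)
  p_last <- setdiff(chain[hi:length(chain)], p_ridge)
  if (i_ivc <= i_svc) { p_post <- p_first; p_ant <- p_last } else {
    p_post <- p_last; p_ant <- p_first
  }

  part <- partition_by_cut(mesh, chain)
  if (part$n != 2L)
    stop("dome cut split the mesh into ", part$n, " components (expected 2)")
  comp_of_rim <- function(loop) {
    el <- incident_elements(mesh, loop)
    as.integer(names(which.max(table(part$component[el]))))
  }

  arcs <- split_loop(tv, c(v_post, v_ant))
  # lateral arc: the one whose elements sit away from the septal
  # structures (SVC + CS)
  sep_ref <- colMeans(v[c(rims$SVC, rims$CS), , drop = FALSE])
  arc_d <- vapply(arcs, function(a)
    mean(sqrt(rowSums(sweep(v[a, , drop = FALSE], 2, sep_ref)^2))), 0)
  tv_lat <- arcs[[which.max(arc_d)]]
  tv_sep <- arcs[[which.min(arc_d)]]
  arc_comp <- function(a) {
    el <- incident_elements(mesh, setdiff(a, c(v_post, v_ant)))
    as.integer(names(which.max(table(part$component[el]))))
  }
  lat_id <- arc_comp(tv_lat)

  coords <- list(
    alpha = list(
      regions = list(
        lateral = list(
          triangles = which(part$component == lat_id),
          bc = rbind(data.frame(node = setdiff(tv_lat, c(v_post, v_ant)),
                                value = 0),
                     data.frame(node = p_ridge, value = 1)),
          range = c(0, alpha_ridge), mean_constraints = list()),
        septal = list(
          triangles = which(part$component != lat_id),
          bc = rbind(data.frame(node = p_ridge, value = 0),
                     data.frame(node = setdiff(tv_sep, c(v_post, v_ant)),
                                value = 1)),
          range = c(alpha_ridge, 1), mean_constraints = list())),
      interface = p_ridge),
    beta = list(
      regions = list(full = list(
        triangles = seq_len(n_triangles(mesh)),
        bc = data.frame(
          node = c(p_post, p_ant),
          value = c(rep(0, length(p_post)), rep(1, length(p_ant)))),
        range = c(0, 1), mean_constraints = list())),
      interface = integer(0)))

  for (i in seq_len(nrow(atlas))) {
    st <- atlas$structure[i]
    if (!st %in% names(rims)) next
    side <- if (comp_of_rim(rims[[st]]) == lat_id) "lateral" else "septal"
    rng <- coords$alpha$regions[[side]]$range
    loc <- (atlas$alpha[i] - rng[1]) / (rng[2] - rng[1])
    if (loc < 0 || loc > 1) {
      loc <- min(0.95, max(0.05, loc))
      warning("alpha target for ", st, " clamped into its ", side,
              " sub-mesh")
    }
    coords$alpha$regions[[side]]$mean_constraints <- c(
      coords$alpha$regions[[side]]$mean_constraints,
      list(list(nodes = rims[[st]], value = loc, structure = st)))
    coords$beta$regions$full$mean_constraints <- c(
      coords$beta$regions$full$mean_constraints,
      list(list(nodes = rims[[st]], value = atlas$beta[i],
                structure = st)))
  }

  structure(list(chamber = "RA", coords = coords,
                 roof = p_ridge,
                 paths = list(tv_lateral = tv_lat, tv_septal = tv_sep,
                              ridge = p_ridge, chain = chain),
                 partition = part$component,
                 posterior_id = lat_id),
            class = "uac_bcs")
}

# Partition triangles into connected components after cutting along a vertex
# chain: triangle adjacency across an edge is severed when both edge
# endpoints lie on the chain.
partition_by_cut <- function(mesh, chain) {
  tr <- mesh$triangles
  on_chain <- logical(nrow(mesh$vertices))
  on_chain[chain] <- TRUE
  et <- edge_table(mesh)
  cutedge <- on_chain[et$a] & on_chain[et$b]
  key <- paste(et$a, et$b)
  keep <- !cutedge
  tri_of <- split(et$tri[keep], key[keep])
  pairs <- tri_of[vapply(tri_of, length, 1L) == 2L]
  component <- rep(1L, nrow(tr))
  if (length(pairs)) {
    em <- matrix(unlist(pairs), ncol = 2, byrow = TRUE)
    g <- igraph::make_empty_graph(n = nrow(tr), directed = FALSE)
    g <- igraph::add_edges(g, t(em))
    comp <- igraph::components(g)
    component <- as.integer(comp$membership)
    # merge stray components (triangles fully surrounded by the chain) into
    # their dominant neighbour side by size ranking
    sizes <- sort(table(component), decreasing = TRUE)
    if (length(sizes) > 2L) {
      main <- as.integer(names(sizes)[1:2])
      cen_all <- triangle_centroids(mesh)
      for (cid in setdiff(unique(component), main)) {
        idx <- which(component == cid)
        cen <- colMeans(cen_all[idx, , drop = FALSE])
        d <- vapply(main, function(mc) {
          cm <- cen_all[component == mc, , drop = FALSE]
          min(sqrt(rowSums(sweep(cm, 2, cen)^2)))
        }, 0)
        component[idx] <- main[which.min(d)]
      }
      component <- as.integer(factor(component))
    }
  }
  list(component = component, n = length(unique(component)))
}

# Elements incident to any of the given vertices.
incident_elements <- function(mesh, vertices) {
  tr <- mesh$triangles
  which(tr[, 1] %in% vertices | tr[, 2] %in% vertices | tr[, 3] %in% vertices)
}

# Split an ordered loop at two of its vertices into the two arcs
# (both arcs include the split vertices as endpoints).
split_loop <- function(loop, at) {
  i <- match(at[1], loop); j <- match(at[2], loop)
  if (is.na(i) || is.na(j) || i == j) stop("invalid loop split points")
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  arc1 <- loop[i:j]
  arc2 <- c(loop[j:length(loop)], loop[1:i])
  list(arc1, arc2)
}

#' Compute the two-coordinate field from a boundary condition set
#'
#' Runs the Laplace solves prescribed by a `uac_bcs` object. Each
#' coordinate is solved on one full mesh or on two sub-meshes whose
#' solutions are rescaled into their global ranges and concatenated;
#' continuity is enforced on the interface (roof/ridge) segment, and
#' the remaining cut vertices -- where the per-region values disagree --
#' form the seam. Structure pins enter as exact mean-coordinate
#' constraints. A local untangling pass then relaxes any folded
#' neighbourhoods (pinning can fold a handful of triangles next to a
#' constrained rim) while preserving all Dirichlet values and pinned
#' means. Per-element corner coordinates carry the region-consistent
#' values used by all downstream geometry.
#'
#' @param mesh a [surface_mesh].
#' @param bcs a `uac_bcs` from [build_la_bcs] / [build_ra_bcs].
#' @return a `uac_field`: per-vertex `alpha`, `beta` in `[0,1]`, M x 3
#'   corner matrices, element `partition`, `seam` vertices, residuals.
#' @export
compute_uac <- function(mesh, bcs) {
  stopifnot(inherits(bcs, "uac_bcs"))
  n <- nrow(mesh$vertices)
  m <- n_triangles(mesh)
  tr <- mesh$triangles
  resid <- numeric(0)
  by_region <- list()
  for (cn in names(bcs$coords)) {
    co <- bcs$coords[[cn]]
    vals <- list()
    for (nm in names(co$regions)) {
      reg <- co$regions[[nm]]
      u <- solve_laplace(mesh, reg$bc, triangles = reg$triangles,
                         mean_constraints = reg$mean_constraints)
      resid[paste(cn, nm, sep = "_")] <- attr(u, "residual")
      vals[[nm]] <- reg$range[1] + u * (reg$range[2] - reg$range[1])
    }
    by_region[[cn]] <- vals
  }
  # seam: cut vertices where a coordinate's region values disagree;
  # interface vertices must agree
  seam <- integer(0)
  for (cn in names(bcs$coords)) {
    vals <- by_region[[cn]]
    if (length(vals) < 2L) next
    B <- do.call(cbind, vals)
    both <- which(rowSums(!is.na(B)) > 1L)
    dis <- both[apply(B[both, , drop = FALSE], 1, function(r)
      diff(range(r, na.rm = TRUE))) > 1e-6]
    bad <- intersect(dis, bcs$coords[[cn]]$interface)
    if (length(bad))
      stop(cn, " discontinuous at ", length(bad), " interface vertices")
    seam <- union(seam, dis)
  }
  ut <- untangle_flattening(mesh, by_region, bcs, seam)
  by_region <- ut$by_region

  corner <- list(); vertex <- list()
  for (cn in names(bcs$coords)) {
    cc <- matrix(NA_real_, m, 3)
    for (nm in names(bcs$coords[[cn]]$regions)) {
      regt <- bcs$coords[[cn]]$regions[[nm]]$triangles
      cc[regt, ] <- matrix(by_region[[cn]][[nm]][tr[regt, , drop = FALSE]],
                           ncol = 3)
    }
    vv <- rep(NA_real_, n)
    for (g in by_region[[cn]]) {
      idx <- which(!is.na(g) & is.na(vv))
      vv[idx] <- g[idx]
    }
    if (anyNA(cc) || anyNA(vv))
      stop("coordinate solve left uncovered vertices (", cn, ")")
    corner[[cn]] <- cc
    vertex[[cn]] <- vv
  }
  structure(list(alpha = vertex$alpha, beta = vertex$beta,
                 alpha_corner = corner$alpha, beta_corner = corner$beta,
                 partition = bcs$partition, seam = seam,
                 chamber = bcs$chamber, residuals = resid,
                 n_untangle_iter = ut$iterations),
            class = "uac_field")
}

# Relax vertices of folded triangles (and their one-ring) towards the
# average of their neighbours until no triangle image is inverted.
# Dirichlet nodes never move; after every sweep each pinned structure is
# shifted uniformly back to its exact mean target. Folds only arise next
# to pinned structures, so the pass is local and converges in a few
# sweeps.
untangle_flattening <- function(mesh, by_region, bcs, seam,
                                max_iter = 100L) {
  tr <- mesh$triangles
  n <- nrow(mesh$vertices)
  m <- nrow(tr)
  sv <- logical(n); sv[seam] <- TRUE
  seam_adj <- rowSums(matrix(sv[tr], ncol = 3)) > 0L
  nb_of <- function(tsub) {
    e <- rbind(tr[tsub, c(1, 2)], tr[tsub, c(2, 3)], tr[tsub, c(3, 1)])
    e <- unique(rbind(e, e[, 2:1]))
    split(e[, 2], e[, 1])
  }
  nb <- list()
  fixed <- list()
  mcs <- list()
  for (cn in names(bcs$coords)) {
    co <- bcs$coords[[cn]]
    nb[[cn]] <- lapply(co$regions, function(r) nb_of(r$triangles))
    fixed[[cn]] <- lapply(co$regions, function(r) unique(r$bc$node))
    mcs[[cn]] <- lapply(co$regions, function(r) {
      lapply(r$mean_constraints, function(mc) {
        mc$value <- r$range[1] + mc$value * (r$range[2] - r$range[1])
        mc
      })
    })
  }
  corner_vals <- function(cn) {
    cc <- matrix(NA_real_, m, 3)
    for (nm in names(bcs$coords[[cn]]$regions)) {
      regt <- bcs$coords[[cn]]$regions[[nm]]$triangles
      cc[regt, ] <- matrix(by_region[[cn]][[nm]][tr[regt, , drop = FALSE]],
                           ncol = 3)
    }
    cc
  }
  it <- 0L
  repeat {
    it <- it + 1L
    A <- corner_vals("alpha"); B <- corner_vals("beta")
    s <- (A[, 2] - A[, 1]) * (B[, 3] - B[, 1]) -
      (A[, 3] - A[, 1]) * (B[, 2] - B[, 1])
    maj <- sign(sum(sign(s)))
    bad <- which(sign(s) != maj & !seam_adj)
    if (!length(bad) || it > max_iter) break
    flipped_v <- unique(as.integer(tr[bad, ]))
    for (cn in names(by_region)) {
      for (nm in names(by_region[[cn]])) {
        g <- by_region[[cn]][[nm]]
        nbs <- nb[[cn]][[nm]]
        reg_nodes <- as.integer(names(nbs))
        relax <- intersect(
          unique(c(flipped_v,
                   unlist(nbs[as.character(intersect(flipped_v,
                                                     reg_nodes))]))),
          reg_nodes)
        relax <- setdiff(relax, fixed[[cn]][[nm]])
        if (length(relax)) {
          newv <- vapply(relax, function(vv) {
            nbv <- nbs[[as.character(vv)]]
            if (length(nbv)) mean(g[nbv], na.rm = TRUE) else g[vv]
          }, 0)
          g[relax] <- newv
        }
        for (mc in mcs[[cn]][[nm]]) {
          cur <- g[mc$nodes]
          g[mc$nodes] <- cur + (mc$value - mean(cur))
        }
        by_region[[cn]][[nm]] <- g
      }
    }
  }
  list(by_region = by_region, iterations = it - 1L)
}

#' @export
print.uac_field <- function(x, ...) {
  cat(sprintf(
    "uac_field (%s): %d vertices, alpha [%.3f, %.3f], beta [%.3f, %.3f], %d seam vertices\n",
    x$chamber, length(x$alpha), min(x$alpha), max(x$alpha),
    min(x$beta), max(x$beta), length(x$seam)))
  invisible(x)
}

#' Per-element coordinates (triangle centroids in coordinate space)
#'
#' @param mesh a [surface_mesh].
#' @param uac a `uac_field`.
#' @return M x 2 matrix of (alpha, beta) element centroids.
#' @export
element_uac <- function(mesh, uac) {
  cbind(rowMeans(uac$alpha_corner), rowMeans(uac$beta_corner))
}

#' Write a coordinate field as CSV (vertex id, alpha, beta)
#'
#' @param uac a `uac_field`.
#' @param path output path.
#' @export
write_uac_csv <- function(uac, path) {
  utils::write.csv(data.frame(vertex = seq_along(uac$alpha),
                              alpha = uac$alpha, beta = uac$beta),
                   path, row.names = FALSE)
  invisible(path)
}

#' Count orientation flips of the 2D flattening
#'
#' A diagnostic for injectivity of the (alpha, beta) flattening: counts
#' triangles whose 2D signed area has the (strict) minority sign.
#' Seam-adjacent triangles are excluded by default (the flattening is
#' discontinuous there by construction); triangles whose image degenerates
#' to a segment of a Dirichlet boundary (signed area 0) are reported
#' separately via attribute `n_degenerate`.
#'
#' @param mesh a [surface_mesh].
#' @param uac a `uac_field`.
#' @param exclude_seam drop seam-adjacent triangles from the count.
#' @return integer count of flipped triangles (attribute `n_degenerate`).
#' @export
count_flipped_triangles <- function(mesh, uac, exclude_seam = TRUE) {
  ax <- uac$alpha_corner[, 1]; ay <- uac$beta_corner[, 1]
  bx <- uac$alpha_corner[, 2]; by <- uac$beta_corner[, 2]
  cx <- uac$alpha_corner[, 3]; cy <- uac$beta_corner[, 3]
  s <- (bx - ax) * (cy - ay) - (cx - ax) * (by - ay)
  keep <- rep(TRUE, length(s))
  if (exclude_seam && length(uac$seam)) {
    sv <- logical(length(uac$alpha)); sv[uac$seam] <- TRUE
    keep <- rowSums(matrix(sv[mesh$triangles], ncol = 3)) == 0L
  }
  s <- s[keep]
  out <- min(sum(s > 0), sum(s < 0))
  attr(out, "n_degenerate") <- sum(s == 0)
  out
}
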