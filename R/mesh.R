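#' Triangulated open-surface mesh
#'
#' Central data container: an oriented triangulated surface, open at the
#' valve/vessel rims, with optional named rim loops, chamber and layer tags.
#' All coordinates are millimetres. Triangle indices are stored 1-based
#' (R convention); file readers/writers translate to the 0-based on-disk
#' dialects.
#'
#' @param vertices numeric N x 3 matrix of vertex positions (mm).
#' @param triangles integer M x 3 matrix of vertex indices (1-based).
#' @param chamber `"LA"`, `"RA"` or `NA`.
#' @param layer `"endo"`, `"epi"` or `NA`.
#' @param rim_labels named list of ordered boundary vertex loops
#'   (integer vectors), e.g. `MV`, `LSPV`, ..., `TV`, `SVC`.
#' @param orient logical; if `TRUE` (default) triangle orientation is made
#'   consistent with normals pointing away from the vertex centroid.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, chamber = NA_character_,
                         layer = NA_character_, rim_labels = list(),
                         orient = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an N x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an M x 3 matrix")
  if (nrow(triangles) < 1L) stop("mesh must contain at least one triangle")
  rng <- range(triangles)
  if (rng[1] < 1L || rng[2] > nrow(vertices))
    stop("triangle index out of range [1, ", nrow(vertices), "]: ", rng[1],
         "..", rng[2])
  if (any(triangles[, 1] == triangles[, 2] |
          triangles[, 2] == triangles[, 3] |
          triangles[, 1] == triangles[, 3]))
    stop("degenerate triangle with repeated vertex")
  mesh <- structure(list(vertices = vertices, triangles = triangles,
                         chamber = chamber, layer = layer,
                         rim_labels = rim_labels),
                    class = "surface_mesh")
  if (orient) mesh <- orient_mesh(mesh)
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles", nrow(x$vertices),
              nrow(x$triangles)))
  if (!is.na(x$chamber)) cat(sprintf(" [%s/%s]", x$chamber, x$layer))
  if (length(x$rim_labels))
    cat(sprintf(", rims: %s", paste(names(x$rim_labels), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Mesh size accessors
#'
#' @param mesh a [surface_mesh].
#' @return vertex / triangle count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_triangles <- function(mesh) nrow(mesh$triangles)

#' Per-triangle geometry
#'
#' @param mesh a `surface_mesh`.
#' @return `triangle_normals`: M x 3 unit normals; `triangle_areas`: length-M
#'   areas (mm^2); `triangle_centroids`: M x 3 centroids.
#' @export
triangle_normals <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  if (any(len <= 0)) stop("zero-area triangle at index ",
                          which(len <= 0)[1])
  n / len
}

#' @rdname triangle_normals
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(n^2))
}

#' @rdname triangle_normals
#' @export
triangle_centroids <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  (v[tr[, 1], , drop = FALSE] + v[tr[, 2], , drop = FALSE] +
     v[tr[, 3], , drop = FALSE]) / 3
}

# Sorted edge table: one row per undirected edge occurrence, with triangle id.
edge_table <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  data.frame(a = pmin(e[, 1], e[, 2]), b = pmax(e[, 1], e[, 2]),
             tri = rep(seq_len(nrow(tr)), 3L))
}

# Undirected edges with multiplicity; errors if any edge is shared by >2
# triangles (non-manifold).
edge_counts <- function(mesh) {
  et <- edge_table(mesh)
  key <- paste(et$a, et$b)
  cnt <- table(key)
  if (any(cnt > 2L))
    stop("non-manifold edge shared by >2 triangles: ",
         names(cnt)[which(cnt > 2L)[1]])
  first <- !duplicated(key)
  data.frame(a = et$a[first], b = et$b[first],
             count = as.integer(cnt[key[first]]))
}

#' Boundary edges of a mesh
#'
#' @param mesh a `surface_mesh`.
#' @return two-column integer matrix of undirected boundary edges.
#' @export
boundary_edges <- function(mesh) {
  ec <- edge_counts(mesh)
  as.matrix(ec[ec$count == 1L, c("a", "b")])
}

#' Make triangle orientation consistent, outward normals
#'
#' Propagates a consistent winding across the triangle adjacency graph, then
#' flips globally so normals point away from the vertex centroid (needed for
#' consistent tangent bases downstream).
#'
#' @param mesh a `surface_mesh`.
#' @return the mesh with possibly re-wound triangles.
#' @export
orient_mesh <- function(mesh) {
  tr <- mesh$triangles
  m <- nrow(tr)
  dir_edges <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  owner <- rep(seq_len(m), 3L)
  und <- paste(pmin(dir_edges[, 1], dir_edges[, 2]),
               pmax(dir_edges[, 1], dir_edges[, 2]))
  dirkey <- paste(dir_edges[, 1], dir_edges[, 2])
  # fast path: winding already consistent iff no directed edge repeats
  if (!anyDuplicated(dirkey)) {
    # nothing to do beyond the global flip below
  } else {
    adj <- split(owner, und)            # triangles sharing each undirected edge
    flipped <- rep(NA, m)
    for (start in seq_len(m)) {
      if (!is.na(flipped[start])) next
      flipped[start] <- FALSE
      queue <- integer(m); queue[1] <- start; qh <- 1L; qt <- 1L
      while (qh <= qt) {
        t <- queue[qh]; qh <- qh + 1L
        tt <- tr[t, ]
        if (flipped[t]) tt <- tt[c(1, 3, 2)]
        de <- rbind(tt[c(1, 2)], tt[c(2, 3)], tt[c(3, 1)])
        for (k in 1:3) {
          uk <- paste(min(de[k, ]), max(de[k, ]))
          for (nb in adj[[uk]]) {
            if (nb == t || !is.na(flipped[nb])) next
            ttn <- tr[nb, ]
            den <- rbind(ttn[c(1, 2)], ttn[c(2, 3)], ttn[c(3, 1)])
            # consistent orientation: shared edge traversed in opposite senses
            same_dir <- any(den[, 1] == de[k, 1] & den[, 2] == de[k, 2])
            flipped[nb] <- if (same_dir) !flipped[t] else flipped[t]
            qt <- qt + 1L; queue[qt] <- nb
          }
        }
      }
    }
    idx <- which(flipped)
    if (length(idx)) tr[idx, ] <- tr[idx, c(1, 3, 2)]
    mesh$triangles <- tr
  }
  # global flip: normals away from centroid
  nrm <- {
    v <- mesh$vertices
    e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
    e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
    cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
          e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
          e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  }
  ctr <- colMeans(mesh$vertices)
  cen <- triangle_centroids(mesh)
  outward <- rowSums(nrm * sweep(cen, 2, ctr))
  if (mean(outward > 0) < 0.5) mesh$triangles <- tr[, c(1, 3, 2)]
  mesh
}

#' Detect and (optionally) label boundary rim loops
#'
#' Finds all closed boundary loops as ordered vertex cycles. If `seeds` is
#' given (a named list/matrix of 3D points), each name is assigned to the
#' loop nearest its seed point; a seed equidistant to two loops is resolved
#' to the smaller loop index with a warning.
#'
#' @param mesh a `surface_mesh`.
#' @param seeds optional named list of length-3 numeric seed points, or a
#'   named 3-column matrix.
#' @return named (if seeds given) list of integer vertex cycles.
#' @export
detect_rims <- function(mesh, seeds = NULL) {
  be <- boundary_edges(mesh)
  if (nrow(be) == 0L)
    stop("mesh has no boundary (closed surface); rims require an open mesh")
  nb <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  bad <- vapply(nb, length, 1L) != 2L
  if (any(bad))
    stop("boundary vertex with != 2 boundary neighbours: ",
         names(nb)[bad][1])
  visited <- character(0)
  loops <- list()
  for (v0 in as.integer(names(nb))) {
    if (as.character(v0) %in% visited) next
    loop <- v0
    prev <- v0
    cur <- nb[[as.character(v0)]][1]
    while (cur != v0) {
      loop <- c(loop, cur)
      nxt <- nb[[as.character(cur)]]
      nxt <- nxt[nxt != prev]
      prev <- cur
      cur <- nxt[1]
    }
    visited <- c(visited, as.character(loop))
    loops[[length(loops) + 1L]] <- loop
  }
  if (is.null(seeds)) return(loops)
  if (is.matrix(seeds))
    seeds <- stats::setNames(lapply(seq_len(nrow(seeds)),
                                    function(i) seeds[i, ]),
                             rownames(seeds))
  out <- list()
  for (nm in names(seeds)) {
    d <- vapply(loops, function(lp) {
      min(sqrt(rowSums(sweep(mesh$vertices[lp, , drop = FALSE], 2,
                             as.numeric(seeds[[nm]]))^2)))
    }, 0)
    best <- which(d <= min(d) + 1e-12)
    if (length(best) > 1L)
      warning("seed '", nm, "' equidistant to ", length(best),
              " loops; taking the smaller loop index")
    out[[nm]] <- loops[[best[1]]]
  }
  out
}

#' Shortest path on the mesh edge graph
#'
#' Edge-graph geodesic (Dijkstra, Euclidean edge weights). Used to seed
#' Dirichlet boundary paths for the coordinate solves; not an exact
#' polyhedral geodesic.
#'
#' @param mesh a `surface_mesh`.
#' @param v_start,v_end vertex indices (1-based).
#' @param forbidden optional vertex indices the path must avoid (must not
#'   include the endpoints).
#' @return integer vector of vertex indices from `v_start` to `v_end`.
#' @export
geodesic_path <- function(mesh, v_start, v_end, forbidden = integer(0)) {
  if (v_start == v_end) return(v_start)
  forbidden <- setdiff(as.integer(forbidden), c(v_start, v_end))
  g <- mesh_edge_graph(mesh)
  if (length(forbidden))
    g <- igraph::delete_vertices(
      g, intersect(as.character(forbidden), igraph::V(g)$name))
  # vertex names survive deletion
  sp <- suppressWarnings(igraph::shortest_paths(
    g, from = as.character(v_start), to = as.character(v_end),
    weights = igraph::E(g)$weight, output = "vpath"))
  path <- as.integer(igraph::V(g)$name[sp$vpath[[1]]])
  if (length(path) == 0L || path[1] != v_start || path[length(path)] != v_end)
    stop("no path between vertices ", v_start, " and ", v_end,
         " (disconnected after exclusion)")
  path
}

mesh_edge_graph <- function(mesh) {
  ec <- edge_counts(mesh)
  v <- mesh$vertices
  w <- sqrt(rowSums((v[ec$a, , drop = FALSE] - v[ec$b, , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(cbind(as.character(ec$a),
                                         as.character(ec$b)),
                                   directed = FALSE)
  igraph::E(g)$weight <- w
  # ensure isolated vertices don't exist (edge graph covers all mesh vertices
  # that appear in triangles, which is all of them for a valid mesh)
  g
}

#' Locate 2D points in a planar triangulation
#'
#' Returns for each query point the containing triangle and its barycentric
#' weights. Points outside the triangulation by more than `tol` are snapped
#' to the nearest triangle (clamped weights) and counted.
#'
#' @param points numeric Q x 2 matrix of query points.
#' @param vertices_2d numeric N x 2 matrix.
#' @param triangles integer M x 3 matrix (1-based).
#' @param tol snap tolerance (default 1e-9 plus announces larger snaps).
#' @return list with `triangle` (Q), `weights` (Q x 3), `snapped` (logical Q),
#'   `distance` (Q) and `n_snapped`.
#' @export
barycentric_locate <- function(points, vertices_2d, triangles, tol = 1e-9) {
  points <- as.matrix(points)
  vertices_2d <- as.matrix(vertices_2d)
  storage.mode(triangles) <- "integer"
  res <- cpp_locate_2d(points[, 1], points[, 2], triangles,
                       vertices_2d[, 1], vertices_2d[, 2], tol)
  res$n_snapped <- sum(res$snapped)
  res
}

#' Per-element fibre field
#'
#' Sense-free unit tangent vectors, one per triangle. Vectors are projected
#' into their triangle plane and renormalised on construction.
#'
#' @param mesh a `surface_mesh`.
#' @param vectors numeric M x 3 matrix.
#' @param project project vectors into their triangle plane and renormalise
#'   (default). With `project = FALSE` the vectors are stored as given
#'   (used by file readers to keep round trips lossless).
#' @return object of class `fibre_field`: M x 3 matrix attribute-tagged.
#' @export
fibre_field <- function(mesh, vectors, project = TRUE) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != n_triangles(mesh))
    stop("fibre field must have one vector per triangle")
  v <- vectors
  if (project) {
    n <- triangle_normals(mesh)
    v <- vectors - n * rowSums(vectors * n)
    len <- sqrt(rowSums(v^2))
    if (any(len < 1e-12))
      stop("fibre vector orthogonal to its triangle plane at element ",
           which(len < 1e-12)[1])
    v <- v / len
  }
  structure(v, class = c("fibre_field", "matrix"))
}
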