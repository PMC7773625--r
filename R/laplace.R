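#' Cotangent-weight Laplacian of a surface mesh
#'
#' Standard piecewise-linear FEM stiffness matrix for the Laplace operator
#' on a triangulated surface (cotangent weights, no mass lumping). Negative
#' weights from obtuse triangles are kept.
#'
#' @param mesh a [surface_mesh].
#' @param triangles optional subset of triangle indices (sub-mesh assembly).
#' @return sparse symmetric N x N `Matrix::dgCMatrix` (rows/cols indexed by
#'   mesh vertex, zero rows for vertices outside the sub-mesh).
#' @export
cotan_laplacian <- function(mesh, triangles = NULL) {
  tr <- mesh$triangles
  if (!is.null(triangles)) tr <- tr[triangles, , drop = FALSE]
  v <- mesh$vertices
  i1 <- tr[, 1]; i2 <- tr[, 2]; i3 <- tr[, 3]
  p1 <- v[i1, , drop = FALSE]; p2 <- v[i2, , drop = FALSE]
  p3 <- v[i3, , drop = FALSE]
  cot_at <- function(a, b, c) {
    # cotangent of angle at vertex a (between edges a->b, a->c)
    u <- b - a; w <- c - a
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    rowSums(u * w) / sqrt(rowSums(cr^2))
  }
  c1 <- cot_at(p1, p2, p3)  # opposite edge (2,3)
  c2 <- cot_at(p2, p3, p1)  # opposite edge (3,1)
  c3 <- cot_at(p3, p1, p2)  # opposite edge (1,2)
  ii <- c(i2, i3, i3, i1, i1, i2)
  jj <- c(i3, i2, i1, i3, i2, i1)
  xx <- 0.5 * c(c1, c1, c2, c2, c3, c3)
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = -xx,
                            dims = c(nrow(v), nrow(v)))
  d <- -Matrix::rowSums(W)
  W + Matrix::Diagonal(nrow(v), d)
}

#' Solve the Laplace equation with Dirichlet boundary conditions
#'
#' Discrete harmonic interpolation on (a sub-mesh of) a surface: the
#' cotangent-FEM Laplace system is reduced over the free vertices and solved
#' sparsely; fixed vertices carry their prescribed values exactly.
#'
#' Mean-value constraints (e.g. pinning a rim's centroid to an atlas
#' coordinate) are imposed exactly through Lagrange multipliers on the
#' reduced system: each constraint forces the average of the field over a
#' node set while leaving the per-node values free, so the field stays as
#' smooth as the constraint allows.
#'
#' @param mesh a [surface_mesh].
#' @param bc data frame / list with `node` (vertex indices) and `value`.
#' @param triangles optional triangle subset defining the solve region.
#' @param dense solve the reduced system densely (reference path for
#'   cross-checks; only sensible for small meshes).
#' @param mean_constraints optional list of `list(nodes =, value =)`
#'   entries: the solution's mean over `nodes` equals `value`.
#' @return numeric vector over all mesh vertices; vertices outside the solve
#'   region are `NA`. Attribute `residual` holds the relative residual of
#'   the reduced system.
#' @export
solve_laplace <- function(mesh, bc, triangles = NULL, dense = FALSE,
                          mean_constraints = NULL) {
  bc <- as.data.frame(bc)
  if (nrow(bc) == 0L) stop("empty boundary condition set")
  if (anyDuplicated(bc$node)) {
    dup <- bc$node[duplicated(bc$node)]
    agree <- all(tapply(bc$value, bc$node, function(x) diff(range(x)) == 0))
    if (!agree) stop("conflicting Dirichlet values at node(s) ",
                     paste(utils::head(unique(dup)), collapse = ", "))
    bc <- bc[!duplicated(bc$node), ]
  }
  tr <- mesh$triangles
  if (!is.null(triangles)) tr <- tr[triangles, , drop = FALSE]
  region_vertices <- sort(unique(as.integer(tr)))
  if (!all(bc$node %in% region_vertices))
    stop("boundary condition node outside the solve region")

  # every connected component of the region must carry a bc node
  g <- igraph::graph_from_edgelist(
    cbind(c(tr[, 1], tr[, 2], tr[, 3]), c(tr[, 2], tr[, 3], tr[, 1])),
    directed = FALSE)
  comp <- igraph::components(g)
  comp_ids <- comp$membership[region_vertices]
  with_bc <- unique(comp$membership[bc$node])
  orphan <- setdiff(unique(comp_ids), with_bc)
  if (length(orphan))
    stop("solve region has ", length(orphan),
         " connected component(s) without any boundary condition")

  L <- cotan_laplacian(mesh, triangles)
  n <- nrow(mesh$vertices)
  x <- rep(NA_real_, n)
  x[bc$node] <- bc$value
  free <- setdiff(region_vertices, bc$node)
  if (length(free)) {
    Lff <- L[free, free, drop = FALSE]
    rhs <- as.numeric(-L[free, bc$node, drop = FALSE] %*% bc$value)
    if (length(mean_constraints)) {
      nc <- length(mean_constraints)
      Ci <- integer(0); Cj <- integer(0); Cx <- numeric(0)
      bvec <- numeric(nc)
      for (k in seq_len(nc)) {
        mc <- mean_constraints[[k]]
        pos <- match(mc$nodes, free)
        if (anyNA(pos))
          stop("mean-constraint node outside the free set")
        Ci <- c(Ci, rep(k, length(pos))); Cj <- c(Cj, pos)
        Cx <- c(Cx, rep(1 / length(pos), length(pos)))
        bvec[k] <- mc$value
      }
      C <- Matrix::sparseMatrix(i = Ci, j = Cj, x = Cx,
                                dims = c(nc, length(free)))
      A <- rbind(cbind(Lff, Matrix::t(C)),
                 cbind(C, Matrix::Matrix(0, nc, nc)))
      rhs2 <- c(rhs, bvec)
      sol <- as.numeric(Matrix::solve(A, rhs2))
      xf <- sol[seq_along(free)]
      res <- sqrt(sum((as.numeric(A %*% sol) - rhs2)^2))
      den <- sqrt(sum(rhs2^2))
    } else {
      xf <- if (dense) {
        solve(as.matrix(Lff), rhs)
      } else {
        as.numeric(Matrix::solve(Lff, rhs))
      }
      res <- sqrt(sum((as.numeric(Lff %*% xf) - rhs)^2))
      den <- sqrt(sum(rhs^2))
    }
    rel <- if (den > 0) res / den else res
    if (rel > 1e-10)
      warning("Laplace solve residual above tolerance: ", signif(rel, 3))
    x[free] <- xf
    attr(x, "residual") <- rel
  } else {
    attr(x, "residual") <- 0
  }
  x
}
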