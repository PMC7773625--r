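test_that("surface_mesh validates its inputs", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  m <- surface_mesh(v, rbind(c(1, 2, 3)), orient = FALSE)
  expect_equal(nrow(m$vertices), 3)
  expect_error(surface_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(surface_mesh(v, rbind(c(1, 2, 2))), "degenerate")
  expect_error(surface_mesh(v[, 1:2], rbind(c(1, 2, 3))), "N x 3")
})

test_that("carp i/o round-trips losslessly and rejects bad cells", {
  td <- withr::local_tempdir()
  # smallest valid mesh: a single triangle
  writeLines(c("3", "0 0 0", "1.25 0 0", "0 2.5 0"),
             file.path(td, "t.pts"))
  writeLines(c("1", "Tr 0 1 2 7"), file.path(td, "t.elem"))
  r <- read_mesh(file.path(td, "t"), "carp")
  expect_equal(nrow(r$mesh$vertices), 3)
  expect_equal(nrow(r$mesh$triangles), 1)

  case <- la_coarse()
  write_mesh(case$mesh, file.path(td, "la"), "carp", fibres = case$fibres)
  back <- read_mesh(file.path(td, "la"), "carp")
  expect_identical(back$mesh$vertices, case$mesh$vertices)
  expect_identical(back$mesh$triangles, case$mesh$triangles)
  expect_identical(unclass(back$fibres)[, ], unclass(case$fibres)[, ])

  writeLines(c("1", "Qd 0 1 2 3 1"), file.path(td, "t.elem"))
  expect_error(read_mesh(file.path(td, "t"), "carp"), "Qd")
})

test_that("vtk i/o round-trips mesh, fibres and point data", {
  td <- withr::local_tempdir()
  case <- la_coarse()
  write_mesh(case$mesh, file.path(td, "la.vtk"), "vtk",
             fibres = case$fibres,
             point_data = list(alpha = case$uac$alpha))
  back <- read_mesh(file.path(td, "la.vtk"), "vtk")
  expect_lt(max(abs(back$mesh$vertices - case$mesh$vertices)), 1e-6)
  expect_identical(back$mesh$triangles, case$mesh$triangles)
  expect_lt(max(abs(unclass(back$fibres) - unclass(case$fibres))), 1e-6)
  expect_lt(max(abs(back$point_data$alpha - case$uac$alpha)), 1e-6)
})

test_that("rim detection finds and labels boundary loops", {
  ann <- make_annulus()
  loops <- detect_rims(ann)
  expect_length(loops, 2)
  # loops partition the boundary edges
  be <- boundary_edges(ann)
  expect_equal(sort(unique(as.integer(be))),
               sort(unlist(loops, use.names = FALSE)))
  # labelled via seeds
  named <- detect_rims(ann, seeds = list(inner = c(0, 0, 0),
                                         outer = c(20, 0, 0)))
  expect_setequal(names(named), c("inner", "outer"))
  expect_lt(max(sqrt(rowSums(ann$vertices[named$inner, ]^2))), 7)

  # closed surface has no rims
  ico <- fibreatlas:::icosphere(2)
  sphere <- surface_mesh(ico$vertices, ico$triangles, orient = FALSE)
  expect_error(detect_rims(sphere), "no boundary")
})

test_that("synthetic LA shell exposes its five labelled rims", {
  case <- la_coarse()
  expect_setequal(names(case$mesh$rim_labels),
                  c("MV", "LSPV", "LIPV", "RSPV", "RIPV"))
})

test_that("geodesic paths match a brute-force shortest-path oracle", {
  mesh <- make_sheet(6, 3, 1)
  # independent oracle: Floyd-Warshall on the dense edge-length matrix
  n <- nrow(mesh$vertices)
  D <- matrix(Inf, n, n); diag(D) <- 0
  et <- fibreatlas:::edge_counts(mesh)
  w <- sqrt(rowSums((mesh$vertices[et$a, ] - mesh$vertices[et$b, ])^2))
  for (k in seq_len(nrow(et))) {
    D[et$a[k], et$b[k]] <- w[k]; D[et$b[k], et$a[k]] <- w[k]
  }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  v_from <- 1
  v_to <- n
  p <- geodesic_path(mesh, v_from, v_to)
  plen <- sum(sqrt(rowSums(diff(mesh$vertices[p, ])^2)))
  expect_equal(plen, D[v_from, v_to], tolerance = 1e-12)
  # path length >= straight-line distance
  expect_gte(plen, sqrt(sum((mesh$vertices[v_to, ] -
                               mesh$vertices[v_from, ])^2)))
  # start == end degenerates to one vertex
  expect_identical(geodesic_path(mesh, 5, 5), 5)
})

test_that("geodesic paths detour around forbidden bands", {
  mesh <- make_sheet(6, 6, 1)
  v <- mesh$vertices
  # forbid a vertical wall with one gap at the top
  wall <- which(abs(v[, 1] - 3) < 1e-9 & v[, 2] < 5.5)
  from <- which(v[, 1] == 0 & v[, 2] == 3)
  to <- which(v[, 1] == 6 & v[, 2] == 3)
  p0 <- geodesic_path(mesh, from, to)
  p1 <- geodesic_path(mesh, from, to, forbidden = wall)
  expect_false(any(p1 %in% wall))
  len <- function(p) sum(sqrt(rowSums(diff(v[p, , drop = FALSE])^2)))
  expect_gt(len(p1), len(p0))
  # fully blocking wall disconnects
  allwall <- which(abs(v[, 1] - 3) < 1e-9)
  expect_error(geodesic_path(mesh, from, to, forbidden = allwall),
               "disconnected")
})

test_that("barycentric location reproduces exact weights and snaps", {
  v2 <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  tri <- rbind(c(1L, 2L, 3L), c(2L, 4L, 3L))
  # centroid of triangle 1
  r <- barycentric_locate(rbind(colMeans(v2[1:3, ])), v2, tri)
  expect_equal(as.numeric(r$weights), rep(1 / 3, 3), tolerance = 1e-12)
  # a vertex gets weight 1 on itself
  r2 <- barycentric_locate(rbind(c(2, 2)), v2, tri)
  w <- r2$weights[1, ]
  expect_equal(sort(w), c(0, 0, 1), tolerance = 1e-12)
  # random interior points reconstruct their position
  set.seed(1)
  q <- cbind(runif(50, 0, 2), runif(50, 0, 2))
  r3 <- barycentric_locate(q, v2, tri)
  rec <- sapply(1:2, function(c)
    rowSums(matrix(v2[tri[r3$triangle, ], c], ncol = 3) * r3$weights))
  expect_lt(max(abs(rec - q)), 1e-9)
  # outside point snaps to the nearest triangle with clamped weights
  r4 <- barycentric_locate(rbind(c(3, 1)), v2, tri)
  expect_true(r4$snapped[1])
  expect_equal(r4$distance[1], 1, tolerance = 1e-9)
  expect_true(all(r4$weights >= -1e-9))
})

test_that("mesh orientation is consistent with outward normals", {
  case <- la_coarse()
  # no directed edge repeats => consistent winding
  tr <- case$mesh$triangles
  de <- paste(c(tr[, 1], tr[, 2], tr[, 3]), c(tr[, 2], tr[, 3], tr[, 1]))
  expect_equal(anyDuplicated(de), 0L)
  # normals point away from the centroid on average
  nrm <- triangle_normals(case$mesh)
  cen <- triangle_centroids(case$mesh)
  ctr <- colMeans(case$mesh$vertices)
  expect_gt(mean(rowSums(nrm * sweep(cen, 2, ctr)) > 0), 0.99)
})
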