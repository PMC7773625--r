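test_that("laplace solve matches the linear closed form on a strip", {
  sh <- make_sheet(10, 4, 1)
  x <- sh$vertices[, 1]
  bc <- data.frame(node = c(which(x < 1e-9), which(x > 10 - 1e-9)),
                   value = rep(c(0, 1), c(sum(x < 1e-9),
                                          sum(x > 10 - 1e-9))))
  u <- solve_laplace(sh, bc)
  expect_lt(max(abs(u - x / 10)), 1e-8)
  expect_lt(attr(u, "residual"), 1e-10)
})

test_that("sparse and dense solvers agree", {
  sh <- make_sheet(8, 8, 1)
  v <- sh$vertices
  edge <- which(v[, 1] < 1e-9 | v[, 1] > 8 - 1e-9)
  bc <- data.frame(node = edge, value = as.numeric(v[edge, 1] > 4))
  u_sparse <- solve_laplace(sh, bc)
  u_dense <- solve_laplace(sh, bc, dense = TRUE)
  expect_lt(max(abs(u_sparse - u_dense)), 1e-9)
})

test_that("constant boundary data yields a constant field", {
  sh <- make_sheet(5, 5, 1)
  edge <- which(sh$vertices[, 1] < 1e-9)
  u <- solve_laplace(sh, data.frame(node = edge, value = 0.5))
  expect_lt(max(abs(u - 0.5)), 1e-10)
})

test_that("solve errors on empty bc and orphan components", {
  sh <- make_sheet(5, 5, 1)
  expect_error(solve_laplace(sh, data.frame(node = integer(),
                                            value = numeric())), "empty")
  # two disjoint triangle islands, bc only on one
  two <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                            c(5, 0, 0), c(6, 0, 0), c(5, 1, 0)),
                      rbind(c(1L, 2L, 3L), c(4L, 5L, 6L)), orient = FALSE)
  expect_error(solve_laplace(two, data.frame(node = 1:2, value = 0:1)),
               "component")
})

test_that("mean-value constraints are honoured exactly", {
  sh <- make_sheet(10, 5, 1)
  x <- sh$vertices[, 1]
  bc <- data.frame(node = c(which(x < 1e-9), which(x > 10 - 1e-9)),
                   value = rep(c(0, 1), c(sum(x < 1e-9),
                                          sum(x > 10 - 1e-9))))
  mid <- which(abs(x - 5) < 0.6 & abs(sh$vertices[, 2] - 2.5) < 1.1)
  u <- solve_laplace(sh, bc, mean_constraints =
                       list(list(nodes = mid, value = 0.9)))
  expect_equal(mean(u[mid]), 0.9, tolerance = 1e-9)
})

test_that("LA coordinates satisfy the construction contract", {
  case <- la_coarse()
  uac <- case$uac
  mesh <- case$mesh
  expect_true(all(uac$alpha >= 0 & uac$alpha <= 1))
  expect_true(all(uac$beta >= 0 & uac$beta <= 1))
  # harmonicity residuals
  expect_true(all(uac$residuals < 1e-10))
  # the roof line carries beta = 0.5 and the cut has exactly 2 sides
  bcs <- fixture("la_coarse_bcs", function() {
    an <- make_anatomy(anatomy_spec("LA", seed = 1, edge_length = 2))
    build_la_bcs(an$endo, an$landmarks$mv_lateral)
  })
  expect_equal(length(unique(bcs$partition)), 2L)
  expect_true(all(abs(uac$beta[bcs$paths$roof] - 0.5) < 1e-9))
  # posterior MV arc at beta 0, anterior at 1 (excluding shared endpoints)
  inner <- function(a) setdiff(a, c(a[1], a[length(a)]))
  expect_true(all(uac$beta[inner(bcs$paths$mv_posterior)] < 1e-9))
  expect_true(all(uac$beta[inner(bcs$paths$mv_anterior)] > 1 - 1e-9))
})

test_that("PV rims land inside their atlas boxes", {
  case <- la_coarse()
  at <- atlas_coordinates("LA")
  for (i in seq_len(nrow(at))) {
    lp <- case$mesh$rim_labels[[at$structure[i]]]
    expect_lt(abs(mean(case$uac$alpha[lp]) - at$alpha[i]), at$box[i])
    expect_lt(abs(mean(case$uac$beta[lp]) - at$beta[i]), at$box[i])
  }
})

test_that("pinning follows rim labels, not geometry", {
  an <- make_anatomy(anatomy_spec("LA", seed = 1, edge_length = 2))
  mesh <- an$endo
  swapped <- mesh
  swapped$rim_labels$RSPV <- mesh$rim_labels$LSPV
  swapped$rim_labels$LSPV <- mesh$rim_labels$RSPV
  uac <- compute_uac(swapped, build_la_bcs(swapped, an$landmarks$mv_lateral))
  at <- atlas_coordinates("LA")
  # the loop labelled RSPV (geometrically the left superior vein) is pinned
  # at the RSPV atlas location
  lp <- swapped$rim_labels$RSPV
  expect_lt(abs(mean(uac$alpha[lp]) - at$alpha[at$structure == "RSPV"]),
            0.1)
})

test_that("the LA flattening is injective off the seam", {
  for (case in list(la_coarse(), la_fine())) {
    n_flip <- count_flipped_triangles(case$mesh, case$uac)
    expect_equal(as.integer(n_flip), 0L)
  }
})

test_that("coordinates are stable under mesh refinement", {
  coarse <- la_coarse()
  fine <- la_fine()
  # interpolate the fine coordinates at the coarse vertices: nearest fine
  # element, 3D barycentric weights of the projected point
  vc <- coarse$mesh$vertices
  cen <- triangle_centroids(fine$mesh)
  nn <- fibreatlas:::cpp_nearest_3d(vc[, 1], vc[, 2], vc[, 3],
                                    cen[, 1], cen[, 2], cen[, 3])
  tr <- fine$mesh$triangles
  interp_at <- function(corner) {
    vals <- numeric(nrow(vc))
    for (i in seq_len(nrow(vc))) {
      t <- nn[i]
      p <- fine$mesh$vertices[tr[t, ], , drop = FALSE]
      A <- cbind(p[2, ] - p[1, ], p[3, ] - p[1, ])
      w23 <- qr.solve(A, vc[i, ] - p[1, ])
      w <- pmax(0, c(1 - sum(w23), w23)); w <- w / sum(w)
      vals[i] <- sum(corner[t, ] * w)
    }
    vals
  }
  fa <- interp_at(fine$uac$alpha_corner)
  fb <- interp_at(fine$uac$beta_corner)
  # compare interior vertices: near the Dirichlet support (cut chain and rims)
  # the boundary-condition geometry itself moves by up to one edge length
  # between resolutions, which is discretisation of the recipe, not of the
  # solution
  bcs <- fixture("la_coarse_bcs", function() {
    an <- make_anatomy(anatomy_spec("LA", seed = 1, edge_length = 2))
    build_la_bcs(an$endo, an$landmarks$mv_lateral)
  })
  bc_nodes <- unique(c(unlist(bcs$paths), coarse$uac$seam,
                       unlist(coarse$mesh$rim_labels)))
  ec <- fibreatlas:::edge_counts(coarse$mesh)
  near <- logical(nrow(vc)); near[bc_nodes] <- TRUE
  for (ring in 1:2) {
    hit <- near[ec$a] | near[ec$b]
    near[ec$a[hit]] <- TRUE; near[ec$b[hit]] <- TRUE
  }
  svf <- logical(nrow(fine$mesh$vertices)); svf[fine$uac$seam] <- TRUE
  fine_seam_tri <- rowSums(matrix(svf[tr], ncol = 3)) > 0
  keep <- !near & !fine_seam_tri[nn]
  expect_lt(stats::quantile(abs(coarse$uac$alpha[keep] - fa[keep]), 0.99),
            0.02)
  expect_lt(stats::quantile(abs(coarse$uac$beta[keep] - fb[keep]), 0.99),
            0.02)
})

test_that("RA coordinates mirror the LA contract", {
  case <- ra_coarse()
  uac <- case$uac
  expect_true(all(uac$alpha >= 0 & uac$alpha <= 1))
  expect_true(all(uac$beta >= 0 & uac$beta <= 1))
  expect_equal(as.integer(count_flipped_triangles(case$mesh, uac)), 0L)
  at <- atlas_coordinates("RA")
  for (i in seq_len(nrow(at))) {
    lp <- case$mesh$rim_labels[[at$structure[i]]]
    expect_lt(abs(mean(uac$alpha[lp]) - at$alpha[i]), at$box[i])
    expect_lt(abs(mean(uac$beta[lp]) - at$beta[i]), at$box[i])
  }
  # beta runs from the IVC side to the SVC side
  expect_lt(mean(uac$beta[case$mesh$rim_labels$IVC]),
            mean(uac$beta[case$mesh$rim_labels$SVC]))
  expect_error(build_ra_bcs(case$mesh[c("vertices", "triangles")],
                            list()), NULL)
})

test_that("missing rim labels are reported", {
  an <- make_anatomy(anatomy_spec("LA", seed = 1, edge_length = 2))
  mesh <- an$endo
  mesh$rim_labels$LSPV <- NULL
  expect_error(build_la_bcs(mesh, an$landmarks$mv_lateral), "LSPV")
})

test_that("coordinate computation is deterministic", {
  an <- make_anatomy(anatomy_spec("LA", seed = 4, edge_length = 2))
  u1 <- compute_uac(an$endo, build_la_bcs(an$endo, an$landmarks$mv_lateral))
  u2 <- compute_uac(an$endo, build_la_bcs(an$endo, an$landmarks$mv_lateral))
  expect_identical(u1$alpha, u2$alpha)
  expect_identical(u1$beta, u2$beta)
})
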