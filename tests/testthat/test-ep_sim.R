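test_that("element conductivity tensors have the stated spectrum", {
  f <- c(1, 0, 0); n <- c(0, 0, 1)
  Tn <- element_conductivity_tensor(f, 0.4, 0.1, n)
  expect_equal(Tn, t(Tn))
  ev <- eigen(Tn, symmetric = TRUE)$values
  expect_equal(sort(ev), c(0, 0.1, 0.4), tolerance = 1e-12)
  # principal axis is the fibre
  expect_equal(as.numeric(Tn %*% f), 0.4 * f, tolerance = 1e-12)
  # in-plane trace
  expect_equal(sum(diag(Tn)), 0.4 + 0.1, tolerance = 1e-12)
  # isotropic when sigma_l = sigma_t
  Ti <- element_conductivity_tensor(c(1, 1, 0) / sqrt(2), 0.2, 0.2, n)
  expect_equal(Ti, 0.2 * (diag(3) - tcrossprod(n)), tolerance = 1e-12)
  expect_error(conductivity_params(0.1, 0.4), "sigma")
})

test_that("an unstimulated tissue stays at rest", {
  sc <- sheet_case(5, 5, 1)
  fib <- fibre_field(sc$mesh, matrix(rep(c(1, 0, 0),
                                         each = nrow(sc$mesh$triangles)),
                                     ncol = 3))
  model <- single_layer_model(sc$mesh, fib)
  tr <- run_monodomain(model, membrane_model(), 1000, dt = 0.1,
                       record_dt = 100)
  expect_lt(max(abs(tr$V)), 1e-4)
})

test_that("the explicit stepper enforces its stability bound", {
  sc <- sheet_case(5, 5, 0.5)
  fib <- fibre_field(sc$mesh, matrix(rep(c(1, 0, 0),
                                         each = nrow(sc$mesh$triangles)),
                                     ncol = 3))
  model <- single_layer_model(sc$mesh, fib)
  expect_error(run_monodomain(model, membrane_model(), 10,
                              dt = 2 * cfl_max_dt(model)), "stability")
})

test_that("cable conduction velocity converges under refinement", {
  mem <- membrane_model()
  cv <- vapply(c(0.4, 0.2, 0.1), function(h)
    planar_wave_cv(conductivity_params(), mem, "fibre", length_mm = 10,
                   width_mm = 0.8, h = h), 0)
  # successive differences shrink (second-order-ish convergence)
  expect_lt(abs(cv[3] - cv[2]), abs(cv[2] - cv[1]))
  expect_lt(abs(cv[3] - cv[2]) / cv[3], 0.05)
})

test_that("activation times follow distance on an isotropic sheet", {
  mesh <- make_sheet(12, 12, 0.4)
  fib <- fibre_field(mesh, matrix(rep(c(1, 0, 0),
                                      each = n_triangles(mesh)), ncol = 3))
  model <- single_layer_model(mesh, fib, conductivity_params(0.2, 0.2))
  mem <- membrane_model()
  dt <- min(0.02, 0.9 * cfl_max_dt(model))
  ctr <- c(6, 6, 0)
  r <- sqrt(rowSums(sweep(mesh$vertices, 2, ctr)^2))
  amp <- 10 * capture_threshold_0d(mem, 2, dt)
  tr <- run_monodomain(model, mem, 60, dt = dt,
                       stimuli = list(list(nodes = which(r < 1),
                                           onset = 0, duration = 2,
                                           amplitude = amp)),
                       record_dt = 0.25)
  lat <- extract_lat(tr)
  # stimulated node activates at about the stimulus onset
  expect_lt(min(lat, na.rm = TRUE), 4)
  band <- r > 2 & r < 5.5 & !is.na(lat)
  fit <- stats::lm(lat[band] ~ r[band])
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("extract_lat flags non-captured nodes", {
  fakes <- list(t = seq(0, 10, by = 0.5),
                V = rbind(rep(0, 21), c(rep(0, 10), rep(1, 11))))
  lat <- extract_lat(fakes, min_amplitude = 0.4)
  expect_true(is.na(lat[1]))
  expect_false(is.na(lat[2]))
  expect_equal(attr(lat, "n_missing"), 1L)
})

test_that("LAT comparison matches a direct recomputation", {
  set.seed(9)
  a <- runif(200, 0, 120)
  b <- a + rnorm(200, 0, 3)
  b[sample(200, 5)] <- NA
  cmp <- compare_lat(a, b)
  ok <- !is.na(b)
  expect_equal(cmp$median_abs_ms, median(abs(b[ok] - a[ok])))
  expect_equal(cmp$max_abs_pct,
               100 * max(abs(b[ok] - a[ok])) / diff(range(a[ok])))
  # self-comparison and uniform shifts
  self <- compare_lat(a, a)
  expect_equal(self$median_abs_ms, 0)
  expect_equal(self$max_abs_pct, 0)
  sh <- compare_lat(a, a + 2.5)
  expect_equal(sh$median_abs_ms, 2.5)
})

test_that("bilayer models couple and decouple as configured", {
  case <- la_coarse()
  mem <- membrane_model()
  single <- single_layer_model(case$mesh, case$fibres)
  b0 <- build_bilayer(case$mesh, case$fibres, case$fibres, kappa_c = 0)
  expect_equal(b0$n, 2L * single$n)
  prot <- pacing_protocol(c(0.75, 0.1), n_beats = 1, cycle_ms = 400,
                          lead_in_ms = 0)
  r_single <- run_lat_protocol(single, mem, prot, case$uac, dt = 0.05)
  r_b0 <- run_lat_protocol(b0, mem, prot, case$uac, dt = 0.05)
  n1 <- b0$n_per_layer
  # decoupled: the stimulated base layer matches the single surface
  expect_lt(max(abs(r_b0$lat[1:n1] - r_single$lat), na.rm = TRUE), 1e-6)
  # strong coupling with identical fibres: sub-ms transmural delay
  b2 <- build_bilayer(case$mesh, case$fibres, case$fibres, kappa_c = 2)
  r_b2 <- run_lat_protocol(b2, mem, prot, case$uac, dt = 0.05)
  d <- abs(r_b2$lat[1:n1] - r_b2$lat[(n1 + 1):(2 * n1)])
  expect_lt(max(d, na.rm = TRUE), 1)
  expect_lt(max(abs(r_b2$lat[1:n1] - r_single$lat), na.rm = TRUE), 1)
})

test_that("the isotropic control field is uniform and tangent", {
  case <- la_coarse()
  f1 <- isotropic_control(case$mesh, seed = 5)
  f2 <- isotropic_control(case$mesh, seed = 5)
  expect_identical(unclass(f1), unclass(f2))
  nrm <- triangle_normals(case$mesh)
  expect_lt(max(abs(rowSums(unclass(f1) * nrm))), 1e-6)
  # theta distribution uniform on [0, pi)
  th <- fibre_to_angle(f1, case$basis, "LA")
  ks <- stats::ks.test(th / pi, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("implicit and explicit stepping agree on a quiet wave", {
  sc <- sheet_case(6, 2, 0.5)
  fib <- fibre_field(sc$mesh, matrix(rep(c(1, 0, 0),
                                         each = nrow(sc$mesh$triangles)),
                                     ncol = 3))
  model <- single_layer_model(sc$mesh, fib)
  mem <- membrane_model()
  stim <- list(list(nodes = which(sc$mesh$vertices[, 1] < 1), onset = 0,
                    duration = 2, amplitude = 0.5))
  t_ex <- run_monodomain(model, mem, 25, dt = 0.01, stimuli = stim,
                         record_dt = 1)
  t_im <- run_monodomain(model, mem, 25, dt = 0.01, stimuli = stim,
                         record_dt = 1, method = "implicit")
  expect_lt(max(abs(t_ex$V - t_im$V)), 0.02)
})
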