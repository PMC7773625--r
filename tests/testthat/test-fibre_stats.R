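test_that("circular mean/std handles the canonical axial cases", {
  r <- circular_mean_std(rep(pi / 4, 5))
  expect_equal(r$mean, pi / 4, tolerance = 1e-12)
  expect_equal(r$sd, 0, tolerance = 1e-12)
  # symmetric about 0 across the wrap
  r2 <- circular_mean_std(c(0.1, pi - 0.1))
  expect_lt(min(r2$mean, pi - r2$mean), 1e-9)
  # antipodal on the doubled circle: perfectly dispersed
  r3 <- circular_mean_std(c(0, pi / 2))
  expect_true(r3$degenerate)
  expect_identical(r3$sd, Inf)
  expect_error(circular_mean_std(numeric()), "empty")
})

test_that("circular mean/std matches the reference implementation", {
  # frozen from scipy.stats circmean/circstd with low = 0, high = pi
  r <- circular_mean_std(c(0.1, 3.0, 0.3, 1.2, 2.9))
  expect_equal(r$mean, 0.117037160838, tolerance = 1e-9)
  expect_equal(r$sd, 0.506144974757, tolerance = 1e-9)
})

test_that("circular mean minimises the circular dispersion", {
  # independent oracle: golden-section-free brute force over a fine grid,
  # minimising the circular analogue of squared deviation
  set.seed(7)
  for (i in 1:25) {
    th <- runif(sample(2:12, 1), 0, pi)
    r <- circular_mean_std(th)
    if (r$degenerate) next
    obj <- function(m) mean(1 - cos(2 * (th - m)))
    grid <- seq(0, pi, length.out = 4001)[-4001]
    m0 <- grid[which.min(vapply(grid, obj, 0))]
    opt <- stats::optimize(obj, c(m0 - 0.01, m0 + 0.01))$minimum %% pi
    expect_lt(min(abs(r$mean - opt), pi - abs(r$mean - opt)), 1e-6)
  }
})

test_that("atlas averaging is symmetric and recovers duplicates", {
  th <- runif(50, 0, pi)
  atl <- average_fibre_field(list(th, th))
  expect_lt(max(axial_diff_deg(atl$mean, th)), 1e-9)
  expect_lt(max(atl$sd), 1e-6)
  th2 <- runif(50, 0, pi); th3 <- runif(50, 0, pi)
  a1 <- average_fibre_field(list(th, th2, th3))
  a2 <- average_fibre_field(list(th3, th, th2))
  expect_equal(a1$mean, a2$mean, tolerance = 1e-12)
  expect_equal(a1$sd, a2$sd, tolerance = 1e-12)
  expect_error(average_fibre_field(list(th, th2[-1])), "differing")
  expect_error(average_fibre_field(list(th)), "at least 2")
})

test_that("angle difference implements the folded-acute-angle formula", {
  sc <- sheet_case(4, 4, 2)
  m <- nrow(sc$mesh$triangles)
  mk <- function(th) matrix(rep(c(cos(th), sin(th), 0), each = m), ncol = 3)
  expect_lt(max(angle_difference(mk(0.4), mk(0.4))), 1e-12)
  expect_equal(max(abs(angle_difference(mk(0), mk(pi / 2)) - pi / 2)), 0,
               tolerance = 1e-9)
  # 3pi/4 apart folds back to pi/4
  expect_equal(max(abs(angle_difference(mk(0), mk(3 * pi / 4)) - pi / 4)),
               0, tolerance = 1e-9)
  # symmetric and sense-free
  E1 <- angle_difference(mk(0.2), mk(1.9))
  E2 <- angle_difference(mk(1.9), mk(0.2))
  E3 <- angle_difference(-mk(0.2), mk(1.9))
  expect_equal(E1, E2, tolerance = 1e-12)
  expect_equal(E1, E3, tolerance = 1e-12)
  expect_error(angle_difference(0 * mk(0), mk(1)), "zero")
})

test_that("the below-threshold proportion obeys its threshold cases", {
  E <- rep(pi / 6, 100)
  expect_equal(q_metric(E), 0)           # pi/6 > pi/8
  expect_equal(q_metric(rep(pi / 16, 100)), 1)
  expect_equal(q_metric(rep(0, 10)), 1)  # field against itself
  # monotone non-increasing in the threshold
  set.seed(2)
  E2 <- runif(500, 0, pi / 2)
  qs <- sapply(seq(0.05, 1.5, by = 0.05), function(t) q_metric(E2, threshold = t))
  expect_true(all(diff(qs) >= 0))
  expect_error(q_metric(E2, integer(0)), "empty")
})

test_that("angle classes split at pi/4 and 5pi/6 with closed reference class", {
  expect_equal(unname(angle_class_percentages(rep(0, 10))), c(100, 0))
  expect_equal(unname(angle_class_percentages(rep(pi / 2, 10))), c(0, 100))
  # boundary values fall in the reference class
  expect_equal(unname(angle_class_percentages(c(pi / 4, 5 * pi / 6))),
               c(100, 0))
  # uniform angles: orthogonal-class fraction = (5pi/6 - pi/4) / pi
  set.seed(3)
  th <- runif(1e6, 0, pi)
  p <- angle_class_percentages(th)
  expect_equal(unname(p[2]), 100 * (5 * pi / 6 - pi / 4) / pi,
               tolerance = 0.005)
})

test_that("region masks partition the elements under the default spec", {
  case <- la_coarse()
  masks <- region_masks(case$uac, default_region_spec("LA"), case$mesh)
  counts <- lengths(masks)
  expect_equal(sum(counts), n_triangles(case$mesh))
  expect_equal(anyDuplicated(unlist(masks)), 0L)
  expect_true(all(c("posterior_wall", "roof", "anterior_wall", "PV",
                    "LAA") %in% names(masks)))
  # an empty box yields an empty mask
  spec0 <- data.frame(region = "nowhere", a0 = 2, a1 = 3, b0 = 2, b1 = 3,
                      priority = 1)
  expect_length(region_masks(case$uac, spec0, case$mesh)$nowhere, 0)
})

test_that("comparison reports aggregate regional metrics", {
  case <- la_coarse()
  b <- la_coarse_b()
  mapped <- map_fibres(list(mesh = b$mesh, uac = b$uac, theta = b$theta),
                       list(mesh = case$mesh, uac = case$uac))
  masks <- region_masks(case$uac, default_region_spec("LA"), case$mesh)
  rep_ <- comparison_report(case$fibres, mapped, case$theta,
                            attr(mapped, "theta"), masks, "LA")
  expect_true("all" %in% rep_$region)
  expect_true(all(rep_$q_pi8 >= 0 & rep_$q_pi8 <= 1))
  expect_true(all(rep_$median_E_deg >= 0 & rep_$median_E_deg <= 90))
})
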