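#' Circular mean and standard deviation for axial (period-pi) data
#'
#' Directional statistics on the doubled angles, respecting fibre
#' orientation while disregarding fibre sense: with `u = 2*pi/period`,
#' the mean is `atan2(mean sin(u*theta), mean cos(u*theta)) / u` wrapped
#' into `[0, period)`, and the standard deviation is
#' `sqrt(-2 log Rbar) / u` where `Rbar` is the mean resultant length.
#' Perfectly dispersed input (`Rbar = 0`) returns mean 0 by convention and
#' an infinite standard deviation, flagged via `degenerate`.
#'
#' @param angles numeric vector (radians).
#' @param period wrap period (default `pi` for axial fibre data).
#' @return list with `mean`, `sd`, `rbar`, `degenerate`.
#' @export
circular_mean_std <- function(angles, period = pi) {
  if (!length(angles)) stop("empty angle set")
  u <- 2 * pi / period
  C <- mean(cos(u * angles)); S <- mean(sin(u * angles))
  rbar <- sqrt(C^2 + S^2)
  if (rbar < 1e-12)
    return(list(mean = 0, sd = Inf, rbar = 0, degenerate = TRUE))
  mu <- (atan2(S, C) / u) %% period
  s <- sqrt(pmax(0, -2 * log(rbar))) / u
  list(mean = mu, sd = s, rbar = rbar, degenerate = FALSE)
}

#' Average co-registered angle fields into an atlas field
#'
#' Per-element circular mean and circular standard deviation (period pi)
#' over two or more angle fields registered to the same mesh — the atlas
#' construction step. Also returns the probability-density histogram of
#' the standard-deviation field.
#'
#' @param angle_fields list of numeric per-element angle vectors, or a
#'   matrix with one column per field.
#' @param breaks histogram breaks for the sd density (radians).
#' @return an `atlas_field`: list with `mean`, `sd` (per element),
#'   `rbar`, `n_fields`, `sd_hist`.
#' @export
average_fibre_field <- function(angle_fields,
                                breaks = seq(0, 1.6, by = 0.05)) {
  if (is.list(angle_fields)) {
    len <- vapply(angle_fields, length, 1L)
    if (length(unique(len)) != 1L)
      stop("angle fields have differing element counts")
    A <- do.call(cbind, angle_fields)
  } else A <- as.matrix(angle_fields)
  if (ncol(A) < 2L) stop("need at least 2 fields to average")
  C <- rowMeans(cos(2 * A)); S <- rowMeans(sin(2 * A))
  rbar <- sqrt(C^2 + S^2)
  mu <- (0.5 * atan2(S, C)) %% pi
  mu[rbar < 1e-12] <- 0
  s <- ifelse(rbar < 1e-12, Inf, sqrt(pmax(0, -2 * log(rbar))) / 2)
  h <- graphics::hist(pmin(s, max(breaks)), breaks = breaks, plot = FALSE)
  structure(list(mean = mu, sd = s, rbar = rbar, n_fields = ncol(A),
                 sd_hist = data.frame(mid = h$mids, density = h$density)),
            class = "atlas_field")
}

#' Acute angle between two fibre fields
#'
#' Per-element angle `E = arccos(|F1 . F2| / (|F1| |F2|))` folded into
#' `[0, pi/2]`: angles above pi/2 are corrected as `pi - E`, so the metric
#' is symmetric and invariant to the sense of either field.
#'
#' @param f1,f2 [fibre_field]s (or M x 3 matrices) on the same mesh.
#' @return numeric vector of angle differences in `[0, pi/2]` (radians).
#' @export
angle_difference <- function(f1, f2) {
  a <- unclass(f1); b <- unclass(f2)
  if (!all(dim(a) == dim(b))) stop("fields have different sizes")
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  if (any(na < 1e-12) || any(nb < 1e-12)) stop("zero-length fibre vector")
  E <- acos(pmin(1, abs(rowSums(a * b)) / (na * nb)))
  pmin(E, pi / 2)
}

#' Proportion of angle differences below a threshold
#'
#' The agreement metric for fibre-field comparison: the fraction of masked
#' elements whose angle difference is strictly below the threshold
#' (default pi/8). Per-element counts, not area-weighted.
#'
#' @param E angle-difference field (radians, from [angle_difference]).
#' @param mask logical or integer element selection (default all).
#' @param threshold radians (default `pi/8`).
#' @return scalar proportion in `[0, 1]`.
#' @export
q_metric <- function(E, mask = NULL, threshold = pi / 8) {
  if (is.null(mask)) mask <- seq_along(E)
  x <- E[mask]
  if (!length(x)) stop("empty mask")
  mean(x < threshold)
}

#' Percentages of the two principal fibre-angle classes
#'
#' Splits an angle histogram into the class aligned with the chamber's
#' reference axis (`theta < pi/4` or `theta > 5*pi/6`; lateral-septal for
#' the LA, IVC-SVC for the RA) and the orthogonal class
#' (`pi/4 < theta < 5*pi/6`; posterior-anterior for the LA, lateral-septal
#' for the RA). Boundary values fall in the reference class (closed
#' complement).
#'
#' @param theta per-element angles in `[0, pi)`.
#' @param mask element selection (default all).
#' @param chamber `"LA"` or `"RA"` (names the classes only).
#' @return named numeric: percentages `class_ref` and `class_orth`,
#'   summing to 100.
#' @export
angle_class_percentages <- function(theta, mask = NULL, chamber = "LA") {
  if (is.null(mask)) mask <- seq_along(theta)
  x <- theta[mask]
  if (!length(x)) stop("empty mask")
  orth <- x > pi / 4 & x < 5 * pi / 6
  p <- 100 * mean(orth)
  out <- c(100 - p, p)
  names(out) <- if (identical(chamber, "RA"))
    c("ivc_svc", "lateral_septal") else c("lateral_septal",
                                          "posterior_anterior")
  out
}

#' Default named coordinate-space regions per chamber
#'
#' Axis-aligned boxes in the unit coordinate square naming the anatomical
#' wall regions plus the vessel/appendage boxes. Wall regions partition
#' the square; vessel/appendage boxes sit on top with higher priority (an
#' element in such a box belongs to it, not to the underlying wall).
#' Editable plain data.
#'
#' @param chamber `"LA"` or `"RA"`.
#' @param atlas atlas coordinate table used to place the vessel boxes.
#' @return data frame with `region`, `a0`, `a1`, `b0`, `b1`, `priority`.
#' @export
default_region_spec <- function(chamber = c("LA", "RA"),
                                atlas = atlas_coordinates(chamber)) {
  chamber <- match.arg(chamber)
  if (chamber == "LA") {
    walls <- data.frame(
      region = c("posterior_wall", "roof", "anterior_wall"),
      a0 = 0, a1 = 1, b0 = c(0, 0.35, 0.65), b1 = c(0.35, 0.65, 1),
      priority = 1)
    pv <- data.frame(region = "PV",
                     a0 = atlas$alpha - atlas$box,
                     a1 = atlas$alpha + atlas$box,
                     b0 = atlas$beta - atlas$box,
                     b1 = atlas$beta + atlas$box, priority = 2)
    laa <- data.frame(region = "LAA", a0 = 0.52, a1 = 0.72, b0 = 0.66,
                      b1 = 0.86, priority = 2)
    rbind(walls, pv, laa)
  } else {
    walls <- data.frame(
      region = c("lateral_wall", "roof", "septal_wall"),
      a0 = c(0, 0.35, 0.65), a1 = c(0.35, 0.65, 1), b0 = 0, b1 = 1,
      priority = 1)
    vcav <- atlas[atlas$structure %in% c("IVC", "SVC"), ]
    vc <- data.frame(region = "vena_cavae",
                     a0 = vcav$alpha - vcav$box,
                     a1 = vcav$alpha + vcav$box,
                     b0 = vcav$beta - vcav$box,
                     b1 = vcav$beta + vcav$box, priority = 2)
    csr <- atlas[atlas$structure == "CS", ]
    cs <- data.frame(region = "CS",
                     a0 = csr$alpha - csr$box, a1 = csr$alpha + csr$box,
                     b0 = csr$beta - csr$box, b1 = csr$beta + csr$box,
                     priority = 2)
    raa <- data.frame(region = "RAA", a0 = 0.74, a1 = 0.94, b0 = 0.86,
                      b1 = 1, priority = 2)
    rbind(walls, vc, cs, raa)
  }
}

#' Element masks for named coordinate-space regions
#'
#' An element belongs to a region iff its coordinate centroid lies in the
#' region's box; where boxes overlap, the highest-priority box wins (so
#' vessel boxes carve their elements out of the underlying wall region).
#'
#' @param uac a `uac_field`.
#' @param region_spec data frame as from [default_region_spec].
#' @param mesh a [surface_mesh].
#' @return named list of integer element index vectors.
#' @export
region_masks <- function(uac, region_spec, mesh) {
  eu <- element_uac(mesh, uac)
  m <- nrow(eu)
  best_r <- rep(NA_character_, m)
  best_p <- rep(-Inf, m)
  for (i in seq_len(nrow(region_spec))) {
    r <- region_spec[i, ]
    inb <- eu[, 1] >= r$a0 & eu[, 1] <= r$a1 &
      eu[, 2] >= r$b0 & eu[, 2] <= r$b1
    take <- inb & r$priority > best_p
    best_r[take] <- r$region
    best_p[take] <- r$priority
  }
  out <- lapply(unique(region_spec$region), function(nm) which(best_r == nm))
  names(out) <- unique(region_spec$region)
  out
}

#' Regional fibre-field comparison report
#'
#' Bundles the comparison metrics for two fibre fields over named regions:
#' median angle difference, the below-threshold proportion, and the
#' angle-class percentages of each field.
#'
#' @param f1,f2 [fibre_field]s on the same mesh.
#' @param theta1,theta2 corresponding angle fields.
#' @param masks named element masks from [region_masks].
#' @param chamber `"LA"` or `"RA"`.
#' @return data frame, one row per region (plus `"all"`).
#' @export
comparison_report <- function(f1, f2, theta1, theta2, masks, chamber = "LA") {
  E <- angle_difference(f1, f2)
  masks <- c(list(all = seq_along(E)), masks)
  rows <- lapply(names(masks), function(nm) {
    mk <- masks[[nm]]
    if (!length(mk)) return(NULL)
    cls1 <- angle_class_percentages(theta1, mk, chamber)
    cls2 <- angle_class_percentages(theta2, mk, chamber)
    data.frame(region = nm, n = length(mk),
               median_E_deg = stats::median(E[mk]) * 180 / pi,
               q_pi8 = q_metric(E, mk),
               f1_class_orth_pct = cls1[2], f2_class_orth_pct = cls2[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
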