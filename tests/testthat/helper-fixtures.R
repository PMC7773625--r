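# Session-cached fixtures: the synthetic cases are deterministic, so they
# are built once and shared across test files.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

la_coarse <- function() fixture("la_coarse", function()
  synth_case("LA", seed = 1, edge_length = 2))
la_coarse_b <- function() fixture("la_coarse_b", function()
  synth_case("LA", seed = 2, edge_length = 2))
la_fine <- function() fixture("la_fine", function()
  synth_case("LA", seed = 1, edge_length = 1))
la_fine_b <- function() fixture("la_fine_b", function()
  synth_case("LA", seed = 2, edge_length = 1))
ra_coarse <- function() fixture("ra_coarse", function()
  synth_case("RA", seed = 1, edge_length = 2))

# A flat sheet with its trivial coordinate field (alpha = x / lx,
# beta = y / ly): the closed-form geometry for basis and streamline tests.
sheet_case <- function(lx = 10, ly = 10, h = 1) {
  mesh <- make_sheet(lx, ly, h)
  alpha <- mesh$vertices[, 1] / lx
  beta <- mesh$vertices[, 2] / ly
  tr <- mesh$triangles
  uac <- structure(list(
    alpha = alpha, beta = beta,
    alpha_corner = matrix(alpha[tr], ncol = 3),
    beta_corner = matrix(beta[tr], ncol = 3),
    partition = rep(1L, nrow(tr)), seam = integer(0),
    chamber = "LA", residuals = numeric(0)), class = "uac_field")
  list(mesh = mesh, uac = uac)
}

# wrapped absolute angle difference for period-pi data, in degrees
axial_diff_deg <- function(a, b) {
  d <- abs(a - b) %% pi
  pmin(d, pi - d) * 180 / pi
}
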