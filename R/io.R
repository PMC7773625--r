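#' Read / write meshes in CARP or VTK legacy ASCII format
#'
#' CARP format: a `.pts` file (first line N, then `x y z` per vertex), an
#' `.elem` file (first line M, then `Tr i j k region` with 0-based indices)
#' and optionally a `.lon` file (one `fx fy fz` unit fibre vector per
#' element). VTK format: legacy ASCII polydata with `POLYGONS`, optional
#' `CELL_DATA`/`VECTORS fibres` and `POINT_DATA` scalar arrays.
#'
#' Positions are millimetres internally; `scale` rescales on read/write for
#' datasets stored in micrometres (the on-disk unit convention is not part
#' of the format, so it is exposed as a flag).
#'
#' @param path file prefix (carp: path without extension) or `.vtk` file.
#' @param format `"carp"` or `"vtk"`.
#' @param scale multiplicative factor applied to coordinates on read
#'   (e.g. `1e-3` for files in micrometres); its inverse is applied on write.
#' @param index_base index base used on disk (0 or 1); internal storage is
#'   always 1-based.
#' @return `read_mesh`: a list with `mesh` (a [surface_mesh]) and `fibres`
#'   (a [fibre_field] or `NULL`).
#' @export
read_mesh <- function(path, format = c("carp", "vtk"), scale = 1,
                      index_base = 0L) {
  format <- match.arg(format)
  if (format == "carp") read_carp(path, scale, index_base)
  else read_vtk(path, scale)
}

#' @rdname read_mesh
#' @param mesh a [surface_mesh].
#' @param fibres optional [fibre_field] written alongside (`.lon` /
#'   `VECTORS fibres`).
#' @param point_data optional named list of per-vertex numeric vectors
#'   (vtk only).
#' @export
write_mesh <- function(mesh, path, format = c("carp", "vtk"), fibres = NULL,
                       scale = 1, index_base = 0L, point_data = NULL) {
  format <- match.arg(format)
  if (format == "carp") write_carp(mesh, path, fibres, scale, index_base)
  else write_vtk(mesh, path, fibres, scale, point_data)
  invisible(path)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

read_carp <- function(prefix, scale = 1, index_base = 0L) {
  pts_f <- paste0(prefix, ".pts")
  elem_f <- paste0(prefix, ".elem")
  lon_f <- paste0(prefix, ".lon")
  if (!file.exists(pts_f)) stop("missing points file: ", pts_f)
  if (!file.exists(elem_f)) stop("missing elements file: ", elem_f)

  pts_lines <- readLines(pts_f)
  n <- suppressWarnings(as.integer(trimws(pts_lines[1])))
  if (is.na(n)) stop("malformed .pts header (line 1): '", pts_lines[1], "'")
  if (length(pts_lines) < n + 1L) stop(".pts: expected ", n, " point lines")
  pts <- matrix(scan(text = pts_lines[2:(n + 1L)], quiet = TRUE),
                ncol = 3, byrow = TRUE) * scale

  el_lines <- readLines(elem_f)
  m <- suppressWarnings(as.integer(trimws(el_lines[1])))
  if (is.na(m)) stop("malformed .elem header (line 1): '", el_lines[1], "'")
  if (length(el_lines) < m + 1L) stop(".elem: expected ", m, " element lines")
  toks <- strsplit(trimws(el_lines[2:(m + 1L)]), "[[:space:]]+")
  tri <- matrix(0L, m, 3)
  for (i in seq_len(m)) {
    tk <- toks[[i]]
    if (tk[1] != "Tr")
      stop(".elem line ", i + 1L, ": unsupported cell type '", tk[1],
           "' (only Tr triangles)")
    if (length(tk) < 4L) stop(".elem line ", i + 1L, ": too few fields")
    tri[i, ] <- as.integer(tk[2:4]) - as.integer(index_base) + 1L
  }
  if (min(tri) < 1L)
    stop(".elem: index below base (check index_base flag)")

  fib <- NULL
  mesh <- surface_mesh(pts, tri, orient = FALSE)
  if (file.exists(lon_f)) {
    lon_lines <- readLines(lon_f)
    # carp .lon may carry a '1' header line (number of fibre vectors per elem)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(lon_lines[1]),
                                                 "[[:space:]]+")[[1]]))
    start <- if (length(vals) == 1L) 2L else 1L
    lon <- matrix(scan(text = lon_lines[start:length(lon_lines)],
                       quiet = TRUE), ncol = 3, byrow = TRUE)
    if (nrow(lon) != m) stop(".lon: expected ", m, " vectors, got ", nrow(lon))
    fib <- fibre_field(mesh, lon, project = FALSE)
  }
  list(mesh = mesh, fibres = fib)
}

write_carp <- function(mesh, prefix, fibres = NULL, scale = 1,
                       index_base = 0L) {
  v <- mesh$vertices / scale
  writeLines(c(as.character(nrow(v)),
               paste(fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3]))),
             paste0(prefix, ".pts"))
  tr <- mesh$triangles - 1L + as.integer(index_base)
  writeLines(c(as.character(nrow(tr)),
               paste("Tr", tr[, 1], tr[, 2], tr[, 3], 1L)),
             paste0(prefix, ".elem"))
  if (!is.null(fibres)) {
    f <- unclass(fibres)
    writeLines(c("1", paste(fmt_num(f[, 1]), fmt_num(f[, 2]),
                            fmt_num(f[, 3]))),
               paste0(prefix, ".lon"))
  }
  invisible(prefix)
}

read_vtk <- function(path, scale = 1) {
  lines <- readLines(path)
  find_kw <- function(kw) grep(paste0("^", kw, "\\b"), lines)
  ip <- find_kw("POINTS")
  if (!length(ip)) stop("vtk: no POINTS section in ", path)
  n <- as.integer(strsplit(trimws(lines[ip[1]]), "[[:space:]]+")[[1]][2])
  pt_vals <- numeric(0)
  i <- ip[1] + 1L
  while (length(pt_vals) < 3L * n) {
    pt_vals <- c(pt_vals, scan(text = lines[i], quiet = TRUE))
    i <- i + 1L
  }
  pts <- matrix(pt_vals, ncol = 3, byrow = TRUE) * scale

  ic <- find_kw("POLYGONS")
  if (!length(ic)) stop("vtk: no POLYGONS section in ", path)
  hdr <- as.integer(strsplit(trimws(lines[ic[1]]), "[[:space:]]+")[[1]][2:3])
  m <- hdr[1]
  cell_vals <- integer(0)
  i <- ic[1] + 1L
  while (length(cell_vals) < hdr[2]) {
    cell_vals <- c(cell_vals, as.integer(scan(text = lines[i], quiet = TRUE)))
    i <- i + 1L
  }
  tri <- matrix(0L, m, 3)
  pos <- 1L
  for (k in seq_len(m)) {
    nv <- cell_vals[pos]
    if (nv != 3L)
      stop("vtk: non-triangle cell (", nv, " vertices) at polygon ", k)
    tri[k, ] <- cell_vals[(pos + 1L):(pos + 3L)] + 1L
    pos <- pos + nv + 1L
  }
  mesh <- surface_mesh(pts, tri, orient = FALSE)

  fib <- NULL
  iv <- grep("^VECTORS[[:space:]]+fibres\\b", lines)
  if (length(iv)) {
    f_vals <- numeric(0)
    i <- iv[1] + 1L
    while (length(f_vals) < 3L * m) {
      f_vals <- c(f_vals, scan(text = lines[i], quiet = TRUE))
      i <- i + 1L
    }
    fib <- fibre_field(mesh, matrix(f_vals, ncol = 3, byrow = TRUE),
                       project = FALSE)
  }
  pd <- list()
  ipd <- find_kw("POINT_DATA")
  if (length(ipd)) {
    isc <- grep("^SCALARS[[:space:]]", lines)
    isc <- isc[isc > ipd[1]]
    for (j in isc) {
      nm <- strsplit(trimws(lines[j]), "[[:space:]]+")[[1]][2]
      vals <- numeric(0)
      i <- j + 2L  # skip LOOKUP_TABLE
      while (length(vals) < n) {
        vals <- c(vals, scan(text = lines[i], quiet = TRUE))
        i <- i + 1L
      }
      pd[[nm]] <- vals
    }
  }
  list(mesh = mesh, fibres = fib, point_data = pd)
}

write_vtk <- function(mesh, path, fibres = NULL, scale = 1,
                      point_data = NULL) {
  v <- mesh$vertices / scale
  tr <- mesh$triangles - 1L
  out <- c("# vtk DataFile Version 3.0",
           "fibreatlas surface mesh", "ASCII", "DATASET POLYDATA",
           paste("POINTS", nrow(v), "double"),
           paste(fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])),
           paste("POLYGONS", nrow(tr), 4L * nrow(tr)),
           paste(3L, tr[, 1], tr[, 2], tr[, 3]))
  if (!is.null(fibres)) {
    f <- unclass(fibres)
    out <- c(out, paste("CELL_DATA", nrow(tr)),
             "VECTORS fibres double",
             paste(fmt_num(f[, 1]), fmt_num(f[, 2]), fmt_num(f[, 3])))
  }
  if (!is.null(point_data) && length(point_data)) {
    out <- c(out, paste("POINT_DATA", nrow(v)))
    for (nm in names(point_data)) {
      out <- c(out, paste("SCALARS", nm, "double 1"),
               "LOOKUP_TABLE default", fmt_num(point_data[[nm]]))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Write streamline polylines as VTK legacy ASCII lines
#'
#' Each polyline becomes a `LINES` cell; per-line `theta` (seed angle summary)
#' is written as `CELL_DATA` when available.
#'
#' @param polylines list of numeric k x 3 matrices.
#' @param path output `.vtk` path.
#' @param theta optional numeric per-line scalar for colouring.
#' @export
write_vtk_lines <- function(polylines, path, theta = NULL) {
  polylines <- polylines[vapply(polylines, nrow, 1L) > 0L]
  np <- vapply(polylines, nrow, 1L)
  all_pts <- do.call(rbind, polylines)
  offs <- cumsum(c(0L, np[-length(np)]))
  out <- c("# vtk DataFile Version 3.0", "fibreatlas streamlines", "ASCII",
           "DATASET POLYDATA",
           paste("POINTS", sum(np), "double"),
           paste(fmt_num(all_pts[, 1]), fmt_num(all_pts[, 2]),
                 fmt_num(all_pts[, 3])),
           paste("LINES", length(np), sum(np) + length(np)))
  for (i in seq_along(np))
    out <- c(out, paste(c(np[i], seq_len(np[i]) - 1L + offs[i]),
                        collapse = " "))
  if (!is.null(theta)) {
    out <- c(out, paste("CELL_DATA", length(np)),
             "SCALARS theta double 1", "LOOKUP_TABLE default",
             fmt_num(theta))
  }
  writeLines(out, path)
  invisible(path)
}
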