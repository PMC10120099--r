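#' Define a raster grid geometry
#'
#' Grids use a lower-left origin, square cells, cell-centre registration and
#' row-major storage with row 1 at the bottom (y = y0). Coordinates are
#' projected metres; the CRS is carried as an EPSG code in metadata only.
#'
#' @param x0,y0 Lower-left corner of the grid (metres).
#' @param cell_m Cell side length in metres.
#' @param nx,ny Number of columns and rows.
#' @param epsg EPSG code recorded in metadata (default 25831, UTM 31N).
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(x0, y0, cell_m, nx, ny, epsg = 25831) {
  stopifnot(cell_m > 0, nx >= 1, ny >= 1)
  structure(list(x0 = x0, y0 = y0, cell_m = cell_m,
                 nx = as.integer(nx), ny = as.integer(ny), epsg = epsg),
            class = "grid_spec")
}

#' Grid geometry covering a set of points with padding
#'
#' @param x,y Point coordinates (metres).
#' @param cell_m Cell side length.
#' @param pad_m Padding added on every side (metres).
#' @param epsg EPSG code.
#' @return A `grid_spec`.
#' @export
grid_spec_for_points <- function(x, y, cell_m = 500, pad_m = 3 * cell_m,
                                 epsg = 25831) {
  x0 <- floor((min(x) - pad_m) / cell_m) * cell_m
  y0 <- floor((min(y) - pad_m) / cell_m) * cell_m
  nx <- ceiling((max(x) + pad_m - x0) / cell_m)
  ny <- ceiling((max(y) + pad_m - y0) / cell_m)
  grid_spec(x0, y0, cell_m, nx, ny, epsg)
}

#' Construct a utilization-distribution grid
#'
#' @param grid A `grid_spec`.
#' @param p Matrix of per-cell probability mass, `ny` rows by `nx` columns
#'   (row 1 = southernmost row). Must be non-negative; it is renormalized to
#'   sum to one.
#' @return A `ud_grid` object.
#' @export
ud_grid <- function(grid, p) {
  stopifnot(inherits(grid, "grid_spec"),
            is.matrix(p), nrow(p) == grid$ny, ncol(p) == grid$nx)
  if (any(p < 0)) stop("UD cell mass must be non-negative")
  tot <- sum(p)
  if (!is.finite(tot) || tot <= 0) stop("UD has no positive mass")
  structure(list(grid = grid, p = p / tot), class = "ud_grid")
}

#' @export
print.ud_grid <- function(x, ...) {
  g <- x$grid
  cat(sprintf("ud_grid: %d x %d cells of %g m, origin (%g, %g), EPSG %s\n",
              g$nx, g$ny, g$cell_m, g$x0, g$y0, g$epsg))
  invisible(x)
}

# cell centre coordinates of column ix / row iy (1-based)
cell_centre_x <- function(grid, ix) grid$x0 + (ix - 0.5) * grid$cell_m
cell_centre_y <- function(grid, iy) grid$y0 + (iy - 0.5) * grid$cell_m

# column/row index containing a point; NA outside the grid
cell_index <- function(grid, x, y) {
  ix <- floor((x - grid$x0) / grid$cell_m) + 1L
  iy <- floor((y - grid$y0) / grid$cell_m) + 1L
  ix[ix < 1L | ix > grid$nx] <- NA_integer_
  iy[iy < 1L | iy > grid$ny] <- NA_integer_
  ix[is.na(iy)] <- NA_integer_
  iy[is.na(ix)] <- NA_integer_
  list(ix = ix, iy = iy)
}

same_geometry <- function(a, b) {
  isTRUE(all.equal(a$x0, b$x0)) && isTRUE(all.equal(a$y0, b$y0)) &&
    isTRUE(all.equal(a$cell_m, b$cell_m)) && a$nx == b$nx && a$ny == b$ny
}

#' Average utilization distributions
#'
#' Per-cell arithmetic mean of the supplied UDs, renormalized to total mass
#' one. All UDs must share the same grid geometry; use [resample_ud()] first
#' if they do not.
#'
#' @param uds List of `ud_grid` objects.
#' @return A `ud_grid` on the common geometry.
#' @export
average_uds <- function(uds) {
  stopifnot(length(uds) >= 1)
  g <- uds[[1]]$grid
  for (u in uds) {
    stopifnot(inherits(u, "ud_grid"))
    if (!same_geometry(u$grid, g))
      stop("UD grids have mismatched geometry; resample to a common grid first")
  }
  p <- Reduce(`+`, lapply(uds, `[[`, "p")) / length(uds)
  ud_grid(g, p)
}

#' Resample a UD onto another grid geometry
#'
#' Mass-conserving nearest-cell transfer: each source cell's mass is moved to
#' the target cell containing its centre (mass falling outside the target is
#' dropped before renormalization).
#'
#' @param ud A `ud_grid`.
#' @param target A `grid_spec`.
#' @return A `ud_grid` on `target`.
#' @export
resample_ud <- function(ud, target) {
  stopifnot(inherits(ud, "ud_grid"), inherits(target, "grid_spec"))
  if (same_geometry(ud$grid, target)) return(ud_grid(target, ud$p))
  g <- ud$grid
  cx <- cell_centre_x(g, col(ud$p) * 0 + matrix(seq_len(g$nx), g$ny, g$nx, byrow = TRUE))
  cy <- cell_centre_y(g, matrix(seq_len(g$ny), g$ny, g$nx))
  idx <- cell_index(target, as.vector(cx), as.vector(cy))
  keep <- !is.na(idx$ix)
  p <- matrix(0, target$ny, target$nx)
  lin <- cbind(idx$iy[keep], idx$ix[keep])
  vals <- as.vector(ud$p)[keep]
  for (k in seq_along(vals)) p[lin[k, 1], lin[k, 2]] <- p[lin[k, 1], lin[k, 2]] + vals[k]
  ud_grid(target, p)
}

#' Write a grid as an ESRI ASCII raster
#'
#' @param m Matrix (`ny` x `nx`, row 1 = south) of numeric values.
#' @param grid A `grid_spec`.
#' @param path Output file.
#' @param digits Significant digits for formatting.
#' @export
write_esri_ascii <- function(m, grid, path, digits = 10) {
  stopifnot(nrow(m) == grid$ny, ncol(m) == grid$nx)
  hdr <- c(sprintf("ncols %d", grid$nx),
           sprintf("nrows %d", grid$ny),
           sprintf("xllcorner %.10g", grid$x0),
           sprintf("yllcorner %.10g", grid$y0),
           sprintf("cellsize %.10g", grid$cell_m),
           "NODATA_value -9999")
  # ESRI ASCII stores the top row first
  rows <- apply(m[rev(seq_len(grid$ny)), , drop = FALSE], 1, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path Input file.
#' @param epsg EPSG code to record.
#' @return List with `grid` (a `grid_spec`) and `m` (matrix, row 1 = south).
#' @export
read_esri_ascii <- function(path, epsg = 25831) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  nx <- as.integer(hdr$ncols); ny <- as.integer(hdr$nrows)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  stopifnot(length(vals) == nx * ny)
  m_top <- matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)
  m <- m_top[rev(seq_len(ny)), , drop = FALSE]
  m[m == -9999] <- NA
  list(grid = grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                        nx, ny, epsg),
       m = m)
}
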