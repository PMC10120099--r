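#' @useDynLib scavnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

RESOURCE_TYPES <- c("landfill", "intensive_farm", "vulture_restaurant",
                    "extensive_livestock", "other")

# ordered by predictability over time (most to least predictable); used as
# the tie-break when two candidate resources sit in equally used UD cells
RESOURCE_PREDICTABILITY <- RESOURCE_TYPES

LANDCOVER_CLASSES <- c("FOR", "PAS", "SCR", "IRR", "NIC", "TREE", "ROC",
                       "URB", "OTH")

# default per-type attractiveness: landfills are by far the most predictable
# and most attractive subsidy; unpredictable carcasses the least
DEFAULT_ATTRACTIVENESS <- c(landfill = 3.5, intensive_farm = 0.8,
                            vulture_restaurant = 0.8,
                            extensive_livestock = 3, other = 0.5)

#' Generate a synthetic landscape: resource sites and a land-cover raster
#'
#' Sites are placed uniformly at random inside the square extent (unless
#' coordinates are supplied). The land-cover raster is a patch mosaic: patch
#' seed points get a random class out of the nine land-use categories and
#' every cell takes the class of its nearest seed.
#'
#' @param n_sites_by_type Named integer vector of site counts; names must be
#'   a subset of `landfill`, `intensive_farm`, `vulture_restaurant`,
#'   `extensive_livestock`, `other`.
#' @param extent_m Side of the square landscape (metres).
#' @param cell_m Land-cover cell size (metres).
#' @param n_patches Number of mosaic patches for the land-cover raster.
#' @param coords Optional data frame with columns `rtype`, `x`, `y` fixing
#'   site positions instead of uniform placement.
#' @param seed Integer seed; identical seeds give identical landscapes.
#' @return List with `sites` (data frame: site_id, x, y, rtype, is_roost,
#'   is_nest, attractiveness), `landcover` (list with `grid`, `m`) and
#'   `legend` (class code to acronym).
#' @export
generate_landscape <- function(n_sites_by_type, extent_m = 60000,
                               cell_m = 500, n_patches = 40,
                               coords = NULL, seed = 1) {
  if (extent_m <= 0) stop("extent_m must be positive")
  if (cell_m <= 0) stop("cell_m must be positive")
  if (any(n_sites_by_type < 0)) stop("site counts must be non-negative")
  bad <- setdiff(names(n_sites_by_type), RESOURCE_TYPES)
  if (length(bad)) stop("unknown resource types: ", paste(bad, collapse = ", "))
  set.seed(seed)

  if (is.null(coords)) {
    rtype <- rep(names(n_sites_by_type), times = n_sites_by_type)
    n <- length(rtype)
    coords <- data.frame(rtype = rtype,
                         x = stats::runif(n, 0, extent_m),
                         y = stats::runif(n, 0, extent_m),
                         stringsAsFactors = FALSE)
  }
  n <- nrow(coords)
  sites <- data.frame(
    site_id = if (n) sprintf("S%02d", seq_len(n)) else character(0),
    x = coords$x, y = coords$y, rtype = coords$rtype,
    is_roost = rep(FALSE, n), is_nest = rep(FALSE, n),
    attractiveness = unname(DEFAULT_ATTRACTIVENESS[coords$rtype]),
    stringsAsFactors = FALSE)
  if (any(sites$x < 0 | sites$x > extent_m | sites$y < 0 | sites$y > extent_m))
    stop("site coordinates outside the landscape extent")

  ncell <- ceiling(extent_m / cell_m)
  g <- grid_spec(0, 0, cell_m, ncell, ncell)
  px <- stats::runif(n_patches, 0, extent_m)
  py <- stats::runif(n_patches, 0, extent_m)
  pc <- sample.int(length(LANDCOVER_CLASSES), n_patches, replace = TRUE)
  cx <- cell_centre_x(g, seq_len(ncell))
  cy <- cell_centre_y(g, seq_len(ncell))
  m <- matrix(0L, ncell, ncell)
  for (iy in seq_len(ncell)) {
    # nearest patch seed per cell in this row
    dd <- (matrix(px, n_patches, ncell) - matrix(cx, n_patches, ncell,
                                                 byrow = TRUE))^2 +
          (py - cy[iy])^2
    m[iy, ] <- pc[max.col(-t(dd))]
  }
  list(sites = sites,
       landcover = list(grid = g, m = m),
       legend = stats::setNames(LANDCOVER_CLASSES,
                                seq_along(LANDCOVER_CLASSES)))
}

#' Default study landscape
#'
#' The landscape the synthetic population is simulated on: a 100 km square
#' with 2 landfills, 10 intensive farms, 8 vulture restaurants, 16 extensive
#' livestock areas and 14 unpredictable sites, plus one nest site per
#' breeder and communal roosts at the landfills.
#'
#' @param n_breeders Number of breeders needing a nest site.
#' @param min_sep_m Minimum separation between any two sites (keeps nodes
#'   single-site at the default UD smoothing scale).
#' @param seed Integer seed.
#' @inheritParams generate_landscape
#' @return As [generate_landscape()], with nest and roost flags set.
#' @export
default_landscape <- function(n_breeders = 6, extent_m = 100000,
                              min_sep_m = 6000, seed = 1) {
  counts <- c(landfill = 2, intensive_farm = 10, vulture_restaurant = 8,
              extensive_livestock = 16, other = 14)
  set.seed(seed)
  n_food <- sum(counts)
  xy <- place_separated(n_food + n_breeders, extent_m, min_sep_m)
  coords <- data.frame(rtype = rep(names(counts), times = counts),
                       x = xy[seq_len(n_food), 1], y = xy[seq_len(n_food), 2],
                       stringsAsFactors = FALSE)
  ls <- generate_landscape(counts, extent_m = extent_m, coords = coords,
                           seed = seed)
  sites <- ls$sites
  # communal roosts sit at the landfills
  sites$is_roost[sites$rtype == "landfill"] <- TRUE
  # nests: separate low-attractiveness sites spread over the landscape
  nest <- data.frame(
    site_id = sprintf("N%02d", seq_len(n_breeders)),
    x = xy[n_food + seq_len(n_breeders), 1],
    y = xy[n_food + seq_len(n_breeders), 2],
    rtype = "other", is_roost = FALSE, is_nest = TRUE,
    attractiveness = 0.5, stringsAsFactors = FALSE)
  ls$sites <- rbind(sites, nest)
  ls
}

# rejection sampling of n points uniform on the square with pairwise
# separation >= min_sep (separation is relaxed if placement stalls)
place_separated <- function(n, extent_m, min_sep) {
  pts <- matrix(NA_real_, n, 2)
  k <- 0L; tries <- 0L
  while (k < n) {
    cand <- stats::runif(2, 0.05 * extent_m, 0.95 * extent_m)
    ok <- k == 0L ||
      min((pts[seq_len(k), 1] - cand[1])^2 +
            (pts[seq_len(k), 2] - cand[2])^2) >= min_sep^2
    if (ok) {
      k <- k + 1L
      pts[k, ] <- cand
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > 2000L) { min_sep <- min_sep * 0.8; tries <- 0L }
    }
  }
  pts
}

#' Write / read the resource-site table
#'
#' @param sites Site data frame.
#' @param path CSV file path.
#' @export
write_sites_csv <- function(sites, path) {
  utils::write.csv(sites, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sites_csv
#' @export
read_sites_csv <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  s$is_roost <- as.logical(s$is_roost)
  s$is_nest <- as.logical(s$is_nest)
  s
}

#' Write the land-cover legend sidecar
#' @param legend Named vector (code -> acronym).
#' @param path Output file.
#' @export
write_legend <- function(legend, path) {
  writeLines(sprintf("%s,%s", names(legend), legend), path)
  invisible(path)
}
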