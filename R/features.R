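#' Land-cover composition of a node
#'
#' Percentage of each of the nine land-use classes among raster cells whose
#' centre falls inside the node polygon, renormalized to sum to 100. When
#' the node is smaller than a raster cell, the cell containing the node
#' centroid is used.
#'
#' @param node One node from a `node_set`.
#' @param landcover List with `grid` (a `grid_spec`) and `m` (integer class
#'   matrix, codes 1-9).
#' @return Named numeric vector of 9 percentages (FOR, PAS, SCR, IRR, NIC,
#'   TREE, ROC, URB, OTH).
#' @export
landcover_composition <- function(node, landcover) {
  g <- landcover$grid
  ring <- node$polygon
  bb <- apply(ring, 2, range)
  ix0 <- max(1L, floor((bb[1, "x"] - g$x0) / g$cell_m) + 1L)
  ix1 <- min(g$nx, floor((bb[2, "x"] - g$x0) / g$cell_m) + 1L)
  iy0 <- max(1L, floor((bb[1, "y"] - g$y0) / g$cell_m) + 1L)
  iy1 <- min(g$ny, floor((bb[2, "y"] - g$y0) / g$cell_m) + 1L)
  if (ix0 > ix1 || iy0 > iy1) stop("node lies outside the land-cover raster")
  ix <- rep(ix0:ix1, times = iy1 - iy0 + 1)
  iy <- rep(iy0:iy1, each = ix1 - ix0 + 1)
  inside <- .cpp_label_points(cell_centre_x(g, ix), cell_centre_y(g, iy),
                              list(ring))
  sel <- which(!is.na(inside))
  if (!length(sel)) {
    ci <- cell_index(g, mean(ring[, "x"]), mean(ring[, "y"]))
    if (is.na(ci$ix)) stop("node lies outside the land-cover raster")
    ix <- ci$ix; iy <- ci$iy; sel <- 1L
  } else {
    ix <- ix[sel]; iy <- iy[sel]
  }
  classes <- landcover$m[cbind(iy, ix)]
  counts <- tabulate(classes, nbins = length(LANDCOVER_CLASSES))
  stats::setNames(100 * counts / sum(counts), LANDCOVER_CLASSES)
}

#' Assign the dominant food resource of a node
#'
#' Among resource sites inside the node polygon, returns the type of the
#' site whose containing UD cell has the highest utilization probability.
#' Ties prefer the more predictable resource (landfill > intensive farm >
#' vulture restaurant > extensive livestock > other); a node without any
#' site is classed `"other"` (unpredictable resources).
#'
#' @param node One node from a `node_set`.
#' @param population_ud Population-level `ud_grid`.
#' @param sites Site data frame.
#' @return Resource type string.
#' @export
assign_resource <- function(node, population_ud, sites) {
  inside <- .cpp_label_points(sites$x, sites$y, list(node$polygon))
  cand <- sites[!is.na(inside), ]
  if (!nrow(cand)) return("other")
  g <- population_ud$grid
  ci <- cell_index(g, cand$x, cand$y)
  p <- rep(0, nrow(cand))
  ok <- !is.na(ci$ix)
  p[ok] <- population_ud$p[cbind(ci$iy[ok], ci$ix[ok])]
  pred_rank <- match(cand$rtype, RESOURCE_PREDICTABILITY)
  best <- order(-p, pred_rank)[1]
  cand$rtype[best]
}

#' Node fidelity: revisits and accumulated residence time
#'
#' A visit is a maximal run of an individual's fixes inside the node; a new
#' visit starts when the observed absence — the gap since the previous
#' inside fix minus the nominal fix interval, since a gap of one interval
#' carries no evidence of absence — is at least `min_absence_s`. Revisits
#' are summed over all individuals of the status;
#' residence time accumulates, per visit, the span from first to last inside
#' fix plus one nominal fix interval (the trailing-interval convention).
#'
#' @param labeled Labelled trajectory from [label_fixes()].
#' @param node_id Node to evaluate.
#' @param status Optional status filter.
#' @param min_absence_s Minimum absence separating two visits (default
#'   1800 s).
#' @return List with `revisits` (integer) and `residence_s` (seconds).
#' @export
node_fidelity <- function(labeled, node_id, status = NULL,
                          min_absence_s = 1800) {
  if (!is.null(status)) labeled <- labeled[labeled$status == status, ]
  revisits <- 0L
  residence <- 0
  for (id in unique(labeled$individual_id)) {
    tr <- labeled[labeled$individual_id == id, ]
    tr <- tr[order(tr$timestamp_utc), ]
    t <- as.numeric(tr$timestamp_utc)
    fix_int <- if (nrow(tr) > 1) stats::median(diff(t)) else min_absence_s
    tin <- t[!is.na(tr$node) & tr$node == node_id]
    if (!length(tin)) next
    new_visit <- c(TRUE, diff(tin) - fix_int >= min_absence_s)
    vid <- cumsum(new_visit)
    revisits <- revisits + max(vid)
    span <- tapply(tin, vid, function(v) max(v) - min(v))
    residence <- residence + sum(span + fix_int)
  }
  list(revisits = revisits, residence_s = residence)
}

#' Full node-feature table
#'
#' One row per node and status: land-cover percentages, dominant resource,
#' roost and breeding-territory flags (from the site table), revisits and
#' residence time.
#'
#' @param nodes A `node_set`.
#' @param labeled Labelled trajectory (all individuals).
#' @param population_ud Population-level `ud_grid`.
#' @param sites Site data frame.
#' @param landcover Land-cover raster list.
#' @param statuses Statuses to tabulate.
#' @param min_absence_s Passed to [node_fidelity()].
#' @return Data frame with one row per node x status.
#' @export
node_features <- function(nodes, labeled, population_ud, sites, landcover,
                          statuses = c("non_breeder", "breeder"),
                          min_absence_s = 1800) {
  base <- lapply(nodes, function(nd) {
    lc <- landcover_composition(nd, landcover)
    inside <- .cpp_label_points(sites$x, sites$y, list(nd$polygon))
    within <- sites[!is.na(inside), ]
    c(list(node_id = nd$node_id,
           resource = assign_resource(nd, population_ud, sites),
           roost = any(within$is_roost),
           breeding_territory = any(within$is_nest)),
      as.list(lc))
  })
  rows <- list()
  for (st in statuses) {
    for (b in base) {
      fid <- node_fidelity(labeled, b$node_id, status = st,
                           min_absence_s = min_absence_s)
      rows[[length(rows) + 1]] <- data.frame(
        c(list(status = st), b, fid), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write the node-feature table as CSV
#' @param features Data frame from [node_features()].
#' @param path Output file.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
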