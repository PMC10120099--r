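#' Label fixes with the node containing them
#'
#' Point-in-polygon assignment of every fix to a node (closed polygons:
#' boundary points belong to the polygon) or to `NA` when outside all nodes.
#' Nodes carrying grid cell sets (from [extract_contour()]) use exact
#' cell-membership lookup; polygon-only nodes use ray casting.
#'
#' @param traj Trajectory data frame (`individual_id`, `status`,
#'   `timestamp_utc`, `x`, `y`).
#' @param nodes A `node_set` (or list of nodes with `node_id` and `polygon`).
#' @return The trajectory with a `node` column (node_id or NA = outside).
#' @export
label_fixes <- function(traj, nodes) {
  ids <- vapply(nodes, `[[`, "", "node_id")
  g <- attr(nodes, "grid")
  have_cells <- !is.null(g) && all(vapply(nodes, function(n)
    !is.null(n$cells), TRUE))
  if (have_cells) {
    cell_ids <- lapply(nodes, function(n)
      n$cells[, "ix"] + (n$cells[, "iy"] - 1) * g$nx)
    if (anyDuplicated(unlist(cell_ids)))
      stop("nodes overlap: shared grid cells")
    owner <- rep(seq_along(nodes), vapply(cell_ids, length, 0L))
    lut <- stats::setNames(owner, unlist(cell_ids))
    ci <- cell_index(g, traj$x, traj$y)
    lin <- ci$ix + (ci$iy - 1L) * g$nx
    idx <- unname(lut[as.character(lin)])
  } else {
    polys <- lapply(nodes, function(n) {
      m <- n$polygon
      stopifnot(is.matrix(m), ncol(m) == 2)
      m
    })
    cents <- lapply(polys, colMeans)
    hit <- .cpp_label_points(vapply(cents, `[[`, 0, 1),
                             vapply(cents, `[[`, 0, 2), polys)
    if (any(hit != seq_along(polys), na.rm = TRUE))
      stop("nodes overlap: polygon centres fall inside other polygons")
    idx <- .cpp_label_points(traj$x, traj$y, polys)
  }
  traj$node <- ids[idx]
  traj
}

#' Extract between-node movement paths
#'
#' A movement path connects an individual's last fix inside a departure node
#' to its first fix inside a different arrival node, with no intermediate
#' fix inside any node. Paths shorter than `min_duration_s` are dropped, as
#' are candidate paths interrupted by a data gap longer than `gap_break_s`
#' (e.g. the nightly device-off period).
#'
#' @param labeled Labelled trajectory from [label_fixes()].
#' @param min_duration_s Minimum trip duration kept (default 3600 s: trips
#'   of one hour or more).
#' @param gap_break_s Maximum inter-fix gap inside a trip (default 5400 s).
#' @return Data frame of paths: `individual_id`, `status`, `from_node`,
#'   `to_node`, `exit_t`, `entry_t`, `duration_s`.
#' @export
extract_paths <- function(labeled, min_duration_s = 3600,
                          gap_break_s = 5400) {
  out <- list()
  for (id in unique(labeled$individual_id)) {
    tr <- labeled[labeled$individual_id == id, ]
    tr <- tr[order(tr$timestamp_utc), ]
    t <- as.numeric(tr$timestamp_utc)
    nd <- tr$node
    last_node <- NA_character_
    last_t <- NA_real_
    for (i in seq_along(nd)) {
      if (i > 1 && t[i] - t[i - 1] > gap_break_s) {
        last_node <- NA_character_
      }
      if (is.na(nd[i])) next
      if (!is.na(last_node) && nd[i] != last_node) {
        dur <- t[i] - last_t
        if (dur >= min_duration_s)
          out[[length(out) + 1]] <- data.frame(
            individual_id = id, status = tr$status[1],
            from_node = last_node, to_node = nd[i],
            exit_t = last_t, entry_t = t[i], duration_s = dur,
            stringsAsFactors = FALSE)
      }
      last_node <- nd[i]
      last_t <- t[i]
    }
  }
  if (!length(out))
    return(data.frame(individual_id = character(0), status = character(0),
                      from_node = character(0), to_node = character(0),
                      exit_t = numeric(0), entry_t = numeric(0),
                      duration_s = numeric(0)))
  do.call(rbind, out)
}

#' Build a spatial-use network from movement paths
#'
#' Nodes are contour polygons with at least one incident path for the given
#' status; edge weight is the count of paths between the ordered node pair.
#' The network stores the directed edge list and an undirected collapsed
#' view (weights summed over both directions), which is the default for all
#' metrics.
#'
#' @param paths Path data frame from [extract_paths()].
#' @param status Optional status filter (`"non_breeder"` / `"breeder"`).
#' @param nodes Optional `node_set` supplying node metadata.
#' @return A `spatial_network` object.
#' @export
build_network <- function(paths, status = NULL, nodes = NULL) {
  if (!is.null(status)) {
    if (!all(paths$status %in% c("non_breeder", "breeder")))
      stop("unknown status label in paths")
    paths <- paths[paths$status == status, ]
  }
  if (nrow(paths)) {
    dir_tab <- stats::aggregate(list(weight = rep(1L, nrow(paths))),
                                by = list(from = paths$from_node,
                                          to = paths$to_node), FUN = sum)
    a <- pmin(dir_tab$from, dir_tab$to)
    b <- pmax(dir_tab$from, dir_tab$to)
    und_tab <- stats::aggregate(list(weight = dir_tab$weight),
                                by = list(from = a, to = b), FUN = sum)
    node_ids <- sort(unique(c(paths$from_node, paths$to_node)))
  } else {
    dir_tab <- und_tab <- data.frame(from = character(0), to = character(0),
                                     weight = integer(0))
    node_ids <- character(0)
  }
  meta <- NULL
  if (!is.null(nodes)) {
    all_meta <- data.frame(
      node_id = vapply(nodes, `[[`, "", "node_id"),
      centroid_x = vapply(nodes, function(n) n$centroid[["x"]], 0),
      centroid_y = vapply(nodes, function(n) n$centroid[["y"]], 0),
      area_m2 = vapply(nodes, `[[`, 0, "area_m2"),
      stringsAsFactors = FALSE)
    meta <- all_meta[all_meta$node_id %in% node_ids, ]
  }
  structure(list(status = if (is.null(status)) "all" else status,
                 node_ids = node_ids, nodes = meta,
                 edges_directed = dir_tab, edges = und_tab),
            class = "spatial_network")
}

#' @export
print.spatial_network <- function(x, ...) {
  cat(sprintf("spatial_network (%s): %d nodes, %d undirected links (%d paths)\n",
              x$status, length(x$node_ids), nrow(x$edges),
              sum(x$edges$weight)))
  invisible(x)
}

#' Convert a spatial network to an igraph graph
#'
#' @param net A `spatial_network`.
#' @param directed Use the directed edge list instead of the collapsed view.
#' @return An igraph graph with a `weight` edge attribute (path counts).
#' @export
as_igraph <- function(net, directed = FALSE) {
  ed <- if (directed) net$edges_directed else net$edges
  igraph::graph_from_data_frame(ed, directed = directed,
                                vertices = data.frame(name = net$node_ids))
}

#' Per individual-year networks and their network-level metrics
#'
#' Builds one network per individual and calendar year (the unit of
#' observation for the status ANOVA contrasts) and tabulates node count,
#' link count, diameter and density for each.
#'
#' @param paths Path data frame.
#' @return Data frame: individual_id, status, year, n_nodes, n_links,
#'   diameter, edge_density, clustering, degree_heterogeneity.
#' @export
individual_year_networks <- function(paths) {
  if (!nrow(paths)) stop("no paths")
  year <- as.integer(format(as.POSIXct(paths$exit_t, tz = "UTC",
                                       origin = "1970-01-01"), "%Y"))
  key <- interaction(paths$individual_id, year, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    pp <- paths[key == k, ]
    net <- build_network(pp)
    dens <- if (length(net$node_ids) >= 2) net_density(net) else
      list(edge_density = NA_real_, clustering = NA_real_,
           degree_heterogeneity = NA_real_)
    data.frame(individual_id = pp$individual_id[1], status = pp$status[1],
               year = year[key == k][1],
               n_nodes = length(net$node_ids), n_links = nrow(net$edges),
               diameter = if (length(net$node_ids)) net_diameter(net) else NA,
               edge_density = dens$edge_density,
               clustering = dens$clustering,
               degree_heterogeneity = dens$degree_heterogeneity)
  })
  do.call(rbind, rows)
}

#' Write a spatial network as JSON and edge-list CSV
#'
#' @param net A `spatial_network`.
#' @param json_path,csv_path Output files (either may be NULL).
#' @export
write_network <- function(net, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    nodes <- if (!is.null(net$nodes)) net$nodes else
      data.frame(node_id = net$node_ids)
    jsonlite::write_json(
      list(status = net$status, nodes = nodes,
           edges = net$edges, edges_directed = net$edges_directed),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (!is.null(csv_path))
    utils::write.csv(net$edges, csv_path, row.names = FALSE, quote = FALSE)
  invisible(net)
}
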