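#' Extract probability contour polygons from a UD
#'
#' Cells are selected in decreasing density order until their cumulative mass
#' first reaches `level` (the minimal such set), labelled into 4-connected
#' components, and each component's outer cell boundary is polygonized. Each
#' polygon is one candidate network node.
#'
#' @param ud A `ud_grid`.
#' @param level Contour level in (0, 1), default 0.50.
#' @return A `node_set`: list of nodes, each with `node_id`, `polygon`
#'   (matrix of ring vertices, metres, counter-clockwise, closed), `cells`
#'   (two-column matrix of column/row indices), `mass`, `centroid`,
#'   `area_m2`; the grid is attached as an attribute.
#' @export
extract_contour <- function(ud, level = 0.5) {
  stopifnot(inherits(ud, "ud_grid"))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  p <- ud$p
  if (level >= sum(p)) stop("level must be below the total UD mass")
  ord <- order(p, decreasing = TRUE)
  cum <- cumsum(p[ord])
  k <- which(cum >= level)[1]
  sel <- ord[seq_len(k)]
  g <- ud$grid
  iy <- (sel - 1) %% g$ny + 1
  ix <- (sel - 1) %/% g$ny + 1

  comp <- label_components(ix, iy, g$nx, g$ny)
  nodes <- list()
  for (ci in sort(unique(comp))) {
    cc <- cbind(ix = ix[comp == ci], iy = iy[comp == ci])
    ring <- trace_outer_ring(cc, g)
    mass <- sum(p[cbind(cc[, "iy"], cc[, "ix"])])
    cx <- mean(cell_centre_x(g, cc[, "ix"]))
    cy <- mean(cell_centre_y(g, cc[, "iy"]))
    nodes[[length(nodes) + 1]] <- list(
      node_id = sprintf("node%02d", length(nodes) + 1),
      polygon = ring, cells = cc, mass = mass,
      centroid = c(x = cx, y = cy),
      area_m2 = nrow(cc) * g$cell_m^2)
  }
  structure(nodes, class = "node_set", grid = g, level = level,
            total_mass = cum[k])
}

#' @export
print.node_set <- function(x, ...) {
  cat(sprintf("node_set: %d polygons at level %.2f (enclosed mass %.4f)\n",
              length(x), attr(x, "level"), attr(x, "total_mass")))
  invisible(x)
}

# 4-connected component labelling of a set of cells
label_components <- function(ix, iy, nx, ny) {
  n <- length(ix)
  id <- ix + (iy - 1) * nx
  lookup <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(id[i]), i, envir = lookup)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      for (nb in c(id[i] - 1L, id[i] + 1L, id[i] - nx, id[i] + nx)) {
        # guard against row wrap-around for left/right neighbours
        if (nb == id[i] - 1L && (id[i] - 1L) %% nx == 0L) next
        if (nb == id[i] + 1L && id[i] %% nx == 0L) next
        j <- lookup[[as.character(nb)]]
        if (!is.null(j) && comp[j] == 0L) {
          comp[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

# Trace the outer boundary ring of a 4-connected cell component.
# Boundary edges are oriented counter-clockwise (interior on the left); at a
# pinch vertex the sharpest left turn is taken. The ring with the largest
# shoelace area is the outer boundary.
trace_outer_ring <- function(cells, grid) {
  key <- function(cx, cy) paste(cx, cy, sep = ",")
  inset <- new.env(hash = TRUE)
  for (i in seq_len(nrow(cells)))
    assign(key(cells[i, 1], cells[i, 2]), TRUE, envir = inset)
  has <- function(cx, cy) !is.null(inset[[key(cx, cy)]])

  # directed edges between lattice corners (corner (c, r) = metres
  # (x0 + c*cell, y0 + r*cell)); CCW orientation around each cell
  from <- list(); to <- list()
  for (i in seq_len(nrow(cells))) {
    cx <- cells[i, 1]; cy <- cells[i, 2]
    if (!has(cx, cy - 1)) { from[[length(from) + 1]] <- c(cx - 1, cy - 1); to[[length(to) + 1]] <- c(cx, cy - 1) }
    if (!has(cx + 1, cy)) { from[[length(from) + 1]] <- c(cx, cy - 1);     to[[length(to) + 1]] <- c(cx, cy) }
    if (!has(cx, cy + 1)) { from[[length(from) + 1]] <- c(cx, cy);         to[[length(to) + 1]] <- c(cx - 1, cy) }
    if (!has(cx - 1, cy)) { from[[length(from) + 1]] <- c(cx - 1, cy);     to[[length(to) + 1]] <- c(cx - 1, cy - 1) }
  }
  nE <- length(from)
  used <- rep(FALSE, nE)
  out <- new.env(hash = TRUE)  # start vertex -> edge indices
  for (e in seq_len(nE)) {
    k <- key(from[[e]][1], from[[e]][2])
    out[[k]] <- c(out[[k]], e)
  }

  rings <- list()
  for (e0 in seq_len(nE)) {
    if (used[e0]) next
    ring <- list(from[[e0]])
    e <- e0
    repeat {
      used[e] <- TRUE
      v <- to[[e]]
      ring[[length(ring) + 1]] <- v
      if (all(v == from[[e0]])) break
      cand <- out[[key(v[1], v[2])]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) == 1) {
        e <- cand[1]
      } else {
        # pinch vertex: take the sharpest left turn relative to the
        # incoming direction to stay on this lobe of the boundary
        din <- v - from[[e]]
        ang <- vapply(cand, function(ce) {
          dout <- to[[ce]] - v
          atan2(din[1] * dout[2] - din[2] * dout[1],
                din[1] * dout[1] + din[2] * dout[2])
        }, 0)
        e <- cand[which.max(ang)]
      }
    }
    if (length(ring) >= 4) rings[[length(rings) + 1]] <- ring
  }

  areas <- vapply(rings, function(r) {
    m <- do.call(rbind, r)
    sum(m[-nrow(m), 1] * m[-1, 2] - m[-1, 1] * m[-nrow(m), 2]) / 2
  }, 0)
  outer <- do.call(rbind, rings[[which.max(areas)]])
  cbind(x = grid$x0 + outer[, 1] * grid$cell_m,
        y = grid$y0 + outer[, 2] * grid$cell_m)
}

#' Enclosed mass of a contour set
#' @param nodes A `node_set`.
#' @return Total UD mass inside the selected cells.
#' @export
contour_mass <- function(nodes) attr(nodes, "total_mass")

#' Write contour polygons as GeoJSON
#'
#' @param nodes A `node_set`.
#' @param path Output file.
#' @export
write_contours_geojson <- function(nodes, path) {
  feats <- lapply(nodes, function(nd) {
    ring <- nd$polygon
    list(type = "Feature",
         properties = list(id = nd$node_id,
                           level = attr(nodes, "level"),
                           mass = nd$mass,
                           area_m2 = nd$area_m2),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
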