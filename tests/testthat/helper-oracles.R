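# Brute-force graph oracles, independent of igraph, for metric verification
# on small graphs (adjacency matrices, n <= 8).

bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# shortest-path counts sigma[s, t] by dynamic programming over distance
bf_path_counts <- function(adj, d) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (t in order(d[s, ])) {
      if (t == s || !is.finite(d[s, t])) next
      pred <- which(adj[, t] == 1 & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, pred])
    }
  }
  sigma
}

# unordered-pair betweenness for every vertex
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- bf_distances(adj)
  sigma <- bf_path_counts(adj, d)
  b <- numeric(n)
  for (v in seq_len(n))
    for (s in seq_len(n - 1))
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t])
          b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
  b
}

# diameter of the largest connected component
bf_diameter <- function(adj) {
  d <- bf_distances(adj)
  reach <- is.finite(d)
  comp_sizes <- rowSums(reach)
  big <- which.max(comp_sizes)
  members <- which(reach[big, ])
  if (length(members) == 1) return(0)
  max(d[members, members])
}

# global transitivity by triplet enumeration
bf_transitivity <- function(adj) {
  n <- nrow(adj)
  closed <- 0
  total <- 0
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) < 2) next
    pairs <- utils::combn(nb, 2)
    total <- total + ncol(pairs)
    closed <- closed + sum(adj[cbind(pairs[1, ], pairs[2, ])])
  }
  if (total == 0) return(NaN)
  closed / total
}

# random undirected simple graph as adjacency matrix
random_adj <- function(n, p = 0.4) {
  adj <- matrix(0L, n, n)
  up <- upper.tri(adj)
  adj[up] <- stats::rbinom(sum(up), 1, p)
  adj + t(adj)
}

is_connected_adj <- function(adj) all(is.finite(bf_distances(adj)))

# spatial_network built from an explicit undirected edge list on named nodes
net_from_edges <- function(edges, nodes = NULL) {
  paths <- data.frame(individual_id = "X", status = "non_breeder",
                      from_node = edges[, 1], to_node = edges[, 2],
                      exit_t = seq_len(nrow(edges)) * 7200,
                      entry_t = seq_len(nrow(edges)) * 7200 + 3600,
                      duration_s = 3600, stringsAsFactors = FALSE)
  build_network(paths)
}

adj_to_net <- function(adj) {
  ids <- sprintf("n%d", seq_len(nrow(adj)))
  e <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  net_from_edges(cbind(ids[e[, 1]], ids[e[, 2]]))
}

# hub-and-spoke fixture: 2 landfill hubs bridged to each other, each hub
# serving its own 5 extensive spokes (hubs carry every cross-spoke path)
hub_spoke_fixture <- function() {
  hubs <- c("H1", "H2")
  spokes1 <- sprintf("S%d", 1:5)
  spokes2 <- sprintf("S%d", 6:10)
  edges <- rbind(cbind("H1", spokes1), cbind("H2", spokes2),
                 c("H1", "H2"))
  net <- net_from_edges(edges)
  features <- data.frame(
    node_id = c(hubs, spokes1, spokes2),
    resource = c("landfill", "landfill", rep("extensive_livestock", 10)),
    stringsAsFactors = FALSE)
  list(net = net, features = features)
}

# labelled-trajectory builder: node labels at a regular fix interval
labeled_track <- function(labels, interval_s = 1800, id = "B1",
                          status = "non_breeder", t0 = 0) {
  n <- length(labels)
  data.frame(individual_id = id, status = status,
             timestamp_utc = as.POSIXct(t0 + (seq_len(n) - 1) * interval_s,
                                        tz = "UTC", origin = "1970-01-01"),
             x = 0, y = 0,
             node = ifelse(labels == "OUT", NA_character_, labels),
             stringsAsFactors = FALSE)
}

# simulated pure Brownian motion track (the dBBMM recovery oracle is the
# generating parameter)
bm_track <- function(n, sigma2, tau = 1800, err = 0, t0 = 0) {
  dx <- stats::rnorm(n - 1, 0, sqrt(sigma2 * tau))
  dy <- stats::rnorm(n - 1, 0, sqrt(sigma2 * tau))
  data.frame(t = t0 + (seq_len(n) - 1) * tau,
             x = cumsum(c(0, dx)) + stats::rnorm(n, 0, err),
             y = cumsum(c(0, dy)) + stats::rnorm(n, 0, err),
             loc_error_m = err)
}

# independent dense quadrature of the single-segment bridge integrand:
# evaluates the time-integrated bivariate normal on cell centres of `grid`
# with `nt` interior time points (midpoint rule), returns the normalized
# cell-probability matrix
bridge_quadrature <- function(x, y, t, err, sigma2, grid, nt = 64) {
  T <- t[2] - t[1]
  p <- matrix(0, grid$ny, grid$nx)
  cx <- grid$x0 + (seq_len(grid$nx) - 0.5) * grid$cell_m
  cy <- grid$y0 + (seq_len(grid$ny) - 0.5) * grid$cell_m
  for (j in seq_len(nt)) {
    a <- (j - 0.5) / nt
    mx <- x[1] + a * (x[2] - x[1])
    my <- y[1] + a * (y[2] - y[1])
    v <- a * (1 - a) * T * sigma2 + (1 - a)^2 * err[1]^2 + a^2 * err[2]^2
    p <- p + outer(stats::dnorm(cy, my, sqrt(v)),
                   stats::dnorm(cx, mx, sqrt(v)))
  }
  p / sum(p)
}

# aggregate a matrix by 4x4 blocks (fine -> coarse grid)
agg4 <- function(m) {
  r <- rowsum(m, rep(seq_len(nrow(m) / 4), each = 4))
  t(rowsum(t(r), rep(seq_len(ncol(m) / 4), each = 4)))
}

# total variation between the rasterized single-bridge UD and an
# independent dense quadrature on a 4x finer grid
bridge_refinement_tv <- function(cell = 50) {
  tr <- data.frame(t = c(0, 1800, 3600), x = c(0, 600, 650),
                   y = c(0, 200, 170), loc_error_m = 5)
  mvs <- estimate_motion_variance(tr, window = 5, margin = 2)
  mvs1 <- structure(mvs[1, , drop = FALSE], class = class(mvs),
                    fixes = attr(mvs, "fixes")[1:2, ])
  nx <- 4000 / cell
  g <- grid_spec(-2000, -2000, cell, nx, nx)
  ud <- compute_ud(mvs1, grid = g, alpha_steps = 32)
  oracle <- bridge_quadrature(tr$x[1:2], tr$y[1:2], tr$t[1:2], rep(5, 2),
                              mvs1$sigma2_m[1],
                              grid_spec(-2000, -2000, cell / 4,
                                        4 * nx, 4 * nx), nt = 64)
  list(ud = ud, tv = 0.5 * sum(abs(ud$p - agg4(oracle))))
}

# gaussian utilization grid centred at (cx, cy)
gaussian_ud <- function(grid, cx, cy, sd) {
  xs <- grid$x0 + (seq_len(grid$nx) - 0.5) * grid$cell_m
  ys <- grid$y0 + (seq_len(grid$ny) - 0.5) * grid$cell_m
  ud_grid(grid, outer(stats::dnorm(ys, cy, sd), stats::dnorm(xs, cx, sd)))
}

# small ring-of-sites landscape for fidelity oracle tests: sites on a circle
# so no straight commute passes near a third site
ring_landscape <- function(n_food = 10, n_nests = 6, radius = 35000,
                           centre = 50000) {
  n <- n_food + n_nests
  ang <- 2 * pi * (seq_len(n) - 1) / n
  rtypes <- rep(c("landfill", "extensive_livestock", "intensive_farm",
                  "vulture_restaurant", "other"), length.out = n_food)
  data.frame(
    site_id = c(sprintf("S%02d", seq_len(n_food)),
                sprintf("N%02d", seq_len(n_nests))),
    x = centre + radius * cos(ang),
    y = centre + radius * sin(ang),
    rtype = c(rtypes, rep("other", n_nests)),
    is_roost = c(rtypes == "landfill", rep(FALSE, n_nests)),
    is_nest = c(rep(FALSE, n_food), rep(TRUE, n_nests)),
    attractiveness = 1, stringsAsFactors = FALSE)
}

# square node polygons (half-width hw) around each site
square_nodes <- function(sites, hw = 900) {
  nodes <- lapply(seq_len(nrow(sites)), function(i) {
    x <- sites$x[i]; y <- sites$y[i]
    list(node_id = sites$site_id[i],
         polygon = cbind(x = c(x - hw, x + hw, x + hw, x - hw, x - hw),
                         y = c(y - hw, y - hw, y + hw, y + hw, y - hw)),
         centroid = c(x = x, y = y), area_m2 = (2 * hw)^2)
  })
  structure(nodes, class = "node_set")
}

# observable ground-truth node fidelity from a visit log: merge entries at
# the same site separated by less than min_absence_s, drop visits containing
# no fix tick (tick grid = multiples of interval_s), then count and time them
log_fidelity <- function(visit_log, site, min_absence_s = 1800,
                         interval_s = 1800) {
  vl <- visit_log[visit_log$site_id == site, ]
  if (!nrow(vl)) return(list(revisits = 0L, residence_s = 0))
  vl <- vl[order(vl$arrival), ]
  new_visit <- c(TRUE, vl$arrival[-1] - vl$departure[-nrow(vl)] >= min_absence_s)
  vid <- cumsum(new_visit)
  arr <- tapply(vl$arrival, vid, min)
  dep <- tapply(vl$departure, vid, max)
  # last emitted tick inside the visit: the dusk tick itself (22:30) is
  # never emitted by the device, so fall back one interval
  last_tick <- floor(dep / interval_s) * interval_s
  dusk <- last_tick %% 86400 == 22.5 * 3600
  last_tick[dusk] <- last_tick[dusk] - interval_s
  has_tick <- last_tick >= arr
  list(revisits = sum(has_tick), residence_s = sum((dep - arr)[has_tick]))
}
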