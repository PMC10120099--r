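#' Network diameter
#'
#' Maximum unweighted shortest-path length (in edges) over node pairs of the
#' largest connected component of the undirected collapsed view.
#'
#' @param net A `spatial_network` (or igraph graph).
#' @return Integer diameter.
#' @export
net_diameter <- function(net) {
  g <- ensure_graph(net)
  if (igraph::vcount(g) == 0) stop("empty network")
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  if (igraph::vcount(sub) == 1) return(0L)
  as.integer(igraph::diameter(sub, directed = FALSE, weights = NA))
}

#' Network density measures
#'
#' Three candidate definitions are computed and returned together:
#' `edge_density` (links over possible links, the headline value),
#' `clustering` (global transitivity: closed triplets over all triplets) and
#' `degree_heterogeneity` (variance over mean of the degree distribution).
#'
#' @param net A `spatial_network` (or igraph graph).
#' @param mode Which value to report as `$value`.
#' @return List with the three measures and `value`.
#' @export
net_density <- function(net, mode = c("edge_density", "clustering",
                                      "degree_heterogeneity")) {
  mode <- match.arg(mode)
  g <- ensure_graph(net)
  n <- igraph::vcount(g)
  if (n < 2) stop("density needs at least 2 nodes")
  deg <- igraph::degree(g)
  out <- list(
    edge_density = igraph::ecount(g) / (n * (n - 1) / 2),
    clustering = igraph::transitivity(g, type = "global"),
    degree_heterogeneity = stats::var(deg) / mean(deg))
  out$value <- out[[mode]]
  out
}

#' Node degree and betweenness
#'
#' Degree counts distinct neighbours in the undirected collapsed view.
#' Betweenness is the unweighted shortest-path betweenness
#' (sum over unordered pairs s != t != v of the fraction of s-t shortest
#' paths through v), unnormalized.
#'
#' @param net A `spatial_network` (or igraph graph).
#' @param node Optional node id; default all nodes.
#' @return Named numeric vector (or scalar if `node` given).
#' @export
node_degree <- function(net, node = NULL) {
  g <- ensure_graph(net)
  d <- igraph::degree(g)
  pick_node(d, node)
}

#' @rdname node_degree
#' @export
node_betweenness <- function(net, node = NULL) {
  g <- ensure_graph(net)
  b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  pick_node(b, node)
}

pick_node <- function(v, node) {
  if (is.null(node)) return(v)
  if (!node %in% names(v)) stop("unknown node: ", node)
  v[[node]]
}

ensure_graph <- function(net) {
  if (inherits(net, "igraph")) return(net)
  if (inherits(net, "spatial_network")) return(as_igraph(net))
  stop("expected a spatial_network or igraph graph")
}

#' Summary of all network- and node-level metrics
#'
#' @param net A `spatial_network`.
#' @return List with `network` (n_nodes, n_links, diameter, the three
#'   density measures) and `nodes` (data frame of degree and betweenness,
#'   with hubs flagged as the top betweenness decile).
#' @export
network_metrics <- function(net) {
  g <- ensure_graph(net)
  n <- igraph::vcount(g)
  deg <- node_degree(net)
  btw <- node_betweenness(net)
  dens <- if (n >= 2) net_density(net) else
    list(edge_density = NA, clustering = NA, degree_heterogeneity = NA)
  hub_cut <- stats::quantile(btw, 0.9, names = FALSE)
  list(network = data.frame(
         status = if (!is.null(net$status)) net$status else NA,
         n_nodes = n, n_links = igraph::ecount(g),
         diameter = if (n) net_diameter(net) else NA,
         edge_density = dens$edge_density,
         clustering = dens$clustering,
         degree_heterogeneity = dens$degree_heterogeneity),
       nodes = data.frame(node_id = names(deg), degree = unname(deg),
                          betweenness = unname(btw),
                          hub = unname(btw >= hub_cut & btw > 0),
                          stringsAsFactors = FALSE))
}

#' Hub nodes: top decile of betweenness
#' @param net A `spatial_network`.
#' @return Character vector of node ids.
#' @export
hubs <- function(net) {
  m <- network_metrics(net)
  m$nodes$node_id[m$nodes$hub]
}
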