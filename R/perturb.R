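#' Define a node-removal scenario
#'
#' @param mode `"random"` (uniformly random nodes, the stochastic baseline)
#'   or `"targeted"` (only nodes carrying `target_feature`, removed in a
#'   random order until none is left).
#' @param target_feature Resource type defining targeted removal; for a
#'   random scenario it sets the matched number of removal steps.
#' @param n_runs Number of independent removal sequences (default 1000).
#' @param seed Scenario seed; run `i` uses the derived substream `i`.
#' @param n_steps Override the number of steps for random scenarios.
#' @return A `removal_scenario` object.
#' @export
removal_scenario <- function(mode = c("random", "targeted"),
                             target_feature = NULL, n_runs = 1000,
                             seed = 1, n_steps = NULL) {
  mode <- match.arg(mode)
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (mode == "targeted" && is.null(target_feature))
    stop("targeted removal needs a target feature")
  structure(list(mode = mode, target_feature = target_feature,
                 n_runs = n_runs, seed = seed, n_steps = n_steps),
            class = "removal_scenario")
}

#' Run a node-removal perturbation experiment
#'
#' Per run, nodes are removed one by one (a random permutation of the
#' feature-bearing nodes for targeted scenarios; uniformly random nodes for
#' random scenarios) and the betweenness of every remaining node is
#' recomputed after each removal and summarized as its mean. Step 0 is the
#' intact network.
#'
#' @param net A `spatial_network`.
#' @param scenario A [removal_scenario()].
#' @param features Node-feature data frame with `node_id` and `resource`
#'   (needed to resolve `target_feature`).
#' @return A `perturbation_result`: `runs` matrix (n_runs x steps+1) of mean
#'   betweenness over remaining nodes, and `summary` (per step: mean, q05,
#'   q95).
#' @export
run_removal <- function(net, scenario, features = NULL) {
  stopifnot(inherits(scenario, "removal_scenario"))
  g0 <- ensure_graph(net)
  n <- igraph::vcount(g0)
  if (n == 0) stop("empty network")
  feature_nodes <- NULL
  if (!is.null(scenario$target_feature)) {
    if (is.null(features))
      stop("a feature table is needed to resolve the target feature")
    feature_nodes <- intersect(
      features$node_id[features$resource == scenario$target_feature],
      igraph::V(g0)$name)
    if (scenario$mode == "targeted" && !length(feature_nodes))
      stop("no node carries the target feature")
  }
  steps <- if (scenario$mode == "targeted") length(feature_nodes)
           else if (!is.null(scenario$n_steps)) scenario$n_steps
           else if (length(feature_nodes)) length(feature_nodes)
           else n - 1L
  steps <- min(steps, n)
  b0 <- mean(igraph::betweenness(g0, directed = FALSE, weights = NA))
  runs <- matrix(NA_real_, scenario$n_runs, steps + 1)
  runs[, 1] <- b0
  all_nodes <- igraph::V(g0)$name
  for (r in seq_len(scenario$n_runs)) {
    set.seed(substream_seed(scenario$seed,
                            paste0("perturb.", scenario$mode, ".", r)))
    order_r <- if (scenario$mode == "targeted")
      sample(feature_nodes, length(feature_nodes)) else
      sample(all_nodes, steps)
    g <- g0
    for (s in seq_len(steps)) {
      g <- igraph::delete_vertices(g, order_r[s])
      runs[r, s + 1] <- if (igraph::vcount(g))
        mean(igraph::betweenness(g, directed = FALSE, weights = NA)) else NA
    }
  }
  summ <- data.frame(step = 0:steps,
                     mean = colMeans(runs),
                     q05 = apply(runs, 2, stats::quantile, 0.05, na.rm = TRUE),
                     q95 = apply(runs, 2, stats::quantile, 0.95, na.rm = TRUE))
  structure(list(mode = scenario$mode, feature = scenario$target_feature,
                 runs = runs, summary = summ),
            class = "perturbation_result")
}

#' Compare random and targeted removal with per-step paired T-tests
#'
#' Pairs run i of the random scenario with run i of the targeted scenario at
#' every removal step and reports the paired T statistic, p-value and
#' significance stars. When all pairwise differences are zero the T
#' statistic is 0 and p is 1 by convention.
#'
#' @param random_result,targeted_result `perturbation_result`s with equal
#'   run and step counts.
#' @return Data frame: step, mean_random, mean_targeted, t, p, stars.
#' @export
compare_scenarios <- function(random_result, targeted_result) {
  a <- random_result$runs; b <- targeted_result$runs
  if (!all(dim(a) == dim(b)))
    stop("mismatched run or step counts between scenarios")
  rows <- lapply(seq_len(ncol(a)), function(s) {
    d <- b[, s] - a[, s]
    d <- d[is.finite(d)]
    if (length(d) < 2 || stats::sd(d) == 0) {
      t <- 0; p <- 1
    } else {
      tt <- stats::t.test(d)
      t <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(step = s - 1,
               mean_random = mean(a[, s], na.rm = TRUE),
               mean_targeted = mean(b[, s], na.rm = TRUE),
               t = t, p = p, stars = p_stars(p))
  })
  do.call(rbind, rows)
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Betweenness by resource group after removing all feature nodes
#'
#' Removes every node carrying `removed_feature` (e.g. all landfill nodes),
#' recomputes betweenness on the remaining graph, and summarizes it per
#' remaining resource group.
#'
#' @param net A `spatial_network`.
#' @param features Node-feature data frame (`node_id`, `resource`).
#' @param removed_feature Resource type to remove entirely.
#' @return Data frame: resource, n, mean_betweenness, q05, q95.
#' @export
resource_summary_after_removal <- function(net, features,
                                           removed_feature = "landfill") {
  g <- ensure_graph(net)
  res <- stats::setNames(features$resource, features$node_id)
  victims <- intersect(names(res)[res == removed_feature],
                       igraph::V(g)$name)
  if (length(victims) == igraph::vcount(g))
    stop("all nodes carry the removed feature")
  g2 <- igraph::delete_vertices(g, victims)
  btw <- igraph::betweenness(g2, directed = FALSE, weights = NA)
  grp <- res[names(btw)]
  grp[is.na(grp)] <- "other"
  out <- lapply(split(btw, grp), function(v)
    data.frame(n = length(v), mean_betweenness = mean(v),
               q05 = stats::quantile(v, 0.05, names = FALSE),
               q95 = stats::quantile(v, 0.95, names = FALSE)))
  cbind(data.frame(resource = names(out)), do.call(rbind, out),
        row.names = NULL)
}
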