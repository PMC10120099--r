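#' Run the full spatial-use network analysis on a simulated population
#'
#' Chains every stage: simulate the tracked population, estimate
#' individual-year dynamic Brownian bridge UDs, average them to the
#' population UD, extract the 50% contour nodes, label fixes, extract
#' movement paths, build the status networks, compute node features and
#' metrics, fit the status contrasts and node regressions, and run the
#' landfill perturbation comparison.
#'
#' @param seed Root seed for all stochastic stages.
#' @param n_nonbreeders,n_breeders Population composition.
#' @param seasons Tracking seasons (default two 150-day summer windows).
#' @param cell_m UD grid cell size (metres, default 500).
#' @param contour_level UD contour defining nodes (default 0.50).
#' @param min_duration_s Movement-path duration filter (default 3600 s).
#' @param n_runs Perturbation runs per scenario (default 1000).
#' @param perturb_feature Feature targeted in the perturbation comparison.
#' @return List with every intermediate artifact (simulation, uds,
#'   population_ud, nodes, labeled, paths, networks, features, metrics,
#'   iy_networks, anova, pca, models, perturbation).
#' @export
run_pipeline <- function(seed = 1, n_nonbreeders = 10, n_breeders = 6,
                         seasons = default_seasons(), cell_m = 500,
                         contour_level = 0.5, min_duration_s = 3600,
                         n_runs = 1000, perturb_feature = "landfill") {
  sim <- simulate_population(n_nonbreeders, n_breeders,
                             seed = substream_seed(seed, "simulate"),
                             seasons = seasons)
  iy <- individual_year_uds(sim$trajectories, cell_m = cell_m)
  population_ud <- average_uds(iy$uds)
  nodes <- extract_contour(population_ud, level = contour_level)
  labeled <- label_fixes(sim$trajectories, nodes)
  paths <- extract_paths(labeled, min_duration_s = min_duration_s)
  networks <- list(
    non_breeder = build_network(paths, "non_breeder", nodes),
    breeder = build_network(paths, "breeder", nodes))
  features <- node_features(nodes, labeled, population_ud,
                            sim$landscape$sites, sim$landscape$landcover)
  metrics <- lapply(networks, network_metrics)
  iy_networks <- individual_year_networks(paths)

  anova <- list(
    n_nodes = anova_status(iy_networks$n_nodes, iy_networks$status),
    n_links = anova_status(iy_networks$n_links, iy_networks$status),
    diameter = anova_status(iy_networks$diameter, iy_networks$status))

  models <- list()
  pca <- NULL
  lc_cols <- LANDCOVER_CLASSES
  for (st in names(networks)) {
    nm <- metrics[[st]]$nodes
    fe <- features[features$status == st &
                     features$node_id %in% nm$node_id, ]
    fe <- merge(fe, nm, by = "node_id")
    if (nrow(fe) >= 4) {
      pca_st <- tryCatch(pca_landcover(fe[, lc_cols]), error = function(e) NULL)
      if (!is.null(pca_st))
        for (j in seq_len(pca_st$n_retained))
          fe[[paste0("PC", j)]] <- pca_st$scores[, j]
      if (st == "non_breeder") pca <- pca_st
      n_pcs <- if (is.null(pca_st)) 0 else pca_st$n_retained
      models[[st]] <- lapply(
        c(log_revisits = "log_revisits", log_residence = "log_residence",
          log_degree = "log_degree", betweenness = "betweenness"),
        function(resp) tryCatch(
          fit_node_models(fe, resp, status = st, n_pcs = n_pcs),
          error = function(e) NULL))
    }
  }

  perturbation <- list()
  for (st in names(networks)) {
    net <- networks[[st]]
    fe <- features[features$status == st, c("node_id", "resource")]
    n_feature <- sum(fe$resource == perturb_feature &
                       fe$node_id %in% net$node_ids)
    if (n_feature >= 1 && length(net$node_ids) > n_feature) {
      tg <- run_removal(net, removal_scenario(
        "targeted", perturb_feature, n_runs = n_runs,
        seed = substream_seed(seed, paste0("perturb.targeted.", st))),
        features = fe)
      rd <- run_removal(net, removal_scenario(
        "random", perturb_feature, n_runs = n_runs,
        seed = substream_seed(seed, paste0("perturb.random.", st))),
        features = fe)
      perturbation[[st]] <- list(
        targeted = tg, random = rd,
        comparison = compare_scenarios(rd, tg),
        post_removal = resource_summary_after_removal(net, fe,
                                                      perturb_feature))
    }
  }

  list(seed = seed, simulation = sim, uds = iy, population_ud = population_ud,
       nodes = nodes, labeled = labeled, paths = paths, networks = networks,
       features = features, metrics = metrics, iy_networks = iy_networks,
       anova = anova, pca = pca, models = models,
       perturbation = perturbation)
}
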