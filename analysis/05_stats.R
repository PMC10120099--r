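#!/usr/bin/env Rscript
# Stage 5: statistical models. ANOVA status contrasts on the individual-year
# network metrics, covariance PCA of node land cover, and the
# status-specific node regressions with drop-one F-ratio importance.

library(scavnet)

outdir <- "results"
iy <- utils::read.csv(file.path(outdir, "individual_year_networks.csv"))
features <- utils::read.csv(file.path(outdir, "node_features.csv"))

# status contrasts (unit of observation: individual-year network)
contrasts <- do.call(rbind, lapply(
  c("n_nodes", "n_links", "diameter", "edge_density"), function(v) {
    keep <- is.finite(iy[[v]])
    a <- anova_status(iy[[v]][keep], iy$status[keep])
    data.frame(metric = v, F = a$F, df1 = a$df1, df2 = a$df2, p = a$p)
  }))
utils::write.csv(contrasts, file.path(outdir, "anova_contrasts.csv"),
                 row.names = FALSE)
print(contrasts)

lc_cols <- c("FOR", "PAS", "SCR", "IRR", "NIC", "TREE", "ROC", "URB", "OTH")
for (st in c("non_breeder", "breeder")) {
  nm <- utils::read.csv(file.path(outdir, paste0("node_metrics_", st, ".csv")))
  fe <- merge(features[features$status == st, ], nm, by = "node_id")
  if (nrow(fe) < 5) next
  pca <- tryCatch(pca_landcover(fe[, lc_cols]), error = function(e) NULL)
  n_pcs <- 0
  if (!is.null(pca)) {
    n_pcs <- pca$n_retained
    for (j in seq_len(n_pcs)) fe[[paste0("PC", j)]] <- pca$scores[, j]
    utils::write.csv(pca$loadings,
                     file.path(outdir, paste0("pca_loadings_", st, ".csv")))
    cat(sprintf("%s: %d PCs retained (%.0f%% variance)\n", st, n_pcs,
                100 * sum(pca$variance_explained[seq_len(n_pcs)])))
  }
  for (resp in c("log_revisits", "log_residence", "log_degree",
                 "betweenness")) {
    m <- tryCatch(suppressWarnings(
      fit_node_models(fe, resp, status = st, n_pcs = n_pcs)),
      error = function(e) NULL)
    if (is.null(m)) next
    write_regression_csv(m, file.path(outdir,
                                      paste0("model_", st, "_", resp, ".csv")))
    cat(sprintf("%s %s: R^2 = %.2f\n", st, resp, m$r2))
  }
}
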