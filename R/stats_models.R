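#' One-way ANOVA status contrast
#'
#' F-test for differences between groups (e.g. non-breeders vs breeders) in
#' a network-level metric, with individual-year networks as the unit of
#' observation.
#'
#' @param values Numeric response per observation.
#' @param groups Grouping factor (>= 2 levels, >= 2 observations each).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_status <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 observations")
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  out <- list(F = s[["F value"]][1], df1 = s[["Df"]][1], df2 = s[["Df"]][2],
              p = s[["Pr(>F)"]][1])
  # degenerate data (no between-group variation): F = 0, p = 1 by convention
  if (s[["Sum Sq"]][1] == 0) {
    out$F <- 0
    out$p <- 1
  }
  out
}

#' Covariance PCA of node land-cover composition
#'
#' Principal components from the covariance matrix (no correlation scaling)
#' of the nine land-cover percentages, retaining the smallest number of
#' components whose cumulative variance reaches `var_threshold`.
#'
#' @param x Numeric matrix or data frame, nodes x 9 classes.
#' @param var_threshold Cumulative variance to retain (default 0.75).
#' @return List with `loadings`, `variance_explained`, `scores`,
#'   `n_retained`.
#' @export
pca_landcover <- function(x, var_threshold = 0.75) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 nodes")
  if (all(apply(x, 2, stats::var) == 0))
    stop("constant composition matrix: zero covariance")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  n_keep <- which(cumsum(ve) >= var_threshold)[1]
  list(loadings = pr$rotation, variance_explained = ve,
       scores = pr$x, n_retained = n_keep)
}

#' Status-specific node regression with drop-one F-ratio importance
#'
#' Ordinary least squares of a node response on resource type (reference
#' level `other`), a roost flag (non-breeders), a breeding-territory flag
#' (breeders only) and retained land-cover principal components. The
#' importance of every explanatory variable is the F-ratio test comparing
#' the full model against the model without that variable. A backward
#' AIC-selected model is reported alongside the full fit.
#'
#' @param features Node-feature rows for one status (see [node_features()]),
#'   optionally with PC score columns `PC1`, `PC2`, ...
#' @param response One of `log_revisits`, `log_residence`, `log_degree`,
#'   `betweenness` (log responses use the natural log; `log1p = TRUE`
#'   switches to log1p for data where zeros can occur).
#' @param status `"non_breeder"` or `"breeder"` (decides which ecological
#'   flag enters the model).
#' @param n_pcs Number of PC score columns to include (0 = none).
#' @param log1p Use log1p instead of log for log responses.
#' @param select Also run backward elimination by AIC.
#' @return A `node_model` list: `fit` (full lm), `selected` (lm after AIC
#'   backward elimination), `table` (term, E, SE, LL, UL, P), `drop1`
#'   (per-variable F and P), `r2`, `response`, `status`.
#' @export
fit_node_models <- function(features, response = c("log_revisits",
                                                   "log_residence",
                                                   "log_degree",
                                                   "betweenness"),
                            status = c("non_breeder", "breeder"),
                            n_pcs = 0, log1p = FALSE, select = TRUE) {
  response <- match.arg(response)
  status <- match.arg(status)
  tl <- if (log1p) base::log1p else base::log
  y <- switch(response,
              log_revisits = tl(features$revisits),
              log_residence = tl(features$residence_s),
              log_degree = tl(features$degree),
              betweenness = features$betweenness)
  df <- data.frame(y = y,
                   resource = factor(features$resource,
                                     levels = RESOURCE_TYPES_REF))
  if (status == "non_breeder" && "roost" %in% names(features))
    df$roost <- factor(features$roost, levels = c(FALSE, TRUE),
                       labels = c("NO", "YES"))
  if (status == "breeder" && "breeding_territory" %in% names(features))
    df$breeding_territory <- factor(features$breeding_territory,
                                    levels = c(FALSE, TRUE),
                                    labels = c("NO", "YES"))
  if (n_pcs > 0)
    for (j in seq_len(n_pcs)) df[[paste0("PC", j)]] <- features[[paste0("PC", j)]]
  keep <- stats::complete.cases(df) & is.finite(df$y)
  df <- df[keep, , drop = FALSE]
  # drop single-level factors (e.g. no roost node in this network)
  for (v in setdiff(names(df), "y"))
    if (is.factor(df[[v]]) && length(unique(df[[v]])) < 2) df[[v]] <- NULL
  fit <- stats::lm(y ~ ., data = df)
  if (anyNA(stats::coef(fit))) {
    warning("rank-deficient design: dropping aliased terms")
    alias_tms <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    drop_vars <- unique(unlist(lapply(setdiff(names(df), "y"), function(v)
      if (any(startsWith(alias_tms, v))) v)))
    df <- df[, !(names(df) %in% drop_vars), drop = FALSE]
    fit <- stats::lm(y ~ ., data = df)
  }
  sm <- summary(fit)
  ci <- stats::confint(fit)
  d1 <- stats::drop1(fit, test = "F")
  tab <- data.frame(term = rownames(sm$coefficients),
                    E = sm$coefficients[, 1], SE = sm$coefficients[, 2],
                    LL = ci[, 1], UL = ci[, 2],
                    P = sm$coefficients[, 4], row.names = NULL)
  d1_tab <- data.frame(variable = rownames(d1)[-1],
                       F = d1[["F value"]][-1], P = d1[["Pr(>F)"]][-1],
                       row.names = NULL)
  selected <- if (select && length(stats::coef(fit)) > 1)
    stats::step(fit, direction = "backward", trace = 0) else fit
  structure(list(fit = fit, selected = selected, table = tab,
                 drop1 = d1_tab, r2 = sm$r.squared,
                 response = response, status = status, data = df),
            class = "node_model")
}

# resource factor levels with the unpredictable baseline first
RESOURCE_TYPES_REF <- c("other", "extensive_livestock", "intensive_farm",
                        "landfill", "vulture_restaurant")

#' @export
print.node_model <- function(x, ...) {
  cat(sprintf("node_model: %s ~ . (%s), R^2 = %.3f\n", x$response,
              x$status, x$r2))
  print(x$table, digits = 3)
  invisible(x)
}

#' Write a regression table as CSV (E, SE, LL, UL, P, R2 layout)
#' @param model A `node_model`.
#' @param path Output file.
#' @export
write_regression_csv <- function(model, path) {
  tab <- model$table
  tab$R2 <- c(model$r2, rep(NA, nrow(tab) - 1))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
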