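test_that("ANOVA matches hand computation and degenerate conventions", {
  # identical groups: F = 0, p = 1 by convention
  r0 <- anova_status(c(5, 5, 5, 5), c("a", "a", "b", "b"))
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)

  # hand computation: SSB = 150 on 1 df, SSW = 4 on 4 df -> F = 150
  r <- anova_status(c(1, 2, 3, 11, 12, 13), rep(c("nb", "b"), each = 3))
  expect_equal(r$F, 150, tolerance = 1e-10)
  expect_equal(r$df1, 1)
  expect_equal(r$df2, 4)

  expect_error(anova_status(1:3, c("a", "a", "b")), "at least 2 observations")
  expect_error(anova_status(1:3, c("a", "a", "a")), "at least 2 groups")
})

test_that("the F-test p-value agrees with a permutation oracle", {
  set.seed(55)
  x <- c(stats::rnorm(12, 0), stats::rnorm(12, 0.9))
  grp <- rep(c("a", "b"), each = 12)
  p_f <- anova_status(x, grp)$p
  fstat <- function(vals) anova_status(vals, grp)$F
  f_obs <- fstat(x)
  perms <- replicate(1000, fstat(sample(x)))
  p_perm <- mean(perms >= f_obs)
  expect_lt(abs(p_f - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 1000) + 0.01)
})

test_that("covariance PCA retains variance structure", {
  # data on a line in 9-space -> PC1 explains everything
  set.seed(61)
  t <- stats::rnorm(30)
  dir <- stats::runif(9)
  x <- outer(t, dir)
  pc <- pca_landcover(x)
  expect_equal(pc$variance_explained[1], 1, tolerance = 1e-10)
  expect_equal(pc$n_retained, 1)

  # isotropic noise: each PC near 1/9
  xi <- matrix(stats::rnorm(9 * 3000), 3000, 9)
  pci <- pca_landcover(xi)
  expect_true(all(abs(pci$variance_explained - 1 / 9) < 0.02))
  expect_true(all(diff(pci$variance_explained) <= 1e-12))
  # scores have zero mean per component
  expect_true(all(abs(colMeans(pci$scores)) < 1e-10))
  # loadings are orthonormal
  expect_equal(crossprod(pci$loadings), diag(9), tolerance = 1e-10,
               ignore_attr = TRUE)

  # planted forest vs non-irrigated anticorrelation shows in PC1 signs
  n <- 200
  f <- stats::runif(n, 10, 60)
  xp <- matrix(5, n, 9, dimnames = list(NULL, c("FOR", "PAS", "SCR", "IRR",
                                                "NIC", "TREE", "ROC", "URB",
                                                "OTH")))
  xp[, "FOR"] <- f
  xp[, "NIC"] <- 70 - f
  xp <- xp + matrix(stats::rnorm(n * 9, 0, 0.5), n, 9)
  pcp <- pca_landcover(xp)
  expect_lt(pcp$loadings["FOR", 1] * pcp$loadings["NIC", 1], 0)

  expect_error(pca_landcover(matrix(3, 5, 9)), "constant")
})

test_that("node regressions recover planted effects exactly and honour scope", {
  # exact fit: log revisits = 2 * PC1 with no noise
  n <- 30
  fe <- data.frame(revisits = 1, residence_s = 1, degree = 1, betweenness = 0,
                   resource = "other", roost = FALSE,
                   PC1 = stats::rnorm(n))
  fe$revisits <- exp(2 * fe$PC1)
  # a zero-residual fit makes summary()/drop1() warn about perfect fits
  m <- suppressWarnings(fit_node_models(fe, "log_revisits", "non_breeder",
                                        n_pcs = 1, select = FALSE))
  expect_equal(m$table$E[m$table$term == "PC1"], 2, tolerance = 1e-8)
  expect_equal(m$r2, 1, tolerance = 1e-8)

  # the breeding-territory flag enters only the breeder model
  fe2 <- data.frame(revisits = exp(stats::rnorm(20) + 1),
                    residence_s = 1, degree = 1, betweenness = 0,
                    resource = rep(c("landfill", "other"), 10),
                    roost = rep(c(TRUE, TRUE, FALSE, FALSE), 5),
                    breeding_territory = rep(c(TRUE, FALSE), each = 10))
  mb <- fit_node_models(fe2, "log_revisits", "breeder", select = FALSE)
  mn <- fit_node_models(fe2, "log_revisits", "non_breeder", select = FALSE)
  expect_true(any(grepl("breeding_territory", mb$table$term)))
  expect_false(any(grepl("breeding_territory", mn$table$term)))
  expect_true(any(grepl("roost", mn$table$term)))
  expect_false(any(grepl("roost", mb$table$term)))
})

test_that("drop-one F equals the squared t statistic for single-df terms", {
  set.seed(71)
  n <- 40
  fe <- data.frame(revisits = exp(stats::rnorm(n)),
                   residence_s = 1, degree = 1, betweenness = 0,
                   resource = "other",
                   PC1 = stats::rnorm(n), PC2 = stats::rnorm(n))
  m <- fit_node_models(fe, "log_revisits", "non_breeder", n_pcs = 2,
                       select = FALSE)
  sm <- summary(m$fit)$coefficients
  for (v in c("PC1", "PC2")) {
    Fv <- m$drop1$F[m$drop1$variable == v]
    expect_equal(Fv, unname(sm[v, "t value"]^2), tolerance = 1e-8)
  }
})

test_that("planted landfill effects are detected with the expected power", {
  set.seed(81)
  hits <- 0
  for (i in 1:100) {
    resource <- rep(c("landfill", "other", "extensive_livestock"),
                    c(10, 15, 15))
    y <- 1 + 2 * (resource == "landfill") + stats::rnorm(40)
    fe <- data.frame(revisits = exp(y), residence_s = 1, degree = 1,
                     betweenness = 0, resource = resource)
    m <- fit_node_models(fe, "log_revisits", "non_breeder", select = FALSE)
    p <- m$table$P[m$table$term == "resourcelandfill"]
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, 90)
})

test_that("the landfill term is calibrated under the null", {
  set.seed(91)
  hits <- 0
  nsim <- 500
  for (i in seq_len(nsim)) {
    resource <- rep(c("landfill", "other", "extensive_livestock"),
                    c(10, 15, 15))
    fe <- data.frame(revisits = exp(1 + stats::rnorm(40)), residence_s = 1,
                     degree = 1, betweenness = 0, resource = resource)
    m <- fit_node_models(fe, "log_revisits", "non_breeder", select = FALSE)
    p <- m$table$P[m$table$term == "resourcelandfill"]
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / nsim, 0.02)
  expect_lte(hits / nsim, 0.08)
})
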