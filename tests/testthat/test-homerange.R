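test_that("motion variance is recovered on simulated Brownian motion", {
  set.seed(101)
  tr <- bm_track(200, sigma2 = 0.5)
  mvs <- estimate_motion_variance(tr)
  expect_equal(mean(mvs$sigma2_m), 0.5, tolerance = 0.2)
  expect_true(all(mvs$bridgeable))
})

test_that("stationary tracks with pure location error land on the floor", {
  set.seed(5)
  n <- 60
  tr <- data.frame(t = (0:(n - 1)) * 1800, x = rep(3, n), y = rep(-2, n),
                   loc_error_m = 10)
  expect_warning(mvs <- estimate_motion_variance(tr), "floor")
  expect_true(all(mvs$sigma2_m <= 2e-8))
  # non-monotone times are rejected
  bad <- tr; bad$t[5] <- bad$t[7]
  expect_error(estimate_motion_variance(bad), "increasing")
})

test_that("windowed estimate equals the static MLE when no break is allowed", {
  set.seed(7)
  tr <- bm_track(21, sigma2 = 0.8, err = 3)
  mvs <- estimate_motion_variance(tr, window = 21, margin = 11)
  # independent static MLE over the same leave-one-out likelihood
  nll <- function(s2) {
    val <- 0
    for (k in seq(2, 20, by = 2)) {
      a <- k - 1; b <- k + 1
      Tab <- tr$t[b] - tr$t[a]
      al <- (tr$t[k] - tr$t[a]) / Tab
      v <- al * (1 - al) * Tab * s2 + (1 - al)^2 * 9 + al^2 * 9
      dx <- tr$x[k] - (tr$x[a] + al * (tr$x[b] - tr$x[a]))
      dy <- tr$y[k] - (tr$y[a] + al * (tr$y[b] - tr$y[a]))
      val <- val + log(2 * pi * v) + (dx^2 + dy^2) / (2 * v)
    }
    val
  }
  static <- stats::optimize(nll, c(1e-6, 100))$minimum
  expect_equal(unique(round(mvs$sigma2_m, 6)), round(static, 6),
               tolerance = 1e-3)
})

test_that("a two-phase track yields an ordered, localized change point", {
  set.seed(13)
  tr1 <- bm_track(101, sigma2 = 0.1)
  tr2 <- bm_track(100, sigma2 = 1.0, t0 = 101 * 1800)
  tr2$x <- tr2$x + tr1$x[101]; tr2$y <- tr2$y + tr1$y[101]
  tr <- rbind(tr1, tr2)
  mvs <- estimate_motion_variance(tr)
  s <- mvs$sigma2_m
  expect_lt(mean(s[1:70]), mean(s[131:200]))
  # two-segment least-squares locator on the log variance profile
  ls <- log(s)
  sse <- vapply(20:180, function(c)
    sum((ls[1:c] - mean(ls[1:c]))^2) +
      sum((ls[(c + 1):length(ls)] - mean(ls[(c + 1):length(ls)]))^2), 0)
  cp <- (20:180)[which.min(sse)]
  expect_lt(abs(cp - 100), 15)
})

test_that("UDs normalize, match dense quadrature, and respect gaps", {
  # single segment: normalization and refinement oracle
  ref <- bridge_refinement_tv()
  expect_equal(sum(ref$ud$p), 1, tolerance = 1e-6)
  expect_lt(ref$tv, 0.01)

  # a gap longer than max_gap_s is not bridged: no mass between the bouts
  set.seed(3)
  bout1 <- bm_track(30, 0.2)
  bout2 <- bm_track(30, 0.2)
  bout2$t <- bout2$t + bout1$t[30] + 40000
  bout2$x <- bout2$x + 30000; bout2$y <- bout2$y + 30000
  tr2 <- rbind(bout1, bout2)
  mvs2 <- estimate_motion_variance(tr2)
  ud2 <- compute_ud(mvs2, cell_m = 500)
  mid <- cell_index(ud2$grid, 15000, 15000)
  expect_lt(ud2$p[mid$iy, mid$ix], 1e-9)

  expect_error(compute_ud(structure(data.frame(sigma2_m = 1,
                                               bridgeable = FALSE),
                                    class = class(mvs2),
                                    fixes = attr(mvs2, "fixes")[1:2, ])),
               "bridgeable")
})

test_that("contours are minimal, nested and split multimodal UDs", {
  g <- grid_spec(0, 0, 100, 41, 41)
  ud <- gaussian_ud(g, 2050, 2050, 400)
  ns <- extract_contour(ud, 0.5)
  expect_length(ns, 1)
  expect_gte(contour_mass(ns), 0.5)
  expect_lt(contour_mass(ns), 0.5 + max(ud$p))
  # minimality: dropping the least dense selected cell goes below the level
  cells <- ns[[1]]$cells
  masses <- ud$p[cbind(cells[, "iy"], cells[, "ix"])]
  expect_lt(contour_mass(ns) - min(masses), 0.5)

  # analytic check: the 50% mass radius of an isotropic Gaussian is
  # sd * sqrt(qchisq(0.5, 2)); the polygon area should be close to that disc
  r50 <- 400 * sqrt(stats::qchisq(0.5, 2))
  expect_equal(ns[[1]]$area_m2, pi * r50^2, tolerance = 0.15)

  # bimodal symmetric UD -> exactly two polygons
  ud2 <- ud_grid(g, gaussian_ud(g, 1000, 1000, 250)$p +
                    gaussian_ud(g, 3100, 3100, 250)$p)
  ns2 <- extract_contour(ud2, 0.5)
  expect_length(ns2, 2)

  # monotone mass in level and spatial nesting of 0.5 within 0.95
  ns95 <- extract_contour(ud, 0.95)
  expect_gt(contour_mass(ns95), contour_mass(ns))
  sel50 <- paste(ns[[1]]$cells[, 1], ns[[1]]$cells[, 2])
  sel95 <- unlist(lapply(ns95, function(nd) paste(nd$cells[, 1],
                                                  nd$cells[, 2])))
  expect_true(all(sel50 %in% sel95))

  expect_error(extract_contour(ud, 1.2), "level")
})
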