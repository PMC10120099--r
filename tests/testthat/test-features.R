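test_that("land-cover composition sums to 100 and matches constructions", {
  g <- grid_spec(0, 0, 100, 40, 40)
  # single-class region
  lc1 <- list(grid = g, m = matrix(3L, 40, 40))
  node <- square_nodes(data.frame(site_id = "A", x = 2000, y = 2000), 600)[[1]]
  pct <- landcover_composition(node, lc1)
  expect_equal(sum(pct), 100, tolerance = 0.01)
  expect_equal(unname(pct["SCR"]), 100)

  # half/half split field: 50/50 within one-cell quantization
  m <- matrix(1L, 40, 40)
  m[, 21:40] <- 5L
  lc2 <- list(grid = g, m = m)
  node2 <- square_nodes(data.frame(site_id = "B", x = 2000, y = 2000), 1000)[[1]]
  pct2 <- landcover_composition(node2, lc2)
  expect_equal(sum(pct2), 100, tolerance = 0.01)
  expect_equal(unname(pct2["FOR"]), 50, tolerance = 5)
  expect_equal(unname(pct2["NIC"]), 50, tolerance = 5)

  # node outside the raster is rejected
  far <- square_nodes(data.frame(site_id = "C", x = 99000, y = 99000), 200)[[1]]
  expect_error(landcover_composition(far, lc1), "outside")
})

test_that("resource assignment follows UD probability with predictability ties", {
  g <- grid_spec(0, 0, 500, 10, 10)
  p <- matrix(1e-4, 10, 10)
  p[3, 3] <- 0.01   # cell of the landfill site
  p[8, 8] <- 0.03   # cell of the extensive site
  ud <- ud_grid(g, p)
  node <- list(node_id = "N", polygon = cbind(x = c(0, 5000, 5000, 0, 0),
                                              y = c(0, 0, 5000, 5000, 0)))
  sites <- data.frame(site_id = c("L", "E"),
                      x = c(1250, 3750), y = c(1250, 3750),
                      rtype = c("landfill", "extensive_livestock"),
                      is_roost = FALSE, is_nest = FALSE, attractiveness = 1)
  expect_equal(assign_resource(node, ud, sites), "extensive_livestock")

  # only a landfill inside -> landfill
  expect_equal(assign_resource(node, ud, sites[1, ]), "landfill")
  # no site inside -> other
  empty_node <- list(node_id = "M", polygon = cbind(x = c(-900, -500, -500, -900, -900),
                                                    y = c(0, 0, 400, 400, 0)))
  expect_equal(assign_resource(empty_node, ud, sites), "other")
  # ties prefer the more predictable resource
  p2 <- p; p2[8, 8] <- 0.01
  expect_equal(assign_resource(node, ud_grid(g, p2), sites), "landfill")
})

test_that("node fidelity matches hand counts and doubles on duplication", {
  nodes <- square_nodes(data.frame(site_id = "A", x = 0, y = 0), 500)
  lab <- labeled_track(c("A", "A", "OUT", "A"))
  fid <- node_fidelity(lab, "A")
  expect_equal(fid$revisits, 2L)
  expect_equal(fid$residence_s, 5400)

  # an individual never entering the node
  expect_equal(node_fidelity(labeled_track(c("OUT", "OUT")), "A"),
               list(revisits = 0L, residence_s = 0))

  # concatenating a far-shifted duplicate doubles both statistics
  lab2 <- labeled_track(c("A", "A", "OUT", "A"), t0 = 86400 * 10, id = "B2")
  both <- rbind(lab, lab2)
  fid2 <- node_fidelity(both, "A")
  expect_equal(fid2$revisits, 2 * fid$revisits)
  expect_equal(fid2$residence_s, 2 * fid$residence_s)

  # status filter
  expect_equal(node_fidelity(lab, "A", status = "breeder")$revisits, 0L)
})

test_that("residence time never exceeds total tracking time per status", {
  set.seed(41)
  labels <- sample(c("A", "B", "OUT"), 400, replace = TRUE)
  lab <- labeled_track(labels)
  total <- diff(range(as.numeric(lab$timestamp_utc))) + 1800
  res <- node_fidelity(lab, "A")$residence_s + node_fidelity(lab, "B")$residence_s
  expect_lte(res, total)
})

test_that("the full feature table is well-formed on a small pipeline", {
  seas <- data.frame(start = as.Date("2019-05-01"), end = as.Date("2019-05-08"))
  sim <- simulate_population(n_nonbreeders = 3, n_breeders = 2, seed = 8,
                             seasons = seas)
  iy <- individual_year_uds(sim$trajectories)
  pud <- average_uds(iy$uds)
  nodes <- extract_contour(pud, 0.5)
  lab <- label_fixes(sim$trajectories, nodes)
  fe <- node_features(nodes, lab, pud, sim$landscape$sites,
                      sim$landscape$landcover)
  expect_equal(nrow(fe), 2 * length(nodes))
  classes <- c("FOR", "PAS", "SCR", "IRR", "NIC", "TREE", "ROC", "URB", "OTH")
  lc <- as.matrix(fe[, classes])
  expect_true(all(abs(rowSums(lc) - 100) < 0.01))
  expect_true(all(fe$resource %in% c("landfill", "intensive_farm",
                                     "vulture_restaurant",
                                     "extensive_livestock", "other")))
  expect_true(all((fe$residence_s > 0) == (fe$revisits >= 1)))
})
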