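test_that("removal on a 3-node path matches hand values and is deterministic", {
  p3 <- net_from_edges(rbind(c("a", "b"), c("b", "c")))
  fe <- data.frame(node_id = c("a", "b", "c"),
                   resource = c("other", "landfill", "other"))
  # intact: betweenness (0, 1, 0) -> mean 1/3
  sc <- removal_scenario("targeted", "landfill", n_runs = 1, seed = 4)
  res <- run_removal(p3, sc, fe)
  expect_equal(res$runs[1, 1], 1 / 3)
  expect_equal(res$runs[1, 2], 0)

  # random mode removing all nodes one at a time
  sc_all <- removal_scenario("random", n_runs = 3, seed = 4, n_steps = 2)
  r1 <- run_removal(p3, sc_all, fe)
  r2 <- run_removal(p3, sc_all, fe)
  expect_identical(r1$runs, r2$runs)
  expect_true(all(r1$runs[, 1] == 1 / 3))

  expect_error(run_removal(p3, removal_scenario("targeted", "landfill"),
                           features = NULL), "feature table")
  expect_error(run_removal(p3, removal_scenario("targeted", "vulture_restaurant"),
                           features = fe), "no node carries")
})

test_that("removing an isolated node leaves other betweenness unchanged", {
  edges <- rbind(c("a", "b"), c("b", "c"), c("c", "d"))
  net <- net_from_edges(edges)
  g <- as_igraph(net)
  g_iso <- igraph::add_vertices(g, 1, name = "iso")
  b_with <- igraph::betweenness(g_iso, directed = FALSE, weights = NA)
  b_without <- igraph::betweenness(g, directed = FALSE, weights = NA)
  expect_equal(b_with[names(b_without)], b_without)
})

test_that("a scenario compared with itself gives t = 0, p = 1", {
  fx <- hub_spoke_fixture()
  sc <- removal_scenario("random", "landfill", n_runs = 20, seed = 6)
  r <- run_removal(fx$net, sc, fx$features)
  cmp <- compare_scenarios(r, r)
  expect_true(all(cmp$t == 0))
  expect_true(all(cmp$p == 1))
  # step 0 equals the intact mean everywhere
  expect_equal(stats::sd(r$runs[, 1]), 0)

  bad <- run_removal(fx$net, removal_scenario("random", "landfill",
                                              n_runs = 10, seed = 6),
                     fx$features)
  expect_error(compare_scenarios(r, bad), "mismatched")
})

test_that("targeted hub removal degrades betweenness versus random", {
  fx <- hub_spoke_fixture()
  tg <- run_removal(fx$net, removal_scenario("targeted", "landfill",
                                             n_runs = 1000, seed = 31),
                    fx$features)
  rd <- run_removal(fx$net, removal_scenario("random", "landfill",
                                             n_runs = 1000, seed = 32),
                    fx$features)
  cmp <- compare_scenarios(rd, tg)
  final <- cmp[nrow(cmp), ]
  expect_lt(final$mean_targeted, final$mean_random)
  expect_lt(final$p, 0.05)
  expect_lt(final$t, 0)
})

test_that("random-vs-random comparisons reject at the nominal rate", {
  fx <- hub_spoke_fixture()
  set.seed(111)
  ps <- c()
  for (i in 1:200) {
    a <- run_removal(fx$net, removal_scenario("random", "landfill",
                                              n_runs = 30,
                                              seed = 1000 + 2 * i),
                     fx$features)
    b <- run_removal(fx$net, removal_scenario("random", "landfill",
                                              n_runs = 30,
                                              seed = 5000 + 2 * i),
                     fx$features)
    cmp <- compare_scenarios(a, b)
    ps <- c(ps, cmp$p[cmp$step > 0])
  }
  rate <- mean(ps < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)
})

test_that("post-removal resource summary matches constructed topologies", {
  fx <- hub_spoke_fixture()
  # no node carries the feature: grouping of intact betweenness
  fe_none <- fx$features
  fe_none$resource <- "extensive_livestock"
  s0 <- resource_summary_after_removal(fx$net, fe_none, "landfill")
  b <- node_betweenness(fx$net)
  expect_equal(s0$mean_betweenness, mean(b), tolerance = 1e-12)

  # removing both hubs isolates the spokes: all betweenness zero
  s1 <- resource_summary_after_removal(fx$net, fx$features, "landfill")
  expect_equal(s1$mean_betweenness, 0)

  # a bridged variant: extensive spokes connect the two halves after
  # removal, so the extensive group holds the central nodes
  edges <- rbind(cbind("H1", sprintf("S%d", 1:4)),
                 cbind("H2", sprintf("S%d", 5:8)),
                 c("S1", "S5"), c("S2", "S5"),
                 c("S3", "O1"), c("S7", "O2"))
  net2 <- net_from_edges(edges)
  fe2 <- data.frame(node_id = c("H1", "H2", sprintf("S%d", 1:8), "O1", "O2"),
                    resource = c("landfill", "landfill",
                                 rep("extensive_livestock", 8),
                                 "other", "other"))
  s2 <- resource_summary_after_removal(net2, fe2, "landfill")
  top <- s2$resource[which.max(s2$mean_betweenness)]
  expect_equal(top, "extensive_livestock")

  # single remaining node has betweenness zero
  tiny <- net_from_edges(rbind(c("L", "E")))
  fe_t <- data.frame(node_id = c("L", "E"),
                     resource = c("landfill", "extensive_livestock"))
  st <- resource_summary_after_removal(tiny, fe_t, "landfill")
  expect_equal(st$mean_betweenness, 0)
  fe_all <- data.frame(node_id = c("L", "E"), resource = "landfill")
  expect_error(resource_summary_after_removal(tiny, fe_all, "landfill"),
               "all nodes")
})
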