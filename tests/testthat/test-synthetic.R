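test_that("landscape generation honours counts, extent and determinism", {
  # empty site list is a valid landscape
  empty <- generate_landscape(c(landfill = 0), extent_m = 10000, seed = 3)
  expect_equal(nrow(empty$sites), 0)
  expect_true(all(empty$landcover$m %in% 1:9))

  ls <- generate_landscape(c(landfill = 2, extensive_livestock = 5),
                           extent_m = 100000, seed = 7)
  expect_equal(nrow(ls$sites), 7)
  expect_true(all(ls$sites$x >= 0 & ls$sites$x <= 100000))
  expect_true(all(ls$sites$y >= 0 & ls$sites$y <= 100000))
  expect_equal(sum(ls$sites$rtype == "landfill"), 2)

  ls2 <- generate_landscape(c(landfill = 2, extensive_livestock = 5),
                            extent_m = 100000, seed = 7)
  expect_identical(ls, ls2)

  expect_error(generate_landscape(c(landfill = 1), extent_m = -5), "positive")
  expect_error(generate_landscape(c(nonsense = 1)), "unknown resource")
})

test_that("a single-site agent stays within scatter radius of the site", {
  sites <- data.frame(site_id = "A", x = 5000, y = 5000, rtype = "landfill",
                      is_roost = FALSE, is_nest = FALSE, attractiveness = 1)
  p <- agent_profile("NB01", "non_breeder",
                     site_weights = c(A = 1), speed_mps = 10,
                     site_scatter_m = 50, commute_jitter_m = 0,
                     loc_error_m = 0,
                     seasons = data.frame(start = as.Date("2019-05-01"),
                                          end = as.Date("2019-05-05")))
  sim <- simulate_agent(p, sites, seed = 2)
  r <- sqrt((sim$trajectory$x - 5000)^2 + (sim$trajectory$y - 5000)^2)
  expect_true(all(r < 50 * 6))
  expect_true(all(sim$visit_log$site_id == "A"))
})

test_that("no fix is timestamped outside the 06:30-22:30 daylight window", {
  ls <- default_landscape(seed = 5)
  p <- default_profiles(ls$sites, n_nonbreeders = 1, n_breeders = 1,
                        seasons = data.frame(start = as.Date("2019-05-01"),
                                             end = as.Date("2019-05-15")))
  for (prof in p) {
    tr <- simulate_agent(prof, ls$sites, seed = 9)$trajectory
    hod <- as.numeric(format(tr$timestamp_utc, "%H")) +
      as.numeric(format(tr$timestamp_utc, "%M")) / 60
    expect_true(all(hod >= 6.5 & hod <= 22.5))
    expect_true(all(diff(as.numeric(tr$timestamp_utc)) > 0))
  }
})

test_that("visit-log dwell fractions converge to the site weights", {
  sites <- data.frame(site_id = c("A", "B"), x = c(0, 4000), y = c(0, 0),
                      rtype = "other", is_roost = FALSE, is_nest = FALSE,
                      attractiveness = 1)
  p <- agent_profile("NB01", "non_breeder",
                     site_weights = c(A = 0.9, B = 0.1),
                     dwell_mean_s = 3000, dwell_min_s = 600,
                     seasons = data.frame(start = as.Date("2019-04-01"),
                                          end = as.Date("2019-07-30")))
  sim <- simulate_agent(p, sites, seed = 11)
  vl <- sim$visit_log
  expect_gt(nrow(vl), 500)
  # visit-count fraction (law of large numbers on the log)
  expect_equal(mean(vl$site_id == "A"), 0.9, tolerance = 0.05)
  # dwell-time fraction
  dur <- vl$departure - vl$arrival
  expect_equal(sum(dur[vl$site_id == "A"]) / sum(dur), 0.9, tolerance = 0.05)
  # log intervals are well-formed and non-overlapping
  expect_true(all(vl$departure > vl$arrival))
  vl <- vl[order(vl$arrival), ]
  expect_true(all(vl$arrival[-1] >= vl$departure[-nrow(vl)] - 1e-6))
})

test_that("population simulation produces 16 reproducible tracks", {
  seas <- data.frame(start = as.Date("2019-05-01"), end = as.Date("2019-05-10"))
  sim <- simulate_population(seed = 42, seasons = seas)
  ids <- unique(sim$trajectories$individual_id)
  expect_length(ids, 16)
  expect_equal(sum(startsWith(ids, "NB")), 10)
  expect_equal(sum(startsWith(ids, "BR")), 6)
  ext <- 100000
  expect_true(all(sim$trajectories$x > -5000 & sim$trajectories$x < ext + 5000))

  # n_nonbreeders = 0 -> breeder tracks only
  sim_b <- simulate_population(n_nonbreeders = 0, seed = 42, seasons = seas)
  expect_true(all(sim_b$trajectories$status == "breeder"))

  # identical seed => bit-identical CSV output
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(sim$trajectories, f1)
  sim2 <- simulate_population(seed = 42, seasons = seas)
  write_trajectory_csv(sim2$trajectories, f2)
  expect_identical(readLines(f1), readLines(f2))

  # trajectory CSV round-trips
  back <- read_trajectory_csv(f1)
  expect_equal(nrow(back), nrow(sim$trajectories))
  expect_equal(back$x, sim$trajectories$x, tolerance = 1e-6)
})

test_that("rejected inputs are caught", {
  expect_error(agent_profile("X", "non_breeder", site_weights = NULL),
               "site weights")
  expect_error(agent_profile("X", "non_breeder", site_weights = c(A = -1)),
               "non-negative")
  expect_error(agent_profile("X", "breeder", site_weights = c(A = 1)),
               "nest")
  sites <- data.frame(site_id = "Z", x = 0, y = 0, rtype = "other",
                      is_roost = FALSE, is_nest = FALSE, attractiveness = 1)
  p <- agent_profile("X", "non_breeder", site_weights = c(A = 1))
  expect_error(simulate_agent(p, sites), "no weighted site")
})
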