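#' Build an agent movement profile
#'
#' Describes one simulated bird: its reproductive status, the probability
#' weights with which it targets resource sites, its commuting speed and mean
#' at-site dwell time, and its sampling regime (fix interval, daylight window,
#' tracking seasons).
#'
#' @param individual_id Identifier string.
#' @param status `"breeder"` or `"non_breeder"`.
#' @param site_weights Named non-negative vector of targeting weights over
#'   `site_id`s; renormalized internally.
#' @param nest_site_id Nest site id (breeders only).
#' @param dwell_mean_s Mean at-site dwell (seconds).
#' @param dwell_min_s Minimum dwell; total dwell is
#'   `dwell_min_s + Exponential(dwell_mean_s - dwell_min_s)`.
#' @param speed_mps Commuting speed (metres per second).
#' @param site_scatter_m SD of Gaussian scatter around a site while dwelling.
#' @param commute_jitter_m SD of Gaussian jitter around the straight commute
#'   line.
#' @param loc_error_m GPS location error SD recorded with every fix.
#' @param range_scale_m Distance-decay length for target sampling: the
#'   weight of a candidate site at distance d from the current site is
#'   multiplied by the Gaussian kernel exp(-(d / range_scale_m)^2), so trips
#'   are local with a sharp tail cut-off. `Inf` (default) disables the decay
#'   so targets are drawn from `site_weights` alone.
#' @param roost_site_ids Sites treated as long-range waypoints (communal
#'   roosts): their decay factor is floored at `roost_floor`, so they remain
#'   reachable from anywhere in the landscape.
#' @param roost_floor Minimum decay factor for roost sites (0 = no floor).
#' @param night_mode Where the bird starts each day: `"none"` (wherever it
#'   ended the previous day), `"roost"` (the nearest communal roost;
#'   non-breeder default) or `"nest"` (its nest; breeder default). The
#'   overnight relocation is unobserved: the device is off and the gap is
#'   never bridged.
#' @param fix_interval_s Fix interval (default 1800 s = 30 min).
#' @param daylight_window Device-on window, decimal hours UTC (default
#'   06:30-22:30; the device is off overnight so no night fixes exist).
#' @param seasons Data frame with `start`, `end` (Date) tracking windows.
#' @return An `agent_profile` object.
#' @export
agent_profile <- function(individual_id, status = c("non_breeder", "breeder"),
                          site_weights, nest_site_id = NULL,
                          dwell_mean_s = 9000, dwell_min_s = 2400,
                          speed_mps = 12, site_scatter_m = 150,
                          commute_jitter_m = 250, loc_error_m = 10,
                          range_scale_m = Inf,
                          roost_site_ids = character(0), roost_floor = 0,
                          night_mode = c("none", "roost", "nest"),
                          fix_interval_s = 1800,
                          daylight_window = c(6.5, 22.5),
                          seasons = default_seasons()) {
  status <- match.arg(status)
  night_mode <- match.arg(night_mode)
  if (fix_interval_s <= 0) stop("fix_interval_s must be positive")
  if (night_mode == "nest" && is.null(nest_site_id))
    stop("night_mode 'nest' needs a nest site")
  if (status == "breeder" && is.null(nest_site_id))
    stop("breeders need a nest site")
  if (status == "non_breeder" && is.null(site_weights))
    stop("non-breeders need site weights")
  if (any(site_weights < 0)) stop("site weights must be non-negative")
  if (sum(site_weights) <= 0) stop("at least one site must have positive weight")
  structure(list(individual_id = individual_id, status = status,
                 site_weights = site_weights / sum(site_weights),
                 nest_site_id = nest_site_id,
                 dwell_mean_s = dwell_mean_s, dwell_min_s = dwell_min_s,
                 speed_mps = speed_mps, site_scatter_m = site_scatter_m,
                 commute_jitter_m = commute_jitter_m,
                 loc_error_m = loc_error_m,
                 range_scale_m = range_scale_m,
                 roost_site_ids = roost_site_ids,
                 roost_floor = roost_floor, night_mode = night_mode,
                 fix_interval_s = fix_interval_s,
                 daylight_window = daylight_window, seasons = seasons),
            class = "agent_profile")
}

#' Default tracking seasons: two 150-day summer windows in consecutive years
#' @export
default_seasons <- function() {
  data.frame(start = as.Date(c("2019-03-15", "2020-03-15")),
             end = as.Date(c("2019-03-15", "2020-03-15")) + 149)
}

# per-season day table: absolute dawn time (POSIXct seconds, UTC) and the
# cumulative "active" (daylight) seconds before each day. The simulation
# clock only runs inside daylight windows: overnight the device is off and
# the bird holds its position and behavioural state.
day_table <- function(seasons, daylight_window) {
  days <- do.call(c, lapply(seq_len(nrow(seasons)), function(i)
    seq(seasons$start[i], seasons$end[i], by = "day")))
  day_len <- (daylight_window[2] - daylight_window[1]) * 3600
  dawn <- as.numeric(as.POSIXct(as.character(days), tz = "UTC")) +
    daylight_window[1] * 3600
  data.frame(dawn = dawn, active0 = (seq_along(dawn) - 1) * day_len,
             day_len = day_len)
}

active_to_abs <- function(tau, dt) {
  di <- findInterval(tau, dt$active0)
  di[di < 1] <- 1
  dt$dawn[di] + (tau - dt$active0[di])
}

abs_to_active <- function(t_abs, dt) {
  di <- findInterval(t_abs, dt$dawn)
  # dusk itself is exclusive: in active time it coincides with the next dawn
  ok <- di >= 1 & (t_abs - dt$dawn[pmax(di, 1)]) < dt$day_len[1]
  out <- rep(NA_real_, length(t_abs))
  out[ok] <- dt$active0[di[ok]] + (t_abs[ok] - dt$dawn[di[ok]])
  out
}

#' Simulate one agent's trajectory and ground-truth visit log
#'
#' The agent alternates dwells and commutes: a target site is sampled with
#' probability proportional to `site_weights` (damped by the trip-locality
#' kernel when `range_scale_m` is finite; redrawing the current site extends
#' the stay), the commute runs in a straight line at `speed_mps` with
#' isotropic Gaussian jitter, and the dwell time is `dwell_min_s` plus an
#' exponential excess, with Gaussian scatter around the site. The
#' behavioural clock runs only inside the daylight window of season days;
#' overnight the device is off and birds with a fixed night site (roost or
#' nest) restart there at dawn, departing shortly after with a decay-free
#' commute to the day's foraging area. Fixes are emitted at `fix_interval_s`
#' ticks inside the daylight window, with Gaussian location error.
#'
#' @param profile An [agent_profile()].
#' @param sites Site data frame (see [generate_landscape()]).
#' @param seed Integer seed.
#' @return List with `trajectory` (data frame: individual_id, status,
#'   timestamp_utc, x, y, loc_error_m) and `visit_log` (data frame: site_id,
#'   arrival, departure; one row per daylight-window dwell interval).
#' @export
simulate_agent <- function(profile, sites, seed = 1) {
  stopifnot(inherits(profile, "agent_profile"))
  w <- profile$site_weights
  w <- w[names(w) %in% sites$site_id]
  if (!length(w) || sum(w) <= 0)
    stop("no weighted site present in the site table")
  set.seed(seed)
  dt <- day_table(profile$seasons, profile$daylight_window)
  total_active <- dt$active0[nrow(dt)] + dt$day_len[1]
  sx <- stats::setNames(sites$x, sites$site_id)
  sy <- stats::setNames(sites$y, sites$site_id)

  # build the alternating dwell/commute event list in active (daylight) time,
  # day by day: each day starts at the night site (roost / nest / wherever
  # the bird ended), and segments are truncated at dusk
  draw_target <- function(cur, local = TRUE) {
    w2 <- w
    if (local && is.finite(profile$range_scale_m)) {
      dall <- sqrt((sx[names(w)] - sx[cur])^2 + (sy[names(w)] - sy[cur])^2)
      decay <- exp(-(dall / profile$range_scale_m)^2)
      is_roost <- names(w) %in% profile$roost_site_ids
      decay[is_roost] <- pmax(decay[is_roost], profile$roost_floor)
      w2 <- w * decay
    }
    if (length(w2) == 1) names(w2) else sample(names(w2), 1, prob = w2)
  }
  roost_ids <- intersect(profile$roost_site_ids, names(w))
  cur <- if (!is.null(profile$nest_site_id)) profile$nest_site_id else
    sample(names(w), 1, prob = w)
  seg_type <- character(0); seg_site <- character(0)
  seg_t0 <- numeric(0); seg_t1 <- numeric(0)
  seg_x0 <- numeric(0); seg_y0 <- numeric(0)
  seg_x1 <- numeric(0); seg_y1 <- numeric(0)
  k <- 0L
  excess <- max(profile$dwell_mean_s - profile$dwell_min_s, 1)
  day_len <- dt$day_len[1]
  for (j in seq_len(nrow(dt))) {
    if (profile$night_mode == "roost" && length(roost_ids)) {
      cur <- roost_ids[which.min((sx[roost_ids] - sx[cur])^2 +
                                   (sy[roost_ids] - sy[cur])^2)]
    } else if (profile$night_mode == "nest") {
      cur <- profile$nest_site_id
    }
    tau <- 0
    while (tau < day_len) {
      # birds with a fixed night site depart it shortly after dawn; later
      # dwells follow the profile's dwell distribution
      dwell <- if (tau == 0 && profile$night_mode != "none")
        profile$dwell_min_s + stats::rexp(1, 1 / 600) else
        profile$dwell_min_s + stats::rexp(1, 1 / excess)
      k <- k + 1L
      seg_type[k] <- "dwell"; seg_site[k] <- cur
      seg_t0[k] <- dt$active0[j] + tau
      seg_t1[k] <- dt$active0[j] + min(tau + dwell, day_len)
      seg_x0[k] <- sx[cur]; seg_y0[k] <- sy[cur]
      seg_x1[k] <- sx[cur]; seg_y1[k] <- sy[cur]
      tau <- tau + dwell
      if (tau >= day_len) break
      # the current site may be redrawn: the dwell then simply continues,
      # logged as a fresh visit entry. The first trip of the day from a
      # fixed night site is a commute to the day's foraging area, drawn from
      # the full site weights without the trip-locality decay.
      first_trip <- k > 0L && seg_t0[k] == dt$active0[j] &&
        profile$night_mode != "none"
      nxt <- draw_target(cur, local = !first_trip)
      if (nxt == cur) next
      d <- sqrt((sx[nxt] - sx[cur])^2 + (sy[nxt] - sy[cur])^2)
      cdur <- max(d / profile$speed_mps, 1)
      frac <- min((day_len - tau) / cdur, 1)
      k <- k + 1L
      seg_type[k] <- "commute"; seg_site[k] <- NA_character_
      seg_t0[k] <- dt$active0[j] + tau
      seg_t1[k] <- dt$active0[j] + tau + frac * cdur
      seg_x0[k] <- sx[cur]; seg_y0[k] <- sy[cur]
      seg_x1[k] <- sx[cur] + frac * (sx[nxt] - sx[cur])
      seg_y1[k] <- sy[cur] + frac * (sy[nxt] - sy[cur])
      tau <- tau + cdur
      cur <- nxt
    }
  }

  # fix ticks: absolute multiples of the fix interval inside daylight windows
  t0 <- dt$dawn[1]
  t_end <- dt$dawn[nrow(dt)] + dt$day_len[1]
  ticks <- seq(ceiling(t0 / profile$fix_interval_s) * profile$fix_interval_s,
               t_end, by = profile$fix_interval_s)
  tau_ticks <- abs_to_active(ticks, dt)
  keep <- !is.na(tau_ticks) & tau_ticks <= total_active
  ticks <- ticks[keep]; tau_ticks <- tau_ticks[keep]

  si <- findInterval(tau_ticks, seg_t0)
  si[si < 1] <- 1
  frac <- (tau_ticks - seg_t0[si]) / pmax(seg_t1[si] - seg_t0[si], 1e-9)
  frac <- pmin(pmax(frac, 0), 1)
  bx <- seg_x0[si] + frac * (seg_x1[si] - seg_x0[si])
  by <- seg_y0[si] + frac * (seg_y1[si] - seg_y0[si])
  n <- length(ticks)
  sdv <- ifelse(seg_type[si] == "dwell", profile$site_scatter_m,
                profile$commute_jitter_m)
  x <- bx + stats::rnorm(n, 0, sdv) + stats::rnorm(n, 0, profile$loc_error_m)
  y <- by + stats::rnorm(n, 0, sdv) + stats::rnorm(n, 0, profile$loc_error_m)

  traj <- data.frame(individual_id = profile$individual_id,
                     status = profile$status,
                     timestamp_utc = as.POSIXct(ticks, tz = "UTC",
                                                origin = "1970-01-01"),
                     x = x, y = y, loc_error_m = profile$loc_error_m,
                     stringsAsFactors = FALSE)

  # ground-truth visit log: dwell segments clipped to daylight windows so a
  # dwell spanning the night splits into one interval per day
  logs <- list()
  di <- which(seg_type == "dwell")
  day_starts <- dt$active0
  day_ends <- dt$active0 + dt$day_len
  for (i in di) {
    a <- seg_t0[i]; b <- min(seg_t1[i], total_active)
    j0 <- findInterval(a, day_starts); j1 <- findInterval(b - 1e-9, day_starts)
    for (j in j0:j1) {
      aa <- max(a, day_starts[j]); bb <- min(b, day_ends[j])
      if (bb > aa)
        logs[[length(logs) + 1]] <- data.frame(
          site_id = seg_site[i],
          arrival = active_to_abs(aa, dt),
          departure = active_to_abs(bb - 1e-9, dt) + 1e-9)
    }
  }
  vl <- do.call(rbind, logs)
  vl$individual_id <- profile$individual_id
  list(trajectory = traj, visit_log = vl)
}

#' Default status-specific profiles for a landscape
#'
#' Non-breeders target every food site with weight proportional to its
#' attractiveness (landfills dominate); breeders target their nest with high
#' weight plus extensive-livestock sites within `breeder_radius_m`, giving
#' nest-centred ranges.
#'
#' @param sites Site data frame.
#' @param n_nonbreeders,n_breeders Population composition.
#' @param breeder_radius_m Radius of a breeder's foraging neighbourhood.
#' @param nb_range_scale_m,br_range_scale_m Distance-decay lengths of target
#'   sampling (trip locality).
#' @param nb_home_range_m Scale of each non-breeder's personal region: its
#'   site weights are damped by exp(-d / nb_home_range_m) around a home
#'   landfill (assigned round-robin), so different birds occupy different
#'   sub-regions as nomadic individuals do.
#' @param ... Passed to [agent_profile()].
#' @return List of `agent_profile`s.
#' @export
default_profiles <- function(sites, n_nonbreeders = 10, n_breeders = 6,
                             breeder_radius_m = 10000,
                             nb_range_scale_m = 12000,
                             br_range_scale_m = 10000,
                             nb_home_range_m = 30000, ...) {
  food <- sites[!sites$is_nest, ]
  nests <- sites[sites$is_nest, ]
  roost_ids <- sites$site_id[sites$is_roost]
  if (n_breeders > nrow(nests))
    stop("not enough nest sites for the requested breeders")
  landfills <- food[food$rtype == "landfill", ]
  profs <- list()
  if (n_nonbreeders > 0) {
    for (i in seq_len(n_nonbreeders)) {
      w_nb <- stats::setNames(food$attractiveness, food$site_id)
      if (nrow(landfills)) {
        home <- landfills[(i - 1) %% nrow(landfills) + 1, ]
        d <- sqrt((food$x - home$x)^2 + (food$y - home$y)^2)
        w_nb <- w_nb * exp(-d / nb_home_range_m)
      }
      profs[[length(profs) + 1]] <- agent_profile(
        sprintf("NB%02d", i), "non_breeder", site_weights = w_nb,
        range_scale_m = nb_range_scale_m, night_mode = "roost",
        roost_site_ids = roost_ids, roost_floor = 0.1, ...)
    }
  }
  for (i in seq_len(n_breeders)) {
    nest <- nests[i, ]
    d <- sqrt((food$x - nest$x)^2 + (food$y - nest$y)^2)
    # breeders: nest-centred, feeding mostly on nearby extensive livestock,
    # with occasional long trips to landfills only
    near <- d <= breeder_radius_m
    near_ext <- food$rtype == "extensive_livestock" & near
    w <- ifelse(near_ext, 2,
                ifelse(near, 0.05,
                       ifelse(food$rtype == "landfill", 0.02, 0))) *
      food$attractiveness
    w <- stats::setNames(c(1.5, w), c(nest$site_id, food$site_id))
    profs[[length(profs) + 1]] <- agent_profile(
      sprintf("BR%02d", i), "breeder", site_weights = w,
      nest_site_id = nest$site_id, range_scale_m = br_range_scale_m,
      night_mode = "nest",
      roost_site_ids = roost_ids, roost_floor = 0.1, ...)
  }
  profs
}

#' Simulate a tracked population
#'
#' @param n_nonbreeders,n_breeders Population composition (defaults 10 + 6).
#' @param landscape A landscape from [default_landscape()] or
#'   [generate_landscape()] (nest sites required if breeders are simulated).
#' @param seed Root seed; per-agent seeds are derived substreams.
#' @param ... Passed to [default_profiles()] (e.g. `seasons` to shorten runs).
#' @return List with `trajectories` (one combined data frame), `visit_logs`
#'   (per individual), `profiles`, `landscape`.
#' @export
simulate_population <- function(n_nonbreeders = 10, n_breeders = 6,
                                landscape = default_landscape(n_breeders),
                                seed = 1, ...) {
  profs <- default_profiles(landscape$sites, n_nonbreeders, n_breeders, ...)
  sims <- lapply(profs, function(p)
    simulate_agent(p, landscape$sites,
                   seed = substream_seed(seed, p$individual_id)))
  trajectories <- do.call(rbind, lapply(sims, `[[`, "trajectory"))
  logs <- lapply(sims, `[[`, "visit_log")
  names(logs) <- vapply(profs, `[[`, "", "individual_id")
  list(trajectories = trajectories, visit_logs = logs,
       profiles = profs, landscape = landscape)
}

#' Derive a reproducible sub-seed from a root seed and a stream name
#' @param root Integer root seed.
#' @param name Stream name.
#' @export
substream_seed <- function(root, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147480009
  as.integer((abs(root) %% 2147480009 + h) %% 2147480009)
}

#' Write / read trajectory CSV (Movebank-like columns)
#'
#' Columns: `individual_id,status,timestamp_utc,x,y,loc_error_m` with ISO
#' 8601 UTC timestamps and projected-metre coordinates.
#'
#' @param traj Trajectory data frame.
#' @param path CSV path.
#' @export
write_trajectory_csv <- function(traj, path) {
  out <- traj
  out$timestamp_utc <- format(traj$timestamp_utc, "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  tr$timestamp_utc <- as.POSIXct(tr$timestamp_utc,
                                 format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  tr
}
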