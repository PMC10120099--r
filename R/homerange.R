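#' Estimate dynamic Brownian bridge motion variance
#'
#' Sliding-window maximum-likelihood estimation of the Brownian motion
#' variance (m^2/s) along a trajectory. Within each window every odd-indexed
#' interior fix is left out and scored against the Gaussian bridge through
#' its two neighbouring fixes; the window's variance maximizes the summed
#' leave-out likelihood. A single change point per window (at least `margin`
#' fixes from the window edges) is accepted when it lowers the BIC relative
#' to the no-break model. The per-segment estimate is the mean over all
#' windows covering that segment. Segments spanning a time gap larger than
#' `max_gap_s` (e.g. the nightly device-off period) are flagged not
#' bridgeable and split the track into bursts estimated independently;
#' bursts shorter than the window fall back to a static whole-burst MLE.
#'
#' @param traj Trajectory data frame for one individual with columns
#'   `timestamp_utc` (or numeric `t`), `x`, `y` and optionally `loc_error_m`.
#' @param window Window size in fixes (odd, >= 5; default 15).
#' @param margin Minimum distance of a change point from the window edge in
#'   fixes (>= 2; default 5).
#' @param max_gap_s Maximum bridgeable inter-fix gap (default 5400 s, three
#'   30-min fix intervals).
#' @param sigma2_floor Lower bound for the variance search; estimates pinned
#'   at the floor (e.g. an all-identical-position track) trigger a warning.
#' @return A `motion_variance` object: data frame of per-segment `sigma2_m`
#'   and `bridgeable`, with the fix table as attribute.
#' @export
estimate_motion_variance <- function(traj, window = 15, margin = 5,
                                     max_gap_s = 5400,
                                     sigma2_floor = 1e-8) {
  fx <- as_fixes(traj)
  n <- nrow(fx)
  if (n < 2) stop("need at least 2 fixes")
  if (window %% 2 == 0 || window < 5) stop("window must be odd and >= 5")
  if (margin < 2) stop("margin must be >= 2")
  if (any(diff(fx$t) <= 0)) stop("timestamps must be strictly increasing")

  res <- .cpp_motion_variance(fx$x, fx$y, fx$t, fx$err,
                              as.integer(window), as.integer(margin),
                              max_gap_s, sigma2_floor, 1e6)
  sigma2 <- res$sigma2
  if (all(is.na(sigma2))) {
    # no burst long enough for interior points anywhere: whole-track static
    # MLE ignoring gap structure as a last resort
    res2 <- .cpp_motion_variance(fx$x, fx$y, fx$t, fx$err,
                                 as.integer(window), as.integer(margin),
                                 Inf, sigma2_floor, 1e6)
    sigma2 <- res2$sigma2
  }
  if (any(is.na(sigma2)))
    sigma2[is.na(sigma2)] <- mean(sigma2, na.rm = TRUE)
  if (all(is.na(sigma2))) stop("motion variance is inestimable (too few fixes)")
  if (all(sigma2 <= sigma2_floor * 2))
    warning("motion variance pinned at the floor; positions may be constant")
  structure(data.frame(sigma2_m = sigma2, bridgeable = res$bridgeable),
            class = c("motion_variance", "data.frame"),
            fixes = fx, window = window, margin = margin,
            max_gap_s = max_gap_s, breaks = res$breaks)
}

# normalize a trajectory data frame to (t [s], x, y, err) sorted by time
as_fixes <- function(traj) {
  t <- if ("t" %in% names(traj)) as.numeric(traj$t) else
    as.numeric(traj$timestamp_utc)
  err <- if ("loc_error_m" %in% names(traj)) traj$loc_error_m else 0
  if (any(err < 0)) stop("location error must be non-negative")
  data.frame(t = t, x = traj$x, y = traj$y,
             err = rep_len(err, nrow(traj)))
}

#' Compute a dynamic Brownian bridge utilization distribution
#'
#' Time-weighted average of Gaussian bridge densities over all bridgeable
#' segments, integrated at `alpha_steps` interior time points per segment
#' (midpoint rule), rasterized by cell-centre evaluation times cell area and
#' renormalized to total mass one.
#'
#' @param mvs A [estimate_motion_variance()] result (carries the fixes).
#' @param grid A `grid_spec` covering the fixes (default: grid over the
#'   fixes with padding of three bridge standard deviations).
#' @param cell_m Cell size used when `grid` is NULL (default 500 m).
#' @param alpha_steps Interior integration points per segment (>= 5).
#' @param trunc_sd Gaussian truncation radius in bridge SDs.
#' @return A `ud_grid`.
#' @export
compute_ud <- function(mvs, grid = NULL, cell_m = 500, alpha_steps = 7,
                       trunc_sd = 5) {
  stopifnot(inherits(mvs, "motion_variance"))
  if (alpha_steps < 5) stop("alpha_steps must be >= 5")
  fx <- attr(mvs, "fixes")
  if (!any(mvs$bridgeable)) stop("no bridgeable segment in trajectory")
  if (is.null(grid)) {
    br <- which(mvs$bridgeable)
    sd_max <- sqrt(max(0.25 * (fx$t[br + 1] - fx$t[br]) * mvs$sigma2_m[br] +
                         max(fx$err)^2))
    grid <- grid_spec_for_points(fx$x, fx$y, cell_m,
                                 pad_m = max(3 * sd_max, 3 * cell_m))
  }
  dens <- .cpp_accumulate_ud(fx$x, fx$y, fx$t, fx$err,
                             mvs$sigma2_m, mvs$bridgeable,
                             grid$x0, grid$y0, grid$cell_m,
                             grid$nx, grid$ny,
                             as.integer(alpha_steps), trunc_sd)
  if (sum(dens) <= 0) stop("UD has no mass on the grid; enlarge the grid")
  ud_grid(grid, dens * grid$cell_m^2)
}

#' Restrict a trajectory to seasonal date windows
#'
#' Keeps fixes whose date falls inside any of the supplied windows
#' (inclusive). Migration and wintering fixes are assumed to be outside the
#' windows; no path-shape-based delimitation is attempted.
#'
#' @param trajectories Trajectory data frame with `timestamp_utc`.
#' @param seasons Data frame with `start`, `end` (Date).
#' @return The filtered trajectory data frame.
#' @export
filter_season <- function(trajectories, seasons = default_seasons()) {
  d <- as.Date(trajectories$timestamp_utc, tz = "UTC")
  keep <- rep(FALSE, length(d))
  for (i in seq_len(nrow(seasons)))
    keep <- keep | (d >= seasons$start[i] & d <= seasons$end[i])
  trajectories[keep, , drop = FALSE]
}

#' Individual-year utilization distributions
#'
#' Splits a multi-individual trajectory table by individual and calendar
#' year, estimates motion variance and computes a UD for each on a common
#' grid, and returns the per-individual-year UDs.
#'
#' @param trajectories Combined trajectory data frame.
#' @param grid Common `grid_spec`; default covers all fixes.
#' @param cell_m Cell size for the default grid.
#' @param min_fixes Minimum fixes for a UD (tracks below are skipped).
#' @param ... Passed to [estimate_motion_variance()].
#' @return List with `uds` (named list of `ud_grid`), `grid`, and `meta`
#'   (data frame: individual_id, status, year, n_fixes).
#' @export
individual_year_uds <- function(trajectories, grid = NULL, cell_m = 500,
                                min_fixes = 20, ...) {
  year <- as.integer(format(trajectories$timestamp_utc, "%Y"))
  if (is.null(grid))
    grid <- grid_spec_for_points(trajectories$x, trajectories$y, cell_m)
  key <- interaction(trajectories$individual_id, year, drop = TRUE)
  uds <- list(); meta <- list()
  for (k in levels(key)) {
    tr <- trajectories[key == k, ]
    tr <- tr[order(tr$timestamp_utc), ]
    if (nrow(tr) < min_fixes) next
    mvs <- estimate_motion_variance(tr, ...)
    uds[[k]] <- compute_ud(mvs, grid = grid)
    meta[[k]] <- data.frame(individual_id = tr$individual_id[1],
                            status = tr$status[1],
                            year = as.integer(format(tr$timestamp_utc[1], "%Y")),
                            n_fixes = nrow(tr))
  }
  if (!length(uds)) stop("no individual-year track had enough fixes")
  list(uds = uds, grid = grid, meta = do.call(rbind, meta))
}
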