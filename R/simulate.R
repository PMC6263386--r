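#' Simulation configuration
#'
#' Parameters of the synthetic greenhouse day used to exercise the
#' pipeline offline: a passage-constrained walk over the layout, a
#' log-distance path-loss radio model for the beacon RSSI, and 50 Hz wrist
#' acceleration with stereotyped ~1 s harvesting-action bursts embedded in
#' background motion. Defaults emulate the reference study conditions: one
#' laborer covering 3 passages x 16 sections past 64 beacons in roughly
#' 25 minutes, harvesting about 100 tomatoes.
#'
#' @param seed integer seed; every generator draws from it reproducibly.
#' @param speed walking speed, m/s.
#' @param dwell_mean,dwell_shape mean (s) and gamma shape of the per-section
#'   harvesting dwell.
#' @param passage_order sequence of 0-based passage indices visited.
#' @param tp position tick length, s.
#' @param rssi_ref RSSI at 1 m, dBm.
#' @param path_exponent path-loss exponent.
#' @param rssi_sd shadowing noise sd, dB.
#' @param rx_rate beacon advertisement receptions per second at close range.
#' @param rx_d50,rx_dslope distance (m) at which reception probability
#'   drops to 1/2, and the logistic slope width (m).
#' @param rate_hz IMU sampling rate, Hz.
#' @param accel_noise_sd white accelerometer noise sd, g.
#' @param swing_amp,swing_hz amplitude (g) and frequency (Hz) of the slow
#'   arm-swing background component.
#' @param burst_amp peak amplitude of the harvesting-action burst, g.
#' @param burst_frames length of the burst template, frames.
#' @param n_events total harvesting actions planted over the day.
#' @param min_event_gap_s minimum spacing between actions, s (must be at
#'   least two window lengths).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       speed = 0.8, dwell_mean = 27, dwell_shape = 4,
                       passage_order = c(0L, 1L, 2L),
                       tp = 1.0,
                       rssi_ref = -59, path_exponent = 2.0, rssi_sd = 4,
                       rx_rate = 2, rx_d50 = 15, rx_dslope = 4,
                       rate_hz = 50, accel_noise_sd = 0.15,
                       swing_amp = 0.25, swing_hz = 0.8,
                       burst_amp = 1.2, burst_frames = 50L,
                       n_events = 100L, min_event_gap_s = 2.5) {
  stopifnot(speed > 0, tp > 0, rate_hz > 0, dwell_mean > 0,
            min_event_gap_s * rate_hz >= 2 * burst_frames)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a passage-constrained walk
#'
#' The laborer enters the first passage at one end, works along it section
#' by section (walking at `speed` and dwelling `~Gamma(shape, .)` seconds
#' per section to harvest), then crosses to the next passage through the
#' end zone, alternating direction like a boustrophedon. The trajectory
#' stays on passage centre lines; the Y coordinate changes only while the
#' X position is inside an end section.
#'
#' @param layout a `field_layout`.
#' @param cfg a [sim_config()].
#' @return List with `trajectory` (data frame `t`, `x`, `y` sampled every
#'   `tp` seconds), `truth` (data frame `tick`, `px`, `py` true section
#'   labels), `dwells` (data frame `t0`, `t1`, `px`, `py` per harvesting
#'   dwell) and `duration` (s).
#' @export
simulate_walk <- function(layout, cfg = sim_config()) {
  stopifnot(inherits(layout, "field_layout"))
  set.seed(as.integer(cfg$seed))
  b <- layout$section_boundaries_x
  nx <- layout$n_sections_x
  yc <- layout$passage_y_centers
  cx <- (b[-1] + b[-length(b)]) / 2

  # piecewise-linear keyframes (t, x, y); dwells recorded as they happen
  t <- 0; x <- b[1]; y <- yc[cfg$passage_order[1] + 1L]
  kt <- t; kx <- x; ky <- y
  dwells <- NULL
  push <- function(nt, nx_, ny_) {
    if (nt > t + 1e-12) {
      kt <<- c(kt, nt); kx <<- c(kx, nx_); ky <<- c(ky, ny_)
      t <<- nt; x <<- nx_; y <<- ny_
    }
  }
  for (pi in seq_along(cfg$passage_order)) {
    py <- cfg$passage_order[pi]
    forward <- pi %% 2 == 1            # odd visits go 0 -> nx-1
    secs <- if (forward) seq_len(nx) else rev(seq_len(nx))
    for (s in secs) {
      # walk to the section centre, then dwell to harvest
      push(t + abs(cx[s] - x) / cfg$speed, cx[s], y)
      d <- stats::rgamma(1, shape = cfg$dwell_shape,
                         rate = cfg$dwell_shape / cfg$dwell_mean)
      dwells <- rbind(dwells,
                      data.frame(t0 = t, t1 = t + d, px = s - 1L, py = py))
      push(t + d, x, y)
    }
    if (pi < length(cfg$passage_order)) {
      # cross to the next passage through the end zone
      edge <- if (forward) b[length(b)] else b[1]
      push(t + abs(edge - x) / cfg$speed, edge, y)
      ny <- yc[cfg$passage_order[pi + 1L] + 1L]
      push(t + abs(ny - y) / cfg$speed, x, ny)
    }
  }
  duration <- t
  tt <- seq(0, duration, by = cfg$tp)
  traj <- data.frame(t = tt,
                     x = stats::approx(kt, kx, tt, rule = 2)$y,
                     y = stats::approx(kt, ky, tt, rule = 2)$y)
  lab <- point_to_section(traj$x, traj$y, layout)
  truth <- data.frame(tick = as.integer(round(tt / cfg$tp)),
                      px = lab$px, py = lab$py)
  list(trajectory = traj, truth = truth, dwells = dwells, duration = duration)
}

#' Simulate a beacon reception log along a trajectory
#'
#' Log-distance path loss with Gaussian shadowing:
#' `rssi = ref - 10 * exponent * log10(d) + N(0, sd)`, with each beacon
#' heard in a tick with a logistic distance-dependent probability and a
#' Poisson number of advertisements. Distances below 0.5 m are floored to
#' keep the near-field finite.
#'
#' @param trajectory data frame `t`, `x`, `y` (one row per tick), as from
#'   [simulate_walk()].
#' @param layout a `field_layout`.
#' @param cfg a [sim_config()].
#' @return Data frame `timestamp`, `beacon_id`, `rssi_dbm` -- the beacon
#'   log consumed by [aggregate_frames()]/[estimate_track()].
#' @export
simulate_rssi <- function(trajectory, layout, cfg = sim_config()) {
  stopifnot(inherits(layout, "field_layout"))
  set.seed(as.integer(cfg$seed) + 1L)
  bx <- layout$beacons$x; by <- layout$beacons$y
  ids <- layout$beacons$beacon_id
  nb <- length(ids); nt <- nrow(trajectory)
  d <- sqrt(outer(trajectory$x, bx, "-")^2 + outer(trajectory$y, by, "-")^2)
  d <- pmax(d, 0.5)
  p_rx <- 1 / (1 + exp((d - cfg$rx_d50) / cfg$rx_dslope))
  n_rx <- matrix(stats::rpois(nt * nb, cfg$rx_rate * cfg$tp * p_rx), nt, nb)
  tot <- sum(n_rx)
  if (tot == 0)
    return(data.frame(timestamp = numeric(0), beacon_id = character(0),
                      rssi_dbm = numeric(0)))
  tick_i <- rep(rep(seq_len(nt), nb), as.vector(n_rx))
  beac_i <- rep(rep(seq_len(nb), each = nt), as.vector(n_rx))
  ts <- trajectory$t[tick_i] + stats::runif(tot, 0, cfg$tp)
  mu <- cfg$rssi_ref - 10 * cfg$path_exponent * log10(d[cbind(tick_i, beac_i)])
  rec <- data.frame(timestamp = ts, beacon_id = ids[beac_i],
                    rssi_dbm = mu + stats::rnorm(tot, 0, cfg$rssi_sd))
  rec[order(rec$timestamp), , drop = FALSE]
}

#' Harvesting-action burst template
#'
#' A hand-designed tri-phase acceleration envelope -- reach toward the
#' fruit, a sharp cutting oscillation, then the throw-and-return -- spread
#' over the six wrist channels with per-channel weights. Values are in g,
#' peak amplitude 1.
#'
#' @param n_frames template length in frames.
#' @param n_channels number of motion channels.
#' @return Matrix `n_frames` by `n_channels`.
#' @export
burst_template <- function(n_frames = 50L, n_channels = 6L) {
  u <- seq(0, 1, length.out = n_frames)
  reach <- sin(pi * pmin(u / 0.4, 1)) * (u < 0.4)
  cut <- sin(2 * pi * (u - 0.35) / 0.1) * exp(-((u - 0.45) / 0.12)^2)
  throw <- -sin(pi * pmax((u - 0.55) / 0.45, 0)) * (u >= 0.55)
  phases <- cbind(reach, cut, throw)
  # per-channel mixing: each wrist axis sees the phases with its own weights
  w <- matrix(c(0.9, 0.8, 0.3,
                0.4, 1.0, 0.5,
                0.6, 0.5, 0.9,
                0.8, 0.9, 0.4,
                0.5, 1.0, 0.4,
                0.7, 0.4, 0.8), nrow = 3)[, seq_len(n_channels), drop = FALSE]
  tpl <- phases %*% w
  tpl / max(abs(tpl))
}

#' Simulate wrist motion with planted harvesting actions
#'
#' Background motion is white accelerometer noise plus a slow sinusoidal
#' arm swing per channel (random phase). At each planted event the burst
#' template is added on all channels with small random amplitude jitter
#' (+-15%) and timing jitter (+-2 frames); annotations keep the nominal
#' start frames.
#'
#' @param event_frames integer vector of 0-based nominal start frames.
#' @param n_frames total sequence length, frames.
#' @param cfg a [sim_config()].
#' @param n_channels number of channels (3 axes x 2 wrists by default).
#' @return List with `seq` (a `motion_sequence`) and `event_frames`
#'   (0-based, as annotated).
#' @export
simulate_motion <- function(event_frames, n_frames, cfg = sim_config(),
                            n_channels = 6L) {
  set.seed(as.integer(cfg$seed) + 2L)
  event_frames <- sort(as.integer(event_frames))
  # 1-frame tolerance absorbs seconds-to-frames rounding of planned times
  if (length(event_frames) > 1 &&
      any(diff(event_frames) < cfg$min_event_gap_s * cfg$rate_hz - 1))
    stop("planted events violate the minimum spacing", call. = FALSE)
  tt <- (seq_len(n_frames) - 1) / cfg$rate_hz
  x <- matrix(stats::rnorm(n_frames * n_channels, 0, cfg$accel_noise_sd),
              n_frames, n_channels)
  for (ch in seq_len(n_channels))
    x[, ch] <- x[, ch] + cfg$swing_amp *
      sin(2 * pi * cfg$swing_hz * tt + stats::runif(1, 0, 2 * pi))
  tpl <- burst_template(cfg$burst_frames, n_channels)
  for (e in event_frames) {
    jit <- sample(-2:2, 1)
    amp <- stats::runif(1, 0.85, 1.15) * cfg$burst_amp
    i0 <- e + jit + 1L
    rows <- seq(max(1L, i0), min(n_frames, i0 + cfg$burst_frames - 1L))
    x[rows, ] <- x[rows, ] + amp * tpl[rows - i0 + 1L, , drop = FALSE]
  }
  colnames(x) <- paste0(rep(c("L", "R"), each = 3),
                        "_a", c("x", "y", "z"))[seq_len(n_channels)]
  list(seq = motion_sequence(x, cfg$rate_hz), event_frames = event_frames)
}

#' Plant harvesting events inside the walk's dwell periods
#'
#' Distributes `n_events` action start times over the harvesting dwells,
#' proportionally to dwell length, respecting the minimum spacing.
#'
#' @param dwells dwell table from [simulate_walk()].
#' @param cfg a [sim_config()].
#' @return Data frame `t` (s), `frame` (0-based), `px`, `py` sorted by time.
#' @export
plan_events <- function(dwells, cfg = sim_config()) {
  set.seed(as.integer(cfg$seed) + 3L)
  gap <- cfg$min_event_gap_s
  slots <- NULL
  for (i in seq_len(nrow(dwells))) {
    len <- dwells$t1[i] - dwells$t0[i]
    if (len < gap) next
    # one random phase per dwell keeps within-dwell slots exactly gap apart;
    # walking time between sections separates slots of different dwells
    off <- stats::runif(1, 0, min(gap / 2, len - gap))
    tt <- seq(dwells$t0[i] + off, dwells$t1[i], by = gap)
    slots <- rbind(slots, data.frame(t = tt, px = dwells$px[i], py = dwells$py[i]))
  }
  if (is.null(slots) || nrow(slots) < cfg$n_events)
    stop("not enough dwell time to plant the requested events", call. = FALSE)
  keep <- sort(sample(nrow(slots), cfg$n_events))
  ev <- slots[keep, , drop = FALSE]
  ev <- ev[order(ev$t), , drop = FALSE]
  ev$frame <- as.integer(round(ev$t * cfg$rate_hz))
  rownames(ev) <- NULL
  ev[, c("t", "frame", "px", "py")]
}

#' Simulate a full working day
#'
#' Runs [simulate_walk()], [plan_events()], [simulate_rssi()] and
#' [simulate_motion()] under one seed and, optionally, writes the fixture
#' files: the beacon log, the IMU log, the ground-truth section track,
#' event annotations and a JSON manifest with the true per-section counts.
#'
#' @param layout a `field_layout`.
#' @param cfg a [sim_config()].
#' @param dir optional output directory for CSV/JSON fixtures.
#' @return List with `beacon_log`, `motion` (`motion_sequence`),
#'   `event_frames`, `events` (with true sections), `truth_track`,
#'   `truth_map` (a `harvesting_map`), `layout`, `cfg`.
#' @export
simulate_day <- function(layout = default_layout(), cfg = sim_config(),
                         dir = NULL) {
  walk <- simulate_walk(layout, cfg)
  events <- plan_events(walk$dwells, cfg)
  beacon_log <- simulate_rssi(walk$trajectory, layout, cfg)
  n_frames <- as.integer(ceiling(walk$duration * cfg$rate_hz) +
                           2L * cfg$burst_frames)
  motion <- simulate_motion(events$frame, n_frames, cfg)
  truth_map <- build_map(events, layout)
  out <- list(beacon_log = beacon_log, motion = motion$seq,
              event_frames = motion$event_frames, events = events,
              truth_track = walk$truth, truth_map = truth_map,
              layout = layout, cfg = cfg)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(beacon_log, file.path(dir, "beacons.csv"), row.names = FALSE)
    imu <- imu_long(motion$seq)
    utils::write.csv(imu, file.path(dir, "imu.csv"), row.names = FALSE)
    utils::write.csv(walk$truth, file.path(dir, "truth_track.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(event_start_frame = events$frame),
                     file.path(dir, "truth_events.csv"), row.names = FALSE)
    write_layout(layout, file.path(dir, "layout.yaml"))
    manifest <- list(
      seed = cfg$seed, duration_s = walk$duration,
      n_events = nrow(events),
      counts = lapply(seq_len(nrow(events)), function(i)
        list(px = events$px[i], py = events$py[i])),
      per_section = as.data.frame(as.table(unclass(truth_map)),
                                  stringsAsFactors = FALSE)
    )
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# wide motion matrix -> long CSV layout (timestamp, wrist, ax, ay, az)
imu_long <- function(seq) {
  x <- seq$data
  tt <- (seq_len(nrow(x)) - 1) / seq$rate_hz
  rbind(
    data.frame(timestamp = tt, wrist = "L",
               ax = x[, "L_ax"], ay = x[, "L_ay"], az = x[, "L_az"]),
    data.frame(timestamp = tt, wrist = "R",
               ax = x[, "R_ax"], ay = x[, "R_ay"], az = x[, "R_az"])
  )
}
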