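#' Section-track accuracy
#'
#' Per-tick exact-match rates of the estimated final track against ground
#' truth, along X, along Y, and jointly.
#'
#' @param est a `section_track` (its `final` series is scored) or a data
#'   frame with columns `px`, `py`.
#' @param truth data frame with columns `px`, `py` (same number of ticks).
#' @return Named numeric vector `c(x_rate, y_rate, both_rate)`.
#' @export
position_accuracy <- function(est, truth) {
  ep <- if (inherits(est, "section_track"))
    data.frame(px = est$final_px, py = est$final_py) else est
  if (nrow(ep) != nrow(truth))
    stop("estimated and true tracks must have equal length", call. = FALSE)
  mx <- ep$px == truth$px
  my <- ep$py == truth$py
  c(x_rate = mean(mx), y_rate = mean(my), both_rate = mean(mx & my))
}

#' Event-level precision and recall
#'
#' Greedy one-to-one matching in time order: each detected event is paired
#' with the earliest unmatched true event within `tolerance` frames.
#' Precision is matched/detected, recall is matched/truth. With zero
#' detections precision is undefined and reported as 0 with the
#' `no_detections` attribute set.
#'
#' @param detected integer vector of detected event frames.
#' @param truth integer vector of true event frames.
#' @param tolerance matching tolerance in frames.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
event_pr <- function(detected, truth, tolerance = 50) {
  if (tolerance < 0) stop("'tolerance' must be >= 0", call. = FALSE)
  detected <- sort(as.numeric(detected))
  truth <- sort(as.numeric(truth))
  used <- rep(FALSE, length(truth))
  matched <- 0L
  for (d in detected) {
    ok <- which(!used & abs(truth - d) <= tolerance)
    if (length(ok) > 0) {
      used[ok[1]] <- TRUE          # earliest unmatched true event wins
      matched <- matched + 1L
    }
  }
  prec <- if (length(detected) == 0) 0 else matched / length(detected)
  rec <- if (length(truth) == 0) 1 else matched / length(truth)
  out <- c(precision = prec, recall = rec)
  attr(out, "no_detections") <- length(detected) == 0
  out
}

#' Mean absolute error between harvesting maps
#'
#' Mean over all sections of the absolute count difference.
#'
#' @param est,truth `harvesting_map` objects (or count matrices) of equal
#'   dimensions.
#' @return A single non-negative number.
#' @export
map_mae <- function(est, truth) {
  est <- unclass(est); truth <- unclass(truth)
  if (!all(dim(est) == dim(truth)))
    stop("maps must have identical dimensions", call. = FALSE)
  mean(abs(est - truth))
}

#' Run the full harvesting-map pipeline on simulated data
#'
#' Simulates a training day and a test day (sub-seeds derived from `seed`),
#' trains the action classifier on the training day's annotations, then on
#' the test day estimates the section track, detects harvesting events,
#' fuses both into a harvesting map, and scores every stage against the
#' simulation's ground truth.
#'
#' @param layout a `field_layout`.
#' @param cfg a [sim_config()]; its `seed` is the master seed.
#' @param fcfg a [feature_config()].
#' @param th_a event-acceptance threshold on the posterior.
#' @param tolerance event-matching tolerance, frames.
#' @param wx,wy mode-filter half-windows.
#' @param epsilon raw-position bias constant.
#' @param out_dir optional directory; writes track/events/map CSVs, the map
#'   figure and a JSON report.
#' @param smooth_weights kernel for [smooth_motion()].
#' @return List of class `harvest_report`: `position`
#'   (x/y/both match rates), `events` (precision, recall), `map_mae`,
#'   plus the `track`, `events_detected`, `map`, `truth_map` and the two
#'   day objects.
#' @export
run_pipeline <- function(layout = default_layout(), cfg = sim_config(),
                         fcfg = feature_config(), th_a = 0.5,
                         tolerance = 50, wx = 3L, wy = 3L, epsilon = 0.1,
                         out_dir = NULL, smooth_weights = c(1, 2, 3, 2, 1)) {
  cfg_train <- cfg; cfg_train$seed <- as.integer(cfg$seed) + 1000L
  train_day <- simulate_day(layout, cfg_train)
  test_day <- simulate_day(layout, cfg)

  sm_train <- smooth_motion(train_day$motion, smooth_weights)
  ts <- make_training_set(sm_train, train_day$event_frames, fcfg,
                          seed = cfg$seed)
  model <- train_classifier(ts$features, ts$labels, seed = cfg$seed)

  track <- estimate_track(test_day$beacon_log, layout, tp = cfg$tp,
                          epsilon = epsilon, wx = wx, wy = wy)
  sm_test <- smooth_motion(test_day$motion, smooth_weights)
  post <- score_sequence(model, sm_test, fcfg)
  ev <- detect_events(post, th_a = th_a, l_w = fcfg$l_w)

  located <- synchronize_events(track, ev, ta = 1 / cfg$rate_hz, tp = cfg$tp)
  est_map <- build_map(located, layout, ideal = attr(test_day$truth_map, "ideal"))

  nt <- min(nrow(track), nrow(test_day$truth_track))
  pos_acc <- position_accuracy(track[seq_len(nt), ],
                               test_day$truth_track[seq_len(nt), ])
  pr <- event_pr(ev$events$frame, test_day$event_frames, tolerance)
  mae <- map_mae(est_map, test_day$truth_map)

  report <- structure(list(
    position = pos_acc, events = pr, map_mae = mae,
    n_detected = nrow(ev$events), n_true = length(test_day$event_frames),
    track = track, events_detected = ev, map = est_map,
    truth_map = test_day$truth_map,
    train_day = train_day, test_day = test_day,
    params = list(seed = cfg$seed, tp = cfg$tp, wx = wx, wy = wy,
                  epsilon = epsilon, th_a = th_a, tolerance = tolerance)
  ), class = "harvest_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_track_csv(track, file.path(out_dir, "track.csv"))
    write_events_csv(ev, 1 / cfg$rate_hz, file.path(out_dir, "events.csv"))
    render_map(est_map, layout, csv = file.path(out_dir, "map.csv"),
               file = file.path(out_dir, "map.svg"))
    jsonlite::write_json(
      list(position = as.list(pos_acc), events = as.list(pr),
           map_mae = mae, params = report$params),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.harvest_report <- function(x, ...) {
  cat("<harvest_report>\n")
  cat(sprintf("  position match rates: X %.1f%%, Y %.1f%%, both %.1f%%\n",
              100 * x$position["x_rate"], 100 * x$position["y_rate"],
              100 * x$position["both_rate"]))
  cat(sprintf("  events: %d detected / %d true; precision %.1f%%, recall %.1f%%\n",
              x$n_detected, x$n_true,
              100 * x$events["precision"], 100 * x$events["recall"]))
  cat(sprintf("  harvesting-map MAE: %.3f tomatoes/section\n", x$map_mae))
  invisible(x)
}
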