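#' Read a beacon reception log
#'
#' CSV with header `timestamp,beacon_id,rssi_dbm` (seconds, id, dBm).
#'
#' @param path CSV file path.
#' @return Data frame with those columns.
#' @export
read_beacon_log <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "beacon_id", "rssi_dbm")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("beacon log is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d
}

#' Read an IMU log into a motion sequence
#'
#' CSV with header `timestamp,wrist,ax,ay,az` and `wrist` in `{L,R}`; both
#' wrists must cover the same frames. Channels come out in the order
#' `L_ax, L_ay, L_az, R_ax, R_ay, R_az`.
#'
#' @param path CSV file path.
#' @param rate_hz sampling rate declared for the log.
#' @return A `motion_sequence`.
#' @export
read_imu_log <- function(path, rate_hz = 50) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "wrist", "ax", "ay", "az")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("IMU log is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  l <- d[d$wrist == "L", ]; r <- d[d$wrist == "R", ]
  l <- l[order(l$timestamp), ]; r <- r[order(r$timestamp), ]
  if (nrow(l) != nrow(r))
    stop("left and right wrist logs must cover the same frames", call. = FALSE)
  x <- cbind(L_ax = l$ax, L_ay = l$ay, L_az = l$az,
             R_ax = r$ax, R_ay = r$ay, R_az = r$az)
  motion_sequence(x, rate_hz)
}

#' Write / read a section track
#'
#' CSV with columns
#' `tick,raw_px,raw_py,smooth_px,smooth_py,final_px,final_py`.
#'
#' @param track a `section_track`.
#' @param path CSV file path.
#' @return `path` (write) or a `section_track` (read), invisibly for write.
#' @export
write_track_csv <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  d <- utils::read.csv(path)
  class(d) <- c("section_track", "data.frame")
  d
}

#' Write detected events
#'
#' CSV with columns `frame,time_s,posterior`.
#'
#' @param events an `event_series`.
#' @param ta IMU sampling interval, seconds.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, ta, path) {
  e <- events$events
  utils::write.csv(data.frame(frame = e$frame, time_s = e$frame * ta,
                              posterior = e$posterior),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read event annotations
#'
#' CSV with a single column `event_start_frame` (0-based frames).
#'
#' @param path CSV file path.
#' @return Integer vector of start frames.
#' @export
read_annotations <- function(path) {
  d <- utils::read.csv(path)
  if (!"event_start_frame" %in% names(d))
    stop("annotation file needs an 'event_start_frame' column", call. = FALSE)
  as.integer(d$event_start_frame)
}
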