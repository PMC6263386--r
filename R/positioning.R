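#' Aggregate a beacon reception log into per-tick RSSI frames
#'
#' Bins timestamped `(beacon_id, rssi)` receptions into ticks of length
#' `tp` seconds and averages the RSSI of each beacon within a tick. Beacons
#' with no reception in a tick are recorded as `NA`. A missing reception is
#' deliberately a sentinel rather than the numeric 0 sometimes used to
#' encode "no signal": 0 dBm would otherwise rank as the strongest signal,
#' and "strongest beacon" must only ever rank beacons actually received.
#'
#' @param records data frame with columns `timestamp` (seconds),
#'   `beacon_id`, `rssi_dbm` (negative dBm), e.g. from [read_beacon_log()].
#' @param layout a `field_layout`; defines the beacon set.
#' @param tp tick length in seconds (sampling interval of position
#'   estimation).
#' @param unknown_beacon what to do with receptions from beacon ids not in
#'   the layout: `"warn"` (drop with a warning) or `"error"`.
#' @return An object of class `rssi_frames`: a list with `values` (a
#'   ticks-by-beacons matrix of mean RSSI, `NA` = missing), `ticks`
#'   (0-based tick numbers `n = t / tp`), `tp`, and `beacon_ids`.
#' @export
aggregate_frames <- function(records, layout, tp = 1.0,
                             unknown_beacon = c("warn", "error")) {
  stopifnot(inherits(layout, "field_layout"), is.data.frame(records))
  unknown_beacon <- match.arg(unknown_beacon)
  if (!is.numeric(tp) || length(tp) != 1 || tp <= 0)
    stop("'tp' must be a single positive number of seconds", call. = FALSE)
  need <- c("timestamp", "beacon_id", "rssi_dbm")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop("beacon log is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  ids <- layout$beacons$beacon_id
  known <- records$beacon_id %in% ids
  if (!all(known)) {
    msg <- sprintf("%d reception(s) from beacon ids not in the layout",
                   sum(!known))
    if (unknown_beacon == "error") stop(msg, call. = FALSE)
    warning(msg, "; ignoring them", call. = FALSE)
    records <- records[known, , drop = FALSE]
  }

  n0 <- if (nrow(records) > 0) floor(min(records$timestamp) / tp) else 0
  n1 <- if (nrow(records) > 0) floor(max(records$timestamp) / tp) else -1
  ticks <- if (n1 >= n0) seq(n0, n1) else integer(0)
  values <- matrix(NA_real_, nrow = length(ticks), ncol = length(ids),
                   dimnames = list(NULL, ids))
  if (nrow(records) > 0) {
    row <- floor(records$timestamp / tp) - n0 + 1
    col <- match(records$beacon_id, ids)
    key <- (col - 1) * length(ticks) + row      # column-major linear index
    sums <- rowsum(records$rssi_dbm, key)
    cnts <- rowsum(rep(1, length(key)), key)
    values[as.integer(rownames(sums))] <- sums / cnts
  }
  structure(list(values = values, ticks = as.integer(ticks), tp = tp,
                 beacon_ids = ids),
            class = "rssi_frames")
}

#' @export
print.rssi_frames <- function(x, ...) {
  cat(sprintf("<rssi_frames> %d ticks (tp = %g s) x %d beacons; %.1f%% slots received\n",
              nrow(x$values), x$tp, ncol(x$values),
              100 * mean(!is.na(x$values))))
  invisible(x)
}

#' Raw position estimate from the two strongest beacons
#'
#' For one RSSI frame, locates the laborer between the beacons with the
#' strongest and second-strongest received RSSI:
#' `p = ((1 + eps) * p_i1 + p_i2) / (2 + eps)`,
#' a weighted midpoint biased toward the strongest beacon. A small positive
#' `eps` keeps the estimate off the exact border between the two beacons'
#' sections. If only one beacon was received the estimate is that beacon's
#' position.
#'
#' @param rssi named numeric vector of per-beacon RSSI for one tick
#'   (`NA` = not received); names are beacon ids in the layout.
#' @param layout a `field_layout`.
#' @param epsilon positive bias constant.
#' @return Numeric `c(x, y)` in metres.
#' @export
estimate_raw_position <- function(rssi, layout, epsilon = 0.1) {
  stopifnot(inherits(layout, "field_layout"))
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("'epsilon' must be positive", call. = FALSE)
  ok <- which(!is.na(rssi))
  if (length(ok) == 0)
    stop("no beacon received in this frame", call. = FALSE)
  ord <- ok[order(rssi[ok], decreasing = TRUE)]
  pos <- layout$beacons
  i1 <- match(names(rssi)[ord[1]], pos$beacon_id)
  p1 <- c(pos$x[i1], pos$y[i1])
  if (length(ord) == 1) return(p1)
  i2 <- match(names(rssi)[ord[2]], pos$beacon_id)
  p2 <- c(pos$x[i2], pos$y[i2])
  ((1 + epsilon) * p1 + p2) / (2 + epsilon)
}

#' Sliding-window mode filter
#'
#' Replaces each element of an integer label sequence by the most frequent
#' value in the window `[n - w, n + w]`, truncated at the sequence ends.
#' Ties break to the smallest label so the filter is deterministic.
#'
#' @param series integer vector of labels.
#' @param w half-window size (window length `2w + 1`); `w = 0` is the
#'   identity.
#' @return Integer vector the same length as `series`.
#' @export
mode_filter <- function(series, w) {
  if (!is.numeric(w) || length(w) != 1 || w < 0)
    stop("'w' must be a single half-window size >= 0", call. = FALSE)
  n <- length(series)
  if (n == 0) return(integer(0))
  series <- as.integer(series)
  if (w == 0) return(series)
  out <- integer(n)
  for (i in seq_len(n)) {
    win <- series[max(1, i - w):min(n, i + w)]
    out[i] <- stat_mode(win)
  }
  out
}

# most frequent value; smallest wins on ties
stat_mode <- function(v) {
  u <- sort(unique(v))
  u[which.max(tabulate(match(v, u)))]
}

#' Segment a track into mid-passage walk intervals
#'
#' Finds the maximal runs of ticks during which the smoothed X section lies
#' strictly inside a passage (not in an end section). Within such a run the
#' laborer cannot have changed passage -- the plants are too tall to cross
#' a ridge -- so each run is one "walk" along a single passage. The run
#' boundaries `(n_in, n_out)` drive the passage map matching.
#'
#' @param x_smoothed integer vector of smoothed X-section labels per tick.
#' @param layout a `field_layout` (supplies `end_sections`).
#' @return Data frame with 1-based tick-index columns `n_in`, `n_out`
#'   (first and last tick of each run), ordered and non-overlapping.
#' @export
segment_passage_walks <- function(x_smoothed, layout) {
  stopifnot(inherits(layout, "field_layout"))
  if (length(x_smoothed) == 0)
    stop("'x_smoothed' must be nonempty", call. = FALSE)
  interior <- !(x_smoothed %in% layout$end_sections)
  r <- rle(interior)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(n_in = starts[keep], n_out = ends[keep])
}

#' Passage map matching for the Y track
#'
#' Within each mid-passage walk segment the Y label is replaced by the
#' mode of the smoothed Y labels over that segment (a laborer cannot change
#' passage mid-walk). Between consecutive segments `i` and `i + 1` the
#' label switches at the midpoint tick `(n_out_i + n_in_{i+1}) / 2`: ticks
#' at or before the midpoint take segment `i`'s passage, later ticks take
#' segment `i + 1`'s. Before the first and after the last segment the
#' nearest segment's passage is extended.
#'
#' @param y_smoothed integer vector of smoothed Y (passage) labels.
#' @param segments data frame from [segment_passage_walks()] computed on
#'   the matching track.
#' @return Integer vector of map-matched passage labels, same length as
#'   `y_smoothed`.
#' @export
map_match_y <- function(y_smoothed, segments) {
  n <- length(y_smoothed)
  if (nrow(segments) == 0) {
    warning("no mid-passage walk segments; returning y_smoothed unchanged",
            call. = FALSE)
    return(as.integer(y_smoothed))
  }
  seg_val <- vapply(seq_len(nrow(segments)), function(i)
    stat_mode(y_smoothed[segments$n_in[i]:segments$n_out[i]]), integer(1))
  out <- integer(n)
  # switch points between consecutive segments (ticks <= cut get segment i)
  cuts <- if (nrow(segments) > 1)
    (segments$n_out[-nrow(segments)] + segments$n_in[-1]) / 2 else numeric(0)
  bounds <- c(-Inf, cuts, Inf)
  for (i in seq_len(nrow(segments))) {
    sel <- which(seq_len(n) > bounds[i] & seq_len(n) <= bounds[i + 1])
    out[sel] <- seg_val[i]
  }
  out
}

#' Estimate a section track from a beacon log
#'
#' The full three-stage position pipeline: (1) per tick, a raw metric
#' position is interpolated between the two strongest beacons and converted
#' to a section label; (2) the X and Y label series are smoothed with a
#' sliding mode filter of half-window `wx` / `wy`; (3) the Y series is map
#' matched so the passage is constant within every mid-passage walk and can
#' change only around passage ends. Ticks in which no beacon at all was
#' received reuse the previous raw position (leading all-missing ticks take
#' the first valid one).
#'
#' @inheritParams aggregate_frames
#' @inheritParams estimate_raw_position
#' @param wx,wy mode-filter half-windows for the X and Y label series.
#' @return An object of class `section_track`: a data frame with columns
#'   `tick` (0-based), `raw_px`, `raw_py`, `smooth_px`, `smooth_py`,
#'   `final_px`, `final_py`, with the walk segmentation in
#'   `attr(, "segments")`.
#' @export
estimate_track <- function(records, layout, tp = 1.0, epsilon = 0.1,
                           wx = 3L, wy = 3L) {
  frames <- if (inherits(records, "rssi_frames")) records
            else aggregate_frames(records, layout, tp)
  v <- frames$values
  nt <- nrow(v)
  if (nt == 0) stop("beacon log contains no receptions", call. = FALSE)
  pos <- matrix(NA_real_, nt, 2)
  for (i in seq_len(nt)) {
    r <- v[i, ]
    if (all(is.na(r))) next
    pos[i, ] <- estimate_raw_position(r, layout, epsilon)
  }
  valid <- which(!is.na(pos[, 1]))
  if (length(valid) == 0) stop("every frame is all-missing", call. = FALSE)
  # carry the previous raw position through all-missing ticks
  idx <- cummax(ifelse(is.na(pos[, 1]), 0L, seq_len(nt)))
  idx[idx == 0L] <- valid[1]
  pos <- pos[idx, , drop = FALSE]

  raw <- point_to_section(pos[, 1], pos[, 2], layout)
  sx <- mode_filter(raw$px, wx)
  sy <- mode_filter(raw$py, wy)
  segments <- segment_passage_walks(sx, layout)
  fy <- if (nrow(segments) == 0)
    suppressWarnings(map_match_y(sy, segments)) else map_match_y(sy, segments)

  out <- data.frame(tick = frames$ticks,
                    raw_px = raw$px, raw_py = raw$py,
                    smooth_px = sx, smooth_py = sy,
                    final_px = sx, final_py = fy)
  attr(out, "segments") <- segments
  class(out) <- c("section_track", "data.frame")
  out
}

#' @export
print.section_track <- function(x, ...) {
  segs <- attr(x, "segments")
  cat(sprintf("<section_track> %d ticks, %d mid-passage walk segment(s), passages visited: %s\n",
              nrow(x), if (is.null(segs)) 0L else nrow(segs),
              paste(unique(x$final_py), collapse = " ")))
  invisible(x)
}
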