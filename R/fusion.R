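#' Synchronize detected events with a section track
#'
#' Position ticks and IMU frames run on different clocks: a tick lasts
#' `tp` seconds, a frame `ta` seconds. The event at frame `m` is assigned
#' the section the track reports at tick `n = floor(m * ta / tp)`. Events
#' falling outside the track's tick span are clamped to the nearest tick
#' with a warning.
#'
#' @param track a `section_track` from [estimate_track()] (the `final`
#'   series is used).
#' @param events an `event_series` from [detect_events()], or an integer
#'   vector of 0-based event frames.
#' @param ta IMU sampling interval in seconds (0.02 at 50 Hz).
#' @param tp position sampling interval in seconds.
#' @return Data frame with columns `frame`, `tick`, `px`, `py` -- one row
#'   per event.
#' @export
synchronize_events <- function(track, events, ta = 0.02, tp = 1.0) {
  stopifnot(inherits(track, "section_track"))
  if (nrow(track) == 0) stop("track is empty", call. = FALSE)
  frames <- if (inherits(events, "event_series")) events$events$frame
            else as.integer(events)
  # tiny nudge so exact-integer products of rational ta/tp are not pushed
  # below the integer by floating-point rounding
  n <- floor(frames * ta / tp + 1e-9)
  lo <- min(track$tick); hi <- max(track$tick)
  if (length(n) > 0 && (any(n < lo) || any(n > hi))) {
    warning("event(s) outside the track's tick span clamped to the nearest tick",
            call. = FALSE)
    n <- pmin(pmax(n, lo), hi)
  }
  i <- match(n, track$tick)
  data.frame(frame = frames, tick = as.integer(n),
             px = track$final_px[i], py = track$final_py[i])
}

#' Build a harvesting map from located events
#'
#' The harvesting map is the 2-dimensional histogram of the sections in
#' which harvesting actions were detected: cell `(px, py)` counts the
#' tomatoes harvested in that section.
#'
#' @param located_events data frame with columns `px`, `py` (0-based
#'   labels), e.g. from [synchronize_events()].
#' @param layout a `field_layout` (fixes the map dimensions).
#' @param laborer_id optional identifier attached to the map.
#' @param ideal ideal per-section count used for percentage rendering.
#' @return An object of class `harvesting_map`: an integer matrix with
#'   `n_sections_x` rows and `n_passages` columns (dimnames are the
#'   0-based labels), with attributes `laborer_id` and `ideal`.
#' @export
build_map <- function(located_events, layout, laborer_id = NULL, ideal = 9) {
  stopifnot(inherits(layout, "field_layout"))
  nx <- layout$n_sections_x; np <- layout$n_passages
  counts <- matrix(0L, nx, np,
                   dimnames = list(px = seq_len(nx) - 1L,
                                   py = seq_len(np) - 1L))
  if (nrow(located_events) > 0) {
    px <- located_events$px; py <- located_events$py
    if (any(px < 0 | px >= nx | py < 0 | py >= np))
      stop("event section labels outside the layout", call. = FALSE)
    t <- table(factor(px, levels = seq_len(nx) - 1L),
               factor(py, levels = seq_len(np) - 1L))
    counts[] <- as.integer(t)
  }
  structure(counts, laborer_id = laborer_id, ideal = ideal,
            class = c("harvesting_map", "matrix"))
}

#' Sum harvesting maps across laborers
#'
#' Elementwise sum of per-laborer maps over identical layouts; the result
#' carries no laborer id.
#'
#' @param maps list of `harvesting_map` objects with identical dimensions.
#' @return A `harvesting_map`.
#' @export
sum_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  dims <- vapply(maps, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1)
    stop("all maps must have identical dimensions", call. = FALSE)
  total <- Reduce(`+`, lapply(maps, unclass))
  structure(total, laborer_id = NULL, ideal = attr(maps[[1]], "ideal"),
            class = c("harvesting_map", "matrix"))
}

#' @export
print.harvesting_map <- function(x, ...) {
  cat(sprintf("<harvesting_map> %d sections x %d passages, %d events%s\n",
              nrow(x), ncol(x), sum(x),
              if (is.null(attr(x, "laborer_id"))) ""
              else paste0(" (laborer ", attr(x, "laborer_id"), ")")))
  print(unclass(x))
  invisible(x)
}

#' Render a harvesting map
#'
#' Draws the section grid of the greenhouse -- ridges as bold lines,
#' section boundaries dotted -- and prints in each cell the harvested
#' count and its percentage of the ideal per-section count `H~`.
#' Percentages are capped at 100% for display; the raw counts are always
#' preserved (and written unmodified when `csv` is given).
#'
#' @param map a `harvesting_map`.
#' @param layout a `field_layout` matching the map dimensions.
#' @param h_ideal ideal harvested count per section (defaults to the map's
#'   `ideal` attribute).
#' @param csv optional path; writes the count matrix as CSV
#'   (rows = X sections, columns = passages).
#' @param file optional path for the figure (`.png` or `.svg`); otherwise
#'   the current graphics device is used.
#' @return Invisibly, a data frame with `px`, `py`, `count`, `percent`.
#' @export
render_map <- function(map, layout, h_ideal = NULL, csv = NULL, file = NULL) {
  stopifnot(inherits(map, "harvesting_map"), inherits(layout, "field_layout"))
  if (is.null(h_ideal)) h_ideal <- attr(map, "ideal")
  if (is.null(h_ideal) || h_ideal <= 0)
    stop("'h_ideal' must be positive", call. = FALSE)
  if (!is.null(csv))
    utils::write.csv(as.data.frame(unclass(map)), csv, row.names = TRUE)

  cells <- section_centers(layout)
  cells$count <- as.integer(map[cbind(cells$px + 1L, cells$py + 1L)])
  cells$percent <- pmin(100, 100 * cells$count / h_ideal)

  if (!is.null(file)) {
    if (grepl("\\.png$", file)) grDevices::png(file, 1200, 400)
    else grDevices::svg(file, 12, 4)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  b <- layout$section_boundaries_x
  ridge_y <- seq(0, layout$field_width_y, length.out = layout$n_passages + 1)
  graphics::plot(NA, xlim = range(b), ylim = c(0, layout$field_width_y),
                 xlab = "X along ridges [m]", ylab = "Y across ridges [m]",
                 main = sprintf("Harvesting map (%d events, ideal %g/section)",
                                sum(map), h_ideal), asp = NA)
  half <- diff(ridge_y)[1] / 2
  for (y in layout$passage_y_centers)
    graphics::abline(h = c(y - half, y + half), lty = 3, col = "grey40")
  graphics::abline(h = ridge_y, lwd = 3, col = "darkgreen")
  graphics::abline(v = b, lty = 3, col = "grey40")
  shade <- grDevices::grey(1 - 0.6 * pmin(1, cells$count / h_ideal))
  graphics::rect(b[cells$px + 1L], cells$y - half * 0.9,
                 b[cells$px + 2L], cells$y + half * 0.9,
                 col = shade, border = NA)
  graphics::abline(h = ridge_y, lwd = 3, col = "darkgreen")
  graphics::text(cells$x, cells$y,
                 sprintf("%d\n%.0f%%", cells$count, cells$percent), cex = 0.55)
  invisible(cells[, c("px", "py", "count", "percent")])
}

#' @rdname render_map
#' @param x a `harvesting_map`.
#' @param ... passed to [render_map()].
#' @export
plot.harvesting_map <- function(x, layout = default_layout(), ...) {
  render_map(x, layout, ...)
}
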