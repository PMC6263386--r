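#' Greenhouse field layout
#'
#' Describes the axis-aligned ridge/passage grid of a tomato greenhouse:
#' the X axis runs along the ridges, the Y axis across them. Each walkable
#' passage is divided into `n_sections_x` sections; a laborer's position is
#' reported at section resolution as a label `(px, py)` with `px` the
#' 0-based X-section index and `py` the 0-based passage index. Passage
#' changes are physically possible only in designated end sections, because
#' the plants are too tall to step over a ridge.
#'
#' @param n_passages number of walkable passages (Y direction).
#' @param n_sections_x number of sections along each passage (X direction).
#' @param field_length_x field length along the ridges, metres.
#' @param field_width_y width of the zone across the ridges, metres.
#' @param section_boundaries_x strictly increasing vector of
#'   `n_sections_x + 1` X coordinates (metres) delimiting the sections.
#'   Defaults to an even split of `field_length_x`.
#' @param passage_y_centers Y coordinate (metres) of each passage centre
#'   line. Defaults to evenly interleaved positions between the ridges.
#' @param end_sections integer vector of 0-based X-section labels where
#'   passage switching is permitted.
#' @param beacons data frame with columns `beacon_id`, `x`, `y`, `ridge`
#'   giving each Bluetooth beacon's identifier, position (metres) and the
#'   ridge it sits on. `beacon_id` must be unique.
#'
#' @return An object of class `field_layout`.
#' @seealso [default_layout()] for the stock 3-passage, 64-beacon geometry;
#'   [load_layout()] to read a layout from YAML/JSON.
#' @export
field_layout <- function(n_passages, n_sections_x,
                         field_length_x, field_width_y,
                         section_boundaries_x = NULL,
                         passage_y_centers = NULL,
                         end_sections = c(0L, n_sections_x - 1L),
                         beacons) {
  stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)

  stop_if(!is.numeric(n_passages) || length(n_passages) != 1 || n_passages < 1,
          "'n_passages' must be a single count >= 1")
  stop_if(!is.numeric(n_sections_x) || length(n_sections_x) != 1 || n_sections_x < 1,
          "'n_sections_x' must be a single count >= 1")
  n_passages <- as.integer(n_passages)
  n_sections_x <- as.integer(n_sections_x)
  stop_if(!is.numeric(field_length_x) || field_length_x <= 0,
          "'field_length_x' must be a positive length in metres")
  stop_if(!is.numeric(field_width_y) || field_width_y <= 0,
          "'field_width_y' must be a positive length in metres")

  if (is.null(section_boundaries_x))
    section_boundaries_x <- seq(0, field_length_x, length.out = n_sections_x + 1)
  stop_if(length(section_boundaries_x) != n_sections_x + 1,
          sprintf("'section_boundaries_x' must have %d values", n_sections_x + 1))
  stop_if(any(diff(section_boundaries_x) <= 0),
          "'section_boundaries_x' must be strictly increasing")

  if (is.null(passage_y_centers)) {
    # passages interleave the n_passages + 1 ridges spanning the zone width
    ridge_y <- seq(0, field_width_y, length.out = n_passages + 1)
    passage_y_centers <- (ridge_y[-1] + ridge_y[-length(ridge_y)]) / 2
  }
  stop_if(length(passage_y_centers) != n_passages,
          "'passage_y_centers' must have one value per passage")

  end_sections <- sort(unique(as.integer(end_sections)))
  stop_if(any(end_sections < 0 | end_sections >= n_sections_x),
          "'end_sections' labels must lie in 0..n_sections_x-1")

  stop_if(missing(beacons) || !is.data.frame(beacons),
          "'beacons' must be a data frame")
  need <- c("beacon_id", "x", "y", "ridge")
  miss <- setdiff(need, names(beacons))
  stop_if(length(miss) > 0,
          paste0("beacon table is missing column(s): ", paste(miss, collapse = ", ")))
  stop_if(anyDuplicated(beacons$beacon_id) > 0,
          "'beacon_id' values must be unique within a layout")
  xr <- range(section_boundaries_x)
  stop_if(any(beacons$x < xr[1] | beacons$x > xr[2] |
                beacons$y < 0 | beacons$y > field_width_y),
          "every beacon position must lie within the field bounds")
  beacons$beacon_id <- as.character(beacons$beacon_id)

  structure(list(
    n_passages = n_passages,
    n_sections_x = n_sections_x,
    field_length_x = field_length_x,
    field_width_y = field_width_y,
    section_boundaries_x = as.numeric(section_boundaries_x),
    passage_y_centers = as.numeric(passage_y_centers),
    end_sections = end_sections,
    beacons = beacons
  ), class = "field_layout")
}

#' Default greenhouse layout
#'
#' The stock geometry used throughout: a 45 m x 6 m experimental zone with
#' four planted ridges separated by three passages, each passage split into
#' 16 sections, and 64 beacons spaced evenly along the four ridges (16 per
#' ridge, each at the X centre of one section). Exact beacon spacing is
#' parametric since real deployments differ.
#'
#' @inheritParams field_layout
#' @param n_beacons_per_ridge beacons placed on each ridge.
#' @return A `field_layout`.
#' @export
default_layout <- function(n_passages = 3L, n_sections_x = 16L,
                           field_length_x = 45, field_width_y = 6,
                           n_beacons_per_ridge = 16L) {
  n_ridges <- n_passages + 1L
  ridge_y <- seq(0, field_width_y, length.out = n_ridges)
  bx <- (seq_len(n_beacons_per_ridge) - 0.5) * field_length_x / n_beacons_per_ridge
  beacons <- data.frame(
    beacon_id = sprintf("B%02d", seq_len(n_ridges * n_beacons_per_ridge)),
    x = rep(bx, times = n_ridges),
    y = rep(ridge_y, each = n_beacons_per_ridge),
    ridge = rep(seq_len(n_ridges) - 1L, each = n_beacons_per_ridge)
  )
  field_layout(n_passages, n_sections_x, field_length_x, field_width_y,
               beacons = beacons)
}

#' Read a field layout from a YAML or JSON config file
#'
#' The document mirrors the [field_layout()] arguments (lengths in metres);
#' `beacons` is a list of records with `beacon_id`, `x`, `y`, `ridge`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file, or a pre-parsed
#'   named list.
#' @return A validated `field_layout`.
#' @export
load_layout <- function(path) {
  cfg <- if (is.list(path)) {
    path
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("n_passages", "n_sections_x", "field_length_x", "field_width_y",
            "beacons")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0)
    stop("layout config is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  beacons <- cfg$beacons
  if (!is.data.frame(beacons))
    beacons <- do.call(rbind, lapply(beacons, function(b) {
      # YAML 1.1 reads a bare key `y` as boolean TRUE; map it back
      names(b)[names(b) %in% c("TRUE", "true")] <- "y"
      as.data.frame(b)
    }))
  field_layout(
    n_passages = cfg$n_passages,
    n_sections_x = cfg$n_sections_x,
    field_length_x = cfg$field_length_x,
    field_width_y = cfg$field_width_y,
    section_boundaries_x = cfg$section_boundaries_x,
    passage_y_centers = cfg$passage_y_centers,
    end_sections = if (is.null(cfg$end_sections))
      c(0L, as.integer(cfg$n_sections_x) - 1L) else cfg$end_sections,
    beacons = beacons
  )
}

#' Write a field layout to YAML
#'
#' @param layout a `field_layout`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "field_layout"))
  cfg <- list(
    n_passages = layout$n_passages,
    n_sections_x = layout$n_sections_x,
    field_length_x = layout$field_length_x,
    field_width_y = layout$field_width_y,
    section_boundaries_x = layout$section_boundaries_x,
    passage_y_centers = layout$passage_y_centers,
    end_sections = layout$end_sections,
    beacons = lapply(seq_len(nrow(layout$beacons)), function(i)
      as.list(layout$beacons[i, c("beacon_id", "x", "y", "ridge")]))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Convert metric coordinates to section labels
#'
#' Maps continuous positions `(x, y)` in metres to section labels
#' `(px, py)`: `px` is the index of the half-open boundary interval
#' `[b_k, b_{k+1})` containing `x` (the last interval is closed above) and
#' `py` is the index of the nearest passage centre line. Points marginally
#' outside the field -- possible when noisy RSSI pulls the raw position
#' estimate past a border -- are clamped to the nearest section so the
#' transform is total.
#'
#' @param x,y numeric vectors of coordinates in metres (recycled to a
#'   common length).
#' @param layout a `field_layout`.
#' @return A data frame with integer columns `px` and `py` (0-based labels).
#' @export
point_to_section <- function(x, y, layout) {
  stopifnot(inherits(layout, "field_layout"))
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  if (anyNA(x) || anyNA(y))
    stop("coordinates must not contain NA/NaN", call. = FALSE)
  b <- layout$section_boundaries_x
  x <- pmin(pmax(x, b[1]), b[length(b)])
  px <- findInterval(x, b, rightmost.closed = TRUE) - 1L
  yc <- layout$passage_y_centers
  # nearest passage centre; on a tie the lower passage index wins
  d <- abs(outer(y, yc, "-"))
  py <- max.col(-d, ties.method = "first") - 1L
  data.frame(px = as.integer(px), py = as.integer(py))
}

#' Section centre coordinates
#'
#' @param layout a `field_layout`.
#' @return Data frame of all sections with columns `px`, `py`, `x`, `y`
#'   (centre coordinates in metres).
#' @export
section_centers <- function(layout) {
  stopifnot(inherits(layout, "field_layout"))
  b <- layout$section_boundaries_x
  cx <- (b[-1] + b[-length(b)]) / 2
  g <- expand.grid(px = seq_len(layout$n_sections_x) - 1L,
                   py = seq_len(layout$n_passages) - 1L)
  g$x <- cx[g$px + 1L]
  g$y <- layout$passage_y_centers[g$py + 1L]
  g
}

#' @export
print.field_layout <- function(x, ...) {
  cat(sprintf("<field_layout> %g m x %g m, %d passages x %d sections, %d beacons\n",
              x$field_length_x, x$field_width_y,
              x$n_passages, x$n_sections_x, nrow(x$beacons)))
  cat(sprintf("  end sections (passage changes allowed): %s\n",
              paste(x$end_sections, collapse = ", ")))
  invisible(x)
}
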