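#' Feature window configuration
#'
#' Geometry of the sliding feature window used for harvesting-action
#' recognition. A window of `l_w = n_sw * n_sq * l_sq` frames is divided
#' into `n_sw` sub-windows, each holding `n_sq` sub-sequences of `l_sq`
#' frames. Every sub-sequence is quantized twice: a SAX symbol (magnitude
#' of the z-normalized sub-sequence mean, 5-letter Gaussian-equiprobable
#' alphabet) and a gradient symbol (angle of the start-to-end slope,
#' 5 levels by thresholding). Per channel and sub-window the `n_sq` symbols
#' of each type are binned into a 5-bin histogram; the concatenation over
#' feature types, sub-windows and channels is the feature vector, of fixed
#' dimension `2 * n_sw * 5 * n_channels`.
#'
#' @param n_sw sub-windows per window.
#' @param n_sq sub-sequences per sub-window.
#' @param l_sq frames per sub-sequence.
#' @param gradient_thresholds four strictly increasing angles (degrees) in
#'   (-90, 90) splitting the slope angle into 5 levels.
#' @param gradient_scale amplitude scale for the slope angle: acceleration
#'   change (signal units) per frame that maps to 45 degrees. The default
#'   0.1 reads as 1 g per 10 frames for data in g.
#' @param sax_breakpoints four breakpoints of the 5-region equiprobable
#'   partition of the standard normal.
#' @return An object of class `feature_config` (a list; `l_w` is derived).
#' @export
feature_config <- function(n_sw = 5L, n_sq = 5L, l_sq = 2L,
                           gradient_thresholds = c(-67.5, -22.5, 22.5, 67.5),
                           gradient_scale = 0.1,
                           sax_breakpoints = stats::qnorm(c(1, 2, 3, 4) / 5)) {
  stopifnot(n_sw >= 1, n_sq >= 1, l_sq >= 2)
  if (length(gradient_thresholds) != 4 || any(diff(gradient_thresholds) <= 0))
    stop("'gradient_thresholds' must be 4 strictly increasing angles",
         call. = FALSE)
  if (length(sax_breakpoints) != 4 || any(diff(sax_breakpoints) <= 0))
    stop("'sax_breakpoints' must be 4 strictly increasing values", call. = FALSE)
  structure(list(
    n_sw = as.integer(n_sw), n_sq = as.integer(n_sq), l_sq = as.integer(l_sq),
    l_w = as.integer(n_sw * n_sq * l_sq),
    gradient_thresholds = gradient_thresholds,
    gradient_scale = gradient_scale,
    sax_breakpoints = sax_breakpoints
  ), class = "feature_config")
}

#' Motion sequence container
#'
#' @param data numeric matrix, frames by channels; column names identify
#'   channels (e.g. `L_ax .. R_az`).
#' @param rate_hz sampling rate in Hz.
#' @return An object of class `motion_sequence`.
#' @export
motion_sequence <- function(data, rate_hz = 50) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), rate_hz > 0)
  if (is.null(colnames(data)))
    colnames(data) <- paste0("ch", seq_len(ncol(data)))
  structure(list(data = data, rate_hz = rate_hz), class = "motion_sequence")
}

#' @export
print.motion_sequence <- function(x, ...) {
  cat(sprintf("<motion_sequence> %d frames x %d channels at %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate_hz, nrow(x$data) / x$rate_hz))
  invisible(x)
}

#' Weighted moving-average smoothing
#'
#' Convolves every channel with the normalized kernel; wrist IMU streams
#' carry high-frequency noise that hurts recognition. Length is preserved:
#' at the edges the kernel is truncated to the available frames and
#' renormalized.
#'
#' @param seq a `motion_sequence` (or plain matrix/vector).
#' @param weights non-negative kernel weights with positive sum; odd length
#'   centres the kernel. Default is a 5-frame triangular kernel.
#' @return Object of the same type as `seq`, smoothed.
#' @export
smooth_motion <- function(seq, weights = c(1, 2, 3, 2, 1)) {
  if (any(weights < 0) || sum(weights) <= 0)
    stop("kernel weights must be non-negative with positive sum", call. = FALSE)
  is_ms <- inherits(seq, "motion_sequence")
  x <- if (is_ms) seq$data else as.matrix(seq)
  k <- length(weights)
  if (k > nrow(x))
    stop("kernel is longer than the sequence", call. = FALSE)
  half <- (k - 1) %/% 2
  n <- nrow(x)
  num <- matrix(0, n, ncol(x))
  den <- numeric(n)
  for (j in seq_len(k)) {
    off <- j - 1 - half
    src <- seq_len(n) + off
    ok <- src >= 1 & src <= n
    num[ok, ] <- num[ok, ] + weights[j] * x[src[ok], , drop = FALSE]
    den[ok] <- den[ok] + weights[j]
  }
  sm <- num / den
  colnames(sm) <- colnames(x)
  if (is_ms) motion_sequence(sm, seq$rate_hz) else sm
}

#' SAX symbol of one sub-sequence
#'
#' Z-normalizes the sub-sequence mean by the statistics of its
#' normalization scope (here, the enclosing window) and maps it through the
#' 5-region Gaussian equiprobable breakpoints to a symbol in -2..+2. A zero
#' (or undefined) scope standard deviation yields the middle symbol 0.
#'
#' @param subseq numeric vector (`l_sq` frames of one channel).
#' @param stats `c(mean, sd)` of the normalization scope.
#' @param breakpoints the 4 breakpoints (see [feature_config()]).
#' @return Integer symbol in -2..+2.
#' @export
sax_symbol <- function(subseq, stats,
                       breakpoints = stats::qnorm(c(1, 2, 3, 4) / 5)) {
  if (!is.finite(stats[2]) || stats[2] <= 0) return(0L)
  z <- (mean(subseq) - stats[1]) / stats[2]
  findInterval(z, breakpoints) - 2L
}

#' Gradient symbol of one sub-sequence
#'
#' The slope between the first and last frame, expressed as an angle
#' `atan((last - first) / ((l_sq - 1) * scale))`, quantized into 5 levels
#' by four angle thresholds.
#'
#' @inheritParams sax_symbol
#' @param thresholds four increasing angles in degrees.
#' @param scale amplitude scale (signal units per frame at 45 degrees).
#' @return Integer symbol in -2..+2.
#' @export
gradient_symbol <- function(subseq, thresholds = c(-67.5, -22.5, 22.5, 67.5),
                            scale = 0.1) {
  l <- length(subseq)
  if (l < 2) stop("sub-sequence needs at least 2 frames", call. = FALSE)
  ang <- atan((subseq[l] - subseq[1]) / ((l - 1) * scale)) * 180 / pi
  findInterval(ang, thresholds) - 2L
}

#' Feature vector of one window
#'
#' @param window numeric matrix of exactly `l_w` frames by channels.
#' @param cfg a [feature_config()].
#' @return Numeric feature vector of length `2 * n_sw * 5 * n_channels`,
#'   ordered channel-major: per channel, per sub-window, the 5-bin SAX
#'   histogram then the 5-bin gradient histogram. Each histogram sums to
#'   `n_sq`.
#' @export
window_features <- function(window, cfg = feature_config()) {
  window <- as.matrix(window)
  if (nrow(window) != cfg$l_w)
    stop(sprintf("window must have exactly l_w = %d frames", cfg$l_w),
         call. = FALSE)
  as.numeric(extract_features(window, starts = 1L, cfg = cfg))
}

#' Feature matrix for many window positions
#'
#' Computes [window_features()] for windows starting at each requested
#' frame, sharing the per-channel rolling statistics so that frame-by-frame
#' scanning of a long sequence stays fast.
#'
#' @param x a `motion_sequence` or frames-by-channels matrix.
#' @param starts 1-based start frames; every window `[s, s + l_w - 1]` must
#'   fit in the sequence.
#' @param cfg a [feature_config()].
#' @return Matrix `length(starts)` by `2 * n_sw * 5 * n_channels`.
#' @export
extract_features <- function(x, starts, cfg = feature_config()) {
  if (inherits(x, "motion_sequence")) x <- x$data
  x <- as.matrix(x)
  n <- nrow(x); nc <- ncol(x)
  lw <- cfg$l_w; lsq <- cfg$l_sq; nsq <- cfg$n_sq; nsw <- cfg$n_sw
  starts <- as.integer(starts)
  if (length(starts) == 0)
    return(matrix(numeric(0), 0, 2L * nsw * 5L * nc))
  if (any(starts < 1 | starts + lw - 1 > n))
    stop("every window must fit within the sequence", call. = FALSE)

  m <- length(starts)
  sub_off <- (seq_len(nsw * nsq) - 1L) * lsq      # sub-sequence offsets in a window
  thr <- cfg$gradient_thresholds
  brk <- cfg$sax_breakpoints
  out <- matrix(0, m, 2L * nsw * 5L * nc)
  col0 <- 0L
  for (ch in seq_len(nc)) {
    v <- x[, ch]
    cs <- cumsum(c(0, v)); cs2 <- cumsum(c(0, v^2))
    # rolling sub-sequence means and window mean/sd via cumulative sums
    smean <- (cs[(lsq + 1):(n + 1)] - cs[1:(n - lsq + 1)]) / lsq
    wmean <- (cs[(lw + 1):(n + 1)] - cs[1:(n - lw + 1)]) / lw
    wvar <- (cs2[(lw + 1):(n + 1)] - cs2[1:(n - lw + 1)]) / lw - wmean^2
    wsd <- sqrt(pmax(wvar, 0) * lw / (lw - 1))
    # guard against float noise on (near-)constant windows: force sd to 0 so
    # the z-score becomes non-finite and the middle symbol is used
    wsd[wvar < 1e-10 * pmax(wmean^2, 1)] <- 0
    gang <- atan((v[(lsq):n] - v[1:(n - lsq + 1)]) /
                   ((lsq - 1) * cfg$gradient_scale)) * 180 / pi

    idx <- outer(starts, sub_off, "+")           # m x (nsw*nsq) sub-sequence starts
    wm <- wmean[starts]; ws <- wsd[starts]
    z <- (matrix(smean[idx], m) - wm) / ws
    ssym <- matrix(findInterval(z, brk) - 2L, m)
    ssym[!is.finite(z)] <- 0L                    # sd == 0: flat window, middle symbol
    gsym <- matrix(findInterval(gang[idx], thr) - 2L, m)

    for (sw in seq_len(nsw)) {
      cols <- ((sw - 1L) * nsq + 1L):(sw * nsq)
      s_sub <- ssym[, cols, drop = FALSE]
      g_sub <- gsym[, cols, drop = FALSE]
      base <- col0 + (sw - 1L) * 10L
      for (b in -2:2) {
        out[, base + b + 3L] <- rowSums(s_sub == b)
        out[, base + b + 8L] <- rowSums(g_sub == b)
      }
    }
    col0 <- col0 + nsw * 10L
  }
  colnames(out) <- feature_names(nc, cfg, colnames(x))
  out
}

feature_names <- function(nc, cfg, ch_names = NULL) {
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(nc))
  unlist(lapply(ch_names, function(ch)
    unlist(lapply(seq_len(cfg$n_sw), function(sw)
      c(sprintf("%s_sw%d_sax_%d", ch, sw, -2:2),
        sprintf("%s_sw%d_grad_%d", ch, sw, -2:2))))))
}
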