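# shared fixtures: tiny layouts and brute-force oracles used across files

tiny_layout <- function() {
  field_layout(
    n_passages = 2, n_sections_x = 4, field_length_x = 8, field_width_y = 4,
    beacons = data.frame(beacon_id = c("a", "b", "c", "d"),
                         x = c(1, 3, 5, 7), y = c(0, 0, 4, 4),
                         ridge = c(0, 0, 2, 2))
  )
}

# quick simulation config: a short day that still spans all passages
short_cfg <- function(seed = 7L, ...) {
  sim_config(seed = seed, dwell_mean = 8, n_events = 20L, ...)
}

# exhaustive rectangle-membership section lookup (independent of
# point_to_section's findInterval path)
oracle_section <- function(x, y, layout) {
  b <- layout$section_boundaries_x
  x <- min(max(x, b[1]), b[length(b)])
  px <- NA_integer_
  for (k in seq_len(layout$n_sections_x)) {
    hi_ok <- if (k == layout$n_sections_x) x <= b[k + 1] else x < b[k + 1]
    if (x >= b[k] && hi_ok) { px <- k - 1L; break }
  }
  d <- abs(layout$passage_y_centers - y)
  py <- which(d == min(d))[1] - 1L
  c(px = px, py = py)
}

# frequency-count mode with smallest-label tie-break
oracle_mode <- function(v) {
  u <- sort(unique(v))
  cnt <- vapply(u, function(z) sum(v == z), integer(1))
  u[which(cnt == max(cnt))[1]]
}

oracle_mode_filter <- function(series, w) {
  n <- length(series)
  out <- integer(n)
  for (i in seq_len(n))
    out[i] <- oracle_mode(series[max(1, i - w):min(n, i + w)])
  out
}

# brute-force application of the event rules: threshold + local maxima
# (first frame of a plateau, ends count as lower) + 2*l_w suppression
oracle_detect <- function(a, th, lw) {
  m <- length(a)
  cand <- integer(0)
  for (i in seq_len(m)) {
    prev <- if (i == 1) -Inf else a[i - 1]
    nxt <- if (i == m) -Inf else a[i + 1]
    if (a[i] > th && a[i] > prev && a[i] >= nxt) cand <- c(cand, i)
  }
  acc <- integer(0)
  for (i in cand)
    if (length(acc) == 0 || i - acc[length(acc)] >= 2 * lw)
      acc <- c(acc, i)
  acc - 1L
}

# maximum bipartite matching size between detections and truths within
# tolerance, by augmenting paths (optimal one-to-one matching oracle)
oracle_max_matching <- function(det, tru, tol) {
  adj <- lapply(seq_along(det), function(i) which(abs(tru - det[i]) <= tol))
  match_t <- rep(0L, length(tru))
  try_aug <- function(i, seen) {
    for (j in adj[[i]]) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (match_t[j] == 0L || Recall(match_t[j], seen)) {
        match_t[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  size <- 0L
  for (i in seq_along(det)) {
    seen <- rep(FALSE, length(tru))
    if (length(adj[[i]]) > 0 && try_aug(i, seen)) size <- size + 1L
  }
  size
}
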