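#' Build a labelled training set for harvesting-action recognition
#'
#' One positive window is extracted per annotated harvesting action,
#' aligned so the window starts at the action's start frame. Negative
#' windows are slid frame by frame over the non-harvesting periods (start
#' frames farther than `l_w` frames from every annotated start, so a
#' negative window can never overlap an action interval) and subsampled to
#' a configurable negative:positive ratio.
#'
#' @param seq a `motion_sequence` (already smoothed if desired).
#' @param event_starts integer vector of 0-based start frames of the true
#'   harvesting actions.
#' @param cfg a [feature_config()].
#' @param neg_ratio negatives kept per positive (`Inf` keeps all).
#' @param seed integer seed for the negative subsampling.
#' @return List with `features` (matrix), `labels` (factor `"0"`/`"1"`),
#'   and `positive_starts` (0-based starts actually used).
#' @export
make_training_set <- function(seq, event_starts, cfg = feature_config(),
                              neg_ratio = 5, seed = 1L) {
  x <- if (inherits(seq, "motion_sequence")) seq$data else as.matrix(seq)
  n <- nrow(x)
  lw <- cfg$l_w
  if (n < lw) stop("sequence shorter than one window", call. = FALSE)
  event_starts <- sort(as.integer(event_starts))
  if (length(event_starts) == 0) stop("no annotated events", call. = FALSE)
  if (any(event_starts < 0 | event_starts >= n))
    stop("event starts must lie within the sequence", call. = FALSE)

  fits <- event_starts + lw <= n          # window [e, e + lw) must fit
  if (any(!fits))
    warning(sum(!fits), " event(s) within the final l_w - 1 frames skipped",
            call. = FALSE)
  pos <- event_starts[fits]
  if (length(pos) == 0) stop("no annotated event fits a full window", call. = FALSE)

  all_starts <- 0:(n - lw)
  near <- outer(all_starts, event_starts, function(a, e) abs(a - e) <= lw)
  neg <- all_starts[!apply(near, 1, any)]
  if (is.finite(neg_ratio) && length(neg) > neg_ratio * length(pos)) {
    set.seed(as.integer(seed))
    neg <- sort(sample(neg, neg_ratio * length(pos)))
  }

  starts <- c(pos, neg)
  feats <- extract_features(x, starts + 1L, cfg)
  labels <- factor(rep(c("1", "0"), c(length(pos), length(neg))),
                   levels = c("0", "1"))
  list(features = feats, labels = labels, positive_starts = pos)
}

#' Train the harvesting-action classifier
#'
#' A random forest in a one-versus-rest framing: the harvesting action is
#' the target class, everything else in the work stream is the rest. The
#' forest's vote fraction for the harvesting class is used downstream as a
#' per-window posterior. Training is deterministic given `seed`.
#'
#' @param features numeric feature matrix (rows = windows).
#' @param labels factor with levels `"0"` (normal) and `"1"` (harvesting).
#' @param seed integer seed.
#' @param ntree number of trees.
#' @return An object of class `harvest_classifier` wrapping the forest.
#' @importFrom randomForest randomForest
#' @export
train_classifier <- function(features, labels, seed = 1L, ntree = 100L) {
  labels <- factor(labels, levels = c("0", "1"))
  if (nlevels(droplevels(labels)) < 2)
    stop("training data must contain both classes", call. = FALSE)
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = features, y = labels, ntree = ntree)
  structure(list(forest = rf, n_features = ncol(features), seed = seed),
            class = "harvest_classifier")
}

#' @export
print.harvest_classifier <- function(x, ...) {
  cat(sprintf("<harvest_classifier> random forest, %d trees, %d features\n",
              x$forest$ntree, x$n_features))
  invisible(x)
}

#' Posterior probability for new windows
#'
#' @param object a `harvest_classifier`.
#' @param features feature matrix as from [extract_features()].
#' @param ... unused.
#' @return Numeric vector in `[0, 1]`: posterior of the harvesting class
#'   per window.
#' @export
predict.harvest_classifier <- function(object, features, ...) {
  unname(predict(object$forest, features, type = "prob")[, "1"])
}

#' Score a motion sequence frame by frame
#'
#' Extracts the window starting at every frame `m` (`0 <= m <= M - l_w`)
#' and evaluates the classifier, yielding the posterior series `a(m)`.
#'
#' @param model a `harvest_classifier`.
#' @param seq a `motion_sequence` (smoothed with the same settings as the
#'   training data).
#' @param cfg a [feature_config()].
#' @param chunk windows scored per batch (memory control).
#' @return Numeric vector `a` with `a[m + 1]` the posterior of the window
#'   starting at 0-based frame `m`.
#' @export
score_sequence <- function(model, seq, cfg = feature_config(), chunk = 20000L) {
  x <- if (inherits(seq, "motion_sequence")) seq$data else as.matrix(seq)
  n <- nrow(x)
  if (n < cfg$l_w) stop("sequence shorter than one window", call. = FALSE)
  starts <- seq_len(n - cfg$l_w + 1L)
  post <- numeric(length(starts))
  for (i in seq(1L, length(starts), by = chunk)) {
    j <- min(i + chunk - 1L, length(starts))
    feats <- extract_features(x, starts[i:j], cfg)
    post[i:j] <- predict.harvest_classifier(model, feats)
  }
  post
}

#' Extract harvesting events from a posterior series
#'
#' Candidate frames are the local maxima of `a(m)` exceeding the threshold
#' `th_a` (a local maximum satisfies `a(m-1) < a(m) >= a(m+1)`, so the
#' first frame of a plateau wins; series ends count as lower neighbours).
#' Scanning candidates in time order, any candidate closer than `2 * l_w`
#' frames to the previously accepted one is discarded -- one harvesting
#' action cannot follow another faster than two window lengths.
#'
#' @param posterior numeric vector `a(m)` (index 1 = frame 0).
#' @param th_a acceptance threshold in (0, 1).
#' @param l_w window length in frames.
#' @return An object of class `event_series`: list with `events` (data
#'   frame `frame` -- 0-based -- and `posterior`), the input `posterior`,
#'   `th_a` and `l_w`. The binary indicator `A(m)` is 1 exactly at the
#'   accepted frames.
#' @export
detect_events <- function(posterior, th_a = 0.5, l_w = 50L) {
  if (!is.numeric(th_a) || th_a <= 0 || th_a >= 1)
    stop("'th_a' must lie in (0, 1)", call. = FALSE)
  m <- length(posterior)
  cand <- integer(0)
  if (m > 0) {
    prev <- c(-Inf, posterior[-m])
    nxt <- c(posterior[-1], -Inf)
    cand <- which(posterior > prev & posterior >= nxt &
                    posterior > th_a)
  }
  acc <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= 2 * l_w) {
      acc <- c(acc, i)
      last <- i
    }
  }
  structure(list(
    events = data.frame(frame = acc - 1L, posterior = posterior[acc]),
    posterior = posterior, th_a = th_a, l_w = as.integer(l_w)
  ), class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %d event(s) over %d scored frames (th_a = %g)\n",
              nrow(x$events), length(x$posterior), x$th_a))
  invisible(x)
}
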