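#' Count revisits to the buffer around each GPS fix
#'
#' For every fix, counts the number of distinct entries of the track into
#' the circle of radius `radius` centred on that fix: a revisit count is
#' the number of maximal time-contiguous runs of fixes lying within the
#' buffer (the run containing the fix itself counts as one, so every
#' count is >= 1). Elevated revisit counts combined with slowed movement
#' are the recursive-movement signature of a mother repeatedly returning
#' to a hidden calf.
#'
#' @param track data.frame of time-ordered fixes: `t`, `x`, `y`.
#' @param radius buffer radius in metres (default 300, wide enough that
#'   return visits to a calf that has shifted hiding spots still register).
#' @return integer vector of revisit counts, one per fix.
#' @export
count_revisits <- function(track, radius = 300) {
  if (nrow(track) < 2) stopf("need at least 2 fixes")
  x <- track$x; y <- track$y
  if (any(!is.finite(x)) || any(!is.finite(y))) stopf("non-finite coordinates")
  r2 <- radius^2
  n <- length(x)
  counts <- integer(n)
  for (i in seq_len(n)) {
    inb <- (x - x[i])^2 + (y - y[i])^2 <= r2
    counts[i] <- sum(inb & !c(FALSE, inb[-n]))
  }
  counts
}

#' Per-fix movement features for calving-event classification
#'
#' Computes the features the event classifier uses: the revisit count in a
#' `radius`-m buffer, the mean step length and the net displacement rate
#' (metres per hour, so values are comparable where the centred window is
#' truncated at the track ends) in a centred 24-h window, and the hour of
#' day. Slow, recursive, low-displacement movement marks the calf-hiding
#' phase.
#'
#' @inheritParams count_revisits
#' @param radius buffer radius (m) for the revisit count.
#' @return data.frame with columns `revisits`, `mean_step`, `disp_rate`,
#'   `hour` (one row per fix).
#' @export
calving_features <- function(track, radius = 300) {
  n <- nrow(track)
  tt <- as.numeric(track$t)
  step_len <- c(sqrt(diff(track$x)^2 + diff(track$y)^2), 0)
  a <- findInterval(tt - 12 * 3600, tt) + 1L
  b <- findInterval(tt + 12 * 3600, tt)
  cs <- c(0, cumsum(step_len))
  mean_step <- (cs[b + 1L] - cs[a]) / (b - a + 1L)
  span_h <- pmax((tt[b] - tt[a]) / 3600, 1e-9)
  disp_rate <- sqrt((track$x[b] - track$x[a])^2 + (track$y[b] - track$y[a])^2) / span_h
  data.frame(
    revisits = count_revisits(track, radius),
    mean_step = mean_step,
    disp_rate = disp_rate,
    hour = as.numeric(format(track$t, "%H", tz = "UTC")) +
      as.numeric(format(track$t, "%M", tz = "UTC")) / 60)
}

#' Configuration for the calving detector
#'
#' @param radius revisit buffer radius, metres.
#' @param event_length calving-event window length, days (the intensive
#'   calf-hiding phase).
#' @param season `"MM-DD"` start/end of the detection season.
#' @param n_repeats number of classifier retrain repeats; repeats differ
#'   only in the down-sampling and classifier seeds.
#' @param classifier a pluggable classifier: a list with
#'   `fit(x, y, seed)` and `predict_prob(model, x)`; default is a
#'   random-forest ensemble ([default_classifier()]).
#' @param seed integer seed.
#' @return list of class `detector_config`.
#' @export
detector_config <- function(radius = 300, event_length = 5,
                            season = c("05-15", "07-20"), n_repeats = 100,
                            classifier = default_classifier(), seed = 1L) {
  if (radius <= 0) stopf("radius must be > 0")
  if (event_length < 1) stopf("event_length must be >= 1 day")
  if (n_repeats < 1) stopf("n_repeats must be >= 1")
  structure(list(radius = radius, event_length = event_length, season = season,
                 n_repeats = n_repeats, classifier = classifier,
                 seed = as.integer(seed)),
            class = "detector_config")
}

#' Default random-forest event classifier
#'
#' A probability random forest (via \pkg{ranger}) satisfying the pluggable
#' classifier contract `fit(x, y, seed)` / `predict_prob(model, x)`.
#'
#' @param num_trees trees per forest.
#' @return classifier list.
#' @export
default_classifier <- function(num_trees = 100) {
  list(
    fit = function(x, y, seed) {
      ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                     num.trees = num_trees, probability = TRUE,
                     seed = as.integer(seed), num.threads = 1L)
    },
    predict_prob = function(model, x) {
      stats::predict(model, data = x, num.threads = 1L)$predictions[, "1"]
    },
    # out-of-bag probabilities for the training rows, in training order
    oob_prob = function(model) model$predictions[, "1"])
}

# pooled labelled feature table for tracks with known events
event_training_table <- function(tracks, events, config) {
  out <- lapply(seq_len(nrow(events)), function(k) {
    tr <- season_window(tracks[tracks$individual_id == events$individual_id[k], ],
                        events$year[k], config)
    if (nrow(tr) < 3) return(NULL)
    ft <- calving_features(tr, config$radius)
    d0 <- as.POSIXct(as.character(events$calving_date[k]), tz = "UTC")
    ft$label <- as.integer(tr$t >= d0 & tr$t < d0 + config$event_length * 86400)
    ft$event <- k
    ft
  })
  do.call(rbind, out)
}

season_window <- function(track, year, config) {
  t0 <- mmdd(year, config$season[1]); t1 <- mmdd(year, config$season[2]) + 86400
  tr <- track[track$t >= t0 & track$t < t1, ]
  tr[order(tr$t), ]
}

#' Train the calving-event classifier and its detection threshold
#'
#' Labels every in-season fix of the training tracks as inside/outside
#' the `[calving_date, calving_date + event_length)` window of its
#' individual's confirmed event, balances the classes by seeded
#' down-sampling without replacement, fits the classifier, and sets the
#' detection threshold to the mean predicted probability over the fixes
#' inside observed calving events. With two or more training events the
#' in-event probabilities are predicted leave-one-event-out (each event
#' scored by a classifier trained on the remaining events), so the
#' threshold reflects how an event the model has not seen scores;
#' otherwise out-of-bag (or, failing that, resubstitution) predictions
#' are used.
#'
#' @param tracks data.frame of fixes for individuals with confirmed
#'   events.
#' @param events data.frame of confirmed events: `individual_id`, `year`,
#'   `calving_date`.
#' @param config a [detector_config()].
#' @param seed integer seed for this training repeat.
#' @param table precomputed labelled feature table (internal cache used by
#'   [screen_calving()] so features are extracted once, not per repeat).
#' @return list with `model`, `threshold`, `classifier`.
#' @export
train_event_classifier <- function(tracks, events, config = detector_config(),
                                   seed = config$seed, table = NULL) {
  tab <- table %||% event_training_table(tracks, events, config)
  if (is.null(tab) || sum(tab$label == 1) == 0)
    stopf("no positive-class fixes inside the confirmed event windows")
  feats <- c("revisits", "mean_step", "disp_rate", "hour")
  balanced_fit <- function(d, key) {
    pos <- which(d$label == 1); neg <- which(d$label == 0)
    nk <- min(length(pos), length(neg))
    if (nk == 0) stopf("training set has a single class after down-sampling")
    keep <- with_seed(child_seed(seed, paste0(key, "balance")),
                      c(sample(pos, nk), sample(neg, nk)))
    list(model = config$classifier$fit(d[keep, feats], d$label[keep],
                                       seed = child_seed(seed, paste0(key, "fit"))),
         n_pos = nk, keep = keep)
  }
  full <- balanced_fit(tab, "full")
  ev_ids <- unique(tab$event[tab$label == 1])
  threshold <- if (length(ev_ids) >= 2) {
    loo <- unlist(lapply(ev_ids, function(e) {
      f <- balanced_fit(tab[tab$event != e, ], paste0("loo", e))
      config$classifier$predict_prob(f$model,
                                     tab[tab$event == e & tab$label == 1, feats])
    }))
    mean(loo)
  } else if (!is.null(config$classifier$oob_prob)) {
    mean(config$classifier$oob_prob(full$model)[seq_len(full$n_pos)], na.rm = TRUE)
  } else {
    mean(config$classifier$predict_prob(full$model, tab[tab$label == 1, feats]))
  }
  list(model = full$model, threshold = threshold, classifier = config$classifier)
}

# windows advance fix-by-fix; only windows fully inside the track count
window_means <- function(tt, p, len_days) {
  L <- len_days * 86400
  ok <- which(tt + L <= tt[length(tt)] + 1e-6)
  if (!length(ok)) stopf("track shorter than one event window")
  e <- findInterval(tt[ok] + L - 1e-6, tt)
  cs <- c(0, cumsum(p))
  mean_p <- (cs[e + 1L] - cs[ok]) / (e - ok + 1L)
  data.frame(start = ok, end = e, mean_p = mean_p)
}

#' Detect a calving event in a GPS track
#'
#' Screens one (or, with [screen_calving()], many) unconfirmed track(s)
#' for a calving event. Per repeat, the classifier is retrained with a
#' fresh seed on the confirmed-event tracks and the test track is scored;
#' per-fix probabilities are then averaged across repeats, and the
#' `event_length`-day rolling window (advancing fix-by-fix, ties broken
#' by the earliest start) with the highest mean probability is returned,
#' provided it exceeds the (repeat-averaged) threshold -- otherwise no
#' event is reported. The spread of the per-repeat best window start
#' dates is recorded as a precision diagnostic.
#'
#' @param track data.frame of fixes for the screened individual.
#' @param year season year to screen.
#' @param train_tracks,train_events confirmed-event training data.
#' @param config a [detector_config()].
#' @return a `calving_prediction` (list with `individual_id`, `year`,
#'   `calving_date`, `window_start`, `window_end`, `mean_prob`,
#'   `threshold`, `date_range_days`, `date_se_days`), or `NULL` when no
#'   window exceeds the threshold.
#' @export
detect_calving <- function(track, year, train_tracks, train_events,
                           config = detector_config()) {
  res <- screen_calving(list(track), years = year, train_tracks = train_tracks,
                        train_events = train_events, config = config)
  res[[1]]
}

#' @rdname detect_calving
#' @param tracks list of test tracks (data.frames).
#' @param years vector of season years, one per test track (recycled).
#' @export
screen_calving <- function(tracks, years, train_tracks, train_events,
                           config = detector_config()) {
  years <- rep_len(years, length(tracks))
  feats <- c("revisits", "mean_step", "disp_rate", "hour")
  test <- lapply(seq_along(tracks), function(i) {
    tr <- season_window(tracks[[i]], years[i], config)
    if (nrow(tr) < 3) stopf("test track %d has fewer than 3 in-season fixes", i)
    list(track = tr, features = calving_features(tr, config$radius))
  })
  probs <- lapply(test, function(d) matrix(0, nrow(d$features), config$n_repeats))
  thresholds <- numeric(config$n_repeats)
  rep_best <- matrix(NA_real_, length(test), config$n_repeats) # best first-date per repeat, numeric days
  tab <- event_training_table(train_tracks, train_events, config)
  for (r in seq_len(config$n_repeats)) {
    cl <- train_event_classifier(train_tracks, train_events, config,
                                 seed = child_seed(config$seed, paste0("rep", r)),
                                 table = tab)
    thresholds[r] <- cl$threshold
    for (i in seq_along(test)) {
      p <- config$classifier$predict_prob(cl$model, test[[i]]$features[, feats])
      probs[[i]][, r] <- p
      wm <- window_means(as.numeric(test[[i]]$track$t), p, config$event_length)
      exc <- wm[wm$mean_p > cl$threshold, ]
      if (nrow(exc))
        rep_best[i, r] <- as.numeric(as.Date(
          test[[i]]$track$t[exc$start[which.max(exc$mean_p)]], tz = "UTC"))
    }
  }
  thr <- mean(thresholds)
  lapply(seq_along(test), function(i) {
    tr <- test[[i]]$track
    p_bar <- rowMeans(probs[[i]])
    wm <- window_means(as.numeric(tr$t), p_bar, config$event_length)
    exc <- wm[wm$mean_p > thr, ]
    if (!nrow(exc)) return(NULL)
    best <- exc[which.max(exc$mean_p), ] # which.max takes the earliest on ties
    firsts <- rep_best[i, !is.na(rep_best[i, ])]
    structure(list(
      individual_id = tr$individual_id[1], year = years[i],
      calving_date = as.Date(tr$t[best$start], tz = "UTC"),
      window_start = tr$t[best$start], window_end = tr$t[best$end],
      mean_prob = best$mean_p, threshold = thr,
      date_range_days = if (length(firsts)) as.numeric(diff(range(firsts))) else NA_real_,
      date_se_days = if (length(firsts) > 1) sd(as.numeric(firsts)) / sqrt(length(firsts)) else NA_real_),
      class = "calving_prediction")
  })
}

#' @export
print.calving_prediction <- function(x, ...) {
  cat(sprintf("calving prediction: %s %d, date %s (window mean prob %.3f > %.3f, repeat range %.1f d)\n",
              x$individual_id, x$year, format(x$calving_date), x$mean_prob,
              x$threshold, x$date_range_days))
  invisible(x)
}
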