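#' Configuration for fecal-sample identity screening
#'
#' @param accuracy_threshold minimum mean predicted identification
#'   accuracy for accepting a sample (default 0.77, the training-model
#'   accuracy used as the decision threshold).
#' @param n_iterations scorer repetitions per (sample, candidate) pair.
#' @param candidate_radius radius (m) of the candidate search around the
#'   sample location.
#' @param lookback_days look-back (d) before sample collection for the
#'   candidate search.
#' @param seed integer seed; per-sample seeds are derived from the sample
#'   id so screening is order-independent.
#' @return list of class `assignment_config`.
#' @export
assignment_config <- function(accuracy_threshold = 0.77, n_iterations = 500,
                              candidate_radius = 20, lookback_days = 2,
                              seed = 1L) {
  if (accuracy_threshold <= 0 || accuracy_threshold >= 1)
    stopf("accuracy_threshold must be in (0, 1)")
  if (n_iterations < 1) stopf("n_iterations must be >= 1")
  structure(list(accuracy_threshold = accuracy_threshold,
                 n_iterations = n_iterations,
                 candidate_radius = candidate_radius,
                 lookback_days = lookback_days, seed = as.integer(seed)),
            class = "assignment_config")
}

# proximity/recency features of a track around a sample's deposition window
assignment_features <- function(sample, track, idx = NULL) {
  t1 <- sample$collection_time
  t0 <- t1 - 2 * 86400
  fx <- track[track$t >= t0 & track$t <= t1, ]
  if (!is.null(idx)) fx <- fx[idx, , drop = FALSE]
  if (nrow(fx) == 0)
    return(c(min_dist = 5000, n_near = 0, dt_hours = 48))
  d <- sqrt((fx$x - sample$x)^2 + (fx$y - sample$y)^2)
  j <- which.min(d)
  c(min_dist = min(min(d), 5000),
    n_near = sum(d <= 100),
    dt_hours = min(abs(as.numeric(difftime(fx$t[j], sample$deposition_time,
                                           units = "hours"))), 48))
}

#' Train the default sample-identity scorer
#'
#' A minimal pluggable scorer standing in for a full movement-based
#' identity model: logistic regression of "sample belongs to this
#' individual" on proximity/recency features of the candidate track
#' around the sample (minimum distance to the sample location in the 2-d
#' pre-collection window, number of fixes within 100 m, and time offset
#' between deposition and the closest approach). Positive training pairs
#' are the DNA-identified samples with their own tracks; negatives pair
#' each with a different randomly drawn individual. Each scoring
#' iteration bootstrap-resamples the window fixes, so repeated scoring of
#' one pair yields a distribution of predicted accuracies whose mean is
#' thresholded by [assign_sample()]. Any replacement scorer needs only a
#' `predict(sample, track, seed)` element returning a value in `[0, 1]`.
#'
#' @param known_samples data.frame of DNA-identified samples (needs `x`,
#'   `y`, `deposition_time`, `collection_time`, `true_individual`).
#' @param tracks data.frame of all fixes.
#' @param seed integer seed.
#' @return scorer list with elements `predict` and `model`.
#' @export
train_default_scorer <- function(known_samples, tracks, seed = 1L) {
  ids <- unique(tracks$individual_id)
  rows <- list()
  with_seed(seed, {
    for (k in seq_len(nrow(known_samples))) {
      s <- known_samples[k, ]
      own <- s$true_individual
      other <- if (length(ids) > 1) sample(setdiff(ids, own), 1) else own
      rows[[length(rows) + 1L]] <- c(assignment_features(
        s, tracks[tracks$individual_id == own, ]), label = 1)
      rows[[length(rows) + 1L]] <- c(assignment_features(
        s, tracks[tracks$individual_id == other, ]), label = 0)
    }
  })
  d <- as.data.frame(do.call(rbind, rows))
  fit <- stats::glm(label ~ min_dist + n_near + dt_hours, data = d,
                    family = stats::binomial())
  co <- coef(fit); co[is.na(co)] <- 0
  list(
    model = fit,
    predict = function(sample, track, seed) {
      t1 <- sample$collection_time
      fx <- track[track$t >= t1 - 2 * 86400 & track$t <= t1, ]
      n <- nrow(fx)
      f <- with_seed(seed, {
        idx <- if (n > 0) sample.int(n, n, replace = TRUE) else NULL
        assignment_features(sample, fx, idx)
      })
      unname(stats::plogis(co[1] + sum(co[-1] * f)))
    })
}

#' Score one sample against one candidate individual
#'
#' Runs the scorer `n_iterations` times with seeds derived from the
#' (sample, individual) pair and averages the predictions; the sample is
#' accepted for the candidate when the mean predicted accuracy reaches
#' the threshold.
#'
#' @param sample one-row data.frame with the sample's location and times.
#' @param track fixes of the candidate individual.
#' @param scorer a scorer (see [train_default_scorer()]).
#' @param config an [assignment_config()].
#' @return list with `mean_accuracy` and `accepted`.
#' @export
assign_sample <- function(sample, track, scorer, config = assignment_config()) {
  t1 <- sample$collection_time
  near <- track$t >= t1 - config$lookback_days * 86400 & track$t <= t1
  if (!any(near))
    stopf("no track data in the sample's spatiotemporal vicinity (sample %s)",
          sample$sample_id %||% "?")
  key <- paste0(sample$sample_id %||% "s", "|", track$individual_id[1])
  preds <- vapply(seq_len(config$n_iterations), function(it)
    scorer$predict(sample, track, seed = child_seed(config$seed, paste0(key, "#", it))),
    numeric(1))
  m <- mean(preds)
  list(mean_accuracy = m, accepted = m >= config$accuracy_threshold)
}

#' Find candidate individuals near a sample
#'
#' Candidates are individuals with at least one fix within
#' `candidate_radius` metres of the sample location in the
#' `lookback_days` before (and up to) the collection time; both the
#' distance and the time window are closed intervals. Returned in
#' descending order of the number of qualifying fixes (the reassignment
#' evaluation order).
#'
#' @param sample one-row sample data.frame (`x`, `y`, `collection_time`).
#' @param tracks data.frame of all fixes.
#' @param config an [assignment_config()].
#' @param exclude individual ids to omit (e.g. the rejected suspect).
#' @return data.frame with `individual_id` and `n_near`, ordered by
#'   decreasing `n_near` (possibly zero rows).
#' @export
find_candidates <- function(sample, tracks, config = assignment_config(),
                            exclude = NULL) {
  t1 <- sample$collection_time
  t0 <- t1 - config$lookback_days * 86400
  w <- tracks$t >= t0 & tracks$t <= t1 &
    sqrt((tracks$x - sample$x)^2 + (tracks$y - sample$y)^2) <= config$candidate_radius
  if (!any(w)) return(data.frame(individual_id = character(), n_near = integer()))
  tab <- table(tracks$individual_id[w])
  d <- data.frame(individual_id = names(tab), n_near = as.integer(tab),
                  stringsAsFactors = FALSE)
  d <- d[!d$individual_id %in% exclude, , drop = FALSE]
  d <- d[order(-d$n_near, d$individual_id), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Run the full sample-screening pipeline
#'
#' DNA-identified samples bypass scoring. Every other sample is scored
#' against its suspected individual; failures go to candidate
#' reassignment: nearby candidates are evaluated in descending order of
#' fix count near the sample (ties resolved by the highest mean
#' accuracy), and the first candidate meeting the threshold recovers the
#' sample. Per-sample seeds derive from the sample id, so permuting the
#' input order changes no disposition.
#'
#' @param samples data.frame of all collected samples (`sample_id`,
#'   `suspected_individual`, `dna_identified`, `x`, `y`,
#'   `deposition_time`, `collection_time`; `true_individual` if DNA-known).
#' @param tracks data.frame of all fixes.
#' @param scorer a scorer (see [train_default_scorer()]).
#' @param config an [assignment_config()].
#' @return list with `dispositions` (one row per sample: `stage`,
#'   `mean_accuracy`, `accepted`, `assigned_individual`) and `ledger`
#'   (a [screening_ledger()]).
#' @export
run_screening <- function(samples, tracks, scorer, config = assignment_config()) {
  if (anyDuplicated(samples$sample_id)) stopf("duplicate sample ids")
  n <- nrow(samples)
  disp <- data.frame(sample_id = samples$sample_id,
                     suspected = samples$suspected_individual,
                     stage = NA_character_, mean_accuracy = NA_real_,
                     accepted = FALSE, assigned_individual = NA_character_,
                     stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    s <- samples[k, ]
    cfg_k <- config
    cfg_k$seed <- child_seed(config$seed, s$sample_id)
    if (isTRUE(s$dna_identified)) {
      disp$stage[k] <- "dna"
      disp$accepted[k] <- TRUE
      disp$assigned_individual[k] <- s$true_individual %||% s$suspected_individual
      next
    }
    tr <- tracks[tracks$individual_id == s$suspected_individual, ]
    res <- if (nrow(tr) && any(tr$t >= s$collection_time - cfg_k$lookback_days * 86400 &
                               tr$t <= s$collection_time)) {
      assign_sample(s, tr, scorer, cfg_k)
    } else list(mean_accuracy = NA_real_, accepted = FALSE)
    disp$mean_accuracy[k] <- res$mean_accuracy
    if (res$accepted) {
      disp$stage[k] <- "ml_suspect"; disp$accepted[k] <- TRUE
      disp$assigned_individual[k] <- s$suspected_individual
      next
    }
    cand <- find_candidates(s, tracks, cfg_k, exclude = s$suspected_individual)
    recovered <- FALSE
    for (nn in unique(cand$n_near)) { # ties share n_near; best accuracy wins
      grp <- cand$individual_id[cand$n_near == nn]
      accs <- vapply(grp, function(id) {
        cfg_c <- cfg_k
        cfg_c$seed <- child_seed(cfg_k$seed, id) # reseeded per (sample, candidate)
        assign_sample(s, tracks[tracks$individual_id == id, ], scorer, cfg_c)$mean_accuracy
      }, numeric(1))
      if (any(accs >= config$accuracy_threshold)) {
        j <- which.max(accs)
        disp$stage[k] <- "ml_reassigned"; disp$accepted[k] <- TRUE
        disp$assigned_individual[k] <- grp[j]
        disp$mean_accuracy[k] <- accs[j]
        recovered <- TRUE
        break
      }
    }
    if (!recovered) disp$stage[k] <- "discarded"
  }
  ledger <- screening_ledger(
    collected = n,
    dna_identified = sum(disp$stage == "dna"),
    failed_threshold = sum(disp$stage %in% c("ml_reassigned", "discarded")),
    recovered = sum(disp$stage == "ml_reassigned"))
  list(dispositions = disp, ledger = ledger)
}

#' Auditable screening ledger
#'
#' Tracks sample counts through every screening stage and enforces the
#' arithmetic identities between them: machine-learning candidates are
#' the non-DNA samples; accepted ML samples are the candidates minus
#' threshold failures plus candidate-rule recoveries; the final accepted
#' total combines accepted ML with DNA identifications.
#'
#' @param collected samples collected.
#' @param dna_identified samples identified by DNA (bypass scoring).
#' @param failed_threshold ML-scored samples below the accuracy threshold
#'   against their suspected individual.
#' @param recovered threshold failures recovered via candidate
#'   reassignment.
#' @param issa_retained accepted samples with enough location data for
#'   the step-selection model (optional; `NA` until bouts are built).
#' @return list of class `screening_ledger` with all derived counts.
#' @export
screening_ledger <- function(collected, dna_identified, failed_threshold,
                             recovered, issa_retained = NA_integer_) {
  ml_candidates <- collected - dna_identified
  accepted_ml <- ml_candidates - failed_threshold + recovered
  final_discarded <- failed_threshold - recovered
  accepted_total <- accepted_ml + dna_identified
  if (ml_candidates < 0 || failed_threshold > ml_candidates ||
      recovered > failed_threshold)
    stopf("inconsistent screening counts")
  if (!is.na(issa_retained) && issa_retained > accepted_total)
    stopf("issa_retained cannot exceed accepted_total")
  structure(list(collected = collected, dna_identified = dna_identified,
                 ml_candidates = ml_candidates,
                 failed_threshold = failed_threshold, recovered = recovered,
                 accepted_ml = accepted_ml, final_discarded = final_discarded,
                 accepted_total = accepted_total,
                 issa_retained = issa_retained),
            class = "screening_ledger")
}

#' @export
print.screening_ledger <- function(x, ...) {
  cat(sprintf(
    paste0("sample screening ledger\n",
           "  collected          %4d\n",
           "  DNA-identified     %4d\n",
           "  ML candidates      %4d\n",
           "  failed threshold   %4d\n",
           "  recovered          %4d\n",
           "  discarded          %4d\n",
           "  accepted (ML)      %4d\n",
           "  accepted total     %4d\n",
           "  retained for iSSA  %4s\n"),
    x$collected, x$dna_identified, x$ml_candidates, x$failed_threshold,
    x$recovered, x$final_discarded, x$accepted_ml, x$accepted_total,
    ifelse(is.na(x$issa_retained), "-", x$issa_retained)))
  invisible(x)
}
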