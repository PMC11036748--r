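#' Configuration for the synthetic elk-movement study generator
#'
#' Bundles every generating parameter of the synthetic study system:
#' landscape geometry, movement kernels, habitat-selection coefficients,
#' the fecal glucocorticoid metabolite (FGM) model, calving behaviour, and
#' the sampling design. Defaults emulate the study conditions: 13 GPS-
#' collared female elk followed over two calving seasons (May--August) at
#' 30-min fix intervals, FGM concentrations whose population 0.2--0.8
#' quantiles fall near 1,200--2,600 ug/g, about 20% DNA identification
#' success, and 4--5 days of post-calving calf hiding during which the
#' mother's movement is suppressed.
#'
#' @param n_individuals number of collared individuals.
#' @param years numeric vector of study years.
#' @param season character `"MM-DD"` start/end of the field season.
#' @param fix_interval GPS fix interval, minutes.
#' @param kernel list: gamma `shape`/`scale` (step length, metres) and von
#'   Mises `mu`/`kappa` (turn angle, radians).
#' @param betas named numeric: selection coefficients on distance to cover
#'   (per 100 m) and its interactions with standardized FGM, calving
#'   period, and days since calving. Defaults are the natural logs of the
#'   odds-scale effects 0.90, 1.44, 0.80, 1.01.
#' @param fgm_model list: population `mean`, between-individual
#'   `sd_individual`, within-individual `sd_within` (all ug/g). Defaults
#'   (1900, 400, 730) put the pooled 0.2/0.8 quantiles near 1,200 and
#'   2,600 ug/g.
#' @param calving list: `"MM-DD"` `window` of possible calving dates,
#'   step-length `suppression` factor in (0, 1] during hiding,
#'   `hiding_days`, `attraction` strength toward the calving site (per
#'   100 m), and `confirmed_prob`, the probability a calving event is
#'   directly observed in the field.
#' @param sampling list: `n_samples` fecal samples per individual-year,
#'   `dna_prob` DNA identification probability, `max_lag_hours` maximum
#'   deposition-to-collection lag (drawn uniformly).
#' @param landscape list: `nx`, `ny`, `cell_size` (m), `n_patches`,
#'   `patch_radius` (m); see [make_landscape()].
#' @param n_candidates candidate steps per move in the simulator.
#' @param seed default integer seed for all generators.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 13,
                       years = c(2019, 2020),
                       season = c("05-01", "08-31"),
                       fix_interval = 30,
                       kernel = list(shape = 1.5, scale = 150, mu = 0, kappa = 0.5),
                       betas = c(dist = log(0.90), dist_fgm = log(1.44),
                                 dist_fgm_period = log(0.80), dist_fgm_days = log(1.01)),
                       fgm_model = list(mean = 1900, sd_individual = 400, sd_within = 730),
                       calving = list(window = c("05-20", "06-25"), suppression = 0.2,
                                      hiding_days = 5, attraction = 2,
                                      confirmed_prob = 11 / 26),
                       sampling = list(n_samples = 3, dna_prob = 0.2, max_lag_hours = 24),
                       landscape = list(nx = 60, ny = 60, cell_size = 100,
                                        n_patches = 6, patch_radius = 400),
                       n_candidates = 50,
                       seed = 1L) {
  if (fix_interval <= 0) stopf("fix_interval must be > 0")
  if (fgm_model$sd_individual < 0 || fgm_model$sd_within < 0)
    stopf("all fgm_model SDs must be >= 0")
  if (calving$suppression <= 0 || calving$suppression > 1)
    stopf("calving suppression factor must be in (0, 1]")
  if (n_candidates < 2) stopf("need at least 2 candidate steps per move")
  stopifnot(kernel$shape > 0, kernel$scale > 0, kernel$kappa >= 0)
  nm <- c("dist", "dist_fgm", "dist_fgm_period", "dist_fgm_days")
  if (!all(nm %in% names(betas))) stopf("betas must be named %s", paste(nm, collapse = ", "))
  structure(
    list(n_individuals = n_individuals, years = years, season = season,
         fix_interval = fix_interval, kernel = kernel, betas = betas[nm],
         fgm_model = fgm_model, calving = calving, sampling = sampling,
         landscape = landscape, n_candidates = n_candidates,
         seed = as.integer(seed)),
    class = "sim_config")
}

mmdd <- function(year, s, tz = "UTC") as.POSIXct(paste0(year, "-", s), tz = tz)

#' Simulate a fecal glucocorticoid metabolite sample series
#'
#' Concentrations follow a Gaussian hierarchy: population mean, one
#' individual-level intercept (drawn once per call from
#' `N(0, sd_individual)`), and within-individual noise `N(0, sd_within)`,
#' redrawn while non-positive so that every concentration is > 0. The
#' deposition-to-collection lag is uniform on `[0, max_lag_hours]` hours,
#' mirroring field collection within 24 h of suspected defecation.
#'
#' @param individual individual id (character or integer).
#' @param dates `POSIXct` deposition times.
#' @param fgm_model list with `mean`, `sd_individual`, `sd_within` (ug/g).
#' @param seed integer seed.
#' @param max_lag_hours maximum collection lag in hours.
#' @param intercept optional fixed individual intercept (ug/g); if `NULL`
#'   it is drawn.
#' @return data.frame with one row per sample: `sample_id`,
#'   `true_individual`, `suspected_individual`, `deposition_time`,
#'   `collection_time`, `concentration` (ug/g), `dna_identified` (`NA`,
#'   set by [simulate_dataset()]).
#' @export
simulate_fgm_series <- function(individual, dates, fgm_model, seed,
                                max_lag_hours = 24, intercept = NULL) {
  if (fgm_model$sd_individual < 0 || fgm_model$sd_within < 0)
    stopf("all fgm_model SDs must be >= 0")
  n <- length(dates)
  with_seed(seed, {
    if (is.null(intercept)) intercept <- rnorm(1, 0, fgm_model$sd_individual)
    conc <- fgm_model$mean + intercept + rnorm(n, 0, fgm_model$sd_within)
    bad <- which(conc <= 0)
    while (length(bad)) {
      conc[bad] <- fgm_model$mean + intercept + rnorm(length(bad), 0, fgm_model$sd_within)
      bad <- bad[conc[bad] <= 0]
    }
    lag <- runif(n, 0, max_lag_hours)
    data.frame(
      sample_id = paste0(individual, "_s", seq_len(n)),
      true_individual = as.character(individual),
      suspected_individual = as.character(individual),
      deposition_time = dates,
      collection_time = dates + lag * 3600,
      concentration = conc,
      dna_identified = NA,
      stringsAsFactors = FALSE)
  })
}

#' Simulate one movement track under a step-selection model
#'
#' At each fix the animal draws `config$n_candidates` candidate steps from
#' the movement kernels (gamma step length, von Mises turn angle relative
#' to the previous bearing) and selects one with probability proportional
#' to `exp(b * dist_cover/100)`, where `b` is the current selection
#' coefficient on distance to cover (per 100 m). During the calf-hiding
#' window (calving date to calving date + `hiding_days`) the mean step
#' length is multiplied by the suppression factor and candidates are
#' additionally weighted toward the calving site (the location where
#' hiding began) with the configured attraction strength, emulating a
#' mother staying close to a hidden calf.
#'
#' Candidate sets that fall entirely off the landscape are redrawn up to
#' `max_retry` times before an error is raised.
#'
#' @param landscape a [landscape_grid()].
#' @param config a [sim_config()].
#' @param times strictly increasing `POSIXct` fix times.
#' @param start numeric `(x, y)` start point inside the landscape; default
#'   is the landscape centre.
#' @param beta_series either a single numeric selection coefficient used
#'   for the whole track, or a data.frame with columns `start`, `end`
#'   (`POSIXct`) and `b`, applied to steps whose start time falls inside
#'   an interval; `config$betas["dist"]` applies elsewhere.
#' @param calving optional list/row with `calving_date` (`Date`) for this
#'   individual; enables hiding behaviour.
#' @param seed integer seed.
#' @param individual_id id recorded on the returned track.
#' @param max_retry retries when all candidates fall off-grid.
#' @return data.frame track: `individual_id`, `t`, `x`, `y`.
#' @export
simulate_track <- function(landscape, config, times, start = NULL,
                           beta_series = NULL, calving = NULL,
                           seed = config$seed, individual_id = "id1",
                           max_retry = 10L) {
  n <- length(times)
  if (n < 2) stopf("need at least 2 fix times")
  ext <- c(ncol(landscape$habitat), nrow(landscape$habitat)) * landscape$cell_size
  if (is.null(start)) start <- landscape$origin + ext / 2
  if (!inside_landscape(landscape, start[1], start[2]))
    stopf("start point is outside the landscape")
  M <- config$n_candidates
  # per-step selection coefficient on dist/100 at step start
  b_step <- rep(unname(config$betas["dist"]), n - 1)
  if (is.numeric(beta_series) && length(beta_series) == 1) {
    b_step[] <- beta_series
  } else if (is.data.frame(beta_series)) {
    for (r in seq_len(nrow(beta_series))) {
      hit <- times[-n] >= beta_series$start[r] & times[-n] <= beta_series$end[r]
      b_step[hit] <- beta_series$b[r]
    }
  }
  hide <- rep(FALSE, n - 1)
  if (!is.null(calving) && !is.na(calving$calving_date[1])) {
    h0 <- as.POSIXct(as.character(calving$calving_date[1]), tz = "UTC")
    h1 <- h0 + config$calving$hiding_days * 86400
    hide <- times[-n] >= h0 & times[-n] < h1
  }
  kern <- config$kernel
  with_seed(seed, {
    len_base <- matrix(rgamma((n - 1) * M, shape = kern$shape, scale = 1), n - 1, M)
    ang <- matrix(rvonmises((n - 1) * M, kern$mu, kern$kappa), n - 1, M)
    x <- numeric(n); y <- numeric(n)
    x[1] <- start[1]; y[1] <- start[2]
    bearing <- runif(1, -pi, pi)
    site <- c(NA_real_, NA_real_)
    dc <- landscape$dist_cover; cs <- landscape$cell_size; org <- landscape$origin
    for (i in seq_len(n - 1)) {
      if (hide[i] && is.na(site[1])) site <- c(x[i], y[i])
      scl <- kern$scale * if (hide[i]) config$calving$suppression else 1
      L <- len_base[i, ] * scl
      th <- bearing + ang[i, ]
      for (try in seq_len(max_retry + 1L)) {
        ex <- x[i] + L * cos(th); ey <- y[i] + L * sin(th)
        d <- bilinear_lookup(dc, cs, org, ex, ey)
        ok <- !is.na(d)
        if (any(ok)) break
        if (try > max_retry) stopf("all candidate steps fell off the landscape after %d retries", max_retry)
        L <- rgamma(M, shape = kern$shape, scale = 1) * scl
        th <- bearing + rvonmises(M, kern$mu, kern$kappa)
      }
      lp <- b_step[i] * d / 100
      if (hide[i])
        lp <- lp - config$calving$attraction * sqrt((ex - site[1])^2 + (ey - site[2])^2) / 100
      lp[!ok] <- -Inf
      w <- exp(lp - max(lp[ok]))
      j <- sample.int(M, 1L, prob = w)
      x[i + 1] <- ex[j]; y[i + 1] <- ey[j]
      bearing <- atan2(ey[j] - y[i], ex[j] - x[i])
    }
    data.frame(individual_id = individual_id, t = times, x = x, y = y,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete synthetic study dataset
#'
#' Generates a landscape, calving events, FGM sample series, and
#' step-selection-consistent movement tracks for every individual and
#' year, together with a truth record holding every generating parameter
#' (for parameter-recovery tests). The per-sample selection coefficient on
#' distance to cover is
#' `b = b_dist + b_df * z + b_dfp * z * period + b_dfd * z * days`,
#' with `z` the FGM concentration standardized across all samples, so a
#' refit of the step-selection model on the simulated bundle targets the
#' configured `betas` exactly.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`. The bundle is a
#'   pure function of `(config, seed)`.
#' @param mode `"bouts"` simulates movement only inside the 20-h window
#'   preceding each fecal sample (the data the selection model uses) and
#'   generates exactly from the step-selection model -- calving dates
#'   enter only through the covariates -- which is the mode
#'   parameter-recovery experiments should use; `"season"` simulates full
#'   season-long tracks including calf-hiding kinematics (movement
#'   suppression and attraction to the calving site), as needed for
#'   calving detection and sample assignment.
#' @param window_hours hormone-integration window length for `"bouts"`.
#' @return list of class `cortmove_sim` with elements `landscape`,
#'   `tracks`, `samples`, `events`, `truth`, `config`.
#' @export
simulate_dataset <- function(config, seed = config$seed,
                             mode = c("bouts", "season"), window_hours = 20) {
  mode <- match.arg(mode)
  season_days <- as.numeric(difftime(mmdd(config$years[1], config$season[2]),
                                     mmdd(config$years[1], config$season[1]), units = "days"))
  if (season_days <= config$calving$hiding_days)
    stopf("season is shorter than the calf-hiding duration")
  ids <- sprintf("elk%02d", seq_len(config$n_individuals))
  landscape <- make_landscape(config, child_seed(seed, "landscape"))

  events <- with_seed(child_seed(seed, "events"), {
    ev <- expand.grid(individual_id = ids, year = config$years,
                      stringsAsFactors = FALSE)
    w0 <- as.Date(paste0(ev$year, "-", config$calving$window[1]))
    w1 <- as.Date(paste0(ev$year, "-", config$calving$window[2]))
    ev$calving_date <- w0 + floor(runif(nrow(ev)) * (as.numeric(w1 - w0) + 1))
    ev$confirmed <- runif(nrow(ev)) < config$calving$confirmed_prob
    ev
  })

  # deposition times, >= 24 h apart within an individual-year
  samples <- with_seed(child_seed(seed, "samples"), {
    out <- lapply(seq_len(nrow(events)), function(k) {
      t0 <- mmdd(events$year[k], config$season[1]) + 86400
      t1 <- mmdd(events$year[k], config$season[2])
      span <- as.numeric(difftime(t1, t0, units = "secs"))
      repeat {
        dep <- sort(t0 + runif(config$sampling$n_samples) * span)
        if (config$sampling$n_samples < 2 || min(diff(as.numeric(dep))) > 86400) break
      }
      data.frame(individual_id = events$individual_id[k], year = events$year[k],
                 deposition_time = dep, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })

  intercepts <- with_seed(child_seed(seed, "intercepts"),
                          setNames(rnorm(length(ids), 0, config$fgm_model$sd_individual), ids))
  fgm <- do.call(rbind, lapply(ids, function(id) {
    rows <- samples[samples$individual_id == id, ]
    ss <- simulate_fgm_series(id, rows$deposition_time, config$fgm_model,
                              seed = child_seed(seed, paste0("fgm_", id)),
                              max_lag_hours = config$sampling$max_lag_hours,
                              intercept = intercepts[[id]])
    ss$year <- rows$year
    ss$sample_id <- paste0(id, "_", rows$year, "_s", seq_len(nrow(rows)))
    ss
  }))
  fgm$dna_identified <- with_seed(child_seed(seed, "dna"),
                                  runif(nrow(fgm)) < config$sampling$dna_prob)

  # per-sample selection coefficient from the generating model
  z <- standardize_fgm(fgm$concentration)
  fgm$fgm_z <- as.numeric(z)
  ev_key <- paste(events$individual_id, events$year)
  cd <- events$calving_date[match(paste(fgm$true_individual, fgm$year), ev_key)]
  dep_date <- as.Date(fgm$deposition_time, tz = "UTC")
  fgm$period_post <- as.integer(dep_date >= cd)
  fgm$days_since <- pmax(0, as.numeric(dep_date - cd))
  be <- config$betas
  fgm$b_true <- be["dist"] + be["dist_fgm"] * fgm$fgm_z +
    be["dist_fgm_period"] * fgm$fgm_z * fgm$period_post +
    be["dist_fgm_days"] * fgm$fgm_z * fgm$days_since

  ext <- c(config$landscape$nx, config$landscape$ny) * config$landscape$cell_size
  tracks <- list(); sx <- numeric(nrow(fgm)); sy <- numeric(nrow(fgm))
  if (mode == "bouts") {
    for (k in seq_len(nrow(fgm))) {
      dep <- fgm$deposition_time[k]
      times <- seq(dep - window_hours * 3600, dep, by = config$fix_interval * 60)
      st <- with_seed(child_seed(seed, paste0("start_", k)),
                      c(runif(1, 0.2, 0.8) * ext[1], runif(1, 0.2, 0.8) * ext[2]) +
                        landscape$origin)
      tr <- simulate_track(landscape, config, times, start = st,
                           beta_series = fgm$b_true[k], calving = NULL,
                           seed = child_seed(seed, paste0("track_", k)),
                           individual_id = fgm$true_individual[k])
      tracks[[k]] <- tr
      sx[k] <- tr$x[nrow(tr)]; sy[k] <- tr$y[nrow(tr)]
    }
  } else {
    for (k in seq_len(nrow(events))) {
      id <- events$individual_id[k]; yr <- events$year[k]
      times <- seq(mmdd(yr, config$season[1]), mmdd(yr, config$season[2]),
                   by = config$fix_interval * 60)
      rows <- fgm[fgm$true_individual == id & fgm$year == yr, ]
      bs <- data.frame(start = rows$deposition_time - window_hours * 3600,
                       end = rows$deposition_time, b = rows$b_true)
      st <- with_seed(child_seed(seed, paste0("start_", id, yr)),
                      c(runif(1, 0.25, 0.75) * ext[1], runif(1, 0.25, 0.75) * ext[2]) +
                        landscape$origin)
      tr <- simulate_track(landscape, config, times, start = st,
                           beta_series = bs, calving = events[k, ],
                           seed = child_seed(seed, paste0("track_", id, yr)),
                           individual_id = id)
      tr$year <- yr
      tracks[[length(tracks) + 1L]] <- tr
      for (j in which(fgm$true_individual == id & fgm$year == yr)) {
        ix <- which.min(abs(as.numeric(tr$t) - as.numeric(fgm$deposition_time[j])))
        sx[j] <- tr$x[ix]; sy[j] <- tr$y[ix]
      }
    }
  }
  noise <- with_seed(child_seed(seed, "samploc"), matrix(rnorm(2 * nrow(fgm), 0, 3), ncol = 2))
  fgm$x <- sx + noise[, 1]; fgm$y <- sy + noise[, 2]

  structure(
    list(landscape = landscape,
         tracks = do.call(rbind, tracks),
         samples = fgm,
         events = events,
         truth = list(betas = config$betas, kernel = config$kernel,
                      fgm_model = config$fgm_model, intercepts = intercepts,
                      fgm_scale = attributes(z), events = events,
                      sample_coefs = fgm[, c("sample_id", "fgm_z", "period_post",
                                             "days_since", "b_true")],
                      seed = seed, mode = mode),
         config = config),
    class = "cortmove_sim")
}

#' Write and read study tables as plain CSV
#'
#' Tracks are stored with ISO-8601 UTC timestamps (`individual_id`,
#' `timestamp`, `x`, `y`), samples with deposition/collection times in the
#' same format.
#'
#' @param tracks,samples data.frames as produced by [simulate_dataset()].
#' @param file output path.
#' @return the file path, invisibly; readers return the parsed data.frame.
#' @export
write_tracks_csv <- function(tracks, file) {
  out <- data.frame(individual_id = tracks$individual_id,
                    timestamp = format(tracks$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                    x = tracks$x, y = tracks$y)
  write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(file) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  d$t <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  d$timestamp <- NULL
  d
}

#' @rdname write_tracks_csv
#' @export
write_samples_csv <- function(samples, file) {
  out <- samples
  for (cc in c("deposition_time", "collection_time"))
    out[[cc]] <- format(out[[cc]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_tracks_csv
#' @export
read_samples_csv <- function(file) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  for (cc in c("deposition_time", "collection_time"))
    d[[cc]] <- as.POSIXct(d[[cc]], format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  d
}
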