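#' Build hormone-window movement bouts
#'
#' A bout is the GPS subset from the 20 h preceding one fecal sample's
#' deposition -- the window over which circulating glucocorticoids are
#' metabolized into the fecal signal -- and is the grouping unit of the
#' step-selection analysis. One bout is built per accepted sample; bouts
#' with fewer than `min_fixes` fixes in the window (too few to define a
#' turn angle) are excluded and listed in the `excluded` attribute. FGM
#' concentrations are standardized to mean 0, SD 1 across the accepted
#' samples; the calving period is `post` when the sample was deposited on
#' or after the individual's calving date (day-of-calving counts as post,
#' with `days_since = 0`).
#'
#' @param tracks data.frame of fixes: `individual_id`, `t` (`POSIXct`),
#'   `x`, `y`.
#' @param samples data.frame of accepted samples: `sample_id`,
#'   `deposition_time`, `concentration`, and an individual id column
#'   (`assigned_individual`, `individual_id`, or `true_individual`, in
#'   that precedence).
#' @param events data.frame: `individual_id`, `year`, `calving_date`.
#'   Samples from individual-years with no event keep `NA` period and are
#'   dropped later by [build_design()].
#' @param window_hours hormone-integration window (h).
#' @param min_fixes minimum fixes per bout.
#' @return list of class `bout_list`; each element has `bout_id`,
#'   `individual_id`, `sample_id`, `fgm_z`, `period_post`, `days_since`,
#'   `fixes`. Attributes: `fgm_scale` (centring constants and the 0.2/0.8
#'   concentration quantiles), `excluded` (data.frame).
#' @export
make_bouts <- function(tracks, samples, events, window_hours = 20, min_fixes = 3) {
  id <- samples$assigned_individual %||% samples$individual_id %||%
    samples$true_individual
  if (is.null(id)) stopf("samples need an individual id column")
  if (anyDuplicated(samples$sample_id)) stopf("duplicate sample ids")
  if (is.null(samples$fgm_z) || nrow(samples) >= 2) {
    zz <- standardize_fgm(samples$concentration)
    z <- if (!is.null(samples$fgm_z)) samples$fgm_z else as.numeric(zz)
    zs <- attributes(zz)
  } else { # single pre-standardized sample: nothing to scale
    z <- samples$fgm_z
    zs <- NULL
  }
  yr <- samples$year %||% as.integer(format(samples$deposition_time, "%Y", tz = "UTC"))
  cd <- events$calving_date[match(paste(id, yr), paste(events$individual_id, events$year))]
  dep_date <- as.Date(samples$deposition_time, tz = "UTC")
  period <- as.integer(dep_date >= cd)
  days <- pmax(0, as.numeric(dep_date - cd))

  bouts <- list(); excluded <- list()
  for (k in seq_len(nrow(samples))) {
    dep <- samples$deposition_time[k]
    tr <- tracks[tracks$individual_id == id[k], ]
    inw <- tr$t > dep - window_hours * 3600 & tr$t <= dep
    fx <- tr[inw, c("t", "x", "y")]
    fx <- fx[order(fx$t), ]
    if (nrow(fx) < min_fixes) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(sample_id = samples$sample_id[k],
                   reason = sprintf("only %d fixes in window", nrow(fx)))
      next
    }
    bouts[[length(bouts) + 1L]] <- list(
      bout_id = sprintf("bout%03d", k),
      individual_id = id[k], sample_id = samples$sample_id[k],
      fgm_z = z[k], period_post = period[k], days_since = days[k],
      fixes = fx)
  }
  structure(bouts, class = "bout_list",
            fgm_scale = c(zs, list(q = quantile(samples$concentration, c(0.2, 0.8),
                                                names = FALSE))),
            excluded = if (length(excluded)) do.call(rbind, excluded) else
              data.frame(sample_id = character(), reason = character()))
}

#' Decompose a bout into movement steps
#'
#' A step joins consecutive fixes; its turn angle is the change in bearing
#' from the previous step and is defined only from the second step on, so
#' a bout of `n` fixes yields `n - 2` usable steps.
#'
#' @param bout one element of a [make_bouts()] list, or any data.frame of
#'   time-ordered fixes with columns `t`, `x`, `y`.
#' @return data.frame of used steps: start/end coordinates and times,
#'   `length` (m), `bearing`, `prior_bearing`, `turn_angle` in
#'   \eqn{(-\pi,\pi]}.
#' @export
build_steps <- function(bout) {
  fx <- if (is.data.frame(bout)) bout else bout$fixes
  n <- nrow(fx)
  if (n < 3) stopf("need at least 3 fixes to build a step with a turn angle")
  if (anyDuplicated(fx$t)) stopf("duplicate timestamps in bout")
  dx <- diff(fx$x); dy <- diff(fx$y)
  len <- sqrt(dx^2 + dy^2)
  brg <- atan2(dy, dx)
  i <- 2:(n - 1) # steps with a defined prior bearing
  data.frame(
    x1 = fx$x[i], y1 = fx$y[i], x2 = fx$x[i + 1], y2 = fx$y[i + 1],
    t1 = fx$t[i], t2 = fx$t[i + 1],
    length = len[i], bearing = brg[i], prior_bearing = brg[i - 1],
    turn_angle = wrap_angle(brg[i] - brg[i - 1]))
}

#' Fit movement kernels to used steps
#'
#' Maximum-likelihood gamma fit to step lengths (metres; zero-length steps
#' floored at `floor_m`) and von Mises fit to turn angles. These kernels
#' define the availability distribution from which candidate steps are
#' sampled.
#'
#' @param steps data.frame with `length` and `turn_angle` columns (pooled
#'   used steps).
#' @param floor_m positive floor applied to step lengths before the gamma
#'   fit.
#' @return list of class `kernel_fit`: `shape`, `scale` (gamma, metres),
#'   `mu`, `kappa` (von Mises, radians), `n_steps`.
#' @export
fit_kernels <- function(steps, floor_m = 1) {
  if (nrow(steps) < 10) stopf("need at least 10 steps to fit kernels")
  len <- pmax(steps$length, floor_m)
  gf <- fitdistrplus::fitdist(len, "gamma",
                              start = list(shape = mean(len)^2 / stats::var(len),
                                           rate = mean(len) / stats::var(len)))
  vm <- fit_vonmises(steps$turn_angle)
  structure(list(shape = unname(gf$estimate["shape"]),
                 scale = 1 / unname(gf$estimate["rate"]),
                 mu = vm$mu, kappa = vm$kappa, n_steps = nrow(steps)),
            class = "kernel_fit")
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat(sprintf(
    "movement kernels (n = %d steps)\n  step length ~ gamma(shape = %.3f, scale = %.1f m)\n  turn angle  ~ von Mises(mu = %.3f, kappa = %.3f)\n",
    x$n_steps, x$shape, x$scale, x$mu, x$kappa))
  invisible(x)
}

#' Sample available steps for each used step
#'
#' Draws `K` available steps per used step from the fitted kernels: the
#' available step shares the used step's start point and prior bearing;
#' its length is gamma and its turn angle von Mises. End points falling
#' off the landscape are resampled up to `max_retry` times and left `NA`
#' afterwards (their stratum is later dropped by [build_design()]).
#'
#' @param used_steps data.frame of used steps carrying `stratum` ids (see
#'   [build_strata()]).
#' @param kernels a [fit_kernels()] result.
#' @param K available:used ratio (>= 1).
#' @param landscape a [landscape_grid()]; `NULL` skips the off-grid check.
#' @param seed integer seed.
#' @param max_retry redraw attempts for off-landscape end points.
#' @return data.frame of available steps with the same stratum ids,
#'   `used = 0`.
#' @export
generate_available <- function(used_steps, kernels, K, landscape = NULL,
                               seed = 1L, max_retry = 10L) {
  if (K < 1) stopf("K must be >= 1")
  n <- nrow(used_steps)
  tot <- n * K
  with_seed(seed, {
    len <- rgamma(tot, shape = kernels$shape, scale = kernels$scale)
    ang <- rvonmises(tot, kernels$mu, kernels$kappa)
    x1 <- rep(used_steps$x1, each = K); y1 <- rep(used_steps$y1, each = K)
    pb <- rep(used_steps$prior_bearing, each = K)
    brg <- pb + ang
    ex <- x1 + len * cos(brg); ey <- y1 + len * sin(brg)
    if (!is.null(landscape)) {
      off <- which(!inside_landscape(landscape, ex, ey))
      tries <- 0L
      while (length(off) && tries < max_retry) {
        len[off] <- rgamma(length(off), shape = kernels$shape, scale = kernels$scale)
        ang[off] <- rvonmises(length(off), kernels$mu, kernels$kappa)
        brg <- pb[off] + ang[off]
        ex[off] <- x1[off] + len[off] * cos(brg)
        ey[off] <- y1[off] + len[off] * sin(brg)
        off <- off[!inside_landscape(landscape, ex[off], ey[off])]
        tries <- tries + 1L
      }
      if (length(off)) { ex[off] <- NA_real_; ey[off] <- NA_real_ }
    }
    data.frame(
      bout_id = rep(used_steps$bout_id, each = K),
      stratum = rep(used_steps$stratum, each = K),
      used = 0L, x1 = x1, y1 = y1, x2 = ex, y2 = ey,
      length = len, turn_angle = ang,
      prior_bearing = pb, stringsAsFactors = FALSE)
  })
}

#' Assemble used and available steps into strata
#'
#' Builds used steps for every bout, fits (or accepts) the movement
#' kernels, samples `K` available steps per used step, and stacks them
#' into the stratified choice-set table consumed by [build_design()]. A
#' stratum is one used step plus its `K` available companions.
#'
#' @param bouts a [make_bouts()] list.
#' @param K available:used ratio.
#' @param landscape a [landscape_grid()].
#' @param kernels optional [fit_kernels()] result; fitted from the pooled
#'   used steps when `NULL`.
#' @param seed integer seed for the availability draws.
#' @return data.frame with columns `bout_id`, `stratum`, `used`,
#'   coordinates, `length`, `turn_angle`; the kernels are attached as
#'   attribute `kernels`, bout-level covariates as attribute `bout_meta`,
#'   and the FGM scaling as attribute `fgm_scale`.
#' @export
build_strata <- function(bouts, K = 40, landscape = NULL, kernels = NULL,
                         seed = 1L) {
  used <- do.call(rbind, lapply(bouts, function(b) {
    st <- build_steps(b)
    st$bout_id <- b$bout_id
    st
  }))
  used$stratum <- seq_len(nrow(used))
  used$used <- 1L
  if (is.null(kernels)) kernels <- fit_kernels(used)
  avail <- generate_available(used, kernels, K, landscape, seed)
  cols <- c("bout_id", "stratum", "used", "x1", "y1", "x2", "y2",
            "length", "turn_angle")
  out <- rbind(used[, cols], avail[, cols])
  out <- out[order(out$stratum, -out$used), ]
  rownames(out) <- NULL
  meta <- data.frame(
    bout_id = vapply(bouts, `[[`, "", "bout_id"),
    individual_id = vapply(bouts, `[[`, "", "individual_id"),
    fgm_z = vapply(bouts, `[[`, 0, "fgm_z"),
    period_post = vapply(bouts, function(b) as.numeric(b$period_post), 0),
    days_since = vapply(bouts, function(b) as.numeric(b$days_since), 0),
    stringsAsFactors = FALSE)
  structure(out, kernels = kernels, bout_meta = meta,
            fgm_scale = attr(bouts, "fgm_scale"))
}

#' Build the model design table
#'
#' One row per step with the distance-to-cover covariate at the step end
#' (bilinear lookup, expressed in 100-m units) and the hormone interaction
#' terms: `dist_fgm = dist_end * fgm_z`,
#' `dist_fgm_period = dist_end * fgm_z * period_post`,
#' `dist_fgm_days = dist_end * fgm_z * days_since`. FGM level, period, and
#' days since calving are constant within a stratum, so only their
#' interactions with the step-varying distance are estimable. Strata
#' containing any missing covariate (off-landscape end point, or a bout
#' with no calving record) are dropped with a message.
#'
#' @param strata a [build_strata()] table.
#' @param landscape a [landscape_grid()].
#' @param bouts the [make_bouts()] list (used for bout-level covariates
#'   when the `bout_meta` attribute is absent).
#' @return data.frame with identifiers and the four model columns;
#'   attributes `fgm_scale` and `kernels` are carried through.
#' @export
build_design <- function(strata, landscape, bouts = NULL) {
  meta <- attr(strata, "bout_meta")
  if (is.null(meta) && !is.null(bouts)) {
    meta <- data.frame(
      bout_id = vapply(bouts, `[[`, "", "bout_id"),
      individual_id = vapply(bouts, `[[`, "", "individual_id"),
      fgm_z = vapply(bouts, `[[`, 0, "fgm_z"),
      period_post = vapply(bouts, function(b) as.numeric(b$period_post), 0),
      days_since = vapply(bouts, function(b) as.numeric(b$days_since), 0))
  }
  if (is.null(meta)) stopf("bout-level covariates not found; pass `bouts`")
  m <- match(strata$bout_id, meta$bout_id)
  d <- data.frame(
    bout_id = strata$bout_id,
    individual_id = meta$individual_id[m],
    stratum = strata$stratum, used = strata$used,
    length = strata$length, turn_angle = strata$turn_angle,
    dist_end = lookup_dist_cover(landscape, strata$x2, strata$y2) / 100,
    fgm_z = meta$fgm_z[m], period_post = meta$period_post[m],
    days_since = meta$days_since[m], stringsAsFactors = FALSE)
  bad <- is.na(d$dist_end) | is.na(d$fgm_z) | is.na(d$period_post) | is.na(d$days_since)
  if (any(bad)) {
    drop <- unique(d$stratum[bad])
    message(length(drop), " stratum/strata dropped for missing covariates")
    d <- d[!d$stratum %in% drop, ]
  }
  d$dist_fgm <- d$dist_end * d$fgm_z
  d$dist_fgm_period <- d$dist_end * d$fgm_z * d$period_post
  d$dist_fgm_days <- d$dist_end * d$fgm_z * d$days_since
  rownames(d) <- NULL
  structure(d, fgm_scale = attr(strata, "fgm_scale"),
            kernels = attr(strata, "kernels"))
}
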