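#' Relative selection strength for a pair of locations
#'
#' The log relative selection strength (log-RSS) of location `x1` over
#' location `x2` is the linear contrast \eqn{\hat\beta^\top (x_1 - x_2)};
#' its exponential is the relative probability of selecting `x1` over
#' `x2` when both are equally available.
#'
#' @param fit an [fit_ssf()] object.
#' @param x1,x2 numeric covariate vectors conformable with the fit's
#'   terms (named, or unnamed in term order).
#' @return scalar log-RSS.
#' @examples
#' # with a single-covariate fit, log_rss over a 2-unit contrast = 2 * beta
#' @export
log_rss <- function(fit, x1, x2) {
  b <- fit$coefficients
  x1 <- align_terms(x1, names(b)); x2 <- align_terms(x2, names(b))
  sum(b * (x1 - x2))
}

align_terms <- function(x, terms) {
  if (length(x) != length(terms)) stopf("covariate vector has %d elements; fit has %d terms",
                                        length(x), length(terms))
  if (!is.null(names(x))) {
    if (!setequal(names(x), terms)) stopf("covariate names do not match fit terms")
    x <- x[terms]
  }
  as.numeric(x)
}

#' Covariate vector for the hormone-interaction model
#'
#' Builds the design vector for a hypothetical step end at `dist` 100-m
#' units from cover, taken during a bout with standardized FGM `fgm_z`,
#' calving period `period` (0 pre, 1 post), and `days` since calving.
#'
#' @param dist distance to cover, 100-m units.
#' @param fgm_z standardized FGM level.
#' @param period 0/1 calving period indicator.
#' @param days days since calving.
#' @return named numeric vector over the four model terms.
#' @export
ssf_x <- function(dist, fgm_z, period = 0, days = 0) {
  c(dist_end = dist, dist_fgm = dist * fgm_z,
    dist_fgm_period = dist * fgm_z * period,
    dist_fgm_days = dist * fgm_z * days)
}

#' Query describing an RSS curve over the FGM range
#'
#' @param fgm grid of FGM values; standardized units by default, ug/g if
#'   `units = "conc"` (requires the fit to carry its FGM scaling). `NULL`
#'   uses 50 points across the 0.2--0.8 population concentration
#'   quantiles stored on the fit.
#' @param units `"z"` or `"conc"`.
#' @param dist_pair distances to cover (100-m units) of the two locations
#'   compared; default in-cover (0) versus 200 m from cover (2).
#' @param period,days bout covariates held fixed along the curve.
#' @param relative_to_reference subtract the curve value at the first
#'   (reference) FGM grid point, so the curve reads as change in selection
#'   relative to the low-FGM reference and is 0 there by construction.
#' @param n_boot parametric bootstrap draws (>= 100).
#' @param seed integer seed.
#' @return list of class `rss_query`.
#' @export
rss_query <- function(fgm = NULL, units = c("z", "conc"), dist_pair = c(0, 2),
                      period = 0, days = 0, relative_to_reference = FALSE,
                      n_boot = 1000, seed = 1L) {
  units <- match.arg(units)
  if (n_boot < 100) stopf("n_boot must be >= 100")
  structure(list(fgm = fgm, units = units, dist_pair = dist_pair,
                 period = period, days = days,
                 relative_to_reference = relative_to_reference,
                 n_boot = n_boot, seed = as.integer(seed)),
            class = "rss_query")
}

#' Relative selection strength across the FGM range, with bootstrap CI
#'
#' Evaluates the log-RSS of the first location over the second at each
#' FGM grid value, with a parametric bootstrap interval: `n_boot`
#' coefficient vectors are drawn from `MVN(beta_hat, vcov)` and the 2.5
#' and 97.5 percentile of the contrast give the 95% ribbon. Non-positive-
#' semi-definite covariance matrices are repaired to the nearest PSD
#' matrix (eigenvalue clipping) with a warning.
#'
#' @param fit an [fit_ssf()] object with a valid covariance matrix.
#' @param query an [rss_query()].
#' @return data.frame of class `rss_curve`: `fgm` (query units), `fgm_z`,
#'   `log_rss`, `lo`, `hi`.
#' @export
rss_curve <- function(fit, query = rss_query()) {
  sc <- fit$fgm_scale
  fgm <- query$fgm
  if (is.null(fgm)) {
    if (is.null(sc$q)) stopf("fit carries no FGM quantiles; supply query$fgm")
    fgm <- seq(sc$q[1], sc$q[2], length.out = 50)
    units <- "conc"
  } else units <- query$units
  z <- if (units == "conc") {
    if (is.null(sc$mean)) stopf("fit carries no FGM scaling; use standardized units")
    (fgm - sc$mean) / sc$sd
  } else fgm
  d1 <- query$dist_pair[1]; d2 <- query$dist_pair[2]
  terms <- names(fit$coefficients)
  Cmat <- t(vapply(z, function(zz)
    align_terms(ssf_x(d1, zz, query$period, query$days), terms) -
      align_terms(ssf_x(d2, zz, query$period, query$days), terms),
    numeric(length(terms))))
  if (query$relative_to_reference) Cmat <- sweep(Cmat, 2, Cmat[1, ])
  est <- as.numeric(Cmat %*% fit$coefficients)
  V <- ensure_psd(fit$vcov)
  draws <- with_seed(query$seed,
                     MASS::mvrnorm(query$n_boot, mu = fit$coefficients, Sigma = V))
  boot <- Cmat %*% t(draws) # grid x n_boot
  qs <- apply(boot, 1, quantile, c(0.025, 0.975))
  structure(data.frame(fgm = fgm, fgm_z = z, log_rss = est,
                       lo = qs[1, ], hi = qs[2, ]),
            class = c("rss_curve", "data.frame"),
            query = query)
}

#' @export
#' @importFrom graphics polygon lines abline legend
plot.rss_curve <- function(x, xlab = "FGM concentration", ylab = "log-RSS", ...) {
  plot(x$fgm, x$log_rss, type = "n", ylim = range(x$lo, x$hi), xlab = xlab,
       ylab = ylab, ...)
  polygon(c(x$fgm, rev(x$fgm)), c(x$lo, rev(x$hi)), border = NA,
          col = grDevices::adjustcolor("steelblue", 0.3))
  lines(x$fgm, x$log_rss, lwd = 2, col = "steelblue4")
  abline(h = 0, lty = 3)
  invisible(x)
}

# clip negative eigenvalues; warn if a real repair was needed
ensure_psd <- function(V, tol = 1e-10) {
  V <- (V + t(V)) / 2
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values))) {
    warning("covariance matrix not positive semi-definite; repaired by eigenvalue clipping")
    V <- e$vectors %*% diag(pmax(e$values, 0), length(e$values)) %*% t(e$vectors)
  }
  V
}
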