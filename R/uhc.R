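#' Used-habitat calibration (UHC) of a step-selection model
#'
#' UHC checks model calibration: the distribution of a habitat covariate
#' at observed used steps should fall inside the envelope of covariate
#' distributions at steps the fitted model predicts as used. The data are
#' split into training and test bouts (splitting by bout, not by step,
#' respects the stratified dependence); the model is fitted on the
#' training strata; then for each of `n_sims` draws of
#' `beta ~ MVN(beta_hat, vcov)` one step is sampled from every test
#' stratum's choice set with probability proportional to
#' `exp(beta' x)`, and the kernel density of the covariate at the sampled
#' steps is accumulated. The pointwise 2.5--97.5% band across simulations
#' is the calibration envelope. All densities are Gaussian-kernel
#' estimates (Silverman's bandwidth) on a fixed 512-point grid, normalized
#' to integrate to 1 by the trapezoid rule.
#'
#' @param design a [build_design()] table.
#' @param terms model columns to fit (use a subset to probe a
#'   misspecified model).
#' @param covariate covariate whose calibration is evaluated.
#' @param split fraction of bouts in the training set.
#' @param n_sims number of posterior-style simulation draws.
#' @param seed integer seed.
#' @param mode passed to [fit_ssf()].
#' @return list of class `uhc_result`: `curves` (data.frame with `x`,
#'   `observed`, `available`, `lo`, `hi`, `sim_mean`), `coverage` (the
#'   fraction of grid points where the observed density lies inside the
#'   envelope), `covariate`, `n_test_strata`, `fit`.
#' @export
uhc_validate <- function(design,
                         terms = c("dist_end", "dist_fgm", "dist_fgm_period",
                                   "dist_fgm_days"),
                         covariate = "dist_end", split = 0.5, n_sims = 200,
                         seed = 1L, mode = "clogit") {
  bouts <- unique(design$bout_id)
  train_b <- with_seed(child_seed(seed, "split"),
                       sample(bouts, max(1L, round(length(bouts) * split))))
  train <- design[design$bout_id %in% train_b, ]
  test <- design[!design$bout_id %in% train_b, ]
  n_test <- length(unique(test$stratum))
  if (n_test < 10) stopf("test split has %d strata (< 10); lower `split` or add data", n_test)
  fit <- fit_ssf(train, mode = mode, terms = terms)

  test <- test[order(test$stratum, -test$used), ]
  sizes <- as.integer(table(test$stratum))
  if (length(unique(sizes)) != 1L)
    stopf("test strata have unequal sizes; regenerate availability before UHC")
  m <- sizes[1]
  X <- as.matrix(test[, terms, drop = FALSE])
  v <- test[[covariate]]
  grid_rng <- range(v)
  dens <- function(x) {
    d <- density(x, n = 512, from = grid_rng[1], to = grid_rng[2])
    dx <- diff(d$x[1:2])
    area <- sum((head(d$y, -1) + tail(d$y, -1)) / 2) * dx
    d$y / area
  }
  gx <- density(v[1:2], n = 512, from = grid_rng[1], to = grid_rng[2])$x

  V <- ensure_psd(fit$vcov)
  sims <- with_seed(child_seed(seed, "sims"), {
    draws <- MASS::mvrnorm(n_sims, mu = fit$coefficients, Sigma = V)
    vm <- matrix(v, nrow = m)          # rows: steps in stratum, cols: strata
    out <- matrix(0, 512, n_sims)
    for (s in seq_len(n_sims)) {
      lp <- matrix(X %*% draws[s, ], nrow = m)
      g <- -log(-log(matrix(runif(length(lp)), nrow = m)))  # Gumbel-max choice
      pick <- max.col(t(lp + g), ties.method = "first")
      out[, s] <- dens(vm[cbind(pick, seq_len(ncol(vm)))])
    }
    out
  })
  env <- apply(sims, 1, quantile, c(0.025, 0.975))
  obs <- dens(v[test$used == 1])
  avail <- dens(v[test$used == 0])
  curves <- data.frame(x = gx, observed = obs, available = avail,
                       lo = env[1, ], hi = env[2, ],
                       sim_mean = rowMeans(sims))
  structure(list(curves = curves,
                 coverage = mean(obs >= env[1, ] & obs <= env[2, ]),
                 covariate = covariate, n_test_strata = n_test, fit = fit),
            class = "uhc_result")
}

#' @export
plot.uhc_result <- function(x, xlab = x$covariate, ylab = "density", ...) {
  cv <- x$curves
  plot(cv$x, cv$observed, type = "n", ylim = range(0, cv$hi, cv$observed,
                                                   cv$available),
       xlab = xlab, ylab = ylab, ...)
  polygon(c(cv$x, rev(cv$x)), c(cv$lo, rev(cv$hi)), border = NA,
          col = grDevices::adjustcolor("grey40", 0.3))
  lines(cv$x, cv$available, lty = 2, col = "firebrick")
  lines(cv$x, cv$observed, lwd = 2)
  legend("topright", bty = "n", lwd = c(2, 1, 8), lty = c(1, 2, 1),
         col = c("black", "firebrick", grDevices::adjustcolor("grey40", 0.3)),
         legend = c("observed used", "available", "predicted-used envelope"))
  invisible(x)
}

#' @export
print.uhc_result <- function(x, ...) {
  cat(sprintf("UHC validation of '%s': %.1f%% of the observed used-density curve\ninside the 95%% envelope (%d test strata)\n",
              x$covariate, 100 * x$coverage, x$n_test_strata))
  invisible(x)
}
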