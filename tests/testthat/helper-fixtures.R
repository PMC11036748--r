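# shared fixtures, all generated in code

# small configuration used across tests: 4 elk, one season
small_config <- function(...) {
  sim_config(n_individuals = 4, years = 2019,
             landscape = list(nx = 40, ny = 40, cell_size = 100,
                              n_patches = 4, patch_radius = 400),
             ...)
}

# a tiny regular track: fixes every 30 min from a coordinate matrix
toy_track <- function(xy, id = "elk01", t0 = as.POSIXct("2019-06-01", tz = "UTC"),
                      interval_min = 30) {
  data.frame(individual_id = id,
             t = t0 + (seq_len(nrow(xy)) - 1) * interval_min * 60,
             x = xy[, 1], y = xy[, 2])
}

# brute-force revisit oracle: explicit run segmentation per fix
oracle_revisits <- function(track, radius) {
  n <- nrow(track)
  sapply(seq_len(n), function(i) {
    inb <- sqrt((track$x - track$x[i])^2 + (track$y - track$y[i])^2) <= radius
    runs <- rle(inb)
    sum(runs$values)
  })
}

# brute-force conditional logistic log-likelihood over strata
oracle_clogit_loglik <- function(beta, X, used, stratum) {
  lp <- as.numeric(X %*% beta)
  sum(vapply(split(seq_along(lp), stratum), function(ix) {
    lp[ix][used[ix] == 1] - log(sum(exp(lp[ix])))
  }, numeric(1)))
}

oracle_clogit_fit <- function(X, used, stratum, start = rep(0, ncol(X))) {
  optim(start, function(b) -oracle_clogit_loglik(b, X, used, stratum),
        method = "BFGS", control = list(maxit = 500, reltol = 1e-14))$par
}

# tiny stratified dataset from a known linear model (for fit oracles)
toy_strata <- function(n_strata = 10, K = 5, beta = c(-0.5, 0.8), seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_strata), function(s) {
      X <- matrix(rnorm((K + 1) * length(beta)), K + 1)
      p <- exp(X %*% beta); p <- p / sum(p)
      used <- as.integer(seq_len(K + 1) == sample(K + 1, 1, prob = p))
      data.frame(stratum = s, used = used, x1 = X[, 1], x2 = X[, 2])
    })
    do.call(rbind, rows)
  })
}
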