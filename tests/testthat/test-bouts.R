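# bundle reused across bout/design tests
bout_sim <- local({
  cfg <- small_config()
  simulate_dataset(cfg, seed = 5)
})
bout_samples <- transform(bout_sim$samples, individual_id = true_individual)

test_that("bout windows, periods, and exclusions follow the sampling design", {
  b <- make_bouts(bout_sim$tracks, bout_samples, bout_sim$events)
  expect_s3_class(b, "bout_list")
  # every retained fix lies in the half-open 20-h window before deposition
  for (bb in b[1:4]) {
    dep <- bout_samples$deposition_time[bout_samples$sample_id == bb$sample_id]
    expect_true(all(bb$fixes$t > dep - 20 * 3600 & bb$fixes$t <= dep))
    expect_gte(nrow(bb$fixes), 3)
  }
  # brute-force window filter oracle on one bout
  bb <- b[[2]]
  dep <- bout_samples$deposition_time[bout_samples$sample_id == bb$sample_id]
  tr <- bout_sim$tracks[bout_sim$tracks$individual_id == bb$individual_id, ]
  oracle <- tr[sapply(seq_len(nrow(tr)), function(i)
    difftime(dep, tr$t[i], units = "hours") < 20 & tr$t[i] <= dep), ]
  expect_equal(bb$fixes$t, sort(oracle$t))
  # deposition exactly on the calving date is post with days_since 0
  ev <- bout_sim$events[1, ]
  dep <- as.POSIXct(as.character(ev$calving_date), tz = "UTC") + 3600
  s1 <- data.frame(sample_id = "b1", individual_id = ev$individual_id,
                   deposition_time = dep, concentration = 1900, fgm_z = 0.5,
                   year = ev$year)
  tr1 <- toy_track(cbind(c(0, 100, 200, 300), 0), id = ev$individual_id,
                   t0 = dep - 2 * 3600)
  b1 <- make_bouts(tr1, s1, bout_sim$events)
  expect_equal(b1[[1]]$period_post, 1L)
  expect_equal(b1[[1]]$days_since, 0)
})

test_that("samples with too few in-window fixes are excluded, not dropped silently", {
  s <- bout_samples
  s$deposition_time[3] <- s$deposition_time[3] + 200 * 86400 # far outside any track
  b <- make_bouts(bout_sim$tracks, s, bout_sim$events)
  exc <- attr(b, "excluded")
  expect_true(s$sample_id[3] %in% exc$sample_id)
  expect_equal(length(b), nrow(s) - 1)
})

test_that("step geometry matches hand computations", {
  # collinear equally spaced fixes: single step, zero turn
  tr <- toy_track(cbind(c(0, 100, 200), 0))
  st <- build_steps(data.frame(t = tr$t, x = tr$x, y = tr$y))
  expect_equal(nrow(st), 1)
  expect_equal(st$length, 100)
  expect_equal(st$turn_angle, 0)
  # right-angle path turns by pi/2
  tr <- toy_track(cbind(c(0, 100, 100), c(0, 0, 100)))
  st <- build_steps(data.frame(t = tr$t, x = tr$x, y = tr$y))
  expect_equal(st$turn_angle, pi / 2)
  # independent geometry oracle on a 20-fix bout
  withr::with_seed(3, xy <- apply(matrix(rnorm(40, sd = 120), ncol = 2), 2, cumsum))
  tr <- toy_track(xy)
  st <- build_steps(data.frame(t = tr$t, x = tr$x, y = tr$y))
  expect_equal(nrow(st), 18)
  i <- 7 # step from fix i+1 to i+2 with bearing history from fix i
  expect_equal(st$length[i], sqrt(sum((xy[i + 2, ] - xy[i + 1, ])^2)))
  b1 <- atan2(xy[i + 1, 2] - xy[i, 2], xy[i + 1, 1] - xy[i, 1])
  b2 <- atan2(xy[i + 2, 2] - xy[i + 1, 2], xy[i + 2, 1] - xy[i + 1, 1])
  expect_equal(st$turn_angle[i], cortmove:::wrap_angle(b2 - b1))
  dup <- data.frame(t = tr$t[c(1, 1, 2)], x = 0:2, y = 0)
  expect_error(build_steps(dup), "duplicate")
})

test_that("kernel fits recover generating distributions within 10%", {
  withr::with_seed(12, {
    steps <- data.frame(length = rgamma(2000, shape = 2, scale = 100),
                        turn_angle = rvonmises(2000, 0, 1.2))
  })
  kf <- fit_kernels(steps)
  expect_equal(kf$shape, 2, tolerance = 0.1)
  expect_equal(kf$scale, 100, tolerance = 0.1)
  expect_equal(kf$kappa, 1.2, tolerance = 0.1)
  # degenerate angles: concentration explodes at mu = 0
  k0 <- fit_kernels(data.frame(length = rgamma(50, 2, scale = 100),
                               turn_angle = rep(c(0, 1e-9), 25)))
  expect_gt(k0$kappa, 1e4)
  expect_equal(k0$mu, 0, tolerance = 1e-6)
  # uniform angles: no directional persistence
  withr::with_seed(4, ku <- fit_kernels(data.frame(length = rgamma(2000, 2, scale = 100),
                                                   turn_angle = runif(2000, -pi, pi))))
  expect_lt(ku$kappa, 0.1)
  expect_error(fit_kernels(steps[1:5, ]), "at least 10")
})

test_that("generated availability matches its kernels and shares stratum anchors", {
  b <- make_bouts(bout_sim$tracks, bout_samples, bout_sim$events)
  used <- do.call(rbind, lapply(b[1:5], function(bb) {
    st <- build_steps(bb); st$bout_id <- bb$bout_id; st
  }))
  used$stratum <- seq_len(nrow(used)); used$used <- 1L
  kern <- structure(list(shape = 1.5, scale = 150, mu = 0, kappa = 0.5,
                         n_steps = NA), class = "kernel_fit")
  av <- generate_available(used, kern, K = 7, landscape = bout_sim$landscape,
                           seed = 2)
  expect_equal(nrow(av), 7 * nrow(used))
  expect_equal(av$x1, rep(used$x1, each = 7))
  expect_true(all(table(av$stratum) == 7))
  # distributional check: 1e5 draws pass a KS test against the gamma kernel
  big <- generate_available(used[rep(1, 2000), ], kern, K = 50,
                            landscape = NULL, seed = 3)
  ks <- suppressWarnings(ks.test(big$length, "pgamma", shape = 1.5, scale = 150))
  expect_gt(ks$p.value, 0.01)
  # degenerate kernels give a closed-form end point
  kdeg <- structure(list(shape = 1e8, scale = 100 / 1e8, mu = 0, kappa = 1e8,
                         n_steps = NA), class = "kernel_fit")
  one <- generate_available(used[1, ], kdeg, K = 1, landscape = NULL, seed = 4)
  expect_equal(one$x2, used$x1[1] + 100 * cos(used$prior_bearing[1]), tolerance = 1e-3)
  expect_equal(one$y2, used$y1[1] + 100 * sin(used$prior_bearing[1]), tolerance = 1e-3)
})

test_that("design columns are exact products and zero-FGM bouts vanish", {
  b <- make_bouts(bout_sim$tracks, bout_samples, bout_sim$events)
  st <- build_strata(b, K = 5, landscape = bout_sim$landscape, seed = 2)
  d <- build_design(st, bout_sim$landscape)
  expect_equal(d$dist_fgm, d$dist_end * d$fgm_z)
  expect_equal(d$dist_fgm_period, d$dist_end * d$fgm_z * d$period_post)
  expect_equal(d$dist_fgm_days, d$dist_end * d$fgm_z * d$days_since)
  # a step ending on a cover cell has distance zero
  ls <- bout_sim$landscape
  cov <- which(ls$habitat == 1L, arr.ind = TRUE)[1, ]
  cx <- (cov[2] - 0.5) * ls$cell_size; cy <- (cov[1] - 0.5) * ls$cell_size
  expect_equal(lookup_dist_cover(ls, cx, cy), 0)
  # hand-built two-stratum toy matches explicit products
  toy <- data.frame(bout_id = "b1", stratum = rep(1:2, each = 2),
                    used = rep(c(1L, 0L), 2), x1 = 0, y1 = 0,
                    x2 = c(cx, cx + 300, cx, cx + 500), y2 = cy,
                    length = 1, turn_angle = 0)
  meta <- data.frame(bout_id = "b1", individual_id = "e1", fgm_z = 2,
                     period_post = 1, days_since = 10)
  attr(toy, "bout_meta") <- meta
  dt <- build_design(toy, ls)
  expect_equal(dt$dist_fgm, dt$dist_end * 2)
  expect_equal(dt$dist_fgm_period, dt$dist_end * 2)
  expect_equal(dt$dist_fgm_days, dt$dist_end * 2 * 10)
})
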