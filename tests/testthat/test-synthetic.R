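test_that("config invariants are enforced", {
  expect_error(sim_config(fix_interval = 0), "fix_interval")
  expect_error(sim_config(fgm_model = list(mean = 1900, sd_individual = -1,
                                           sd_within = 700)), "SD")
  expect_error(sim_config(calving = list(window = c("05-20", "06-25"),
                                         suppression = 0, hiding_days = 5,
                                         attraction = 2, confirmed_prob = 0.4)),
               "suppression")
})

test_that("FGM series is degenerate without noise and spans the target quantiles", {
  dates <- as.POSIXct("2019-06-01", tz = "UTC") + (0:9) * 86400
  s0 <- simulate_fgm_series("a", dates, list(mean = 1900, sd_individual = 0,
                                             sd_within = 0), seed = 1)
  expect_true(all(s0$concentration == 1900))
  expect_true(all(s0$concentration > 0))
  expect_true(all(s0$deposition_time < s0$collection_time))
  expect_true(all(s0$collection_time <= s0$deposition_time + 24 * 3600))

  # pooled quantiles with default parameters target ~1,200 / ~2,600 ug/g
  cfg <- sim_config()
  many <- do.call(rbind, lapply(1:200, function(i)
    simulate_fgm_series(paste0("e", i),
                        as.POSIXct("2019-06-01", tz = "UTC") + (0:49) * 3600,
                        cfg$fgm_model, seed = 100 + i)))
  q <- quantile(many$concentration, c(0.2, 0.8))
  expect_equal(unname(q[1]), 1200, tolerance = 0.10)
  expect_equal(unname(q[2]), 2600, tolerance = 0.10)
})

test_that("individual intercepts dominate pooled variance when configured", {
  dates <- as.POSIXct("2019-06-01", tz = "UTC") + (0:199) * 3600
  fm <- list(mean = 1900, sd_individual = 600, sd_within = 30)
  pool <- do.call(rbind, lapply(1:30, function(i)
    simulate_fgm_series(paste0("e", i), dates, fm, seed = i)))
  mus <- tapply(pool$concentration, pool$true_individual, mean)
  between <- var(mus)
  within <- mean(tapply(pool$concentration, pool$true_individual, var))
  expect_gt(between, 10 * within)
})

test_that("track simulation honours kernels and selection sign", {
  cfg <- sim_config(n_individuals = 4, years = 2019,
                    kernel = list(shape = 2, scale = 100, mu = 0, kappa = 1),
                    landscape = list(nx = 150, ny = 150, cell_size = 100,
                                     n_patches = 10, patch_radius = 400))
  ls <- make_landscape(cfg, seed = 2)
  times <- as.POSIXct("2019-06-01", tz = "UTC") + (0:1200) * 1800
  # beta = 0: kernel-only null
  tr0 <- simulate_track(ls, cfg, times, beta_series = 0, seed = 7)
  expect_equal(nrow(tr0), length(times))
  expect_true(all(inside_landscape <- !is.na(lookup_dist_cover(ls, tr0$x, tr0$y))))
  st <- build_steps(data.frame(t = tr0$t, x = tr0$x, y = tr0$y))
  kf <- fit_kernels(st)
  expect_equal(kf$shape, 2, tolerance = 0.1)
  expect_equal(kf$scale, 100, tolerance = 0.1)
  expect_equal(kf$kappa, 1, tolerance = 0.1)
  # strong avoidance of open cropland pulls end points toward cover
  tr_neg <- simulate_track(ls, cfg, times, beta_series = -2, seed = 7)
  d0 <- mean(lookup_dist_cover(ls, tr0$x, tr0$y))
  dneg <- mean(lookup_dist_cover(ls, tr_neg$x, tr_neg$y))
  expect_lt(dneg, d0)
})

test_that("calving suppression shortens steps in the hiding window", {
  cfg <- small_config()
  ls <- make_landscape(cfg, seed = 2)
  times <- as.POSIXct("2019-06-01", tz = "UTC") + (0:(20 * 48)) * 1800
  ev <- data.frame(calving_date = as.Date("2019-06-08"))
  reps <- sapply(1:5, function(r) {
    tr <- simulate_track(ls, cfg, times, beta_series = 0, calving = ev, seed = r)
    sl <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    hide <- tr$t[-1] > as.POSIXct("2019-06-08", tz = "UTC") &
      tr$t[-1] <= as.POSIXct("2019-06-13", tz = "UTC")
    pre <- tr$t[-1] <= as.POSIXct("2019-06-08", tz = "UTC")
    mean(sl[hide]) / mean(sl[pre])
  })
  expect_true(all(reps < 0.4)) # suppression factor 0.2 plus site attraction
})

test_that("track and sample tables round-trip through CSV", {
  cfg <- small_config()
  sim <- simulate_dataset(cfg, seed = 9)
  ft <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(sim$tracks, ft)
  rt <- read_tracks_csv(ft)
  # ISO-8601 stores whole seconds; sub-second phase is not preserved
  expect_lt(max(abs(as.numeric(rt$t) - as.numeric(sim$tracks$t))), 1)
  expect_equal(rt$x, sim$tracks$x, tolerance = 1e-9)
  expect_equal(rt$individual_id, sim$tracks$individual_id)
  fs <- withr::local_tempfile(fileext = ".csv")
  write_samples_csv(sim$samples, fs)
  rs <- read_samples_csv(fs)
  expect_lt(max(abs(as.numeric(rs$deposition_time) -
                      as.numeric(sim$samples$deposition_time))), 1)
  expect_equal(rs$concentration, sim$samples$concentration, tolerance = 1e-9)
})

test_that("dataset bundles are reproducible and respect the DNA rate", {
  cfg <- small_config()
  s1 <- simulate_dataset(cfg, seed = 9)
  s2 <- simulate_dataset(cfg, seed = 9)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$events, s2$events)

  cfg13 <- sim_config() # the study design: 13 elk over 2 seasons
  ev <- simulate_dataset(cfg13, seed = 3)$events
  expect_equal(nrow(ev), 26)

  cfg_dna <- small_config(sampling = list(n_samples = 3, dna_prob = 1,
                                          max_lag_hours = 24))
  expect_true(all(simulate_dataset(cfg_dna, seed = 2)$samples$dna_identified))

  short <- small_config(season = c("06-01", "06-04"))
  expect_error(simulate_dataset(short, seed = 1), "shorter than")
})
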