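# shared bundle for screening tests: season tracks so candidate searches
# have data; sample locations sit on the depositor's track
assign_sim <- local({
  cfg <- sim_config(n_individuals = 5, years = 2019,
                    season = c("05-01", "06-30"),
                    landscape = list(nx = 40, ny = 40, cell_size = 100,
                                     n_patches = 4, patch_radius = 400),
                    sampling = list(n_samples = 3, dna_prob = 0.4, max_lag_hours = 24))
  simulate_dataset(cfg, seed = 31, mode = "season")
})

constant_scorer <- function(value) list(predict = function(sample, track, seed) value)
coin_scorer <- list(predict = function(sample, track, seed)
  withr::with_seed(seed, as.numeric(runif(1) < 0.5)))

test_that("degenerate scorers are accepted or rejected as the threshold dictates", {
  cfg <- assignment_config(n_iterations = 200, seed = 3)
  s <- assign_sim$samples[1, ]
  tr <- assign_sim$tracks[assign_sim$tracks$individual_id == s$true_individual, ]
  always <- assign_sample(s, tr, constant_scorer(1), cfg)
  expect_true(always$accepted)
  expect_equal(always$mean_accuracy, 1)
  coin <- assign_sample(s, tr, coin_scorer, cfg)
  expect_false(coin$accepted) # ~0.5 < 0.77
  expect_equal(coin$mean_accuracy, 0.5, tolerance = 0.12)
  # with threshold ~0 everything passes; threshold ~1 rejects a stochastic scorer
  expect_true(assign_sample(s, tr, coin_scorer,
                            assignment_config(accuracy_threshold = 0.01,
                                              n_iterations = 200, seed = 3))$accepted)
  expect_false(assign_sample(s, tr, coin_scorer,
                             assignment_config(accuracy_threshold = 0.99,
                                               n_iterations = 200, seed = 3))$accepted)
})

test_that("candidate search honours closed distance and time boundaries", {
  t1 <- as.POSIXct("2019-06-10 12:00:00", tz = "UTC")
  s <- data.frame(sample_id = "s1", x = 0, y = 0, collection_time = t1,
                  deposition_time = t1 - 3600)
  mk <- function(id, x, dt) data.frame(individual_id = id, t = t1 - dt,
                                       x = x, y = 0)
  tracks <- rbind(
    mk("at20m", 20, 86400),        # exactly 20 m, 1 d before: included
    mk("at21m", 20.5, 86400),      # just outside the radius
    mk("stale", 0, 86400 * 2 + 1), # just outside the look-back
    mk("edge_time", 0, 86400 * 2)) # exactly 2 d before: included
  cand <- find_candidates(s, tracks, assignment_config())
  expect_setequal(cand$individual_id, c("at20m", "edge_time"))
  # exclusion removes the rejected suspect
  expect_false("at20m" %in%
                 find_candidates(s, tracks, assignment_config(),
                                 exclude = "at20m")$individual_id)
  # empty result is allowed
  far <- data.frame(sample_id = "s2", x = 1e6, y = 1e6, collection_time = t1,
                    deposition_time = t1 - 3600)
  expect_equal(nrow(find_candidates(far, tracks, assignment_config())), 0)
})

test_that("candidate search matches a brute-force filter on simulated data", {
  cfg <- assignment_config()
  for (k in c(2, 5, 9)) {
    s <- assign_sim$samples[k, ]
    cand <- find_candidates(s, assign_sim$tracks, cfg)
    # oracle: exhaustive loop over individuals and fixes
    oracle <- sapply(unique(assign_sim$tracks$individual_id), function(id) {
      tr <- assign_sim$tracks[assign_sim$tracks$individual_id == id, ]
      keep <- tr$t >= s$collection_time - 2 * 86400 & tr$t <= s$collection_time &
        sqrt((tr$x - s$x)^2 + (tr$y - s$y)^2) <= 20
      sum(keep)
    })
    oracle <- oracle[oracle > 0]
    expect_setequal(cand$individual_id, names(oracle))
    expect_equal(cand$n_near[order(cand$individual_id)],
                 unname(oracle[order(names(oracle))]))
  }
})

test_that("screening produces a consistent ledger and is order-independent", {
  cfg <- assignment_config(n_iterations = 40, seed = 7)
  known <- assign_sim$samples[assign_sim$samples$dna_identified, ]
  scorer <- train_default_scorer(known, assign_sim$tracks, seed = 2)
  res <- run_screening(assign_sim$samples, assign_sim$tracks, scorer, cfg)
  led <- res$ledger
  # arithmetic identities
  expect_equal(led$dna_identified + led$ml_candidates, led$collected)
  expect_equal(led$ml_candidates - led$failed_threshold + led$recovered,
               led$accepted_ml)
  expect_equal(led$accepted_total, led$accepted_ml + led$dna_identified)
  # ledger equals a recount from dispositions
  expect_equal(led$collected, nrow(res$dispositions))
  expect_equal(led$dna_identified, sum(res$dispositions$stage == "dna"))
  expect_equal(led$recovered, sum(res$dispositions$stage == "ml_reassigned"))
  expect_equal(led$accepted_total, sum(res$dispositions$accepted))
  # permuting the sample order changes no disposition
  perm <- withr::with_seed(1, sample(nrow(assign_sim$samples)))
  res2 <- run_screening(assign_sim$samples[perm, ], assign_sim$tracks, scorer, cfg)
  d1 <- res$dispositions[order(res$dispositions$sample_id), ]
  d2 <- res2$dispositions[order(res2$dispositions$sample_id), ]
  rownames(d1) <- rownames(d2) <- NULL
  expect_equal(d1, d2)
  # all-DNA reduces the ledger to pass-through
  all_dna <- transform(assign_sim$samples, dna_identified = TRUE)
  res3 <- run_screening(all_dna, assign_sim$tracks, scorer, cfg)
  expect_equal(res3$ledger$accepted_total, res3$ledger$collected)
  expect_error(run_screening(rbind(assign_sim$samples, assign_sim$samples[1, ]),
                             assign_sim$tracks, scorer, cfg), "duplicate")
})

test_that("the recorded screening stage counts reproduce the analysis totals", {
  led <- screening_ledger(collected = 154, dna_identified = 32,
                          failed_threshold = 85, recovered = 7)
  expect_equal(led$ml_candidates, 122)
  expect_equal(led$accepted_ml, 44)
  expect_equal(led$final_discarded, 78)
  expect_equal(led$accepted_total, 76)
  led2 <- screening_ledger(154, 32, 85, 7, issa_retained = 68)
  expect_equal(led2$issa_retained, 68)
  expect_error(screening_ledger(154, 32, 85, 90), "inconsistent")
  expect_error(screening_ledger(10, 2, 3, 1, issa_retained = 11), "issa_retained")
})
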