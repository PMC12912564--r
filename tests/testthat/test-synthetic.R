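test_that("display generation satisfies counts and the separation constraint", {
  d <- generate_displays(seed = 5)
  expect_equal(length(unique(d$scene_id)), 29)
  expect_equal(nrow(d), 87)                       # target slots
  all_objects <- c(d$target_object, d$lure_object)
  expect_equal(length(unique(all_objects)), 174)  # target/lure pairs
  seps <- tapply(d$position_deg, d$scene_id, function(p) {
    dd <- abs(outer(p, p, "-"))
    dd <- pmin(dd, 360 - dd)
    min(dd[upper.tri(dd)])
  })
  expect_true(all(seps >= 62.04))
  expect_true(all(d$position_deg >= 0 & d$position_deg < 360))
})

test_that("display generation refuses infeasible configs, allows vacuous ones", {
  expect_error(generate_displays(objects_per_display = 6,
                                 min_separation = 62.04),
               "infeasible")
  d1 <- generate_displays(n_scenes = 4, objects_per_display = 1, seed = 1)
  expect_equal(nrow(d1), 4)
  expect_identical(generate_displays(seed = 9), generate_displays(seed = 9))
})

test_that("cohort generator reproduces the configured lifestyle structure", {
  cors <- numeric(40)
  drops <- numeric(40)
  for (s in seq_len(40)) {
    co <- generate_cohort(n_subjects = 59, seed = 1000 + s,
                          simulate_trials = FALSE)$cohort
    one <- co[co$timepoint == "T1", ]
    cors[s] <- cor(one$lifestyle_typical, one$lifestyle_pandemic)
    drops[s] <- mean(one$lifestyle_typical - one$lifestyle_pandemic)
  }
  expect_lt(mean(abs(cors - 0.86)), 0.1)
  expect_true(all(abs(drops - 4.47) < 1.5 + 3))   # generous per-seed band
  expect_lt(abs(mean(drops) - 4.47), 1.5)
})

test_that("cohort generator is a pure function of config and seed", {
  a <- generate_cohort(n_subjects = 8, trials_per_subject = 10, seed = 42)
  b <- generate_cohort(n_subjects = 8, trials_per_subject = 10, seed = 42)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$trials, b$trials)
  # null config: true change in pT centred at zero across seeds
  deltas <- sapply(1:30, function(s) {
    co <- generate_cohort(n_subjects = 40, seed = s,
                          simulate_trials = FALSE)$cohort
    wide <- tidyr::pivot_wider(co[, c("subject_id", "timepoint", "true_pT")],
                               names_from = "timepoint",
                               values_from = "true_pT")
    mean(wide$T1 - wide$T2)
  })
  expect_lt(abs(mean(deltas)), 0.03)
})

test_that("fitting simulated subjects recovers the generating parameters", {
  co <- generate_cohort(n_subjects = 6, trials_per_subject = 10000, seed = 77)
  per <- split(co$trials, interaction(co$trials$subject_id,
                                      co$trials$timepoint, drop = TRUE))
  fits <- lapply(per, function(d) fit_mixture_mle(d$error_deg,
                                                  hessian = FALSE))
  truth <- co$cohort$true_pT[match(
    names(per),
    interaction(co$cohort$subject_id, co$cohort$timepoint, drop = TRUE))]
  bias <- mean(sapply(fits, `[[`, "pT") - truth)
  expect_lt(abs(bias), 0.02)
})

test_that("lifestyle coupling induces the configured change correlation", {
  cfg <- cohort_config(lifestyle_memory_r = 0.6, t2_pT_shift = -0.2)
  co <- generate_cohort(n_subjects = 400, config = cfg, seed = 11,
                        simulate_trials = FALSE)$cohort
  wide <- tidyr::pivot_wider(co[, c("subject_id", "timepoint", "true_pT")],
                             names_from = "timepoint",
                             values_from = "true_pT")
  info <- unique(co[, c("subject_id", "lifestyle_typical",
                        "lifestyle_pandemic")])
  wide <- dplyr::left_join(wide, info, by = "subject_id")
  r <- cor(wide$lifestyle_typical - wide$lifestyle_pandemic,
           wide$T1 - wide$T2)
  expect_gt(r, 0.4)  # decline in lifestyle tracks decline in memory
})

test_that("lifestyle item generator respects the scale and configured shifts", {
  it <- generate_lifestyle_items(n_subjects = 59, seed = 13)
  expect_true(all(it$response %in% 0:5))
  expect_equal(sort(unique(it$phase)), c("pandemic", "typical"))
  # zero shifts: no item significant at the Bonferroni level in a null run
  cfg0 <- default_item_config()
  cfg0$pandemic_shift <- 0
  null_it <- generate_lifestyle_items(n_subjects = 59, item_config = cfg0,
                                      seed = 14)
  tests <- item_change_tests(null_it)
  expect_lte(sum(tests$significant), 1)
  # a large targeted shift is detected on exactly the shifted items
  cfg1 <- cfg0
  cfg1$pandemic_shift[cfg1$item_id %in%
                        c("socialising_friends", "social_outings")] <- 2
  shifted <- generate_lifestyle_items(n_subjects = 59, item_config = cfg1,
                                      seed = 15)
  tt <- item_change_tests(shifted)
  expect_true(all(tt$significant[tt$item_id %in%
                                   c("socialising_friends",
                                     "social_outings")]))
  expect_lte(sum(tt$significant[!tt$item_id %in%
                                  c("socialising_friends",
                                    "social_outings")]), 1)
  expect_error(generate_lifestyle_items(item_config =
    tibble::tibble(item_id = "x", typical_mean = 9, typical_sd = 1,
                   pandemic_shift = 0)), "range")
})
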