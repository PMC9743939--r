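# Synthetic generator: seed contract, planted structure, distribution
# fidelity of bout-length draws, cohort construction.

test_that("identical specs and seeds give bit-identical series; seeds differ", {
  sp <- signal_spec(days = 2, seed = 11)
  a <- generate_epoch_series(sp)
  b <- generate_epoch_series(sp)
  expect_identical(a$enmo, b$enmo)
  d <- generate_epoch_series(signal_spec(days = 2, seed = 12))
  expect_false(identical(a$enmo, d$enmo))
})

test_that("degenerate fixed-bout spec plants constant waking level and a
           recoverable bout structure", {
  sp <- signal_spec(days = 2,
                    bout_dist = list(SB = dist_fixed(10),
                                     LPA = dist_fixed(10),
                                     MVPA = dist_fixed(10)),
                    state_weights = c(SB = 1, LPA = 0, MVPA = 0),
                    noise = noise_white(0), seed = 5)
  es <- generate_epoch_series(sp)
  truth <- attr(es, "truth")
  awake <- truth$state != "SLEEP"
  expect_true(all(es$enmo[awake] == sp$intensity_levels[["SB"]]))
  # detector (with planted sleep) recovers exactly the planted bouts
  sl <- detect_sleep(es, ground_truth = tibble::tibble(onset = truth$sleep_onset,
                                                       wake = truth$wake))
  iseries <- classify_intensity(es, sl)
  bouts <- find_bouts(iseries)
  expect_equal(nrow(bouts), nrow(truth$bouts))
  expect_equal(bouts$duration_min, truth$bouts$duration_min)
})

test_that("power-law bout draws recover the requested exponent and family", {
  set.seed(31)
  d <- draw_bout_lengths(dist_power_law(2.5, xmin = 1), 1e4)
  expect_equal(power_law_exponent(d), 2.5, tolerance = 0.1 / 2.5)
  # KS against the Pareto cdf, alpha = 0.01
  ks <- suppressWarnings(
    stats::ks.test(d, function(q) 1 - (1 / q)^(2.5 - 1)))
  expect_gt(ks$p.value, 0.01)
  set.seed(32)
  ln <- draw_bout_lengths(dist_lognormal(log(2), 0.6), 1e4)
  ks2 <- suppressWarnings(stats::ks.test(ln, "plnorm", log(2), 0.6))
  expect_gt(ks2$p.value, 0.01)
})

test_that("planted sleep windows are recoverable by the detector", {
  es <- generate_epoch_series(signal_spec(days = 4, seed = 21))
  truth <- attr(es, "truth")
  win <- detect_sleep(es)
  sod <- as.numeric(es$time) %% 86400
  planted <- sod >= truth$sleep_onset | sod < truth$wake
  detected <- rep(FALSE, length(es))
  for (i in seq_len(nrow(win))) {
    detected[es$time >= win$start[i] & es$time < win$end[i]] <- TRUE
  }
  expect_gt(mean(planted == detected), 0.95)
})

test_that("cohort generation honours n, missingness and the effect map", {
  one <- generate_cohort(cohort_spec(1, missingness = 0, seed = 2))
  expect_equal(nrow(one), 1)
  expect_false(anyNA(one[setdiff(names(one), "series")]))
  expect_error(cohort_spec(5, effect_map = list(not_a_feature = c(quicki = 1))),
               "unknown feature")
  co <- generate_cohort(cohort_spec(40, seed = 3))
  expect_true(anyNA(co$income))
  expect_identical(co$quicki, generate_cohort(cohort_spec(40, seed = 3))$quicki)
  # quicki round-trips through insulin and glucose
  ok <- !is.na(co$quicki)
  expect_equal(quicki(co$insulin[ok], co$glucose[ok]), co$quicki[ok])
})

test_that("null effect map yields no systematic feature-outcome association", {
  hits <- 0
  for (s in 1:20) {
    co <- generate_cohort(cohort_spec(200, missingness = 0, seed = 100 + s))
    p <- stats::cor.test(co$time_mvpa, co$quicki)$p.value
    if (p < 0.05) hits <- hits + 1
  }
  expect_lte(hits, 4)  # binomial(20, .05): P(X > 4) < 0.004
})

test_that("signal-mode cohort carries per-participant series", {
  co <- generate_cohort(cohort_spec(2, mode = "signal", seed = 9),
                        signal_spec(days = 1, seed = 9))
  expect_length(co$series, 2)
  expect_s3_class(co$series[[1]], "epoch_series")
  expect_false(identical(co$series[[1]]$enmo, co$series[[2]]$enmo))
})
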