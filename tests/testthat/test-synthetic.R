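test_that("every generator is deterministic under a fixed seed", {
  expect_identical(gen_distance_series(n_frames = 500, occupancy = 0.5,
                                       seed = 3),
                   gen_distance_series(n_frames = 500, occupancy = 0.5,
                                       seed = 3))
  expect_identical(gen_ct_table(degradation = 0.3, seed = 3),
                   gen_ct_table(degradation = 0.3, seed = 3))
  expect_identical(gen_ussing_trace(noise_sd = 0.1, seed = 3),
                   gen_ussing_trace(noise_sd = 0.1, seed = 3))
  expect_identical(gen_cbf_stack(duration = 1, noise_sd = 0.5, seed = 3),
                   gen_cbf_stack(duration = 1, noise_sd = 0.5, seed = 3))
  expect_identical(gen_blot_lanes(control_noise_sd = 0.05, seed = 3),
                   gen_blot_lanes(control_noise_sd = 0.05, seed = 3))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(gen_distance_series(n_frames = 100, seed = 42))
  invisible(gen_cbf_stack(duration = 1, seed = 42))
  expect_identical(runif(1), before)
})

test_that("single-state trajectories pin the contact fraction", {
  bound <- gen_distance_series(n_frames = 2000, occupancy = 1,
                               mean_contact = 3.9, sd_contact = 0.2,
                               seed = 21)
  expect_equal(contact_fraction(bound$series, 5), 1)
  expect_true(all(abs(bound$series$distances - 3.9) < 1.5))

  lost <- gen_distance_series(n_frames = 2000, occupancy = 0,
                              mean_open = 10.7, sd_open = 0.9, seed = 22)
  expect_equal(contact_fraction(lost$series, 7), 0)
})

test_that("two-state occupancy converges at large n", {
  gen <- gen_distance_series(n_frames = 1e5, occupancy = 0.57,
                             mean_contact = 3.9, sd_contact = 0.2,
                             mean_open = 10.7, sd_open = 0.9, seed = 23)
  expect_lt(abs(contact_fraction(gen$series, 7) - 0.57), 0.01)
  expect_error(gen_distance_series(occupancy = 1.4), "<= 1")
})

test_that("dwell-scaled switching preserves the stationary occupancy", {
  gen <- gen_distance_series(n_frames = 2e5, occupancy = 0.57,
                             switch_scale = 10, mean_contact = 3.9,
                             mean_open = 10.7, seed = 29)
  # longer dwells inflate the SE; allow a wider band than the iid case
  expect_lt(abs(gen$truth$empirical_occupancy - 0.57), 0.05)
  runs <- rle(gen$truth$states)
  expect_gt(mean(runs$lengths), 2) # persistence actually increased
})

test_that("CT generation round-trips degradation in closed form", {
  gen <- gen_ct_table(degradation = 0.5094, ct_noise_sd = 0, seed = 31)
  res <- allele_quant(gen$ct_table, gen$calibrators)
  expect_equal(res$pct_degradation, 50.94, tolerance = 1e-9)
  expect_equal(gen$truth$pct_allele_a, 100 * (1 - 0.5094) / (2 - 0.5094),
               tolerance = 1e-9)
  expect_error(gen_ct_table(allele_fractions = c(0.6, 0.6)), "sum to 1")
  expect_error(gen_ct_table(allele_fractions = c(1, 0), degradation = 1),
               "zero")
})

test_that("flat Ussing configs generate flat traces", {
  gen <- gen_ussing_trace(deltas = c(forskolin = 0), noise_sd = 0,
                          drift = 0, baseline = 5)
  expect_equal(range(gen$trace$isc), c(5, 5))
  expect_error(gen_ussing_trace(tau = 500), "inter-event gap")
  expect_error(gen_ussing_trace(deltas = c(bogus = 1)), "absent from")
})

test_that("generated ETI-like activity reproduces the printed fold", {
  gen <- gen_ussing_trace(
    deltas = c(IVA = 0, forskolin = 5.73),
    schedule = default_schedule(potentiator = "IVA"),
    noise_sd = 0, drift = 0
  )
  r <- segment_trace(gen$trace, gen$schedule)
  act <- cftr_activity(r, "ELX/TEZ+IVA", baseline_fsk = 3.45)
  expect_equal(round(act$fold_change, 2), 1.66)
  expect_equal(round(act$above_baseline, 2), 2.28)
})

test_that("CBF stacks respect Nyquist and expose the no-signal path", {
  expect_error(gen_cbf_stack(frequency = 60, frame_rate = 100), "Nyquist")
  still <- gen_cbf_stack(frequency = 5, amplitude = 0, noise_sd = 0,
                         duration = 1, seed = 2)
  expect_error(field_spectrum(still$stack), "no oscillation")
  in_range <- gen_cbf_stack(frequency = 9, duration = 2, seed = 2)
  sp <- field_spectrum(in_range$stack, band = c(3, 11))
  agg <- aggregate_cbf(list(sp))
  expect_true(agg$per_culture$in_physiological_range)
})

test_that("generator truth records carry what the recovery suites need", {
  g1 <- gen_distance_series(n_frames = 10, seed = 1)
  expect_named(g1, c("series", "truth"))
  expect_true(all(c("occupancy", "empirical_occupancy", "states") %in%
                    names(g1$truth)))
  g2 <- gen_ussing_trace(seed = 1)
  expect_named(g2, c("trace", "schedule", "truth"))
  expect_true("forskolin" %in% names(g2$truth$deltas))
  g3 <- gen_cbf_stack(duration = 1, seed = 1)
  expect_true(all(c("frequency", "bin_width") %in% names(g3$truth)))
})
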