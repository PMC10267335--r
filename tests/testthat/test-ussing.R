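flat_trace <- function(level = 5, t_end = 900) {
  tt <- seq(0, t_end, by = 0.5)
  isc_trace(tt, rep(level, length(tt)))
}

test_that("segmenting a flat trace yields zero responses everywhere", {
  r <- segment_trace(flat_trace(), default_schedule())
  expect_equal(nrow(r), 5)
  expect_equal(r$delta_isc, rep(0, 5))
  expect_equal(r$pre_plateau, rep(5, 5))
})

test_that("a clean step at forskolin is recovered exactly", {
  sched <- default_schedule()
  tt <- seq(0, 900, by = 0.5)
  fsk_t <- sched$events$time[sched$events$compound == "forskolin"]
  isc <- ifelse(tt > fsk_t, 15, 5)
  r <- segment_trace(isc_trace(tt, isc), sched)
  expect_equal(r$delta_isc[r$compound == "forskolin"], 10)
  expect_equal(sum(r$delta_isc), 10) # only one event moved the trace
})

test_that("responses telescope: deltas sum to the net plateau change", {
  gen <- gen_ussing_trace(
    deltas = c(amiloride = -2, forskolin = 6, `CFTRinh-172` = -6, ATP = 4),
    noise_sd = 0, drift = 0
  )
  r <- segment_trace(gen$trace, gen$schedule)
  first_plateau <- r$pre_plateau[1L]
  last_plateau <- r$post_plateau[nrow(r)]
  expect_equal(sum(r$delta_isc), last_plateau - first_plateau,
               tolerance = 1e-9)
})

test_that("segmentation validates events and window size", {
  tr <- flat_trace(t_end = 500)
  expect_error(segment_trace(tr, default_schedule()), "outside the trace")
  sched <- event_schedule(data.frame(
    time = c(100, 110), compound = c("amiloride", "forskolin"),
    compartment = "apical", concentration = 1
  ))
  expect_error(segment_trace(flat_trace(), sched, plateau_window = 30),
               "exceeds the gap before event 'forskolin'")
})

test_that("CFTR activity sums potentiator and forskolin responses", {
  resp <- data.frame(
    compound = c("amiloride", "IVA", "forskolin", "CFTRinh-172"),
    delta_isc = c(-2, 0.3, 5.43, -5.73)
  )
  act <- cftr_activity(resp, "ELX/TEZ+IVA", baseline_fsk = 3.45)
  expect_equal(act$total_current, 5.73)
  expect_equal(round(act$fold_change, 2), 1.66)
  expect_equal(round(act$above_baseline, 2), 2.28)
  expect_equal(act$inh172_response, -5.73)
  # identity holds at full precision
  expect_equal(act$above_baseline + act$baseline_fsk, act$total_current)
})

test_that("the vehicle condition defines its own baseline", {
  resp <- data.frame(compound = c("DMSO", "forskolin"),
                     delta_isc = c(0, 3.45))
  act <- cftr_activity(resp, "DMSO", baseline_fsk = 3.45)
  expect_equal(act$total_current, 3.45)
  expect_equal(act$fold_change, 1)
  expect_equal(act$above_baseline, 0)
  expect_true(is.na(act$inh172_response))

  no_fsk <- data.frame(compound = "IVA", delta_isc = 1)
  expect_error(cftr_activity(no_fsk, "IVA", 3.45), "no forskolin")
})

test_that("a zero-effect potentiator leaves activity at baseline", {
  resp <- data.frame(compound = c("IVA", "forskolin"),
                     delta_isc = c(0, 3.45))
  act <- cftr_activity(resp, "IVA", baseline_fsk = 3.45)
  expect_equal(act$fold_change, 1)
  expect_equal(act$above_baseline, 0)
})

test_that("fold change divides total by a positive baseline", {
  expect_equal(round(fold_change(3.45, 3.45), 2), 1)
  expect_equal(round(fold_change(5.73, 3.45), 2), 1.66)
  expect_equal(round(fold_change(27.19, 27.19 - 25.75), 2), 18.88)
  expect_error(fold_change(5, 0), "> 0")
})

test_that("TEER maturity bounds are inclusive", {
  expect_true(teer_qc(242.3))
  expect_true(teer_qc(188))
  expect_true(teer_qc(1250))
  expect_false(teer_qc(100))
  expect_false(teer_qc(1300))
  expect_error(teer_qc(-5), "> 0")
})

test_that("noiseless generated responses are recovered near-exactly", {
  gen <- gen_ussing_trace(deltas = c(forskolin = 15.33), noise_sd = 0,
                          drift = 0)
  r <- segment_trace(gen$trace, gen$schedule)
  expect_lt(abs(r$delta_isc[r$compound == "forskolin"] - 15.33), 0.05)
})

test_that("linear detrending removes additive drift bias from responses", {
  gen <- gen_ussing_trace(deltas = c(forskolin = 3.45), noise_sd = 0,
                          drift = 0.002)
  raw <- segment_trace(gen$trace, gen$schedule)
  corrected <- segment_trace(gen$trace, gen$schedule, detrend = "linear")
  err_raw <- abs(raw$delta_isc[raw$compound == "forskolin"] - 3.45)
  err_cor <- abs(corrected$delta_isc[corrected$compound == "forskolin"] -
                   3.45)
  expect_gt(err_raw, 0.2)  # 0.002 uA/cm2/s over a 120 s interval
  expect_lt(err_cor, 0.01)
})

test_that("the CFTR inhibitor reverses the activated current", {
  gen <- gen_ussing_trace(
    deltas = c(IVA = 0.3, forskolin = 5.43, `CFTRinh-172` = -5.73),
    schedule = default_schedule(potentiator = "IVA"),
    noise_sd = 0.05, drift = 0.001, seed = 17
  )
  r <- segment_trace(gen$trace, gen$schedule)
  act <- cftr_activity(r, "ELX/TEZ+IVA", baseline_fsk = 3.45)
  expect_lt(abs(act$inh172_response + act$total_current), 0.5)
})

test_that("Isc traces round-trip through CSV with metadata sidecar", {
  gen <- gen_ussing_trace(deltas = c(forskolin = 3), noise_sd = 0.02,
                          genotype = "Q1291H/F508del", treatment = "DMSO",
                          culture_id = "c1", teer = 242.3, seed = 4)
  csv <- tempfile(fileext = ".csv")
  meta <- tempfile(fileext = ".yaml")
  write_isc_csv(gen$trace, csv, metadata_path = meta)
  back <- read_isc_csv(csv, metadata = meta)
  expect_equal(back$isc, gen$trace$isc, tolerance = 1e-9)
  expect_equal(back$genotype, "Q1291H/F508del")
  expect_equal(back$teer, 242.3)
})

test_that("schedules read from YAML preserve order and fields", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(events = list(
    list(time = 100, compound = "amiloride", compartment = "apical",
         concentration = 100),
    list(time = 200, compound = "forskolin", compartment = "basal",
         concentration = 10)
  )), path)
  sched <- read_schedule(path)
  expect_equal(sched$events$compound, c("amiloride", "forskolin"))
  expect_equal(sched$events$time, c(100, 200))
})
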