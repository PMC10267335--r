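# Seeded generators with known ground truth for every pipeline stage.
# Each returns the object(s) the corresponding analysis functions consume
# plus a `truth` record; identical seed + config gives identical output.

#' Generate a two-state residue-ligand distance series
#'
#' Emulates the bound/disrupted dynamics of a binding-site contact: a
#' two-state Markov switching process whose stationary occupancy of the
#' contact state is configurable, with Gaussian distances around a
#' state-specific mean within each state. Dwell times are geometric with a
#' common switching scale, so the empirical occupancy converges to the
#' configured value as the series grows.
#'
#' @param n_frames Number of frames (>= 1).
#' @param occupancy Stationary probability of the contact state, in
#'   \[0, 1\]; 0 or 1 give a single-state series.
#' @param mean_contact,sd_contact Distance distribution in the contact
#'   state (Å).
#' @param mean_open,sd_open Distance distribution in the disrupted state (Å).
#' @param switch_scale Dwell scale in frames; transition probabilities are
#'   `(1 - occupancy) / switch_scale` out of contact and
#'   `occupancy / switch_scale` into contact, so the stationary occupancy is
#'   unchanged while dwell times stretch with the scale. Must be >=
#'   `max(occupancy, 1 - occupancy)`. The default 1 makes successive frames
#'   independent draws at the stationary occupancy, so the empirical
#'   occupancy carries plain binomial error; larger scales emulate the long
#'   bound/disrupted episodes seen in real trajectories at the cost of a
#'   proportionally larger occupancy standard error.
#' @param dt_ns Frame interval in ns.
#' @param metric,replicate_id Labels for the series.
#' @param seed Integer seed (`NULL` = use the current RNG state).
#' @return List with `series` (a [distance_series()]), and `truth`
#'   (configured occupancy, state means/SDs, realised per-frame states and
#'   empirical occupancy).
#' @export
gen_distance_series <- function(n_frames = 1000, occupancy = 0.5,
                                mean_contact = 3.9, sd_contact = 0.2,
                                mean_open = 10.7, sd_open = 0.9,
                                switch_scale = 1, dt_ns = 1,
                                metric = "metric", replicate_id = "rep1",
                                seed = NULL) {
  check_number(occupancy, "occupancy", lower = 0, upper = 1)
  check_number(n_frames, "n_frames", lower = 1)
  check_number(switch_scale, "switch_scale",
               lower = max(occupancy, 1 - occupancy))
  stopifnot(sd_contact >= 0, sd_open >= 0)
  with_seed(seed, {
    if (occupancy %in% c(0, 1)) {
      states <- rep(as.integer(occupancy), n_frames)
    } else {
      p_leave_contact <- (1 - occupancy) / switch_scale
      p_enter_contact <- occupancy / switch_scale
      states <- integer(n_frames)
      states[1L] <- stats::rbinom(1L, 1L, occupancy)
      flips <- stats::runif(n_frames)
      for (i in seq_len(n_frames - 1L)) {
        p <- if (states[i] == 1L) p_leave_contact else p_enter_contact
        states[i + 1L] <- if (flips[i] < p) 1L - states[i] else states[i]
      }
    }
    mu <- ifelse(states == 1L, mean_contact, mean_open)
    sig <- ifelse(states == 1L, sd_contact, sd_open)
    d <- pmax(0, stats::rnorm(n_frames, mu, sig))
    list(
      series = distance_series(d, times = dt_ns * (seq_len(n_frames) - 1L),
                               metric = metric, replicate_id = replicate_id),
      truth = list(
        occupancy = occupancy, empirical_occupancy = mean(states == 1L),
        mean_contact = mean_contact, sd_contact = sd_contact,
        mean_open = mean_open, sd_open = sd_open, states = states,
        seed = seed
      )
    )
  })
}

#' Generate an allele-specific qPCR CT table
#'
#' Emulates a two-allele transcript mixture measured in technical
#' replicates: allele quantities are the configured fractions, with the
#' splicing-defective allele (`allele_a`) reduced by the configured
#' degradation fraction; CT values follow
#' `CT = base_CT - log2(quantity) + noise`. Calibrator samples carry an
#' undegraded 50:50 mixture, mirroring homozygous-intact-allele reference
#' participants.
#'
#' @param allele_fractions Transcription fractions `c(f_a, f_b)` summing
#'   to 1.
#' @param degradation Fraction of allele-a transcript degraded, in \[0, 1).
#' @param ct_noise_sd Gaussian CT noise SD (cycles).
#' @param reference_ct Reference-gene CT (cycles).
#' @param target_base_ct CT of an allele target at unit relative quantity.
#' @param n_replicates Technical replicates per target.
#' @param n_calibrators Number of calibrator samples.
#' @param sample_id Label of the test sample.
#' @param seed Integer seed.
#' @return List with `ct_table` (long-format data frame ready for
#'   [allele_quant()]), `calibrators` (their sample ids) and `truth`
#'   (expected percentages and degradation).
#' @export
gen_ct_table <- function(allele_fractions = c(0.5, 0.5), degradation = 0,
                         ct_noise_sd = 0.1, reference_ct = 20,
                         target_base_ct = 24, n_replicates = 3,
                         n_calibrators = 3, sample_id = "patient",
                         seed = NULL) {
  if (abs(sum(allele_fractions) - 1) > 1e-9) {
    stop_("allele fractions must sum to 1")
  }
  check_number(degradation, "degradation", lower = 0, upper = 1)
  stopifnot(ct_noise_sd >= 0)
  q_a <- allele_fractions[1L] * (1 - degradation)
  q_b <- allele_fractions[2L]
  if (q_a + q_b <= 0) stop_("total transcript quantity is zero")
  with_seed(seed, {
    quantities <- list()
    for (i in seq_len(n_calibrators)) {
      quantities[[paste0("cal", i)]] <- c(allele_a = 0.5, allele_b = 0.5)
    }
    quantities[[sample_id]] <- c(allele_a = q_a, allele_b = q_b)
    rows <- list()
    for (s in names(quantities)) {
      for (target in c("allele_a", "allele_b", "reference")) {
        base <- if (target == "reference") reference_ct else {
          target_base_ct - log2(quantities[[s]][[target]])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, target = target,
          replicate = seq_len(n_replicates),
          ct = base + stats::rnorm(n_replicates, 0, ct_noise_sd),
          stringsAsFactors = FALSE
        )
      }
    }
    pct_a <- 100 * q_a / (q_a + q_b)
    list(
      ct_table = do.call(rbind, rows),
      calibrators = paste0("cal", seq_len(n_calibrators)),
      truth = list(
        degradation_pct = 100 * degradation,
        pct_allele_a = pct_a, pct_allele_b = 100 - pct_a,
        quantities = quantities[[sample_id]], seed = seed
      )
    )
  })
}

#' Generate a short-circuit current trace for a compound schedule
#'
#' Emulates an Ussing-chamber recording: a constant pre-stimulus level, one
#' exponential step per scheduled compound (configured amplitude, shared
#' time constant), linear baseline drift and Gaussian sampling noise.
#'
#' @param deltas Named numeric vector of true plateau changes (µA/cm²), one
#'   entry per scheduled compound (missing compounds default to 0).
#' @param schedule An [event_schedule()]; the time constant must be well
#'   inside every inter-event gap.
#' @param tau Exponential transition time constant (s).
#' @param drift Linear drift (µA/cm² per s).
#' @param noise_sd Gaussian noise SD (µA/cm²).
#' @param sampling_rate Samples per second (Hz).
#' @param baseline Pre-stimulus Isc level (µA/cm²).
#' @param tail Recording time after the last event (s).
#' @param genotype,treatment,culture_id,teer Metadata for the trace.
#' @param seed Integer seed.
#' @return List with `trace` (an [isc_trace()]), `schedule`, and `truth`
#'   (the configured per-compound deltas and drift).
#' @export
gen_ussing_trace <- function(deltas = c(forskolin = 3.45),
                             schedule = default_schedule(), tau = 10,
                             drift = 0, noise_sd = 0, sampling_rate = 2,
                             baseline = 5, tail = 120,
                             genotype = NA_character_,
                             treatment = NA_character_,
                             culture_id = NA_character_, teer = NA_real_,
                             seed = NULL) {
  stopifnot(inherits(schedule, "event_schedule"))
  check_number(tau, "tau", lower = 0, strict_lower = TRUE)
  stopifnot(noise_sd >= 0)
  ev <- schedule$events
  gaps <- c(diff(ev$time), tail)
  if (any(tau >= gaps)) {
    stop_("transition time constant (%g s) must be below every inter-event gap (min %g s)",
          tau, min(gaps))
  }
  full <- stats::setNames(rep(0, nrow(ev)), ev$compound)
  unknown <- setdiff(names(deltas), ev$compound)
  if (length(unknown)) {
    stop_("deltas name compounds absent from the schedule: %s",
          paste(unknown, collapse = ", "))
  }
  full[names(deltas)] <- deltas
  t_end <- ev$time[nrow(ev)] + tail
  times <- seq(0, t_end, by = 1 / sampling_rate)
  level <- rep(baseline, length(times))
  for (i in seq_len(nrow(ev))) {
    after <- times > ev$time[i]
    level[after] <- level[after] +
      full[i] * (1 - exp(-(times[after] - ev$time[i]) / tau))
  }
  with_seed(seed, {
    isc <- level + drift * times +
      stats::rnorm(length(times), 0, noise_sd)
    list(
      trace = isc_trace(times, isc, genotype = genotype,
                        treatment = treatment, culture_id = culture_id,
                        teer = teer),
      schedule = schedule,
      truth = list(deltas = full, tau = tau, drift = drift,
                   baseline = baseline, noise_sd = noise_sd, seed = seed)
    )
  })
}

#' Generate an oscillating pixel stack at a set beat frequency
#'
#' Sinusoidal intensity at the configured frequency with an independent
#' random phase per pixel (cilia in a field do not beat in phase), additive
#' Gaussian noise, and a configurable fraction of static background pixels.
#'
#' @param frequency Beat frequency in Hz, below Nyquist.
#' @param amplitude Oscillation amplitude (intensity units); 0 gives a
#'   static stack (exercises the no-oscillation error path downstream).
#' @param noise_sd Gaussian noise SD (intensity units).
#' @param frame_rate Acquisition rate (Hz).
#' @param duration Recording length (s).
#' @param dims Spatial dimensions `c(height, width)`.
#' @param background_fraction Fraction of pixels held static.
#' @param baseline_intensity Mean intensity level.
#' @param field_id,culture_id Labels.
#' @param seed Integer seed.
#' @return List with `stack` (a [pixel_stack()]) and `truth` (the
#'   configured frequency and the spectral bin width implied by the stack
#'   length after zero-padding).
#' @export
gen_cbf_stack <- function(frequency = 5.43, amplitude = 1, noise_sd = 0,
                          frame_rate = 100, duration = 10,
                          dims = c(12, 12), background_fraction = 0.2,
                          baseline_intensity = 100,
                          field_id = "field1", culture_id = "culture1",
                          seed = NULL) {
  check_number(frequency, "frequency", lower = 0, strict_lower = TRUE)
  if (frequency >= frame_rate / 2) {
    stop_("frequency %g Hz violates Nyquist for frame rate %g Hz",
          frequency, frame_rate)
  }
  stopifnot(amplitude >= 0, noise_sd >= 0)
  check_number(background_fraction, "background_fraction", lower = 0,
               upper = 1)
  n_t <- round(duration * frame_rate)
  if (n_t < 2L) stop_("duration x frame_rate must give >= 2 frames")
  n_px <- dims[1L] * dims[2L]
  with_seed(seed, {
    phases <- stats::runif(n_px, 0, 2 * pi)
    is_bg <- stats::runif(n_px) < background_fraction
    tt <- (seq_len(n_t) - 1L) / frame_rate
    px <- baseline_intensity +
      amplitude * sin(outer(2 * pi * frequency * tt, phases, `+`)) *
        rep(!is_bg, each = n_t)
    if (noise_sd > 0) px <- px + stats::rnorm(length(px), 0, noise_sd)
    frames <- array(px, dim = c(n_t, dims[1L], dims[2L]))
    list(
      stack = pixel_stack(frames, frame_rate, field_id = field_id,
                          culture_id = culture_id),
      truth = list(frequency = frequency,
                   bin_width = frame_rate / next_pow2(n_t),
                   n_background = sum(is_bg), seed = seed)
    )
  })
}

#' Generate blot lanes at known percent-of-wild-type levels
#'
#' Band C intensity is `level x loaded µg x exposure`; the loading-control
#' intensity is `loaded µg x exposure x (1 + noise)`. Because the control
#' scales with loading and shares the lane's exposure, the
#' loading-control-normalised percent-of-WT recovers the configured level
#' exactly in the noiseless case regardless of unequal loading or exposure.
#'
#' @param levels Named numeric vector of true percent-of-WT levels per lane;
#'   must include a lane at 100 (the WT reference, first lane at 100 is
#'   used).
#' @param loads_ug Protein loaded per lane (µg); recycled.
#' @param exposures Per-lane exposure factors; recycled.
#' @param control_noise_sd Relative SD of the loading-control signal.
#' @param band_scale,control_scale Arbitrary intensity scales.
#' @param seed Integer seed.
#' @return List with `lanes` (data frame: `lane_id`, `condition`,
#'   `band_c_intensity`, `calnexin_intensity`, `protein_ug`), `wt_lane`, and
#'   `truth` (the configured levels).
#' @export
gen_blot_lanes <- function(levels = c(WT = 100, Q1291H_F508del = 3.18),
                           loads_ug = c(20, 40), exposures = 1,
                           control_noise_sd = 0, band_scale = 50,
                           control_scale = 1000, seed = NULL) {
  if (any(levels < 0)) stop_("levels must be >= 0")
  wt_idx <- which(levels == 100)[1L]
  if (is.na(wt_idx)) stop_("`levels` must include a WT lane at 100")
  n <- length(levels)
  loads_ug <- rep_len(loads_ug, n)
  exposures <- rep_len(exposures, n)
  stopifnot(control_noise_sd >= 0)
  with_seed(seed, {
    noise <- 1 + stats::rnorm(n, 0, control_noise_sd)
    if (any(noise <= 0)) {
      stop_("control noise produced a non-positive control signal; lower control_noise_sd")
    }
    lanes <- data.frame(
      lane_id = names(levels),
      condition = names(levels),
      band_c_intensity = levels / 100 * loads_ug * exposures * band_scale,
      calnexin_intensity = loads_ug * exposures * control_scale * noise,
      protein_ug = loads_ug,
      stringsAsFactors = FALSE
    )
    rownames(lanes) <- NULL
    list(lanes = lanes, wt_lane = names(levels)[wt_idx],
         truth = list(levels = levels, seed = seed))
  })
}
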