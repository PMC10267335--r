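#' A short-circuit current recording
#'
#' @param times Sampling times in seconds, strictly increasing.
#' @param isc Short-circuit current in µA/cm², same length as `times`.
#'   Positive Isc is lumen-negative anion secretory current; amiloride
#'   responses are expected negative and no sign flipping is performed.
#' @param genotype,treatment,culture_id Metadata labels (treatment e.g.
#'   `"DMSO"`, `"IVA"`, `"ELX/TEZ+DMSO"`, `"ELX/TEZ+IVA"`).
#' @param teer Transepithelial electrical resistance of the culture in
#'   Ω·cm² (optional, used by [teer_qc()]).
#' @return An object of class `"isc_trace"`.
#' @export
isc_trace <- function(times, isc, genotype = NA_character_,
                      treatment = NA_character_, culture_id = NA_character_,
                      teer = NA_real_) {
  if (length(times) != length(isc)) {
    stop_("`times` and `isc` must have equal length")
  }
  if (length(times) < 2L) stop_("a trace needs >= 2 samples")
  if (any(!is.finite(times)) || any(!is.finite(isc))) {
    stop_("times and currents must be finite")
  }
  if (any(diff(times) <= 0)) stop_("`times` must be strictly increasing")
  structure(
    list(times = as.numeric(times), isc = as.numeric(isc),
         genotype = genotype, treatment = treatment,
         culture_id = culture_id, teer = teer),
    class = "isc_trace"
  )
}

#' @export
print.isc_trace <- function(x, ...) {
  cat(sprintf(
    "<isc_trace> %d samples over %.0f s, %.2f to %.2f uA/cm2%s\n",
    length(x$isc), diff(range(x$times)), min(x$isc), max(x$isc),
    if (is.na(x$genotype)) "" else paste0(" [", x$genotype, ", ",
                                          x$treatment, "]")
  ))
  invisible(x)
}

#' An ordered compound-addition schedule
#'
#' @param events Data frame with columns `time` (s, strictly increasing),
#'   `compound`, `compartment` (`"apical"` or `"basal"`) and `concentration`
#'   (µM).
#' @return An object of class `"event_schedule"`.
#' @seealso [default_schedule()] for the standard potentiator-response
#'   protocol.
#' @export
event_schedule <- function(events) {
  need <- c("time", "compound", "compartment", "concentration")
  missing <- setdiff(need, names(events))
  if (length(missing)) {
    stop_("schedule lacks columns: %s", paste(missing, collapse = ", "))
  }
  if (nrow(events) < 1L) stop_("schedule must contain >= 1 event")
  if (any(diff(events$time) <= 0)) {
    stop_("event times must be strictly increasing")
  }
  bad <- setdiff(unique(events$compartment), c("apical", "basal"))
  if (length(bad)) stop_("unknown compartment: %s", paste(bad, collapse = ", "))
  structure(list(events = as.data.frame(events)), class = "event_schedule")
}

#' The standard Ussing-chamber compound sequence
#'
#' Sequential additions used to dissect the short-circuit current: amiloride
#' (100 µM apical) to block ENaC; acute potentiator — ivacaftor (10 µM
#' apical) or DMSO vehicle; forskolin (10 µM basal) to raise cAMP and
#' activate CFTR; CFTRinh-172 (30 µM apical) to confirm the CFTR-specific
#' component; ATP (100 µM apical) to elicit calcium-activated chloride
#' currents.
#'
#' @param start Time of the first addition (s).
#' @param spacing Interval between additions (s).
#' @param potentiator `"IVA"` or `"DMSO"` for the acute-addition step.
#' @return An [event_schedule()].
#' @export
default_schedule <- function(start = 300, spacing = 120,
                             potentiator = c("DMSO", "IVA")) {
  potentiator <- match.arg(potentiator)
  event_schedule(data.frame(
    time = start + spacing * (0:4),
    compound = c("amiloride", potentiator, "forskolin", "CFTRinh-172", "ATP"),
    compartment = c("apical", "apical", "basal", "apical", "apical"),
    concentration = c(100, if (potentiator == "DMSO") 0.01 else 10,
                      10, 30, 100),
    stringsAsFactors = FALSE
  ))
}

#' Segment a current trace by its compound-addition schedule
#'
#' For each event, the pre-addition plateau is the median Isc over
#' `plateau_window` seconds immediately before the addition, and the
#' post-response plateau is the median over the window immediately before
#' the *next* addition (or the trace end for the last event), by which time
#' the response has had the full inter-event interval to settle. The
#' response is `delta_isc = post_plateau - pre_plateau` (signed).
#'
#' @param trace An [isc_trace()].
#' @param schedule An [event_schedule()]; every event must fall within the
#'   trace and `plateau_window` must fit inside every inter-event gap (and
#'   before the first event).
#' @param plateau_window Width of the trailing median window in seconds.
#' @param detrend `"none"` (default: plateaus are read off the raw trace) or
#'   `"linear"`: a linear baseline drift is estimated by least squares on
#'   the pre-stimulus stabilisation period (all samples before the first
#'   event) and subtracted before plateau extraction. Useful when a slow
#'   additive drift would otherwise bias plateau differences across the
#'   long inter-event intervals.
#' @return Data frame of class `"segment_responses"`, one row per event:
#'   `compound`, `time`, `pre_plateau`, `post_plateau`, `delta_isc`.
#' @export
segment_trace <- function(trace, schedule, plateau_window = 30,
                          detrend = c("none", "linear")) {
  stopifnot(inherits(trace, "isc_trace"), inherits(schedule, "event_schedule"))
  detrend <- match.arg(detrend)
  check_number(plateau_window, "plateau_window", lower = 0,
               strict_lower = TRUE)
  ev <- schedule$events
  t0 <- trace$times[1L]
  t1 <- trace$times[length(trace$times)]
  outside <- which(ev$time <= t0 | ev$time > t1)
  if (length(outside)) {
    stop_("event '%s' at %g s lies outside the trace span [%g, %g] s",
          ev$compound[outside[1L]], ev$time[outside[1L]], t0, t1)
  }
  gaps <- diff(c(t0, ev$time))
  tight <- which(gaps < plateau_window)
  if (length(tight)) {
    stop_("plateau window (%g s) exceeds the gap before event '%s' (%g s)",
          plateau_window, ev$compound[tight[1L]], gaps[tight[1L]])
  }
  isc <- trace$isc
  if (detrend == "linear") {
    pre <- trace$times < ev$time[1L]
    if (sum(pre) < 2L) {
      stop_("too few pre-stimulus samples to estimate a linear baseline")
    }
    fit <- stats::lm.fit(cbind(1, trace$times[pre]), isc[pre])
    isc <- isc - fit$coefficients[2L] * (trace$times - trace$times[1L])
  }
  window_median <- function(t_end) {
    sel <- trace$times > (t_end - plateau_window) & trace$times <= t_end
    if (!any(sel)) stop_("no samples in the plateau window ending at %g s",
                         t_end)
    stats::median(isc[sel])
  }
  ends <- c(ev$time[-1L], t1)
  out <- data.frame(
    compound = ev$compound,
    time = ev$time,
    pre_plateau = vapply(ev$time, window_median, numeric(1)),
    post_plateau = vapply(ends, window_median, numeric(1)),
    stringsAsFactors = FALSE
  )
  out$delta_isc <- out$post_plateau - out$pre_plateau
  class(out) <- c("segment_responses", "data.frame")
  out
}

response_for <- function(responses, compound) {
  i <- which(responses$compound == compound)
  if (length(i) == 0L) return(NULL)
  responses$delta_isc[i[1L]]
}

#' Baseline, total and relative CFTR-activated current for a condition
#'
#' Total CFTR-activated current is the cumulative change in Isc attributable
#' to CFTR: the forskolin response plus the acute-potentiator (ivacaftor)
#' response when ivacaftor was added. For the vehicle condition (DMSO in
#' place of ivacaftor, no corrector pre-treatment) the total is the forskolin
#' response alone, which defines baseline activity (ΔIsc-Fsk). Fold change
#' and the above-baseline increment compare a condition's total against that
#' baseline.
#'
#' @param responses A `segment_responses` data frame from [segment_trace()],
#'   or any data frame with `compound` and `delta_isc` columns. Must contain
#'   a `forskolin` row; the potentiator row (`IVA` or `DMSO`) is used when
#'   present.
#' @param condition Treatment label carried onto the summary (e.g. `"DMSO"`,
#'   `"IVA"`, `"ELX/TEZ+DMSO"`, `"ELX/TEZ+IVA"`).
#' @param baseline_fsk Baseline ΔIsc-Fsk for this genotype (µA/cm², > 0),
#'   i.e. the vehicle condition's forskolin response.
#' @return An object of class `"cftr_activity"`: list with `condition`,
#'   `baseline_fsk`, `total_current`, `fold_change`, `above_baseline`,
#'   `inh172_response` (NA when the inhibitor row is absent).
#' @export
cftr_activity <- function(responses, condition, baseline_fsk) {
  need <- c("compound", "delta_isc")
  if (!all(need %in% names(responses))) {
    stop_("`responses` needs columns `compound` and `delta_isc`")
  }
  check_number(baseline_fsk, "baseline_fsk", lower = 0, strict_lower = TRUE)
  d_fsk <- response_for(responses, "forskolin")
  if (is.null(d_fsk)) stop_("no forskolin response in `responses`")
  d_iva <- response_for(responses, "IVA")
  total <- if (is.null(d_iva)) d_fsk else d_fsk + d_iva
  d_inh <- response_for(responses, "CFTRinh-172")
  structure(
    list(
      condition = condition,
      baseline_fsk = baseline_fsk,
      total_current = total,
      fold_change = fold_change(total, baseline_fsk),
      above_baseline = total - baseline_fsk,
      inh172_response = if (is.null(d_inh)) NA_real_ else d_inh
    ),
    class = "cftr_activity"
  )
}

#' @export
print.cftr_activity <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<cftr_activity> condition '%s'\n",
      "  total CFTR-activated current: %.2f uA/cm2\n",
      "  baseline dIsc-Fsk: %.2f uA/cm2\n",
      "  fold change: %.2f; above baseline: %.2f uA/cm2\n"
    ),
    x$condition, x$total_current, x$baseline_fsk,
    x$fold_change, x$above_baseline
  ))
  invisible(x)
}

#' Fold change of total CFTR-activated current over baseline
#'
#' @param total Total CFTR-activated current (µA/cm²).
#' @param baseline Baseline ΔIsc-Fsk (µA/cm², > 0).
#' @return `total / baseline` at full precision (round to 2 decimals for
#'   reporting).
#' @export
#' @examples
#' fold_change(5.73, 3.45) # ~1.66
fold_change <- function(total, baseline) {
  check_number(total, "total")
  check_number(baseline, "baseline", lower = 0, strict_lower = TRUE)
  total / baseline
}

#' Epithelial maturity check on TEER
#'
#' A differentiated culture is considered mature when its transepithelial
#' electrical resistance falls within the range reported for airway cell
#' models at air-liquid interface, 188–1250 Ω·cm² by default (bounds
#' inclusive).
#'
#' @param teer TEER in Ω·cm², > 0.
#' @param range_low,range_high Acceptance bounds in Ω·cm².
#' @return `TRUE` (mature) or `FALSE`.
#' @export
#' @examples
#' teer_qc(242.3) # TRUE
teer_qc <- function(teer, range_low = 188, range_high = 1250) {
  check_number(teer, "teer", lower = 0, strict_lower = TRUE)
  check_number(range_low, "range_low", lower = 0, strict_lower = TRUE)
  check_number(range_high, "range_high", lower = range_low)
  teer >= range_low && teer <= range_high
}

#' Read an Isc trace from CSV (+ optional metadata sidecar)
#'
#' @param path CSV with columns `time_s`, `isc_uA_per_cm2`.
#' @param metadata Optional path to a YAML/JSON sidecar with fields
#'   `genotype`, `treatment`, `culture_id`, `teer`.
#' @return An [isc_trace()].
#' @export
read_isc_csv <- function(path, metadata = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "isc_uA_per_cm2")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_("trace CSV lacks columns: %s", paste(missing, collapse = ", "))
  }
  meta <- list()
  if (!is.null(metadata)) {
    meta <- if (grepl("\\.json$", metadata, ignore.case = TRUE)) {
      jsonlite::read_json(metadata, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(metadata)
    }
  }
  isc_trace(
    df$time_s, df$isc_uA_per_cm2,
    genotype = meta$genotype %||% NA_character_,
    treatment = meta$treatment %||% NA_character_,
    culture_id = meta$culture_id %||% NA_character_,
    teer = meta$teer %||% NA_real_
  )
}

#' Read a compound schedule from YAML or JSON
#'
#' The file holds a list of events, each with `time`, `compound`,
#' `compartment`, `concentration`.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON file.
#' @return An [event_schedule()].
#' @export
read_schedule <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.data.frame(raw)) return(event_schedule(raw))
  if (!is.null(raw$events)) raw <- raw$events
  df <- do.call(rbind, lapply(raw, function(e) {
    data.frame(time = e$time, compound = e$compound,
               compartment = e$compartment,
               concentration = e$concentration, stringsAsFactors = FALSE)
  }))
  event_schedule(df)
}

#' Write an Isc trace to CSV (+ optional metadata sidecar)
#'
#' Inverse of [read_isc_csv()].
#'
#' @param trace An [isc_trace()].
#' @param path Output CSV path.
#' @param metadata_path Optional YAML sidecar path for the trace metadata.
#' @return `path`, invisibly.
#' @export
write_isc_csv <- function(trace, path, metadata_path = NULL) {
  stopifnot(inherits(trace, "isc_trace"))
  utils::write.csv(
    data.frame(time_s = trace$times, isc_uA_per_cm2 = trace$isc),
    path, row.names = FALSE
  )
  if (!is.null(metadata_path)) {
    yaml::write_yaml(
      list(genotype = trace$genotype, treatment = trace$treatment,
           culture_id = trace$culture_id, teer = trace$teer),
      metadata_path
    )
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
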