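#' A qPCR CT record for one sample and one target
#'
#' Holds the technical-replicate CT values measured for one primer target in
#' one sample. Non-detects may be recorded as `NA`: they are dropped from the
#' replicate mean, and a target with no detected replicate at all is an error
#' rather than an imputed cycle number.
#'
#' @param sample_id Sample label.
#' @param target Target label, conventionally one of `"allele_a"` (the
#'   non-F508del primer), `"allele_b"` (the F508del primer) or `"reference"`
#'   (the reference gene, e.g. ACTB).
#' @param ct_values Numeric CT values (technical replicates); `NA` =
#'   non-detect.
#' @return An object of class `"ct_record"`.
#' @export
ct_record <- function(sample_id, target, ct_values) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  stopifnot(is.character(target), length(target) == 1L)
  if (length(ct_values) < 1L) stop_("need >= 1 CT value")
  detected <- ct_values[!is.na(ct_values)]
  if (length(detected) == 0L) {
    stop_("all replicates non-detect for sample '%s', target '%s'",
          sample_id, target)
  }
  if (any(!is.finite(detected)) || any(detected <= 0)) {
    stop_("CT values must be finite and > 0")
  }
  structure(
    list(sample_id = sample_id, target = target,
         ct_values = as.numeric(ct_values)),
    class = "ct_record"
  )
}

mean_ct <- function(record) mean(record$ct_values, na.rm = TRUE)

#' Reference-gene-normalised CT (delta CT)
#'
#' @param record [ct_record()] for the target of interest.
#' @param reference [ct_record()] for the reference gene in the same sample.
#' @return `mean(CT_target) - mean(CT_reference)`.
#' @export
#' @examples
#' a <- ct_record("s1", "allele_a", c(25, 25, 25))
#' r <- ct_record("s1", "reference", c(20, 20, 20))
#' delta_ct(a, r) # 5
delta_ct <- function(record, reference) {
  stopifnot(inherits(record, "ct_record"), inherits(reference, "ct_record"))
  if (!identical(record$sample_id, reference$sample_id)) {
    stop_("target sample '%s' and reference sample '%s' differ",
          record$sample_id, reference$sample_id)
  }
  mean_ct(record) - mean_ct(reference)
}

#' Fold change by the delta-delta-CT method
#'
#' Normalises a sample's delta-CT to the mean delta-CT of the calibrator
#' samples and converts the cycle difference to a fold change,
#' `FC = efficiency^(-ddCT)` with the conventional efficiency of 2 (perfect
#' doubling per cycle).
#'
#' @param delta_ct_sample Sample delta-CT.
#' @param calibrator_delta_cts Delta-CTs of the calibrator samples (>= 1).
#' @param efficiency Amplification efficiency per cycle, default 2.
#' @return Fold change (dimensionless, >= 0).
#' @export
#' @examples
#' fold_change_ddct(4, c(6, 6, 6)) # 2^2 = 4
fold_change_ddct <- function(delta_ct_sample, calibrator_delta_cts,
                             efficiency = 2) {
  check_number(delta_ct_sample, "delta_ct_sample")
  if (length(calibrator_delta_cts) < 1L) stop_("no calibrator delta-CTs")
  if (any(!is.finite(calibrator_delta_cts))) {
    stop_("calibrator delta-CTs must be finite")
  }
  check_number(efficiency, "efficiency", lower = 1)
  ddct <- delta_ct_sample - mean(calibrator_delta_cts)
  efficiency^(-ddct)
}

#' Per-allele percentage of total transcript
#'
#' @param fc_a,fc_b Fold changes for the two allele-specific targets; both
#'   >= 0 and not both zero.
#' @return Named numeric vector `c(pct_a, pct_b)` summing to 100.
#' @export
#' @examples
#' allele_percentages(1, 1) # 50 / 50
allele_percentages <- function(fc_a, fc_b) {
  check_number(fc_a, "fc_a", lower = 0)
  check_number(fc_b, "fc_b", lower = 0)
  total <- fc_a + fc_b
  if (total == 0) stop_("both fold changes are zero")
  c(pct_a = 100 * fc_a / total, pct_b = 100 * fc_b / total)
}

#' Percent of splicing-defective-allele transcript inferred degraded
#'
#' Under the assumption that both alleles are transcribed 50:50, any deficit
#' of the splicing-defective allele's steady-state transcript relative to the
#' intact allele is attributed to missplicing followed by degradation:
#' `% degradation = (Y - X) / Y * 100`, with `X` the observed percent of
#' total transcript from the splicing-defective allele and `Y` the percent
#' from the intact allele.
#'
#' A negative result (X > Y) signals a violated 50:50 transcription
#' assumption; it is returned as-is with attribute `flag = "negative"` and a
#' warning, never clamped.
#'
#' @param x_pct Percent of total transcript from the splicing-defective
#'   allele, in \[0, 100\].
#' @param y_pct Percent from the intact allele, in (0, 100\].
#' @return Percent degraded (may be negative, see above).
#' @export
#' @examples
#' percent_degradation(32.91, 67.09) # ~50.95
percent_degradation <- function(x_pct, y_pct) {
  check_number(x_pct, "x_pct", lower = 0, upper = 100)
  check_number(y_pct, "y_pct", lower = 0, upper = 100, strict_lower = TRUE)
  out <- 100 * (y_pct - x_pct) / y_pct
  if (out < 0) {
    warning("x_pct exceeds y_pct: no degradation inferred; ",
            "50:50 transcription assumption may not hold", call. = FALSE)
    attr(out, "flag") <- "negative"
  }
  out
}

#' Allele-specific transcript quantification from a CT table
#'
#' Runs the full delta-delta-CT pipeline on a long-format CT table: replicate
#' CTs are averaged per (sample, target), normalised to the reference gene,
#' calibrated against the named calibrator samples per target, converted to
#' fold changes, expressed as per-allele percentages of total, and the
#' degradation of the `allele_a` transcript estimated from the percentage
#' asymmetry.
#'
#' @param ct_table Data frame with columns `sample_id`, `target`, `ct`
#'   (optionally `replicate`); `target` values must include `allele_a`,
#'   `allele_b` and `reference` for every sample.
#' @param calibrators Character vector of calibrator `sample_id`s (e.g. the
#'   homozygous-intact-allele samples); must be present in the table.
#' @param efficiency Amplification efficiency, default 2.
#' @return Data frame with one row per non-calibrator sample: `sample_id`,
#'   `fc_allele_a`, `fc_allele_b`, `pct_allele_a`, `pct_allele_b`,
#'   `pct_degradation`, `degradation_flag`.
#' @export
allele_quant <- function(ct_table, calibrators, efficiency = 2) {
  need <- c("sample_id", "target", "ct")
  missing <- setdiff(need, names(ct_table))
  if (length(missing)) {
    stop_("CT table lacks columns: %s", paste(missing, collapse = ", "))
  }
  samples <- unique(ct_table$sample_id)
  absent <- setdiff(calibrators, samples)
  if (length(absent)) {
    stop_("calibrator samples not in table: %s", paste(absent, collapse = ", "))
  }
  rec <- function(sample, target) {
    ct <- ct_table$ct[ct_table$sample_id == sample & ct_table$target == target]
    if (length(ct) == 0L) {
      stop_("sample '%s' has no rows for target '%s'", sample, target)
    }
    ct_record(sample, target, ct)
  }
  dct <- function(sample, target) {
    delta_ct(rec(sample, target), rec(sample, "reference"))
  }
  cal_dct <- function(target) vapply(calibrators, dct, numeric(1), target)

  test_samples <- setdiff(samples, calibrators)
  if (length(test_samples) == 0L) {
    stop_("all samples are calibrators; nothing to quantify")
  }
  rows <- lapply(test_samples, function(s) {
    fc_a <- fold_change_ddct(dct(s, "allele_a"), cal_dct("allele_a"),
                             efficiency)
    fc_b <- fold_change_ddct(dct(s, "allele_b"), cal_dct("allele_b"),
                             efficiency)
    pct <- allele_percentages(fc_a, fc_b)
    deg <- suppressWarnings(percent_degradation(pct[["pct_a"]],
                                                pct[["pct_b"]]))
    data.frame(
      sample_id = s,
      fc_allele_a = fc_a, fc_allele_b = fc_b,
      pct_allele_a = pct[["pct_a"]], pct_allele_b = pct[["pct_b"]],
      pct_degradation = as.numeric(deg),
      degradation_flag = identical(attr(deg, "flag"), "negative"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
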