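#' Mean and standard error of the mean
#'
#' The aggregation convention used for every reported summary: arithmetic
#' mean with SEM = sample SD / sqrt(n); with a single value the SEM is `NA`
#' (flagged as unavailable, never reported as 0).
#'
#' @param values Numeric vector (>= 1 finite value).
#' @return List with `mean`, `sem`, `n`.
#' @export
#' @examples
#' aggregate_mean_sem(c(5.2, 5.4, 5.7)) # mean 5.43, sem ~0.145
aggregate_mean_sem <- function(values) {
  if (length(values) < 1L) stop_("no values to aggregate")
  mean_sem(values)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_("stage '%s': %s", name, conditionMessage(e))
  })
}

read_study_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_("config file not found: %s", config)
    cfg <- yaml::read_yaml(config)
    cfg$`.dir` <- dirname(normalizePath(config))
    cfg
  } else if (is.list(config)) {
    config$`.dir` <- config$`.dir` %||% getwd()
    config
  } else {
    stop_("`config` must be a file path or a list")
  }
}

resolve_path <- function(path, dir) {
  if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(dir, path)
}

#' Worked-example Ussing arithmetic from a table of printed summaries
#'
#' Given per-condition total CFTR-activated currents together with either
#' the baseline ΔIsc-Fsk or the above-baseline increment (the baseline is
#' recovered as `total - increment` when not given directly), computes the
#' fold change and above-baseline increment for every row, reported to two
#' decimals.
#'
#' @param table Data frame with columns `genotype`, `condition`,
#'   `total_uA_cm2`, and at least one of `baseline_uA_cm2`,
#'   `increment_uA_cm2` per row.
#' @return The table with `baseline_uA_cm2` filled in and `fold_change`,
#'   `above_baseline` columns appended (2-decimal rounding).
#' @export
worked_example_activity <- function(table) {
  need <- c("genotype", "condition", "total_uA_cm2")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop_("worked-example table lacks columns: %s",
          paste(missing, collapse = ", "))
  }
  if (is.null(table$baseline_uA_cm2)) table$baseline_uA_cm2 <- NA_real_
  if (is.null(table$increment_uA_cm2)) table$increment_uA_cm2 <- NA_real_
  derive <- is.na(table$baseline_uA_cm2)
  table$baseline_uA_cm2[derive] <-
    table$total_uA_cm2[derive] - table$increment_uA_cm2[derive]
  if (any(is.na(table$baseline_uA_cm2))) {
    stop_("row %d has neither baseline nor increment",
          which(is.na(table$baseline_uA_cm2))[1L])
  }
  table$fold_change <- round(
    mapply(fold_change, table$total_uA_cm2, table$baseline_uA_cm2), 2
  )
  table$above_baseline <- round(
    table$total_uA_cm2 - table$baseline_uA_cm2, 2
  )
  table
}

pipeline_trajectory <- function(cfgs, seed) {
  rows <- lapply(seq_along(cfgs), function(i) {
    cfg <- cfgs[[i]]
    reps <- cfg$replicates %||% 3
    series <- lapply(seq_len(reps), function(r) {
      gen_distance_series(
        n_frames = cfg$n_frames %||% 2000,
        occupancy = cfg$occupancy %||% 1,
        mean_contact = cfg$mean_contact %||% 3.9,
        sd_contact = cfg$sd_contact %||% 0.2,
        mean_open = cfg$mean_open %||% 10.7,
        sd_open = cfg$sd_open %||% 0.9,
        metric = cfg$metric %||% paste0("metric", i),
        replicate_id = paste0("rep", r),
        seed = seed + 101 * i + r
      )$series
    })
    s <- summarize_distances(series, threshold = cfg$threshold %||% 5)
    data.frame(
      metric = s$metric, threshold_angstrom = s$threshold,
      pooled_occupancy_pct = round(100 * s$pooled_fraction, 1),
      mean_distance_angstrom = round(s$mean_distance, 2),
      sd_distance_angstrom = round(s$sd_distance, 2),
      n_frames = s$n_frames_total,
      configured_occupancy_pct = 100 * (cfg$occupancy %||% 1),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

pipeline_ussing <- function(cfg, seed) {
  conditions <- cfg$conditions
  if (is.null(conditions)) stop_("ussing config needs a `conditions` list")
  plateau_window <- cfg$plateau_window %||% 30
  runs <- lapply(seq_along(conditions), function(i) {
    cc <- conditions[[i]]
    pot <- cc$potentiator %||% "DMSO"
    sched <- default_schedule(potentiator = pot)
    gen <- gen_ussing_trace(
      deltas = unlist(cc$deltas),
      schedule = sched,
      tau = cfg$tau %||% 10,
      drift = cfg$drift %||% 0,
      noise_sd = cfg$noise_sd %||% 0,
      baseline = cfg$baseline_level %||% 5,
      teer = cfg$teer %||% NA_real_,
      treatment = cc$condition,
      seed = seed + 211 * i
    )
    responses <- segment_trace(gen$trace, gen$schedule, plateau_window)
    list(condition = cc$condition, responses = responses,
         teer = cfg$teer %||% NA_real_)
  })
  base_cond <- cfg$baseline_condition %||% runs[[1L]]$condition
  base_run <- Filter(function(r) identical(r$condition, base_cond), runs)
  if (length(base_run) == 0L) {
    stop_("baseline condition '%s' not among the conditions", base_cond)
  }
  baseline_fsk <- response_for(base_run[[1L]]$responses, "forskolin")
  teer_range <- unlist(cfg$teer_range %||% c(188, 1250))
  rows <- lapply(runs, function(r) {
    act <- cftr_activity(r$responses, r$condition, baseline_fsk)
    data.frame(
      condition = act$condition,
      baseline_fsk_uA_cm2 = round(act$baseline_fsk, 2),
      total_uA_cm2 = round(act$total_current, 2),
      fold_change = round(act$fold_change, 2),
      above_baseline_uA_cm2 = round(act$above_baseline, 2),
      inh172_uA_cm2 = round(act$inh172_response, 2),
      teer_ohm_cm2 = r$teer,
      teer_mature = if (is.na(r$teer)) NA else {
        teer_qc(r$teer, teer_range[1L], teer_range[2L])
      },
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

pipeline_cbf <- function(cfg, seed) {
  n_cult <- cfg$cultures %||% 3
  n_fields <- cfg$fields_per_culture %||% 6
  band <- unlist(cfg$band %||% c(0.5, 30))
  results <- list()
  for (ci in seq_len(n_cult)) {
    for (fi in seq_len(n_fields)) {
      gen <- gen_cbf_stack(
        frequency = cfg$frequency %||% 5.43,
        amplitude = cfg$amplitude %||% 1,
        noise_sd = cfg$noise_sd %||% 0,
        frame_rate = cfg$frame_rate %||% 100,
        duration = cfg$duration %||% 4,
        dims = unlist(cfg$dims %||% c(8, 8)),
        field_id = paste0("field", fi),
        culture_id = paste0("culture", ci),
        seed = seed + 307 * ci + fi
      )
      results[[length(results) + 1L]] <- field_spectrum(gen$stack, band)
    }
  }
  aggregate_cbf(results,
                physiological_range = unlist(cfg$physiological_range %||%
                                               c(3.0, 11.1)))
}

#' Run the full theratyping pipeline from a study config
#'
#' Orchestrates every stage named in a YAML (or list) study config —
#' worked-example Ussing arithmetic from a table of printed summaries,
#' trajectory contact statistics, allele quantification, synthetic Ussing
#' recordings, ciliary beat frequency, and blot densitometry — writing one
#' CSV per stage plus a combined `report.json` with input provenance to
#' `out_dir`. All randomness derives from the config's `seed`, so re-running
#' an identical config gives byte-identical outputs. Any stage failure
#' aborts with a stage-labelled error.
#'
#' @param config Path to a YAML study config or an equivalent named list.
#'   Relative input paths resolve against the config file's directory. See
#'   the packaged demo: `system.file("extdata/demo/study.yaml", package =
#'   "theratype")`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the report list written to `report.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_study_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed %||% 1
  check_number(seed, "seed")
  report <- list(
    provenance = list(
      package = "theratype",
      version = as.character(utils::packageVersion("theratype")),
      seed = seed
    )
  )
  out <- function(name) file.path(out_dir, name)

  if (!is.null(cfg$worked_example)) {
    report$worked_example <- stage("worked_example", {
      path <- resolve_path(cfg$worked_example, cfg$`.dir`)
      if (!file.exists(path)) stop_("input file not found: %s", path)
      tab <- worked_example_activity(utils::read.csv(path,
                                                     stringsAsFactors = FALSE))
      utils::write.csv(tab, out("worked_example.csv"), row.names = FALSE)
      tab
    })
  }
  if (!is.null(cfg$trajectory)) {
    report$trajectory <- stage("trajectory", {
      tab <- pipeline_trajectory(cfg$trajectory, seed)
      utils::write.csv(tab, out("trajectory_contacts.csv"),
                       row.names = FALSE)
      tab
    })
  }
  if (!is.null(cfg$qpcr)) {
    report$allele_quant <- stage("qpcr", {
      q <- cfg$qpcr
      gen <- gen_ct_table(
        allele_fractions = unlist(q$allele_fractions %||% c(0.5, 0.5)),
        degradation = q$degradation %||% 0,
        ct_noise_sd = q$ct_noise_sd %||% 0.1,
        seed = seed + 401
      )
      res <- allele_quant(gen$ct_table, gen$calibrators)
      res$pct_degradation <- round(res$pct_degradation, 2)
      res$pct_allele_a <- round(res$pct_allele_a, 2)
      res$pct_allele_b <- round(res$pct_allele_b, 2)
      res$fc_allele_a <- round(res$fc_allele_a, 4)
      res$fc_allele_b <- round(res$fc_allele_b, 4)
      utils::write.csv(res, out("allele_quant.csv"), row.names = FALSE)
      res
    })
  }
  if (!is.null(cfg$ussing)) {
    report$ussing <- stage("ussing", {
      tab <- pipeline_ussing(cfg$ussing, seed)
      utils::write.csv(tab, out("ussing_summary.csv"), row.names = FALSE)
      tab
    })
  }
  if (!is.null(cfg$cbf)) {
    report$cbf <- stage("cbf", {
      agg <- pipeline_cbf(cfg$cbf, seed)
      utils::write.csv(agg$per_culture, out("cbf_per_culture.csv"),
                       row.names = FALSE)
      list(mean_hz = round(agg$mean, 2),
           sem_hz = if (is.na(agg$sem)) NA else round(agg$sem, 3),
           n_cultures = agg$n_cultures,
           per_culture = agg$per_culture)
    })
  }
  if (!is.null(cfg$blot)) {
    report$blot <- stage("blot", {
      b <- cfg$blot
      gen <- gen_blot_lanes(
        levels = unlist(b$levels %||% c(WT = 100)),
        loads_ug = unlist(b$loads_ug %||% 20),
        exposures = unlist(b$exposures %||% 1),
        control_noise_sd = b$control_noise_sd %||% 0,
        seed = seed + 503
      )
      tab <- blot_percent_of_wt(gen$lanes, gen$wt_lane)
      tab$percent_of_wt <- round(tab$percent_of_wt, 2)
      utils::write.csv(tab, out("blot_summary.csv"), row.names = FALSE)
      tab
    })
  }
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(report)
}
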