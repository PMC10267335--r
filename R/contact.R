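#' Define a residue-ligand contact metric
#'
#' A contact metric names a pair of atoms whose separation is tracked along a
#' trajectory, together with the distance threshold below which the pair is
#' considered "in contact". Two metrics are in routine use for assessing ATP
#' binding-site integrity in CFTR gating mutants: `lambda`, the distance from
#' the backbone amide nitrogen of residue 551 to the ATP gamma-phosphate
#' phosphorus (threshold 5 Å), and `sigma`, the distance from the alpha carbon
#' of residue 1291 to the bound Mg2+ ion (threshold 7 Å).
#'
#' @param name Short label for the metric (e.g. `"lambda"`, `"sigma"`).
#' @param atom_a,atom_b Atom selectors: named lists with elements `resno`
#'   (residue number) and `elety` (PDB atom name, e.g. `"N"`, `"CA"`, `"PG"`,
#'   `"MG"`), optionally `chain`. Each selector must resolve to exactly one
#'   atom per model.
#' @param threshold Contact threshold in Å; strictly positive. Frames with
#'   distance strictly below the threshold count as in contact (ties at the
#'   threshold do not).
#'
#' @return An object of class `"contact_metric"`.
#' @seealso [contact_metric_lambda()], [contact_metric_sigma()] for the two
#'   canonical metrics.
#' @export
#' @examples
#' m <- contact_metric("lambda",
#'   atom_a = list(resno = 551, elety = "N"),
#'   atom_b = list(resno = 900, elety = "PG"),
#'   threshold = 5
#' )
contact_metric <- function(name, atom_a, atom_b, threshold) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_number(threshold, "threshold", lower = 0, strict_lower = TRUE)
  for (sel in list(atom_a, atom_b)) {
    if (!is.list(sel) || is.null(sel$resno) || is.null(sel$elety)) {
      stop_("atom selectors must be lists with elements `resno` and `elety`")
    }
  }
  if (identical(atom_a[c("resno", "elety", "chain")],
                atom_b[c("resno", "elety", "chain")])) {
    stop_("`atom_a` and `atom_b` must select different atoms")
  }
  structure(
    list(name = name, atom_a = atom_a, atom_b = atom_b,
         threshold = threshold),
    class = "contact_metric"
  )
}

#' @describeIn contact_metric The lambda metric: residue 551 backbone amide N
#'   to the ATP gamma-phosphate P, 5 Å threshold. `atp_resno` locates the ATP
#'   residue in the model.
#' @param atp_resno,mg_resno Residue numbers of the ATP molecule and Mg2+ ion
#'   in the structure files at hand.
#' @export
contact_metric_lambda <- function(atp_resno = 1480) {
  contact_metric("lambda",
    atom_a = list(resno = 551, elety = "N"),
    atom_b = list(resno = atp_resno, elety = "PG"),
    threshold = 5
  )
}

#' @describeIn contact_metric The sigma metric: residue 1291 alpha carbon to
#'   the Mg2+ ion, 7 Å threshold.
#' @export
contact_metric_sigma <- function(mg_resno = 1482) {
  contact_metric("sigma",
    atom_a = list(resno = 1291, elety = "CA"),
    atom_b = list(resno = mg_resno, elety = "MG"),
    threshold = 7
  )
}

#' Construct a distance time series for one trajectory replicate
#'
#' @param times Simulation times in ns, strictly increasing, one per frame.
#'   When `NULL`, frames are numbered 0, 1, 2, ... ns.
#' @param distances Distances in Å, all non-negative, same length as `times`.
#' @param metric Metric label or a [contact_metric()] object.
#' @param replicate_id Replicate label.
#'
#' @return An object of class `"distance_series"`: a list with elements
#'   `times`, `distances`, `metric` (label), `threshold` (Å or `NA` if the
#'   metric was given as a bare label) and `replicate_id`.
#' @export
distance_series <- function(distances, times = NULL, metric = "metric",
                            replicate_id = "rep1") {
  if (length(distances) < 1L) stop_("a distance series needs >= 1 frame")
  if (!is.numeric(distances) || any(!is.finite(distances))) {
    stop_("`distances` must be finite numbers")
  }
  if (any(distances < 0)) stop_("distances must be >= 0 Angstrom")
  if (is.null(times)) times <- seq_along(distances) - 1
  if (length(times) != length(distances)) {
    stop_("`times` and `distances` must have equal length")
  }
  if (any(diff(times) <= 0)) stop_("`times` must be strictly increasing")
  threshold <- NA_real_
  if (inherits(metric, "contact_metric")) {
    threshold <- metric$threshold
    metric <- metric$name
  }
  structure(
    list(times = as.numeric(times), distances = as.numeric(distances),
         metric = metric, threshold = threshold,
         replicate_id = replicate_id),
    class = "distance_series"
  )
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf(
    "<distance_series> metric '%s', replicate '%s', %d frames, %.2f-%.2f A\n",
    x$metric, x$replicate_id, length(x$distances),
    min(x$distances), max(x$distances)
  ))
  invisible(x)
}

# Resolve a selector to a single atom index in a bio3d pdb object; errors
# name the selector so a missing atom is diagnosable per input file.
resolve_atom <- function(pdb, sel) {
  hits <- which(pdb$atom$resno == sel$resno & pdb$atom$elety == sel$elety)
  if (!is.null(sel$chain)) {
    hits <- hits[pdb$atom$chain[hits] %in% sel$chain]
  }
  label <- sprintf("resno %s / atom %s%s", sel$resno, sel$elety,
                   if (is.null(sel$chain)) "" else paste0(" / chain ", sel$chain))
  if (length(hits) == 0L) stop_("selector matched no atom: %s", label)
  if (length(hits) > 1L) {
    stop_("selector matched %d atoms (must be exactly 1): %s",
          length(hits), label)
  }
  hits
}

#' Distance time series from a multi-model structure file
#'
#' Reads a multi-model PDB (MODEL/ENDMDL records, e.g. a trajectory exported
#' frame-by-frame) and computes the Euclidean distance between the two atoms
#' of a contact metric in every model, in model order.
#'
#' @param models Path to a multi-model PDB file, or a `bio3d` `pdb` object
#'   read with `multi = TRUE`.
#' @param spec A [contact_metric()].
#' @param frame_times Optional simulation times (ns), one per model; defaults
#'   to 0, 1, 2, ... ns.
#' @param replicate_id Replicate label stored on the result.
#'
#' @return A [distance_series()].
#' @export
distance_series_from_models <- function(models, spec, frame_times = NULL,
                                        replicate_id = "rep1") {
  stopifnot(inherits(spec, "contact_metric"))
  pdb <- if (inherits(models, "pdb")) models else {
    bio3d::read.pdb(models, multi = TRUE, verbose = FALSE)
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_models <- nrow(xyz)
  if (!is.null(frame_times) && length(frame_times) != n_models) {
    stop_("%d frame times supplied for %d models",
          length(frame_times), n_models)
  }
  ia <- resolve_atom(pdb, spec$atom_a)
  ib <- resolve_atom(pdb, spec$atom_b)
  ca <- xyz[, (3 * ia - 2):(3 * ia), drop = FALSE]
  cb <- xyz[, (3 * ib - 2):(3 * ib), drop = FALSE]
  bad <- which(!stats::complete.cases(ca) | !stats::complete.cases(cb))
  if (length(bad)) {
    stop_("model %d is missing coordinates for a selected atom", bad[1L])
  }
  d <- sqrt(rowSums((ca - cb)^2))
  distance_series(d, times = frame_times, metric = spec,
                  replicate_id = replicate_id)
}

#' Fraction of frames in contact
#'
#' The occupancy of a contact: the fraction of frames whose distance lies
#' strictly below the threshold.
#'
#' @param series A [distance_series()].
#' @param threshold Contact threshold in Å; defaults to the threshold carried
#'   by the series' metric.
#' @return A fraction in \[0, 1\].
#' @export
#' @examples
#' s <- distance_series(c(4, 6, 4, 6))
#' contact_fraction(s, threshold = 5) # 0.5
contact_fraction <- function(series, threshold = NULL) {
  stopifnot(inherits(series, "distance_series"))
  if (is.null(threshold)) threshold <- series$threshold
  check_number(threshold, "threshold", lower = 0, strict_lower = TRUE)
  if (length(series$distances) == 0L) stop_("empty distance series")
  mean(series$distances < threshold)
}

check_same_metric <- function(series_list) {
  if (length(series_list) < 1L) stop_("need at least one distance series")
  ok <- vapply(series_list, inherits, logical(1), "distance_series")
  if (!all(ok)) stop_("all elements must be distance_series objects")
  metrics <- unique(vapply(series_list, `[[`, character(1), "metric"))
  if (length(metrics) > 1L) {
    stop_("replicates mix metrics: %s", paste(metrics, collapse = ", "))
  }
  metrics
}

#' Frame-weighted contact fraction over replicates
#'
#' Pools replicates by total frame count: the occupancy is the number of
#' in-contact frames across all replicates divided by the total number of
#' frames ("percent of the simulation data"), not the mean of per-replicate
#' fractions. Replicates of unequal length therefore contribute in proportion
#' to their length.
#'
#' @param series_list List of [distance_series()] of one metric.
#' @inheritParams contact_fraction
#' @return A fraction in \[0, 1\].
#' @export
pooled_contact_fraction <- function(series_list, threshold = NULL) {
  check_same_metric(series_list)
  if (is.null(threshold)) threshold <- series_list[[1L]]$threshold
  check_number(threshold, "threshold", lower = 0, strict_lower = TRUE)
  counts <- vapply(series_list, function(s) sum(s$distances < threshold),
                   numeric(1))
  n <- vapply(series_list, function(s) length(s$distances), numeric(1))
  sum(counts) / sum(n)
}

#' Summarise a contact metric over trajectory replicates
#'
#' Computes per-replicate and pooled (frame-weighted) contact fractions at
#' the metric threshold, plus the mean and sample SD of the distance over all
#' pooled frames. Per-replicate means are also reported, since mean-of-pooled
#' and mean-across-replicates conventions differ for unequal-length
#' replicates.
#'
#' @param series_list List of [distance_series()] of one metric (or a single
#'   series).
#' @param threshold Contact threshold in Å; defaults to the metric's.
#' @return An object of class `"contact_summary"`: list with `metric`,
#'   `threshold`, `per_replicate_fraction`, `pooled_fraction`,
#'   `mean_distance`, `sd_distance`, `per_replicate_mean`, `n_frames_total`.
#' @export
summarize_distances <- function(series_list, threshold = NULL) {
  if (inherits(series_list, "distance_series")) series_list <- list(series_list)
  metric <- check_same_metric(series_list)
  if (is.null(threshold)) threshold <- series_list[[1L]]$threshold
  check_number(threshold, "threshold", lower = 0, strict_lower = TRUE)
  pooled <- unlist(lapply(series_list, `[[`, "distances"))
  per_frac <- vapply(series_list, contact_fraction, numeric(1),
                     threshold = threshold)
  names(per_frac) <- vapply(series_list, `[[`, character(1), "replicate_id")
  per_mean <- vapply(series_list, function(s) mean(s$distances), numeric(1))
  names(per_mean) <- names(per_frac)
  structure(
    list(
      metric = metric,
      threshold = threshold,
      per_replicate_fraction = per_frac,
      pooled_fraction = pooled_contact_fraction(series_list, threshold),
      mean_distance = mean(pooled),
      sd_distance = if (length(pooled) > 1L) stats::sd(pooled) else 0,
      per_replicate_mean = per_mean,
      n_frames_total = length(pooled)
    ),
    class = "contact_summary"
  )
}

#' @export
print.contact_summary <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<contact_summary> metric '%s' (threshold %.1f A)\n",
      "  pooled occupancy: %.1f%% of %d frames\n",
      "  distance: %.2f +/- %.2f A (pooled mean +/- sample SD)\n",
      "  per-replicate occupancy: %s\n"
    ),
    x$metric, x$threshold, 100 * x$pooled_fraction, x$n_frames_total,
    x$mean_distance, x$sd_distance,
    paste(sprintf("%s=%.1f%%", names(x$per_replicate_fraction),
                  100 * x$per_replicate_fraction), collapse = ", ")
  ))
  invisible(x)
}

#' Read tabular distance series from CSV
#'
#' Expects columns `time_ns`, `distance_angstrom`, `replicate_id`, `metric`;
#' returns one [distance_series()] per (metric, replicate) pair.
#'
#' @param path CSV file path.
#' @return Named list of [distance_series()] (names `metric/replicate`).
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_ns", "distance_angstrom", "replicate_id", "metric")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_("distance CSV lacks columns: %s", paste(missing, collapse = ", "))
  }
  parts <- split(df, list(df$metric, df$replicate_id), drop = TRUE)
  out <- lapply(parts, function(p) {
    p <- p[order(p$time_ns), ]
    distance_series(p$distance_angstrom, times = p$time_ns,
                    metric = p$metric[1L], replicate_id = p$replicate_id[1L])
  })
  names(out) <- vapply(parts, function(p) {
    paste(p$metric[1L], p$replicate_id[1L], sep = "/")
  }, character(1))
  out
}

#' Write distance series to the tabular CSV format
#'
#' @param series_list A [distance_series()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(series_list, path) {
  if (inherits(series_list, "distance_series")) series_list <- list(series_list)
  df <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(
      time_ns = s$times, distance_angstrom = s$distances,
      replicate_id = s$replicate_id, metric = s$metric,
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
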