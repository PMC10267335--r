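#' A time-lapse pixel-intensity stack for one field of view
#'
#' @param frames 3-D numeric array, time x height x width (a matrix is
#'   accepted as time x pixels).
#' @param frame_rate Acquisition rate in Hz.
#' @param field_id,culture_id Labels.
#' @return An object of class `"pixel_stack"`.
#' @export
pixel_stack <- function(frames, frame_rate, field_id = "field1",
                        culture_id = "culture1") {
  if (is.matrix(frames)) dim(frames) <- c(nrow(frames), ncol(frames), 1L)
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop_("`frames` must be a time x height x width array")
  }
  if (dim(frames)[1L] < 2L) stop_("need >= 2 frames")
  if (any(!is.finite(frames))) stop_("frame intensities must be finite")
  check_number(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  structure(
    list(frames = frames, frame_rate = frame_rate,
         field_id = field_id, culture_id = culture_id),
    class = "pixel_stack"
  )
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
}

next_pow2 <- function(n) 2^ceiling(log2(n))

#' Ciliary beat frequency as the dominant power-spectrum peak
#'
#' Each pixel's intensity series is mean-detrended, Hann-windowed, zero-padded
#' to the next power of two and Fourier-transformed; the field spectrum is
#' the mean per-pixel power spectrum over pixels with non-negligible temporal
#' variance (static background pixels — variance below `1e-12` of the maximum
#' pixel variance — are excluded). The beat frequency is the frequency of the
#' highest peak within the search band. Detrending and per-pixel
#' transformation before averaging make the estimate insensitive to global
#' intensity offset or scaling and to phase differences between cilia.
#'
#' @param stack A [pixel_stack()].
#' @param band Search band `c(low, high)` in Hz; must lie within
#'   (0, Nyquist). The default 0.5–30 Hz is intentionally wider than the
#'   physiological plausibility range so that out-of-range beats are
#'   reported (and flagged downstream) rather than silently forced in-range.
#' @return An object of class `"spectrum_result"`: list with `frequencies`
#'   (Hz), `power`, `dominant_frequency` (Hz), `bin_width` (Hz), `band`,
#'   `field_id`, `culture_id`.
#' @export
field_spectrum <- function(stack, band = c(0.5, 30)) {
  stopifnot(inherits(stack, "pixel_stack"))
  if (length(band) != 2L || band[1L] <= 0 || band[2L] <= band[1L]) {
    stop_("`band` must be c(low, high) with 0 < low < high")
  }
  nyquist <- stack$frame_rate / 2
  if (band[2L] > nyquist) {
    stop_("band upper edge %g Hz exceeds the Nyquist frequency %g Hz",
          band[2L], nyquist)
  }
  d <- dim(stack$frames)
  n_t <- d[1L]
  px <- matrix(stack$frames, nrow = n_t)          # time x pixels
  px <- sweep(px, 2L, colMeans(px))               # mean detrend
  v <- colSums(px^2)
  vmax <- max(v)
  if (vmax == 0) {
    stop_("no oscillation: all pixel series are constant")
  }
  px <- px[, v > 1e-12 * vmax, drop = FALSE]
  nfft <- next_pow2(n_t)
  w <- hann_window(n_t)
  padded <- matrix(0, nrow = nfft, ncol = ncol(px))
  padded[seq_len(n_t), ] <- px * w
  spec <- Mod(stats::mvfft(padded))^2
  n_keep <- nfft %/% 2 + 1L
  power <- rowMeans(spec[seq_len(n_keep), , drop = FALSE])
  freqs <- (seq_len(n_keep) - 1L) * stack$frame_rate / nfft
  in_band <- freqs >= band[1L] & freqs <= band[2L]
  if (!any(in_band)) stop_("no spectral bins inside the band")
  if (max(power[in_band]) == 0) {
    stop_("no oscillation: zero power inside the band")
  }
  dominant <- freqs[in_band][which.max(power[in_band])]
  structure(
    list(
      frequencies = freqs, power = power,
      dominant_frequency = dominant,
      bin_width = stack$frame_rate / nfft,
      band = band,
      field_id = stack$field_id, culture_id = stack$culture_id
    ),
    class = "spectrum_result"
  )
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf(
    "<spectrum_result> field '%s' (culture '%s'): %.2f Hz dominant (bin %.3f Hz, band %g-%g Hz)\n",
    x$field_id, x$culture_id, x$dominant_frequency, x$bin_width,
    x$band[1L], x$band[2L]
  ))
  invisible(x)
}

#' Aggregate field-level beat frequencies to culture and participant level
#'
#' Field dominant frequencies are averaged per culture, then culture means
#' are combined as mean ± SEM (sample SD / sqrt(n); SEM is `NA` when only
#' one culture is available). Values outside the physiological range are
#' flagged, not removed.
#'
#' @param results List of [field_spectrum()] results, or a data frame with
#'   columns `culture_id` and `dominant_frequency`.
#' @param physiological_range Plausibility range `c(low, high)` in Hz used
#'   for the QC flag (default 3.0–11.1 Hz).
#' @return List with `per_culture` (data frame: `culture_id`, `mean_hz`,
#'   `n_fields`, `in_physiological_range`), `mean`, `sem`, `n_cultures`.
#' @export
aggregate_cbf <- function(results, physiological_range = c(3.0, 11.1)) {
  if (is.data.frame(results)) {
    df <- results
  } else {
    if (length(results) < 1L) stop_("no spectrum results to aggregate")
    df <- data.frame(
      culture_id = vapply(results, `[[`, character(1), "culture_id"),
      dominant_frequency = vapply(results, `[[`, numeric(1),
                                  "dominant_frequency"),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(df) < 1L) stop_("no spectrum results to aggregate")
  per_culture <- do.call(rbind, lapply(split(df, df$culture_id), function(p) {
    m <- mean(p$dominant_frequency)
    data.frame(
      culture_id = p$culture_id[1L], mean_hz = m, n_fields = nrow(p),
      in_physiological_range = m >= physiological_range[1L] &
        m <= physiological_range[2L],
      stringsAsFactors = FALSE
    )
  }))
  rownames(per_culture) <- NULL
  agg <- mean_sem(per_culture$mean_hz)
  list(per_culture = per_culture, mean = agg$mean, sem = agg$sem,
       n_cultures = agg$n)
}

#' Read a pixel stack from a multi-page TIFF or CSV matrix
#'
#' CSV input holds one row per frame (pixels flattened); `height`/`width`
#' restore the spatial dimensions (a single-column layout is assumed when
#' omitted). TIFF input requires the `tiff` package.
#'
#' @param path `.tif`/`.tiff` or `.csv` file.
#' @param frame_rate Acquisition rate in Hz.
#' @param height,width Spatial dimensions for CSV input.
#' @param field_id,culture_id Labels.
#' @return A [pixel_stack()].
#' @export
read_pixel_stack <- function(path, frame_rate, height = NULL, width = NULL,
                             field_id = "field1", culture_id = "culture1") {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop_("reading TIFF stacks requires the 'tiff' package")
    }
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    # keep the first channel of multi-channel pages
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p[, , 1L] else p
    })
    h <- nrow(pages[[1L]])
    w <- ncol(pages[[1L]])
    frames <- array(0, dim = c(length(pages), h, w))
    for (i in seq_along(pages)) frames[i, , ] <- pages[[i]]
  } else {
    m <- as.matrix(utils::read.csv(path, header = FALSE))
    storage.mode(m) <- "double"
    h <- height %||% ncol(m)
    w <- width %||% 1L
    if (h * w != ncol(m)) {
      stop_("height * width (%d) does not match %d pixels per frame",
            h * w, ncol(m))
    }
    frames <- array(m, dim = c(nrow(m), h, w))
  }
  pixel_stack(frames, frame_rate, field_id = field_id,
              culture_id = culture_id)
}

#' Write a pixel stack as a CSV matrix (one row per frame)
#'
#' Inverse of the CSV branch of [read_pixel_stack()]; spatial dimensions are
#' flattened, so pass the stack's height back to `read_pixel_stack()` to
#' restore them (the estimate itself is invariant to pixel order).
#'
#' @param stack A [pixel_stack()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pixel_csv <- function(stack, path) {
  stopifnot(inherits(stack, "pixel_stack"))
  m <- matrix(stack$frames, nrow = dim(stack$frames)[1L])
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
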