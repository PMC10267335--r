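# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_("`%s` must be a single finite number", name)
  }
  if (strict_lower && x <= lower) {
    stop_("`%s` must be > %g (got %g)", name, lower, x)
  }
  if (!strict_lower && x < lower) {
    stop_("`%s` must be >= %g (got %g)", name, lower, x)
  }
  if (x > upper) stop_("`%s` must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

# mean +/- SEM with the n = 1 convention used throughout the reports:
# SEM is NA (flagged, not zero) when only one value is available.
mean_sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop_("no finite values to aggregate")
  n <- length(x)
  list(
    mean = mean(x),
    sem = if (n > 1L) stats::sd(x) / sqrt(n) else NA_real_,
    n = n
  )
}
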