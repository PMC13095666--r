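# Internal helpers shared across modules.

#' @keywords internal
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Validate a probability-like scalar lies in an open or closed interval.
#' @keywords internal
.check_fraction <- function(x, name, lower = 0, upper = 1,
                            open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    .stopf("'%s' must be a single finite number", name)
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    .stopf("'%s' = %g is outside its valid range %s%g, %g%s", name, x,
           if (open_lower) "(" else "[", lower, upper,
           if (open_upper) ")" else "]")
  }
  invisible(x)
}

#' @keywords internal
.check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    .stopf("'%s' must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

# Sample variance with the n-1 denominator; NA-free input assumed.
#' @keywords internal
.sample_var <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  stats::var(x)
}

# Column-wise sample variance of a matrix without forming apply() overhead.
#' @keywords internal
.col_vars <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  (colSums(m * m) - n * mu * mu) / (n - 1)
}

# Derive independent substream seeds from one master seed so pipeline stages
# can be regenerated in isolation. Seeds stay below 2^31.
#' @keywords internal
.substream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' @keywords internal
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}
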