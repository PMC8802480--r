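## Internal helpers shared across modules.

#' @keywords internal
ventwave_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "ventwave_error")))
}

abort_format     <- function(msg) ventwave_error(msg, "ventwave_format_error")
abort_data       <- function(msg) ventwave_error(msg, "ventwave_data_error")
abort_argument   <- function(msg) ventwave_error(msg, "ventwave_argument_error")
abort_capability <- function(msg) ventwave_error(msg, "ventwave_capability_error")
abort_contract   <- function(msg) ventwave_error(msg, "ventwave_contract_error")
abort_detection  <- function(msg) ventwave_error(msg, "ventwave_detection_error")
abort_io         <- function(msg) ventwave_error(msg, "ventwave_io_error")

#' Centered moving average
#'
#' Smooths a numeric series with a centered boxcar of odd length; the
#' ends are padded by repeating the edge values so the output has the
#' same length and no phase shift.
#' @keywords internal
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L || length(x) < width) return(x)
  half <- (width - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  cs <- cumsum(xp)
  (cs[(width):length(xp)] - c(0, cs[seq_len(length(xp) - width)])) / width
}

## Smoothed first derivative (per second) of a uniformly sampled series.
smooth_deriv <- function(x, rate, smooth_s = 0.05) {
  xs <- moving_average(x, round(smooth_s * rate))
  d <- c(xs[2L] - xs[1L], diff(xs)) * rate
  moving_average(d, round(smooth_s * rate))
}

## Evaluate an expression with a temporarily fixed RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

## First index of a run of at least `len` consecutive TRUE values, or NA.
first_sustained <- function(flag, len) {
  if (!any(flag)) return(NA_integer_)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= len
  if (!any(ok)) return(NA_integer_)
  starts[which(ok)[1L]]
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is_scalar_number(x))
    abort_argument(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    abort_argument(sprintf("`%s` must be > 0", name))
  invisible(x)
}
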