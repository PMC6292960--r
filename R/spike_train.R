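#' Spike train on an observation interval
#'
#' The atomic input of all distance computations: an ordered sequence of
#' spike times (seconds) together with the observation interval over which
#' the unit was recorded. Spike times must be strictly increasing and lie
#' inside the interval.
#'
#' @param times Numeric vector of spike times in seconds, strictly
#'   increasing. May be empty.
#' @param interval_start,interval_end Interval bounds in seconds,
#'   `interval_end > interval_start`.
#' @return An object of class `spike_train` with fields `times`,
#'   `interval_start`, `interval_end`.
#' @examples
#' st <- spike_train(c(0.1, 0.5, 0.9), 0, 1)
#' n_spikes(st)
#' @export
spike_train <- function(times = numeric(0), interval_start, interval_end) {
  if (!is.numeric(times)) stop_contract("spike times must be numeric")
  times <- as.numeric(times)
  interval_start <- as.numeric(interval_start)
  interval_end <- as.numeric(interval_end)
  if (length(interval_start) != 1 || length(interval_end) != 1 ||
      !is.finite(interval_start) || !is.finite(interval_end)) {
    stop_contract("interval bounds must be single finite numbers")
  }
  if (interval_end <= interval_start) {
    stop_contract("interval_end (%g) must exceed interval_start (%g)",
                  interval_end, interval_start)
  }
  if (length(times) > 0) {
    if (any(!is.finite(times))) stop_contract("spike times must be finite")
    if (any(diff(times) <= 0)) {
      stop_contract("spike times must be strictly increasing (duplicates rejected)")
    }
    if (times[1] < interval_start || times[length(times)] > interval_end) {
      stop_contract("spike times must lie within [%g, %g]",
                    interval_start, interval_end)
    }
  }
  structure(list(times = times,
                 interval_start = interval_start,
                 interval_end = interval_end),
            class = "spike_train")
}

#' @rdname spike_train
#' @param x A `spike_train`.
#' @export
n_spikes <- function(x) {
  stopifnot(inherits(x, "spike_train"))
  length(x$times)
}

#' @rdname spike_train
#' @export
train_duration <- function(x) {
  stopifnot(inherits(x, "spike_train"))
  x$interval_end - x$interval_start
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train: %d spikes on [%g, %g] s>\n",
              length(x$times), x$interval_start, x$interval_end))
  invisible(x)
}

# both trains must share an observation interval for a pairwise distance
check_same_interval <- function(x, y, tol = 1e-9) {
  stopifnot(inherits(x, "spike_train"), inherits(y, "spike_train"))
  if (abs(x$interval_start - y$interval_start) > tol ||
      abs(x$interval_end - y$interval_end) > tol) {
    stop_contract("spike trains must share the same observation interval")
  }
  invisible(TRUE)
}
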