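#' Time-sampled stimulus profile
#'
#' A full-field luminance trace sampled at a fixed step, with labeled
#' segments. Intensities are normalized to `[0, 1]` with 0.5 the midpoint
#' ("gray") luminance. Segments must tile the stimulus duration without
#' overlap.
#'
#' @param trace Numeric vector of intensities in `[0, 1]`.
#' @param dt Sample step in seconds.
#' @param segments Data frame with columns `label`, `start`, `end` (s).
#' @return An object of class `stimulus_profile`.
#' @export
stimulus_profile <- function(trace, dt, segments) {
  if (dt <= 0) stop_contract("dt must be positive")
  if (any(trace < -1e-12 | trace > 1 + 1e-12)) {
    stop_contract("stimulus trace values must lie in [0, 1]")
  }
  trace <- pmin(pmax(trace, 0), 1)
  stopifnot(is.data.frame(segments),
            all(c("label", "start", "end") %in% names(segments)))
  segments <- segments[order(segments$start), , drop = FALSE]
  dur <- length(trace) * dt
  tol <- dt / 2
  ok_tile <- abs(segments$start[1]) <= tol &&
    abs(segments$end[nrow(segments)] - dur) <= tol &&
    (nrow(segments) < 2 ||
       all(abs(segments$start[-1] - segments$end[-nrow(segments)]) <= tol))
  if (!ok_tile) stop_contract("segments must tile [0, duration] without overlap")
  structure(list(trace = trace, dt = dt, segments = segments),
            class = "stimulus_profile")
}

#' @rdname stimulus_profile
#' @param x A `stimulus_profile`.
#' @export
stimulus_duration <- function(x) length(x$trace) * x$dt

#' @rdname stimulus_profile
#' @param t Time(s) in seconds.
#' @export
stimulus_value_at <- function(x, t) {
  idx <- pmin(pmax(floor(t / x$dt) + 1, 1), length(x$trace))
  x$trace[idx]
}

#' @export
print.stimulus_profile <- function(x, ...) {
  cat(sprintf("<stimulus_profile: %.3g s at dt = %g s; segments: %s>\n",
              stimulus_duration(x), x$dt,
              paste(x$segments$label, collapse = ", ")))
  invisible(x)
}

#' Chirp stimulus
#'
#' The standard full-field chirp sequence used for physiological typing:
#' 1.5 s darkness, 2 s full intensity, 2 s darkness, 2 s gray, a 5 s
#' frequency-modulated sweep `sin(pi * t^2)` around gray, 2 s gray, a 5 s
#' amplitude-modulated sweep `0.2 * t * sin(3 * pi * t)` around gray, and a
#' final 2 s gray; 21.5 s in total. Samples are clipped to `[0, 1]`.
#'
#' @param dt Sample step in seconds (default 1 ms).
#' @return A [stimulus_profile()].
#' @examples
#' ch <- chirp_stimulus()
#' stimulus_duration(ch)  # 21.5
#' @export
chirp_stimulus <- function(dt = 0.001) {
  if (dt <= 0) stop_contract("dt must be positive")
  segs <- data.frame(
    label = c("dark1", "full", "dark2", "gray1", "freq_chirp",
              "gray2", "ampl_chirp", "gray3"),
    start = c(0, 1.5, 3.5, 5.5, 7.5, 12.5, 14.5, 19.5),
    end   = c(1.5, 3.5, 5.5, 7.5, 12.5, 14.5, 19.5, 21.5),
    stringsAsFactors = FALSE)
  n <- round(21.5 / dt)
  t <- (seq_len(n) - 1) * dt
  val <- numeric(n)
  in_seg <- function(lab) t >= segs$start[segs$label == lab] &
    t < segs$end[segs$label == lab]
  val[in_seg("dark1") | in_seg("dark2")] <- 0
  val[in_seg("full")] <- 1
  val[in_seg("gray1") | in_seg("gray2") | in_seg("gray3")] <- 0.5
  fc <- in_seg("freq_chirp")
  tf <- t[fc] - 7.5
  val[fc] <- 0.5 + 0.5 * sin(pi * tf^2)
  ac <- in_seg("ampl_chirp")
  ta <- t[ac] - 14.5
  val[ac] <- 0.5 + 0.2 * ta * sin(3 * pi * ta)
  stimulus_profile(pmin(pmax(val, 0), 1), dt, segs)
}

#' Full-field flash stimulus
#'
#' Alternating 2 s bright / 2 s dark full-field blocks.
#'
#' @param dt Sample step in seconds (default 1 ms).
#' @param n_cycles Number of bright/dark cycles (default 1, i.e. 4 s).
#' @return A [stimulus_profile()] with `bright` / `dark` segments.
#' @export
full_field_stimulus <- function(dt = 0.001, n_cycles = 1) {
  if (dt <= 0) stop_contract("dt must be positive")
  stopifnot(n_cycles >= 1)
  segs <- do.call(rbind, lapply(seq_len(n_cycles) - 1, function(i) {
    data.frame(label = c("bright", "dark"),
               start = 4 * i + c(0, 2), end = 4 * i + c(2, 4),
               stringsAsFactors = FALSE)
  }))
  n <- round(4 * n_cycles / dt)
  t <- (seq_len(n) - 1) * dt
  val <- ifelse((t %% 4) < 2, 1, 0)
  stimulus_profile(val, dt, segs)
}
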