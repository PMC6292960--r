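#' Parameters of one simulated cell type
#'
#' The linear-nonlinear-Poisson (LNP) cascade of a simulated retinal
#' ganglion cell is determined by a temporal Gabor receptive-field kernel
#' (polarity `p`, length `l`, speed `v`) and a logistic output nonlinearity
#' (`r_min`, `r_max`, steepness `c`).
#'
#' @param polarity Response polarity, +1 (ON) or -1 (OFF).
#' @param l Kernel "length" in seconds: the Gaussian envelope SD, sets over
#'   how much time the receptive field integrates the stimulus.
#' @param v Kernel "speed" (dimensionless): cycles of the sinusoidal carrier
#'   per envelope length, sets how quickly the cell responds to intensity
#'   changes.
#' @param r_min,r_max Firing-rate floor and ceiling, spikes/s.
#' @param c Sigmoid steepness (dimensionless).
#' @return An object of class `cell_type_params`.
#' @export
cell_type_params <- function(polarity, l, v, r_min = 0.5, r_max = 100,
                             c = 4.0) {
  if (!polarity %in% c(1, -1)) stop_contract("polarity must be +1 or -1")
  if (l <= 0 || v <= 0) stop_contract("l and v must be positive")
  if (!(r_max > r_min && r_min >= 0)) {
    stop_contract("need r_max > r_min >= 0")
  }
  structure(list(polarity = polarity, l = l, v = v,
                 r_min = r_min, r_max = r_max, c = c),
            class = "cell_type_params")
}

#' The eight baseline cell types
#'
#' All combinations of ON/OFF polarity (`p = +1 / -1`), fast/slow kinetics
#' (`l = 0.4 / 1.0` s) and transient/sustained responses
#' (`v = 0.65 / 1.2`).
#'
#' @return Named list of eight [cell_type_params()].
#' @export
rgc_base_types <- function() {
  types <- list()
  for (pol in c(on = 1, off = -1)) {
    for (spd in c(fast = 0.4, slow = 1.0)) {
      for (vv in c(transient = 0.65, sustained = 1.2)) {
        nm <- paste(names(which(c(on = 1, off = -1) == pol)),
                    names(which(c(fast = 0.4, slow = 1.0) == spd)),
                    names(which(c(transient = 0.65, sustained = 1.2) == vv)),
                    sep = "_")
        types[[nm]] <- cell_type_params(pol, spd, vv)
      }
    }
  }
  types
}

#' Temporal receptive-field kernel (Gabor)
#'
#' `k(t) = g * p * N(t; 0, l^2) * sin(2 * pi * (t / l) * v)` for `t >= 0`,
#' where `N` is the Gaussian density and `g` a single global gain shared by
#' all cell types (see [kernel_gain()]). For a fixed speed `v` the integral
#' of `k` is invariant to the length `l`, so kernels differing only in
#' kinetics produce identical maximum linear-response magnitudes.
#'
#' @param params A [cell_type_params()].
#' @param dt Sample step, seconds.
#' @param support Kernel support in seconds (default `4 * l`, covering the
#'   Gaussian envelope).
#' @param gain Global scale constant; defaults to the cached value from
#'   [kernel_gain()].
#' @return Object of class `temporal_kernel`: list with `t`, `values`, `dt`.
#' @export
temporal_kernel <- function(params, dt = 0.001, support = 4 * params$l,
                            gain = kernel_gain(dt)) {
  stopifnot(inherits(params, "cell_type_params"), dt > 0, support > 0)
  t <- seq(0, support, by = dt)
  k <- gain * params$polarity * dnorm(t, 0, params$l) *
    sin(2 * pi * (t / params$l) * params$v)
  structure(list(t = t, values = k, dt = dt), class = "temporal_kernel")
}

#' Global kernel gain
#'
#' One scale constant applied to every kernel, chosen so that the linear
#' chirp responses of all eight baseline types span `[-1, 1]` (the largest
#' baseline response magnitude maps to 1, the sigmoid midpoint input of the
#' output nonlinearity). Computed once and cached; recorded in simulated
#' dataset provenance.
#'
#' @param dt Sample step used for the reference computation (default 1 ms).
#' @return The scalar gain.
#' @export
kernel_gain <- function(dt = 0.001) {
  key <- sprintf("gain_%.9g", dt)
  if (!is.null(.rgcclust_cache[[key]])) return(.rgcclust_cache[[key]])
  chirp <- chirp_stimulus(dt)
  peak <- 0
  for (ty in rgc_base_types()) {
    kern <- temporal_kernel(ty, dt, support = 5 * ty$l, gain = 1)
    resp <- linear_response(kern, chirp)
    peak <- max(peak, max(abs(resp)))
  }
  g <- 1 / peak
  .rgcclust_cache[[key]] <- g
  g
}

#' Linear response of a cell to a stimulus
#'
#' Convolves the temporal kernel with the zero-mean stimulus drive
#' `s(t) - 0.5` (gray = no drive, so ON/OFF responses are symmetric about
#' the midpoint luminance). The convolution is causal; pre-stimulus history
#' is padded with the first stimulus sample, and the output has the same
#' length as the stimulus.
#'
#' @param kernel A [temporal_kernel()].
#' @param stimulus A [stimulus_profile()] sampled at the same `dt`.
#' @return Numeric vector of linear-response values (dimensionless).
#' @export
linear_response <- function(kernel, stimulus) {
  stopifnot(inherits(kernel, "temporal_kernel"),
            inherits(stimulus, "stimulus_profile"))
  if (abs(kernel$dt - stimulus$dt) > 1e-12) {
    stop_contract("kernel and stimulus sample steps differ (%g vs %g)",
                  kernel$dt, stimulus$dt)
  }
  drive <- stimulus$trace - 0.5
  k <- kernel$values
  K <- length(k)
  xp <- c(rep(drive[1], K - 1), drive)
  # linear convolution via FFT, zero-padded to a smooth composite length
  N <- stats::nextn(length(xp) + K - 1, c(2, 3, 5))
  fx <- stats::fft(c(xp, numeric(N - length(xp))))
  fk <- stats::fft(c(k, numeric(N - K)))
  full <- Re(stats::fft(fx * fk, inverse = TRUE)) / N
  full[K - 1 + seq_along(drive)] * kernel$dt
}

#' Logistic output nonlinearity
#'
#' Maps a linear-response value `x` to an instantaneous firing rate:
#' `r(x) = 2 * (r_max - r_min) / (1 + exp(-c * (x - 1))) + r_min`.
#' The sigmoid midpoint sits at `x = 1`, where the rate equals exactly
#' `r_max`; the rate tends to `r_min` for strongly negative drive. Strictly
#' increasing in `x`.
#'
#' @param x Linear response value(s).
#' @param params A [cell_type_params()] supplying `r_min`, `r_max`, `c`.
#' @return Firing rate(s), spikes/s.
#' @examples
#' nonlinearity(1, cell_type_params(1, 0.4, 0.65))   # 100
#' nonlinearity(-100, cell_type_params(1, 0.4, 0.65)) # 0.5
#' @export
nonlinearity <- function(x, params) {
  stopifnot(inherits(params, "cell_type_params"))
  2 * (params$r_max - params$r_min) / (1 + exp(-params$c * (x - 1))) +
    params$r_min
}

#' Poisson spike generation in discrete bins
#'
#' Draws at most one spike per bin of width `dt` with probability
#' `r(t) * dt` (an independent Bernoulli trial per bin); spikes are placed
#' at bin centers. With the default 1 ms bins, rates up to 1000 spikes/s
#' are representable.
#'
#' @param rate Numeric vector of instantaneous rates, spikes/s.
#' @param dt Bin width in seconds (default 1 ms).
#' @param seed Optional integer; when given, the draw is reproducible and
#'   the caller's RNG state is untouched.
#' @param t0 Interval start time (default 0).
#' @return A [spike_train()] on `[t0, t0 + length(rate) * dt]`.
#' @export
poisson_spikes <- function(rate, dt = 0.001, seed = NULL, t0 = 0) {
  if (dt <= 0) stop_contract("dt must be positive")
  if (any(rate < 0)) stop_contract("rates must be nonnegative")
  p <- rate * dt
  if (any(p > 1)) {
    stop_contract("rate * dt exceeds 1: rate too high for bin width")
  }
  draw <- function() runif(length(p)) < p
  hit <- if (is.null(seed)) draw() else with_seed(seed, draw())
  times <- t0 + (which(hit) - 0.5) * dt
  spike_train(times, t0, t0 + length(rate) * dt)
}

# instantaneous rate trace of one unit for one stimulus
lnp_rate <- function(params, stimulus, gain = kernel_gain(stimulus$dt)) {
  kern <- temporal_kernel(params, stimulus$dt, support = 5 * params$l,
                          gain = gain)
  nonlinearity(linear_response(kern, stimulus), params)
}

#' Simulate spike trains of one LNP unit
#'
#' Runs the full cascade (kernel convolution, logistic nonlinearity,
#' Bernoulli-bin Poisson spiking) for one cell over one stimulus.
#'
#' @param params A [cell_type_params()].
#' @param stimulus A [stimulus_profile()].
#' @param n_trials Number of independent trials.
#' @param seed Optional integer seed (trial `i` uses sub-seed `seed + i`
#'   derivation, reproducible).
#' @return List of [spike_train()] of length `n_trials`.
#' @export
simulate_unit <- function(params, stimulus, n_trials = 5, seed = NULL) {
  rate <- lnp_rate(params, stimulus)
  lapply(seq_len(n_trials), function(i) {
    s <- if (is.null(seed)) NULL else derive_seed(seed, i)
    poisson_spikes(rate, stimulus$dt, seed = s)
  })
}
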