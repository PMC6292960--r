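# Independent oracles used across the suite. These evaluate the
# instantaneous distance definitions pointwise from raw spike times and
# integrate numerically, sharing no code with the package's exact
# piecewise-integration path.

aug_spikes <- function(tt, a, b) c(a, tt, b)

isi_value_at <- function(t, sx, sy) {
  vx <- {
    i <- max(which(sx <= t))
    if (i == length(sx)) i <- i - 1
    sx[i + 1] - sx[i]
  }
  vy <- {
    i <- max(which(sy <= t))
    if (i == length(sy)) i <- i - 1
    sy[i + 1] - sy[i]
  }
  if (vx == vy) 0 else if (vx <= vy) vx / vy - 1 else -(vy / vx - 1)
}

spike_value_at <- function(t, sx, sy) {
  tP1 <- max(sx[sx <= t]); tF1 <- min(sx[sx >= t])
  tP2 <- max(sy[sy <= t]); tF2 <- min(sy[sy >= t])
  dtP <- abs(tP1 - tP2); dtF <- abs(tF1 - tF2)
  xF <- ((tF1 - t) + (tF2 - t)) / 2
  xP <- ((t - tP1) + (t - tP2)) / 2
  mI <- ((tF1 - tP1) + (tF2 - tP2)) / 2
  if (mI <= 0) 0 else (dtP * xF + dtF * xP) / mI^2
}

# dense numerical integration with sample points placed within the
# inter-event panels (midpoint rule; exact for the piecewise-constant and
# piecewise-linear profiles, so agreement is limited only by round-off)
dense_scalar_distance <- function(x, y, metric, n_sub = 32) {
  a <- x$interval_start; b <- x$interval_end
  sx <- aug_spikes(x$times, a, b)
  sy <- aug_spikes(y$times, a, b)
  ev <- sort(unique(c(sx, sy)))
  f <- if (metric == "isi") {
    function(t) abs(isi_value_at(t, sx, sy))
  } else {
    function(t) spike_value_at(t, sx, sy)
  }
  acc <- 0
  for (i in seq_len(length(ev) - 1)) {
    t0 <- ev[i]; t1 <- ev[i + 1]
    if (t1 <= t0) next
    ts <- t0 + (t1 - t0) * (seq_len(n_sub) - 0.5) / n_sub
    acc <- acc + mean(vapply(ts, f, 0)) * (t1 - t0)
  }
  acc / (b - a)
}

# plain uniform-grid sampler (no knowledge of event times)
uniform_scalar_distance <- function(x, y, metric, dt = 1e-4) {
  a <- x$interval_start; b <- x$interval_end
  sx <- aug_spikes(x$times, a, b)
  sy <- aug_spikes(y$times, a, b)
  ts <- seq(a + dt / 2, b, by = dt)
  f <- if (metric == "isi") {
    function(t) abs(isi_value_at(t, sx, sy))
  } else {
    function(t) spike_value_at(t, sx, sy)
  }
  mean(vapply(ts, f, 0))
}

# homogeneous Poisson train on [0, T]
random_train <- function(rate, T) {
  n <- rpois(1, rate * T)
  spike_train(sort(runif(n, 0, T)), 0, T)
}

# brute-force pair-counting clustering scores (independent of scores.R)
pair_counting_oracle <- function(true, pred) {
  n <- length(true)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_t <- true[i] == true[j]
      same_p <- pred[i] == pred[j]
      if (same_t && same_p) tp <- tp + 1
      else if (!same_t && same_p) fp <- fp + 1
      else if (same_t && !same_p) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  total <- tp + fp + fn + tn
  expected <- (tp + fn) * (tp + fp) / total
  list(
    ari = (tp - expected) / ((tp + fn + tp + fp) / 2 - expected),
    fm = if (tp + fp == 0 || tp + fn == 0) NA_real_
         else tp / sqrt((tp + fp) * (tp + fn)))
}

entropy_oracle <- function(labels) {
  p <- table(labels) / length(labels)
  -sum(p * log(p))
}

completeness_oracle <- function(true, pred) {
  hk <- entropy_oracle(pred)
  if (hk == 0) return(1)
  # H(K | C) accumulated class by class
  hkc <- 0
  n <- length(true)
  for (cl in unique(true)) {
    sub <- pred[true == cl]
    p_c <- length(sub) / n
    q <- table(sub) / length(sub)
    hkc <- hkc - p_c * sum(q * log(q))
  }
  1 - hkc / hk
}

# small deterministic labeled dataset for evaluation tests
tiny_population <- function(n_units = 24, rf_variation = 0, n_trials = 2,
                            seed = 1, stimuli = list(chirp = chirp_stimulus())) {
  make_population(population_spec(n_units, rf_variation = rf_variation,
                                  n_trials = n_trials, seed = seed),
                  stimuli = stimuli)
}
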