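#' Peri-stimulus time histogram
#'
#' Trial-averaged binned firing rate: spike counts per bin across trials,
#' divided by `bin * n_trials`, in spikes/s. Bins tile the trial interval
#' from its start; if the bin width does not divide the interval, the last
#' bin is kept (rate still normalized by the full bin width) so that total
#' counts are conserved: `sum(psth) * bin * n_trials` equals the total
#' number of spikes.
#'
#' @param trains List of [spike_train()] trials on a common interval.
#' @param bin Bin width in seconds.
#' @return Numeric vector of rates, spikes/s, with `attr(, "bin")`.
#' @export
psth <- function(trains, bin) {
  stopifnot(length(trains) >= 1, bin > 0)
  ref <- trains[[1]]
  dur <- train_duration(ref)
  if (bin > dur + 1e-12) stop_contract("bin exceeds the trial interval")
  nb <- ceiling(dur / bin - 1e-9)
  breaks <- ref$interval_start + bin * seq(0, nb)
  counts <- numeric(nb)
  for (tr in trains) {
    if (n_spikes(tr) == 0) next
    idx <- pmin(findInterval(tr$times, breaks, rightmost.closed = TRUE), nb)
    tab <- tabulate(idx, nbins = nb)
    counts <- counts + tab
  }
  structure(counts / (bin * length(trains)), bin = bin)
}

#' ON/OFF bias index
#'
#' Contrast of spike counts during the bright and dark phases of a
#' full-field stimulus: `(r_on - r_off) / (r_on + r_off)`, +1 for a pure ON
#' response, -1 for pure OFF, 0 for a balanced response. Undefined (NA)
#' when both counts are zero.
#'
#' @param r_on,r_off Spike counts (or mean rates) during the bright and
#'   dark phases.
#' @return Scalar in `[-1, 1]`, or `NA` if both inputs are zero.
#' @export
bias_index <- function(r_on, r_off) {
  stopifnot(r_on >= 0, r_off >= 0)
  if (r_on + r_off == 0) return(NA_real_)
  unname((r_on - r_off) / (r_on + r_off))
}

#' Full-field ON/OFF spike counts of a unit
#'
#' Counts spikes over the entire bright and dark segments of a full-field
#' stimulus, summed across trials; feeds [bias_index()].
#'
#' @param trains List of [spike_train()] trials.
#' @param stimulus The full-field [stimulus_profile()] (segments labeled
#'   `bright` / `dark`).
#' @return Named vector `c(on = ..., off = ...)`.
#' @export
full_field_counts <- function(trains, stimulus) {
  segs <- stimulus$segments
  count_in <- function(labels) {
    s <- segs[segs$label %in% labels, , drop = FALSE]
    sum(vapply(trains, function(tr) {
      sum(vapply(seq_len(nrow(s)), function(i) {
        sum(tr$times >= s$start[i] & tr$times < s$end[i])
      }, 0))
    }, 0))
  }
  c(on = count_in("bright"), off = count_in("dark"))
}

#' Direction-selectivity index
#'
#' Each direction's relative rate `w_d` is turned into the vector
#' `w_d * (cos theta_d, sin theta_d)`; the two eigenvalues
#' `lambda_1 <= lambda_2` of the 2x2 second-moment matrix of these vectors
#' (normalized to sum to 1) give `DSi = 1 - lambda_1 / lambda_2`, bounded
#' in `[0, 1]`: 0 for uniform tuning (the second-moment matrix is
#' isotropic), 1 when all mass lies along a single direction (rank-one
#' matrix).
#'
#' @param tuning A [direction_tuning()].
#' @return Scalar DSi in `[0, 1]`, `NA` when all rates are zero.
#' @export
direction_selectivity <- function(tuning) {
  stopifnot(inherits(tuning, "direction_tuning"))
  w <- tuning$relative_rates
  if (all(w == 0)) return(NA_real_)
  th <- tuning$directions * pi / 180
  V <- cbind(w * cos(th), w * sin(th))
  M <- crossprod(V)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  lambda2 <- ev[1]
  lambda1 <- max(ev[2], 0)
  if (lambda2 <= 0) return(NA_real_)
  1 - lambda1 / lambda2
}

#' Spike-triggered average from a white-noise movie
#'
#' Mean of the mean-subtracted stimulus frames in the `window` preceding
#' each spike, the standard linear receptive-field estimate. Spikes earlier
#' than one full window after movie onset are skipped (their count is
#' reported). The frame at the lag of largest absolute deviation is fitted
#' with a bivariate Gaussian ([fit_rf_gaussian()]) to estimate the
#' receptive-field center and size.
#'
#' @param train A [spike_train()] covering (part of) the movie.
#' @param movie A [white_noise_movie()] (class `stimulus_movie`).
#' @param window STA window in seconds before each spike (default 0.5).
#' @return Object of class `sta_result`: `sta` (array lag x y x x),
#'   `lag_times` (seconds before spike, decreasing to 0), `peak_time`,
#'   `n_spikes_used`, `n_spikes_skipped`, and the Gaussian fit fields
#'   `fit_center`, `fit_widths`, `rf_size`, `fit_ok`.
#' @export
sta <- function(train, movie, window = 0.5) {
  stopifnot(inherits(train, "spike_train"),
            inherits(movie, "stimulus_movie"))
  dt <- movie$dt
  L <- max(1, round(window / dt))
  nf <- dim(movie$frames)[1]
  frames <- movie$frames - mean(movie$frames)
  fidx <- floor((train$times - train$interval_start) / dt) + 1
  usable <- fidx >= L & fidx <= nf
  if (!any(usable)) stop_contract("no spikes with a full STA window")
  n_skip <- sum(!usable)
  if (n_skip > 0) {
    warning(sprintf("%d spike(s) before the first full window skipped", n_skip))
  }
  acc <- array(0, c(L, dim(frames)[2], dim(frames)[3]))
  for (i in fidx[usable]) {
    acc <- acc + frames[(i - L + 1):i, , , drop = FALSE]
  }
  acc <- acc / sum(usable)
  lag_times <- rev(seq_len(L) - 1) * dt  # seconds before the spike
  peak_lag <- which.max(apply(abs(acc), 1, max))
  fit <- fit_rf_gaussian(acc[peak_lag, , ])
  structure(list(sta = acc, lag_times = lag_times,
                 peak_time = lag_times[peak_lag],
                 n_spikes_used = sum(usable), n_spikes_skipped = n_skip,
                 fit_center = fit$center, fit_widths = fit$widths,
                 rf_size = fit$rf_size, fit_ok = fit$fit_ok),
            class = "sta_result")
}

#' Bivariate Gaussian receptive-field fit
#'
#' Least-squares fit of an axis-aligned bivariate Gaussian (baseline,
#' amplitude, center, two widths) to an STA frame. The fit is flagged as
#' unsuccessful (`fit_ok = FALSE`, never an error) when the optimization
#' fails, when the fitted amplitude is not distinguishable from noise
#' (|amplitude| below 3x the robust SD of the frame), or when the fitted
#' widths are implausible (sub-pixel or wider than the frame). The
#' receptive-field size is the average of the two widths.
#'
#' @param frame Numeric matrix (y by x), finite.
#' @return List with `center` (x, y in pixel coordinates), `widths`
#'   (sigma_1, sigma_2, pixels), `rf_size`, `amplitude`, `baseline`,
#'   `fit_ok`.
#' @export
fit_rf_gaussian <- function(frame) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  ny <- nrow(frame)
  nx <- ncol(frame)
  grid <- expand.grid(y = seq_len(ny), x = seq_len(nx))
  z <- as.vector(frame)
  b0 <- median(z)
  ipk <- which.max(abs(z - b0))
  a0 <- z[ipk] - b0
  x0 <- grid$x[ipk]
  y0 <- grid$y[ipk]
  noise_sd <- mad(z)
  fail <- list(center = c(NA_real_, NA_real_),
               widths = c(NA_real_, NA_real_), rf_size = NA_real_,
               amplitude = NA_real_, baseline = b0, fit_ok = FALSE)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ b + a * exp(-((x - cx)^2 / (2 * s1^2) + (y - cy)^2 / (2 * s2^2))),
      data = cbind(grid, z = z),
      start = list(b = b0, a = a0, cx = x0, cy = y0, s1 = 1.5, s2 = 1.5),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  p <- coef(fit)
  widths <- abs(c(p[["s1"]], p[["s2"]]))
  # a believable receptive field needs an amplitude above the noise floor
  # and widths that are neither sub-pixel (a fit latched onto one noisy
  # pixel) nor wider than the frame
  ok <- is.finite(p[["a"]]) && abs(p[["a"]]) >= 3 * noise_sd &&
    all(is.finite(widths)) && all(widths >= 0.5) &&
    all(widths <= max(ny, nx))
  list(center = c(p[["cx"]], p[["cy"]]), widths = widths,
       rf_size = mean(widths), amplitude = p[["a"]], baseline = p[["b"]],
       fit_ok = ok)
}

#' Peak-normalize PSTH rows
#'
#' Divides every row of a PSTH matrix by its maximum so each row peaks at
#' 1. All-zero rows are left unchanged and flagged in
#' `attr(, "zero_rows")`. Idempotent.
#'
#' @param psths Numeric matrix, units in rows.
#' @return Matrix of the same shape.
#' @export
peak_normalize <- function(psths) {
  psths <- as.matrix(psths)
  mx <- apply(psths, 1, max)
  zero <- mx <= 0
  mx[zero] <- 1
  out <- psths / mx
  attr(out, "zero_rows") <- unname(which(zero))
  out
}

# L1-penalized sparse PCA by alternating soft-thresholded rank-one SVD with
# projection deflation; penalty 0 reduces to ordinary PCA loadings.
sparse_pca_loadings <- function(X, n_components, penalty, max_iter = 200,
                                tol = 1e-9) {
  Xd <- X
  V <- matrix(0, ncol(X), n_components)
  for (comp in seq_len(n_components)) {
    sv <- svd(Xd, nu = 1, nv = 1)
    u <- sv$u[, 1]
    v <- sv$v[, 1] * sv$d[1]
    for (it in seq_len(max_iter)) {
      v_new <- crossprod(Xd, u)
      v_new <- sign(v_new) * pmax(abs(v_new) - penalty / 2, 0)
      if (sum(abs(v_new)) == 0) break
      Xv <- Xd %*% v_new
      nr <- sqrt(sum(Xv^2))
      if (nr == 0) break
      u_new <- as.vector(Xv / nr)
      delta <- sum((u_new - u)^2)
      u <- u_new
      v <- as.vector(v_new)
      if (delta < tol) break
    }
    nv <- sqrt(sum(v^2))
    if (nv > 0) V[, comp] <- v / nv
    Xd <- Xd - u %*% crossprod(u, Xd)  # projection deflation
  }
  V
}

#' Per-unit feature vectors for baseline clustering methods
#'
#' Computes a PSTH per unit at the given bin width and optionally projects
#' the PSTH matrix onto `n_components` principal components (`"pca"`) or
#' L1-penalized sparse principal components (`"sparse_pca"`). The returned
#' features are meant to be clustered with the same Ward procedure via
#' Euclidean distances, providing the parameterized baselines against which
#' the parameter-free spike-distance clustering is compared.
#'
#' @param dataset A [recording_dataset()].
#' @param stimulus Stimulus name.
#' @param method `"psth"`, `"pca"` or `"sparse_pca"`.
#' @param bin PSTH bin width in seconds (default 0.2).
#' @param n_components Projection dimensionality (default 8 for PCA, 12
#'   for sparse PCA per the grid-search optimum).
#' @param penalty L1 penalty of sparse PCA (default 50).
#' @return Numeric matrix, one row per unit (rownames = unit ids).
#' @export
feature_vectors <- function(dataset, stimulus,
                            method = c("psth", "pca", "sparse_pca"),
                            bin = 0.2,
                            n_components = if (method == "sparse_pca") 12 else 8,
                            penalty = 50) {
  method <- match.arg(method)
  X <- t(vapply(dataset$units, function(u) {
    tr <- u$trials[[stimulus]]
    if (is.null(tr)) {
      stop_contract("unit %s has no trials for stimulus '%s'",
                    u$unit_id, stimulus)
    }
    as.numeric(psth(tr, bin))
  }, numeric(length(psth(dataset$units[[1]]$trials[[stimulus]], bin)))))
  rownames(X) <- unit_ids(dataset)
  if (method == "psth") return(X)
  if (n_components > ncol(X)) {
    stop_contract("n_components (%d) exceeds the number of bins (%d)",
                  n_components, ncol(X))
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (method == "pca") {
    pc <- prcomp(Xc, center = FALSE)
    nc <- min(n_components, ncol(pc$x))
    scores <- pc$x[, seq_len(nc), drop = FALSE]
  } else {
    V <- sparse_pca_loadings(Xc, n_components, penalty)
    scores <- Xc %*% V
  }
  rownames(scores) <- unit_ids(dataset)
  scores
}
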