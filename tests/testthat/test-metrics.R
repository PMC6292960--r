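test_that("psth conserves counts and recovers constant rates", {
  # 1 spike in each 0.2 s bin -> constant 5 spikes/s
  st <- spike_train(seq(0.1, 1.9, by = 0.2), 0, 2)
  r <- psth(list(st), 0.2)
  expect_equal(as.numeric(r), rep(5, 10))
  # count conservation with a partial last bin and several trials
  set.seed(12)
  trains <- replicate(3, random_train(20, 2.13), simplify = FALSE)
  r2 <- psth(trains, 0.2)
  total <- sum(vapply(trains, n_spikes, 0L))
  expect_equal(sum(r2) * 0.2 * 3, total)
  # empty trials give a zero vector; oversized bins error
  expect_true(all(psth(list(spike_train(numeric(0), 0, 2)), 0.5) == 0))
  expect_error(psth(list(st), 3), "bin exceeds")
})

test_that("bias index covers the ON/OFF/balanced cases", {
  expect_equal(bias_index(30, 0), 1)
  expect_equal(bias_index(0, 12), -1)
  expect_equal(bias_index(7, 7), 0)
  expect_equal(bias_index(30, 10), 0.5)
  expect_true(is.na(bias_index(0, 0)))
  # antisymmetric under swapping
  expect_equal(bias_index(3, 11), -bias_index(11, 3))
})

test_that("full-field counts split spikes by segment", {
  ff <- full_field_stimulus(0.001, n_cycles = 1)
  trains <- list(spike_train(c(0.5, 1.0, 1.5, 2.5), 0, 4))
  cnt <- full_field_counts(trains, ff)
  expect_equal(unname(cnt), c(3, 1))
  expect_equal(bias_index(cnt["on"], cnt["off"]), 0.5)
})

test_that("direction selectivity matches eigenvalue analysis", {
  dirs <- seq(0, 330, by = 30)
  # uniform tuning: isotropic second moment, DSi = 0
  expect_equal(direction_selectivity(direction_tuning(dirs, rep(4, 12))), 0,
               tolerance = 1e-12)
  # single direction: rank-one, DSi = 1
  one <- rep(0, 12); one[4] <- 9
  expect_equal(direction_selectivity(direction_tuning(dirs, one)), 1)
  # rates (10, 5) along 0 and 90 degrees: lambda = (25, 100), DSi = 0.75
  two <- rep(0, 12); two[1] <- 10; two[4] <- 5
  expect_equal(direction_selectivity(direction_tuning(dirs, two)), 0.75,
               tolerance = 1e-12)
  expect_true(is.na(direction_selectivity(direction_tuning(dirs, rep(0, 12)))))
})

test_that("DSi stays in [0, 1] over random tunings", {
  set.seed(13)
  dirs <- seq(0, 330, by = 30)
  for (i in 1:1000) {
    dsi <- direction_selectivity(direction_tuning(dirs, runif(12, 0, 50)))
    expect_true(dsi >= 0 && dsi <= 1)
  }
})

test_that("peak normalization scales rows to unit peak, idempotently", {
  X <- rbind(a = c(1, 5, 2), b = c(0, 0, 0), c = c(2, 2, 2))
  Y <- peak_normalize(X)
  expect_equal(unname(apply(Y[c(1, 3), ], 1, max)), c(1, 1))
  expect_equal(unname(Y[2, ]), c(0, 0, 0))
  expect_equal(attr(Y, "zero_rows"), 2)
  expect_equal(unname(peak_normalize(Y)), unname(Y))
  expect_equal(dim(Y), dim(X))
})

test_that("gaussian RF fit recovers parameters and rejects pure noise", {
  grid <- expand.grid(y = 1:24, x = 1:24)
  frame <- matrix(0.1 + 0.9 * exp(-((grid$x - 10)^2 / (2 * 2^2) +
                                      (grid$y - 15)^2 / (2 * 4^2))),
                  24, 24)
  fit <- fit_rf_gaussian(frame)
  expect_true(fit$fit_ok)
  expect_equal(fit$center, c(10, 15), tolerance = 1e-6)
  expect_equal(sort(fit$widths), c(2, 4), tolerance = 1e-6)
  expect_equal(fit$rf_size, 3, tolerance = 1e-6)  # (2 + 4) / 2

  set.seed(14)
  noise_frames <- replicate(20, {
    fit_rf_gaussian(matrix(rnorm(24 * 24, 0, 0.05), 24, 24))$fit_ok
  })
  expect_lt(mean(noise_frames), 0.25)  # almost always flagged as no RF
})

test_that("STA recovers a planted spatial receptive field", {
  mv <- white_noise_movie(4000, grid = c(6, 6), upsample = 2, seed = 15)
  ny <- dim(mv$frames)[2]
  # LNP cell with a Gaussian blob filter centered at (8, 5), driven by the
  # immediately preceding frame
  grid <- expand.grid(y = 1:ny, x = 1:ny)
  blob <- matrix(exp(-((grid$x - 8)^2 + (grid$y - 5)^2) / (2 * 1.5^2)), ny, ny)
  drive <- vapply(seq_len(dim(mv$frames)[1]), function(f) {
    sum((mv$frames[f, , ] - 0.5) * blob)
  }, 0)
  rate <- 30 * pmax(drive, 0) / max(drive)
  st <- poisson_spikes(rate, mv$dt, seed = 16)
  res <- sta(st, mv, window = 3 * mv$dt)
  expect_s3_class(res, "sta_result")
  # peak of the STA lies within one pixel of the blob center
  pk <- which(abs(res$sta) == max(abs(res$sta)), arr.ind = TRUE)[1, ]
  expect_lt(abs(pk[3] - 8), 1.5)
  expect_lt(abs(pk[2] - 5), 1.5)
  expect_equal(res$peak_time, 0)  # driven by the frame containing the spike
  expect_true(res$fit_ok)
  expect_equal(unname(res$fit_center), c(8, 5), tolerance = 1.0)
})

test_that("STA of stimulus-independent spiking stays at the noise floor", {
  mv <- white_noise_movie(2000, grid = c(4, 4), upsample = 1, seed = 17)
  st <- poisson_spikes(rep(20, 2000), mv$dt, seed = 18)
  res <- sta(st, mv, window = 2 * mv$dt)
  se <- 0.5 / sqrt(res$n_spikes_used)  # binomial SD of a frame pixel
  expect_lt(max(abs(res$sta)), 5 * se)
  expect_error(sta(spike_train(numeric(0), 0, 1), mv), "no spikes|times")
})

test_that("feature vectors: raw PSTH, PCA invariance, sparse limit", {
  ds <- tiny_population(n_units = 16, rf_variation = 0.05, n_trials = 2,
                        seed = 19)
  X <- feature_vectors(ds, "chirp", "psth", bin = 0.5)
  expect_equal(dim(X), c(16, 43))
  expect_equal(rownames(X), unit_ids(ds))
  # full-dimensional PCA preserves Euclidean distances exactly
  P <- feature_vectors(ds, "chirp", "pca", bin = 0.5, n_components = 16)
  expect_equal(as.matrix(dist(P)), as.matrix(dist(X)), tolerance = 1e-8)
  # sparse PCA with zero penalty spans the PCA subspace
  S0 <- feature_vectors(ds, "chirp", "sparse_pca", bin = 0.5,
                        n_components = 3, penalty = 0)
  P3 <- feature_vectors(ds, "chirp", "pca", bin = 0.5, n_components = 3)
  angles <- svd(crossprod(qr.Q(qr(S0)), qr.Q(qr(P3))))$d
  expect_true(all(acos(pmin(angles, 1)) < 1e-3))
  expect_error(feature_vectors(ds, "chirp", "pca", bin = 0.5,
                               n_components = 99), "exceeds")
})
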