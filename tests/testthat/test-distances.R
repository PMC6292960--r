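test_that("identical trains have zero profiles and zero distance", {
  set.seed(1)
  for (i in 1:5) {
    x <- random_train(10, 2)
    expect_identical(isi_distance(x, x), 0)
    expect_identical(spike_distance(x, x), 0)
    expect_true(all(isi_profile(x, x)$values == 0))
    expect_true(all(spike_profile(x, x)$values == 0))
  }
})

test_that("ISI profile is antisymmetric, SPIKE profile symmetric", {
  set.seed(2)
  for (i in 1:10) {
    x <- random_train(8, 2)
    y <- random_train(12, 2)
    pxy <- isi_profile(x, y)
    pyx <- isi_profile(y, x)
    expect_equal(pxy$values, -pyx$values)
    expect_equal(spike_profile(x, y)$values, spike_profile(y, x)$values)
    expect_equal(isi_distance(x, y), isi_distance(y, x))
    expect_equal(spike_distance(x, y), spike_distance(y, x))
  }
})

test_that("constant-ISI trains: interior ratio -1/2, scalar near 0.5", {
  # x fires every 1 s, y every 2 s: vISIx / vISIy - 1 = -0.5 throughout
  T <- 400
  x <- spike_train(seq(1, T - 1, by = 1), 0, T)
  y <- spike_train(seq(2, T - 2, by = 2), 0, T)
  p <- isi_profile(x, y)
  interior <- p$times[-length(p$times)] > 4 & p$times[-length(p$times)] < T - 4
  expect_true(all(abs(p$values[interior] + 0.5) < 1e-12))
  # edge effects vanish as the interval grows
  expect_equal(isi_distance(x, y), 0.5, tolerance = 0.01)
})

test_that("two single-spike trains match the brute-force evaluation", {
  x <- spike_train(0.4, 0, 1)
  y <- spike_train(0.6, 0, 1)
  expect_equal(spike_distance(x, y),
               dense_scalar_distance(x, y, "spike"), tolerance = 1e-12)
  expect_equal(isi_distance(x, y),
               dense_scalar_distance(x, y, "isi"), tolerance = 1e-12)
  # the value is symmetric in the two configurations
  expect_equal(spike_distance(x, y), spike_distance(y, x))
})

test_that("scalar distances agree with dense numerical integration", {
  set.seed(3)
  for (i in 1:40) {
    x <- random_train(runif(1, 2, 25), 3)
    y <- random_train(runif(1, 2, 25), 3)
    expect_equal(isi_distance(x, y), dense_scalar_distance(x, y, "isi"),
                 tolerance = 1e-9)
    expect_equal(spike_distance(x, y), dense_scalar_distance(x, y, "spike"),
                 tolerance = 1e-9)
  }
  # a plain uniform-grid sampler (dt = 1e-4, blind to event times) agrees
  # to its own discretization error
  set.seed(4)
  x <- random_train(10, 2)
  y <- random_train(10, 2)
  expect_equal(isi_distance(x, y), uniform_scalar_distance(x, y, "isi"),
               tolerance = 1e-3)
  expect_equal(spike_distance(x, y), uniform_scalar_distance(x, y, "spike"),
               tolerance = 1e-3)
})

test_that("profile averaging reproduces the scalar distances", {
  set.seed(5)
  for (i in 1:10) {
    x <- random_train(10, 2)
    y <- random_train(15, 2)
    expect_equal(profile_average(isi_profile(x, y)), isi_distance(x, y),
                 tolerance = 1e-12)
    expect_equal(profile_average(spike_profile(x, y)), spike_distance(x, y),
                 tolerance = 1e-12)
  }
})

test_that("distances are bounded in [0, 1] including edge cases", {
  set.seed(6)
  for (i in 1:200) {
    x <- random_train(runif(1, 0.5, 40), 1.5)
    y <- random_train(runif(1, 0.5, 40), 1.5)
    di <- isi_distance(x, y)
    ds <- spike_distance(x, y)
    expect_true(di >= 0 && di <= 1)
    expect_true(ds >= 0 && ds <= 1)
  }
  # empty vs empty and empty vs nonempty are defined
  e <- spike_train(numeric(0), 0, 1)
  s <- spike_train(0.5, 0, 1)
  expect_identical(isi_distance(e, e), 0)
  expect_identical(spike_distance(e, e), 0)
  expect_true(isi_distance(e, s) >= 0 && isi_distance(e, s) <= 1)
  expect_true(spike_distance(e, s) >= 0 && spike_distance(e, s) <= 1)
})

test_that("mismatched intervals are a contract error", {
  x <- spike_train(0.5, 0, 1)
  y <- spike_train(0.5, 0, 2)
  expect_error(isi_distance(x, y), "interval")
  expect_error(spike_profile(x, y), "interval")
})

test_that("unit pair distance averages all cross trial pairs", {
  tr <- function(...) spike_train(c(...), 0, 2)
  a <- unit_record("a", trials = list(chirp = list(tr(0.2, 1.0), tr(0.4, 1.4))))
  b <- unit_record("b", trials = list(chirp = list(tr(0.3, 0.9), tr(0.5, 1.7))))
  d <- unit_pair_distance(a, b, "chirp", "spike")
  scalars <- outer(1:2, 1:2, Vectorize(function(i, j) {
    spike_distance(a$trials$chirp[[i]], b$trials$chirp[[j]])
  }))
  expect_equal(d, mean(scalars), tolerance = 1e-12)
  expect_equal(unit_pair_distance(b, a, "chirp", "spike"), d)
  # all-identical trials across two units give zero
  same <- unit_record("s", trials = list(chirp = list(tr(0.2, 1.0), tr(0.2, 1.0))))
  same2 <- unit_record("s2", trials = list(chirp = list(tr(0.2, 1.0))))
  expect_equal(unit_pair_distance(same, same2, "chirp", "isi"), 0)
  expect_error(unit_pair_distance(a, b, "nope", "isi"), "a has no trials|no trials")
})

test_that("distance matrix composes pairwise calls and permutes with ids", {
  ds <- tiny_population(n_units = 6, rf_variation = 0.2, n_trials = 2, seed = 21)
  D <- distance_matrix(ds, "chirp", "spike")
  # matches individual unit_pair_distance calls
  for (pair in list(c(1, 2), c(2, 5), c(3, 6))) {
    expect_equal(D$values[pair[1], pair[2]],
                 unit_pair_distance(ds$units[[pair[1]]], ds$units[[pair[2]]],
                                    "chirp", "spike"),
                 tolerance = 1e-12)
  }
  expect_true(isSymmetric(D$values))
  expect_true(all(diag(D$values) == 0))
  # permutation equivariance
  perm <- c(4, 1, 6, 2, 5, 3)
  ds_p <- recording_dataset(ds$units[perm], ds$stimuli,
                            ds$ground_truth_labels[perm])
  Dp <- distance_matrix(ds_p, "chirp", "spike")
  expect_equal(Dp$values, D$values[perm, perm], tolerance = 1e-12)
  # fewer than two units is a contract error
  expect_error(distance_matrix(subset_ds <- recording_dataset(ds$units[1],
                                                              ds$stimuli),
                               "chirp", "spike"),
               "at least 2")
})

test_that("metric axioms hold on sampled random train triples", {
  set.seed(7)
  viol <- 0
  for (i in 1:300) {
    tr <- replicate(3, random_train(runif(1, 2, 20), 2), simplify = FALSE)
    for (metric in list(isi_distance, spike_distance)) {
      d12 <- metric(tr[[1]], tr[[2]])
      d23 <- metric(tr[[2]], tr[[3]])
      d13 <- metric(tr[[1]], tr[[3]])
      expect_true(all(c(d12, d23, d13) >= 0))
      if (d13 > d12 + d23 + 1e-9 || d12 > d13 + d23 + 1e-9 ||
          d23 > d12 + d13 + 1e-9) viol <- viol + 1
    }
  }
  expect_equal(viol, 0)
})
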