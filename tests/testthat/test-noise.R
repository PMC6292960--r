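test_that("noise fraction 0 leaves the dataset unchanged", {
  ds <- tiny_population(10, n_trials = 1, seed = 4)
  expect_identical(apply_noise(ds, noise_spec(0)), ds)
})

test_that("noisy units are split evenly across the four models", {
  ds <- tiny_population(100, rf_variation = 0, n_trials = 1, seed = 6)
  noisy <- apply_noise(ds, noise_spec(0.4, seed = 8))
  expect_equal(length(noisy$noise_models), 40)
  expect_true(all(table(noisy$noise_models) == 10))
  # type labels are preserved; contamination is flagged separately
  expect_identical(noisy$ground_truth_labels, ds$ground_truth_labels)
  expect_equal(sum(!good_unit_mask(noisy)), 40)
  # non-picked units untouched
  clean_id <- setdiff(unit_ids(ds), names(noisy$noise_models))[1]
  i <- match(clean_id, unit_ids(ds))
  expect_identical(noisy$units[[i]]$trials, ds$units[[i]]$trials)
})

test_that("spike-removal model deletes the configured fraction", {
  # four units with ~100,000 spikes each (100 Hz over 2 x 500 s trials);
  # at fraction 1 the four noise models are assigned one unit each
  mk <- function(i) {
    trials <- list(chirp = list(
      poisson_spikes(rep(100, 5e5), 0.001, seed = i),
      poisson_spikes(rep(100, 5e5), 0.001, seed = 100 + i)))
    unit_record(sprintf("b%d", i), eccentricity = 0.1, trials = trials)
  }
  ds <- recording_dataset(lapply(1:4, mk),
                          ground_truth_labels = setNames(
                            rep("on_fast_transient", 4), sprintf("b%d", 1:4)))
  noisy <- apply_noise(ds, noise_spec(1, seed = 12))
  rid <- names(noisy$noise_models)[noisy$noise_models == "spike_removal"]
  expect_length(rid, 1)
  i <- match(rid, unit_ids(ds))
  n0 <- sum(vapply(ds$units[[i]]$trials$chirp, n_spikes, 0L))
  n1 <- sum(vapply(noisy$units[[i]]$trials$chirp, n_spikes, 0L))
  removed <- 1 - n1 / n0
  expect_gt(n0, 90000)
  expect_lt(abs(removed - 0.7), 3 * sqrt(0.7 * 0.3 / n0))
})

test_that("apply_noise removal and merge models act as specified", {
  ds <- tiny_population(8, rf_variation = 0, n_trials = 2, seed = 9)
  noisy <- apply_noise(ds, noise_spec(1, seed = 10))
  models <- noisy$noise_models[unit_ids(ds)]
  n_before <- vapply(ds$units, function(u) {
    sum(vapply(u$trials$chirp, n_spikes, 0L))
  }, 0L)
  n_after <- vapply(noisy$units, function(u) {
    sum(vapply(u$trials$chirp, n_spikes, 0L))
  }, 0L)
  rem <- models == "spike_removal"
  mer <- models == "unit_merge"
  # removal thins to ~30% of the original count
  expect_true(all(n_after[rem] < 0.6 * n_before[rem]))
  expect_true(all(abs(n_after[rem] / n_before[rem] - 0.3) < 0.15))
  # merging adds spikes
  expect_true(all(n_after[mer] > n_before[mer]))
  # every contaminated train still satisfies the invariants
  for (u in noisy$units) {
    for (st in u$trials$chirp) {
      expect_true(all(diff(st$times) > 0))
      expect_true(train_duration(st) == 21.5)
    }
  }
})

test_that("fixed-rate noise units fire near the configured rate", {
  ds <- tiny_population(4, rf_variation = 0, n_trials = 3, seed = 13)
  noisy <- apply_noise(ds, noise_spec(1, fixed_rate = 2, seed = 14))
  fixed_ids <- names(noisy$noise_models)[noisy$noise_models == "fixed_rate_poisson"]
  counts <- vapply(fixed_ids, function(id) {
    u <- noisy$units[[match(id, unit_ids(noisy))]]
    sum(vapply(u$trials$chirp, n_spikes, 0L))
  }, 0L)
  total_time <- 3 * 21.5 * length(fixed_ids)
  rate <- sum(counts) / total_time
  expect_lt(abs(rate - 2), 3 * sqrt(2 / total_time))
})
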