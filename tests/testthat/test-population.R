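test_that("zero-variation population realizes exactly the 8 baseline types", {
  ds <- tiny_population(n_units = 8, rf_variation = 0, n_trials = 1, seed = 3)
  expect_equal(sort(unname(ds$ground_truth_labels)),
               sort(names(rgc_base_types())))
  expect_true(all(vapply(ds$units, function(u) {
    all(vapply(u$trials$chirp, inherits, TRUE, "spike_train"))
  }, TRUE)))
})

test_that("type allocation is deterministic largest-remainder rounding", {
  # 70% ON total across the four ON types -> exactly 70 of 100 units ON
  fr <- fractions_from_pcts(70, 50, 50)
  expect_equal(sum(fr), 1)
  sp <- population_spec(100, fr, rf_variation = 0, n_trials = 1, seed = 1)
  ds <- make_population(sp)
  on_count <- sum(startsWith(unname(ds$ground_truth_labels), "on_"))
  expect_equal(on_count, 70)
  # allocation error at most 1 unit per type
  counts <- table(ds$ground_truth_labels)
  expect_true(all(abs(counts - fr[names(counts)] * 100) <= 1))
})

test_that("same seed reproduces the dataset exactly", {
  a <- tiny_population(n_units = 6, rf_variation = 0.1, n_trials = 2, seed = 11)
  b <- tiny_population(n_units = 6, rf_variation = 0.1, n_trials = 2, seed = 11)
  expect_identical(a$ground_truth_labels, b$ground_truth_labels)
  for (i in seq_along(a$units)) {
    expect_identical(a$units[[i]]$trials$chirp[[1]]$times,
                     b$units[[i]]$trials$chirp[[1]]$times)
  }
})

test_that("suite conditions enumerate the sweep and the imbalance grid", {
  conds <- suite_conditions()
  expect_equal(sum(conds$kind == "variation"), 20)   # 5 variations x 4 sizes
  expect_equal(sum(conds$kind == "imbalance"), 135)  # 45 per axis pair x 3
  expect_equal(nrow(conds), 155)
  # every imbalance tuple respects the printed ranges
  imb <- conds[conds$kind == "imbalance", ]
  expect_true(all(imb$pct_on >= 30 | imb$pct_on == 50))
  expect_true(all(imb$pct_fast >= 10 & imb$pct_fast <= 90))
  # materialized datasets carry complete ground-truth labels
  ds <- make_suite_dataset(conds[1, ], seed = 2, n_trials = 1)
  expect_equal(length(ds$ground_truth_labels), n_units(ds))
  expect_equal(ds$provenance$condition$condition_id, 1)
})

test_that("white-noise movie is balanced, seeded, and shift-controllable", {
  mv <- white_noise_movie(400, grid = c(4, 4), upsample = 2, seed = 5)
  # per-pixel mean near 0.5 within 3 binomial SDs
  m <- apply(mv$frames, c(2, 3), mean)
  expect_true(all(abs(m - 0.5) < 3 * sqrt(0.25 / 400) + 1e-12))
  mv2 <- white_noise_movie(400, grid = c(4, 4), upsample = 2, seed = 5)
  expect_identical(mv$frames, mv2$frames)
  # without shifting, the coarse lattice is fixed: every frame constant
  # within each upsampled block
  mv3 <- white_noise_movie(10, grid = c(3, 3), upsample = 3, shift = FALSE,
                           seed = 1)
  blocks <- mv3$frames[, 1:3, 1:3]
  expanded <- mv3$frames[, rep(1:3, each = 3) * 3 - 2, rep(1:3, each = 3) * 3 - 2]
  expect_identical(blocks, expanded[, 1:3, 1:3])
})

test_that("moving-bar tuning peaks at the preferred direction", {
  flat <- moving_bar_tuning(90, concentration = 0, noise = FALSE)
  expect_true(all(flat$relative_rates == flat$relative_rates[1]))
  sharp <- moving_bar_tuning(120, concentration = 50, noise = FALSE)
  expect_equal(sharp$directions[which.max(sharp$relative_rates)], 120)
  expect_gt(max(sharp$relative_rates) / (sum(sharp$relative_rates) + 1e-12),
            0.99)  # concentration -> all mass in one direction
  seeded <- moving_bar_tuning(0, 2, seed = 9)
  expect_identical(seeded$relative_rates,
                   moving_bar_tuning(0, 2, seed = 9)$relative_rates)
})
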