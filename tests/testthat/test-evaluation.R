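test_that("noise-free low-variation datasets are clustered near-perfectly", {
  ds <- tiny_population(n_units = 40, rf_variation = 0, n_trials = 3,
                        seed = 23)
  tab <- run_method_comparison(list(ds), methods = c("spike", "psth"), k = 8)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$median_score > 0.95))
  # deterministic: identical reruns
  tab2 <- run_method_comparison(list(ds), methods = c("spike", "psth"), k = 8)
  expect_identical(tab, tab2)
})

test_that("scoring is restricted to good units after contamination", {
  ds <- tiny_population(n_units = 30, rf_variation = 0, n_trials = 2,
                        seed = 24)
  noisy <- apply_noise(ds, noise_spec(0.3, seed = 25))
  pred <- cluster_dataset(noisy, "spike", 8)
  full <- quality_scores(noisy$ground_truth_labels, pred)
  good <- quality_scores(noisy$ground_truth_labels, pred,
                         restrict_to = unname(good_unit_mask(noisy)))
  # restricting to clean units cannot do worse on identical trivial cases
  expect_equal(length(pred), 30)
  expect_true(good$median_score >= full$median_score - 1e-9)
})

test_that("match_clusters is the identity on a self-match", {
  ds <- tiny_population(n_units = 32, rf_variation = 0.05, n_trials = 2,
                        seed = 26)
  X <- peak_normalize(feature_vectors(ds, "chirp", "psth", bin = 0.1))
  labels <- ds$ground_truth_labels
  m <- match_clusters(X, labels, X, labels, method = "pca",
                      n_components = 8)
  expect_equal(nrow(m$pairs), length(unique(labels)))
  expect_identical(m$pairs$cluster_a, m$pairs$cluster_b)
  # pair distances equal each cluster's within-cluster mean distance:
  # small relative to the orthogonality scale 1, but nonzero
  expect_lt(max(m$pairs$distance), 0.5)
  expect_length(m$unmatched_a, 0)
})

test_that("cosine distance spans [0, 2] with opposing vectors at 2", {
  u <- c(1, 2, -1)
  expect_equal(rgcclust:::cosine_distance(u, u), 0)
  expect_equal(rgcclust:::cosine_distance(u, -u), 2)
  expect_equal(rgcclust:::cosine_distance(c(1, 0), c(0, 3)), 1)
})

test_that("two gain-shifted retinas match most of their types", {
  mk <- function(seed, gain) {
    ds <- tiny_population(n_units = 48, rf_variation = 0.05, n_trials = 3,
                          seed = seed)
    X <- feature_vectors(ds, "chirp", "psth", bin = 0.1) * gain
    list(X = peak_normalize(X), labels = ds$ground_truth_labels)
  }
  a <- mk(27, 1.0)
  b <- mk(28, 1.3)
  m <- match_clusters(a$X, a$labels, b$X, b$labels, method = "kernel_pca",
                      n_components = 20)
  correct <- sum(m$pairs$cluster_a == m$pairs$cluster_b)
  expect_gte(correct, 7)  # at least 7 of the 8 types matched
})

test_that("pooling a dataset with itself yields balanced cluster origins", {
  ds <- tiny_population(n_units = 40, rf_variation = 0.1, n_trials = 2,
                        seed = 29)
  comp <- pooled_origin_composition(ds, ds, n_each = 30, k = 6, seed = 30)
  expect_equal(comp$frac_a + comp$frac_b, rep(1, nrow(comp)))
  # multinomial error bound on the overall origin balance
  overall <- sum(comp$frac_a * comp$n) / sum(comp$n)
  expect_equal(overall, 0.5, tolerance = 1e-9)
  expect_error(pooled_origin_composition(ds, ds, n_each = 1000),
               "at least")
})

test_that("cross-retina curve is zero for identical datasets", {
  ds <- tiny_population(n_units = 24, rf_variation = 0.05, n_trials = 2,
                        seed = 31)
  tab <- cross_retina_distance_curve(list(ds, ds), k_range = c(4, 8),
                                     bin = 0.1)
  expect_equal(nrow(tab), 4)  # 2 ordered pairs x 2 k values
  expect_true(all(tab$mean_min_distance < 1e-9))
})
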