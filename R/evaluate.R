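#' Cluster a dataset with one method
#'
#' Unified front end over the two clustering routes: the spike-distance
#' metrics (`"isi"`, `"spike"`) cluster the trial-averaged distance matrix
#' directly, while the feature baselines (`"psth"`, `"pca"`,
#' `"sparse_pca"`) cluster Euclidean distances between per-unit feature
#' vectors. Both routes use Ward linkage and a flat cut at `k`.
#'
#' @param dataset A [recording_dataset()].
#' @param method One of `"isi"`, `"spike"`, `"psth"`, `"pca"`,
#'   `"sparse_pca"`.
#' @param k Number of flat clusters.
#' @param stimulus Stimulus name (default `"chirp"`).
#' @param bin,n_components,penalty Feature parameters, see
#'   [feature_vectors()].
#' @return Named integer labels per unit.
#' @export
cluster_dataset <- function(dataset, method, k, stimulus = "chirp",
                            bin = 0.2,
                            n_components = if (method == "sparse_pca") 12 else 8,
                            penalty = 50) {
  method <- match.arg(method, c("isi", "spike", "psth", "pca", "sparse_pca"))
  tree <- if (method %in% c("isi", "spike")) {
    ward_linkage(distance_matrix(dataset, stimulus, method))
  } else {
    X <- feature_vectors(dataset, stimulus, method, bin = bin,
                         n_components = n_components, penalty = penalty)
    V <- as.matrix(dist(X))
    ward_linkage(V)
  }
  cut_tree(tree, k)
}

score_against_truth <- function(dataset, pred) {
  truth <- dataset$ground_truth_labels
  if (is.null(truth)) stop_contract("dataset carries no ground-truth labels")
  mask <- good_unit_mask(dataset)
  quality_scores(truth, pred[names(truth)], restrict_to = unname(mask))
}

#' Method comparison over a suite of ground-truth datasets
#'
#' Clusters every dataset with every method at a fixed flat cut and scores
#' the result against ground truth, restricted to the noise-free units.
#'
#' @param datasets List of labeled [recording_dataset()]s.
#' @param methods Methods passed to [cluster_dataset()].
#' @param k Flat cluster count (default 8, the number of base types).
#' @param stimulus,bin,penalty See [cluster_dataset()].
#' @return Tibble with one row per (dataset, method): the five quality
#'   scores and their median.
#' @export
run_method_comparison <- function(datasets,
                                  methods = c("isi", "spike", "psth",
                                              "pca", "sparse_pca"),
                                  k = 8, stimulus = "chirp", bin = 0.2,
                                  penalty = 50) {
  rows <- list()
  for (d in seq_along(datasets)) {
    ds <- datasets[[d]]
    for (m in methods) {
      pred <- cluster_dataset(ds, m, k, stimulus, bin = bin,
                              penalty = penalty)
      qs <- score_against_truth(ds, pred)
      rows[[length(rows) + 1]] <- tibble::tibble(
        dataset = d, method = m, k = k,
        n_units = n_units(ds),
        rf_variation = ds$provenance$rf_variation %||% NA_real_,
        ari = qs$ari, ami = qs$ami, v_measure = qs$v_measure,
        completeness = qs$completeness,
        fowlkes_mallows = qs$fowlkes_mallows,
        median_score = qs$median_score)
    }
  }
  do.call(rbind, rows)
}

#' Receptive-field variation sweep
#'
#' Generates datasets across jitter levels and population sizes and scores
#' each method at the eight-type flat cut, reproducing the
#' variability-robustness experiment at a configurable scale.
#'
#' @param seed Master seed.
#' @param sizes Population sizes.
#' @param variations Relative jitter levels.
#' @param methods Methods to compare.
#' @param n_trials Trials per unit.
#' @param stimulus Stimulus name.
#' @return Tibble of scores by (rf_variation, n_units, method).
#' @export
run_variation_sweep <- function(seed = 1,
                                sizes = c(100, 200, 400, 800),
                                variations = c(0.05, 0.10, 0.15, 0.20, 0.30),
                                methods = c("isi", "spike", "psth",
                                            "pca", "sparse_pca"),
                                n_trials = 5, stimulus = "chirp") {
  conds <- suite_conditions(sizes = sizes, variations = variations)
  conds <- conds[conds$kind == "variation", ]
  rows <- list()
  for (i in seq_len(nrow(conds))) {
    ds <- make_suite_dataset(conds[i, ], seed = seed, n_trials = n_trials)
    tab <- run_method_comparison(list(ds), methods, k = 8,
                                 stimulus = stimulus)
    tab$dataset <- conds$condition_id[i]
    rows[[i]] <- tab
  }
  do.call(rbind, rows)
}

#' Noise-robustness experiment
#'
#' Contaminates a base dataset with increasing fractions of noisy units,
#' clusters at each flat cut in `k_values`, and scores against ground
#' truth restricted to the good units; completeness is reported alongside
#' the median score since it isolates whether true types stay grouped even
#' when noisy units claim their own clusters.
#'
#' @param base_dataset Labeled noise-free [recording_dataset()].
#' @param fractions Noisy-unit fractions (default 10-90% in 10% steps).
#' @param k_values Flat cluster counts (default 8 and 16).
#' @param methods Methods to compare.
#' @param seed Master seed for the contamination draws.
#' @param stimulus Stimulus name.
#' @return Tibble of scores by (fraction, k, method).
#' @export
run_noise_robustness <- function(base_dataset,
                                 fractions = seq(0.1, 0.9, by = 0.1),
                                 k_values = c(8, 16),
                                 methods = c("isi", "spike", "psth",
                                             "pca", "sparse_pca"),
                                 seed = 1, stimulus = "chirp") {
  rows <- list()
  for (f in fractions) {
    ds <- if (f == 0) base_dataset else {
      apply_noise(base_dataset,
                  noise_spec(f, seed = derive_seed(seed, round(100 * f))))
    }
    for (m in methods) {
      tree <- NULL
      for (k in k_values) {
        pred <- cluster_dataset(ds, m, k, stimulus)
        qs <- score_against_truth(ds, pred)
        rows[[length(rows) + 1]] <- tibble::tibble(
          fraction = f, k = k, method = m,
          ari = qs$ari, ami = qs$ami, v_measure = qs$v_measure,
          completeness = qs$completeness,
          fowlkes_mallows = qs$fowlkes_mallows,
          median_score = qs$median_score)
      }
    }
  }
  do.call(rbind, rows)
}

#' Grid search over PSTH bin sizes
#'
#' For each candidate bin size, clusters the raw PSTH vectors of every
#' dataset into `k` flat clusters (Ward on Euclidean distances) and
#' records the median external quality score; returns the score table, the
#' best bin per master seed, and the majority-vote best bin in
#' milliseconds.
#'
#' @param seeds Master seeds (one reduced suite generated per seed).
#' @param bins Candidate bin widths in seconds.
#' @param n_datasets,n_units,variations,n_trials Reduced-suite shape: each
#'   suite has `n_datasets` datasets of `n_units` units, jitter levels
#'   cycling through `variations`.
#' @param k Flat cluster count (default 8).
#' @return List with `table` (tibble of per-dataset median scores),
#'   `best_per_seed` and `best_bin_ms`: the strict majority winner over
#'   the per-seed argmax bins; when no bin wins a strict majority, the
#'   argmax of the per-seed score curves averaged across seeds.
#' @export
bin_size_grid_search <- function(seeds = 1:3,
                                 bins = c(0.025, 0.05, 0.1, 0.2, 0.5, 1.0),
                                 n_datasets = 10, n_units = 200,
                                 variations = c(0.05, 0.10, 0.15),
                                 n_trials = 5, k = 8) {
  rows <- list()
  best <- integer(0)
  for (s in seeds) {
    datasets <- lapply(seq_len(n_datasets), function(i) {
      sp <- population_spec(
        n_units,
        rf_variation = variations[((i - 1) %% length(variations)) + 1],
        n_trials = n_trials, seed = derive_seed(s, i, 42L))
      make_population(sp)
    })
    for (b in bins) {
      meds <- vapply(datasets, function(ds) {
        pred <- cluster_dataset(ds, "psth", k, bin = b)
        score_against_truth(ds, pred)$median_score
      }, 0)
      rows[[length(rows) + 1]] <- tibble::tibble(
        seed = s, bin_ms = round(b * 1000), dataset = seq_along(meds),
        median_score = meds)
    }
    seed_tab <- do.call(rbind, rows[seq(length(rows) - length(bins) + 1,
                                        length(rows))])
    by_bin <- vapply(split(seed_tab$median_score, seed_tab$bin_ms), median, 0)
    best <- c(best, as.integer(names(by_bin)[which.max(
      by_bin[as.character(round(bins * 1000))])]))
  }
  tab <- do.call(rbind, rows)
  counts <- table(best)
  majority <- counts[counts > length(seeds) / 2]
  best_bin_ms <- if (length(majority) == 1) {
    as.integer(names(majority))
  } else {
    # no strict majority: average the per-seed score curves (replicate
    # measurements of the same curve) and take that argmax
    per_seed_curves <- vapply(unique(tab$seed), function(s) {
      sub <- tab[tab$seed == s, ]
      vapply(round(bins * 1000), function(bm) {
        median(sub$median_score[sub$bin_ms == bm])
      }, 0)
    }, numeric(length(bins)))
    round(bins[which.max(rowMeans(per_seed_curves))] * 1000)
  }
  list(table = tab, best_per_seed = best, best_bin_ms = best_bin_ms)
}

cluster_mean_matrix <- function(X, labels) {
  gs <- sort(unique(labels))
  M <- t(vapply(gs, function(g) colMeans(X[labels == g, , drop = FALSE]),
                numeric(ncol(X))))
  rownames(M) <- gs
  M
}

embed_features <- function(X, method = c("kernel_pca", "pca"),
                           n_components = 20, sigma = NULL) {
  method <- match.arg(method)
  if (method == "pca") {
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    nc <- min(n_components, ncol(pc$x))
    return(pc$x[, seq_len(nc), drop = FALSE])
  }
  if (is.null(sigma)) {
    # median heuristic for the RBF bandwidth
    idx <- seq_len(min(nrow(X), 200))
    d2 <- as.vector(dist(X[idx, , drop = FALSE]))^2
    sigma <- 1 / (2 * stats::median(d2[d2 > 0]))
  }
  nc <- min(n_components, nrow(X) - 1)
  kp <- kernlab::kpca(as.matrix(X), kernel = "rbfdot",
                      kpar = list(sigma = sigma), features = nc)
  kernlab::rotated(kp)
}

#' Match clusters between two preparations
#'
#' Embeds the peak-normalized PSTHs of both sides jointly (RBF kernel PCA
#' with 20 components by default, or plain PCA), computes the mean cosine
#' distance between the embedded vectors of every cross-side cluster pair,
#' and pairs clusters greedily by ascending distance (each cluster used at
#' most once).
#'
#' @param psths_a,psths_b PSTH matrices (units in rows, rownames = ids).
#' @param labels_a,labels_b Named cluster labels for each side.
#' @param method Embedding: `"kernel_pca"` (default) or `"pca"`.
#' @param n_components Embedding dimensionality (default 20).
#' @return Object of class `match_result`: `pairs` (tibble `cluster_a`,
#'   `cluster_b`, `distance`, ascending), `unmatched_a`, `unmatched_b`,
#'   and `cumulative` (cumulative mean pair distance by rank).
#' @export
match_clusters <- function(psths_a, labels_a, psths_b, labels_b,
                           method = c("kernel_pca", "pca"),
                           n_components = 20) {
  method <- match.arg(method)
  psths_a <- peak_normalize(as.matrix(psths_a))
  psths_b <- peak_normalize(as.matrix(psths_b))
  stopifnot(nrow(psths_a) == length(labels_a),
            nrow(psths_b) == length(labels_b))
  emb <- embed_features(rbind(psths_a, psths_b), method, n_components)
  ea <- emb[seq_len(nrow(psths_a)), , drop = FALSE]
  eb <- emb[nrow(psths_a) + seq_len(nrow(psths_b)), , drop = FALSE]
  ga <- sort(unique(labels_a))
  gb <- sort(unique(labels_b))
  Dm <- matrix(NA_real_, length(ga), length(gb), dimnames = list(ga, gb))
  for (i in seq_along(ga)) {
    A <- ea[labels_a == ga[i], , drop = FALSE]
    for (j in seq_along(gb)) {
      B <- eb[labels_b == gb[j], , drop = FALSE]
      dd <- outer(seq_len(nrow(A)), seq_len(nrow(B)),
                  Vectorize(function(p, q) cosine_distance(A[p, ], B[q, ])))
      Dm[i, j] <- mean(dd, na.rm = TRUE)
    }
  }
  ord <- order(Dm)
  used_a <- logical(length(ga))
  used_b <- logical(length(gb))
  pairs <- list()
  for (o in ord) {
    i <- ((o - 1) %% length(ga)) + 1
    j <- ((o - 1) %/% length(ga)) + 1
    if (used_a[i] || used_b[j] || !is.finite(Dm[i, j])) next
    used_a[i] <- TRUE
    used_b[j] <- TRUE
    pairs[[length(pairs) + 1]] <- tibble::tibble(
      cluster_a = ga[i], cluster_b = gb[j], distance = Dm[i, j])
  }
  pairs <- do.call(rbind, pairs)
  structure(list(pairs = pairs,
                 unmatched_a = ga[!used_a], unmatched_b = gb[!used_b],
                 cumulative = cumsum(pairs$distance) / seq_len(nrow(pairs)),
                 distance_matrix = Dm),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: %d pairs, %d + %d unmatched>\n",
              nrow(x$pairs), length(x$unmatched_a), length(x$unmatched_b)))
  invisible(x)
}

#' Origin composition of clusters of pooled data
#'
#' Samples `n_each` units from each of two datasets, pools them, clusters
#' the pooled spike-distance matrix, and reports the fraction of each
#' cluster originating from either source — a direct probe of
#' between-preparation heterogeneity (strongly single-origin clusters mean
#' pooling separates preparations, not cell types).
#'
#' @param dataset_a,dataset_b Datasets sharing stimulus definitions.
#' @param n_each Units sampled per dataset.
#' @param metric Spike metric (`"spike"` or `"isi"`).
#' @param k Flat cluster count.
#' @param seed Integer seed for the sampling.
#' @param stimulus Stimulus name.
#' @return Tibble: `cluster`, `n`, `frac_a`, `frac_b`.
#' @export
pooled_origin_composition <- function(dataset_a, dataset_b, n_each = 500,
                                      metric = "spike", k = 16, seed = 1,
                                      stimulus = "chirp") {
  if (n_units(dataset_a) < n_each || n_units(dataset_b) < n_each) {
    stop_contract("both datasets must have at least n_each = %d units", n_each)
  }
  pick <- with_seed(seed, list(a = sample(n_units(dataset_a), n_each),
                               b = sample(n_units(dataset_b), n_each)))
  retag <- function(units, prefix) {
    lapply(units, function(u) {
      unit_record(paste0(prefix, u$unit_id), u$location, u$fit_axes,
                  u$eccentricity, u$trials)
    })
  }
  pooled <- recording_dataset(
    c(retag(dataset_a$units[pick$a], "a_"),
      retag(dataset_b$units[pick$b], "b_")),
    dataset_a$stimuli)
  labels <- cut_tree(ward_linkage(distance_matrix(pooled, stimulus, metric)), k)
  origin <- ifelse(startsWith(names(labels), "a_"), "a", "b")
  gs <- sort(unique(labels))
  tibble::tibble(
    cluster = gs,
    n = vapply(gs, function(g) sum(labels == g), 0L),
    frac_a = vapply(gs, function(g) mean(origin[labels == g] == "a"), 0),
    frac_b = vapply(gs, function(g) mean(origin[labels == g] == "b"), 0))
}

#' Cross-preparation best-match distance curve
#'
#' For every dataset pair and every `k`: cluster each dataset at `k`
#' (SPIKE metric), embed the cluster-mean peak-normalized PSTHs with a PCA
#' model fit on the combined units of all datasets, and average, over the
#' clusters of the first dataset, the minimum cosine distance to any
#' cluster of the second.
#'
#' @param datasets List of at least two datasets.
#' @param k_range Cluster numbers to evaluate.
#' @param n_components PCA dimensionality (default 8).
#' @param stimulus,bin PSTH parameters.
#' @return Tibble: `pair`, `k`, `mean_min_distance`.
#' @export
cross_retina_distance_curve <- function(datasets, k_range = c(8, 16, 24),
                                        n_components = 8,
                                        stimulus = "chirp", bin = 0.05) {
  stopifnot(length(datasets) >= 2)
  psths <- lapply(datasets, function(ds) {
    peak_normalize(feature_vectors(ds, stimulus, "psth", bin = bin))
  })
  all_units <- do.call(rbind, psths)
  pc <- prcomp(all_units, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(pc$x))
  project <- function(X) {
    scale(X, center = pc$center, scale = FALSE) %*% pc$rotation[, 1:nc]
  }
  trees <- lapply(datasets, function(ds) {
    ward_linkage(distance_matrix(ds, stimulus, "spike"))
  })
  rows <- list()
  for (i in seq_along(datasets)) {
    for (j in seq_along(datasets)) {
      if (i == j) next
      for (k in k_range) {
        la <- cut_tree(trees[[i]], k)
        lb <- cut_tree(trees[[j]], k)
        Ma <- project(cluster_mean_matrix(psths[[i]], la))
        Mb <- project(cluster_mean_matrix(psths[[j]], lb))
        mins <- vapply(seq_len(nrow(Ma)), function(r) {
          min(vapply(seq_len(nrow(Mb)), function(s) {
            cosine_distance(Ma[r, ], Mb[s, ])
          }, 0), na.rm = TRUE)
        }, 0)
        rows[[length(rows) + 1]] <- tibble::tibble(
          pair = sprintf("%d-%d", i, j), k = k,
          mean_min_distance = mean(mins, na.rm = TRUE))
      }
    }
  }
  do.call(rbind, rows)
}
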