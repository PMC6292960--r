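#' Hierarchical Ward clustering of a distance matrix
#'
#' Agglomerative clustering of the unit-by-unit dissimilarity matrix under
#' Ward's minimum-variance criterion (`stats::hclust` with
#' `method = "ward.D2"`, the Lance-Williams update equivalent to Ward
#' linkage on the supplied dissimilarities). Treating a non-Euclidean
#' spike-train distance matrix as if its entries were Euclidean is standard
#' practice and documented as an approximation.
#'
#' @param D A [distance_matrix()] or a symmetric numeric matrix.
#' @return Object of class `cluster_tree`: the `hclust` merge structure
#'   plus `leaf_ids`.
#' @export
ward_linkage <- function(D) {
  if (inherits(D, "distance_matrix")) {
    ids <- D$unit_ids
    V <- D$values
  } else {
    V <- as.matrix(D)
    ids <- rownames(V) %||% sprintf("u%04d", seq_len(nrow(V)))
    if (max(abs(V - t(V))) > 1e-12 || any(V < 0)) {
      stop_contract("distance matrix must be symmetric and nonnegative")
    }
  }
  if (nrow(V) < 2) stop_contract("need at least 2 units to cluster")
  d <- as.dist(V)
  attr(d, "Labels") <- ids
  hc <- hclust(d, method = "ward.D2")
  structure(list(hclust = hc, leaf_ids = ids, n_leaves = length(ids)),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree: %d leaves, Ward linkage>\n", x$n_leaves))
  invisible(x)
}

#' Flat clusters from a tree
#'
#' Cuts the dendrogram so that exactly `k` flat clusters are obtained.
#' Label values are arbitrary but stable for a given tree, and the
#' partitions are nested across `k`.
#'
#' @param tree A [ward_linkage()] tree.
#' @param k Number of flat clusters, `1 <= k <= n_leaves`.
#' @return Named integer vector of cluster labels per unit.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "cluster_tree"))
  if (k < 1 || k > tree$n_leaves) {
    stop_contract("k must lie in [1, %d]", tree$n_leaves)
  }
  labels <- cutree(tree$hclust, k = k)
  setNames(as.integer(labels), tree$leaf_ids)
}

# pooled within-cluster dispersion: sum over clusters of
# (1 / (2 n_r)) * sum of all within-cluster pairwise distances (both orders)
within_dispersion <- function(V, labels) {
  w <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) > 1) {
      w <- w + sum(V[idx, idx]) / (2 * length(idx))
    }
  }
  w
}

#' Gap statistic on a distance matrix
#'
#' Compares the compactness of the clustering at each `k` against random
#' surrogates obtained by permuting the off-diagonal entries of the
#' distance matrix (preserving symmetry and the zero diagonal). Each
#' surrogate is re-clustered from scratch. The pooled within-cluster
#' dispersion is `W_k = sum_r (1/(2 n_r)) sum_{i,j in r} D_ij`, and
#' `gap(k) = mean_s log W_k(surrogate s) - log W_k(D)`. Zero dispersions
#' are floored at machine epsilon before taking logs.
#'
#' @param D A [distance_matrix()] or symmetric matrix.
#' @param tree Optional precomputed [ward_linkage()] tree of `D`.
#' @param k_max Largest number of clusters evaluated.
#' @param n_surrogates Number of shuffled surrogates (default 20).
#' @param seed Integer seed; the curve is deterministic given it.
#' @return Object of class `gap_curve`: tibble-like list with `k`, `gap`,
#'   `log_w`, `log_w_surrogate`, and the argmax `k_hat` (smallest k on
#'   ties).
#' @export
gap_statistic <- function(D, tree = NULL, k_max = 20, n_surrogates = 20,
                          seed = 1) {
  V <- if (inherits(D, "distance_matrix")) D$values else as.matrix(D)
  n <- nrow(V)
  if (k_max >= n) stop_contract("k_max must be below the number of units")
  if (n_surrogates < 2) stop_contract("need at least 2 surrogates")
  if (is.null(tree)) tree <- ward_linkage(D)
  ks <- seq_len(k_max)
  log_w <- vapply(ks, function(k) {
    log(max(within_dispersion(V, cut_tree(tree, k)), .Machine$double.eps))
  }, 0)
  ut <- upper.tri(V)
  surro <- with_seed(seed, {
    vapply(seq_len(n_surrogates), function(s) {
      Vs <- matrix(0, n, n)
      Vs[ut] <- sample(V[ut])
      Vs <- Vs + t(Vs)
      ts <- ward_linkage(Vs)
      vapply(ks, function(k) {
        log(max(within_dispersion(Vs, cut_tree(ts, k)),
                .Machine$double.eps))
      }, 0)
    }, numeric(k_max))
  })
  gap <- rowMeans(surro) - log_w
  structure(list(k = ks, gap = gap, log_w = log_w,
                 log_w_surrogate = rowMeans(surro),
                 k_hat = ks[which.max(gap)]),
            class = "gap_curve")
}

#' @export
print.gap_curve <- function(x, ...) {
  cat(sprintf("<gap_curve: k = 1..%d, k_hat = %d>\n",
              max(x$k), x$k_hat))
  invisible(x)
}

#' Cross-metric consensus curve (adjusted mutual information)
#'
#' Clusters two distance matrices over the same units independently (Ward),
#' cuts both at each `k`, and scores the agreement of the two flat
#' partitions with adjusted mutual information. The location of the AMI
#' peak is a consensus estimate of the number of clusters supported by both
#' metrics (or both stimuli).
#'
#' @param D1,D2 [distance_matrix()] objects over identical unit ids.
#' @param k_range Integer vector of cluster numbers to evaluate.
#' @return List with `k`, `ami` and the argmax `k_hat` (smallest on ties).
#' @export
consensus_ami_curve <- function(D1, D2, k_range = 2:20) {
  stopifnot(inherits(D1, "distance_matrix"), inherits(D2, "distance_matrix"))
  if (!identical(D1$unit_ids, D2$unit_ids)) {
    stop_contract("distance matrices must cover identical unit ids")
  }
  t1 <- ward_linkage(D1)
  t2 <- ward_linkage(D2)
  ami <- vapply(k_range, function(k) {
    ami_score(cut_tree(t1, k), cut_tree(t2, k))
  }, 0)
  list(k = k_range, ami = ami, k_hat = k_range[which.max(ami)])
}
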