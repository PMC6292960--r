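block_matrix <- function(sizes, within = 0.01, between = 1.0, noise = 0,
                         seed = 1) {
  n <- sum(sizes)
  labels <- rep(seq_along(sizes), sizes)
  V <- matrix(between, n, n)
  for (g in seq_along(sizes)) {
    idx <- which(labels == g)
    V[idx, idx] <- within
  }
  if (noise > 0) {
    set.seed(seed)
    E <- matrix(runif(n * n, 0, noise), n, n)
    V <- V + (E + t(E)) / 2
  }
  diag(V) <- 0
  rownames(V) <- colnames(V) <- sprintf("u%03d", seq_len(n))
  list(V = V, labels = labels)
}

test_that("ward linkage merges well-separated blocks first", {
  bm <- block_matrix(c(10, 10))
  tree <- ward_linkage(bm$V)
  expect_equal(tree$n_leaves, 20)
  # the first n - 2 merges stay within blocks: heights of all but the last
  # merge are far below the between-block scale
  h <- tree$hclust$height
  expect_true(all(h[1:18] < 0.5))
  expect_gt(h[19], 0.5)
  # flat cut at 2 recovers the construction exactly
  labs <- cut_tree(tree, 2)
  expect_equal(ari_score(bm$labels, labs), 1)
})

test_that("cut_tree spans singletons to one cluster with nested partitions", {
  bm <- block_matrix(c(5, 5, 5), noise = 0.2)
  tree <- ward_linkage(bm$V)
  expect_equal(length(unique(cut_tree(tree, 1))), 1)
  expect_equal(length(unique(cut_tree(tree, 15))), 15)
  for (k in 2:14) {
    expect_equal(length(unique(cut_tree(tree, k))), k)
    # refinement: the k-partition refines the (k-1)-partition
    fine <- cut_tree(tree, k)
    coarse <- cut_tree(tree, k - 1)
    expect_true(all(tapply(coarse, fine, function(v) length(unique(v))) == 1))
  }
  expect_error(cut_tree(tree, 0), "k must")
  expect_error(cut_tree(tree, 16), "k must")
})

test_that("two units merge at a single node", {
  V <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  tree <- ward_linkage(V)
  expect_equal(length(tree$hclust$height), 1)
  expect_equal(length(unique(cut_tree(tree, 2))), 2)
})

test_that("permuting unit order yields equivalent flat cuts", {
  bm <- block_matrix(c(6, 6, 6), noise = 0.3, seed = 2)
  perm <- sample(18)
  t1 <- ward_linkage(bm$V)
  t2 <- ward_linkage(bm$V[perm, perm])
  l1 <- cut_tree(t1, 3)
  l2 <- cut_tree(t2, 3)[rownames(bm$V)]
  expect_equal(ari_score(l1, l2), 1)
})

test_that("gap statistic finds a planted five-block structure", {
  bm <- block_matrix(c(12, 12, 12, 12, 12), within = 0.02, between = 1,
                     noise = 0.05, seed = 3)
  gc <- gap_statistic(bm$V, k_max = 10, n_surrogates = 10, seed = 4)
  expect_equal(gc$k_hat, 5)
  # deterministic given the seed
  gc2 <- gap_statistic(bm$V, k_max = 10, n_surrogates = 10, seed = 4)
  expect_identical(gc$gap, gc2$gap)
})

test_that("gap curve is flat for structureless matrices", {
  set.seed(8)
  n <- 40
  E <- matrix(runif(n * n, 0.5, 1), n, n)
  V <- (E + t(E)) / 2
  diag(V) <- 0
  gc <- gap_statistic(V, k_max = 8, n_surrogates = 10, seed = 5)
  # no pronounced structure: every gap value stays small
  expect_lt(max(gc$gap), 0.25)
})

test_that("consensus AMI curve is 1 on itself and ~0 for independent noise", {
  bm <- block_matrix(c(10, 10, 10), noise = 0.2, seed = 6)
  D <- rgcclust:::new_distance_matrix(rownames(bm$V), bm$V)
  cc <- consensus_ami_curve(D, D, k_range = 2:8)
  expect_true(all(cc$ami > 1 - 1e-9))

  mkrand <- function(s) {
    set.seed(s)
    n <- 200
    E <- matrix(runif(n * n), n, n)
    V <- (E + t(E)) / 2
    diag(V) <- 0
    rgcclust:::new_distance_matrix(sprintf("r%03d", 1:n), V)
  }
  cc2 <- consensus_ami_curve(mkrand(1), mkrand(2), k_range = c(4, 8))
  expect_true(all(abs(cc2$ami) < 0.1))

  # noisy copies of a planted 8-block structure peak at or next to k = 8
  mk8 <- function(s) {
    bm <- block_matrix(rep(10, 8), within = 0.05, between = 1,
                       noise = 0.35, seed = s)
    rgcclust:::new_distance_matrix(rownames(bm$V), bm$V)
  }
  cc3 <- consensus_ami_curve(mk8(3), mk8(4), k_range = 2:16)
  expect_true(abs(cc3$k_hat - 8) <= 1)

  # mismatched ids are a contract error
  expect_error(consensus_ami_curve(D, mkrand(1), k_range = 2:4),
               "identical unit ids")
})
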