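# External clustering quality scores, computed from the contingency table
# of a true and a predicted labeling. Conventions for degenerate inputs
# follow the standard machine-learning definitions: when both partitions
# are trivial (a single class and a single cluster) the partitions are
# identical and every score is 1; a conditional entropy with an empty
# marginal entropy is taken as perfect (homogeneity/completeness 1).

contingency_table <- function(true, pred) {
  stopifnot(length(true) == length(pred))
  table(factor(true), factor(pred))
}

#' Adjusted Rand index
#'
#' Chance-corrected fraction of pairwise clustering decisions agreeing
#' between two labelings; 1 for identical partitions, ~0 for random ones.
#'
#' @param true,pred Label vectors of equal length.
#' @return Scalar ARI (at most 1; can be negative).
#' @export
ari_score <- function(true, pred) {
  ct <- contingency_table(true, pred)
  n <- sum(ct)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < .Machine$double.eps * 4) return(1)
  (sum_ij - expected) / (max_index - expected)
}

entropy_counts <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  -sum(counts / n * log(counts / n))
}

mutual_information <- function(ct) {
  n <- sum(ct)
  a <- unname(rowSums(ct))
  b <- unname(colSums(ct))
  mi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      nij <- ct[i, j]
      if (nij > 0) mi <- mi + nij / n * log(n * nij / (a[i] * b[j]))
    }
  }
  mi
}

# expected mutual information under the permutation (hypergeometric) model
expected_mutual_information <- function(ct) {
  n <- sum(ct)
  a <- unname(rowSums(ct))
  b <- unname(colSums(ct))
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      logp <- lchoose(bj, nij) + lchoose(n - bj, ai - nij) - lchoose(n, ai)
      emi <- emi + sum(nij / n * log(n * nij / (ai * bj)) * exp(logp))
    }
  }
  emi
}

#' Adjusted mutual information
#'
#' Mutual information between two labelings corrected for chance under the
#' permutation model and normalized by the arithmetic mean of the two
#' entropies: `(MI - E[MI]) / (mean(H_true, H_pred) - E[MI])`. 1 for
#' identical partitions, ~0 for independent ones.
#'
#' @param true,pred Label vectors of equal length.
#' @return Scalar AMI (at most 1).
#' @export
ami_score <- function(true, pred) {
  ct <- contingency_table(true, pred)
  hu <- entropy_counts(rowSums(ct))
  hv <- entropy_counts(colSums(ct))
  if (hu == 0 && hv == 0) return(1)
  mi <- mutual_information(ct)
  emi <- expected_mutual_information(ct)
  denom <- (hu + hv) / 2 - emi
  if (abs(denom) < .Machine$double.eps * 4) {
    return(if (abs(mi - emi) < .Machine$double.eps * 4) 0 else 1)
  }
  (mi - emi) / denom
}

#' Homogeneity, completeness and V-measure
#'
#' Entropy-based scores: completeness is 1 when all members of each true
#' class fall into a single predicted cluster (even if several classes
#' share one cluster); homogeneity is its dual; the V-measure is their
#' harmonic mean.
#'
#' @param true,pred Label vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
completeness_score <- function(true, pred) {
  ct <- contingency_table(true, pred)
  hv <- entropy_counts(colSums(ct))
  if (hv == 0) return(1)
  hvu <- hv - mutual_information(ct)
  1 - hvu / hv
}

#' @rdname completeness_score
#' @export
homogeneity_score <- function(true, pred) {
  completeness_score(pred, true)
}

#' @rdname completeness_score
#' @export
v_measure_score <- function(true, pred) {
  h <- homogeneity_score(true, pred)
  c <- completeness_score(true, pred)
  if (h + c == 0) return(0)
  2 * h * c / (h + c)
}

#' Fowlkes-Mallows score
#'
#' Geometric mean of pairwise precision and recall between two labelings.
#'
#' @param true,pred Label vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
fowlkes_mallows_score <- function(true, pred) {
  ct <- contingency_table(true, pred)
  n <- sum(ct)
  tp <- sum(ct^2) - n
  pa <- sum(rowSums(ct)^2) - n   # 2 * (TP + FN)
  pb <- sum(colSums(ct)^2) - n   # 2 * (TP + FP)
  if (pa == 0 || pb == 0) {
    return(if (pa == 0 && pb == 0) 1 else 0)
  }
  tp / sqrt(pa * pb)
}

#' External clustering quality report
#'
#' Computes the adjusted Rand index, adjusted mutual information,
#' V-measure, completeness and Fowlkes-Mallows scores of a predicted
#' labeling against ground truth, optionally restricted to a subset of
#' units (e.g. the noise-free "good" units), plus the median of the four
#' scores used for figure-level summaries (ARI, AMI, V-measure, FM).
#'
#' @param true,pred Label vectors of equal length. Named vectors are
#'   matched by name.
#' @param restrict_to Optional logical mask (or vector of names/indices)
#'   selecting the units to score.
#' @return Object of class `quality_report`: named list with `ari`, `ami`,
#'   `v_measure`, `completeness`, `fowlkes_mallows`, `median_score`.
#' @export
quality_scores <- function(true, pred, restrict_to = NULL) {
  if (!is.null(names(true)) && !is.null(names(pred))) {
    if (!setequal(names(true), names(pred))) {
      stop_contract("true and pred labels cover different units")
    }
    pred <- pred[names(true)]
  }
  if (length(true) != length(pred)) {
    stop_contract("label vectors must have equal length")
  }
  if (!is.null(restrict_to)) {
    if (is.logical(restrict_to)) {
      stopifnot(length(restrict_to) == length(true))
      true <- true[restrict_to]
      pred <- pred[restrict_to]
    } else {
      true <- true[restrict_to]
      pred <- pred[restrict_to]
    }
  }
  rep <- list(ari = unname(ari_score(true, pred)),
              ami = unname(ami_score(true, pred)),
              v_measure = unname(v_measure_score(true, pred)),
              completeness = unname(completeness_score(true, pred)),
              fowlkes_mallows = unname(fowlkes_mallows_score(true, pred)))
  rep$median_score <- median(c(rep$ari, rep$ami, rep$v_measure,
                               rep$fowlkes_mallows))
  structure(rep, class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(
    "<quality_report: ARI %.3f, AMI %.3f, V %.3f, completeness %.3f, FM %.3f; median %.3f>\n",
    x$ari, x$ami, x$v_measure, x$completeness, x$fowlkes_mallows,
    x$median_score))
  invisible(x)
}
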