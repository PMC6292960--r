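#' Time-resolved distance profiles between two spike trains
#'
#' `isi_profile()` returns the signed instantaneous ISI-distance profile:
#' at every time `t` the ratio of the two trains' instantaneous inter-spike
#' intervals, `vISIx/vISIy - 1` when `vISIx <= vISIy` and the negated
#' reciprocal ratio otherwise, which is antisymmetric under swapping the
#' trains and bounded in `(-1, 1)`. The profile is piecewise constant
#' between spike events.
#'
#' `spike_profile()` returns the SPIKE-distance profile: the absolute
#' offsets between the two trains' preceding and following spikes, each
#' weighted by the mean distance to the other pair and normalized by the
#' squared mean local inter-spike interval, so that spikes close together
#' in time dominate. Piecewise linear between events, nonnegative, and
#' symmetric under swapping the trains.
#'
#' Both profiles use auxiliary spikes at the interval boundaries so that
#' edge intervals (before the first and after the last spike) and empty
#' trains are well defined.
#'
#' @param x,y [spike_train()] objects sharing one observation interval.
#' @return An object of class `distance_profile`: `times`, `values`,
#'   `interval`, and `kind` (`"step"` for piecewise constant, `"linear"`
#'   for piecewise linear with doubled breakpoints at discontinuities).
#' @seealso [isi_distance()], [spike_distance()], [profile_average()]
#' @export
isi_profile <- function(x, y) {
  check_same_interval(x, y)
  p <- isi_profile_cpp(x$times, y$times, x$interval_start, x$interval_end)
  structure(list(times = p$times, values = p$values,
                 interval = c(x$interval_start, x$interval_end),
                 kind = "step"),
            class = "distance_profile")
}

#' @rdname isi_profile
#' @export
spike_profile <- function(x, y) {
  check_same_interval(x, y)
  p <- spike_profile_cpp(x$times, y$times, x$interval_start, x$interval_end)
  structure(list(times = p$times, values = p$values,
                 interval = c(x$interval_start, x$interval_end),
                 kind = "linear"),
            class = "distance_profile")
}

#' Time-weighted average of a distance profile
#'
#' Integrates `|profile|` exactly over its interval (piecewise-constant
#' segments directly; piecewise-linear segments by the trapezoid rule with
#' zero crossings split) and divides by the interval length.
#'
#' @param profile A `distance_profile`.
#' @return Scalar average in `[0, 1]`.
#' @export
profile_average <- function(profile) {
  stopifnot(inherits(profile, "distance_profile"))
  a <- profile$interval[1]
  b <- profile$interval[2]
  if (profile$kind == "step") {
    len <- diff(profile$times)
    return(sum(abs(profile$values) * len) / (b - a))
  }
  # linear kind: values at segment endpoints, times come in (t0, t1) pairs
  acc <- 0
  tt <- profile$times
  vv <- profile$values
  for (i in seq(1, length(tt) - 1, by = 2)) {
    t0 <- tt[i]; t1 <- tt[i + 1]
    v0 <- vv[i]; v1 <- vv[i + 1]
    if (t1 <= t0) next
    if (v0 * v1 >= 0) {
      acc <- acc + 0.5 * (abs(v0) + abs(v1)) * (t1 - t0)
    } else {
      tc <- t0 + (t1 - t0) * abs(v0) / (abs(v0) + abs(v1))
      acc <- acc + 0.5 * abs(v0) * (tc - t0) + 0.5 * abs(v1) * (t1 - tc)
    }
  }
  acc / (b - a)
}

#' Scalar ISI and SPIKE distances
#'
#' Time-weighted averages of the absolute distance profiles: dimensionless
#' dissimilarities in `[0, 1]`, zero exactly for identical trains,
#' symmetric in the two trains.
#'
#' @param x,y [spike_train()] objects sharing one observation interval.
#' @return Scalar distance in `[0, 1]`.
#' @examples
#' a <- spike_train(seq(1, 19, by = 1), 0, 20)
#' b <- spike_train(seq(2, 18, by = 2), 0, 20)
#' isi_distance(a, b)  # ~0.5: constant ISI ratio 1:2
#' @export
isi_distance <- function(x, y) {
  check_same_interval(x, y)
  isi_distance_cpp(x$times, y$times, x$interval_start, x$interval_end)
}

#' @rdname isi_distance
#' @export
spike_distance <- function(x, y) {
  check_same_interval(x, y)
  spike_distance_cpp(x$times, y$times, x$interval_start, x$interval_end)
}

#' Trial-averaged distance between two units
#'
#' Mean of the chosen scalar spike-train distance over all cross-unit trial
#' pairs (every trial of `a` against every trial of `b`) for one stimulus.
#'
#' @param a,b [unit_record()] objects carrying trials for `stimulus`.
#' @param stimulus Stimulus name.
#' @param metric `"isi"` or `"spike"`.
#' @return Scalar dissimilarity.
#' @export
unit_pair_distance <- function(a, b, stimulus, metric = c("spike", "isi")) {
  metric <- match.arg(metric)
  stopifnot(inherits(a, "unit_record"), inherits(b, "unit_record"))
  for (u in list(a, b)) {
    if (is.null(u$trials[[stimulus]]) || length(u$trials[[stimulus]]) == 0) {
      stop_contract("unit %s has no trials for stimulus '%s'",
                    u$unit_id, stimulus)
    }
  }
  ta <- a$trials[[stimulus]]
  tb <- b$trials[[stimulus]]
  check_same_interval(ta[[1]], tb[[1]])
  trial_mean_distance_cpp(lapply(ta, `[[`, "times"),
                          lapply(tb, `[[`, "times"),
                          ta[[1]]$interval_start, ta[[1]]$interval_end,
                          metric)
}

#' Unit-by-unit spike-train distance matrix
#'
#' Symmetric matrix of trial-averaged pairwise distances
#' ([unit_pair_distance()]) between all units of a dataset for one
#' stimulus, the input of the hierarchical clustering step.
#'
#' @param dataset A [recording_dataset()] with at least two units, each
#'   carrying trials for `stimulus` on a common observation interval.
#' @param stimulus Stimulus name.
#' @param metric `"isi"` or `"spike"`.
#' @return Object of class `distance_matrix`: `unit_ids`, `values` (n x n
#'   symmetric, zero diagonal), `metric`, `stimulus`.
#' @export
distance_matrix <- function(dataset, stimulus, metric = c("spike", "isi")) {
  metric <- match.arg(metric)
  stopifnot(inherits(dataset, "recording_dataset"))
  if (n_units(dataset) < 2) stop_contract("need at least 2 units")
  ids <- unit_ids(dataset)
  trains <- lapply(dataset$units, function(u) {
    tr <- u$trials[[stimulus]]
    if (is.null(tr) || length(tr) == 0) {
      stop_contract("unit %s has no trials for stimulus '%s'",
                    u$unit_id, stimulus)
    }
    tr
  })
  ref <- trains[[1]][[1]]
  for (tr in trains) check_same_interval(ref, tr[[1]])
  V <- distance_matrix_cpp(lapply(trains, lapply, `[[`, "times"),
                           ref$interval_start, ref$interval_end, metric)
  dimnames(V) <- list(ids, ids)
  new_distance_matrix(ids, V, metric, stimulus)
}

new_distance_matrix <- function(ids, values, metric = NA_character_,
                                stimulus = NA_character_) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values) ||
      max(abs(values - t(values))) > 1e-12 || any(values < 0) ||
      any(abs(diag(values)) > 1e-12)) {
    stop_contract("distance matrix must be symmetric, nonnegative, zero-diagonal")
  }
  structure(list(unit_ids = ids, values = values, metric = metric,
                 stimulus = stimulus),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix: %d units, metric = %s, stimulus = %s>\n",
              length(x$unit_ids), x$metric, x$stimulus))
  invisible(x)
}

#' Read/write a distance matrix as CSV
#'
#' The CSV has unit ids as header and row names; metric and stimulus are
#' stored in a `#`-comment first line.
#'
#' @param D A `distance_matrix`.
#' @param path CSV file path.
#' @export
write_distance_matrix <- function(D, path) {
  stopifnot(inherits(D, "distance_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# metric=%s stimulus=%s", D$metric, D$stimulus), con)
  df <- as.data.frame(apply(D$values, 2, format_double))
  names(df) <- D$unit_ids
  df <- cbind(unit_id = D$unit_ids, df)
  write.csv(df, con, row.names = FALSE)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  header <- readLines(path, n = 1)
  meta <- regmatches(header,
                     regexec("# metric=(\\S+) stimulus=(\\S+)", header))[[1]]
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  ids <- as.character(df$unit_id)
  V <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(V) <- "double"
  dimnames(V) <- list(ids, ids)
  new_distance_matrix(ids, V, meta[2], meta[3])
}
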