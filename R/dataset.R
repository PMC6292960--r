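#' Recorded unit with trial-tagged spike trains
#'
#' One sorted unit: its identifier, spatial position on the array, the
#' spatial spike-location fit metadata produced upstream by spike sorting
#' (ellipse axes and eccentricity), and its spike trains organized as
#' stimulus name -> list of trials. All trials under one stimulus must share
#' the same interval length (within `interval_tol` seconds).
#'
#' @param unit_id Character scalar, unique within a dataset.
#' @param location Numeric `(x, y)` position in micrometers.
#' @param fit_axes Numeric `(a, b)` ellipse axes of the spatial spike-location
#'   fit, micrometers.
#' @param eccentricity Ellipse eccentricity in `[0, 1)`.
#' @param trials Named list: stimulus name -> list of [spike_train()].
#' @param interval_tol Tolerance (s) for equal trial interval lengths;
#'   defaults to one millisecond sample step.
#' @return An object of class `unit_record`.
#' @export
unit_record <- function(unit_id, location = c(NA_real_, NA_real_),
                        fit_axes = c(NA_real_, NA_real_),
                        eccentricity = NA_real_, trials = list(),
                        interval_tol = 1e-3) {
  if (!is.character(unit_id) || length(unit_id) != 1 || !nzchar(unit_id)) {
    stop_contract("unit_id must be a non-empty string")
  }
  if (length(location) != 2) stop_contract("location must be (x, y)")
  if (length(fit_axes) != 2) stop_contract("fit_axes must be (a, b)")
  if (!is.na(eccentricity) && (eccentricity < 0 || eccentricity >= 1)) {
    stop_contract("eccentricity must lie in [0, 1) (unit %s)", unit_id)
  }
  if (length(trials) > 0 &&
      (is.null(names(trials)) || any(!nzchar(names(trials))))) {
    stop_contract("trials must be a named list (stimulus name -> trials)")
  }
  for (stim in names(trials)) {
    tr <- trials[[stim]]
    if (!is.list(tr) || !all(vapply(tr, inherits, TRUE, "spike_train"))) {
      stop_contract("trials for stimulus '%s' of unit %s must be spike_train objects",
                    stim, unit_id)
    }
    if (length(tr) > 1) {
      lens <- vapply(tr, train_duration, 0)
      if (max(lens) - min(lens) > interval_tol) {
        stop_contract("trials of unit %s under stimulus '%s' differ in interval length",
                      unit_id, stim)
      }
    }
  }
  structure(list(unit_id = unit_id,
                 location = as.numeric(location),
                 fit_axes = as.numeric(fit_axes),
                 eccentricity = as.numeric(eccentricity),
                 trials = trials),
            class = "unit_record")
}

#' Recording dataset: units, stimuli, optional ground truth
#'
#' Container tying together the recorded (or simulated) units, the stimulus
#' profiles they were driven with, optional ground-truth type labels (for
#' synthetic data), an optional per-unit noise-model flag kept separate from
#' the type label, and free-form provenance metadata.
#'
#' @param units List of [unit_record()] with unique `unit_id`s.
#' @param stimuli Named list of [stimulus_profile()].
#' @param ground_truth_labels Optional named character vector
#'   (unit_id -> type label) covering every unit.
#' @param noise_models Optional named character vector (unit_id -> noise
#'   model name) flagging contaminated units; may cover a subset.
#' @param provenance Free-form list of metadata.
#' @return An object of class `recording_dataset`.
#' @export
recording_dataset <- function(units, stimuli = list(),
                              ground_truth_labels = NULL,
                              noise_models = NULL,
                              provenance = list()) {
  if (!is.list(units) || !all(vapply(units, inherits, TRUE, "unit_record"))) {
    stop_contract("units must be a list of unit_record objects")
  }
  ids <- vapply(units, function(u) u$unit_id, "")
  if (anyDuplicated(ids)) {
    stop_contract("unit ids must be unique (duplicate: %s)",
                  ids[duplicated(ids)][1])
  }
  if (!is.null(ground_truth_labels)) {
    if (is.null(names(ground_truth_labels)) ||
        !all(ids %in% names(ground_truth_labels))) {
      stop_contract("ground_truth_labels must cover every unit")
    }
    ground_truth_labels <- ground_truth_labels[ids]
  }
  if (!is.null(noise_models)) {
    if (length(noise_models) > 0 && !all(names(noise_models) %in% ids)) {
      stop_contract("noise_models must refer to units present in the dataset")
    }
  }
  structure(list(units = units, stimuli = stimuli,
                 ground_truth_labels = ground_truth_labels,
                 noise_models = noise_models,
                 provenance = provenance),
            class = "recording_dataset")
}

#' @rdname recording_dataset
#' @param dataset A `recording_dataset`.
#' @export
unit_ids <- function(dataset) {
  vapply(dataset$units, function(u) u$unit_id, "")
}

#' @rdname recording_dataset
#' @export
n_units <- function(dataset) length(dataset$units)

#' @rdname recording_dataset
#' @export
good_unit_mask <- function(dataset) {
  ids <- unit_ids(dataset)
  setNames(!(ids %in% names(dataset$noise_models)), ids)
}

#' @export
print.recording_dataset <- function(x, ...) {
  cat(sprintf("<recording_dataset: %d units, stimuli: %s%s%s>\n",
              length(x$units), paste(names(x$stimuli), collapse = ", "),
              if (!is.null(x$ground_truth_labels)) ", labeled" else "",
              if (length(x$noise_models) > 0)
                sprintf(", %d noisy", length(x$noise_models)) else ""))
  invisible(x)
}

subset_dataset <- function(dataset, keep_ids) {
  keep <- vapply(dataset$units, function(u) u$unit_id %in% keep_ids, TRUE)
  labels <- dataset$ground_truth_labels
  if (!is.null(labels)) labels <- labels[names(labels) %in% keep_ids]
  noise <- dataset$noise_models
  if (!is.null(noise)) noise <- noise[names(noise) %in% keep_ids]
  recording_dataset(dataset$units[keep], dataset$stimuli, labels, noise,
                    dataset$provenance)
}

#' Unit-selection heuristics for sorted MEA units
#'
#' Filters poorly localized or weakly responsive units before clustering.
#' A unit is retained when all of the following hold: eccentricity of the
#' spatial spike-location fit strictly below `ecc_max`; mean of the two fit
#' axes strictly below `axis_max` (17% of the 42 um channel pitch by
#' default); the unit's electrode row (derived from its y position and the
#' row pitch) not among the excluded border rows; and at least
#' `min_spikes_per_trial` spikes in every trial of the reference stimulus.
#'
#' Selection is idempotent and never modifies spike times.
#'
#' @param dataset A [recording_dataset()].
#' @param ecc_max Eccentricity threshold (strict `<`), default 0.85.
#' @param axis_max Mean fit-axis threshold in micrometers (strict `<`),
#'   default 7.14.
#' @param min_spikes_per_trial Minimum spikes required in every trial of
#'   `stimulus`, default 10.
#' @param excluded_rows Integer row indices removed from the array border
#'   (default the two outer rows on each edge of a 64-row array).
#' @param row_pitch Electrode row pitch in micrometers, default 42.
#' @param stimulus Reference stimulus name, default `"chirp"`.
#' @return The filtered `recording_dataset`.
#' @export
select_units <- function(dataset, ecc_max = 0.85, axis_max = 7.14,
                         min_spikes_per_trial = 10,
                         excluded_rows = c(0L, 1L, 62L, 63L),
                         row_pitch = 42, stimulus = "chirp") {
  stopifnot(inherits(dataset, "recording_dataset"))
  keep <- vapply(dataset$units, function(u) {
    if (is.null(u$trials[[stimulus]])) {
      stop_contract("unit %s has no trials for stimulus '%s'",
                    u$unit_id, stimulus)
    }
    row <- as.integer(round(u$location[2] / row_pitch))
    counts <- vapply(u$trials[[stimulus]], n_spikes, 0L)
    !is.na(u$eccentricity) && u$eccentricity < ecc_max &&
      mean(u$fit_axes) < axis_max &&
      !(row %in% excluded_rows) &&
      all(counts >= min_spikes_per_trial)
  }, TRUE)
  subset_dataset(dataset, unit_ids(dataset)[keep])
}
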