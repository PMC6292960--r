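# On-disk dataset layout: a directory of plain CSV/JSON files, lossless for
# spike times at double precision (numbers serialized with 17 significant
# digits).
#
#   units.csv     unit_id, x, y, axis_a, axis_b, eccentricity
#   trials.csv    unit_id, stimulus, trial, interval_start_s, interval_end_s
#   spikes.csv    unit_id, stimulus, trial, spike_time_s
#   stimuli.csv   stimulus, dt, sample_index, value
#   segments.csv  stimulus, label, start_s, end_s
#   labels.csv    unit_id, label              (optional, ground truth)
#   noise.csv     unit_id, noise_model        (optional)
#   provenance.json                           (optional)
#
# All times are in seconds, aligned to stimulus onset at t = 0.

require_columns <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop_contract("file %s is missing required column(s): %s",
                  file, paste(miss, collapse = ", "))
  }
}

#' Write a dataset to a directory of CSV files
#'
#' Serializes a [recording_dataset()] (units, trial intervals, spike
#' times, stimulus traces and segments, optional ground-truth labels,
#' noise flags and provenance) to plain CSV/JSON files that
#' [read_dataset()] restores losslessly.
#'
#' @param dataset A [recording_dataset()].
#' @param path Directory path (created if needed).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "recording_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop_contract("cannot create directory %s", path)

  units_df <- do.call(rbind, lapply(dataset$units, function(u) {
    data.frame(unit_id = u$unit_id,
               x = format_double(u$location[1]),
               y = format_double(u$location[2]),
               axis_a = format_double(u$fit_axes[1]),
               axis_b = format_double(u$fit_axes[2]),
               eccentricity = format_double(u$eccentricity))
  }))
  if (is.null(units_df)) {
    units_df <- data.frame(unit_id = character(0), x = character(0),
                           y = character(0), axis_a = character(0),
                           axis_b = character(0),
                           eccentricity = character(0))
  }
  write.csv(units_df, file.path(path, "units.csv"), row.names = FALSE)

  trials_rows <- list()
  spikes_rows <- list()
  for (u in dataset$units) {
    for (stim in names(u$trials)) {
      for (k in seq_along(u$trials[[stim]])) {
        st <- u$trials[[stim]][[k]]
        trials_rows[[length(trials_rows) + 1]] <- data.frame(
          unit_id = u$unit_id, stimulus = stim, trial = k,
          interval_start_s = format_double(st$interval_start),
          interval_end_s = format_double(st$interval_end))
        if (n_spikes(st) > 0) {
          spikes_rows[[length(spikes_rows) + 1]] <- data.frame(
            unit_id = u$unit_id, stimulus = stim, trial = k,
            spike_time_s = format_double(st$times))
        }
      }
    }
  }
  empty_trials <- data.frame(unit_id = character(0), stimulus = character(0),
                             trial = integer(0),
                             interval_start_s = character(0),
                             interval_end_s = character(0))
  empty_spikes <- data.frame(unit_id = character(0), stimulus = character(0),
                             trial = integer(0), spike_time_s = character(0))
  write.csv(if (length(trials_rows)) do.call(rbind, trials_rows) else empty_trials,
            file.path(path, "trials.csv"), row.names = FALSE)
  write.csv(if (length(spikes_rows)) do.call(rbind, spikes_rows) else empty_spikes,
            file.path(path, "spikes.csv"), row.names = FALSE)

  stim_rows <- lapply(names(dataset$stimuli), function(nm) {
    s <- dataset$stimuli[[nm]]
    data.frame(stimulus = nm, dt = format_double(s$dt),
               sample_index = seq_along(s$trace),
               value = format_double(s$trace))
  })
  empty_stim <- data.frame(stimulus = character(0), dt = character(0),
                           sample_index = integer(0), value = character(0))
  write.csv(if (length(stim_rows)) do.call(rbind, stim_rows) else empty_stim,
            file.path(path, "stimuli.csv"), row.names = FALSE)
  seg_rows <- lapply(names(dataset$stimuli), function(nm) {
    s <- dataset$stimuli[[nm]]$segments
    data.frame(stimulus = nm, label = s$label,
               start_s = format_double(s$start),
               end_s = format_double(s$end))
  })
  empty_seg <- data.frame(stimulus = character(0), label = character(0),
                          start_s = character(0), end_s = character(0))
  write.csv(if (length(seg_rows)) do.call(rbind, seg_rows) else empty_seg,
            file.path(path, "segments.csv"), row.names = FALSE)

  if (!is.null(dataset$ground_truth_labels)) {
    write.csv(data.frame(unit_id = names(dataset$ground_truth_labels),
                         label = unname(dataset$ground_truth_labels)),
              file.path(path, "labels.csv"), row.names = FALSE)
  }
  if (length(dataset$noise_models) > 0) {
    write.csv(data.frame(unit_id = names(dataset$noise_models),
                         noise_model = unname(dataset$noise_models)),
              file.path(path, "noise.csv"), row.names = FALSE)
  }
  if (length(dataset$provenance) > 0) {
    jsonlite::write_json(dataset$provenance,
                         file.path(path, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a dataset from a directory of CSV files
#'
#' Restores a [recording_dataset()] written by [write_dataset()]; all
#' invariants (strictly increasing spike times within intervals, unique
#' unit ids, label coverage) are re-checked on load, and validation errors
#' name the offending unit and trial.
#'
#' @param path Directory path.
#' @return A [recording_dataset()].
#' @export
read_dataset <- function(path) {
  need <- c("units.csv", "trials.csv", "spikes.csv", "stimuli.csv",
            "segments.csv")
  for (f in need) {
    if (!file.exists(file.path(path, f))) {
      stop_contract("dataset at %s is missing required file %s", path, f)
    }
  }
  units_df <- read.csv(file.path(path, "units.csv"),
                       colClasses = c(unit_id = "character"))
  require_columns(units_df, c("unit_id", "x", "y", "axis_a", "axis_b",
                              "eccentricity"), "units.csv")
  trials_df <- read.csv(file.path(path, "trials.csv"),
                        colClasses = c(unit_id = "character"))
  require_columns(trials_df, c("unit_id", "stimulus", "trial",
                               "interval_start_s", "interval_end_s"),
                  "trials.csv")
  spikes_df <- read.csv(file.path(path, "spikes.csv"),
                        colClasses = c(unit_id = "character"))
  require_columns(spikes_df, c("unit_id", "stimulus", "trial",
                               "spike_time_s"), "spikes.csv")
  stim_df <- read.csv(file.path(path, "stimuli.csv"))
  require_columns(stim_df, c("stimulus", "dt", "sample_index", "value"),
                  "stimuli.csv")
  seg_df <- read.csv(file.path(path, "segments.csv"))
  require_columns(seg_df, c("stimulus", "label", "start_s", "end_s"),
                  "segments.csv")

  stimuli <- list()
  for (nm in unique(stim_df$stimulus)) {
    rows <- stim_df[stim_df$stimulus == nm, ]
    rows <- rows[order(rows$sample_index), ]
    segs <- seg_df[seg_df$stimulus == nm, ]
    stimuli[[nm]] <- stimulus_profile(
      rows$value, rows$dt[1],
      data.frame(label = segs$label, start = segs$start_s,
                 end = segs$end_s))
  }

  spike_key <- paste(spikes_df$unit_id, spikes_df$stimulus, spikes_df$trial)
  units <- lapply(seq_len(nrow(units_df)), function(i) {
    uid <- units_df$unit_id[i]
    ut <- trials_df[trials_df$unit_id == uid, , drop = FALSE]
    trials <- list()
    for (stim in unique(ut$stimulus)) {
      us <- ut[ut$stimulus == stim, , drop = FALSE]
      trials[[stim]] <- lapply(seq_len(nrow(us)), function(r) {
        key <- paste(uid, stim, us$trial[r])
        tt <- spikes_df$spike_time_s[spike_key == key]
        tryCatch(
          spike_train(tt, us$interval_start_s[r], us$interval_end_s[r]),
          error = function(e) {
            stop_contract("invalid spike train for unit %s, stimulus %s, trial %d: %s",
                          uid, stim, us$trial[r], conditionMessage(e))
          })
      })
    }
    unit_record(uid, c(units_df$x[i], units_df$y[i]),
                c(units_df$axis_a[i], units_df$axis_b[i]),
                units_df$eccentricity[i], trials)
  })

  labels <- NULL
  if (file.exists(file.path(path, "labels.csv"))) {
    ldf <- read.csv(file.path(path, "labels.csv"),
                    colClasses = "character")
    require_columns(ldf, c("unit_id", "label"), "labels.csv")
    labels <- setNames(ldf$label, ldf$unit_id)
  }
  noise <- NULL
  if (file.exists(file.path(path, "noise.csv"))) {
    ndf <- read.csv(file.path(path, "noise.csv"), colClasses = "character")
    require_columns(ndf, c("unit_id", "noise_model"), "noise.csv")
    noise <- setNames(ndf$noise_model, ndf$unit_id)
  }
  prov <- list()
  if (file.exists(file.path(path, "provenance.json"))) {
    prov <- jsonlite::read_json(file.path(path, "provenance.json"),
                                simplifyVector = TRUE)
  }
  recording_dataset(units, stimuli, labels, noise, prov)
}
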