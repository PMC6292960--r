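#' Specification of a simulated population
#'
#' @param n_units Number of units to simulate.
#' @param type_fractions Named numeric vector over the eight base types
#'   (see [rgc_base_types()]), nonnegative and summing to 1. Default: equal.
#' @param rf_variation Relative SD of the Gaussian jitter applied to the
#'   kernel parameters `l` and `v`, as a fraction of each baseline value
#'   (e.g. 0.05-0.30). 0 disables jitter.
#' @param n_trials Trials per stimulus per unit (default 5).
#' @param seed Master integer seed.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(n_units, type_fractions = NULL,
                            rf_variation = 0.1, n_trials = 5, seed = 1) {
  type_names <- names(rgc_base_types())
  if (is.null(type_fractions)) {
    type_fractions <- setNames(rep(1 / 8, 8), type_names)
  }
  if (is.null(names(type_fractions)) ||
      !setequal(names(type_fractions), type_names)) {
    stop_contract("type_fractions must be named over the eight base types")
  }
  type_fractions <- type_fractions[type_names]
  if (any(type_fractions < 0) || abs(sum(type_fractions) - 1) > 1e-9) {
    stop_contract("type fractions must be nonnegative and sum to 1")
  }
  stopifnot(n_units >= 1, rf_variation >= 0, n_trials >= 1)
  structure(list(n_units = as.integer(n_units),
                 type_fractions = type_fractions,
                 rf_variation = rf_variation,
                 n_trials = as.integer(n_trials),
                 seed = as.integer(seed)),
            class = "population_spec")
}

# deterministic largest-remainder apportionment of n units to fractions
allocate_counts <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    # largest remainder first; ties broken by position in the type list
    extra <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Hierarchical apportionment over the factorial type structure
# (polarity, then kinetics, then transience): marginal percentages such as
# "70% ON" are met exactly, and each type's count differs from
# fraction * n by at most one unit.
allocate_type_counts <- function(fractions, n) {
  nms <- names(fractions)
  parts <- do.call(rbind, strsplit(nms, "_"))
  counts <- setNames(integer(length(fractions)), nms)
  split_level <- function(idx, n_here, level) {
    if (n_here == 0) return()
    if (level > ncol(parts) || length(idx) == 1) {
      # distribute within the remaining leaf set by plain largest remainder
      f <- fractions[idx]
      f <- if (sum(f) > 0) f / sum(f) else rep(1 / length(idx), length(idx))
      counts[idx] <<- counts[idx] + allocate_counts(f, n_here)
      return()
    }
    grp <- parts[idx, level]
    levels_here <- unique(grp)
    gf <- vapply(levels_here, function(g) sum(fractions[idx[grp == g]]), 0)
    gf <- if (sum(gf) > 0) gf / sum(gf) else rep(1 / length(gf), length(gf))
    gn <- allocate_counts(gf, n_here)
    for (gi in seq_along(levels_here)) {
      split_level(idx[grp == levels_here[gi]], gn[gi], level + 1)
    }
  }
  split_level(seq_along(fractions), n, 1)
  counts
}

# Gaussian jitter around a baseline, redrawn until positive
jitter_positive <- function(base, rel_sd) {
  if (rel_sd == 0) return(base)
  repeat {
    x <- rnorm(1, base, rel_sd * base)
    if (x > 0) return(x)
  }
}

#' Generate a ground-truth population of LNP units
#'
#' Allocates units to the eight base types by deterministic
#' largest-remainder apportionment of `type_fractions`, applied
#' hierarchically over the factorial type structure (polarity, kinetics,
#' transience) so that marginal percentages are met exactly (then shuffles
#' the unit order by seed), jitters each unit's kernel parameters `l` and `v` with a
#' positive-truncated Gaussian of relative SD `rf_variation`, and simulates
#' `n_trials` independent Poisson spike trains per stimulus per unit.
#' Ground-truth type labels are attached to the dataset. Unit metadata
#' (array location, spatial-fit axes and eccentricity) is synthesized so
#' that all units pass the default [select_units()] criteria.
#'
#' @param spec A [population_spec()].
#' @param stimuli Named list of [stimulus_profile()]; default one chirp.
#' @return A labeled [recording_dataset()].
#' @export
make_population <- function(spec, stimuli = list(chirp = chirp_stimulus())) {
  stopifnot(inherits(spec, "population_spec"), length(stimuli) >= 1)
  types <- rgc_base_types()
  counts <- allocate_type_counts(spec$type_fractions, spec$n_units)
  type_of <- rep(names(types), counts)
  type_of <- with_seed(derive_seed(spec$seed, 0L, 1L), sample(type_of))
  gains <- vapply(stimuli, function(s) kernel_gain(s$dt), 0)
  rates_cache <- new.env(parent = emptyenv())

  units <- vector("list", spec$n_units)
  for (i in seq_len(spec$n_units)) {
    tname <- type_of[i]
    base <- types[[tname]]
    meta_seed <- derive_seed(spec$seed, i, 2L)
    params <- with_seed(meta_seed, {
      cell_type_params(base$polarity,
                       jitter_positive(base$l, spec$rf_variation),
                       jitter_positive(base$v, spec$rf_variation),
                       base$r_min, base$r_max, base$c)
    })
    meta <- with_seed(derive_seed(spec$seed, i, 3L), {
      list(row = sample(4:59, 1), col = sample(4:59, 1),
           ecc = runif(1, 0, 0.5), axes = runif(2, 1, 5))
    })
    trials <- list()
    for (sname in names(stimuli)) {
      stim <- stimuli[[sname]]
      key <- if (spec$rf_variation == 0) paste(tname, sname) else NULL
      rate <- if (!is.null(key) && !is.null(rates_cache[[key]])) {
        rates_cache[[key]]
      } else {
        r <- lnp_rate(params, stim, gain = gains[[sname]])
        if (!is.null(key)) rates_cache[[key]] <- r
        r
      }
      trials[[sname]] <- lapply(seq_len(spec$n_trials), function(k) {
        poisson_spikes(rate, stim$dt,
                       seed = derive_seed(spec$seed, i, 10L + k +
                                            1000L * match(sname, names(stimuli))))
      })
    }
    units[[i]] <- unit_record(sprintf("u%04d", i),
                              location = c(meta$col, meta$row) * 42,
                              fit_axes = meta$axes,
                              eccentricity = meta$ecc,
                              trials = trials)
  }
  recording_dataset(
    units, stimuli,
    ground_truth_labels = setNames(type_of, sprintf("u%04d", seq_len(spec$n_units))),
    provenance = list(generator = "lnp",
                      kernel_gain = unname(gains[1]),
                      n_units = spec$n_units,
                      rf_variation = spec$rf_variation,
                      n_trials = spec$n_trials,
                      seed = spec$seed))
}

#' Specification of experimental-noise contamination
#'
#' Four noise models emulating imperfect spike detection and sorting:
#' (1) a homogeneous Poisson unit at a fixed rate (default 2 spikes/s),
#' (2) a homogeneous Poisson unit at a per-unit rate drawn uniformly from
#' `rate_range`, (3) random deletion of `removal_fraction` (default 70%) of
#' the unit's spikes across all trials (false negatives), and (4) merging
#' the unit's trains with those of a freshly simulated unit of a different
#' type (failed single-unit isolation).
#'
#' @param fraction_noisy Fraction of units replaced, in `[0, 1]`.
#' @param fixed_rate Rate of model (1), spikes/s.
#' @param rate_range Range of model (2) rates, spikes/s.
#' @param removal_fraction Deletion probability of model (3).
#' @param seed Integer seed.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(fraction_noisy, fixed_rate = 2,
                       rate_range = c(5, 30), removal_fraction = 0.7,
                       seed = 1) {
  if (fraction_noisy < 0 || fraction_noisy > 1) {
    stop_contract("fraction_noisy must lie in [0, 1]")
  }
  if (removal_fraction < 0 || removal_fraction > 1) {
    stop_contract("removal_fraction must lie in [0, 1]")
  }
  structure(list(fraction_noisy = fraction_noisy, fixed_rate = fixed_rate,
                 rate_range = rate_range,
                 removal_fraction = removal_fraction,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

.noise_model_names <- c("fixed_rate_poisson", "uniform_rate_poisson",
                        "spike_removal", "unit_merge")

homogeneous_poisson_trials <- function(template_trials, rate, seed) {
  lapply(seq_along(template_trials), function(k) {
    tr <- template_trials[[k]]
    nbins <- round(train_duration(tr) / 0.001)
    poisson_spikes(rep(rate, nbins), 0.001, seed = derive_seed(seed, k),
                   t0 = tr$interval_start)
  })
}

#' Contaminate a dataset with noisy units
#'
#' Replaces `round(fraction_noisy * n)` randomly picked units with one of
#' the four noise models of [noise_spec()], split as evenly as possible
#' across models. The ground-truth type label of a replaced unit is kept;
#' the contamination is recorded separately in the dataset's
#' `noise_models` flag so that evaluation can be restricted to the "good"
#' units.
#'
#' @param dataset A labeled [recording_dataset()].
#' @param noise A [noise_spec()].
#' @return The contaminated `recording_dataset`.
#' @export
apply_noise <- function(dataset, noise) {
  stopifnot(inherits(dataset, "recording_dataset"),
            inherits(noise, "noise_spec"))
  n <- n_units(dataset)
  n_noisy <- round(noise$fraction_noisy * n)
  if (n_noisy == 0) return(dataset)
  ids <- unit_ids(dataset)
  picked <- with_seed(derive_seed(noise$seed, 0L), sample(n, n_noisy))
  model <- .noise_model_names[((seq_len(n_noisy) - 1) %% 4) + 1]

  units <- dataset$units
  labels <- dataset$ground_truth_labels
  type_names <- names(rgc_base_types())
  for (j in seq_len(n_noisy)) {
    i <- picked[j]
    u <- units[[i]]
    useed <- derive_seed(noise$seed, i, 7L)
    new_trials <- switch(
      model[j],
      fixed_rate_poisson = mapply(function(tr, s) {
        homogeneous_poisson_trials(tr, noise$fixed_rate,
                                   seed = derive_seed(useed, s))
      }, u$trials, seq_along(u$trials), SIMPLIFY = FALSE),
      uniform_rate_poisson = {
        r <- with_seed(useed, runif(1, noise$rate_range[1], noise$rate_range[2]))
        mapply(function(tr, s) {
          homogeneous_poisson_trials(tr, r, seed = derive_seed(useed, s, 9L))
        }, u$trials, seq_along(u$trials), SIMPLIFY = FALSE)
      },
      spike_removal = with_seed(useed, {
        lapply(u$trials, function(tr) lapply(tr, function(st) {
          keep <- runif(n_spikes(st)) >= noise$removal_fraction
          spike_train(st$times[keep], st$interval_start, st$interval_end)
        }))
      }),
      unit_merge = {
        own <- if (!is.null(labels)) labels[[u$unit_id]] else type_names[1]
        other <- with_seed(useed, sample(setdiff(type_names, own), 1))
        op <- rgc_base_types()[[other]]
        merged <- u$trials
        for (sname in names(u$trials)) {
          stim <- dataset$stimuli[[sname]]
          if (is.null(stim)) next
          rate <- lnp_rate(op, stim)
          merged[[sname]] <- lapply(seq_along(u$trials[[sname]]), function(k) {
            st <- u$trials[[sname]][[k]]
            extra <- poisson_spikes(rate, stim$dt,
                                    seed = derive_seed(useed, k, 5L),
                                    t0 = st$interval_start)
            tt <- sort(unique(c(st$times, extra$times)))
            spike_train(tt, st$interval_start, st$interval_end)
          })
        }
        merged
      })
    units[[i]] <- unit_record(u$unit_id, u$location, u$fit_axes,
                              u$eccentricity, new_trials)
  }
  recording_dataset(units, dataset$stimuli, labels,
                    noise_models = setNames(model, ids[picked]),
                    provenance = c(dataset$provenance,
                                   list(noise_fraction = noise$fraction_noisy,
                                        noise_seed = noise$seed)))
}

#' Enumerate the ground-truth suite conditions
#'
#' The validation suite covers (a) a variation sweep: Gaussian
#' receptive-field parameter jitter of 5, 10, 15, 20 and 30% crossed with
#' population sizes (default 100, 200, 400 and 800 units, all eight types
#' equally frequent), and (b) an imbalance grid over type frequencies along
#' three axis pairs in 10% steps: %-ON 30-70 x %-fast 10-90 (transient
#' fixed at 50), %-ON 30-70 x %-transient 10-90 (fast fixed at 50) and
#' %-transient 30-70 x %-fast 10-90 (ON fixed at 50), enumerated without
#' deduplication (135 tuples).
#'
#' @param sizes Population sizes of the variation sweep.
#' @param variations Relative jitter levels of the variation sweep.
#' @param imbalance_n_units,imbalance_rf_variation Size and jitter level
#'   used for every imbalance dataset.
#' @return A tibble with one row per condition: `condition_id`, `kind`,
#'   `n_units`, `rf_variation`, `pct_on`, `pct_fast`, `pct_transient`.
#' @export
suite_conditions <- function(sizes = c(100, 200, 400, 800),
                             variations = c(0.05, 0.10, 0.15, 0.20, 0.30),
                             imbalance_n_units = 400,
                             imbalance_rf_variation = 0.10) {
  sweep <- expand.grid(rf_variation = variations, n_units = sizes)
  sweep$kind <- "variation"
  sweep$pct_on <- 50; sweep$pct_fast <- 50; sweep$pct_transient <- 50
  g1 <- expand.grid(pct_on = seq(30, 70, 10), pct_fast = seq(10, 90, 10))
  g1$pct_transient <- 50
  g2 <- expand.grid(pct_on = seq(30, 70, 10), pct_transient = seq(10, 90, 10))
  g2$pct_fast <- 50
  g3 <- expand.grid(pct_transient = seq(30, 70, 10), pct_fast = seq(10, 90, 10))
  g3$pct_on <- 50
  imb <- rbind(g1[c("pct_on", "pct_fast", "pct_transient")],
               g2[c("pct_on", "pct_fast", "pct_transient")],
               g3[c("pct_on", "pct_fast", "pct_transient")])
  imb$kind <- "imbalance"
  imb$n_units <- imbalance_n_units
  imb$rf_variation <- imbalance_rf_variation
  cols <- c("kind", "n_units", "rf_variation", "pct_on", "pct_fast",
            "pct_transient")
  out <- rbind(sweep[cols], imb[cols])
  out <- cbind(condition_id = seq_len(nrow(out)), out)
  tibble::as_tibble(out)
}

#' Type fractions from marginal percentages
#'
#' Converts marginal percentages of ON, fast and transient cells into the
#' eight per-type fractions under independence (e.g. the fraction of
#' ON-fast-transient cells is `p_on * p_fast * p_transient`).
#'
#' @param pct_on,pct_fast,pct_transient Marginal percentages in `[0, 100]`.
#' @return Named fractions over [rgc_base_types()], summing to 1.
#' @export
fractions_from_pcts <- function(pct_on, pct_fast, pct_transient) {
  p_on <- pct_on / 100; p_fast <- pct_fast / 100; p_tr <- pct_transient / 100
  types <- names(rgc_base_types())
  f <- vapply(types, function(nm) {
    parts <- strsplit(nm, "_")[[1]]
    (if (parts[1] == "on") p_on else 1 - p_on) *
      (if (parts[2] == "fast") p_fast else 1 - p_fast) *
      (if (parts[3] == "transient") p_tr else 1 - p_tr)
  }, 0)
  f / sum(f)
}

#' Materialize one suite condition as a dataset
#'
#' @param condition One row of [suite_conditions()].
#' @param seed Master seed; combined with the condition id.
#' @param n_trials Trials per unit.
#' @param stimuli Stimuli to simulate.
#' @return A labeled [recording_dataset()].
#' @export
make_suite_dataset <- function(condition, seed = 1, n_trials = 5,
                               stimuli = list(chirp = chirp_stimulus())) {
  fr <- fractions_from_pcts(condition$pct_on, condition$pct_fast,
                            condition$pct_transient)
  sp <- population_spec(condition$n_units, fr,
                        rf_variation = condition$rf_variation,
                        n_trials = n_trials,
                        seed = derive_seed(seed, condition$condition_id))
  ds <- make_population(sp, stimuli)
  ds$provenance$condition <- as.list(condition)
  ds
}

#' Generate the full ground-truth suite
#'
#' Materializes every row of `conditions` via [make_suite_dataset()].
#' With the full default condition grid and population sizes this is a
#' sizeable computation; pass a subset of conditions (or smaller sizes) for
#' reduced-scale runs.
#'
#' @param seed Master seed.
#' @param conditions Condition table, default [suite_conditions()].
#' @param n_trials Trials per unit.
#' @param stimuli Stimuli to simulate.
#' @return List of labeled datasets, one per condition row.
#' @export
make_suite <- function(seed = 1, conditions = suite_conditions(),
                       n_trials = 5,
                       stimuli = list(chirp = chirp_stimulus())) {
  lapply(seq_len(nrow(conditions)), function(i) {
    make_suite_dataset(conditions[i, ], seed = seed, n_trials = n_trials,
                       stimuli = stimuli)
  })
}

#' Shifted binary white-noise checkerboard movie
#'
#' Binary checkerboard frames for spike-triggered-average estimation. Each
#' frame is an independent random binary pattern on a coarse grid, rendered
#' at `upsample`-fold spatial resolution; when `shift` is enabled the
#' lattice of each frame is offset by a random sub-square shift, increasing
#' the effective spatial resolution of the STA.
#'
#' @param n_frames Number of frames.
#' @param grid Coarse grid size `(ny, nx)`, at least 2x2.
#' @param upsample Sub-squares per checker side (default 4).
#' @param shift Randomly offset the lattice each frame?
#' @param dt Frame duration, seconds (default 1/60).
#' @param seed Integer seed.
#' @return Object of class `stimulus_movie`: list with `frames` (array
#'   `n_frames x ny*upsample x nx*upsample`) and `dt`.
#' @export
white_noise_movie <- function(n_frames, grid = c(8, 8), upsample = 4,
                              shift = TRUE, dt = 1 / 60, seed = 1) {
  stopifnot(all(grid >= 2), n_frames >= 1, upsample >= 1)
  ny <- grid[1] * upsample
  nx <- grid[2] * upsample
  frames <- array(0, c(n_frames, ny, nx))
  with_seed(seed, {
    for (f in seq_len(n_frames)) {
      pat <- matrix(runif(grid[1] * grid[2]) < 0.5, grid[1], grid[2])
      img <- pat[rep(seq_len(grid[1]), each = upsample),
                 rep(seq_len(grid[2]), each = upsample)]
      if (shift && upsample > 1) {
        sy <- sample(0:(upsample - 1), 1)
        sx <- sample(0:(upsample - 1), 1)
        img <- img[((seq_len(ny) - 1 + sy) %% ny) + 1,
                   ((seq_len(nx) - 1 + sx) %% nx) + 1]
      }
      frames[f, , ] <- img
    }
  })
  structure(list(frames = frames, dt = dt), class = "stimulus_movie")
}

#' Direction tuning of one unit
#'
#' Relative rates (`r_max - r_min` of the binned rate, spikes/s) over a set
#' of evenly spaced moving-bar directions.
#'
#' @param directions Directions in degrees, strictly increasing in
#'   `[0, 360)`.
#' @param relative_rates Nonnegative relative rates, one per direction.
#' @return Object of class `direction_tuning`.
#' @export
direction_tuning <- function(directions, relative_rates) {
  stopifnot(length(directions) == length(relative_rates),
            length(directions) >= 2)
  if (any(diff(directions) <= 0) || any(directions < 0) ||
      any(directions >= 360)) {
    stop_contract("directions must be strictly increasing in [0, 360)")
  }
  if (any(relative_rates < 0)) stop_contract("relative rates must be >= 0")
  structure(list(directions = directions, relative_rates = relative_rates),
            class = "direction_tuning")
}

#' Simulated moving-bar direction tuning
#'
#' Unimodal (von-Mises-shaped) tuning over `n_directions` evenly spaced
#' directions, with optional Poisson count noise. Concentration 0 gives
#' uniform tuning; large concentrations put all mass near the preferred
#' direction.
#'
#' @param preferred_direction Preferred direction, degrees.
#' @param concentration Von-Mises concentration (>= 0).
#' @param n_directions Number of directions (default 12).
#' @param peak_rate Peak relative rate, spikes/s.
#' @param noise Add Poisson count noise?
#' @param seed Integer seed (used when `noise = TRUE`).
#' @return A [direction_tuning()].
#' @export
moving_bar_tuning <- function(preferred_direction, concentration,
                              n_directions = 12, peak_rate = 30,
                              noise = TRUE, seed = 1) {
  stopifnot(n_directions >= 2, concentration >= 0)
  dirs <- seq(0, 360 - 360 / n_directions, length.out = n_directions)
  w <- exp(concentration * (cos((dirs - preferred_direction) * pi / 180) - 1))
  rates <- peak_rate * w
  if (noise) rates <- with_seed(seed, as.numeric(rpois(n_directions, rates)))
  direction_tuning(dirs, rates)
}
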