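# Synthetic-observer simulation of the seven-condition dual-task session.
# All functions draw from R's global RNG; generate_experiment() seeds one
# independent, reproducible stream per subject from a single master seed.

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler for the von Mises distribution on the
#' circle. Used as the latent angular-noise model of the synthetic observer;
#' `kappa = 0` reduces to the uniform distribution on the circle.
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param kappa Concentration, `>= 0` (dimensionless).
#' @return Numeric vector of angles in radians (unwrapped around `mu`).
#' @export
#' @examples
#' set.seed(1)
#' rvonmises(5, 0, 4)
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0, is.finite(mu))
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return(mu + runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    z <- cos(pi * runif(1))
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    u2 <- runif(1)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      i <- i + 1L
      out[i] <- mu + sign(runif(1) - 0.5) * acos(pmin(pmax(f, -1), 1))
    }
  }
  out
}

empty_cues <- function() {
  tibble(
    onset_s = numeric(0), direction = character(0), modality = character(0)
  )
}

empty_responses <- function() {
  tibble(time_s = numeric(0), key = integer(0))
}

#' Generate a within-trial cue schedule
#'
#' Draws cue onsets uniformly at random subject to the timing constraints:
#' onsets strictly increasing, consecutive onsets at least `min_gap_s`
#' apart, and the last cue ending (`onset + cue_duration_s`) within the
#' active interval. For an 11-s localization-only trial the cue count is
#' drawn from `cues_min:cues_max` (4-5 by default); for other active
#' durations (dual-task trials last as long as the search does, and cues are
#' delivered throughout) the range scales pro rata and is capped at what the
#' gap constraint can accommodate.
#'
#' @param active_duration_s Length of the interval over which cues are
#'   delivered, seconds.
#' @param design A [design_spec()] object (timing constraints).
#' @param modality Modality label stamped on every cue (`VI`, `TA`, `VITA`).
#' @param n_range Optional integer vector `c(lo, hi)` overriding the cue
#'   count range; an error is raised if `lo` cues cannot be packed into the
#'   interval.
#' @return A tibble with columns `onset_s`, `direction`, `modality`; zero
#'   rows when the interval is too short for a single cue (derived range
#'   only).
#' @export
#' @examples
#' set.seed(1)
#' generate_cue_schedule(11, design_spec(), "VI")
generate_cue_schedule <- function(active_duration_s,
                                  design = design_spec(),
                                  modality = "VI",
                                  n_range = NULL) {
  stopifnot(inherits(design, "vt_design"))
  if (!modality %in% .LOC_CONDITIONS) abort("`modality` must be VI, TA or VITA.")
  if (!is.numeric(active_duration_s) || active_duration_s < 0) {
    abort("`active_duration_s` must be a non-negative number.")
  }
  gap <- design$min_gap_s
  dur <- design$cue_duration_s
  # most cues that can be packed with min_gap spacing and a full last cue
  n_max_feasible <- if (active_duration_s < dur) {
    0L
  } else {
    as.integer(floor((active_duration_s - dur) / gap)) + 1L
  }
  forced <- !is.null(n_range)
  if (forced) {
    stopifnot(length(n_range) == 2, n_range[1] >= 1, n_range[2] >= n_range[1])
    lo <- as.integer(n_range[1])
    hi <- as.integer(n_range[2])
    if (lo > n_max_feasible) {
      abort(sprintf(
        "Cannot fit %d cues of %.3gs with >=%.3gs onset gaps into %.3gs.",
        lo, dur, gap, active_duration_s
      ))
    }
    hi <- min(hi, n_max_feasible)
  } else {
    scale <- active_duration_s / design$trial_duration_s
    lo <- as.integer(floor(design$cues_min * scale))
    hi <- max(lo, as.integer(floor(design$cues_max * scale)))
    lo <- min(lo, n_max_feasible)
    hi <- min(hi, n_max_feasible)
    if (hi <= 0L) return(empty_cues())
    lo <- max(lo, 1L)
  }
  n <- if (lo == hi) lo else sample(lo:hi, 1)
  if (n == 0L) return(empty_cues())
  slack <- active_duration_s - dur - (n - 1) * gap
  onsets <- sort(runif(n, 0, slack)) + (seq_len(n) - 1) * gap
  tibble(
    onset_s = onsets,
    direction = sample(.DIRECTIONS, n, replace = TRUE),
    modality = modality
  )
}

rt_lognormal_pars <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  c(meanlog = meanlog, sdlog = sdlog)
}

#' Simulate the keypad response to one location cue
#'
#' With probability `p_detect` (reduced additively by the dual-task penalty
#' when searching) the observer responds after a lognormal latency; the
#' response direction is the latent von Mises estimate of the cue direction,
#' discretized to the nearest of the eight keypad directions. Otherwise the
#' cue goes unanswered, which is a valid outcome (a miss), returned as a
#' zero-row tibble.
#'
#' @param onset_s Cue onset, seconds from trial start.
#' @param direction Cue direction label.
#' @param modality Cue modality (`VI`, `TA`, `VITA`).
#' @param obs A [observer_params()] object.
#' @param dual Logical; is the observer simultaneously searching?
#' @return A tibble with columns `time_s`, `key` (one row, or zero rows for
#'   a miss).
#' @export
#' @examples
#' set.seed(1)
#' simulate_localization_response(1.2, "N", "VI", observer_params())
simulate_localization_response <- function(onset_s, direction, modality, obs,
                                           dual = FALSE) {
  stopifnot(inherits(obs, "vt_observer"), length(onset_s) == 1)
  p <- obs$p_detect[[modality]] - (if (dual) obs$dual_detect_penalty else 0)
  p <- min(max(p, 0), 1)
  if (runif(1) >= p) return(empty_responses())
  kappa <- effective_kappa(obs, modality, dual)
  theta <- rvonmises(1, direction_angle(direction) * pi / 180, kappa)
  resp_dir <- nearest_direction(theta * 180 / pi)
  lp <- rt_lognormal_pars(obs$rt_mean_s, obs$rt_sd_s)
  latency <- rlnorm(1, lp[["meanlog"]], lp[["sdlog"]]) +
    (if (dual) obs$rt_dual_penalty_s else 0)
  tibble(time_s = onset_s + latency, key = direction_to_key(resp_dir))
}

#' Simulate one self-terminating visual search trial
#'
#' Serial self-terminating search over `n_search_items` items with
#' exponentially distributed per-item inspection times. Under dual task the
#' per-item mean is inflated by the penalty of the concurrent localization
#' modality. When the target is present it occupies a uniformly random
#' position in the inspection order and is overlooked with probability
#' `p_miss_target` when inspected; search stops at the target (a hit) or at
#' list exhaustion (reported "absent": a correct rejection when the target
#' is absent, a miss when present).
#'
#' @param condition A condition label containing `VS`.
#' @param obs A [observer_params()] object.
#' @param design A [design_spec()] object.
#' @return A list with `search_time_s`, `target_present`,
#'   `search_response_correct`.
#' @export
#' @examples
#' set.seed(1)
#' simulate_search_trial("VI+VS", observer_params(), design_spec())
simulate_search_trial <- function(condition, obs, design = design_spec()) {
  stopifnot(inherits(obs, "vt_observer"), inherits(design, "vt_design"))
  if (!condition_has_search(condition)) {
    abort("`condition` must include the visual search task (contain VS).")
  }
  modality <- condition_modality(condition)
  per_item <- obs$base_item_time_s +
    (if (!is.na(modality)) obs$dual_item_penalty_s[[modality]] else 0)
  n_items <- design$n_search_items
  target_present <- runif(1) < design$p_target_present
  found <- FALSE
  n_inspected <- n_items
  if (target_present) {
    pos <- sample.int(n_items, 1)
    if (runif(1) >= obs$p_miss_target) {
      found <- TRUE
      n_inspected <- pos
    }
  }
  search_time <- sum(rexp(n_inspected, rate = 1 / per_item))
  correct <- if (found) TRUE else !target_present
  list(
    search_time_s = search_time,
    target_present = target_present,
    search_response_correct = correct
  )
}

simulate_trial <- function(condition, obs, design) {
  has_search <- condition_has_search(condition)
  modality <- condition_modality(condition)
  if (has_search) {
    s <- simulate_search_trial(condition, obs, design)
    active <- s$search_time_s
  } else {
    s <- list(
      search_time_s = NA_real_, target_present = NA,
      search_response_correct = NA
    )
    active <- design$trial_duration_s
  }
  if (!is.na(modality)) {
    cues <- generate_cue_schedule(active, design, modality)
    responses <- purrr::pmap(cues, function(onset_s, direction, modality) {
      simulate_localization_response(onset_s, direction, modality, obs,
        dual = has_search
      )
    })
    responses <- dplyr::bind_rows(responses)
    if (nrow(responses) == 0) responses <- empty_responses()
    # responses only count while the trial (or the search) is still running
    responses <- responses[responses$time_s <= active, , drop = FALSE]
  } else {
    cues <- empty_cues()
    responses <- empty_responses()
  }
  tibble(
    condition = condition,
    target_present = s$target_present,
    search_time_s = s$search_time_s,
    search_response_correct = s$search_response_correct,
    active_duration_s = active,
    cues = list(cues),
    responses = list(responses),
    gaze_median_deg = abs(rnorm(1, obs$gaze_mean_deg, obs$gaze_sd_deg))
  )
}

subject_seed <- function(seed, i) {
  # keep derived seeds strictly below 2^31 regardless of the master seed
  as.integer((abs(as.numeric(seed)) %% 1000003) * 1009 + i)
}

#' Generate a full synthetic experiment
#'
#' Simulates every trial of the seven-condition session for a cohort of
#' synthetic observers: a pseudorandomized block sequence per subject (each
#' set of seven blocks covers all conditions, no condition repeated across
#' consecutive blocks), cue schedules, keypad responses, self-terminating
#' searches, and per-trial gaze-deviation medians (folded normal). Each
#' subject runs on an independent RNG stream derived from the master seed,
#' so the table is bit-reproducible and individual subjects can be
#' regenerated in isolation.
#'
#' @param design A [design_spec()] object.
#' @param observers Optional list of [observer_params()], one per subject;
#'   by default a cohort is drawn with [sample_observers()] from the master
#'   seed.
#' @param seed Master integer seed.
#' @return A tibble with one row per trial: `subject_id`, `block`, `trial`,
#'   `condition`, `target_present`, `search_time_s`,
#'   `search_response_correct`, `active_duration_s`, list-columns `cues` and
#'   `responses`, and `gaze_median_deg`.
#' @export
#' @examples
#' trials <- generate_experiment(design_spec(n_subjects = 2, n_blocks = 7), seed = 1)
#' dplyr::count(trials, subject_id, condition)
generate_experiment <- function(design = design_spec(), observers = NULL,
                                seed = 1) {
  stopifnot(inherits(design, "vt_design"))
  if (is.null(observers)) {
    set.seed(subject_seed(seed, 0L))
    observers <- sample_observers(design$n_subjects)
  }
  if (length(observers) != design$n_subjects) {
    abort(sprintf(
      "Got %d observers for %d subjects; supply one ObserverParams per subject.",
      length(observers), design$n_subjects
    ))
  }
  subjects <- sprintf("S%02d", seq_len(design$n_subjects))
  out <- purrr::map(seq_along(subjects), function(i) {
    set.seed(subject_seed(seed, i))
    obs <- observers[[i]]
    blocks <- block_sequence(design)
    rows <- purrr::map(seq_along(blocks), function(b) {
      trials <- purrr::map(
        seq_len(design$trials_per_block),
        function(t) simulate_trial(blocks[b], obs, design)
      )
      dplyr::bind_rows(trials) |>
        dplyr::mutate(
          block = b, trial = seq_len(design$trials_per_block),
          .before = 1
        )
    })
    dplyr::bind_rows(rows) |>
      dplyr::mutate(subject_id = subjects[i], .before = 1)
  })
  dplyr::bind_rows(out)
}
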