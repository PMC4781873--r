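# Experimental design and synthetic-observer parameter containers.

.LOC_CONDITIONS <- c("VI", "TA", "VITA")
.ALL_CONDITIONS <- c("VI", "TA", "VITA", "VS", "VI+VS", "TA+VS", "VITA+VS")

#' Condition labels of the seven-condition design
#'
#' Three localization-only conditions (visual `VI`, tactile `TA`,
#' redundant visuotactile `VITA`), visual search alone (`VS`), and the three
#' dual-task combinations (`VI+VS`, `TA+VS`, `VITA+VS`).
#'
#' @return Character vector of the seven condition labels.
#' @export
vt_conditions <- function() .ALL_CONDITIONS

#' @rdname vt_conditions
#' @param condition Character vector of condition labels.
#' @return `condition_modality()` returns the localization modality
#'   (`"VI"`, `"TA"` or `"VITA"`) of each condition, or `NA` for search-only
#'   trials; `condition_has_search()` and `condition_is_dual()` return
#'   logicals.
#' @export
condition_modality <- function(condition) {
  validate_conditions(condition)
  m <- sub("\\+VS$", "", condition)
  m[m == "VS"] <- NA_character_
  m
}

#' @rdname vt_conditions
#' @export
condition_has_search <- function(condition) {
  validate_conditions(condition)
  grepl("VS", condition, fixed = TRUE)
}

#' @rdname vt_conditions
#' @export
condition_is_dual <- function(condition) {
  validate_conditions(condition)
  grepl("+", condition, fixed = TRUE)
}

validate_conditions <- function(condition) {
  bad <- !condition %in% .ALL_CONDITIONS
  if (any(bad)) {
    abort(sprintf(
      "Unknown condition label(s): %s. Valid labels are %s.",
      paste(unique(condition[bad]), collapse = ", "),
      paste(.ALL_CONDITIONS, collapse = ", ")
    ))
  }
  invisible(condition)
}

#' Design of the dual-task experiment
#'
#' Parameters of the within-subject design: block structure, trial timing,
#' cue schedule constraints, and the visual search display. Defaults mirror
#' the seven-condition session of 21 blocks of 10 trials, 11-s
#' localization-only trials, 600-ms cues at least 1 s apart (4-5 cues per
#' 11-s trial), and a 20-item search display with a target on half the
#' trials.
#'
#' @param n_subjects Number of participants.
#' @param n_blocks Number of blocks per participant; every consecutive run of
#'   7 blocks covers all 7 conditions, with no condition repeated in
#'   consecutive blocks, so `n_blocks` must be a multiple of 7.
#' @param trials_per_block Trials per block (one condition per block).
#' @param trial_duration_s Duration of a localization-only trial, seconds.
#' @param cue_duration_s Duration of one location cue (position change),
#'   seconds.
#' @param min_gap_s Minimum time between consecutive cue onsets, seconds.
#' @param cues_min,cues_max Number of cues per localization-only trial is
#'   drawn uniformly from `cues_min:cues_max`; dual-task trials scale the
#'   range pro rata with the realized search duration (cues continue for as
#'   long as the search does).
#' @param n_search_items Number of items in the search display.
#' @param p_target_present Probability that the search target is present.
#' @return An object of class `vt_design` (a named list).
#' @export
#' @examples
#' design_spec()
design_spec <- function(n_subjects = 12,
                        n_blocks = 21,
                        trials_per_block = 10,
                        trial_duration_s = 11,
                        cue_duration_s = 0.6,
                        min_gap_s = 1,
                        cues_min = 4L,
                        cues_max = 5L,
                        n_search_items = 20,
                        p_target_present = 0.5) {
  stopifnot(
    n_subjects >= 1, n_blocks >= 1, trials_per_block >= 1,
    n_search_items >= 1, cues_min >= 1, cues_max >= cues_min
  )
  if (n_blocks %% length(.ALL_CONDITIONS) != 0) {
    abort("`n_blocks` must be a multiple of 7 so each set of 7 blocks covers all conditions.")
  }
  if (!(cue_duration_s < min_gap_s && min_gap_s <= trial_duration_s)) {
    abort("Timing must satisfy cue_duration_s < min_gap_s <= trial_duration_s.")
  }
  if (p_target_present < 0 || p_target_present > 1) {
    abort("`p_target_present` must be a probability in [0, 1].")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_blocks = as.integer(n_blocks),
      trials_per_block = as.integer(trials_per_block),
      conditions = .ALL_CONDITIONS,
      trial_duration_s = trial_duration_s,
      cue_duration_s = cue_duration_s,
      min_gap_s = min_gap_s,
      cues_min = as.integer(cues_min),
      cues_max = as.integer(cues_max),
      n_search_items = as.integer(n_search_items),
      p_target_present = p_target_present
    ),
    class = "vt_design"
  )
}

#' @export
print.vt_design <- function(x, ...) {
  cat("<vt_design> ", x$n_subjects, " subjects, ", x$n_blocks, " blocks x ",
    x$trials_per_block, " trials, 7 conditions\n",
    sep = ""
  )
  cat(sprintf(
    "  cues: %d-%d per %gs trial, %.3gs duration, >=%.3gs between onsets\n",
    x$cues_min, x$cues_max, x$trial_duration_s, x$cue_duration_s, x$min_gap_s
  ))
  cat(sprintf(
    "  search: %d items, P(target) = %.2f\n",
    x$n_search_items, x$p_target_present
  ))
  invisible(x)
}

#' Generative parameters of a synthetic observer
#'
#' Per-subject parameters of the ideal-observer simulator. Localization is
#' modelled as a latent von Mises direction estimate, discretized to the
#' nearest of the eight keypad directions; `kappa` is the angular
#' concentration (higher = more precise) per unimodal cue. In the default
#' `"mle"` fusion mode the bimodal (visuotactile) concentration is the *sum*
#' of the unimodal concentrations, the generative analogue of
#' reliability-weighted maximum-likelihood fusion; in `"pinned"` mode the
#' bimodal precision equals the better single cue (no fusion), which serves
#' as a negative control. Performing the search task concurrently costs an
#' additive drop in cue-detection probability, a multiplicative reduction of
#' concentration, and a per-item search slowdown that depends on the
#' localization modality.
#'
#' @param p_detect Named probabilities of responding to a cue at all, one per
#'   modality (`VI`, `TA`, `VITA`), under single-task conditions.
#' @param kappa Named von Mises concentrations for the unimodal cues
#'   (`VI`, `TA`); the `VITA` concentration is derived from `fusion_mode`.
#' @param fusion_mode `"mle"` (precision-additive fusion) or `"pinned"`
#'   (bimodal precision equals the better unimodal precision).
#' @param dual_detect_penalty Additive drop in `p_detect` under dual task.
#' @param dual_kappa_factor Multiplicative concentration reduction under dual
#'   task, in `(0, 1]`.
#' @param base_item_time_s Mean inspection time per search item, seconds.
#' @param dual_item_penalty_s Named per-item slowdown (seconds) added under
#'   dual task, one value per localization modality.
#' @param p_miss_target Probability of overlooking a present target when it
#'   is inspected.
#' @param rt_mean_s,rt_sd_s Mean and SD of the lognormal response latency,
#'   seconds.
#' @param rt_dual_penalty_s Additive latency slowdown under dual task,
#'   seconds.
#' @param gaze_mean_deg,gaze_sd_deg Location and spread of the folded-normal
#'   distribution of per-trial median gaze deviation, visual degrees.
#' @return An object of class `vt_observer` (a named list).
#' @export
#' @examples
#' observer_params()
observer_params <- function(p_detect = c(VI = 0.93, TA = 0.90, VITA = 0.96),
                            kappa = c(VI = 8, TA = 4),
                            fusion_mode = c("mle", "pinned"),
                            dual_detect_penalty = 0.12,
                            dual_kappa_factor = 0.7,
                            base_item_time_s = 0.4,
                            dual_item_penalty_s = c(VI = 0.30, TA = 0.20, VITA = 0.20),
                            p_miss_target = 0.1,
                            rt_mean_s = 0.55,
                            rt_sd_s = 0.15,
                            rt_dual_penalty_s = 0.05,
                            gaze_mean_deg = 0.62,
                            gaze_sd_deg = 0.15) {
  fusion_mode <- match.arg(fusion_mode)
  if (!all(.LOC_CONDITIONS %in% names(p_detect))) {
    abort("`p_detect` must be named with VI, TA and VITA.")
  }
  if (!all(c("VI", "TA") %in% names(kappa))) {
    abort("`kappa` must be named with VI and TA.")
  }
  if (!all(.LOC_CONDITIONS %in% names(dual_item_penalty_s))) {
    abort("`dual_item_penalty_s` must be named with VI, TA and VITA.")
  }
  probs <- c(p_detect, dual_detect_penalty, p_miss_target)
  if (any(probs < 0 | probs > 1)) abort("All probabilities must lie in [0, 1].")
  if (any(kappa < 0)) abort("`kappa` must be >= 0.")
  if (dual_kappa_factor <= 0 || dual_kappa_factor > 1) {
    abort("`dual_kappa_factor` must lie in (0, 1].")
  }
  times <- c(base_item_time_s, rt_mean_s, rt_sd_s)
  if (any(times <= 0)) abort("Times must be > 0.")
  if (any(dual_item_penalty_s < 0) || rt_dual_penalty_s < 0) {
    abort("Dual-task penalties must be >= 0.")
  }
  if (gaze_mean_deg < 0 || gaze_sd_deg <= 0) {
    abort("`gaze_mean_deg` must be >= 0 and `gaze_sd_deg` > 0.")
  }
  structure(
    list(
      p_detect = p_detect[.LOC_CONDITIONS],
      kappa = kappa[c("VI", "TA")],
      fusion_mode = fusion_mode,
      dual_detect_penalty = dual_detect_penalty,
      dual_kappa_factor = dual_kappa_factor,
      base_item_time_s = base_item_time_s,
      dual_item_penalty_s = dual_item_penalty_s[.LOC_CONDITIONS],
      p_miss_target = p_miss_target,
      rt_mean_s = rt_mean_s,
      rt_sd_s = rt_sd_s,
      rt_dual_penalty_s = rt_dual_penalty_s,
      gaze_mean_deg = gaze_mean_deg,
      gaze_sd_deg = gaze_sd_deg
    ),
    class = "vt_observer"
  )
}

#' @export
print.vt_observer <- function(x, ...) {
  cat("<vt_observer> fusion:", x$fusion_mode, "\n")
  cat(sprintf(
    "  p_detect VI/TA/VITA = %.2f/%.2f/%.2f (dual penalty %.2f)\n",
    x$p_detect[["VI"]], x$p_detect[["TA"]], x$p_detect[["VITA"]],
    x$dual_detect_penalty
  ))
  cat(sprintf(
    "  kappa VI/TA = %.2f/%.2f (VITA %s; dual factor %.2f)\n",
    x$kappa[["VI"]], x$kappa[["TA"]],
    if (x$fusion_mode == "mle") "= VI + TA" else "= max(VI, TA)",
    x$dual_kappa_factor
  ))
  invisible(x)
}

#' Effective von Mises concentration for a cue
#'
#' Resolves the concentration used when simulating one localization
#' response: the per-modality base concentration (with the visuotactile
#' concentration derived from the fusion mode) times the dual-task reduction
#' factor when the observer is simultaneously searching.
#'
#' @param obs A [observer_params()] object.
#' @param modality One of `"VI"`, `"TA"`, `"VITA"`.
#' @param dual Logical; is the localization performed during search?
#' @return A single concentration value.
#' @export
effective_kappa <- function(obs, modality, dual = FALSE) {
  stopifnot(inherits(obs, "vt_observer"))
  if (!modality %in% .LOC_CONDITIONS) abort("`modality` must be VI, TA or VITA.")
  k <- if (modality == "VITA") {
    if (obs$fusion_mode == "mle") {
      obs$kappa[["VI"]] + obs$kappa[["TA"]]
    } else {
      max(obs$kappa[["VI"]], obs$kappa[["TA"]])
    }
  } else {
    obs$kappa[[modality]]
  }
  if (dual) k <- k * obs$dual_kappa_factor
  k
}

#' Draw a cohort of synthetic observers
#'
#' Jitters a base parameter set to produce between-subject variability.
#' Subject-level multipliers are shared across modalities (a "good localizer"
#' is good in every modality), so within-subject orderings are preserved
#' while the repeated-measures subject stratum receives genuine variance.
#'
#' @param n Number of observers.
#' @param base A [observer_params()] object used as the cohort centre.
#' @param kappa_jitter_sd SD of the lognormal multiplier on both unimodal
#'   concentrations.
#' @param detect_jitter_sd SD of the normal shift applied to `p_detect` on
#'   the log-odds scale.
#' @param time_jitter_sd SD of the lognormal multiplier on item time, mean
#'   response latency, and mean gaze deviation.
#' @return A list of `n` `vt_observer` objects.
#' @export
#' @examples
#' set.seed(1)
#' obs <- sample_observers(3)
sample_observers <- function(n,
                             base = observer_params(),
                             kappa_jitter_sd = 0.15,
                             detect_jitter_sd = 0.30,
                             time_jitter_sd = 0.12) {
  stopifnot(inherits(base, "vt_observer"), n >= 1)
  lapply(seq_len(n), function(i) {
    k_mult <- exp(rnorm(1, 0, kappa_jitter_sd))
    d_shift <- rnorm(1, 0, detect_jitter_sd)
    t_mult <- exp(rnorm(1, 0, time_jitter_sd))
    p <- stats::plogis(stats::qlogis(pmin(pmax(base$p_detect, 1e-6), 1 - 1e-6)) + d_shift)
    obs <- base
    obs$p_detect <- setNames(p, names(base$p_detect))
    obs$kappa <- base$kappa * k_mult
    obs$base_item_time_s <- base$base_item_time_s * t_mult
    obs$rt_mean_s <- base$rt_mean_s * exp(rnorm(1, 0, time_jitter_sd / 2))
    obs$gaze_mean_deg <- base$gaze_mean_deg * exp(rnorm(1, 0, time_jitter_sd / 2))
    obs
  })
}

#' Pseudorandomized block sequence
#'
#' Assigns one condition per block such that every consecutive set of seven
#' blocks contains all seven conditions and no condition repeats in
#' consecutive blocks (including across set boundaries).
#'
#' @param design A [design_spec()] object.
#' @return Character vector of length `design$n_blocks`.
#' @export
block_sequence <- function(design = design_spec()) {
  stopifnot(inherits(design, "vt_design"))
  n_sets <- design$n_blocks %/% length(design$conditions)
  out <- character(0)
  prev <- NA_character_
  for (s in seq_len(n_sets)) {
    repeat {
      perm <- sample(design$conditions)
      if (is.na(prev) || perm[1] != prev) break
    }
    out <- c(out, perm)
    prev <- perm[length(perm)]
  }
  out
}
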