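# Per-subject, per-condition behavioural measures.

#' Pair keypad responses with location cues
#'
#' A key press recorded between the onsets of two consecutive location cues
#' is regarded as a response to the earlier cue (a hit); the last cue's
#' window extends to the end of the trial's active interval. Only the first
#' press in each window counts; additional presses in the same window are
#' ignored, and presses before the first cue onset (or after the active
#' interval) are discarded and counted.
#'
#' @param cues Tibble of cues (`onset_s`, `direction`, ...) sorted by onset.
#' @param responses Tibble of responses (`time_s`, `key`).
#' @param trial_end_s End of the trial's active interval, seconds (trial
#'   duration for localization-only trials, search termination for dual
#'   trials).
#' @return A tibble with one row per cue: the cue columns plus `time_s`,
#'   `key` (`NA` for a miss) and `hit`. The number of discarded responses is
#'   attached as attribute `"n_discarded"`.
#' @export
#' @examples
#' cues <- tibble::tibble(onset_s = c(1, 2.5), direction = c("N", "E"))
#' resp <- tibble::tibble(time_s = c(1.4, 2.9), key = c(8L, 6L))
#' assign_hits(cues, resp, trial_end_s = 11)
assign_hits <- function(cues, responses, trial_end_s) {
  stopifnot(is.data.frame(cues), is.data.frame(responses))
  if (nrow(cues) > 1 && is.unsorted(cues$onset_s, strictly = TRUE)) {
    abort("`cues` must be sorted by strictly increasing onset.")
  }
  out <- cues
  out$time_s <- NA_real_
  out$key <- NA_integer_
  n_discarded <- 0L
  if (nrow(responses) > 0 && nrow(cues) > 0) {
    responses <- responses[order(responses$time_s), , drop = FALSE]
    idx <- findInterval(responses$time_s, cues$onset_s)
    late <- responses$time_s > trial_end_s
    keep <- idx >= 1L & !late
    n_discarded <- sum(!keep)
    idx <- idx[keep]
    responses <- responses[keep, , drop = FALSE]
    first <- !duplicated(idx)
    out$time_s[idx[first]] <- responses$time_s[first]
    out$key[idx[first]] <- as.integer(responses$key[first])
  } else {
    n_discarded <- nrow(responses)
  }
  out$hit <- !is.na(out$time_s)
  attr(out, "n_discarded") <- n_discarded
  out
}

#' Detection performance of location cues
#'
#' Fraction of presented location cues that elicited any key press in their
#' response window, irrespective of whether the direction was correct.
#'
#' @param paired A hit assignment from [assign_hits()].
#' @return A fraction in `[0, 1]`.
#' @export
detection_performance <- function(paired) {
  if (nrow(paired) == 0) {
    abort("Detection performance is undefined for zero cues.")
  }
  mean(paired$hit)
}

#' Localization accuracy of detected cues
#'
#' Among detected cues (hits), the fraction whose response direction equals
#' the cue direction. Misses are excluded from the denominator; with zero
#' hits the quantity is undefined and an error is raised rather than
#' returning 0.
#'
#' @inheritParams detection_performance
#' @return A fraction in `[0, 1]`.
#' @export
localization_accuracy <- function(paired) {
  hits <- paired[paired$hit, , drop = FALSE]
  if (nrow(hits) == 0) {
    abort("Localization accuracy is undefined with zero detected cues.")
  }
  mean(key_to_direction(hits$key) == hits$direction)
}

#' Signed angular errors of detected cues
#'
#' @inheritParams detection_performance
#' @return Numeric vector, one error (degrees) per detected cue.
#' @export
paired_errors <- function(paired) {
  hits <- paired[paired$hit, , drop = FALSE]
  if (nrow(hits) == 0) return(numeric(0))
  signed_angular_error(hits$direction, key_to_direction(hits$key))
}

#' Variance of the signed angular error
#'
#' Sample variance (denominator `n - 1`) of the signed angular errors of all
#' detected cues in a subject-by-condition cell; correctly localized cues
#' contribute an error of 0 degrees.
#'
#' @param errors Numeric vector of signed angular errors, degrees.
#' @return Variance in squared degrees, or `NA` (with a message) when fewer
#'   than two detected cues are available.
#' @export
#' @examples
#' error_variance(c(45, -45)) # 4050
error_variance <- function(errors) {
  if (length(errors) < 2) {
    inform("error_variance: fewer than 2 detected cues; cell flagged missing.")
    return(NA_real_)
  }
  var(errors)
}

#' Median search time of a cell
#'
#' The median is used as a robust estimator of central tendency for search
#' times, which are heavily influenced by outliers; even counts use midpoint
#' interpolation.
#'
#' @param times Numeric vector of search times, seconds.
#' @return Median in seconds.
#' @export
median_search_time <- function(times) {
  if (length(times) == 0) abort("Empty cell: no search trials.")
  median(times)
}

#' Search accuracy of a cell
#'
#' Fraction of search trials on which the target-present/absent judgement
#' was correct.
#'
#' @param correct Logical vector of per-trial correctness.
#' @return A fraction in `[0, 1]`.
#' @export
search_accuracy <- function(correct) {
  if (length(correct) == 0) abort("Empty cell: no search trials.")
  mean(correct)
}

#' Dual-task interference on search time
#'
#' `interference()` is the dual-task minus single-task search time (it may
#' be negative). `interference_reduction_pct()` expresses a between-modality
#' difference in interference as a percentage of the overall interference,
#' rounded to the nearest integer percent for reporting.
#'
#' @param dual_median_s,single_median_s Search-time summaries, seconds.
#' @return `interference()` returns seconds.
#' @export
#' @examples
#' interference(7, 4) # 3
#' interference_reduction_pct(0.98, 2.96) # 33
interference <- function(dual_median_s, single_median_s) {
  if (anyNA(dual_median_s) || anyNA(single_median_s)) {
    abort("Both dual and single search-time summaries must be present.")
  }
  dual_median_s - single_median_s
}

#' @rdname interference
#' @param visual_dual_diff_s Difference between two dual conditions'
#'   interference (or search time), seconds.
#' @param overall_interference_s Overall dual-vs-single interference,
#'   seconds; must be nonzero.
#' @export
interference_reduction_pct <- function(visual_dual_diff_s,
                                       overall_interference_s) {
  if (anyNA(visual_dual_diff_s) || anyNA(overall_interference_s)) {
    abort("Inputs must be present.")
  }
  if (any(overall_interference_s == 0)) {
    abort("Reduction is undefined when the overall interference is zero.")
  }
  round(100 * visual_dual_diff_s / overall_interference_s)
}

#' Mean reaction time of correctly localized cues
#'
#' Mean of response time minus cue onset over the correctly localized cues
#' only (the speed-accuracy check of the localization task).
#'
#' @inheritParams detection_performance
#' @return Mean RT in seconds, or `NA` (with a message) when the cell has no
#'   correct localization.
#' @export
mean_rt_correct <- function(paired) {
  hits <- paired[paired$hit, , drop = FALSE]
  if (nrow(hits) == 0) {
    inform("mean_rt_correct: no detected cues; cell flagged missing.")
    return(NA_real_)
  }
  correct <- key_to_direction(hits$key) == hits$direction
  if (!any(correct)) {
    inform("mean_rt_correct: no correct localization; cell flagged missing.")
    return(NA_real_)
  }
  mean(hits$time_s[correct] - hits$onset_s[correct])
}

validate_trials <- function(trials) {
  required <- c(
    "subject_id", "block", "trial", "condition", "target_present",
    "search_time_s", "search_response_correct", "active_duration_s",
    "cues", "responses", "gaze_median_deg"
  )
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0) {
    abort(sprintf(
      "Trial table is missing required column(s): %s.",
      paste(missing, collapse = ", ")
    ))
  }
  validate_conditions(unique(trials$condition))
  invisible(trials)
}

summarize_cell <- function(df, condition) {
  has_search <- condition_has_search(condition)
  modality <- condition_modality(condition)
  out <- tibble(
    n_trials = nrow(df),
    median_search_time_s = NA_real_,
    search_accuracy = NA_real_,
    detection_performance = NA_real_,
    localization_accuracy = NA_real_,
    error_variance_deg2 = NA_real_,
    mean_rt_correct_s = NA_real_,
    median_gaze_deg = mean(df$gaze_median_deg)
  )
  if (has_search) {
    out$median_search_time_s <- median_search_time(df$search_time_s)
    out$search_accuracy <- search_accuracy(df$search_response_correct)
  }
  if (!is.na(modality)) {
    paired <- purrr::pmap(
      list(df$cues, df$responses, df$active_duration_s),
      assign_hits
    )
    all_paired <- dplyr::bind_rows(paired)
    if (nrow(all_paired) > 0) {
      out$detection_performance <- detection_performance(all_paired)
      if (any(all_paired$hit)) {
        out$localization_accuracy <- localization_accuracy(all_paired)
        out$mean_rt_correct_s <- suppressMessages(mean_rt_correct(all_paired))
      }
      out$error_variance_deg2 <-
        suppressMessages(error_variance(paired_errors(all_paired)))
    }
  }
  out
}

#' Per-subject, per-condition summary of a trial table
#'
#' Aggregates a long-format trial table to one row per subject and
#' condition, computing every behavioural measure that applies to that
#' condition: median search time and search accuracy (conditions with
#' search), detection performance, localization accuracy, signed-angular
#' -error variance and mean correct-localization RT (conditions with cues;
#' cues are pooled across the cell's trials), and the mean of the per-trial
#' median gaze deviations. Measures that do not apply to a condition are
#' `NA`, never zero-filled.
#'
#' @param trials A trial table from [generate_experiment()] or
#'   [read_trial_table()].
#' @param by_target Also split search measures by target presence (adds a
#'   `target_present` grouping column).
#' @return A tibble, one row per subject x condition (x target presence).
#' @export
#' @examples
#' trials <- generate_experiment(design_spec(n_subjects = 2, n_blocks = 7), seed = 1)
#' condition_summaries(trials)
condition_summaries <- function(trials, by_target = FALSE) {
  validate_trials(trials)
  groups <- if (by_target) {
    c("subject_id", "condition", "target_present")
  } else {
    c("subject_id", "condition")
  }
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::group_modify(~ summarize_cell(.x, .y$condition)) |>
    dplyr::ungroup()
}

#' Dual-task interference table
#'
#' Per subject and dual condition, the dual-task median search time minus
#' the single-task (`VS`) median search time, plus a group summary (mean
#' interference per condition and overall, and a one-sample t-test of the
#' per-subject overall interference against zero).
#'
#' @param summaries A [condition_summaries()] table.
#' @return A list with `per_subject` (tibble) and `group` (list with
#'   `mean_by_condition`, `overall_mean_s`, `test`).
#' @export
interference_table <- function(summaries) {
  dual <- summaries[condition_is_dual(summaries$condition), ]
  single <- summaries[summaries$condition == "VS", c("subject_id", "median_search_time_s")]
  names(single)[2] <- "single_median_s"
  per_subject <- dplyr::left_join(
    dual[, c("subject_id", "condition", "median_search_time_s")],
    single,
    by = "subject_id"
  )
  per_subject$interference_s <- interference(
    per_subject$median_search_time_s, per_subject$single_median_s
  )
  by_cond <- per_subject |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean_interference_s = mean(.data$interference_s))
  overall <- per_subject |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(interference_s = mean(.data$interference_s))
  test <- one_sample_t(overall$interference_s, mu = 0)
  list(
    per_subject = per_subject,
    group = list(
      mean_by_condition = by_cond,
      overall_mean_s = mean(overall$interference_s),
      test = test
    )
  )
}

#' Gaze-deviation screening
#'
#' Tests, for each condition involving visual search, whether the gaze
#' deviated less than `threshold_deg` visual degrees from screen centre:
#' per subject the mean of per-trial median gaze deviations, then a
#' one-sample t-test against the threshold per condition, Holm-corrected
#' across conditions.
#'
#' @param summaries A [condition_summaries()] table (uses
#'   `median_gaze_deg`).
#' @param threshold_deg Screening threshold, visual degrees.
#' @param conditions Conditions to screen; defaults to all conditions with a
#'   search component.
#' @return A tibble with one row per condition: mean gaze deviation, t, df,
#'   raw and Holm-corrected p.
#' @export
gaze_screen <- function(summaries, threshold_deg = 1,
                        conditions = c("VS", "VI+VS", "TA+VS", "VITA+VS")) {
  if (!"median_gaze_deg" %in% names(summaries) ||
    all(is.na(summaries$median_gaze_deg))) {
    warn("No gaze data available; gaze screening skipped.")
    return(invisible(NULL))
  }
  rows <- lapply(conditions, function(cond) {
    x <- summaries$median_gaze_deg[summaries$condition == cond]
    x <- x[!is.na(x)]
    tt <- tryCatch(
      one_sample_t(x, mu = threshold_deg),
      error = function(e) {
        # degenerate spread: report the limiting statistic
        m <- mean(x)
        t0 <- if (m == threshold_deg) 0 else sign(m - threshold_deg) * Inf
        list(t = t0, df = length(x) - 1, p = if (is.finite(t0)) 1 else 0)
      }
    )
    tibble(
      condition = cond, n = length(x), mean_gaze_deg = mean(x),
      t = tt$t, df = tt$df, p = tt$p
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_holm <- holm_bonferroni(out$p)
  out
}
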