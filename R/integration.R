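# Maximum-likelihood cue integration: predicted bimodal variance and the
# optimality assessment comparing observed visuotactile variance with the
# prediction, separately for single- and dual-task load.

#' MLE-predicted variance of the fused estimate
#'
#' Under reliability-weighted maximum-likelihood fusion of two independent
#' unimodal estimates, the variance of the optimally integrated estimate is
#' the product of the unimodal variances over their sum:
#' `sigma2_v * sigma2_t / (sigma2_v + sigma2_t)`. The prediction is
#' symmetric in its arguments and always lies between half the smaller
#' unimodal variance (attained when the two variances agree) and the smaller
#' unimodal variance itself (approached as the other cue becomes
#' arbitrarily unreliable).
#'
#' @param sigma2_v Variance of the visual location estimate, squared
#'   degrees.
#' @param sigma2_t Variance of the tactile location estimate, squared
#'   degrees.
#' @return Predicted visuotactile variance, squared degrees (vectorized).
#' @export
#' @examples
#' mle_predicted_variance(4, 12) # 3
#' mle_predicted_variance(6, 6) # 3
mle_predicted_variance <- function(sigma2_v, sigma2_t) {
  if (!is.numeric(sigma2_v) || !is.numeric(sigma2_t)) {
    abort("Variances must be numeric.")
  }
  if (any(sigma2_v < 0, na.rm = TRUE) || any(sigma2_t < 0, na.rm = TRUE)) {
    abort("Variances must be >= 0.")
  }
  if (any(sigma2_v + sigma2_t == 0, na.rm = TRUE)) {
    abort("The prediction is undefined when both variances are zero.")
  }
  sigma2_v * sigma2_t / (sigma2_v + sigma2_t)
}

#' Per-subject unimodal/bimodal variance triples
#'
#' Extracts, for each subject and load level, the visual, tactile and
#' observed visuotactile angular-error variances. Unimodal estimates are
#' taken from the unisensory localization conditions of the matching load:
#' `VI`/`TA`/`VITA` for single-task load and `VI+VS`/`TA+VS`/`VITA+VS` for
#' dual-task load. Subjects with any missing cell at a load level are
#' dropped from that level with a message.
#'
#' @param summaries A [condition_summaries()] table.
#' @return A tibble with columns `subject_id`, `load` (`"single"`/`"dual"`),
#'   `sigma2_visual`, `sigma2_tactile`, `sigma2_visuotactile_observed`.
#' @export
cue_variance_triples <- function(summaries) {
  stopifnot(all(c("subject_id", "condition", "error_variance_deg2") %in%
    names(summaries)))
  map <- list(
    single = c(VI = "VI", TA = "TA", VITA = "VITA"),
    dual = c(VI = "VI+VS", TA = "TA+VS", VITA = "VITA+VS")
  )
  out <- purrr::map(names(map), function(load) {
    conds <- map[[load]]
    wide <- summaries[summaries$condition %in% conds,
      c("subject_id", "condition", "error_variance_deg2")
    ]
    wide$modality <- names(conds)[match(wide$condition, conds)]
    wide <- tidyr::pivot_wider(
      wide[, c("subject_id", "modality", "error_variance_deg2")],
      names_from = "modality", values_from = "error_variance_deg2"
    )
    for (m in c("VI", "TA", "VITA")) {
      if (!m %in% names(wide)) wide[[m]] <- NA_real_
    }
    complete <- stats::complete.cases(wide[, c("VI", "TA", "VITA")])
    if (any(!complete)) {
      inform(sprintf(
        "cue_variance_triples: dropping %d subject(s) with missing %s-load cells.",
        sum(!complete), load
      ))
    }
    wide <- wide[complete, , drop = FALSE]
    tibble(
      subject_id = wide$subject_id,
      load = load,
      sigma2_visual = wide$VI,
      sigma2_tactile = wide$TA,
      sigma2_visuotactile_observed = wide$VITA
    )
  })
  dplyr::bind_rows(out)
}

#' Optimality assessment of visuotactile integration
#'
#' Compares, per subject and load level, the observed visuotactile
#' angular-error variance with the maximum-likelihood prediction computed
#' from the same subject's unimodal variances ([mle_predicted_variance()]).
#' Reports the per-subject ratio observed/predicted, the weaker qualitative
#' criterion that the bimodal variance falls below both unimodal variances,
#' and a group summary per load: mean predicted and observed variance, the
#' ratio of group means, the fraction of subjects meeting the qualitative
#' criterion, and a paired t-test of observed vs predicted (a formal
#' extension of the descriptive comparison).
#'
#' @param x A [condition_summaries()] table or a [cue_variance_triples()]
#'   tibble.
#' @return An object of class `vt_optimality`: a list with tibbles
#'   `per_subject` and `group`.
#' @export
#' @examples
#' trials <- generate_experiment(design_spec(n_subjects = 4, n_blocks = 21), seed = 2)
#' optimality_assessment(condition_summaries(trials))
optimality_assessment <- function(x) {
  triples <- if (all(c("sigma2_visual", "sigma2_tactile") %in% names(x))) {
    x
  } else {
    cue_variance_triples(x)
  }
  if (nrow(triples) == 0) abort("No complete subjects to assess.")
  per_subject <- triples
  per_subject$sigma2_predicted <- mle_predicted_variance(
    triples$sigma2_visual, triples$sigma2_tactile
  )
  per_subject$ratio_obs_pred <-
    per_subject$sigma2_visuotactile_observed / per_subject$sigma2_predicted
  per_subject$below_both_unimodal <-
    per_subject$sigma2_visuotactile_observed <
      pmin(per_subject$sigma2_visual, per_subject$sigma2_tactile)
  group <- per_subject |>
    dplyr::group_by(.data$load) |>
    dplyr::group_modify(function(df, key) {
      tt <- tryCatch(
        paired_t(df$sigma2_visuotactile_observed, df$sigma2_predicted),
        error = function(e) {
          inform("optimality_assessment: degenerate paired differences; t-test omitted.")
          list(
            t = NA_real_, df = NA_real_, p = NA_real_,
            mean_diff = mean(df$sigma2_visuotactile_observed - df$sigma2_predicted)
          )
        }
      )
      tibble(
        n_subjects = nrow(df),
        mean_predicted_deg2 = mean(df$sigma2_predicted),
        mean_observed_deg2 = mean(df$sigma2_visuotactile_observed),
        ratio_of_means = mean(df$sigma2_visuotactile_observed) /
          mean(df$sigma2_predicted),
        prop_below_both_unimodal = mean(df$below_both_unimodal),
        t = tt$t, df = tt$df, p = tt$p, mean_diff_deg2 = tt$mean_diff
      )
    }) |>
    dplyr::ungroup()
  structure(list(per_subject = per_subject, group = group),
    class = "vt_optimality"
  )
}

#' @export
print.vt_optimality <- function(x, ...) {
  cat("<vt_optimality> observed vs MLE-predicted visuotactile variance\n")
  g <- x$group
  for (i in seq_len(nrow(g))) {
    cat(sprintf(
      "  %-6s n = %d: observed %.1f vs predicted %.1f deg^2 (ratio %.3f); %0.f%% of subjects below both unimodal variances\n",
      g$load[i], g$n_subjects[i], g$mean_observed_deg2[i],
      g$mean_predicted_deg2[i], g$ratio_of_means[i],
      100 * g$prop_below_both_unimodal[i]
    ))
  }
  invisible(x)
}
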