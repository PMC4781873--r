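# End-to-end pipeline: simulate -> summarise -> interference, gaze
# screening, ANOVAs with post-hoc tests, optimality assessment, figure,
# manifest.

pipeline_stage <- function(name, verbose, expr) {
  if (verbose) inform(sprintf("[%s] ...", name))
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

anova_cell_table <- function(summaries, measure) {
  conds <- c(
    "VI", "TA", "VITA", "VI+VS", "TA+VS", "VITA+VS"
  )
  d <- summaries[summaries$condition %in% conds,
    c("subject_id", "condition", measure)
  ]
  d$task <- ifelse(condition_is_dual(d$condition), "dual", "single")
  d$modality <- condition_modality(d$condition)
  d$value <- d[[measure]]
  d[, c("subject_id", "task", "modality", "value")]
}

run_measure_anova <- function(summaries, measure, alpha) {
  d <- anova_cell_table(summaries, measure)
  if (anyNA(d$value)) {
    warn(sprintf(
      "%s: %d missing cell(s); ANOVA skipped.", measure, sum(is.na(d$value))
    ))
    return(NULL)
  }
  res <- rm_anova(d, "value", "subject_id", c("task", "modality"), alpha = alpha)
  post <- posthoc_pairwise(d, "value", "subject_id", "modality")
  list(anova = res, posthoc = post)
}

variance_figure <- function(optimality) {
  per <- optimality$per_subject
  long <- dplyr::bind_rows(
    tibble(
      load = per$load, subject_id = per$subject_id,
      what = "VI", variance = per$sigma2_visual
    ),
    tibble(
      load = per$load, subject_id = per$subject_id,
      what = "TA", variance = per$sigma2_tactile
    ),
    tibble(
      load = per$load, subject_id = per$subject_id,
      what = "VITA obs", variance = per$sigma2_visuotactile_observed
    ),
    tibble(
      load = per$load, subject_id = per$subject_id,
      what = "VITA pred", variance = per$sigma2_predicted
    )
  )
  long$what <- factor(long$what, levels = c("VI", "TA", "VITA obs", "VITA pred"))
  long$load <- factor(long$load, levels = c("single", "dual"))
  grp <- long |>
    dplyr::group_by(.data$load, .data$what) |>
    dplyr::summarise(
      mean = mean(.data$variance),
      sem = sd(.data$variance) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(grp, ggplot2::aes(x = .data$what, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "black") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean - .data$sem,
        ymax = .data$mean + .data$sem
      ),
      width = 0.2
    ) +
    ggplot2::facet_wrap(~load) +
    ggplot2::labs(
      x = NULL, y = "variance of signed angular error (deg²)",
      title = "Observed vs MLE-predicted visuotactile variance"
    ) +
    ggplot2::theme_minimal()
}

#' Run the full simulation-and-analysis pipeline
#'
#' Generates (or loads) a trial table, computes the per-subject condition
#' summaries, the interference report, the gaze screening, the
#' repeated-measures ANOVAs with Holm-corrected post-hoc tests for
#' detection performance, localization accuracy, error variance and correct
#' -localization RT, the search-time ANOVA (target x modality), and the
#' cue-integration optimality report, and writes every artifact to
#' `out_dir` as CSV plus one figure (PNG) and a run manifest (JSON with the
#' seed and a config hash). A failure in any stage aborts with the stage
#' name; artifacts written up to that point are preserved.
#'
#' @param config A configuration list (see [default_config()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding `config$seed`.
#' @param trials Optional pre-loaded trial table (skips simulation).
#' @param verbose Log stage progress.
#' @return Invisibly, a list with all in-memory results (`trials`,
#'   `summaries`, `interference`, `gaze`, `anovas`, `optimality`,
#'   `manifest`).
#' @export
#' @examples
#' \donttest{
#' cfg <- default_config()
#' cfg$design$n_subjects <- 4
#' res <- run_pipeline(cfg, out_dir = tempfile("vt"))
#' res$optimality
#' }
run_pipeline <- function(config = default_config(), out_dir, seed = NULL,
                         trials = NULL, verbose = FALSE) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  alpha <- config$analysis$alpha

  trials <- pipeline_stage("simulate", verbose, {
    if (is.null(trials)) {
      design <- config_to_design(config)
      set.seed(subject_seed(config$seed, 0L))
      observers <- sample_observers(
        design$n_subjects,
        base = config_to_observer(config)
      )
      generate_experiment(design, observers, seed = config$seed)
    } else {
      validate_trials(trials)
      trials
    }
  })
  pipeline_stage("write-trials", verbose, {
    write_trial_table(trials, file.path(out_dir, "trial_table.csv"))
    cfg_path <- file.path(out_dir, "config.yaml")
    write_config(config, cfg_path)
  })

  summaries <- pipeline_stage("summaries", verbose, {
    s <- suppressMessages(condition_summaries(trials))
    utils::write.csv(s, file.path(out_dir, "condition_summary.csv"),
      row.names = FALSE
    )
    s
  })

  interference <- pipeline_stage("interference", verbose, {
    it <- interference_table(summaries)
    utils::write.csv(it$per_subject,
      file.path(out_dir, "interference.csv"),
      row.names = FALSE
    )
    it
  })

  gaze <- pipeline_stage("gaze-screen", verbose, {
    g <- gaze_screen(summaries, threshold_deg = config$analysis$gaze_threshold_deg)
    if (!is.null(g)) {
      utils::write.csv(g, file.path(out_dir, "gaze_screen.csv"),
        row.names = FALSE
      )
    }
    g
  })

  anovas <- pipeline_stage("anovas", verbose, {
    measures <- c(
      "detection_performance", "localization_accuracy",
      "error_variance_deg2", "mean_rt_correct_s"
    )
    out <- lapply(measures, function(m) {
      res <- run_measure_anova(summaries, m, alpha)
      if (!is.null(res)) {
        utils::write.csv(res$anova,
          file.path(out_dir, paste0("anova_", m, ".csv")),
          row.names = FALSE
        )
        utils::write.csv(res$posthoc,
          file.path(out_dir, paste0("posthoc_", m, ".csv")),
          row.names = FALSE
        )
      }
      res
    })
    names(out) <- measures
    # search time: target x modality on the dual conditions
    st <- suppressMessages(condition_summaries(trials, by_target = TRUE))
    st <- st[condition_is_dual(st$condition) & !is.na(st$target_present), ]
    st$modality <- condition_modality(st$condition)
    st$target <- ifelse(st$target_present, "present", "absent")
    if (!anyNA(st$median_search_time_s)) {
      search_anova <- rm_anova(
        st, "median_search_time_s", "subject_id", c("target", "modality"),
        alpha = alpha
      )
      utils::write.csv(search_anova,
        file.path(out_dir, "anova_search_time.csv"),
        row.names = FALSE
      )
      search_post <- posthoc_pairwise(
        st, "median_search_time_s", "subject_id", "modality"
      )
      utils::write.csv(search_post,
        file.path(out_dir, "posthoc_search_time.csv"),
        row.names = FALSE
      )
      out$search_time <- list(anova = search_anova, posthoc = search_post)
    } else {
      warn("search-time ANOVA skipped: incomplete target-by-modality cells.")
    }
    out
  })

  optimality <- pipeline_stage("optimality", verbose, {
    opt <- suppressMessages(optimality_assessment(summaries))
    utils::write.csv(opt$per_subject,
      file.path(out_dir, "optimality.csv"),
      row.names = FALSE
    )
    utils::write.csv(opt$group,
      file.path(out_dir, "optimality_group.csv"),
      row.names = FALSE
    )
    opt
  })

  pipeline_stage("figure", verbose, {
    fig <- variance_figure(optimality)
    grDevices::png(file.path(out_dir, "variance_figure.png"),
      width = 1200, height = 700, res = 150
    )
    print(fig)
    grDevices::dev.off()
  })

  manifest <- pipeline_stage("manifest", verbose, {
    m <- list(
      seed = config$seed,
      config_hash = unname(tools::md5sum(file.path(out_dir, "config.yaml"))),
      n_trials = nrow(trials),
      n_subjects = length(unique(trials$subject_id)),
      artifacts = sort(list.files(out_dir))
    )
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
    m
  })

  invisible(list(
    trials = trials, summaries = summaries, interference = interference,
    gaze = gaze, anovas = anovas, optimality = optimality,
    manifest = manifest
  ))
}
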