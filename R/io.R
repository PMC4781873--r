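# Trial-table and configuration I/O. The trial table travels as long-format
# CSV, one row per trial, with the per-trial cue and response event lists
# serialized as JSON strings in dedicated columns, so the schema stays
# inspectable with ordinary tabular tools.

.TRIAL_CSV_COLS <- c(
  "subject_id", "block", "trial", "condition", "target_present",
  "search_time_s", "search_response_correct", "active_duration_s",
  "cues_json", "responses_json", "gaze_median_deg"
)

#' Write / read the trial table
#'
#' `write_trial_table()` serializes a trial table to CSV with the `cues` and
#' `responses` list-columns rendered as JSON arrays of objects;
#' `read_trial_table()` reads it back, validating the schema and condition
#' labels and reporting offending rows. A header-only file yields an empty
#' table, not an error.
#'
#' @param trials A trial table (see [generate_experiment()]).
#' @param path Path of the CSV file.
#' @return `read_trial_table()` returns the trial tibble;
#'   `write_trial_table()` returns `path` invisibly.
#' @export
write_trial_table <- function(trials, path) {
  validate_trials(trials)
  flat <- trials
  flat$cues_json <- vapply(
    trials$cues,
    function(x) as.character(jsonlite::toJSON(x, digits = NA)),
    character(1)
  )
  flat$responses_json <- vapply(
    trials$responses,
    function(x) as.character(jsonlite::toJSON(x, digits = NA)),
    character(1)
  )
  flat <- flat[, .TRIAL_CSV_COLS]
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

parse_events_json <- function(json, row, what, cols) {
  parsed <- tryCatch(
    jsonlite::fromJSON(json),
    error = function(e) {
      abort(sprintf("Row %d: malformed %s JSON (%s).", row, what, conditionMessage(e)))
    }
  )
  if (length(parsed) == 0) {
    empty <- if (what == "cues") empty_cues() else empty_responses()
    return(empty[, cols])
  }
  parsed <- as_tibble(parsed)
  missing <- setdiff(cols, names(parsed))
  if (length(missing) > 0) {
    abort(sprintf(
      "Row %d: %s events lack field(s) %s.", row, what,
      paste(missing, collapse = ", ")
    ))
  }
  parsed[, cols]
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  flat <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.TRIAL_CSV_COLS, names(flat))
  if (length(missing) > 0) {
    abort(sprintf(
      "Trial CSV is missing required column(s): %s.",
      paste(missing, collapse = ", ")
    ))
  }
  flat <- as_tibble(flat)
  if (nrow(flat) == 0) {
    out <- flat[, setdiff(.TRIAL_CSV_COLS, c("cues_json", "responses_json"))]
    out$cues <- list()
    out$responses <- list()
    return(out[, names(generate_trial_prototype())])
  }
  bad <- which(!flat$condition %in% .ALL_CONDITIONS)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown condition label %s in row(s) %s.",
      paste(unique(flat$condition[bad]), collapse = ", "),
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  cues <- lapply(seq_len(nrow(flat)), function(i) {
    ev <- parse_events_json(
      flat$cues_json[i], i, "cues", c("onset_s", "direction", "modality")
    )
    if (nrow(ev) > 0) {
      bad_dir <- !ev$direction %in% .DIRECTIONS
      if (any(bad_dir)) abort(sprintf("Row %d: invalid cue direction.", i))
    }
    ev
  })
  responses <- lapply(seq_len(nrow(flat)), function(i) {
    ev <- parse_events_json(
      flat$responses_json[i], i, "responses", c("time_s", "key")
    )
    if (nrow(ev) > 0) ev$key <- as.integer(ev$key)
    ev
  })
  out <- flat[, setdiff(.TRIAL_CSV_COLS, c("cues_json", "responses_json"))]
  out$target_present <- as.logical(out$target_present)
  out$search_response_correct <- as.logical(out$search_response_correct)
  out$cues <- cues
  out$responses <- responses
  out[, names(generate_trial_prototype())]
}

generate_trial_prototype <- function() {
  tibble(
    subject_id = character(0), block = integer(0), trial = integer(0),
    condition = character(0), target_present = logical(0),
    search_time_s = numeric(0), search_response_correct = logical(0),
    active_duration_s = numeric(0), cues = list(), responses = list(),
    gaze_median_deg = numeric(0)
  )
}

config_defaults <- function() {
  list(
    seed = 1L,
    design = list(
      n_subjects = 12L, n_blocks = 21L, trials_per_block = 10L,
      trial_duration_s = 11, cue_duration_s = 0.6, min_gap_s = 1,
      cues_min = 4L, cues_max = 5L, n_search_items = 20L,
      p_target_present = 0.5
    ),
    observer = list(
      p_detect = list(VI = 0.93, TA = 0.90, VITA = 0.96),
      kappa = list(VI = 8, TA = 4),
      fusion_mode = "mle",
      dual_detect_penalty = 0.12,
      dual_kappa_factor = 0.7,
      base_item_time_s = 0.4,
      dual_item_penalty_s = list(VI = 0.30, TA = 0.20, VITA = 0.20),
      p_miss_target = 0.1,
      rt_mean_s = 0.55, rt_sd_s = 0.15, rt_dual_penalty_s = 0.05,
      gaze_mean_deg = 0.62, gaze_sd_deg = 0.15
    ),
    analysis = list(
      alpha = 0.05,
      gaze_threshold_deg = 1,
      variance_ratio_tolerance = 0.10
    )
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    if (!key %in% names(defaults)) {
      abort(sprintf("Unknown configuration key: %s%s.", path, key))
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        abort(sprintf("Configuration key %s%s must be a mapping.", path, key))
      }
      defaults[[key]] <- merge_config(
        defaults[[key]], user[[key]], paste0(path, key, ".")
      )
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Pipeline configuration
#'
#' `default_config()` returns the full default configuration (design,
#' observer parameters, analysis options, seed); `read_config()` merges a
#' YAML file over the defaults, rejecting unknown keys;
#' `write_config()` writes a configuration as YAML (round-trips
#' losslessly).
#'
#' @param path YAML file path.
#' @return A nested named list.
#' @export
default_config <- function() config_defaults()

#' @rdname default_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  merge_config(config_defaults(), user)
}

#' @rdname default_config
#' @param config A configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_to_design <- function(config) {
  d <- config$design
  design_spec(
    n_subjects = d$n_subjects, n_blocks = d$n_blocks,
    trials_per_block = d$trials_per_block,
    trial_duration_s = d$trial_duration_s,
    cue_duration_s = d$cue_duration_s, min_gap_s = d$min_gap_s,
    cues_min = d$cues_min, cues_max = d$cues_max,
    n_search_items = d$n_search_items,
    p_target_present = d$p_target_present
  )
}

config_to_observer <- function(config) {
  o <- config$observer
  observer_params(
    p_detect = unlist(o$p_detect),
    kappa = unlist(o$kappa),
    fusion_mode = o$fusion_mode,
    dual_detect_penalty = o$dual_detect_penalty,
    dual_kappa_factor = o$dual_kappa_factor,
    base_item_time_s = o$base_item_time_s,
    dual_item_penalty_s = unlist(o$dual_item_penalty_s),
    p_miss_target = o$p_miss_target,
    rt_mean_s = o$rt_mean_s, rt_sd_s = o$rt_sd_s,
    rt_dual_penalty_s = o$rt_dual_penalty_s,
    gaze_mean_deg = o$gaze_mean_deg, gaze_sd_deg = o$gaze_sd_deg
  )
}
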