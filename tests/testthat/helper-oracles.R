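# Independent brute-force oracles used to cross-check the package's
# computations, plus a memoized full-cohort fixture shared by the slower
# end-to-end tests.

# naive interval matcher: for each cue, scan all responses for the first
# one falling inside its window
brute_force_assign <- function(cues, responses, trial_end_s) {
  n <- nrow(cues)
  out_time <- rep(NA_real_, n)
  out_key <- rep(NA_integer_, n)
  responses <- responses[order(responses$time_s), , drop = FALSE]
  for (i in seq_len(n)) {
    lo <- cues$onset_s[i]
    hi <- if (i < n) cues$onset_s[i + 1] else trial_end_s
    for (j in seq_len(nrow(responses))) {
      t <- responses$time_s[j]
      inside <- if (i < n) (t >= lo && t < hi) else (t >= lo && t <= hi)
      if (inside) {
        out_time[i] <- t
        out_key[i] <- as.integer(responses$key[j])
        break
      }
    }
  }
  list(time_s = out_time, key = out_key)
}

# two-pass textbook sample variance
brute_force_variance <- function(x) {
  m <- sum(x) / length(x)
  sum((x - m)^2) / (length(x) - 1)
}

# Greenhouse-Geisser epsilon straight from the raw k x k level covariance
# (Box's formula), independent of the orthonormal-contrast route
brute_force_gg_epsilon <- function(Y) {
  S <- stats::cov(Y)
  k <- ncol(S)
  sbar <- mean(S)
  sdiag <- mean(diag(S))
  srow <- rowMeans(S)
  num <- (k * (sdiag - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(srow^2) + k^2 * sbar^2)
  num / den
}

# memoized 12-subject cohorts (the study-scale fixture)
.cohort_cache <- new.env(parent = emptyenv())

vt_cohort <- function(mode = c("mle", "pinned"), seed = 1) {
  mode <- match.arg(mode)
  key <- paste0(mode, "_", seed)
  if (is.null(.cohort_cache[[key]])) {
    design <- design_spec()
    set.seed(vtdual:::subject_seed(seed, 0L))
    observers <- sample_observers(
      design$n_subjects,
      base = observer_params(fusion_mode = mode)
    )
    trials <- generate_experiment(design, observers, seed = seed)
    summaries <- suppressMessages(condition_summaries(trials))
    .cohort_cache[[key]] <- list(trials = trials, summaries = summaries)
  }
  .cohort_cache[[key]]
}
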