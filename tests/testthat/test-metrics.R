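cue_tbl <- function(onsets, dirs) {
  tibble::tibble(onset_s = onsets, direction = dirs, modality = "VI")
}
resp_tbl <- function(times, keys) {
  tibble::tibble(time_s = times, key = as.integer(keys))
}

test_that("hit assignment follows the between-onsets window rule", {
  cues <- cue_tbl(c(1, 2.5), c("N", "E"))
  # one response per window -> both hits
  p1 <- assign_hits(cues, resp_tbl(c(1.4, 2.9), c(8, 6)), 11)
  expect_equal(p1$hit, c(TRUE, TRUE))
  # empty first window -> first cue missed
  p2 <- assign_hits(cues, resp_tbl(2.9, 6), 11)
  expect_equal(p2$hit, c(FALSE, TRUE))
  # two presses in the first window: first paired, second ignored
  p3 <- assign_hits(cues, resp_tbl(c(1.2, 1.9), c(8, 6)), 11)
  expect_equal(p3$hit, c(TRUE, FALSE))
  expect_equal(p3$time_s[1], 1.2)
  # presses before the first onset are discarded and counted
  p4 <- assign_hits(cues, resp_tbl(c(0.5, 1.4), c(8, 8)), 11)
  expect_equal(attr(p4, "n_discarded"), 1L)
  expect_equal(p4$hit, c(TRUE, FALSE))
  # last window extends to trial end, not beyond
  p5 <- assign_hits(cues, resp_tbl(c(10.9, 11.5), c(6, 6)), 11)
  expect_equal(p5$hit, c(FALSE, TRUE))
  expect_equal(attr(p5, "n_discarded"), 1L)
})

test_that("hit assignment matches a brute-force interval matcher on random fixtures", {
  set.seed(21)
  for (rep in 1:50) {
    n_cues <- sample(2:6, 1)
    cues <- cue_tbl(
      sort(runif(n_cues, 0, 9)) + seq(0, by = 1, length.out = n_cues),
      sample(compass_directions(), n_cues, replace = TRUE)
    )
    n_resp <- sample(0:8, 1)
    resp <- resp_tbl(
      runif(n_resp, 0, 16),
      sample(c(1, 2, 3, 4, 6, 7, 8, 9), n_resp, replace = TRUE)
    )
    trial_end <- max(cues$onset_s) + runif(1, 0.6, 4)
    mine <- assign_hits(cues, resp, trial_end)
    oracle <- brute_force_assign(cues, resp, trial_end)
    expect_equal(mine$time_s, oracle$time_s)
    expect_equal(mine$key, oracle$key)
  }
})

test_that("detection performance counts any key press, localization accuracy only correct ones", {
  cues <- cue_tbl(c(1, 2.5, 4, 5.5), c("N", "E", "S", "W"))
  all_resp <- resp_tbl(c(1.3, 2.8, 4.2, 5.9), c(2, 6, 2, 8)) # 4 presses, 2 correct
  p <- assign_hits(cues, all_resp, 11)
  expect_equal(detection_performance(p), 1.0)
  expect_equal(localization_accuracy(p), 0.5)
  # detection ignores which keys were pressed
  perm_resp <- resp_tbl(c(1.3, 2.8, 4.2, 5.9), c(6, 2, 8, 2))
  expect_equal(detection_performance(assign_hits(cues, perm_resp, 11)), 1.0)
  # misses leave the localization denominator: 4 cues, 2 hits, 1 correct -> 0.5
  p2 <- assign_hits(cues, resp_tbl(c(1.3, 2.8), c(8, 2)), 11)
  expect_equal(detection_performance(p2), 0.5)
  expect_equal(localization_accuracy(p2), 0.5)
  # degenerate cells are signalled, not zero-filled
  expect_error(detection_performance(p[0, ]), "zero cues")
  p_none <- assign_hits(cues, resp_tbl(numeric(0), integer(0)), 11)
  expect_equal(detection_performance(p_none), 0)
  expect_error(localization_accuracy(p_none), "zero detected")
})

test_that("error variance is the n-1 sample variance of signed errors", {
  expect_equal(error_variance(c(0, 0, 0, 0)), 0)
  expect_equal(error_variance(c(45, -45)), 4050)
  expect_message(expect_true(is.na(error_variance(45))), "fewer than 2")
  set.seed(22)
  for (rep in 1:20) {
    errs <- sample(c(0, 45, -45, 90, -90, 135, -135, 180), sample(2:40, 1), replace = TRUE)
    expect_equal(error_variance(errs), brute_force_variance(errs))
    expect_equal(error_variance(-errs), error_variance(errs))
  }
})

test_that("median search time uses midpoint interpolation and resists outliers", {
  expect_equal(median_search_time(c(2, 4, 9)), 4)
  expect_equal(median_search_time(c(2, 4)), 3)
  set.seed(23)
  times <- c(rlnorm(30, log(4), 0.4), 100)
  m1 <- median_search_time(times)
  expect_true(m1 >= min(times) && m1 <= max(times))
  expect_equal(median_search_time(c(times[1:30], 1000)), m1)
  expect_equal(m1, sort(times)[16]) # brute-force sort-and-pick, odd n
  expect_error(median_search_time(numeric(0)), "Empty cell")
})

test_that("interference and its percentage reduction follow the definitions", {
  expect_equal(interference(7, 4), 3)
  expect_equal(interference(3.5, 4), -0.5)
  expect_equal(interference_reduction_pct(0.98, 2.96), 33)
  expect_equal(interference_reduction_pct(0, 2.96), 0)
  expect_error(interference_reduction_pct(1, 0), "undefined")
})

test_that("search accuracy is the fraction of correct present/absent judgements", {
  expect_equal(search_accuracy(rep(TRUE, 10)), 1.0)
  expect_equal(search_accuracy(c(rep(TRUE, 8), rep(FALSE, 2))), 0.8)
  # chance-level generator lands in the binomial interval around 0.5
  set.seed(24)
  acc <- search_accuracy(sample(c(TRUE, FALSE), 1000, replace = TRUE))
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("mean RT over correct localizations only", {
  cues <- cue_tbl(c(1, 3, 5), c("N", "E", "S"))
  resp <- resp_tbl(c(1.4, 3.6, 5.2), c(8, 6, 4)) # first two correct, last wrong
  p <- assign_hits(cues, resp, 11)
  expect_equal(mean_rt_correct(p), mean(c(0.4, 0.6)))
  one <- assign_hits(cue_tbl(1, "N"), resp_tbl(1.45, 8), 11)
  expect_equal(mean_rt_correct(one), 0.45)
  wrong <- assign_hits(cue_tbl(1, "N"), resp_tbl(1.45, 2), 11)
  expect_message(expect_true(is.na(mean_rt_correct(wrong))), "no correct")
})

test_that("gaze screening rejects the one-degree bound for typical gaze spreads", {
  # per-subject means drawn as folded normal(0.6, 0.1): the one-sample test
  # against 1 degree should reject essentially always at n = 30
  set.seed(25)
  rejections <- vapply(1:500, function(i) {
    x <- abs(rnorm(30, 0.6, 0.1))
    one_sample_t(x, mu = 1)$p < 0.05 && mean(x) < 1
  }, logical(1))
  expect_gte(mean(rejections), 0.99)

  s <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:12),
    condition = "VS",
    median_gaze_deg = rep(0.65, 12)
  )
  g <- gaze_screen(s, threshold_deg = 1, conditions = "VS")
  expect_equal(g$mean_gaze_deg, 0.65)
  expect_lt(g$t, 0)
})

test_that("condition summaries agree with brute-force recomputation from raw events", {
  tr <- generate_experiment(design_spec(n_subjects = 2, n_blocks = 7), seed = 77)
  s <- suppressMessages(condition_summaries(tr))
  cell <- function(subj, cond) s[s$subject_id == subj & s$condition == cond, ]
  for (subj in c("S01", "S02")) {
    for (cond in c("VI", "TA+VS")) {
      rows <- tr[tr$subject_id == subj & tr$condition == cond, ]
      n_cues <- 0L
      n_hits <- 0L
      n_correct <- 0L
      errs <- numeric(0)
      rts <- numeric(0)
      for (i in seq_len(nrow(rows))) {
        o <- brute_force_assign(rows$cues[[i]], rows$responses[[i]], rows$active_duration_s[i])
        hit <- !is.na(o$time_s)
        n_cues <- n_cues + nrow(rows$cues[[i]])
        n_hits <- n_hits + sum(hit)
        dirs <- rows$cues[[i]]$direction[hit]
        resp_dirs <- key_to_direction(o$key[hit])
        n_correct <- n_correct + sum(dirs == resp_dirs)
        errs <- c(errs, signed_angular_error(dirs, resp_dirs))
        ok <- dirs == resp_dirs
        rts <- c(rts, (o$time_s[hit] - rows$cues[[i]]$onset_s[hit])[ok])
      }
      got <- cell(subj, cond)
      expect_equal(got$detection_performance, n_hits / n_cues)
      expect_equal(got$localization_accuracy, n_correct / n_hits)
      expect_equal(got$error_variance_deg2, brute_force_variance(errs))
      expect_equal(got$mean_rt_correct_s, mean(rts))
      if (cond == "TA+VS") {
        expect_equal(got$median_search_time_s, median(rows$search_time_s))
        expect_equal(got$search_accuracy, mean(rows$search_response_correct))
      } else {
        expect_true(is.na(got$median_search_time_s))
      }
    }
  }
})

test_that("interference table subtracts the single-task search median per subject", {
  s <- tibble::tibble(
    subject_id = rep(c("S01", "S02"), each = 4),
    condition = rep(c("VS", "VI+VS", "TA+VS", "VITA+VS"), 2),
    median_search_time_s = c(4, 7, 6, 6.2, 5, 9, 7.5, 7.4)
  )
  it <- interference_table(s)
  expect_equal(
    it$per_subject$interference_s[it$per_subject$subject_id == "S01"],
    c(3, 2, 2.2)
  )
  expect_equal(it$group$overall_mean_s, mean(c(mean(c(3, 2, 2.2)), mean(c(4, 2.5, 2.4)))))
})
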