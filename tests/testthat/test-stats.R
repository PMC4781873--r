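make_rm_data <- function(n = 12, levels_a = c("single", "dual"),
                         levels_b = c("VI", "TA", "VITA"),
                         effect_a = 0, effect_b = 0, mean0 = 100, sd = 10) {
  d <- expand.grid(
    subject = factor(seq_len(n)),
    task = factor(levels_a, levels = levels_a),
    modality = factor(levels_b, levels = levels_b)
  )
  d$y <- mean0 + rnorm(n)[d$subject] +
    effect_a * as.integer(d$task) + effect_b * as.integer(d$modality) +
    rnorm(nrow(d), 0, sd)
  d
}

test_that("Holm correction matches the hand-computed step-down fixture", {
  # sorted (0.01 x 3, 0.03 x 2, 0.04 x 1) = (0.03, 0.06, 0.04), running max
  # (0.03, 0.06, 0.06), mapped back to the input order
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(0.2), 0.2)
  expect_error(holm_bonferroni(c(0.1, 1.3)), "\\[0, 1\\]")
  set.seed(31)
  for (rep in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holm_bonferroni(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # invariant under permutation after mapping back
    perm <- sample(seq_along(p))
    expect_equal(holm_bonferroni(p[perm]), adj[perm])
    # monotone in rank
    expect_true(all(diff(adj[order(p)]) >= 0))
  }
})

test_that("t-test wrappers return two-sided results and signal degenerate input", {
  set.seed(32)
  x <- rnorm(12, 0.65, 0.1)
  tt <- one_sample_t(x, mu = 1)
  expect_lt(tt$t, 0)
  expect_equal(tt$df, 11)
  ref <- t.test(x, mu = 1)
  expect_equal(tt$p, ref$p.value)
  y <- rnorm(12)
  expect_error(paired_t(y + 1, y), "Zero variance")
  expect_error(one_sample_t(rep(2, 5), 1), "Zero variance")
  expect_error(paired_t(1, 2), "two pairs")
})

test_that("null-generated paired tests reject at about the nominal rate", {
  set.seed(33)
  rej <- vapply(1:1000, function(i) {
    x <- rnorm(12)
    y <- rnorm(12)
    paired_t(x, y)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("Mauchly's test is trivial for two levels and matches car on fixtures", {
  skip_if_not_installed("car")
  set.seed(34)
  Y2 <- matrix(rnorm(24), 12, 2)
  m2 <- mauchly_test(Y2)
  expect_equal(m2$W, 1)
  expect_equal(m2$p, 1)
  for (rep in 1:5) {
    Y <- matrix(rnorm(12 * 3), 12, 3) %*% matrix(runif(9, -1, 1), 3, 3)
    Y <- Y + 50
    mine <- mauchly_test(Y)
    idata <- data.frame(level = factor(1:3))
    aa <- car::Anova(lm(Y ~ 1), idata = idata, idesign = ~level, type = 3)
    s <- suppressWarnings(summary(aa, multivariate = FALSE))
    expect_equal(unname(mine$W), unname(s$sphericity.tests[1, 1]), tolerance = 1e-10)
    expect_equal(unname(mine$p), unname(s$sphericity.tests[1, 2]), tolerance = 1e-10)
  }
})

test_that("Mauchly's test detects strong heteroscedasticity and keeps its size under sphericity", {
  set.seed(35)
  # power: wildly different level variances at n = 50
  Y <- cbind(rnorm(50, 0, 0.2), rnorm(50, 0, 3), rnorm(50, 0, 12))
  m <- mauchly_test(Y)
  expect_lt(m$W, 1)
  expect_lt(m$p, 0.01)
  # size: iid (hence compound-symmetric) generator, k = 3, n = 12
  rej <- vapply(1:1000, function(i) {
    mauchly_test(matrix(rnorm(36), 12, 3))$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("GG epsilon is 1 for two levels and exactly spherical scores, and matches Box's formula", {
  expect_equal(gg_epsilon(matrix(rnorm(24), 12, 2)), 1)
  # construct data whose orthonormal-contrast covariance is exactly identity
  set.seed(36)
  n <- 12
  k <- 4
  Z <- matrix(rnorm(n * (k - 1)), n, k - 1)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- Z %*% solve(chol(cov(Z))) # contrast scores with unit sample covariance
  M <- qr.Q(qr(stats::contr.helmert(k)))
  Y <- Z %*% t(M)
  expect_equal(gg_epsilon(Y), 1)
  # fixture equivalence against the independent raw-covariance formula
  for (rep in 1:10) {
    Yr <- matrix(rnorm(12 * 3), 12, 3) %*% matrix(runif(9, -1, 1), 3, 3)
    expect_equal(gg_epsilon(Yr), brute_force_gg_epsilon(Yr), tolerance = 1e-12)
  }
})

test_that("the normality gate passes normal residuals and transforms lognormal ones", {
  set.seed(37)
  flags <- vapply(1:500, function(i) {
    d <- make_rm_data(n = 14, sd = 5)
    normality_gate(d, "y", c("task", "modality"))$transformed
  }, logical(1))
  expect_lt(mean(flags), 0.10)

  res <- vapply(1:200, function(i) {
    d <- make_rm_data(n = 14, sd = 0)
    d$y <- exp(rnorm(nrow(d), 1, 0.8)) # heavily skewed positive values
    g <- normality_gate(d, "y", c("task", "modality"))
    cell <- interaction(d[c("task", "modality")])
    p_after <- shapiro.test(g$data$y - ave(g$data$y, cell))$p.value
    p_before <- g$shapiro_p
    c(flag = g$transformed, improved = p_after > p_before)
  }, c(flag = NA, improved = NA))
  expect_gt(mean(res["flag", ]), 0.5)
  expect_gt(median(res["improved", res["flag", ] == 1]), 0.5)

  d <- make_rm_data(n = 6)
  d$y <- 5
  expect_message(g <- normality_gate(d, "y", c("task", "modality")), "degenerate")
  expect_false(g$transformed)

  d2 <- make_rm_data(n = 14, sd = 0)
  d2$y <- exp(rnorm(nrow(d2), 0, 1)) - 0.5 # skewed with non-positive values
  expect_error(normality_gate(d2, "y", c("task", "modality")), "non-positive")
})

test_that("two-level within factors give F equal to the squared paired t", {
  set.seed(38)
  n <- 12
  d <- expand.grid(subject = factor(1:n), task = factor(c("single", "dual")))
  d$y <- 100 + rnorm(n)[d$subject] + 2 * as.integer(d$task) + rnorm(nrow(d), 0, 3)
  res <- rm_anova(d, "y", "subject", "task", gate = FALSE)
  x <- d$y[d$task == "single"]
  y <- d$y[d$task == "dual"]
  tt <- paired_t(x, y)
  expect_equal(res$F, tt$t^2, tolerance = 1e-12)
  expect_equal(res$p, tt$p, tolerance = 1e-12)
  expect_equal(res$df_num, 1)
  expect_equal(res$df_den, n - 1)
  # two-level pipeline is correction-free
  expect_equal(res$mauchly_W, 1)
  expect_equal(res$gg_epsilon, 1)
  expect_false(res$correction_applied)
})

test_that("the two-factor ANOVA agrees with an orthogonal-contrast GLM and car", {
  skip_if_not_installed("car")
  set.seed(39)
  for (rep in 1:3) {
    d <- make_rm_data(n = 12, effect_a = 2, effect_b = 1.5, sd = 4)
    mine <- rm_anova(d, "y", "subject", c("task", "modality"), gate = FALSE)

    # independent orthogonal-contrast GLM: per effect, contrast scores of the
    # cell matrix; F = n * ||mean score||^2 / df over within-subject residuals
    Y <- tapply(d$y, list(d$subject, d$task, d$modality), mean)
    n <- dim(Y)[1]
    contrast_F <- function(C, Ymat, df_num) {
      Z <- Ymat %*% C
      zbar <- colMeans(Z)
      ss_eff <- n * sum(zbar^2)
      ss_err <- sum(sweep(Z, 2, zbar)^2)
      df_den <- df_num * (n - 1)
      (ss_eff / df_num) / (ss_err / df_den)
    }
    Qa <- qr.Q(qr(stats::contr.helmert(2)))
    Qb <- qr.Q(qr(stats::contr.helmert(3)))
    Ya <- apply(Y, c(1, 2), mean)
    Yb <- apply(Y, c(1, 3), mean)
    Yab <- matrix(aperm(Y, c(1, 3, 2)), nrow = n)
    F_oracle <- c(
      contrast_F(Qa, Ya, 1),
      contrast_F(Qb, Yb, 2),
      contrast_F(kronecker(Qa, Qb), Yab, 2)
    )
    expect_equal(mine$F, F_oracle, tolerance = 1e-9)

    # car agreement on F, p, sphericity and GG correction
    idata <- expand.grid(
      task = factor(c("single", "dual"), levels = c("single", "dual")),
      modality = factor(c("VI", "TA", "VITA"), levels = c("VI", "TA", "VITA"))
    )
    Ymat <- matrix(Y, nrow = n)
    aa <- car::Anova(lm(Ymat ~ 1), idata = idata, idesign = ~ task * modality, type = 3)
    s <- suppressWarnings(summary(aa, multivariate = FALSE))
    u <- s$univariate.tests
    expect_equal(mine$F, unname(u[-1, "F value"]), tolerance = 1e-6)
    expect_equal(mine$p, unname(u[-1, "Pr(>F)"]), tolerance = 1e-6)
    expect_equal(
      mine$mauchly_W[2:3],
      unname(s$sphericity.tests[, "Test statistic"]),
      tolerance = 1e-6
    )
    expect_equal(
      mine$gg_epsilon[2:3],
      unname(s$pval.adjustments[, "GG eps"]),
      tolerance = 1e-6
    )
    expect_equal(
      mine$corrected_p[2:3],
      unname(s$pval.adjustments[, "Pr(>F[GG])"]),
      tolerance = 1e-6
    )
  }
})

test_that("one-factor ANOVA matches aov and GG-corrected p never falls below raw", {
  set.seed(40)
  n <- 10
  d <- expand.grid(subject = factor(1:n), cond = factor(paste0("c", 1:4)))
  d$y <- 60 + rnorm(n)[d$subject] + rep(c(0, 1, 0.5, 2), each = n) + rnorm(nrow(d), 0, 2)
  mine <- rm_anova(d, "y", "subject", "cond", gate = FALSE)
  fit <- summary(aov(y ~ cond + Error(subject / cond), data = d))
  tab <- fit[["Error: subject:cond"]][[1]]
  expect_equal(mine$F, tab["cond", "F value"], tolerance = 1e-10)
  expect_equal(mine$p, tab["cond", "Pr(>F)"], tolerance = 1e-10)
  expect_lte(mine$gg_epsilon, 1)
  expect_gte(mine$gg_epsilon, 1 / 3)
  expect_gte(mine$corrected_p, mine$p)
})

test_that("incomplete or unbalanced cell tables are rejected with the subject named", {
  d <- make_rm_data(n = 6)
  expect_error(
    rm_anova(d[-1, ], "y", "subject", c("task", "modality")),
    "offending subject"
  )
  d2 <- rbind(d, d[1, ])
  expect_error(
    rm_anova(d2, "y", "subject", c("task", "modality")),
    "exactly one observation"
  )
})

test_that("post-hoc pairwise table averages over the other factor and applies Holm", {
  set.seed(41)
  d <- make_rm_data(n = 12, effect_b = 3, sd = 2)
  post <- posthoc_pairwise(d, "y", "subject", "modality")
  expect_equal(nrow(post), 3)
  expect_equal(post$p_holm, holm_bonferroni(post$p))
  # the marginal-mean differences match manual averaging
  agg <- aggregate(y ~ subject + modality, d, mean)
  for (i in seq_len(nrow(post))) {
    lv <- strsplit(post$comparison[i], " vs ")[[1]]
    tt <- paired_t(
      agg$y[agg$modality == lv[1]],
      agg$y[agg$modality == lv[2]]
    )
    expect_equal(post$t[i], tt$t)
  }
})
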