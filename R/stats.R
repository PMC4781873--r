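# Repeated-measures inference: Shapiro-Wilk normality gate with natural-log
# transform, one- and two-factor within-subject ANOVA with Mauchly's
# sphericity test and Greenhouse-Geisser correction, t-test wrappers, and
# Holm-Bonferroni correction.
#
# The sum-of-squares partition is computed from cell/marginal means
# (classical balanced within-subject decomposition). Sphericity diagnostics
# are computed from the covariance of orthonormal-contrast scores with the
# sample (n - 1) divisor.

orthonormal_contrasts <- function(k) {
  qr.Q(qr(stats::contr.helmert(k)))
}

mauchly_from_scores <- function(Z) {
  p <- ncol(Z)
  n <- nrow(Z)
  if (p == 1) return(list(W = 1, p = 1))
  S <- cov(Z)
  detS <- det(S)
  trS <- sum(diag(S))
  if (!is.finite(detS) || detS <= 0 || trS <= 0) {
    abort("Singular contrast covariance: Mauchly's test is undefined.")
  }
  W <- detS / (trS / p)^p
  d <- n - 1
  A <- (2 * p^2 + p + 2) / (6 * p)
  chisq <- -(d - A) * log(W)
  df <- p * (p + 1) / 2 - 1
  list(W = W, p = pchisq(chisq, df, lower.tail = FALSE))
}

gg_from_scores <- function(Z) {
  p <- ncol(Z)
  if (p == 1) return(1)
  S <- cov(Z)
  trS <- sum(diag(S))
  if (!all(is.finite(S)) || trS <= 0) {
    abort("Singular contrast covariance: epsilon is undefined.")
  }
  eps <- trS^2 / (p * sum(S^2))
  min(max(eps, 1 / p), 1)
}

#' Mauchly's test for sphericity
#'
#' Likelihood-ratio test of the sphericity assumption on a within-subject
#' factor: equal variances of all pairwise level differences. `W` is
#' computed from the sample covariance of the `k - 1` orthonormal-contrast
#' scores; the p-value uses the standard chi-square approximation. With two
#' levels sphericity holds trivially (`W = 1`, `p = 1`).
#'
#' @param values A numeric matrix, subjects in rows, the `k` levels of one
#'   within-subject factor in columns.
#' @return A list with `W` and `p`.
#' @export
#' @examples
#' set.seed(1)
#' mauchly_test(matrix(rnorm(36), 12, 3))
mauchly_test <- function(values) {
  values <- as.matrix(values)
  k <- ncol(values)
  if (k < 2) abort("At least two levels are required.")
  if (nrow(values) < 3) abort("At least three subjects are required.")
  Z <- values %*% orthonormal_contrasts(k)
  mauchly_from_scores(Z)
}

#' Greenhouse-Geisser epsilon
#'
#' Estimates the sphericity-departure index epsilon-hat from the
#' orthonormal-contrast covariance of a within-subject factor:
#' `tr(S)^2 / ((k - 1) * tr(S^2))`, clipped to `[1/(k - 1), 1]`. The
#' covariance uses the sample (`n - 1`) divisor. ANOVA degrees of freedom
#' are multiplied by epsilon when sphericity is rejected.
#'
#' @inheritParams mauchly_test
#' @return A single epsilon value in `[1/(k - 1), 1]`.
#' @export
gg_epsilon <- function(values) {
  values <- as.matrix(values)
  k <- ncol(values)
  if (k < 2) abort("At least two levels are required.")
  Z <- values %*% orthonormal_contrasts(k)
  gg_from_scores(Z)
}

#' Normality gate with natural-log transform
#'
#' Tests the cell-mean-centred residuals of a dependent variable with a
#' pooled Shapiro-Wilk test; when normality is rejected at `alpha` the
#' variable is transformed with the natural logarithm (requiring strictly
#' positive values) before analysis.
#'
#' @param data A data frame in long format.
#' @param dv Name of the dependent-variable column.
#' @param cells Character vector of columns defining the design cells used
#'   for centring.
#' @param alpha Significance level of the Shapiro-Wilk test.
#' @return A list with `data` (possibly log-transformed `dv`),
#'   `transformed` (logical flag) and `shapiro_p`.
#' @export
normality_gate <- function(data, dv, cells, alpha = 0.05) {
  stopifnot(dv %in% names(data), all(cells %in% names(data)))
  y <- data[[dv]]
  if (!is.numeric(y)) abort("The dependent variable must be numeric.")
  cell_id <- interaction(data[cells], drop = TRUE)
  resid <- y - stats::ave(y, cell_id)
  if (sd(resid) == 0) {
    inform("normality_gate: degenerate (constant) residuals; no transform applied.")
    return(list(data = data, transformed = FALSE, shapiro_p = NA_real_))
  }
  p <- shapiro.test(resid)$p.value
  if (p >= alpha) {
    return(list(data = data, transformed = FALSE, shapiro_p = p))
  }
  if (any(y <= 0)) {
    abort(paste(
      "Normality is rejected but the dependent variable has non-positive",
      "values; add an offset or analyse untransformed data explicitly."
    ))
  }
  data[[dv]] <- log(y)
  list(data = data, transformed = TRUE, shapiro_p = p)
}

check_complete_balanced <- function(data, dv, subject, within) {
  cell_id <- interaction(data[within], drop = FALSE)
  tab <- table(data[[subject]], cell_id)
  if (any(tab != 1)) {
    bad <- rownames(tab)[apply(tab != 1, 1, any)]
    abort(sprintf(
      "Each subject needs exactly one observation per cell; offending subject(s): %s. Aggregate to cell means first.",
      paste(bad, collapse = ", ")
    ))
  }
  if (anyNA(data[[dv]])) abort("The dependent variable contains missing values.")
  if (length(unique(data[[subject]])) < 2) abort("At least two subjects are required.")
  invisible(TRUE)
}

effect_row <- function(effect, ss, df_num, ss_err, df_den, Z, alpha) {
  F_val <- (ss / df_num) / (ss_err / df_den)
  p_val <- pf(F_val, df_num, df_den, lower.tail = FALSE)
  if (ncol(Z) > 1) {
    mau <- mauchly_from_scores(Z)
    eps <- gg_from_scores(Z)
  } else {
    mau <- list(W = 1, p = 1)
    eps <- 1
  }
  corrected <- mau$p < alpha && eps < 1
  tibble(
    effect = effect,
    df_num = df_num, df_den = df_den, F = F_val, p = p_val,
    mauchly_W = mau$W, mauchly_p = mau$p, gg_epsilon = eps,
    corrected_df_num = eps * df_num, corrected_df_den = eps * df_den,
    corrected_p = pf(F_val, eps * df_num, eps * df_den, lower.tail = FALSE),
    correction_applied = corrected
  )
}

#' Repeated-measures ANOVA with sphericity correction
#'
#' One- or two-factor fully within-subject ANOVA on a complete balanced
#' cell-mean table. The dependent variable first passes the
#' [normality_gate()] (log transform on Shapiro-Wilk rejection). Sums of
#' squares are partitioned into effect and subject-by-effect error strata;
#' for every effect with more than two levels Mauchly's test is run and,
#' when it rejects at `alpha`, the Greenhouse-Geisser-corrected degrees of
#' freedom and p-value are the ones to report (`correction_applied` marks
#' those effects; corrected columns are provided for all effects).
#' Two-level effects are correction-free by construction (`W = 1`,
#' `epsilon = 1`).
#'
#' @param data Long-format data frame with one row per subject and cell.
#' @param dv Name of the dependent-variable column.
#' @param subject Name of the subject-identifier column.
#' @param within Character vector of one or two within-subject factor
#'   columns.
#' @param alpha Significance level used by the normality gate and the
#'   sphericity gate.
#' @param gate Apply the normality gate (set `FALSE` to analyse the
#'   variable as supplied).
#' @return A tibble of class `vt_anova`, one row per effect, with columns
#'   `effect`, `df_num`, `df_den`, `F`, `p`, `mauchly_W`, `mauchly_p`,
#'   `gg_epsilon`, `corrected_df_num`, `corrected_df_den`, `corrected_p`,
#'   `correction_applied`, `transform_applied`.
#' @export
#' @examples
#' d <- expand.grid(subject = factor(1:12), task = c("single", "dual"),
#'                  modality = c("VI", "TA", "VITA"))
#' set.seed(1)
#' d$y <- 10 + as.integer(d$task) + rnorm(nrow(d))
#' rm_anova(d, "y", "subject", c("task", "modality"))
rm_anova <- function(data, dv, subject, within, alpha = 0.05, gate = TRUE) {
  stopifnot(
    is.data.frame(data), dv %in% names(data), subject %in% names(data),
    all(within %in% names(data)), length(within) %in% c(1, 2)
  )
  check_complete_balanced(data, dv, subject, within)
  transformed <- FALSE
  if (gate) {
    gated <- normality_gate(data, dv, cells = within, alpha = alpha)
    data <- gated$data
    transformed <- gated$transformed
  }
  for (w in within) {
    if (!is.factor(data[[w]])) data[[w]] <- factor(data[[w]], levels = unique(data[[w]]))
    data[[w]] <- droplevels(data[[w]])
  }
  subj <- factor(data[[subject]])
  n <- nlevels(subj)
  y <- data[[dv]]
  A <- data[[within[1]]]
  a <- nlevels(A)
  Qa <- orthonormal_contrasts(a)

  if (length(within) == 1) {
    # one-way: Y[n, a] (exactly one observation per cell, validated above)
    Y <- tapply(y, list(subj, A), mean)
    G <- mean(Y)
    A_m <- colMeans(Y)
    S_m <- rowMeans(Y)
    ss_A <- n * sum((A_m - G)^2)
    ss_err <- sum((Y - outer(S_m, A_m, `+`) + G)^2)
    res <- effect_row(
      within[1], ss_A, a - 1, ss_err, (a - 1) * (n - 1),
      Z = Y %*% Qa, alpha
    )
  } else {
    B <- data[[within[2]]]
    b <- nlevels(B)
    Qb <- orthonormal_contrasts(b)
    Y <- tapply(y, list(subj, A, B), mean)
    G <- mean(Y)
    A_m <- apply(Y, 2, mean)
    B_m <- apply(Y, 3, mean)
    AB_m <- apply(Y, c(2, 3), mean)
    S_m <- apply(Y, 1, mean)
    SA_m <- apply(Y, c(1, 2), mean)
    SB_m <- apply(Y, c(1, 3), mean)
    ss_A <- n * b * sum((A_m - G)^2)
    ss_B <- n * a * sum((B_m - G)^2)
    ss_AB <- n * sum((AB_m - outer(A_m, B_m, `+`) + G)^2)
    ss_SA <- b * sum((SA_m - outer(S_m, A_m, `+`) + G)^2)
    ss_SB <- a * sum((SB_m - outer(S_m, B_m, `+`) + G)^2)
    ss_total <- sum((Y - G)^2)
    ss_S <- a * b * sum((S_m - G)^2)
    ss_SAB <- ss_total - ss_A - ss_B - ss_AB - ss_S - ss_SA - ss_SB
    # cell matrix n x (a*b), columns ordered with B fastest to match
    # kronecker(Qa, Qb) on interaction contrasts
    Ymat <- matrix(aperm(Y, c(1, 3, 2)), nrow = n) # columns: (A1,B1..Bb), (A2,B1..)
    res <- dplyr::bind_rows(
      effect_row(
        within[1], ss_A, a - 1, ss_SA, (a - 1) * (n - 1),
        Z = apply(Y, c(1, 2), mean) %*% Qa, alpha
      ),
      effect_row(
        within[2], ss_B, b - 1, ss_SB, (b - 1) * (n - 1),
        Z = apply(Y, c(1, 3), mean) %*% Qb, alpha
      ),
      effect_row(
        paste(within, collapse = ":"), ss_AB, (a - 1) * (b - 1),
        ss_SAB, (a - 1) * (b - 1) * (n - 1),
        Z = Ymat %*% kronecker(Qa, Qb), alpha
      )
    )
  }
  res$transform_applied <- transformed
  class(res) <- c("vt_anova", class(res))
  attr(res, "n_subjects") <- n
  res
}

#' @export
print.vt_anova <- function(x, ...) {
  cat("<vt_anova> within-subject ANOVA, n =", attr(x, "n_subjects"),
    "subjects", if (x$transform_applied[1]) "(log-transformed DV)" else "",
    "\n"
  )
  for (i in seq_len(nrow(x))) {
    if (x$correction_applied[i]) {
      cat(sprintf(
        "  %-16s F(%.2f, %.2f) = %.2f, p = %.4g  [GG eps = %.3f, Mauchly p = %.3g]\n",
        x$effect[i], x$corrected_df_num[i], x$corrected_df_den[i], x$F[i],
        x$corrected_p[i], x$gg_epsilon[i], x$mauchly_p[i]
      ))
    } else {
      cat(sprintf(
        "  %-16s F(%d, %d) = %.2f, p = %.4g\n",
        x$effect[i], x$df_num[i], x$df_den[i], x$F[i], x$p[i]
      ))
    }
  }
  invisible(x)
}

#' Paired and one-sample t-tests
#'
#' Thin wrappers around [stats::t.test()] returning tidy lists and
#' signalling degenerate (zero-variance) inputs with a clear error. Tests
#' are two-sided with `df = n - 1`.
#'
#' @param x,y Numeric vectors (paired for `paired_t`).
#' @param mu Null value for the one-sample test.
#' @return A list with `t`, `df`, `p`, `mean_diff`.
#' @export
#' @examples
#' paired_t(c(1, 2, 3, 5), c(2, 2, 5, 7))
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  if (length(d) < 2) abort("At least two pairs are required.")
  se <- sd(d) / sqrt(length(d))
  if (se == 0 || se < 10 * .Machine$double.eps * abs(mean(d))) {
    abort("Zero variance of the paired differences: the t-test is undefined.")
  }
  tt <- t.test(x, y, paired = TRUE)
  list(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, mean_diff = unname(tt$estimate)
  )
}

#' @rdname paired_t
#' @export
one_sample_t <- function(x, mu = 0) {
  if (length(x) < 2) abort("At least two observations are required.")
  se <- sd(x) / sqrt(length(x))
  if (se == 0 || se < 10 * .Machine$double.eps * abs(mean(x) - mu)) {
    abort("Zero variance: the t-test is undefined.")
  }
  tt <- t.test(x, mu = mu)
  list(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, mean_diff = unname(tt$estimate) - mu
  )
}

#' Holm-Bonferroni step-down correction
#'
#' Sequentially rejective family-wise error correction: sorted p-values are
#' multiplied by decreasing factors and a running maximum enforces
#' monotonicity, capped at 1. Output order matches input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Corrected p-values, same length and order.
#' @export
#' @examples
#' holm_bonferroni(c(0.01, 0.04, 0.03))
holm_bonferroni <- function(pvals) {
  if (!is.numeric(pvals) || any(!is.finite(pvals)) ||
    any(pvals < 0 | pvals > 1)) {
    abort("All p-values must be finite numbers in [0, 1].")
  }
  p.adjust(pvals, method = "holm")
}

#' Holm-corrected pairwise post-hoc comparisons
#'
#' Averages the dependent variable over the remaining design cells per
#' subject and factor level (the marginal means the omnibus effect tested),
#' then runs all pairwise paired t-tests between levels and corrects the
#' family with [holm_bonferroni()].
#'
#' @inheritParams rm_anova
#' @param factor_name The within-subject factor whose levels are compared.
#' @return A tibble: `comparison`, `mean_diff`, `t`, `df`, `p`, `p_holm`.
#' @export
posthoc_pairwise <- function(data, dv, subject, factor_name) {
  stopifnot(
    dv %in% names(data), subject %in% names(data),
    factor_name %in% names(data)
  )
  agg <- data |>
    dplyr::group_by(
      .data[[subject]], .data[[factor_name]]
    ) |>
    dplyr::summarise(.y = mean(.data[[dv]]), .groups = "drop")
  wide <- tidyr::pivot_wider(agg,
    names_from = dplyr::all_of(factor_name), values_from = ".y"
  )
  levels <- setdiff(names(wide), subject)
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    tt <- paired_t(wide[[pr[1]]], wide[[pr[2]]])
    tibble(
      comparison = paste(pr, collapse = " vs "),
      mean_diff = tt$mean_diff, t = tt$t, df = tt$df, p = tt$p
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_holm <- holm_bonferroni(out$p)
  out
}
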