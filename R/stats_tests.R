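#' Group-level test result
#'
#' Light container for a nonparametric test outcome: the test name, the
#' z (or other) statistic, the p value, the effective sample size, and the
#' sidedness. Rank tests use the normal approximation with tie and
#' continuity corrections, appropriate for the group sizes this task
#' produces (tens of participants); exact enumeration is used only as an
#' oracle in the test suite.
#'
#' @param statistic_name character label.
#' @param z_or_stat the statistic.
#' @param p p value in \[0, 1\].
#' @param n effective sample size.
#' @param direction `"one-sided"` or `"two-sided"`.
#' @return Object of class `group_result`.
#' @export
group_result <- function(statistic_name, z_or_stat, p, n, direction) {
  stopifnot(p >= 0, p <= 1)
  structure(list(statistic_name = statistic_name, z_or_stat = z_or_stat,
                 p = p, n = n, direction = direction),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<%s: stat = %.3f, p = %.4g, n = %d (%s)>\n",
              x$statistic_name, x$z_or_stat, x$p, x$n, x$direction))
  invisible(x)
}

# Signed ranks of |d| with ties averaged; V = sum of ranks of positive d.
# Normal approximation: E[V] = n(n+1)/4,
# Var[V] = n(n+1)(2n+1)/24 - sum(t^3 - t)/48, continuity correction 0.5.
signed_rank_z <- function(d, alternative) {
  d <- d[d != 0]                     # standard convention: drop exact zeros
  n <- length(d)
  if (n < 1L) {
    stop(errorCondition("all differences are zero; test undefined",
                        class = c("circlelearn_undefined_test",
                                  "circlelearn_error")))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
  cc <- switch(alternative, greater = 0.5, less = -0.5, two.sided = 0.5 * sign(V - mu))
  z <- (V - mu - cc) / sqrt(sigma2)
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  list(V = V, z = z, p = min(p, 1), n = n)
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether the values are shifted away from `mu` (default 0), e.g.
#' whether a group's fraction learned exceeds zero. One-sided by default.
#' Zero differences are dropped before ranking.
#'
#' @param values numeric vector.
#' @param mu null location (default 0).
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return A [group_result()] carrying the z statistic; attribute `"V"`
#'   holds the signed-rank sum.
#' @export
wilcoxon_signed_rank <- function(values, mu = 0,
                                 alternative = c("greater", "less",
                                                 "two.sided")) {
  alternative <- match.arg(alternative)
  res <- signed_rank_z(values - mu, alternative)
  out <- group_result("wilcoxon_signed_rank", res$z, res$p, res$n,
                      if (alternative == "two.sided") "two-sided"
                      else "one-sided")
  attr(out, "V") <- res$V
  out
}

#' Paired Wilcoxon test on two matched samples
#'
#' Signed-rank test on the element-wise differences `x - y`; used to compare
#' each participant's median trial-to-trial ratio after failure with the one
#' after success. `alternative = "greater"` tests x > y.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return A [group_result()].
#' @export
paired_wilcoxon <- function(x, y, alternative = c("greater", "less",
                                                  "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop_domain("paired samples differ in length")
  res <- signed_rank_z(x - y, alternative)
  out <- group_result("paired_wilcoxon", res$z, res$p, res$n,
                      if (alternative == "two.sided") "two-sided"
                      else "one-sided")
  attr(out, "V") <- res$V
  out
}

#' Mann-Whitney U test for two independent groups
#'
#' U counts, over all cross-group pairs, how often a value from `group_a`
#' exceeds one from `group_b` (ties count one half). Normal approximation
#' with tie and continuity corrections. `alternative = "less"` tests that
#' `group_a` is stochastically smaller (e.g. children learned less than
#' adults).
#'
#' @param group_a,group_b numeric vectors.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return A [group_result()]; `z_or_stat` holds the z value, with the U
#'   statistic in attribute `"U"`.
#' @export
mann_whitney_u <- function(group_a, group_b,
                           alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  na <- length(group_a); nb <- length(group_b)
  if (na < 1L || nb < 1L) stop_domain("both groups must be non-empty")
  r <- rank(c(group_a, group_b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  N <- na + nb
  mu <- na * nb / 2
  tie <- table(r)
  sigma2 <- na * nb / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  cc <- switch(alternative, greater = 0.5, less = -0.5,
               two.sided = 0.5 * sign(U - mu))
  z <- if (sigma2 > 0) (U - mu - cc) / sqrt(sigma2) else 0
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  out <- group_result("mann_whitney_u", z, min(p, 1), N,
                      if (alternative == "two.sided") "two-sided"
                      else "one-sided")
  attr(out, "U") <- U
  out
}

#' Linear regression of a learning measure on capped age
#'
#' Ordinary least squares of `values` on `pmin(age, adult_cap)`: ages 7-17
#' enter as-is and all adults are grouped at the cap (default 18), so the
#' slope reflects development across childhood. Two-sided p for the slope.
#'
#' @param ages ages in years.
#' @param values response values.
#' @param adult_cap cap applied to adult ages (default 18).
#' @return List with `b` (slope per year), `intercept`, `r_squared`, `p`,
#'   `n`.
#' @export
regress_learning_on_age <- function(ages, values, adult_cap = 18) {
  stopifnot(length(ages) == length(values))
  if (length(ages) < 3L) stop_domain("need at least 3 observations")
  x <- pmin(ages, adult_cap)
  if (length(unique(x)) < 2L) stop_domain("constant predictor")
  fit <- stats::lm(values ~ x)
  sm <- summary(fit)
  list(b = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p = sm$coefficients[2, 4],
       n = length(values))
}

#' Pearson chi-square comparison of motivation scores between groups
#'
#' Builds a group x score-level contingency table over the discrete score
#' levels present in either group (two-item mean scores produce half-point
#' levels) and applies Pearson's chi-square without continuity correction;
#' df = levels - 1 for two groups.
#'
#' @param scores_a,scores_b numeric score vectors (discrete levels).
#' @return A [group_result()] with the chi-square statistic; attribute
#'   `"df"` holds the degrees of freedom, `"table"` the contingency table.
#' @export
chi_square_motivation <- function(scores_a, scores_b) {
  if (!length(scores_a) || !length(scores_b)) stop_domain("empty group")
  lev <- sort(unique(c(scores_a, scores_b)))
  tab <- rbind(a = table(factor(scores_a, levels = lev)),
               b = table(factor(scores_b, levels = lev)))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  out <- group_result("pearson_chi_square", unname(ct$statistic),
                      unname(ct$p.value), length(scores_a) + length(scores_b),
                      "two-sided")
  attr(out, "df") <- unname(ct$parameter)
  attr(out, "table") <- tab
  out
}

#' Cronbach's alpha of a questionnaire
#'
#' alpha = k/(k-1) * (1 - sum(item variances)/variance(total score)) over
#' complete respondents.
#'
#' @param items numeric matrix/data.frame, respondents x items.
#' @return Alpha (scalar).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  items <- items[stats::complete.cases(items), , drop = FALSE]
  k <- ncol(items)
  if (k < 2L || nrow(items) < 2L) {
    stop_domain("need at least 2 items and 2 complete respondents")
  }
  vt <- stats::var(rowSums(items))
  if (vt == 0) {
    stop(errorCondition("zero total-score variance; alpha undefined",
                        class = c("circlelearn_undefined_test",
                                  "circlelearn_error")))
  }
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / vt)
}

#' Motivation score from questionnaire items
#'
#' Screens the item battery by Cronbach's alpha and pairwise Pearson
#' item-item correlations, selects the pair of items that correlates most
#' strongly, and scores motivation as each respondent's mean of those two
#' items (rows with a missing value in the pair get `NA`).
#'
#' @param items numeric matrix/data.frame, respondents x items (1-5 Likert).
#' @return List: `score` (per respondent), `selected_items` (column indices
#'   of the chosen pair), `max_correlation`, `alpha_all` (full battery),
#'   `alpha_selected` (chosen pair), `correlations` (item-item matrix).
#' @export
motivation_score <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) < 2L) stop_domain("need at least 2 items")
  cors <- stats::cor(items, use = "pairwise.complete.obs")
  cc <- cors
  cc[!upper.tri(cc)] <- -Inf
  best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  pair <- as.integer(best)
  list(score = rowMeans(items[, pair, drop = FALSE]),
       selected_items = pair,
       max_correlation = cors[best[1], best[2]],
       alpha_all = cronbach_alpha(items),
       alpha_selected = cronbach_alpha(items[, pair, drop = FALSE]),
       correlations = cors)
}

#' Gaussian-kernel smoothing of a measure against log-age
#'
#' For visualizing development, values are averaged with Gaussian weights in
#' log-transformed age: at each grid point g the weight of participant i is
#' exp(-(log(age_i) - g)^2 / (2 * bw^2)), normalized. The default bandwidth
#' is log(1.1), i.e. one decade-of-life step of about 10%.
#'
#' @param ages ages in years (> 0).
#' @param values measure per participant.
#' @param bandwidth kernel SD in log-age units (default `log(1.1)`).
#' @param grid grid in log-age; default: log of each integer age present in
#'   the data range.
#' @return List of class `smoothed_curve`: `grid` (log-age), `age`
#'   (years), `value`, `bandwidth`.
#' @export
smooth_vs_age <- function(ages, values, bandwidth = log(1.1), grid = NULL) {
  stopifnot(length(ages) == length(values), all(ages > 0), bandwidth > 0)
  if (length(ages) < 2L) stop_domain("need at least 2 observations")
  la <- log(ages)
  if (is.null(grid)) grid <- log(seq(floor(min(ages)), ceiling(max(ages))))
  val <- vapply(grid, function(g) {
    w <- exp(-(la - g)^2 / (2 * bandwidth^2))
    sum(w * values) / sum(w)
  }, numeric(1))
  structure(list(grid = grid, age = exp(grid), value = val,
                 bandwidth = bandwidth),
            class = "smoothed_curve")
}
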