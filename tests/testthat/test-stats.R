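test_that("signed-rank statistic matches brute-force oracles up to n = 8", {
  set.seed(9)
  for (k in 1:25) {
    n <- sample(3:8, 1)
    d <- round(rnorm(n, 0.3, 1), 3)
    d <- d[d != 0]
    if (length(d) < 2 || anyDuplicated(abs(d))) next  # Walsh identity needs no ties
    res <- wilcoxon_signed_rank(d)
    # Walsh-average count identity (independent of the rank formula)
    expect_equal(attr(res, "V"), walsh_V(d))
    # agreement with the standard implementation
    wt <- suppressWarnings(stats::wilcox.test(d, mu = 0,
                                              alternative = "greater"))
    expect_equal(attr(res, "V"), unname(wt$statistic))
  }
})

test_that("signed-rank p matches exhaustive sign enumeration for small n", {
  set.seed(10)
  for (k in 1:5) {
    n <- sample(6:8, 1)
    d <- round(rnorm(n, 0.4, 1), 2)
    d <- unique(d[d != 0])
    n <- length(d)
    if (n < 5) next
    res <- wilcoxon_signed_rank(d)
    # exact null distribution of V by enumerating all 2^n sign patterns
    a <- abs(d); r <- rank(a)
    signs <- expand.grid(rep(list(c(0, 1)), n))
    vs <- as.matrix(signs) %*% r
    p_exact <- mean(vs >= attr(res, "V"))
    expect_lt(abs(res$p - p_exact), 0.06)
  }
})

test_that("signed-rank direction and null behavior are sane", {
  pos <- wilcoxon_signed_rank(c(0.2, 0.5, 0.1, 0.9, 0.4, 0.3))
  expect_gt(pos$z_or_stat, 0)
  expect_lt(pos$p, 0.05)
  sym <- wilcoxon_signed_rank(c(-3, -2, -1, 1, 2, 3))
  expect_lt(abs(sym$p - 0.5), 0.1)
  expect_error(wilcoxon_signed_rank(rep(0, 6)),
               class = "circlelearn_undefined_test")
})

test_that("paired test rejects when failure ratios exceed success ratios", {
  s <- c(1.05, 1.08, 1.11, 1.06, 1.09, 1.12, 1.07, 1.1, 1.04, 1.08)
  res <- paired_wilcoxon(s + 0.05, s)
  expect_lt(res$p, 0.01)
  expect_error(paired_wilcoxon(s, s), class = "circlelearn_undefined_test")
  expect_error(paired_wilcoxon(s, s[-1]), class = "circlelearn_domain_error")
})

test_that("paired test holds its nominal type-I error under the null", {
  set.seed(14)
  n_rep <- 400
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    x <- rnorm(25); y <- rnorm(25)
    rej[i] <- paired_wilcoxon(x, y)$p < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("Mann-Whitney U matches the pair-count oracle and wilcox.test", {
  set.seed(15)
  for (k in 1:25) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    a <- round(rnorm(na), 2); b <- round(rnorm(nb), 2)
    res <- mann_whitney_u(a, b, "greater")
    expect_equal(attr(res, "U"), pair_U(a, b))
    wt <- suppressWarnings(stats::wilcox.test(a, b,
                                              alternative = "greater"))
    expect_equal(attr(res, "U"), unname(wt$statistic))
  }
  # exhaustive single-element case
  expect_equal(attr(mann_whitney_u(1, 2, "greater"), "U"), 0)
  expect_equal(attr(mann_whitney_u(2, 1, "greater"), "U"), 1)
})

test_that("Mann-Whitney keeps its error rate and detects real shifts", {
  set.seed(16)
  n_rep <- 300
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    rej[i] <- mann_whitney_u(rnorm(20), rnorm(20), "greater")$p < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
  # power: a stochastically larger group at n = 30/30
  ps <- replicate(50, mann_whitney_u(rnorm(30, 0.8), rnorm(30),
                                     "greater")$p)
  expect_lt(median(ps), 0.05)
})

test_that("age regression caps adults and recovers exact lines", {
  ages <- c(7:17, 25, 40, 60)
  fit <- suppressWarnings(regress_learning_on_age(ages, 0.1 * pmin(ages, 18)))
  expect_equal(fit$b, 0.1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # all adults share the capped predictor: identical fitted values
  fit2 <- regress_learning_on_age(c(10, 14, 40, 60),
                                  c(0.2, 0.4, 0.5, 0.9))
  pred <- fit2$intercept + fit2$b * pmin(c(40, 60), 18)
  expect_equal(pred[1], pred[2])
  # age-independent values: negligible R^2
  set.seed(17)
  fit3 <- regress_learning_on_age(sample(7:60, 80, TRUE), rnorm(80))
  expect_lt(fit3$r_squared, 0.1)
  expect_error(regress_learning_on_age(c(20, 30, 40), 1:3),
               class = "circlelearn_domain_error")
})

test_that("chi-square over score levels matches hand computation", {
  expect_equal(chi_square_motivation(c(1, 2, 3, 3), c(1, 2, 3, 3))$z_or_stat,
               0)
  res <- chi_square_motivation(rep(1, 10), rep(2, 10))
  expect_equal(res$z_or_stat, 20)
  expect_equal(attr(res, "df"), 1)
  # df is levels - 1: nine observed half-point levels give 8
  a <- c(1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5)
  res2 <- chi_square_motivation(a, rev(a))
  expect_equal(attr(res2, "df"), 8)
})

test_that("alpha and item selection behave on constructed batteries", {
  # perfectly correlated items
  x <- rnorm(40)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1)
  # independent items: alpha near zero at large n
  set.seed(18)
  ind <- matrix(rnorm(5 * 4000), ncol = 5)
  expect_lt(abs(cronbach_alpha(ind)), 0.1)
  # the most-correlated pair is selected and scored as the row mean
  set.seed(19)
  n <- 300
  base <- rnorm(n)
  items <- cbind(q1 = base + rnorm(n, 0, 1),
                 q2 = base + rnorm(n, 0, 1),
                 q3 = rnorm(n), q4 = rnorm(n))
  ms <- motivation_score(items)
  cors <- cor(items); diag(cors) <- -Inf
  best <- which(cors == max(cors), arr.ind = TRUE)[1, ]
  expect_setequal(ms$selected_items, as.integer(best))
  expect_equal(ms$score, rowMeans(items[, ms$selected_items]))
  expect_gt(ms$alpha_selected, cronbach_alpha(items[, c(1, 3)]))
})

test_that("log-age smoothing interpolates, averages and shifts correctly", {
  ages <- c(8, 10, 13, 16, 20)
  const <- smooth_vs_age(ages, rep(0.4, 5))
  expect_true(all(abs(const$value - 0.4) < 1e-12))
  # two points, grid at the log midpoint: arithmetic mean
  two <- smooth_vs_age(c(8, 18), c(0.2, 0.8),
                       grid = mean(log(c(8, 18))))
  expect_equal(two$value, 0.5)
  # vanishing bandwidth at a data point returns that point's value
  tight <- smooth_vs_age(ages, c(1, 2, 3, 4, 5), bandwidth = 1e-4,
                         grid = log(13))
  expect_equal(tight$value, 3)
  # shift equivariance in the response
  sm1 <- smooth_vs_age(ages, c(1, 2, 3, 4, 5))
  sm2 <- smooth_vs_age(ages, c(1, 2, 3, 4, 5) + 10)
  expect_equal(sm2$value, sm1$value + 10)
  # weights decay monotonically with log-age distance
  w <- exp(-(log(ages) - log(12))^2 / (2 * log(1.1)^2))
  expect_true(all(rank(-w) == rank(abs(log(ages) - log(12)))))
})
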