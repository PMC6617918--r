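fig_pairs <- tibble::tibble(surgeon = c(75, 45, 35, 20),
                            patient = c(76, 44, 35, 18))

test_that("Bland-Altman on the four fundus-photograph pairs matches hand computation", {
  # surgeon - patient differences are (-1, +1, 0, +2):
  # mean 0.5, sample SD sqrt(5/3) = 1.2910, LoA = 0.5 +/- 1.96 * SD
  ba <- bland_altman(fig_pairs, surgeon, patient)
  expect_equal(ba$bias, 0.5)
  expect_equal(ba$sd_diff, 1.2909944487358056, tolerance = 1e-12)
  expect_equal(ba$loa_low, -2.030349119522179, tolerance = 1e-12)
  expect_equal(ba$loa_high, 3.030349119522179, tolerance = 1e-12)
  expect_equal(ba$n, 4L)
})

test_that("Bland-Altman oracle equivalence and shift invariance", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    df <- tibble::tibble(s = runif(n, 0, 100),
                         p = runif(n, 0, 100))
    ba <- bland_altman(df, s, p)
    d <- df$s - df$p
    expect_equal(ba$bias, mean(d), tolerance = 1e-12)
    expect_equal(ba$sd_diff, sqrt(sum((d - mean(d))^2) / (n - 1)),
                 tolerance = 1e-12)
    expect_equal(ba$loa_high - ba$bias, ba$bias - ba$loa_low,
                 tolerance = 1e-10)
    shifted <- bland_altman(dplyr::mutate(df, p = p + 7), s, p)
    expect_equal(shifted$bias, ba$bias - 7, tolerance = 1e-10)
    expect_equal(shifted$sd_diff, ba$sd_diff, tolerance = 1e-12)
  }
  ident <- bland_altman(tibble::tibble(s = c(3, 6, 9), p = c(3, 6, 9)), s, p)
  expect_equal(c(ident$bias, ident$sd_diff, ident$loa_low, ident$loa_high),
               c(0, 0, 0, 0))
  expect_error(bland_altman(tibble::tibble(s = 1, p = 2), s, p),
               class = "gasrisk_insufficient_data")
})

test_that("tidy, glance and autoplot methods expose the agreement fit", {
  ba <- bland_altman(fig_pairs, surgeon, patient)
  td <- generics::tidy(ba)
  expect_equal(td$term, c("bias", "loa_low", "loa_high"))
  expect_equal(td$estimate[1], 0.5)
  gl <- generics::glance(ba)
  expect_equal(gl$n, 4L)
  expect_equal(gl$multiplier, 1.96)
  p <- ggplot2::autoplot(ba)
  expect_s3_class(p, "ggplot")
})

test_that("Wilcoxon exact p-values come from full sign enumeration", {
  # six positive differences: the one-sided tail is the single all-positive
  # assignment out of 2^6, doubled for the two-sided test
  d6 <- tibble::tibble(a = c(1, 2, 3, 4, 5, 6), b = rep(0, 6))
  res <- wilcoxon_signed_rank(d6, a, b)
  expect_equal(res$p_value, 2 / 64)
  expect_equal(res$method, "exact")
  # role swap leaves the two-sided p unchanged
  df <- tibble::tibble(x = c(1, 3, 6), y = c(2, 5, 9))
  expect_equal(wilcoxon_signed_rank(df, x, y)$p_value,
               wilcoxon_signed_rank(df, y, x)$p_value)
  # degenerate: all differences zero
  same <- tibble::tibble(x = 1:4, y = 1:4)
  res0 <- wilcoxon_signed_rank(same, x, y)
  expect_true(res0$degenerate)
  expect_equal(res0$p_value, 1)
})

test_that("exact p matches stats::wilcox.test on tie-free data", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    ours <- wilcoxon_signed_rank(tibble::tibble(x = x, y = y), x, y,
                                 method = "exact")
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("approximate p matches stats::wilcox.test with continuity correction", {
  set.seed(6)
  for (i in 1:10) {
    x <- rnorm(40)
    y <- rnorm(40)
    ours <- wilcoxon_signed_rank(tibble::tibble(x = x, y = y), x, y,
                                 method = "approx")
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                              correct = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("exact and approximate p agree closely at n = 15", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(15)
    y <- rnorm(15)
    df <- tibble::tibble(x = x, y = y)
    pe <- wilcoxon_signed_rank(df, x, y, method = "exact")$p_value
    pa <- wilcoxon_signed_rank(df, x, y, method = "approx")$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("exact enumeration handles ties through doubled average ranks", {
  # tied absolute differences: |d| = (1, 1, 2, 2) -> average ranks
  # (1.5, 1.5, 3.5, 3.5); the null distribution over 2^4 assignments is
  # enumerable by hand through doubled ranks (3, 3, 7, 7)
  df <- tibble::tibble(x = c(1, 0, 2, 0), y = c(0, 1, 0, 2))
  res <- wilcoxon_signed_rank(df, x, y, method = "exact")
  # brute-force enumeration oracle
  r2 <- c(3, 3, 7, 7)
  sums <- vapply(0:15, function(mask)
    sum(r2[bitwAnd(mask, 2^(0:3)) > 0]), numeric(1))
  s_obs <- 3 + 7  # positive differences hold one rank-1.5 and one rank-3.5
  p_brute <- min(1, 2 * min(mean(sums <= s_obs), mean(sums >= s_obs)))
  expect_equal(res$p_value, p_brute)
})

test_that("median/range summary and Likert tabulation", {
  s <- summarize_range(c(75, 45, 35, 20))
  expect_equal(s$median, 40)
  expect_equal(c(s$min, s$max), c(20, 75))
  expect_equal(summarize_range(5)$median, 5)
  expect_equal(summarize_range(c(1, 2, 3))$median, 2)
  expect_error(summarize_range(numeric(0)),
               class = "gasrisk_insufficient_data")

  tab <- tabulate_likert(c(5, 5, 4))
  expect_equal(tab$count, c(0, 0, 0, 1, 2))
  expect_equal(tab$proportion, c(0, 0, 0, 1 / 3, 2 / 3))
  empty <- tabulate_likert(integer(0))
  expect_equal(empty$count, rep(0L, 5))
  expect_error(tabulate_likert(c(5, 6)), "index 2",
               class = "gasrisk_validation_error")
  set.seed(13)
  draws <- sample(1:5, 50, replace = TRUE, prob = c(.1, .1, .2, .3, .3))
  tab50 <- tabulate_likert(draws)
  expect_equal(tab50$count,
               vapply(1:5, function(l) sum(draws == l), integer(1)))
  expect_equal(sum(tab50$count), 50)
  expect_equal(sum(tab50$proportion), 1)
})
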