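#' Bland-Altman agreement between two raters
#'
#' Computes the bias (mean of paired differences), the sample SD of the
#' differences (n - 1 denominator) and the limits of agreement
#' `bias +/- multiplier * sd`. Differences are taken as
#' `surgeon - patient` (first rater minus second), the convention under
#' which a rater who under-reads relative to the other produces a negative
#' bias.
#'
#' @param data A data frame with one row per paired judgment.
#' @param surgeon,patient Columns holding the two raters' interface
#'   heights (percent), tidy-eval style.
#' @param multiplier Half-width of the limits of agreement in SD units;
#'   1.96 gives the conventional 95% limits.
#' @return An object of class `bland_altman` with fields `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n`, `multiplier`, and the
#'   per-pair `means`/`diffs` used for plotting. Use [tidy()] or
#'   [glance()] for tabular output and [autoplot()] for the classic
#'   difference-vs-mean plot.
#' @examples
#' pairs <- tibble::tibble(surgeon = c(75, 45, 35, 20),
#'                         patient = c(76, 44, 35, 18))
#' bland_altman(pairs, surgeon, patient)
#' @export
bland_altman <- function(data, surgeon, patient, multiplier = 1.96) {
  s <- dplyr::pull(data, {{ surgeon }})
  p <- dplyr::pull(data, {{ patient }})
  check_number(s, "surgeon", allow_vector = TRUE)
  check_number(p, "patient", allow_vector = TRUE)
  if (length(s) != length(p)) {
    abort("Rater columns must have equal length.",
          class = "gasrisk_domain_error")
  }
  n <- length(s)
  if (n < 2L) {
    abort("Bland-Altman analysis needs at least 2 pairs.",
          class = "gasrisk_insufficient_data")
  }
  d <- s - p
  bias <- mean(d)
  sd_diff <- sd(d)
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - multiplier * sd_diff,
                 loa_high = bias + multiplier * sd_diff,
                 n = n, multiplier = multiplier,
                 means = (s + p) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d pairs\n  bias %.4g, SD of differences %.4g\n  %s%% limits of agreement: [%.4g, %.4g]\n",
    x$n, x$bias, x$sd_diff,
    format(100 * (2 * pnorm(x$multiplier) - 1), digits = 3),
    x$loa_low, x$loa_high))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(term = c("bias", "loa_low", "loa_high"),
         estimate = c(x$bias, x$loa_low, x$loa_high))
}

#' @rdname bland_altman
#' @exportS3Method generics::glance
glance.bland_altman <- function(x, ...) {
  tibble(bias = x$bias, sd_diff = x$sd_diff, loa_low = x$loa_low,
         loa_high = x$loa_high, n = x$n, multiplier = x$multiplier)
}

#' @rdname bland_altman
#' @param object A `bland_altman` object.
#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman <- function(object, ...) {
  df <- tibble(mean = object$means, diff = object$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "Mean of the two judgments (%)",
      y = "Difference, surgeon - patient (%)",
      title = sprintf("Bland-Altman: bias %.2f%%, LoA [%.2f, %.2f]%%",
                      object$bias, object$loa_low, object$loa_high)) +
    ggplot2::theme_minimal()
}

# null distribution of the signed-rank sum over doubled average ranks;
# returns counts over S = 0..sum(r2) with 2^n total mass
signed_rank_null_counts <- function(r2) {
  total <- sum(r2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  counts
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided paired test on `surgeon - patient` differences. Zero
#' differences are dropped (Wilcoxon's method); ties among the remaining
#' absolute differences receive average ranks. With 25 or fewer nonzero
#' differences the p-value comes from exact enumeration of the null
#' distribution of the rank sum (a generating-function convolution over
#' doubled ranks, so tied average ranks are handled exactly); above that, a
#' normal approximation with continuity correction and the usual tie
#' correction to the variance is used.
#'
#' @param data A data frame with one row per pair.
#' @param surgeon,patient Columns holding the paired values (tidy-eval).
#' @param method `"auto"` (exact for <= 25 nonzero differences),
#'   `"exact"`, or `"approx"`.
#' @param exact_limit Largest number of nonzero differences for which
#'   `"auto"` picks the exact enumeration.
#' @return A tibble with columns `statistic` (rank sum of positive
#'   differences), `p_value`, `n_nonzero`, `method`, `degenerate`. When
#'   every difference is zero the test is degenerate and `p_value` is 1.
#' @examples
#' d <- tibble::tibble(a = 1:6, b = c(0, 0, 0, 0, 0, 0))
#' wilcoxon_signed_rank(d, a, b)
#' @export
wilcoxon_signed_rank <- function(data, surgeon, patient,
                                 method = c("auto", "exact", "approx"),
                                 exact_limit = 25L) {
  method <- match.arg(method)
  s <- dplyr::pull(data, {{ surgeon }})
  p <- dplyr::pull(data, {{ patient }})
  check_number(s, "surgeon", allow_vector = TRUE)
  check_number(p, "patient", allow_vector = TRUE)
  if (length(s) != length(p)) {
    abort("Paired columns must have equal length.",
          class = "gasrisk_domain_error")
  }
  d <- (s - p)[s != p]
  n <- length(d)
  if (n == 0L) {
    return(tibble(statistic = NA_real_, p_value = 1, n_nonzero = 0L,
                  method = "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  use_exact <- method == "exact" || (method == "auto" && n <= exact_limit)
  if (use_exact) {
    r2 <- as.integer(round(2 * r))
    counts <- signed_rank_null_counts(r2)
    s_obs <- sum(r2[d > 0])
    lower <- sum(counts[seq_len(s_obs + 1)])
    upper <- sum(counts[(s_obs + 1):length(counts)])
    p_val <- min(1, 2 * min(lower, upper) / 2^n)
    meth <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- w_pos - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p_val <- min(1, 2 * pnorm(-abs(z)))
    meth <- "approx"
  }
  tibble(statistic = w_pos, p_value = p_val, n_nonzero = n,
         method = meth, degenerate = FALSE)
}

#' Median and range summary
#'
#' Descriptive summary used for non-normally distributed variables:
#' median with minimum and maximum.
#'
#' @param x A nonempty numeric vector.
#' @return A tibble with columns `n`, `median`, `min`, `max`.
#' @examples
#' summarize_range(c(75, 45, 35, 20))
#' @export
summarize_range <- function(x) {
  if (length(x) == 0L) {
    abort("Cannot summarise an empty vector.",
          class = "gasrisk_insufficient_data")
  }
  check_number(x, "x", allow_vector = TRUE)
  tibble(n = length(x), median = median(x), min = min(x), max = max(x))
}

#' Tabulate 5-point Likert responses
#'
#' @param responses Integer responses, each in 1..5 (1 = strongly
#'   disagree, 5 = strongly agree). May be empty.
#' @return A tibble with one row per level 1..5: `level`, `count`,
#'   `proportion` (all zero / NaN-free zeros for an empty input).
#' @examples
#' tabulate_likert(c(5, 5, 4))
#' @export
tabulate_likert <- function(responses) {
  if (length(responses) > 0) {
    ok <- !is.na(responses) & responses %in% 1:5
    if (!all(ok)) {
      abort(sprintf("Likert responses must be integers 1-5; invalid at index %s.",
                    paste(which(!ok), collapse = ", ")),
            class = "gasrisk_validation_error")
    }
  }
  n <- length(responses)
  counts <- vapply(1:5, function(l) sum(responses == l), integer(1))
  tibble(level = 1:5, count = counts,
         proportion = if (n > 0) counts / n else rep(0, 5))
}
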