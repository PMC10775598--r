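#' Delta of absolute inter- vs intrafractional deviations
#'
#' Per (fraction, parameter) pair, `|inter| - |intra|`: positive values mean
#' the anatomy moved more between fractions than within one. Rows with a
#' missing member of the pair are dropped and counted.
#'
#' @param table data.frame with columns `parameter`, `inter_mm`, `intra_mm`
#'   (signed deviations).
#' @return data.frame with `parameter`, `delta_mm`; attribute `n_dropped`.
#' @export
delta_abs <- function(table) {
  ok <- stats::complete.cases(table[, c("inter_mm", "intra_mm")])
  out <- data.frame(parameter = table$parameter[ok],
                    delta_mm = abs(table$inter_mm[ok]) -
                      abs(table$intra_mm[ok]))
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Order-statistic percentile
#'
#' The same convention as the dose-volume metrics: for ascending sorted
#' values, the `ceiling(q * n)`-th smallest, no interpolation.
#'
#' @param x numeric values.
#' @param q probability in (0, 1].
#' @return the percentile.
#' @export
percentile_os <- function(x, q) {
  if (q <= 0 || q > 1) stop("q must lie in (0, 1]")
  x <- sort(x)
  x[ceiling(q * length(x))]
}

#' Per-parameter percentile summary of absolute deviations
#'
#' @param table data.frame with `parameter` and a deviation column.
#' @param q percentile (default 0.95).
#' @param column which column to summarize (absolute value is taken).
#' @return list with `per_parameter` (named vector of percentiles of the
#'   absolute deviation) and `median_across` (median of those percentiles).
#' @export
percentile_summary <- function(table, q = 0.95, column = "inter_mm") {
  sp <- split(abs(table[[column]]), table$parameter)
  n_min <- min(vapply(sp, length, integer(1)))
  if (n_min < 20)
    warning(sprintf("only %d rows for some parameter; percentile unstable",
                    n_min))
  per <- vapply(sp, function(v) {
    if (length(v) == 0L) stop("empty parameter column")
    percentile_os(v, q)
  }, numeric(1))
  list(per_parameter = per, median_across = stats::median(per))
}

test_result <- function(method, statistic, p_value, n, estimate = NA_real_,
                        ci = c(NA_real_, NA_real_), note = NULL) {
  structure(list(method = method, statistic = statistic,
                 p_value = p_value, n = n, estimate = estimate,
                 ci = ci, note = note),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d)\n",
              x$method, x$statistic, x$p_value, x$n))
  if (!is.na(x$estimate)) cat(sprintf("  estimate = %.4g\n", x$estimate))
  if (!any(is.na(x$ci))) cat(sprintf("  95%% CI [%.4g, %.4g]\n",
                                     x$ci[1], x$ci[2]))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Wilcoxon signed-rank test (Pratt zeros, two-sided)
#'
#' Location test for paired differences against zero. Zeros are handled by
#' the Pratt convention: they take part in ranking the absolute values but
#' their ranks are then discarded from the statistic. The null distribution
#' is exact (via the signed-rank distribution) when there are no zeros or
#' ties and at most 25 informative pairs; otherwise a normal approximation
#' with continuity correction, Pratt zero correction and midrank tie
#' correction is used.
#'
#' @param x paired differences, or first sample when `y` is given.
#' @param y optional second sample (`x - y` is tested).
#' @return a `test_result` with the `W+` statistic (sum of positive ranks).
#' @export
signed_rank_test <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  n_all <- length(d)
  if (n_all == 0L) stop("no data")
  if (all(d == 0))
    return(test_result("wilcoxon_signed_rank", NA_real_, NA_real_, n_all,
                       note = "degenerate: all differences zero"))
  r <- rank(abs(d))  # zeros included in the ranking (Pratt)
  w_pos <- sum(r[d > 0])
  n_zero <- sum(d == 0)
  n_inf <- n_all - n_zero
  has_ties <- any(duplicated(abs(d[d != 0])))
  if (n_zero == 0L && !has_ties && n_inf <= 25) {
    p <- 2 * min(stats::psignrank(w_pos, n_inf),
                 stats::psignrank(w_pos - 1, n_inf, lower.tail = FALSE))
    p <- min(1, p)
    method <- "wilcoxon_signed_rank_exact"
  } else {
    # moments of W+ with zero ranks removed (Pratt) and midranks
    mu <- (n_all * (n_all + 1) - n_zero * (n_zero + 1)) / 4
    tie_tab <- table(r[d != 0])
    sigma2 <- (n_all * (n_all + 1) * (2 * n_all + 1) -
                 n_zero * (n_zero + 1) * (2 * n_zero + 1)) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "wilcoxon_signed_rank_normal"
  }
  test_result(method, w_pos, p, n_all,
              estimate = stats::median(d[d != 0]))
}

#' Wilcoxon rank-sum (Mann-Whitney) test, two-sided
#'
#' Exact null distribution when there are no ties and the smaller sample has
#' at most 10 observations; otherwise normal approximation with midrank tie
#' correction and continuity correction. The statistic reported is the
#' Mann-Whitney `U` of the first sample.
#'
#' @param x,y independent samples.
#' @return a `test_result`.
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("empty sample")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- any(duplicated(c(x, y)))
  if (!has_ties && min(n1, n2) <= 10) {
    p <- 2 * min(stats::pwilcox(u, n1, n2),
                 stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE))
    p <- min(1, p)
    method <- "wilcoxon_rank_sum_exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 * (n + 1 - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "wilcoxon_rank_sum_normal"
  }
  test_result(method, u, p, n1 + n2,
              estimate = stats::median(x) - stats::median(y))
}

# scores for the two supported dispersion tests, from pooled midranks
scale_scores <- function(r, n, method) {
  if (method == "ansari_bradley") pmin(r, n + 1 - r)
  else (r - (n + 1) / 2)^2
}

ab_moments <- function(n1, n2) {
  n <- n1 + n2
  if (n %% 2 == 0)
    c(mu = n1 * (n + 2) / 4,
      s2 = n1 * n2 * (n + 2) * (n - 2) / (48 * (n - 1)))
  else
    c(mu = n1 * (n + 1)^2 / (4 * n),
      s2 = n1 * n2 * (n + 1) * (3 + n^2) / (48 * n^2))
}

mood_moments <- function(n1, n2) {
  n <- n1 + n2
  c(mu = n1 * (n^2 - 1) / 12,
    s2 = n1 * n2 * (n + 1) * (n^2 - 4) / 180)
}

#' Rank dispersion tests (Ansari-Bradley, Mood), two-sided
#'
#' Compares the scale of two distributions around their medians. Inputs are
#' median-centred per sample first, so only dispersion is compared.
#' Ansari-Bradley scores are the rank distance from the nearer extreme of
#' the pooled ordering; Mood scores are squared deviations of the rank from
#' the mean rank. The null distribution is exact (full enumeration of label
#' assignments) for combined `n <= 20` without ties, otherwise a normal
#' approximation with the standard moments. Midranks are used under ties
#' (normal path only); heavy tying (> 50% of pooled values) draws a warning.
#'
#' @param x,y independent samples.
#' @param method `"ansari_bradley"` or `"mood"`.
#' @param center median-centre the samples first (default TRUE).
#' @return a `test_result`; the statistic is the score sum of sample `x`.
#' @export
scale_test <- function(x, y, method = c("ansari_bradley", "mood"),
                       center = TRUE) {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 < 2L || n2 < 2L) stop("need at least two values per sample")
  if (center) {
    x <- x - stats::median(x)
    y <- y - stats::median(y)
  }
  pooled <- c(x, y)
  if (mean(duplicated(pooled)) > 0.5)
    warning("more than half of the pooled values are tied")
  r <- rank(pooled)
  sc <- scale_scores(r, n, method)
  stat <- sum(sc[seq_len(n1)])
  has_ties <- any(duplicated(pooled))
  if (!has_ties && n <= 20) {
    idx <- utils::combn(n, n1)
    sums <- colSums(matrix(sc[idx], nrow = n1))
    p_le <- mean(sums <= stat)
    p_ge <- mean(sums >= stat)
    p <- min(1, 2 * min(p_le, p_ge))
    meth <- paste0(method, "_exact")
  } else {
    mom <- if (method == "ansari_bradley") ab_moments(n1, n2)
    else mood_moments(n1, n2)
    s2 <- mom["s2"]
    if (has_ties) {
      # condition moments on the observed (midrank) scores
      s2 <- n1 * n2 / (n * (n - 1)) * (n * sum(sc^2) - sum(sc)^2) / n
      mom["mu"] <- n1 * mean(sc)
    }
    z <- (stat - mom["mu"]) / sqrt(s2)
    p <- 2 * stats::pnorm(-abs(z))
    meth <- paste0(method, "_normal")
  }
  test_result(meth, stat, unname(p), n)
}

#' Pearson or Spearman correlation with Fisher-z interval
#'
#' Two-sided t-approximation p-value; the confidence interval is the
#' Fisher-z interval (`atanh` transform, se `1/sqrt(n-3)`), applied to the
#' rank correlation as well — a documented approximation.
#'
#' @param x,y numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @param conf_level confidence level.
#' @return a `test_result` with `estimate` the correlation.
#' @export
correlations <- function(x, y, method = c("pearson", "spearman"),
                         conf_level = 0.95) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L) stop("need at least 5 paired observations")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- tanh(atanh(r) + c(-1, 1) * zcrit / sqrt(n - 3))
  test_result(paste0(method, "_correlation"), tstat, p, n, estimate = r,
              ci = ci)
}

#' Empirical distribution function
#'
#' Thin wrapper returning the right-continuous ECDF step function used for
#' the per-fraction EUD and homogeneity distribution plots.
#'
#' @param values numeric sample.
#' @return a function of class `ecdf`.
#' @export
step_ecdf <- function(values) stats::ecdf(values[!is.na(values)])

#' Order-statistic percentile with confidence interval
#'
#' Point estimate by the order-statistic convention of [percentile_os()].
#' The default interval inverts the binomial distribution of order
#' statistics: the narrowest pair of order statistics whose coverage of the
#' true quantile is at least `level`. A seeded percentile bootstrap is
#' available as an alternative. When `q * n < 1` the first order statistic
#' is used with a warning (widest-order fallback).
#'
#' @param values numeric sample (n >= 20 recommended).
#' @param q quantile (default 0.025).
#' @param level confidence level.
#' @param method `"order_statistic"` or `"bootstrap"`.
#' @param B bootstrap replicates.
#' @param seed bootstrap seed.
#' @return list with `estimate`, `ci`, `method`.
#' @export
percentile_with_ci <- function(values, q = 0.025, level = 0.95,
                               method = c("order_statistic", "bootstrap"),
                               B = 2000, seed = 1L) {
  method <- match.arg(method)
  values <- sort(values[!is.na(values)])
  n <- length(values)
  if (q * n < 1) {
    warning("q * n < 1: falling back to the first order statistic")
    est <- values[1]
  } else est <- values[ceiling(q * n)]
  if (method == "order_statistic") {
    alpha <- 1 - level
    lo <- stats::qbinom(alpha / 2, n, q)           # may be 0
    hi <- stats::qbinom(1 - alpha / 2, n, q) + 1   # may exceed n
    # widen until the coverage P(lo < Bin <= hi-1) reaches the level
    cover <- function(l, h) stats::pbinom(h - 1, n, q) - stats::pbinom(l - 1, n, q)
    while (cover(lo, hi) < level && (lo > 0 || hi < n)) {
      if (lo > 0) lo <- lo - 1 else hi <- hi + 1
    }
    ci <- c(values[max(lo, 1)], values[min(hi, n)])
  } else {
    boot <- with_local_seed(seed, {
      vapply(seq_len(B), function(i) {
        s <- sort(sample(values, n, replace = TRUE))
        s[max(1, ceiling(q * n))]
      }, numeric(1))
    })
    alpha <- 1 - level
    ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2),
                                 type = 1))
  }
  list(estimate = est, ci = ci, n = n, method = method)
}

#' Rank-vs-deviation adaptation fit
#'
#' Ordinary least squares of the (0, 1]-scaled EUD ranks on a landmark
#' deviation, with an optional quadratic term; reports slope(s), intercept,
#' r-squared and the F-test p-value. Used to quantify how strongly poor
#' scheduled-plan coverage tracks anatomical deviation.
#'
#' @param eud_ranks ranks scaled to (0, 1].
#' @param deviation_mm landmark deviations (mm).
#' @param quadratic include a quadratic term.
#' @return list with `coefficients`, `r_squared`, `p_value`, `fit` (the lm).
#' @export
rank_adaptation_fit <- function(eud_ranks, deviation_mm, quadratic = FALSE) {
  if (any(eud_ranks < 0 | eud_ranks > 1))
    stop("ranks must be scaled to [0, 1]")
  df <- data.frame(rank = eud_ranks, dev = deviation_mm)
  fit <- if (quadratic) stats::lm(rank ~ dev + I(dev^2), data = df)
  else stats::lm(rank ~ dev, data = df)
  sm <- summary(fit)
  fs <- sm$fstatistic
  p <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  list(coefficients = stats::coef(fit), r_squared = sm$r.squared,
       p_value = unname(p), fit = fit)
}
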