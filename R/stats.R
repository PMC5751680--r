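#' Descriptive statistics of an interval series
#'
#' Mean, sample standard deviation (n - 1 denominator), coefficient of
#' variation (CV = sd/mean), minimum and maximum. The CV is the quantity of
#' interest for vocal timing: a low CV within bouts indicates temporal
#' regularity, while the pooled series mixes within- and between-bout
#' timescales and has a much higher CV.
#'
#' @param s An [interval_series()], or a bare numeric vector of ms values.
#' @return A one-row tibble: `kind`, `n`, `mean`, `sd`, `cv`, `min`, `max`
#'   (ms except the dimensionless `cv`). With a single value, `sd` and `cv`
#'   are undefined and returned as `NA` with a warning rather than 0.
#' @export
summarize_series <- function(s) {
  if (inherits(s, "interval_series")) {
    v <- s$value_ms
    kind <- series_kind(s)
  } else {
    v <- as.numeric(s)
    kind <- NA_character_
  }
  if (length(v) == 0L) abort("cannot summarise an empty interval series")
  if (length(v) == 1L) {
    warn("series has a single value: sd and cv are undefined (NA)")
    s_dev <- NA_real_
  } else {
    s_dev <- sd(v)
  }
  tibble(
    kind = kind, n = length(v), mean = mean(v), sd = s_dev,
    cv = s_dev / mean(v), min = min(v), max = max(v)
  )
}

#' Empirical cumulative distribution value
#'
#' Fraction of the sample at or below `x` (right-continuous ECDF). Used as
#' the elementary building block — and independent oracle — for the
#' Kolmogorov–Smirnov statistic.
#'
#' @param s An [interval_series()] or numeric vector.
#' @param x Evaluation point(s).
#' @return Proportion(s) in `[0, 1]`, vectorized over `x`.
#' @export
ecdf_value <- function(s, x) {
  v <- if (inherits(s, "interval_series")) s$value_ms else as.numeric(s)
  if (length(v) == 0L) abort("ECDF of an empty sample is undefined")
  vapply(x, function(q) mean(v <= q), numeric(1))
}

#' Two-sample Kolmogorov–Smirnov test
#'
#' Computes the supremum distance D between the two empirical cumulative
#' distribution functions and the asymptotic two-sided p-value. D is found
#' by a single merge pass over the pooled sorted sample (ties handled by
#' evaluating the ECDF difference after each group of tied values), and the
#' p-value comes from the asymptotic Kolmogorov distribution
#' \deqn{Q(\lambda) = 2 \sum_{k \ge 1} (-1)^{k-1} e^{-2 k^2 \lambda^2}}
#' with \eqn{\lambda = D \sqrt{n_1 n_2 / (n_1 + n_2)}}, clamped to
#' `[0, 1]`. No continuity correction or small-sample exact computation is
#' applied.
#'
#' @param a,b [interval_series()] objects or numeric vectors; both
#'   non-empty.
#' @return A `ks_result` object with fields `d`, `p`, `n1`, `n2`. Use
#'   [tidy()] / [glance()] for a tibble view.
#' @export
ks_two_sample <- function(a, b) {
  x <- if (inherits(a, "interval_series")) a$value_ms else as.numeric(a)
  y <- if (inherits(b, "interval_series")) b$value_ms else as.numeric(b)
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) abort("both samples must be non-empty")
  w <- c(x, y)
  ord <- order(w)
  # +1/n1 steps for sample a, -1/n2 for sample b, in pooled sorted order
  step <- c(rep(1 / n1, n1), rep(-1 / n2, n2))[ord]
  cum <- cumsum(step)
  ws <- w[ord]
  # at tied pooled values only the last cumulative value is a valid
  # ECDF difference
  keep <- c(ws[-1] != ws[-length(ws)], TRUE)
  d <- max(abs(cum[keep]))
  lambda <- d * sqrt(n1 * n2 / (n1 + n2))
  p <- min(1, max(0, ks_q(lambda)))
  structure(list(d = d, p = p, n1 = n1, n2 = n2), class = "ks_result")
}

# Asymptotic Kolmogorov survival function Q(lambda).
ks_q <- function(lambda, terms = 100L) {
  if (lambda < 1e-10) return(1)
  k <- seq_len(terms)
  2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf(
    "Two-sample Kolmogorov-Smirnov test\n  D = %.2f, p = %.2f  (n1 = %d, n2 = %d)\n",
    x$d, x$p, x$n1, x$n2))
  invisible(x)
}

#' Tidy a Kolmogorov–Smirnov result
#'
#' @param x A `ks_result` from [ks_two_sample()].
#' @param ... Unused.
#' @return A one-row tibble with `statistic` (D), `p.value`, `n1`, `n2`,
#'   and `method`.
#' @exportS3Method generics::tidy
tidy.ks_result <- function(x, ...) {
  tibble(statistic = x$d, p.value = x$p, n1 = x$n1, n2 = x$n2,
         method = "Two-sample Kolmogorov-Smirnov test (asymptotic)")
}

#' @rdname tidy.ks_result
#' @exportS3Method generics::glance
glance.ks_result <- function(x, ...) tidy(x)
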