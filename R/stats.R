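#' Bland-Altman agreement analysis
#'
#' Computes the bias (mean difference `a - m`), the standard deviation of
#' the differences, and the conventional 95% limits of agreement
#' `bias +/- 1.96 * SD`. Significance of the bias is assessed with a
#' two-sided one-sample t-test of the differences against zero; a
#' zero-variance difference set returns `p_bias = 1` ("no evidence" rather
#' than failure).
#'
#' @param a,m Paired measurements (e.g. automated and manual), equal length,
#'   at least 3 finite pairs.
#' @return An object of class `bland_altman` with fields `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `p_bias`, `n`, and the per-pair means and
#'   differences for plotting. Has [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @export
#' @examples
#' ba <- bland_altman(c(10, 12, 11, 14), c(9, 13, 10, 15))
#' tidy(ba)
bland_altman <- function(a, m) {
  if (length(a) != length(m))
    stop("`a` and `m` must be paired (equal length)", call. = FALSE)
  ok <- is.finite(a) & is.finite(m)
  a <- a[ok]; m <- m[ok]
  n <- length(a)
  if (n < 3) stop("Bland-Altman needs at least 3 pairs", call. = FALSE)
  d <- a - m
  bias <- mean(d)
  s <- stats::sd(d)
  p <- if (s == 0) 1 else stats::t.test(d, mu = 0)$p.value
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 p_bias = p, n = n,
                 mean_pair = (a + m) / 2, diff = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4g (95%% LoA %.4g to %.4g), n = %d, p = %.3g\n",
              x$bias, x$loa_low, x$loa_high, x$n, x$p_bias))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(bias = x$bias, sd_diff = x$sd_diff, loa_low = x$loa_low,
         loa_high = x$loa_high, p_bias = x$p_bias, n = x$n)
}

#' @export
glance.bland_altman <- function(x, ...) tidy.bland_altman(x)

#' Exact McNemar test for paired binary outcomes
#'
#' Uses the exact binomial form on the discordant counts:
#' `p = min(1, 2 * P(X <= min(b, c)))` with `X ~ Binom(b + c, 1/2)`;
#' `p = 1` when there are no discordant pairs.
#'
#' @param b,c Discordant counts (nonnegative integers).
#' @return An object of class `mcnemar_exact` with fields `b`, `c`, `p`.
#' @export
#' @examples
#' mcnemar_exact(10, 0)$p  # 2 * 0.5^10
mcnemar_exact <- function(b, c) {
  if (length(b) != 1 || length(c) != 1 || is.na(b) || is.na(c) ||
      b < 0 || c < 0 || b != round(b) || c != round(c))
    stop("`b` and `c` must be nonnegative integer counts", call. = FALSE)
  n <- b + c
  p <- if (n == 0) 1 else min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
  structure(list(b = as.integer(b), c = as.integer(c), p = p),
            class = "mcnemar_exact")
}

#' @export
print.mcnemar_exact <- function(x, ...) {
  cat(sprintf("Exact McNemar: b = %d, c = %d, p = %.4g\n", x$b, x$c, x$p))
  invisible(x)
}

#' @export
tidy.mcnemar_exact <- function(x, ...) tibble(b = x$b, c = x$c, p = x$p)

#' Mann-Whitney U test (two-sided)
#'
#' Midranks handle ties. For `n1 + n2 <= 20` the two-sided p-value is exact,
#' computed by full enumeration of all group assignments (valid with ties);
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y Numeric samples, each nonempty.
#' @return An object of class `rank_test` with fields `statistic` (U for the
#'   first sample), `p`, `n1`, `n2`, `method`, `exact`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p  # 2/6 by enumeration
mann_whitney_u <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0)
    stop("both samples must be nonempty", call. = FALSE)
  nn <- n1 + n2
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (nn <= 20) {
    combos <- utils::combn(nn, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    exact <- TRUE
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    exact <- FALSE
  }
  structure(list(statistic = u_obs, p = p, n1 = n1, n2 = n2,
                 method = "Mann-Whitney U", exact = exact),
            class = "rank_test")
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Omnibus nonparametric comparison of two or more groups: the H statistic
#' with tie correction and a chi-square p-value (via [stats::kruskal.test()]).
#' When every observation is identical the test is degenerate and `H = 0`,
#' `p = 1` is returned.
#'
#' @param groups A list of numeric vectors (each nonempty), or a numeric
#'   vector together with `g`, a grouping factor.
#' @param g Optional grouping factor when `groups` is a plain vector.
#' @return An object of class `rank_test` with fields `statistic` (H), `p`,
#'   `df`, `sizes`, `method`.
#' @export
kruskal_wallis <- function(groups, g = NULL) {
  if (!is.null(g)) groups <- split(as.numeric(groups), g)
  groups <- lapply(groups, function(v) v[is.finite(v)])
  groups <- groups[vapply(groups, length, 1L) > 0]
  if (length(groups) < 2)
    stop("need at least 2 nonempty groups", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (length(unique(values)) == 1) {
    h <- 0; p <- 1; df <- length(groups) - 1
  } else {
    kt <- stats::kruskal.test(values, fac)
    h <- unname(kt$statistic); p <- kt$p.value; df <- unname(kt$parameter)
  }
  structure(list(statistic = h, p = p, df = df,
                 sizes = vapply(groups, length, 1L),
                 method = "Kruskal-Wallis", exact = FALSE),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$method, x$statistic, x$p))
  invisible(x)
}

#' @export
tidy.rank_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p = x$p)
}

#' Wald 95% confidence interval for a proportion, in percent
#'
#' `100 * (p_hat +/- 1.96 * sqrt(p_hat (1 - p_hat) / n))`, clipped to
#' `[0, 100]`. Degenerate at `k = 0` or `k = n` (zero-width interval), a
#' known Wald pathology that is kept as-is.
#'
#' @param k Number of successes (`0 <= k <= n`).
#' @param n Number of trials (`>= 1`).
#' @return Numeric length-2: lower and upper bound in percent.
#' @export
#' @examples
#' wald_ci(176, 178)
wald_ci <- function(k, n) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      n < 1 || k < 0 || k > n || k != round(k) || n != round(n))
    stop("need integer counts with 0 <= k <= n, n >= 1", call. = FALSE)
  p <- k / n
  half <- 1.96 * sqrt(p * (1 - p) / n)
  pmin(100, pmax(0, 100 * c(p - half, p + half)))
}
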