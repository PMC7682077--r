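# Shared statistics. Degenerate inputs return flagged results instead of
# raising, so cohort-wide scans never abort on a constant gene or an
# event-free stratum.

#' Test-result container
#'
#' Uniform return value for the statistics layer: statistic, two-sided p,
#' point estimate (Rs, mean difference, hazard ratio, ...), sample size /
#' degrees of freedom, and a `degenerate` flag marking results produced under
#' zero variance, too-few observations or non-convergence.
#'
#' @param statistic Test statistic.
#' @param p_value Two-sided p value in \[0, 1\].
#' @param estimate Point estimate.
#' @param n Number of observations used.
#' @param df Degrees of freedom (may be a length-2 vector for F tests).
#' @param method Short method label.
#' @param degenerate Logical flag.
#' @return A list of class `hsp_test`.
#' @export
test_result <- function(statistic = NA_real_, p_value = NA_real_,
                        estimate = NA_real_, n = NA_integer_, df = NA_real_,
                        method = "", degenerate = FALSE) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(statistic = statistic, p_value = p_value,
                 estimate = estimate, n = n, df = df, method = method,
                 degenerate = degenerate),
            class = "hsp_test")
}

#' @export
print.hsp_test <- function(x, ...) {
  cat(sprintf("<hsp_test:%s> statistic=%.4g estimate=%.4g p=%.3g%s\n",
              x$method, x$statistic, x$estimate, x$p_value,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rs from average-ranked data (ties get mean ranks). The two-sided p value
#' uses the t approximation `t = Rs * sqrt((n - 2) / (1 - Rs^2))` on `n - 2`
#' degrees of freedom, the standard choice at cohort-scale sample sizes. An
#' exact permutation p is available for small tie-free samples
#' (`exact = TRUE`, n <= 7).
#'
#' @param x,y Equal-length numeric vectors, n >= 3, finite values.
#' @param exact Use full permutation enumeration of `y` (n <= 7 only).
#' @return An [test_result()] with `estimate` = Rs. Fewer than 3 observations
#'   or a zero-variance argument gives a degenerate result with p = 1.
#' @export
spearman <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("`x` and `y` must be finite")
  }
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(test_result(p_value = 1, n = n, method = "spearman",
                       degenerate = TRUE))
  }
  rx <- rank(x)
  ry <- rank(y)
  rs <- stats::cor(rx, ry)
  if (exact) {
    if (n > 7L) stop("exact permutation p only supported for n <= 7")
    perms <- permutations_of(n)
    null_rs <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(null_rs) >= abs(rs) - 1e-12)
    return(test_result(statistic = rs, p_value = p, estimate = rs, n = n,
                       df = NA_real_, method = "spearman_exact"))
  }
  if (abs(rs) >= 1) {
    return(test_result(statistic = sign(rs) * Inf, p_value = 0, estimate = rs,
                       n = n, df = n - 2, method = "spearman"))
  }
  tt <- rs * sqrt((n - 2) / (1 - rs^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  test_result(statistic = tt, p_value = p, estimate = rs, n = n, df = n - 2,
              method = "spearman")
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Vectorized Spearman over all row pairs of a genes x samples matrix:
# rank-transform rows, Pearson on ranks, p from the same t approximation.
spearman_matrix <- function(mat) {
  n <- ncol(mat)
  rs <- stats::cor(t(mat), method = "spearman")
  tt <- rs * sqrt((n - 2) / pmax(1 - rs^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(rs) >= 1] <- 0
  list(rs = rs, p = p, n = n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: sort ascending, `q_(i) = min_{j>=i} p_(j) * m / j`
#' capped at 1, returned in input order (delegates to
#' [stats::p.adjust()]`(method = "BH")`).
#'
#' @param p Numeric vector of p values in \[0, 1\]; NAs are not allowed.
#' @return Adjusted q values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}

#' Student's t test
#'
#' Two-sided t test; paired mode tests the mean difference, unpaired mode
#' uses the pooled-variance Student statistic (set `var_equal = FALSE` for
#' Welch). Zero-variance inputs return a degenerate result: p = 1 when the
#' group means (or mean difference) agree, p = 0 otherwise.
#'
#' @param a,b Numeric vectors (equal length when `paired`).
#' @param paired Paired test?
#' @param var_equal Pooled variance for the unpaired test (default TRUE).
#' @return An [test_result()] with `estimate` = mean difference.
#' @export
t_test <- function(a, b, paired = FALSE, var_equal = TRUE) {
  if (paired && length(a) != length(b)) {
    stop("paired test needs equal-length vectors")
  }
  if (paired) {
    if (length(a) < 2L) stop("paired test needs n >= 2")
    d <- a - b
    if (stats::sd(d) == 0) {
      return(test_result(estimate = mean(d),
                         p_value = if (mean(d) == 0) 1 else 0,
                         n = length(d), method = "t_paired",
                         degenerate = TRUE))
    }
    fit <- stats::t.test(a, b, paired = TRUE)
    return(test_result(statistic = unname(fit$statistic),
                       p_value = fit$p.value, estimate = mean(d),
                       n = length(d), df = unname(fit$parameter),
                       method = "t_paired"))
  }
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  est <- mean(a) - mean(b)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(test_result(estimate = est, p_value = if (est == 0) 1 else 0,
                       n = length(a) + length(b), method = "t_unpaired",
                       degenerate = TRUE))
  }
  fit <- stats::t.test(a, b, var.equal = var_equal)
  test_result(statistic = unname(fit$statistic), p_value = fit$p.value,
              estimate = est, n = length(a) + length(b),
              df = unname(fit$parameter), method = "t_unpaired")
}

#' One-way analysis of variance
#'
#' F statistic with (k - 1, N - k) degrees of freedom, equal-variance
#' one-way ANOVA. All values identical gives the degenerate F = 0, p = 1;
#' zero within-group variance with unequal means gives a degenerate p = 0.
#'
#' @param groups List of >= 2 numeric vectors, each of length >= 2.
#' @return An [test_result()] with `statistic` = F.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  if (any(vapply(groups, length, integer(1L)) < 2L)) {
    stop("each group needs n >= 2")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1L))))
  k <- length(groups)
  df <- c(k - 1, length(values) - k)
  within_var <- vapply(groups, stats::var, numeric(1L))
  if (all(within_var == 0)) {
    means <- vapply(groups, mean, numeric(1L))
    if (all(means == means[1L])) {
      return(test_result(statistic = 0, p_value = 1, n = length(values),
                         df = df, method = "anova", degenerate = TRUE))
    }
    return(test_result(statistic = Inf, p_value = 0, n = length(values),
                       df = df, method = "anova", degenerate = TRUE))
  }
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  test_result(statistic = unname(fit$statistic), p_value = fit$p.value,
              n = length(values), df = unname(fit$parameter),
              method = "anova")
}

#' Chi-squared goodness-of-fit test
#'
#' `sum((O - E)^2 / E)` on k - 1 degrees of freedom, upper-tail p, no
#' continuity correction. Expected proportions default to equal.
#'
#' @param counts Non-negative integer counts (sum > 0).
#' @param expected_proportions Probabilities summing to 1; all expected
#'   counts must be positive.
#' @return An [test_result()] with `statistic` = chi-squared.
#' @export
chi_square_gof <- function(counts, expected_proportions = NULL) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("counts must sum to a positive total")
  k <- length(counts)
  expected_proportions <- expected_proportions %||% rep(1 / k, k)
  if (length(expected_proportions) != k) {
    stop("`expected_proportions` must match `counts` in length")
  }
  if (abs(sum(expected_proportions) - 1) > 1e-8) {
    stop("`expected_proportions` must sum to 1")
  }
  if (any(expected_proportions * total <= 0)) {
    stop("all expected counts must be positive")
  }
  fit <- suppressWarnings(stats::chisq.test(counts, p = expected_proportions))
  test_result(statistic = unname(fit$statistic), p_value = fit$p.value,
              n = total, df = unname(fit$parameter), method = "chisq_gof")
}

#' Two-group log-rank test
#'
#' Standard (rho = 0) log-rank statistic `(sum(O - E))^2 / V` on one degree
#' of freedom via [survival::survdiff()]. The `estimate` is the excess
#' observed deaths `O - E` in group b, so its sign gives the direction of
#' effect for group b.
#'
#' @param time_a,event_a Times and 0/1 event indicators for group a.
#' @param time_b,event_b Times and 0/1 event indicators for group b.
#' @return An [test_result()]; no events at all gives a degenerate p = 1.
#' @export
logrank <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b)) stop("both groups must be non-empty")
  if (!all(c(event_a, event_b) %in% c(0, 1))) stop("events must be 0/1")
  n <- length(time_a) + length(time_b)
  if (sum(event_a) + sum(event_b) == 0) {
    return(test_result(statistic = 0, p_value = 1, n = n, df = 1,
                       method = "logrank", degenerate = TRUE))
  }
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- factor(rep(c("a", "b"), c(length(time_a), length(time_b))))
  fit <- survival::survdiff(survival::Surv(time, event) ~ grp, rho = 0)
  excess_b <- unname(fit$obs[2L] - fit$exp[2L])
  test_result(statistic = unname(fit$chisq),
              p_value = stats::pchisq(unname(fit$chisq), df = 1,
                                      lower.tail = FALSE),
              estimate = excess_b, n = n, df = 1, method = "logrank")
}

#' Univariate Cox proportional-hazards fit
#'
#' Single-covariate partial-likelihood fit with Breslow tie handling and a
#' Wald p value. A constant covariate or fewer than 2 events returns a
#' degenerate HR = 1, p = 1; non-convergence (monotone likelihood) returns a
#' degenerate flagged result that downstream scans exclude.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param covariate Numeric covariate (e.g. expression).
#' @return An [test_result()] with `estimate` = hazard ratio and the log
#'   hazard ratio in the `"beta"` attribute.
#' @export
cox_ph <- function(time, event, covariate) {
  if (length(unique(c(length(time), length(event), length(covariate)))) != 1L) {
    stop("time, event and covariate must have equal length")
  }
  if (!all(event %in% c(0, 1))) stop("events must be 0/1")
  if (any(!is.finite(covariate))) stop("covariate must be finite")
  n <- length(time)
  if (sum(event) < 2L || stats::sd(covariate) == 0) {
    out <- test_result(estimate = 1, p_value = 1, n = n, method = "cox",
                       degenerate = TRUE)
    attr(out, "beta") <- 0
    return(out)
  }
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ covariate,
                    ties = "breslow"),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  s <- summary(fit)$coefficients
  beta <- unname(s[1L, "coef"])
  out <- test_result(statistic = unname(s[1L, "z"]),
                     p_value = unname(s[1L, "Pr(>|z|)"]),
                     estimate = exp(beta), n = n, df = 1, method = "cox",
                     degenerate = warned || !is.finite(beta) ||
                       abs(beta) > 20)
  attr(out, "beta") <- beta
  out
}
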