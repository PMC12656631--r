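#' Cohen's d effect size
#'
#' For paired data, the mean difference divided by the SD of the differences;
#' for independent groups, the mean difference divided by the pooled SD. The
#' sign follows `mean(a) - mean(b)` (paired: `mean(a - b)`), so a growing
#' weighted time from the earlier to the later section gives a negative d.
#'
#' @param a,b Numeric samples (paired: equal length, compared element-wise).
#' @param paired Paired (default) or independent-groups d.
#' @return A single numeric value; `Inf` with a warning when the relevant SD
#'   is zero but the means differ, 0 when both are degenerate and equal.
#' @export
cohens_d <- function(a, b, paired = TRUE) {
  if (paired) {
    stopifnot(length(a) == length(b))
    keep <- !is.na(a) & !is.na(b)
    d <- a[keep] - b[keep]
    if (length(d) < 2) stop("need at least 2 complete pairs", call. = FALSE)
    s <- sd(d)
    if (s == 0) {
      if (mean(d) == 0) return(0)
      warning("zero-variance differences: effect size degenerate", call. = FALSE)
      return(sign(mean(d)) * Inf)
    }
    mean(d) / s
  } else {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    n1 <- length(a); n2 <- length(b)
    if (n1 < 2 || n2 < 2) stop("need at least 2 values per group", call. = FALSE)
    sp <- sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2))
    if (sp == 0) {
      if (mean(a) == mean(b)) return(0)
      warning("zero pooled variance: effect size degenerate", call. = FALSE)
      return(sign(mean(a) - mean(b)) * Inf)
    }
    (mean(a) - mean(b)) / sp
  }
}

#' Qualitative effect-size label
#'
#' Conventional magnitude bands: trivial < 0.2 <= small < 0.5 <= medium
#' < 0.8 <= large.
#'
#' @param d Effect size(s).
#' @return Character vector.
#' @export
effect_size_label <- function(d) {
  cut(abs(d), breaks = c(-Inf, 0.2, 0.5, 0.8, Inf),
      labels = c("trivial", "small", "medium", "large"), right = FALSE)
}

#' Pearson correlation with significance and post hoc power
#'
#' Product-moment correlation with the usual two-sided t-test p-value and a
#' post hoc power estimate at the observed r via the Fisher-z approximation.
#'
#' @param x,y Paired numeric vectors (pairwise-complete, n >= 3 after
#'   removal).
#' @param alpha Significance level for the power computation.
#' @return List with `r`, `p`, `n`, `power`.
#' @export
pearson_r <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined: zero variance in x or y", call. = FALSE)
  }
  ct <- cor.test(x, y)
  r <- unname(ct$estimate)
  list(r = r, p = ct$p.value, n = n,
       power = posthoc_power(r, n, "correlation", alpha))
}

#' Post hoc statistical power
#'
#' Power of the two-sided test at level `alpha` for the observed effect size
#' and sample size: via the noncentral-t distribution for paired and
#' independent t-tests, and the Fisher-z normal approximation for a
#' correlation. At effect 0 the power equals `alpha` by construction.
#'
#' @param effect_size Cohen's d (t-tests) or r (correlation).
#' @param n Sample size: number of pairs (paired), a length-2 vector of
#'   group sizes or a single per-group size (independent), number of pairs
#'   (correlation).
#' @param test_kind `"paired"`, `"independent"` or `"correlation"`.
#' @param alpha Two-sided significance level in (0, 1).
#' @return Power in \[0, 1\].
#' @examples
#' posthoc_power(0, 50, "paired")        # 0.05
#' posthoc_power(2, 200, "independent")  # ~1
#' @export
posthoc_power <- function(effect_size, n,
                          test_kind = c("paired", "independent", "correlation"),
                          alpha = 0.05) {
  test_kind <- match.arg(test_kind)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  if (!is.finite(effect_size)) return(1)
  if (test_kind == "correlation") {
    r <- effect_size
    if (abs(r) >= 1) return(1)
    if (n < 4) stop("correlation power needs n >= 4", call. = FALSE)
    za <- qnorm(1 - alpha / 2)
    z <- atanh(r) * sqrt(n - 3)
    return(pnorm(z - za) + pnorm(-z - za))
  }
  if (test_kind == "paired") {
    if (any(n < 2)) stop("need n >= 2", call. = FALSE)
    df <- n - 1
    ncp <- effect_size * sqrt(n)
  } else {
    if (length(n) == 1) n <- c(n, n)
    if (any(n < 2)) stop("need n >= 2 per group", call. = FALSE)
    df <- sum(n) - 2
    ncp <- effect_size * sqrt(prod(n) / sum(n))
  }
  tc <- qt(1 - alpha / 2, df)
  pt(tc, df, ncp = ncp, lower.tail = FALSE) + pt(-tc, df, ncp = ncp)
}

# column means/SDs of a matrix without apply overhead
col_mean_sd <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  v <- (colSums(m * m) - n * mu * mu) / (n - 1)
  list(mean = mu, sd = sqrt(pmax(v, 0)))
}

boot_p_value <- function(t_star, t_obs) {
  (1 + sum(abs(t_star) >= abs(t_obs))) / (length(t_star) + 1)
}

#' Paired t-test with bootstrap p-value
#'
#' Intra-group comparison of two paired measurements (e.g. the weighted
#' times of two same-slope sections). The t statistic is computed on the
#' differences; the p-value comes from resampling the mean-centred
#' differences `n_resamples` times (null enforced by centring), two-sided
#' with the +1 finite-sample correction. The analytic t-test p-value is also
#' reported. Effect size is the paired Cohen's d (mean difference / SD of
#' differences), so `a` systematically smaller than `b` gives d < 0.
#'
#' @param a,b Equal-length paired samples; incomplete pairs are dropped.
#' @param n_resamples Number of bootstrap resamples (default 1000).
#' @param seed RNG seed, mandatory for reproducibility.
#' @param alpha Significance level used for the power computation.
#' @return A `group_comparison` list: group means/SDs/n, `t`, `d`,
#'   `p` (bootstrap), `p_param` (analytic), `power`, `degenerate` flag.
#' @export
paired_t_bootstrap <- function(a, b, n_resamples = 1000, seed, alpha = 0.05) {
  stopifnot(length(a) == length(b), n_resamples >= 1)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  d_i <- a - b
  s <- sd(d_i)
  degenerate <- s == 0
  res <- list(kind = "paired",
              groups = c("a", "b"),
              mean = c(mean(a), mean(b)), sd = c(sd(a), sd(b)),
              n = c(n, n), n_resamples = n_resamples, seed = seed,
              degenerate = degenerate)
  if (degenerate) {
    res$d <- suppressWarnings(cohens_d(a, b, paired = TRUE))
    res$t <- if (mean(d_i) == 0) 0 else sign(mean(d_i)) * Inf
    res$p <- if (mean(d_i) == 0) 1 else NA_real_
    res$p_param <- res$p
    res$power <- if (mean(d_i) == 0) alpha else NA_real_
    warning("zero-variance paired differences: comparison degenerate",
            call. = FALSE)
    return(structure(res, class = "group_comparison"))
  }
  t_obs <- mean(d_i) / (s / sqrt(n))
  set.seed(seed)
  centred <- d_i - mean(d_i)
  idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE), nrow = n)
  ms <- col_mean_sd(matrix(centred[idx], nrow = n))
  t_star <- ms$mean / (ms$sd / sqrt(n))
  t_star <- t_star[is.finite(t_star)]
  res$t <- t_obs
  res$d <- mean(d_i) / s
  res$p <- boot_p_value(t_star, t_obs)
  res$p_param <- 2 * pt(-abs(t_obs), df = n - 1)
  res$power <- posthoc_power(res$d, n, "paired", alpha)
  structure(res, class = "group_comparison")
}

#' Independent-groups t-test with bootstrap p-value
#'
#' Inter-group comparison (race modality, sex, performance quartile). The
#' observed statistic is the Welch t (robust to the very unequal group sizes
#' typical of race fields); `var_equal = TRUE` gives the pooled-variance
#' variant. The bootstrap p resamples each mean-centred group independently.
#' Effect size is Cohen's d with the pooled SD.
#'
#' @param g1,g2 Numeric samples (NAs dropped, n >= 2 each).
#' @param n_resamples Number of bootstrap resamples (default 1000).
#' @param seed RNG seed, mandatory.
#' @param var_equal Use the pooled-variance t statistic.
#' @param alpha Significance level used for the power computation.
#' @return A `group_comparison` list (see [paired_t_bootstrap()]).
#' @export
independent_t_bootstrap <- function(g1, g2, n_resamples = 1000, seed,
                                    var_equal = FALSE, alpha = 0.05) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(n_resamples >= 1)
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2 || n2 < 2) stop("need at least 2 values per group", call. = FALSE)
  welch_t <- function(m1, s1, m2, s2) {
    (m1 - m2) / sqrt(s1^2 / n1 + s2^2 / n2)
  }
  pooled_t <- function(m1, s1, m2, s2) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  t_fun <- if (var_equal) pooled_t else welch_t
  degenerate <- sd(g1) == 0 && sd(g2) == 0
  res <- list(kind = if (var_equal) "independent-pooled" else "independent-welch",
              groups = c("g1", "g2"),
              mean = c(mean(g1), mean(g2)), sd = c(sd(g1), sd(g2)),
              n = c(n1, n2), n_resamples = n_resamples, seed = seed,
              degenerate = degenerate)
  if (degenerate) {
    res$d <- suppressWarnings(cohens_d(g1, g2, paired = FALSE))
    res$t <- if (mean(g1) == mean(g2)) 0 else sign(mean(g1) - mean(g2)) * Inf
    res$p <- if (mean(g1) == mean(g2)) 1 else NA_real_
    res$p_param <- res$p
    res$power <- if (mean(g1) == mean(g2)) alpha else NA_real_
    warning("both groups constant: comparison degenerate", call. = FALSE)
    return(structure(res, class = "group_comparison"))
  }
  t_obs <- t_fun(mean(g1), sd(g1), mean(g2), sd(g2))
  set.seed(seed)
  c1 <- g1 - mean(g1); c2 <- g2 - mean(g2)
  i1 <- matrix(sample.int(n1, n1 * n_resamples, replace = TRUE), nrow = n1)
  i2 <- matrix(sample.int(n2, n2 * n_resamples, replace = TRUE), nrow = n2)
  s1 <- col_mean_sd(matrix(c1[i1], nrow = n1))
  s2 <- col_mean_sd(matrix(c2[i2], nrow = n2))
  t_star <- t_fun(s1$mean, s1$sd, s2$mean, s2$sd)
  t_star <- t_star[is.finite(t_star)]
  res$t <- t_obs
  res$d <- cohens_d(g1, g2, paired = FALSE)
  res$p <- boot_p_value(t_star, t_obs)
  res$p_param <- t.test(g1, g2, var.equal = var_equal)$p.value
  res$power <- posthoc_power(res$d, c(n1, n2), "independent", alpha)
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (n = %s)\n", x$kind,
              paste(x$n, collapse = "/")))
  cat(sprintf("  means %.4g vs %.4g, t = %.3f, d = %.3f (%s)\n",
              x$mean[1], x$mean[2], x$t, x$d, effect_size_label(x$d)))
  cat(sprintf("  bootstrap p = %.4g (B = %d), analytic p = %.4g, power = %.3f\n",
              x$p, x$n_resamples, x$p_param, x$power))
  if (isTRUE(x$degenerate)) cat("  [degenerate: zero variance]\n")
  invisible(x)
}

#' Normality screen
#'
#' Runs both a Lilliefors-corrected Kolmogorov-Smirnov test (sample-level
#' screening) and a Shapiro-Wilk test (residual screening) and reports a
#' joint verdict at `alpha`. Shapiro-Wilk is computed on a fixed-seed
#' subsample when n exceeds its 5000 limit.
#'
#' @param x Numeric sample (n >= 4 after NA removal).
#' @param alpha Significance level for the verdict.
#' @return List with `ks` and `shapiro` (each `statistic`, `p`), and
#'   `normal`: `TRUE` iff neither test rejects at `alpha`.
#' @export
normality_screen <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 4) stop("need at least 4 values", call. = FALSE)
  if (sd(x) == 0) {
    warning("constant sample: treated as non-normal", call. = FALSE)
    return(list(ks = list(statistic = NA_real_, p = 0),
                shapiro = list(statistic = NA_real_, p = 0),
                normal = FALSE))
  }
  ks <- nortest::lillie.test(x)
  xs <- if (length(x) > 5000) {
    set.seed(1L)
    sample(x, 5000)
  } else x
  sw <- shapiro.test(xs)
  list(ks = list(statistic = unname(ks$statistic), p = ks$p.value),
       shapiro = list(statistic = unname(sw$statistic), p = sw$p.value),
       normal = ks$p.value > alpha && sw$p.value > alpha)
}
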