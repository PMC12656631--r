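segment_predictors <- function(segment) {
  switch(segment,
         ascent1 = c(wt = "WT_1", wtv = "WTV_13", cpr = "CPR_1"),
         descent = c(wt = "WT_2", wtv = "WTV_24", cpr = "CPR_2"),
         ascent2 = c(wt = "WT_3", wtv = "WTV_35", cpr = "CPR_3"),
         stop("unknown segment: ", segment, call. = FALSE))
}

#' Segment sections and opening checkpoint
#'
#' Each regression/prediction segment pairs two same-slope sections and the
#' checkpoint percentile rank at the first of them: ascent 1 = sections 1
#' and 3 with the rank at cp1; descent = sections 2 and 4 with cp2;
#' ascent 2 = sections 3 and 5 with cp3.
#'
#' @param segment `"ascent1"`, `"descent"` or `"ascent2"`.
#' @return List with `sections` (length-2 integer) and `cp` (integer).
#' @export
segment_layout <- function(segment = c("ascent1", "descent", "ascent2")) {
  segment <- match.arg(segment)
  switch(segment,
         ascent1 = list(sections = c(1L, 3L), cp = 1L),
         descent = list(sections = c(2L, 4L), cp = 2L),
         ascent2 = list(sections = c(3L, 5L), cp = 3L))
}

#' Durbin-Watson statistic
#'
#' First-order autocorrelation diagnostic for ordered residuals:
#' `sum(diff(e)^2) / sum(e^2)`, in \[0, 4\]; values near 2 indicate
#' independent residuals, and 1-3 is the conventionally acceptable band.
#'
#' @param residuals Model residuals in modelling order (n >= 2).
#' @return The statistic.
#' @examples
#' durbin_watson(c(1, -1, 1, -1)) # 3
#' @export
durbin_watson <- function(residuals) {
  residuals <- residuals[!is.na(residuals)]
  if (length(residuals) < 2) stop("need at least 2 residuals", call. = FALSE)
  denom <- sum(residuals^2)
  if (denom == 0) stop("all residuals are zero: statistic undefined", call. = FALSE)
  sum(diff(residuals)^2) / denom
}

#' Variance inflation factors
#'
#' For each predictor, `1 / (1 - R^2_j)` from regressing it on the others;
#' values above 10 conventionally flag excessive multicollinearity. Perfect
#' collinearity yields `Inf` with a warning.
#'
#' @param design Numeric matrix or data frame of predictors (no intercept
#'   column; >= 2 columns, more rows than columns).
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(design) {
  x <- as.matrix(design)
  p <- ncol(x)
  if (p < 2) stop("need at least 2 predictors", call. = FALSE)
  if (nrow(x) <= p) stop("need more observations than predictors", call. = FALSE)
  out <- vapply(seq_len(p), function(j) {
    fit <- lm(x[, j] ~ x[, -j, drop = FALSE])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) return(Inf)
    1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(x) %||% paste0("x", seq_len(p))
  if (any(!is.finite(out))) {
    warning("perfect collinearity among predictors: infinite VIF", call. = FALSE)
  }
  out
}

#' Cook's distance with influence flags
#'
#' Standard Cook's distance of each case in a fitted linear model, with the
#' conventional D > 1 influence flag used for case screening.
#'
#' @param fit An `lm` fit (or a `segment_fit`, whose underlying `lm` is used).
#' @return Tibble with `case`, `cooks_d`, `influential`.
#' @export
cooks_distance <- function(fit) {
  if (inherits(fit, "segment_fit")) fit <- fit$fit
  stopifnot(inherits(fit, "lm"))
  d <- cooks.distance(fit)
  tibble::tibble(case = names(d) %||% as.character(seq_along(d)),
                 cooks_d = unname(d), influential = unname(d) > 1)
}

#' Fit a terrain-segment finish-time model
#'
#' Ordinary least squares of finish time `TT` on the segment's predictor
#' triple — weighted time, same-slope pacing variability, and checkpoint
#' percentile rank — with all three predictors entered simultaneously
#' ("enter" method; no stepwise selection). Rows with any missing
#' constituent are dropped for this segment only. After the initial fit,
#' cases with Cook's distance > 1 or |standardized residual| > 3 are
#' excluded in a single pass and the model refitted once.
#'
#' The percentile rank enters as a fraction in (0, 1] (rank / field size);
#' its coefficient scale depends on that convention.
#'
#' @param features Feature table from [build_feature_table()].
#' @param segment `"ascent1"`, `"descent"` or `"ascent2"`.
#' @param exclude_influential Apply the single-pass case screening
#'   (default TRUE).
#' @param conf_level Confidence level for coefficient intervals.
#' @return A `segment_fit`: coefficient table (`B`, `SE`, `t`, `p`, CI
#'   bounds, standardized `beta`), fit statistics (`r`, `r_squared`,
#'   `adj_r_squared`, `see`), diagnostics (`dw`, `vif`), `excluded_cases`,
#'   `n_used`, and the underlying `lm` in `$fit`.
#' @export
fit_segment_model <- function(features, segment = c("ascent1", "descent", "ascent2"),
                              exclude_influential = TRUE, conf_level = 0.95) {
  segment <- match.arg(segment)
  vars <- segment_predictors(segment)
  cols <- c("TT", unname(vars))
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols)) {
    stop("feature table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dat <- features[cols]
  names(dat) <- c("TT", "wt", "wtv", "cpr")
  ids <- if ("runner_id" %in% names(features)) {
    as.character(features$runner_id)
  } else as.character(seq_len(nrow(features)))
  keep <- stats::complete.cases(dat)
  dat <- dat[keep, , drop = FALSE]
  ids <- ids[keep]
  if (nrow(dat) < 10) {
    stop(sprintf("segment %s has %d complete rows; need at least 10",
                 segment, nrow(dat)), call. = FALSE)
  }
  x <- as.matrix(dat[c("wt", "wtv", "cpr")])
  qrx <- qr(cbind(1, x))
  if (qrx$rank < 4) {
    stop("rank-deficient design: predictors ", paste(c("wt", "wtv", "cpr"),
         collapse = ", "), " are collinear", call. = FALSE)
  }

  fit <- lm(TT ~ wt + wtv + cpr, data = dat)
  excluded <- character(0)
  # exact interpolation leaves only floating-point noise in the residuals;
  # influence measures are then meaningless ratios of that noise
  exactfit <- suppressWarnings(summary(fit)$sigma) <= 1e-10 * max(1, sd(dat$TT))
  if (exclude_influential && !exactfit) {
    d <- cooks.distance(fit)
    rs <- rstandard(fit)
    bad <- d > 1 | abs(rs) > 3
    bad[is.na(bad)] <- FALSE # exact fits give 0/0 influence measures
    if (any(bad)) {
      excluded <- ids[bad]
      dat <- dat[!bad, , drop = FALSE]
      ids <- ids[!bad]
      fit <- lm(TT ~ wt + wtv + cpr, data = dat)
    }
  }

  sm <- suppressWarnings(summary(fit)) # silence the essentially-perfect-fit note
  ci <- suppressWarnings(confint(fit, level = conf_level))
  b <- coef(fit)
  sds <- vapply(dat, sd, numeric(1))
  beta <- c(NA_real_, b[-1] * sds[c("wt", "wtv", "cpr")] / sds["TT"])
  coef_tab <- tibble::tibble(
    term = c("constant", unname(vars)),
    B = unname(b),
    SE = unname(sm$coefficients[, "Std. Error"]),
    t = unname(sm$coefficients[, "t value"]),
    p = unname(sm$coefficients[, "Pr(>|t|)"]),
    ll = unname(ci[, 1]),
    ul = unname(ci[, 2]),
    beta = unname(beta)
  )
  vifs <- vif(dat[c("wt", "wtv", "cpr")])
  names(vifs) <- unname(vars)
  structure(list(
    segment = segment,
    predictors = vars,
    coefficients = coef_tab,
    r = sqrt(sm$r.squared),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    see = sm$sigma,
    dw = durbin_watson(residuals(fit)),
    vif = vifs,
    excluded_cases = excluded,
    n_used = nrow(dat),
    conf_level = conf_level,
    source = "fitted",
    fit = fit
  ), class = "segment_fit")
}

#' @export
print.segment_fit <- function(x, ...) {
  cat(sprintf("<segment_fit> %s: n = %d, R2 = %.4f (adj %.4f), SEE = %.3f h\n",
              x$segment, x$n_used, x$r_squared, x$adj_r_squared, x$see))
  cat(sprintf("  Durbin-Watson = %.3f; VIF: %s\n", x$dw,
              paste(sprintf("%s %.2f", names(x$vif), x$vif), collapse = ", ")))
  if (length(x$excluded_cases)) {
    cat(sprintf("  excluded %d influential/outlier case(s)\n",
                length(x$excluded_cases)))
  }
  print(x$coefficients, ...)
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Agreement between predicted and actual finish times: the bias (mean
#' difference), the +/- 1.96 SD limits of agreement, the fraction of pairs
#' outside those limits, and a normality screen of the differences.
#'
#' @param predicted,actual Paired numeric vectors (hours; n >= 3 complete
#'   pairs).
#' @return An `agreement_summary`: `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `pct_outside`, `n`, `normality` (NULL when degenerate), `degenerate`
#'   flag, and the paired `differences`/`means` for plotting.
#' @export
bland_altman <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  keep <- !is.na(predicted) & !is.na(actual)
  predicted <- predicted[keep]; actual <- actual[keep]
  n <- length(predicted)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  diffs <- predicted - actual
  bias <- mean(diffs)
  s <- sd(diffs)
  degenerate <- s == 0
  if (degenerate) {
    warning("zero-variance differences: limits of agreement degenerate",
            call. = FALSE)
  }
  loa <- bias + c(-1, 1) * 1.96 * s
  structure(list(
    bias = bias, sd_diff = s, loa_low = loa[1], loa_high = loa[2],
    pct_outside = mean(diffs < loa[1] | diffs > loa[2]),
    n = n,
    normality = if (degenerate || n < 4) NULL else normality_screen(diffs),
    degenerate = degenerate,
    differences = diffs, means = (predicted + actual) / 2
  ), class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("<agreement_summary> n = %d: bias %.4f h, LoA [%.4f, %.4f] h, %.1f%% outside\n",
              x$n, x$bias, x$loa_low, x$loa_high, 100 * x$pct_outside))
  if (isTRUE(x$degenerate)) cat("  [degenerate: zero-variance differences]\n")
  invisible(x)
}
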