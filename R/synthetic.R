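lnorm_params <- function(mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Configuration for the synthetic race generator
#'
#' Defaults emulate the study conditions of the two-modality cohort the
#' analysis pipeline targets: a 764-runner marathon-modality field and a
#' 183-runner ultra field (947 total, male fraction 871/947); a lognormal
#' latent ability on the weighted-time scale matched to the observed
#' first-ascent weighted times (mean 7.30 h, SD 1.02 h and 16.85 h, 2.75 h
#' respectively); same-slope fatigue drift targeting mean pacing-variability
#' values of 0.31 (ascent 1 to ascent 2), 0.15 (descent 1 to descent 2) and
#' -0.02 (ascent 2 to ascent 3); multiplicative per-section noise with
#' SD 0.08 (which puts the paired first-vs-second-ascent effect size near
#' -2); and a post-section-5 remainder proportional to ability (0.373 /
#' 0.577 of ability), solved so mean finish times land at 9.98 h and
#' 18.35 h.
#'
#' @param field_size Named integer vector of runners per modality.
#' @param male_fraction Probability a simulated runner is male.
#' @param ability Named list per modality: `c(meanlog, sdlog)` of the latent
#'   ability (hours, weighted-time scale).
#' @param wtv_ascent Target mean pacing-variability between successive
#'   ascents (length = number of ascent pairs).
#' @param wtv_descent Target mean pacing-variability between successive
#'   descents.
#' @param noise_sd SD of the multiplicative per-section noise (>= 0).
#' @param remainder_factor Named vector: the unmodelled race remainder after
#'   the last timed section, as a fraction of ability.
#' @param seed RNG seed; mandatory.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(field_size = c(`4K` = 764L, `8K` = 183L),
                             male_fraction = 871 / 947,
                             ability = list(`4K` = lnorm_params(7.30, 1.02),
                                            `8K` = lnorm_params(16.85, 2.75)),
                             wtv_ascent = c(0.31, -0.02),
                             wtv_descent = 0.15,
                             noise_sd = 0.08,
                             remainder_factor = c(`4K` = 0.373, `8K` = 0.577),
                             seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (is.null(names(field_size)) || any(!nzchar(names(field_size)))) {
    stop("`field_size` must be named by modality", call. = FALSE)
  }
  if (any(field_size < 4)) stop("field sizes must be >= 4", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (male_fraction < 0 || male_fraction > 1) {
    stop("`male_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (any(1 + wtv_ascent <= 0) || any(1 + wtv_descent <= 0)) {
    stop("drift targets must keep 1 + target positive", call. = FALSE)
  }
  for (mod in names(field_size)) {
    if (is.null(ability[[mod]])) {
      stop("no ability parameters for modality ", mod, call. = FALSE)
    }
    if (is.na(remainder_factor[mod]) || remainder_factor[mod] < 0) {
      stop("`remainder_factor` must be >= 0 for modality ", mod, call. = FALSE)
    }
  }
  structure(list(field_size = field_size, male_fraction = male_fraction,
                 ability = ability, wtv_ascent = wtv_ascent,
                 wtv_descent = wtv_descent, noise_sd = noise_sd,
                 remainder_factor = remainder_factor, seed = as.integer(seed)),
            class = "synthetic_config")
}

# cumulative same-slope drift multiplier for each of the first k sections
drift_multipliers <- function(course, k, wtv_ascent, wtv_descent) {
  slopes <- course$sections$net_slope[seq_len(k)]
  f <- numeric(k)
  for (sl in c("positive", "negative")) {
    pos <- which(slopes == sl)
    targets <- if (sl == "positive") wtv_ascent else wtv_descent
    if (length(pos) - 1 > length(targets)) {
      stop(sprintf("course %s has %d %s-slope sections but only %d drift target(s)",
                   course$name, length(pos), sl, length(targets)), call. = FALSE)
    }
    f[pos] <- cumprod(c(1, 1 + targets))[seq_along(pos)]
  }
  f
}

#' Simulate a race field's split table
#'
#' Generates a complete split table with the statistical structure the
#' feature pipeline assumes. Each runner draws a latent ability `A` (hours,
#' on the weighted-time scale); the time of section `n` is
#' `IRDC_n * A * f_n * (1 + e_n)` with `f_n` the cumulative same-slope
#' fatigue drift and `e_n` Gaussian noise, so in the noiseless, driftless
#' limit every weighted time equals `A` exactly — difficulty-proportional
#' pacing by construction. The finish time adds an unstructured remainder
#' proportional to ability for the course beyond the last timed checkpoint.
#'
#' @param config A [synthetic_config()].
#' @param courses Named list of `trail_course` objects covering every
#'   modality in the config.
#' @return A split tibble (`runner_id`, `modality`, `sex`, `cp_1..cp_k`,
#'   `finish`), checkpoint times strictly increasing for every runner.
#' @examples
#' sim <- simulate_field(synthetic_config(field_size = c(`4K` = 50), seed = 1))
#' @export
simulate_field <- function(config,
                           courses = list(`4K` = course_4k(),
                                          `8K` = course_8k())) {
  stopifnot(inherits(config, "synthetic_config"))
  mods <- names(config$field_size)
  unknown <- setdiff(mods, names(courses))
  if (length(unknown)) {
    stop("no course supplied for modality: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  set.seed(config$seed)
  out <- vector("list", length(mods))
  for (m in seq_along(mods)) {
    mod <- mods[m]
    crs <- courses[[mod]]
    k <- nrow(crs$sections)
    n <- config$field_size[[mod]]
    ir <- course_irdc(crs, "full")
    f <- drift_multipliers(crs, k, config$wtv_ascent, config$wtv_descent)
    ab <- config$ability[[mod]]
    a <- rlnorm(n, ab[["meanlog"]], ab[["sdlog"]])
    sex <- ifelse(rbinom(n, 1, config$male_fraction) == 1, "male", "female")
    noise <- matrix(rnorm(n * k, 0, config$noise_sd), nrow = n)
    noise <- pmax(1 + noise, 0.05) # keep section times positive
    t_mat <- a * noise * rep(ir * f, each = n)
    cp_mat <- t(apply(t_mat, 1, cumsum))
    rem_noise <- pmax(1 + rnorm(n, 0, config$noise_sd), 0.05)
    finish <- cp_mat[, k] + config$remainder_factor[[mod]] * a * rem_noise
    df <- tibble::tibble(
      runner_id = sprintf("%s-%04d", mod, seq_len(n)),
      modality = mod, sex = sex)
    for (j in seq_len(k)) df[[paste0("cp_", j)]] <- cp_mat[, j]
    df$finish <- finish
    df$ability <- a
    out[[m]] <- df
  }
  do.call(rbind, out)
}

#' Simulate a field whose finish time follows a known linear model
#'
#' Parameter-recovery harness for the segment regressions: generates a field
#' with [simulate_field()], computes its features, then overwrites the
#' finish time with an exact linear combination of the segment's predictor
#' triple plus Gaussian noise, back-filling a consistent finish time (never
#' earlier than the last checkpoint). Refitting the segment model on the
#' result should recover `coefficients` up to sampling error.
#'
#' @param config A [synthetic_config()].
#' @param coefficients Named vector `c(constant, wt, wtv, cpr)`; defaults to
#'   the published ascent-1 coefficients.
#' @param segment Which segment's predictors generate the finish time.
#' @param tt_noise_sd SD (hours) of the additive finish-time noise.
#' @param courses Named list of courses, as in [simulate_field()].
#' @return A split tibble; the generating truth is attached as
#'   `attr(, "truth")` (`coefficients`, `segment`, `tt_noise_sd`).
#' @export
simulate_linear_tt <- function(config,
                               coefficients = paper_coefficient_table$ascent1,
                               segment = c("ascent1", "descent", "ascent2"),
                               tt_noise_sd = 0.3,
                               courses = list(`4K` = course_4k(),
                                              `8K` = course_8k())) {
  segment <- match.arg(segment)
  stopifnot(all(c("constant", "wt", "wtv", "cpr") %in% names(coefficients)),
            tt_noise_sd >= 0)
  splits <- simulate_field(config, courses)
  feats <- build_feature_table(splits, courses, rounding = "full", quiet = TRUE)
  vars <- segment_predictors(segment)
  tt <- coefficients[["constant"]] +
    coefficients[["wt"]] * feats[[vars[["wt"]]]] +
    coefficients[["wtv"]] * feats[[vars[["wtv"]]]] +
    coefficients[["cpr"]] * feats[[vars[["cpr"]]]] +
    rnorm(nrow(feats), 0, tt_noise_sd)
  cp_cols <- cp_columns(splits)
  last_cp <- splits[[cp_cols[length(cp_cols)]]]
  clamped <- tt <= last_cp
  if (any(clamped)) {
    warning(sprintf("%d generated finish time(s) fell before the last checkpoint and were clamped",
                    sum(clamped)), call. = FALSE)
    tt[clamped] <- last_cp[clamped] * 1.001
  }
  splits$finish <- tt
  attr(splits, "truth") <- list(coefficients = coefficients, segment = segment,
                                tt_noise_sd = tt_noise_sd)
  splits
}
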