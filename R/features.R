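#' Parse race times to decimal hours
#'
#' Accepts `"HH:MM:SS"` (or `"HH:MM"`) strings and plain decimal hours;
#' internal arithmetic throughout the package is in decimal hours.
#'
#' @param x Character or numeric vector.
#' @return Numeric vector of hours; `NA` and empty strings stay `NA`.
#' @examples
#' parse_race_time(c("01:30:00", "2.25", NA)) # 1.5 2.25 NA
#' @export
parse_race_time <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  out <- rep(NA_real_, length(x))
  is_clock <- !is.na(x) & grepl(":", x, fixed = TRUE)
  if (any(is_clock)) {
    parts <- strsplit(x[is_clock], ":", fixed = TRUE)
    out[is_clock] <- vapply(parts, function(p) {
      p <- as.numeric(p)
      if (length(p) == 2) p <- c(p, 0)
      if (length(p) != 3 || anyNA(p)) return(NA_real_)
      p[1] + p[2] / 60 + p[3] / 3600
    }, numeric(1))
  }
  plain <- !is.na(x) & !is_clock
  out[plain] <- suppressWarnings(as.numeric(x[plain]))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop("unparseable time value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Format decimal hours as HH:MM:SS
#' @param hours Numeric vector of decimal hours.
#' @return Character vector.
#' @export
format_race_time <- function(hours) {
  ifelse(is.na(hours), NA_character_, {
    s <- round(hours * 3600)
    sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
  })
}

#' Read a split table from CSV
#'
#' Expected columns: `runner_id`, `modality`, `sex`, checkpoint passage times
#' `cp_1` ... `cp_k` (also accepted as `cp1` ...), and `finish`. Times may be
#' `"HH:MM:SS"` or decimal hours; all are elapsed from the start. Missing
#' passages are allowed and stay `NA`.
#'
#' @param path CSV path.
#' @return A tibble with times in decimal hours (`cp_1`..`cp_k`, `finish`).
#' @export
read_splits <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- sub("^cp([0-9]+)$", "cp_\\1", names(df))
  needed <- c("runner_id", "modality", "sex", "finish")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("split CSV lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cp_cols <- grep("^cp_[0-9]+$", names(df), value = TRUE)
  if (!length(cp_cols)) stop("split CSV has no checkpoint columns", call. = FALSE)
  for (cl in c(cp_cols, "finish")) df[[cl]] <- parse_race_time(df[[cl]])
  df$runner_id <- as.character(df$runner_id)
  tibble::as_tibble(df)
}

cp_columns <- function(splits) {
  cols <- grep("^cp_[0-9]+$", names(splits), value = TRUE)
  cols[order(as.integer(sub("cp_", "", cols)))]
}

#' Section times from checkpoint passage times
#'
#' Successive differences of the elapsed passage times: the first section
#' time is the first passage time itself (the start is checkpoint 0). A
#' missing checkpoint makes both adjacent section times missing, since each
#' bounds two sections.
#'
#' @param cp_times Numeric vector of elapsed passage times (hours), `NA` for
#'   missed checkpoints.
#' @param runner_id Optional label used in validation messages.
#' @return Numeric vector of section times, same length as `cp_times`.
#' @examples
#' section_times(c(2.0, 3.5, 5.0)) # 2.0 1.5 1.5
#' section_times(c(2.0, NA, 5.0))  # 2.0 NA NA
#' @export
section_times <- function(cp_times, runner_id = NULL) {
  cp_times <- as.numeric(cp_times)
  present <- which(!is.na(cp_times))
  if (length(present) > 1 && any(diff(cp_times[present]) <= 0)) {
    stop(sprintf("non-monotone checkpoint times%s",
                 if (is.null(runner_id)) "" else paste0(" for runner ", runner_id)),
         call. = FALSE)
  }
  if (length(present) && any(cp_times[present] <= 0)) {
    stop(sprintf("non-positive checkpoint time%s",
                 if (is.null(runner_id)) "" else paste0(" for runner ", runner_id)),
         call. = FALSE)
  }
  t_n <- diff(c(0, cp_times))
  # a missing passage also voids the section that starts there
  miss <- which(is.na(cp_times))
  t_n[miss[miss < length(cp_times)] + 1] <- NA_real_
  t_n
}

#' Difficulty-weighted section time
#'
#' A section time divided by the section's relative difficulty coefficient:
#' the section's effort extrapolated to whole-race scale. Under constant
#' effort on uniform terrain the weighted time of every section equals the
#' finish time, which is what makes it comparable across sections of very
#' different length and slope.
#'
#' @param t_n Section time in hours (> 0, `NA` passes through).
#' @param irdc_n The section's relative difficulty coefficient in (0, 1].
#' @return Weighted time in hours.
#' @export
weighted_time <- function(t_n, irdc_n) {
  stopifnot(is.numeric(t_n), is.numeric(irdc_n))
  if (any(!is.na(t_n) & t_n <= 0)) {
    stop("section times must be positive", call. = FALSE)
  }
  if (any(is.na(irdc_n)) || any(irdc_n <= 0) || any(irdc_n > 1)) {
    stop("`irdc_n` must lie in (0, 1]", call. = FALSE)
  }
  t_n / irdc_n
}

#' Weighted-time variability between same-slope sections
#'
#' Relative change in weighted time between two sections of the same slope
#' type that are consecutive *in terrain order* (skipping the intervening
#' opposite-slope section): `WT_later / WT_earlier - 1`. Positive values mean
#' slowing on comparable terrain as the race progresses.
#'
#' @param wt_earlier,wt_later Weighted times (hours, > 0; `NA` propagates).
#' @param slope_earlier,slope_later Optional slope types of the two sections;
#'   when both are given they must match.
#' @return Dimensionless variability value.
#' @examples
#' weighted_time_variability(4, 5) # 0.25
#' @export
weighted_time_variability <- function(wt_earlier, wt_later,
                                      slope_earlier = NULL, slope_later = NULL) {
  if (!is.null(slope_earlier) && !is.null(slope_later) &&
      any(slope_earlier != slope_later)) {
    stop("weighted-time variability compares sections of the same slope type",
         call. = FALSE)
  }
  if (any(!is.na(wt_earlier) & wt_earlier <= 0) ||
      any(!is.na(wt_later) & wt_later <= 0)) {
    stop("weighted times must be positive", call. = FALSE)
  }
  wt_later / wt_earlier - 1
}

#' Checkpoint percentile rank
#'
#' The pooled-field percentile position at one checkpoint: ascending rank of
#' the passage time divided by the number of ranked runners, so the fastest
#' runner of `n` gets `1/n` and the slowest gets 1. Ties share the mean rank.
#' Pooling is across race modalities — the checkpoint lies on the shared
#' course portion, so the rank reflects the whole field.
#'
#' @param passage_times Elapsed passage times of every runner at one
#'   checkpoint (hours); `NA` for runners who missed it.
#' @return Numeric vector of percentile ranks in (0, 1], `NA` preserved.
#' @examples
#' checkpoint_percentile_rank(c(1.0, 1.2, 1.1)) # 1/3, 1, 2/3
#' @export
checkpoint_percentile_rank <- function(passage_times) {
  n <- sum(!is.na(passage_times))
  if (n == 0) return(rep(NA_real_, length(passage_times)))
  rank(passage_times, na.last = "keep", ties.method = "average") / n
}

#' Assign performance quartiles from percentile ranks
#'
#' Splits the field into the fastest quarter (`Q1`) and the rest (`Q2_4`).
#' The boundary is inclusive at rank `ceiling(0.25 * n)`: with 947 ranked
#' runners the boundary rank is 237 (237/947 = 0.2503), which belongs to Q1.
#'
#' @param cpr Percentile ranks from [checkpoint_percentile_rank()].
#' @return Factor with levels `Q1`, `Q2_4`; `NA` preserved.
#' @export
assign_quartiles <- function(cpr) {
  m <- sum(!is.na(cpr))
  if (m == 0) stop("no non-missing percentile ranks", call. = FALSE)
  cutoff <- ceiling(0.25 * m) / m
  factor(ifelse(cpr <= cutoff + 1e-12, "Q1", "Q2_4"), levels = c("Q1", "Q2_4"))
}

#' Build the per-runner feature table
#'
#' Joins, for every runner: raw section times `T_1..T_5`, difficulty-weighted
#' times `WT_1..WT_5` (each modality weighted by its own course), the three
#' same-slope pacing-variability values `WTV_13`, `WTV_24`, `WTV_35`, pooled
#' checkpoint percentile ranks `CPR_1..CPR_3`, the performance quartile (from
#' `CPR_1`), and the finish time `TT`. A runner missing a constituent of one
#' feature carries `NA` for that feature only (pairwise, not listwise,
#' exclusion downstream).
#'
#' @param splits Split tibble as from [read_splits()] or [simulate_field()].
#' @param courses Named list of `trail_course` objects keyed by modality.
#' @param rounding IRDC precision handed to [course_irdc()]; `"full"`
#'   (default) or `"paper"`.
#' @param quiet Suppress the partial-row log message.
#' @return A tibble, one row per runner.
#' @export
build_feature_table <- function(splits,
                                courses = list(`4K` = course_4k(),
                                               `8K` = course_8k()),
                                rounding = c("full", "paper"),
                                quiet = FALSE) {
  rounding <- match.arg(rounding)
  stopifnot(is.data.frame(splits))
  cp_cols <- cp_columns(splits)
  k <- length(cp_cols)
  unknown <- setdiff(unique(splits$modality), names(courses))
  if (length(unknown)) {
    stop("no course supplied for modality: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  irdc_by_mod <- lapply(courses, function(crs) {
    if (nrow(crs$sections) < k) {
      stop(sprintf("course %s has %d sections but splits have %d checkpoints",
                   crs$name, nrow(crs$sections), k), call. = FALSE)
    }
    course_irdc(crs, rounding)[seq_len(k)]
  })
  slopes_by_mod <- lapply(courses, function(crs) crs$sections$net_slope[seq_len(k)])

  cp_mat <- as.matrix(splits[cp_cols])
  t_mat <- t(vapply(seq_len(nrow(splits)), function(i) {
    section_times(cp_mat[i, ], runner_id = splits$runner_id[i])
  }, numeric(k)))
  irdc_mat <- do.call(rbind, irdc_by_mod[splits$modality])
  dimnames(irdc_mat) <- NULL
  wt_mat <- t_mat / irdc_mat

  out <- tibble::tibble(runner_id = as.character(splits$runner_id),
                        modality = splits$modality,
                        sex = splits$sex)
  for (n in seq_len(k)) out[[paste0("T_", n)]] <- t_mat[, n]
  for (n in seq_len(k)) out[[paste0("WT_", n)]] <- wt_mat[, n]

  wtv_pairs <- list(WTV_13 = c(1, 3), WTV_24 = c(2, 4), WTV_35 = c(3, 5))
  for (nm in names(wtv_pairs)) {
    pr <- wtv_pairs[[nm]]
    if (max(pr) > k) next
    for (mod in unique(splits$modality)) {
      sl <- slopes_by_mod[[mod]]
      if (sl[pr[1]] != sl[pr[2]]) {
        stop(sprintf("sections %d and %d of course %s differ in slope type",
                     pr[1], pr[2], mod), call. = FALSE)
      }
    }
    out[[nm]] <- weighted_time_variability(wt_mat[, pr[1]], wt_mat[, pr[2]])
  }
  for (j in seq_len(min(3L, k))) {
    out[[paste0("CPR_", j)]] <- checkpoint_percentile_rank(cp_mat[, j])
  }
  out$quartile <- assign_quartiles(out$CPR_1)
  out$TT <- splits$finish

  feat_cols <- setdiff(names(out), c("runner_id", "modality", "sex"))
  n_partial <- sum(apply(is.na(out[feat_cols]), 1, any))
  if (!quiet && n_partial > 0) {
    message(sprintf("%d of %d runners have one or more missing features (kept, excluded pairwise downstream)",
                    n_partial, nrow(out)))
  }
  out
}
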