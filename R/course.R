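#' Uphill terrain difficulty factor
#'
#' The ITRA-style difficulty factor for a track (or section) with a net
#' uphill profile: distance in km plus accumulated elevation gain in metres
#' divided by 100. A flat course reduces to its distance.
#'
#' @param distance_km Track or section distance in kilometres (> 0).
#' @param gain_m Accumulated positive elevation in metres (>= 0).
#' @return The dimensionless difficulty factor, at full floating precision.
#' @examples
#' idf_positive(42, 3500) # 77
#' idf_positive(78, 6900) # 147
#' @seealso [idf_negative()], [summarize_course()]
#' @export
idf_positive <- function(distance_km, gain_m) {
  check_idf_inputs(distance_km, gain_m, "gain_m")
  distance_km + gain_m / 100
}

#' Downhill terrain difficulty factor
#'
#' The downhill analogue of [idf_positive()]: distance in km plus accumulated
#' elevation loss (as a non-negative magnitude, metres) divided by 100.
#'
#' @param distance_km Track or section distance in kilometres (> 0).
#' @param loss_m Accumulated negative elevation, magnitude in metres (>= 0).
#' @return The dimensionless difficulty factor.
#' @examples
#' idf_negative(42, 4000) # 82
#' @export
idf_negative <- function(distance_km, loss_m) {
  check_idf_inputs(distance_km, loss_m, "loss_m")
  distance_km + loss_m / 100
}

check_idf_inputs <- function(distance_km, elev_m, elev_name) {
  stopifnot(is.numeric(distance_km), is.numeric(elev_m))
  if (any(!is.finite(distance_km)) || any(distance_km <= 0)) {
    stop("`distance_km` must be a positive finite number", call. = FALSE)
  }
  if (any(!is.finite(elev_m)) || any(elev_m < 0)) {
    stop(sprintf("`%s` must be a non-negative finite number", elev_name),
         call. = FALSE)
  }
  invisible(NULL)
}

#' Construct a course profile
#'
#' A course profile holds the race totals (distance, accumulated gain and
#' loss) and an ordered table of timed sections between checkpoints. Sections
#' need not cover the full course distance: timing commonly stops partway,
#' and only the timed portion enters the feature pipeline. Elevation loss is
#' stored as a non-negative magnitude; each section carries an explicit net
#' slope flag rather than re-deriving it, so published section tables can be
#' reproduced exactly. A section (or the race totals) may carry a published
#' difficulty-factor override where the official table disagrees with the
#' raw distance/slope arithmetic.
#'
#' @param name Race label, e.g. `"4K"`.
#' @param distance_km Total track distance (km).
#' @param gain_m Total accumulated positive slope (m).
#' @param loss_m Total accumulated negative slope, magnitude (m).
#' @param sections A data frame with columns `index` (1-based, contiguous),
#'   `start_cp`, `end_cp`, `distance_km`, `gain_m`, `loss_m`, optionally
#'   `net_slope` (`"positive"`/`"negative"`, derived from gain vs loss when
#'   absent) and `idf_override` (published section factor, `NA` to compute).
#' @param idf_pos,idf_neg Optional published race-level factors overriding
#'   the computed values.
#' @return An object of class `trail_course`.
#' @examples
#' crs <- trail_course("toy", 10, 800, 800,
#'   data.frame(index = 1:2, start_cp = c("cp0", "cp1"),
#'              end_cp = c("cp1", "cp2"), distance_km = c(6, 4),
#'              gain_m = c(800, 0), loss_m = c(0, 800)))
#' summarize_course(crs)
#' @export
trail_course <- function(name, distance_km, gain_m, loss_m, sections,
                         idf_pos = NULL, idf_neg = NULL) {
  check_idf_inputs(distance_km, gain_m, "gain_m")
  check_idf_inputs(distance_km, loss_m, "loss_m")
  sections <- as.data.frame(sections)
  needed <- c("index", "start_cp", "end_cp", "distance_km", "gain_m", "loss_m")
  missing_cols <- setdiff(needed, names(sections))
  if (length(missing_cols)) {
    stop("sections table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(as.integer(sections$index), seq_len(nrow(sections)))) {
    stop("section indices must be contiguous from 1 in order", call. = FALSE)
  }
  if (any(sections$distance_km <= 0) || any(sections$gain_m < 0) ||
      any(sections$loss_m < 0)) {
    stop("sections need distance_km > 0 and non-negative gain_m/loss_m",
         call. = FALSE)
  }
  if (is.null(sections$net_slope)) {
    sections$net_slope <- ifelse(sections$gain_m >= sections$loss_m,
                                 "positive", "negative")
  }
  if (!all(sections$net_slope %in% c("positive", "negative"))) {
    stop('net_slope must be "positive" or "negative"', call. = FALSE)
  }
  if (is.null(sections$idf_override)) sections$idf_override <- NA_real_
  structure(
    list(name = name,
         distance_km = distance_km, gain_m = gain_m, loss_m = loss_m,
         idf_pos = idf_pos %||% idf_positive(distance_km, gain_m),
         idf_neg = idf_neg %||% idf_negative(distance_km, loss_m),
         sections = tibble::as_tibble(sections)),
    class = "trail_course")
}

#' @export
print.trail_course <- function(x, ...) {
  cat(sprintf("<trail_course> %s: %.1f km, +%.0f m / -%.0f m (IDF+ %.1f, IDF- %.1f)\n",
              x$name, x$distance_km, x$gain_m, x$loss_m, x$idf_pos, x$idf_neg))
  cat(sprintf("%d timed section(s):\n", nrow(x$sections)))
  print(x$sections, ...)
  invisible(x)
}

#' Read a course profile from a YAML or JSON config file
#'
#' The config carries `name`, `distance_km`, `gain_m`, `loss_m`, optional
#' race-level `idf_pos`/`idf_neg` overrides, and a `sections` list whose
#' entries mirror the columns documented in [trail_course()]. Units are
#' fixed: km for distances, m for elevation.
#'
#' @param path Path to the config file (`yaml::read_yaml()` also parses JSON).
#' @return A `trail_course`.
#' @export
read_course <- function(path) {
  cfg <- yaml::read_yaml(path)
  secs <- do.call(rbind, lapply(cfg$sections, function(s) {
    data.frame(index = s$index, start_cp = s$start_cp, end_cp = s$end_cp,
               distance_km = s$distance_km, gain_m = s$gain_m,
               loss_m = s$loss_m,
               net_slope = s$net_slope %||% NA_character_,
               idf_override = s$idf_override %||% NA_real_)
  }))
  if (all(is.na(secs$net_slope))) secs$net_slope <- NULL
  trail_course(cfg$name, cfg$distance_km, cfg$gain_m, cfg$loss_m, secs,
               idf_pos = cfg$idf_pos, idf_neg = cfg$idf_neg)
}

#' Built-in course fixtures
#'
#' The two Trail Valle de Tena modalities: the 4K marathon-distance course
#' (42 km, +3500 m, -4000 m) and the 8K ultra course (78 km, +6900 m,
#' -6950 m), sharing the same five timed sections between the start and the
#' fifth common checkpoint. Section factors carry the published override
#' values where the official table differs from the raw arithmetic, and the
#' 8K downhill race factor uses the published 148 (raw inputs give 147.5).
#'
#' @return A `trail_course`.
#' @examples
#' summarize_course(course_4k(), rounding = "paper")
#' @name course-fixtures
NULL

#' @rdname course-fixtures
#' @export
course_4k <- function() {
  read_course(system.file("extdata", "course_4k.yaml", package = "trailpace",
                          mustWork = TRUE))
}

#' @rdname course-fixtures
#' @export
course_8k <- function() {
  read_course(system.file("extdata", "course_8k.yaml", package = "trailpace",
                          mustWork = TRUE))
}

#' Difficulty factor of a single section
#'
#' Applies [idf_positive()] to (distance, gain) for a net-uphill section and
#' [idf_negative()] to (distance, loss) for a net-downhill section. When the
#' section carries a published override and `use_override = TRUE` (default),
#' the override is returned instead of the recomputed value.
#'
#' @param section A one-row section (row of `course$sections`, data frame or
#'   list) with `distance_km`, `gain_m`, `loss_m`, `net_slope`, optionally
#'   `idf_override`.
#' @param use_override Honour a published `idf_override` if present.
#' @return The section's dimensionless difficulty factor.
#' @export
section_difficulty <- function(section, use_override = TRUE) {
  section <- as.list(section)
  ov <- section$idf_override %||% NA_real_
  if (use_override && length(ov) == 1 && !is.na(ov)) return(as.numeric(ov))
  if (identical(section$net_slope, "positive")) {
    idf_positive(section$distance_km, section$gain_m)
  } else if (identical(section$net_slope, "negative")) {
    idf_negative(section$distance_km, section$loss_m)
  } else {
    stop('section$net_slope must be "positive" or "negative"', call. = FALSE)
  }
}

#' Relative difficulty coefficient of a section
#'
#' A section's difficulty factor divided by the race-level factor of the same
#' slope sign: the section's share of the race's total uphill (or downhill)
#' difficulty, in (0, 1]. All arithmetic is at full floating precision;
#' `rounding = "paper"` rounds to 2 decimals, the precision at which
#' published difficulty tables (and the closed-form predictors built on
#' them) state these coefficients.
#'
#' @param section A section row (see [section_difficulty()]).
#' @param course The `trail_course` the section belongs to.
#' @param rounding `"full"` (default) or `"paper"` (2-decimal).
#' @param use_override Honour published per-section factor overrides.
#' @return The relative difficulty coefficient.
#' @export
irdc <- function(section, course, rounding = c("full", "paper"),
                 use_override = TRUE) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(course, "trail_course"))
  section <- as.list(section)
  denom <- if (identical(section$net_slope, "positive")) course$idf_pos else course$idf_neg
  if (!is.finite(denom) || denom <= 0) {
    stop("race-level difficulty factor must be positive", call. = FALSE)
  }
  val <- section_difficulty(section, use_override = use_override) / denom
  if (rounding == "paper") round(val, 2) else val
}

#' Per-section relative difficulty coefficients of a course
#'
#' @inheritParams irdc
#' @return Numeric vector, one coefficient per section in order.
#' @export
course_irdc <- function(course, rounding = c("full", "paper"),
                        use_override = TRUE) {
  rounding <- match.arg(rounding)
  vapply(seq_len(nrow(course$sections)), function(i) {
    irdc(course$sections[i, ], course, rounding, use_override)
  }, numeric(1))
}

#' Summarise a course's difficulty structure
#'
#' Computes the race-level uphill/downhill difficulty factors and, for every
#' timed section, its own factor and relative difficulty coefficient.
#'
#' @inheritParams irdc
#' @return A `difficulty_summary`: list with `name`, `idf_pos`, `idf_neg` and
#'   a tibble `sections` (`index`, `start_cp`, `end_cp`, `net_slope`,
#'   `idf_section`, `irdc`).
#' @examples
#' summarize_course(course_4k(), rounding = "paper")$sections$irdc
#' # 0.27 0.21 0.16 0.13 0.12
#' @export
summarize_course <- function(course, rounding = c("full", "paper"),
                             use_override = TRUE) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(course, "trail_course"))
  secs <- course$sections
  tab <- tibble::tibble(
    index = secs$index,
    start_cp = secs$start_cp,
    end_cp = secs$end_cp,
    net_slope = secs$net_slope,
    idf_section = vapply(seq_len(nrow(secs)), function(i) {
      section_difficulty(secs[i, ], use_override = use_override)
    }, numeric(1)),
    irdc = course_irdc(course, rounding, use_override)
  )
  structure(list(name = course$name, idf_pos = course$idf_pos,
                 idf_neg = course$idf_neg, sections = tab,
                 rounding = rounding),
            class = "difficulty_summary")
}

#' @export
print.difficulty_summary <- function(x, ...) {
  cat(sprintf("<difficulty_summary> %s (IDF+ %.1f, IDF- %.1f, %s precision)\n",
              x$name, x$idf_pos, x$idf_neg, x$rounding))
  print(x$sections, ...)
  invisible(x)
}
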