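paper_coefficient_table <- list(
  ascent1 = c(constant = 0.939, wt = 0.914, wtv = 4.993, cpr = 1.468),
  descent = c(constant = 1.796, wt = 1.411, wtv = 3.321, cpr = -0.465),
  ascent2 = c(constant = 2.295, wt = 0.746, wtv = 2.555, cpr = 0.888)
)

#' Published segment-model coefficients
#'
#' The published regression coefficients for the three terrain segments of
#' the Trail Valle de Tena cohort, for use in replication mode: evaluating
#' these models pins the relative difficulty coefficients to their published
#' 2-decimal values (the scale on which the coefficients were estimated).
#' Mixing published coefficients with full-precision coefficients — or
#' freshly fitted coefficients with 2-decimal rounding — is refused by
#' [predict_tt()].
#'
#' @param segment `"ascent1"` (the published closed forms), `"descent"` or
#'   `"ascent2"`.
#' @return A `segment_model` with `segment`, named `coefficients`
#'   (`constant`, `wt`, `wtv`, `cpr`) and `source = "paper"`.
#' @export
paper_model <- function(segment = c("ascent1", "descent", "ascent2")) {
  segment <- match.arg(segment)
  structure(list(segment = segment,
                 coefficients = paper_coefficient_table[[segment]],
                 source = "paper"),
            class = "segment_model")
}

model_coefficients <- function(model) {
  if (inherits(model, "segment_model")) {
    list(segment = model$segment, coefs = model$coefficients,
         source = model$source)
  } else if (inherits(model, "segment_fit")) {
    list(segment = model$segment,
         coefs = setNames(model$coefficients$B,
                          c("constant", "wt", "wtv", "cpr")),
         source = "fitted")
  } else {
    stop("`model` must be a segment_fit or segment_model", call. = FALSE)
  }
}

resolve_rounding <- function(source, rounding) {
  if (is.null(rounding)) {
    return(if (source == "paper") "paper" else "full")
  }
  rounding <- match.arg(rounding, c("full", "paper"))
  if (source == "paper" && rounding != "paper") {
    stop("published coefficients must be evaluated with 2-decimal ('paper') difficulty coefficients; refusing to mix precision modes",
         call. = FALSE)
  }
  if (source == "fitted" && rounding != "full") {
    stop("freshly fitted coefficients must be evaluated with full-precision difficulty coefficients; refusing to mix precision modes",
         call. = FALSE)
  }
  rounding
}

#' Predict finish time mid-race from a segment model
#'
#' Evaluates a fitted or published segment model for one runner using only
#' in-race quantities: the raw times of the segment's two same-slope
#' sections, and the runner's position at the segment's opening checkpoint.
#' Internally the raw times are converted to weighted times via the course's
#' relative difficulty coefficients, the pacing-variability value is their
#' ratio minus one, and the percentile rank is `rank / field_size`.
#'
#' The field size at prediction time is whatever the live timing reports
#' (the cohort models were fitted with the pooled finisher count; mid-race
#' these differ — the caller chooses which field the rank refers to).
#'
#' @param model A `segment_fit` from [fit_segment_model()] or a
#'   [paper_model()].
#' @param course The runner's `trail_course`.
#' @param t_first,t_second Raw times (hours) of the segment's earlier and
#'   later same-slope sections (for ascent 1: sections 1 and 3).
#' @param rank Integer position at the segment's opening checkpoint
#'   (1 = fastest).
#' @param field_size Number of runners ranked at that checkpoint.
#' @param rounding Difficulty-coefficient precision; defaults to the mode
#'   matching the model's provenance, and refuses a mismatch.
#' @return Predicted total race time in hours.
#' @examples
#' predict_tt(paper_model("ascent1"), course_4k(),
#'            t_first = 2, t_second = 1.6, rank = 100, field_size = 764)
#' @export
predict_tt <- function(model, course, t_first, t_second, rank, field_size,
                       rounding = NULL) {
  mc <- model_coefficients(model)
  rounding <- resolve_rounding(mc$source, rounding)
  stopifnot(inherits(course, "trail_course"))
  if (missing(t_first) || is.na(t_first)) {
    stop("missing time for the segment's earlier section", call. = FALSE)
  }
  if (missing(t_second) || is.na(t_second)) {
    stop("missing time for the segment's later section", call. = FALSE)
  }
  stopifnot(t_first > 0, t_second > 0)
  if (rank < 1 || rank > field_size) {
    stop("`rank` must lie in 1..field_size", call. = FALSE)
  }
  lay <- segment_layout(mc$segment)
  ir <- course_irdc(course, rounding)[lay$sections]
  wt1 <- weighted_time(t_first, ir[1])
  wt2 <- weighted_time(t_second, ir[2])
  wtv <- weighted_time_variability(wt1, wt2)
  cpr <- rank / field_size
  b <- mc$coefs
  unname(b["constant"] + b["wt"] * wt1 + b["wtv"] * wtv + b["cpr"] * cpr)
}

#' Expand a segment model into a closed form over raw section times
#'
#' Substitutes the weighted-time definitions into the linear model, yielding
#' an expression directly in the raw section times and the checkpoint rank:
#'
#' `TT = b_wt * T_a/i_a + b_wtv * ((T_b/i_b) / (T_a/i_a) - 1)
#'       + b_cpr * rank/field + constant`
#'
#' where `i_a`, `i_b` are the course's relative difficulty coefficients of
#' the segment's two same-slope sections. With the published ascent-1
#' coefficients and 2-decimal coefficients this reproduces the published
#' closed-form predictors term for term (denominators 0.27/0.16 for the 4K
#' course and 0.14/0.08 for the 8K).
#'
#' @inheritParams predict_tt
#' @return A `closed_form`: `modality`, `segment`, coefficient fields
#'   (`constant`, `b_wt`, `b_wtv`, `b_cpr`) and denominators `irdc_first`,
#'   `irdc_second`. Evaluate with [predict.closed_form()].
#' @examples
#' expand_closed_form(paper_model("ascent1"), course_4k())
#' @export
expand_closed_form <- function(model, course, rounding = NULL) {
  mc <- model_coefficients(model)
  rounding <- resolve_rounding(mc$source, rounding)
  stopifnot(inherits(course, "trail_course"))
  lay <- segment_layout(mc$segment)
  ir <- course_irdc(course, rounding)[lay$sections]
  b <- mc$coefs
  structure(list(modality = course$name, segment = mc$segment,
                 source = mc$source, rounding = rounding,
                 constant = unname(b["constant"]), b_wt = unname(b["wt"]),
                 b_wtv = unname(b["wtv"]), b_cpr = unname(b["cpr"]),
                 irdc_first = ir[1], irdc_second = ir[2],
                 sections = lay$sections, cp = lay$cp),
            class = "closed_form")
}

#' Evaluate a closed-form finish-time predictor
#'
#' @param object A `closed_form` from [expand_closed_form()].
#' @param t_first,t_second Raw section times (hours) of the segment's two
#'   same-slope sections.
#' @param rank,field_size Position and field size at the segment's opening
#'   checkpoint.
#' @param ... Unused.
#' @return Predicted total race time in hours (vectorised over inputs).
#' @export
predict.closed_form <- function(object, t_first, t_second, rank, field_size,
                                ...) {
  stopifnot(all(t_first > 0), all(t_second > 0),
            all(rank >= 1), all(rank <= field_size))
  wt1 <- t_first / object$irdc_first
  object$b_wt * wt1 +
    object$b_wtv * ((t_second / object$irdc_second) / wt1 - 1) +
    object$b_cpr * rank / field_size +
    object$constant
}

#' @export
print.closed_form <- function(x, ...) {
  cat(sprintf("<closed_form> %s / %s (%s coefficients, %s-precision IRDC)\n",
              x$modality, x$segment, x$source, x$rounding))
  cat(sprintf("  TT = %.3f * T%d/%.4g + %.3f * ((T%d/%.4g)/(T%d/%.4g) - 1) + %.3f * rank/n + %.3f\n",
              x$b_wt, x$sections[1], x$irdc_first,
              x$b_wtv, x$sections[2], x$irdc_second,
              x$sections[1], x$irdc_first,
              x$b_cpr, x$constant))
  invisible(x)
}
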