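# Reference labeling by the rule-based sonographic criteria, and quantitative
# classification by per-view StdDev cut-offs.

# Sex-specific sheath-swelling thresholds (mm), inclusive.
SHEATH_THRESHOLDS <- list(
  transverse = c(F = 4.6, M = 5.5),
  longitudinal = c(F = 2.5, M = 2.8)
)
FLUID_DEPTH_MM <- 3

#' Sheath measurements feeding the reference criteria
#'
#' @param transverse_sheath_mm,longitudinal_sheath_mm tendon-sheath thickness
#'   per view, mm (`NA` if not measured).
#' @param fluid_depth_mm sheath effusion depth, mm.
#' @param fluid_displaceable,fluid_compressible effusion behaviour under
#'   probe pressure.
#' @param color_flow_increased increased Doppler color-flow signal around the
#'   tendon (boolean input; Doppler processing itself is out of scope).
#' @param sex `"F"` or `"M"`; required because the swelling thresholds are
#'   sex-specific.
#' @return An object of class `qus_sheath`.
#' @export
sheath_measurements <- function(transverse_sheath_mm = NA_real_,
                                longitudinal_sheath_mm = NA_real_,
                                fluid_depth_mm = NA_real_,
                                fluid_displaceable = FALSE,
                                fluid_compressible = FALSE,
                                color_flow_increased = FALSE,
                                sex = NA_character_) {
  for (v in c(transverse_sheath_mm, longitudinal_sheath_mm, fluid_depth_mm)) {
    if (!is.na(v) && (!is.numeric(v) || v < 0)) {
      qus_stop("sheath/fluid measurements must be non-negative", "qus_label_error")
    }
  }
  structure(
    list(
      transverse_sheath_mm = as.numeric(transverse_sheath_mm),
      longitudinal_sheath_mm = as.numeric(longitudinal_sheath_mm),
      fluid_depth_mm = as.numeric(fluid_depth_mm),
      fluid_displaceable = isTRUE(fluid_displaceable),
      fluid_compressible = isTRUE(fluid_compressible),
      color_flow_increased = isTRUE(color_flow_increased),
      sex = sex
    ),
    class = "qus_sheath"
  )
}

#' Rule-based reference label
#'
#' Tendinitis-positive iff at least one structural criterion holds --
#' (1) sheath swelling: transverse thickness at or above 4.6 mm (women) /
#' 5.5 mm (men), or longitudinal thickness at or above 2.5 mm (women) /
#' 2.8 mm (men); (2) sheath effusion at least 3 mm deep that is both
#' displaceable and compressible -- AND increased color-flow signal is
#' present (the vascularity sign treated as essential; set
#' `require_color_flow = FALSE` to relax it to the structural criteria
#' alone). Thresholds are inclusive. Missing measurements simply fail their
#' criterion; it is an error if sex is unknown or no measurement is present.
#'
#' @param m a [sheath_measurements()].
#' @param require_color_flow AND the color-flow sign into the label
#'   (default `TRUE`).
#' @return `"pos"` or `"neg"`.
#' @export
criteria_label <- function(m, require_color_flow = TRUE) {
  stopifnot(inherits(m, "qus_sheath"))
  if (is.na(m$sex) || !m$sex %in% c("F", "M")) {
    qus_stop("sex is required for the sex-specific swelling thresholds",
             "qus_label_error")
  }
  if (is.na(m$transverse_sheath_mm) && is.na(m$longitudinal_sheath_mm) &&
      is.na(m$fluid_depth_mm)) {
    qus_stop("no evaluable measurement: all sheath and fluid fields missing",
             "qus_label_error")
  }
  swelling <-
    (!is.na(m$transverse_sheath_mm) &&
       m$transverse_sheath_mm >= SHEATH_THRESHOLDS$transverse[[m$sex]]) ||
    (!is.na(m$longitudinal_sheath_mm) &&
       m$longitudinal_sheath_mm >= SHEATH_THRESHOLDS$longitudinal[[m$sex]])
  fluid <- !is.na(m$fluid_depth_mm) && m$fluid_depth_mm >= FLUID_DEPTH_MM &&
    m$fluid_displaceable && m$fluid_compressible
  structural <- swelling || fluid
  if (require_color_flow) {
    if (structural && m$color_flow_increased) "pos" else "neg"
  } else {
    if (structural) "pos" else "neg"
  }
}

#' Per-view StdDev cut-off model
#'
#' Published operating points: 26.85 for the transverse view and 21.25 for
#' the longitudinal view. (The Results text of the source study prints the
#' longitudinal cut-off once as 23.25; the abstract and the accuracy table
#' agree on 21.25, which is adopted here.)
#'
#' @param view `"transverse"` or `"longitudinal"`.
#' @param cutoff positive StdDev threshold; scores strictly greater are
#'   classified positive.
#' @return An object of class `qus_cutoff`.
#' @export
cutoff_model <- function(view, cutoff) {
  if (!is_scalar_number(cutoff) || cutoff <= 0) {
    qus_stop("`cutoff` must be a positive number", "qus_usage_error")
  }
  structure(list(view = match_view(view), cutoff = cutoff),
            class = "qus_cutoff")
}

#' Published default cut-off models
#' @return Named list of [cutoff_model()]s for both views.
#' @export
default_cutoffs <- function() {
  list(transverse = cutoff_model("transverse", 26.85),
       longitudinal = cutoff_model("longitudinal", 21.25))
}

#' Classify a single view by its StdDev cut-off
#'
#' Positive iff the ROI StdDev strictly surpasses the cut-off.
#'
#' @param stats a [roi_stats()] result.
#' @param model a [cutoff_model()] for the same view.
#' @return `"pos"` or `"neg"`.
#' @export
classify_quantitative <- function(stats, model) {
  stopifnot(inherits(stats, "qus_roi_stats"), inherits(model, "qus_cutoff"))
  if (stats$view != model$view) {
    qus_stop(sprintf("view mismatch: stats are %s, model is %s",
                     stats$view, model$view), "qus_usage_error")
  }
  if (stats$stddev > model$cutoff) "pos" else "neg"
}

#' Combine per-view classifications for a subject
#'
#' @param stats_by_view named list (names `"transverse"`,
#'   `"longitudinal"`) of [roi_stats()]; either view may be absent.
#' @param models named list of [cutoff_model()]s, as [default_cutoffs()].
#' @param rule `"any_view"` (positive if either view fires; default),
#'   `"transverse_only"`, or `"longitudinal_only"`.
#' @return `"pos"` or `"neg"`.
#' @export
classify_subject <- function(stats_by_view, models = default_cutoffs(),
                             rule = c("any_view", "transverse_only",
                                      "longitudinal_only")) {
  rule <- match.arg(rule)
  views <- switch(rule,
    any_view = c("transverse", "longitudinal"),
    transverse_only = "transverse",
    longitudinal_only = "longitudinal"
  )
  avail <- intersect(views, names(stats_by_view))
  avail <- avail[!vapply(stats_by_view[avail], is.null, logical(1))]
  if (!length(avail)) {
    qus_stop(sprintf("no view available for rule \"%s\"", rule),
             "qus_usage_error")
  }
  labels <- vapply(avail, function(v) {
    classify_quantitative(stats_by_view[[v]], models[[v]])
  }, character(1))
  if (any(labels == "pos")) "pos" else "neg"
}
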