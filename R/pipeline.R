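# Pipeline verbs behind the command-line interface:
# quantify -> classify -> calibrate -> report.

#' Quantify ROI statistics over a set of images
#'
#' For each image (with its JSON sidecar) the ROI stored in the sidecar is
#' used when present; otherwise a centered 2 mm^2 ROI with the view's
#' conventional shape (circle transverse, square longitudinal) is applied.
#'
#' @param input a directory containing images + sidecars, or a character
#'   vector of image paths.
#' @return Data frame with one row per image: `subject_id`, `view`,
#'   `n_pixels`, `min`, `max`, `mean`, `sd`, `group_label`.
#' @export
quantify_images <- function(input) {
  paths <- if (length(input) == 1L && dir.exists(input)) {
    list.files(input, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
               full.names = TRUE)
  } else {
    input
  }
  if (!length(paths)) {
    qus_stop("no images found to quantify", "qus_usage_error")
  }
  rows <- lapply(sort(paths), function(p) {
    img <- read_image(p)
    spec <- attr(img, "roi") %||% roi_spec(
      if (img$view == "transverse") "circle" else "square",
      center = c((nrow(img$pixels) + 1) / 2, (ncol(img$pixels) + 1) / 2),
      area_mm2 = 2
    )
    st <- roi_stats(img, roi_pixel_mask(spec, img))
    data.frame(subject_id = img$subject_id, view = img$view,
               n_pixels = st$n_pixels, min = st$min, max = st$max,
               mean = st$mean, sd = st$stddev, group_label = img$group_label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify quantified scores by the per-view StdDev cut-offs
#'
#' Adds a per-row `label` (strictly-greater rule against the view's cut-off)
#' and returns, per subject, the combined label under the chosen rule.
#'
#' @param quant data frame from [quantify_images()] (or its CSV re-read).
#' @param models named list of [cutoff_model()]s, as [default_cutoffs()].
#' @param rule combination rule for [classify_subject()].
#' @return `quant` with an added `label` column and, as attribute
#'   `"subjects"`, a per-subject data frame `subject_id`, `label`.
#' @export
classify_scores <- function(quant, models = default_cutoffs(),
                            rule = "any_view") {
  needed <- c("subject_id", "view", "sd")
  if (!all(needed %in% names(quant))) {
    qus_stop("quantified table must have subject_id, view, sd columns",
             "qus_schema_error")
  }
  quant$label <- vapply(seq_len(nrow(quant)), function(i) {
    m <- models[[quant$view[i]]]
    if (is.null(m)) qus_stop(sprintf("no cut-off model for view %s",
                                     quant$view[i]), "qus_usage_error")
    if (quant$sd[i] > m$cutoff) "pos" else "neg"
  }, character(1))
  per_subject <- do.call(rbind, lapply(split(quant, quant$subject_id), function(d) {
    stats_by_view <- lapply(seq_len(nrow(d)), function(i) {
      structure(list(min = d$min[i], max = d$max[i], mean = d$mean[i],
                     stddev = d$sd[i], n_pixels = d$n_pixels[i],
                     view = d$view[i]), class = "qus_roi_stats")
    })
    names(stats_by_view) <- d$view
    data.frame(subject_id = d$subject_id[1],
               label = classify_subject(stats_by_view, models, rule),
               stringsAsFactors = FALSE)
  }))
  rownames(per_subject) <- NULL
  attr(quant, "subjects") <- per_subject
  quant
}

#' Calibrate cut-offs and report diagnostic performance per view
#'
#' For each view present, fits the empirical ROC of the StdDev score against
#' the reference labels (Youden-optimal cut-off, AUROC with Hanley-McNeil SE
#' and 95% CI) and screens each first-order predictor (`min`, `max`, `mean`,
#' `sd`) with a univariate logistic fit. Rows labeled `"unknown"` are
#' dropped; a view with a single class raises a calibration error.
#'
#' @param quant data frame from [quantify_images()] with `group_label`.
#' @return An object of class `qus_calibration`: per-view list of `roc` and
#'   `predictors`.
#' @export
calibrate_scores <- function(quant) {
  if (!all(c("view", "sd", "group_label") %in% names(quant))) {
    qus_stop("quantified table must have view, sd, group_label columns",
             "qus_schema_error")
  }
  quant <- quant[quant$group_label %in% c("pos", "neg"), , drop = FALSE]
  if (!nrow(quant)) {
    qus_stop("no labeled rows to calibrate on", "qus_calibration_error")
  }
  views <- intersect(c("transverse", "longitudinal"), unique(quant$view))
  res <- lapply(views, function(v) {
    d <- quant[quant$view == v, , drop = FALSE]
    roc <- roc_curve(d$sd, d$group_label)
    predictors <- c("min", "max", "mean", "sd")
    predictors <- predictors[predictors %in% names(d)]
    fits <- lapply(predictors, function(p) logistic_fit_univariate(d[[p]], d$group_label))
    names(fits) <- predictors
    list(roc = roc, predictors = fits)
  })
  names(res) <- views
  structure(list(views = res, n = nrow(quant)), class = "qus_calibration")
}

calibration_as_list <- function(calib) {
  stopifnot(inherits(calib, "qus_calibration"))
  lapply(calib$views, function(v) {
    roc <- v$roc
    list(
      auc = roc$auc, auc_se = roc$auc_se,
      ci95 = list(lo = roc$ci95[1], hi = roc$ci95[2]),
      cutoff = roc$best_cutoff, youden = roc$youden_j,
      sens = roc$sens_at_best, spec = roc$spec_at_best,
      n_pos = roc$n_pos, n_neg = roc$n_neg,
      predictors = lapply(v$predictors, function(f) {
        list(beta = f$beta, se = f$se, wald = f$wald, p = f$p,
             or = f$odds_ratio, converged = f$converged)
      })
    )
  })
}

#' Write a calibration result as JSON
#'
#' Sensitivity and specificity are written as proportions; percentage
#' formatting is left to the human-readable report.
#'
#' @param calib a [calibrate_scores()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
calibration_to_json <- function(calib, path) {
  jsonlite::write_json(calibration_as_list(calib), path,
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

#' Write the ROC points of a calibration as CSV
#'
#' @param calib a [calibrate_scores()] result.
#' @param path output CSV path; columns `view`, `threshold`, `fpr`, `tpr`.
#' @return `path`, invisibly.
#' @export
roc_points_to_csv <- function(calib, path) {
  stopifnot(inherits(calib, "qus_calibration"))
  pts <- do.call(rbind, lapply(names(calib$views), function(v) {
    cbind(view = v, calib$views[[v]]$roc$points)
  }))
  utils::write.csv(pts, path, row.names = FALSE)
  invisible(path)
}

#' Render a calibration as a Markdown report
#'
#' @param calib a [calibrate_scores()] result.
#' @return Character vector of Markdown lines.
#' @export
calibration_report <- function(calib) {
  stopifnot(inherits(calib, "qus_calibration"))
  lines <- c("# Quantitative echotexture calibration report", "",
             "## Cut-off accuracy (StdDev score)", "",
             "| View | AUROC ± SE | 95% CI | Cut-off | Youden J | Sensitivity (%) | Specificity (%) |",
             "|---|---|---|---|---|---|---|")
  for (v in names(calib$views)) {
    r <- calib$views[[v]]$roc
    lines <- c(lines, sprintf(
      "| %s ROI StdDev | %.3f ± %.3f | %.3f–%.3f | %.2f | %.2f | %.0f | %.0f |",
      v, r$auc, r$auc_se, r$ci95[1], r$ci95[2], r$best_cutoff, r$youden_j,
      100 * r$sens_at_best, 100 * r$spec_at_best))
  }
  lines <- c(lines, "", "## Univariate logistic screens", "",
             "| View | Predictor | β | SE | Wald | P | OR |",
             "|---|---|---|---|---|---|---|")
  for (v in names(calib$views)) {
    for (p in names(calib$views[[v]]$predictors)) {
      f <- calib$views[[v]]$predictors[[p]]
      lines <- c(lines, sprintf(
        "| %s | %s | %.3f | %.3f | %.3f | %s | %.3f |",
        v, p, f$beta, f$se, f$wald,
        if (f$p < 0.001) "<0.001" else sprintf("%.3f", f$p), f$odds_ratio))
    }
  }
  lines
}
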