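# Subject-table I/O and cohort exclusion accounting.

SUBJECT_MANDATORY_COLS <- c(
  "subject_id", "age", "sex", "weight_kg", "height_cm", "duration_wk",
  "tear_or_rupture", "prior_injection", "fracture_or_surgery", "reference_label"
)
SUBJECT_NUMERIC_COLS <- c(
  "age", "weight_kg", "height_cm", "duration_wk",
  "t_min", "t_max", "t_mean", "t_sd", "l_min", "l_max", "l_mean", "l_sd",
  "t_sheath_mm", "l_sheath_mm", "fluid_mm"
)
SUBJECT_FLAG_COLS <- c(
  "tear_or_rupture", "prior_injection", "fracture_or_surgery",
  "fluid_displaceable", "fluid_compressible", "color_flow"
)

parse_flag <- function(x, col, row) {
  out <- rep(NA, length(x))
  x <- trimws(tolower(as.character(x)))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  bad <- !is.na(x) & x != "" & x != "na" & is.na(out)
  if (any(bad)) {
    qus_stop(sprintf("row %d: column \"%s\" has non-boolean value \"%s\"",
                     row[which(bad)[1]], col, x[which(bad)[1]]),
             "qus_parse_error")
  }
  out
}

#' Read a subject table from CSV
#'
#' Expected header: `subject_id, age, sex, weight_kg, height_cm, duration_wk,
#' tear_or_rupture, prior_injection, fracture_or_surgery, reference_label`,
#' plus optional per-view ROI statistic columns
#' (`t_min, t_max, t_mean, t_sd, l_min, l_max, l_mean, l_sd`) and reference
#' criteria columns (`t_sheath_mm, l_sheath_mm, fluid_mm, fluid_displaceable,
#' fluid_compressible, color_flow`). Empty cells become `NA`
#' (`reference_label`: `"unknown"`). Malformed cells raise a parse error
#' naming the offending row.
#'
#' @param csv_path path to the CSV file.
#' @return A data frame, one row per subject.
#' @export
read_subject_table <- function(csv_path) {
  if (!file.exists(csv_path)) {
    qus_stop(sprintf("subject table not found: %s", csv_path), "qus_schema_error")
  }
  raw <- utils::read.csv(csv_path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  missing_cols <- setdiff(SUBJECT_MANDATORY_COLS, names(raw))
  if (length(missing_cols)) {
    qus_stop(sprintf("subject table lacks mandatory column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             "qus_schema_error")
  }
  n <- nrow(raw)
  rows <- seq_len(n)
  out <- data.frame(subject_id = raw$subject_id, stringsAsFactors = FALSE)

  sex <- toupper(trimws(raw$sex))
  sex[sex == ""] <- NA
  bad <- !is.na(sex) & !sex %in% c("F", "M")
  if (any(bad)) {
    qus_stop(sprintf("row %d: column \"sex\" has invalid value \"%s\"",
                     rows[which(bad)[1]], raw$sex[which(bad)[1]]),
             "qus_parse_error")
  }
  out$sex <- sex

  for (col in intersect(SUBJECT_NUMERIC_COLS, names(raw))) {
    x <- trimws(raw[[col]])
    val <- suppressWarnings(as.numeric(x))
    bad <- x != "" & !toupper(x) %in% "NA" & is.na(val)
    if (any(bad)) {
      qus_stop(sprintf("row %d: column \"%s\" has non-numeric value \"%s\"",
                       rows[which(bad)[1]], col, x[which(bad)[1]]),
               "qus_parse_error")
    }
    neg <- !is.na(val) & val < 0
    if (any(neg)) {
      qus_stop(sprintf("row %d: column \"%s\" is negative (%s)",
                       rows[which(neg)[1]], col, x[which(neg)[1]]),
               "qus_parse_error")
    }
    out[[col]] <- val
  }

  for (col in intersect(SUBJECT_FLAG_COLS, names(raw))) {
    out[[col]] <- parse_flag(raw[[col]], col, rows)
  }

  lab <- tolower(trimws(raw$reference_label))
  lab[lab %in% c("", "na")] <- "unknown"
  bad <- !lab %in% c("pos", "neg", "unknown")
  if (any(bad)) {
    qus_stop(sprintf("row %d: column \"reference_label\" has invalid value \"%s\"",
                     rows[which(bad)[1]], raw$reference_label[which(bad)[1]]),
             "qus_parse_error")
  }
  out$reference_label <- lab
  out
}

#' Write a subject table to CSV
#'
#' @param subjects data frame as returned by [read_subject_table()].
#' @param csv_path output path.
#' @return `csv_path`, invisibly.
#' @export
write_subject_table <- function(subjects, csv_path) {
  utils::write.csv(subjects, csv_path, row.names = FALSE, na = "")
  invisible(csv_path)
}

#' Apply cohort exclusion flags
#'
#' A subject is kept iff all exclusion flags are false. A subject with several
#' flags set is counted once, under the first matching reason in the fixed
#' order tear/rupture > prior injection > fracture/surgery. A missing flag
#' column is treated as all-false (and noted via `message()`).
#'
#' @param subjects data frame with logical columns `tear_or_rupture`,
#'   `prior_injection`, `fracture_or_surgery` (`NA` treated as `FALSE`).
#' @return list with `kept` (the retained rows) and `report` (a data frame of
#'   per-reason exclusion counts in the order above).
#' @export
apply_exclusions <- function(subjects) {
  reasons <- c("tear_or_rupture", "prior_injection", "fracture_or_surgery")
  for (col in reasons) {
    if (is.null(subjects[[col]])) {
      message(sprintf("apply_exclusions: flag column \"%s\" missing, treated as FALSE", col))
      subjects[[col]] <- FALSE
    }
  }
  flags <- vapply(reasons, function(col) {
    f <- subjects[[col]]
    f[is.na(f)] <- FALSE
    as.logical(f)
  }, logical(nrow(subjects)))
  flags <- matrix(flags, nrow = nrow(subjects),
                  dimnames = list(NULL, reasons))
  first_reason <- apply(flags, 1L, function(f) {
    i <- which(f)
    if (length(i)) reasons[min(i)] else NA_character_
  })
  keep <- is.na(first_reason)
  counts <- vapply(reasons, function(r) sum(first_reason == r, na.rm = TRUE),
                   integer(1))
  list(
    kept = subjects[keep, , drop = FALSE],
    report = data.frame(reason = reasons, n_excluded = unname(counts),
                        stringsAsFactors = FALSE)
  )
}
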