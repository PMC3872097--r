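# End-to-end study generator: images + sidecars + subject table + manifest.

# Group-level draws for demographics and per-view ROI mean targets, anchored
# on the published cohort table. (The positive-group longitudinal mean SD is
# printed implausibly as 99.2 in the source table; 25 is used, in line with
# the other three mean SDs.)
STUDY_DEMOGRAPHICS <- list(
  pos = list(age = c(53.8, 11.9), weight = c(59.1, 11.2),
             height = c(160.7, 7.4), duration = c(11.7, 9.4), p_male = 0.397),
  neg = list(age = c(52.2, 14.3), weight = c(60.0, 12.3),
             height = c(161.6, 8.4), duration = c(10.4, 9.6), p_male = 0.410)
)
STUDY_MEAN_TARGETS <- list(
  pos = list(transverse = c(112.4, 24.9), longitudinal = c(102.9, 25.0)),
  neg = list(transverse = c(111.8, 28.6), longitudinal = c(94.2, 25.1))
)

draw_criteria_fields <- function(label, sex, equivocal_rate = 0.05) {
  thr_t <- SHEATH_THRESHOLDS$transverse[[sex]]
  thr_l <- SHEATH_THRESHOLDS$longitudinal[[sex]]
  effective_pos <- if (stats::runif(1) < equivocal_rate) label != "pos" else label == "pos"
  if (effective_pos) {
    list(
      t_sheath_mm = thr_t + stats::runif(1, 0.1, 1.5),
      l_sheath_mm = max(0, thr_l + stats::runif(1, -0.5, 1.2)),
      fluid_mm = abs(stats::rnorm(1, 2.5, 1.2)),
      fluid_displaceable = stats::runif(1) < 0.8,
      fluid_compressible = stats::runif(1) < 0.8,
      color_flow = TRUE
    )
  } else {
    list(
      t_sheath_mm = max(0, thr_t - stats::runif(1, 0.3, 1.8)),
      l_sheath_mm = max(0, thr_l - stats::runif(1, 0.2, 1.0)),
      fluid_mm = stats::runif(1, 0, 2.8),
      fluid_displaceable = stats::runif(1) < 0.5,
      fluid_compressible = stats::runif(1) < 0.5,
      color_flow = stats::runif(1) < 0.15
    )
  }
}

#' Simulate a complete diagnostic study on disk
#'
#' Writes, under `out_dir`: one PNG + JSON sidecar per subject and view
#' (the sidecar stores the calibrated ROI), a subject CSV in the
#' [read_subject_table()] schema, and a `manifest.json` recording every
#' parameter, the seed and every file written. Per-subject StdDev targets are
#' drawn by [simulate_scores()]; per-subject mean targets and demographics
#' come from the published group distributions. Reference criteria fields are
#' drawn so the rule-based [criteria_label()] agrees with the intended group
#' label for ~95% of subjects, the remainder emulating equivocal cases.
#' A single root seed drives everything; per-image streams are derived by
#' hashing `(subject_id, view)`.
#'
#' @param cohort a [cohort_params()].
#' @param texture a [texture_params()].
#' @param out_dir output directory (created if needed).
#' @param seed root RNG seed.
#' @param spacing_mm,size_px image geometry passed to
#'   [simulate_tendon_image()].
#' @return The manifest, invisibly.
#' @export
simulate_study <- function(cohort = cohort_params(),
                           texture = texture_params(),
                           out_dir, seed = 1L,
                           spacing_mm = c(0.02, 0.02),
                           size_px = c(120, 120)) {
  stopifnot(inherits(cohort, "qus_cohort_params"),
            inherits(texture, "qus_texture_params"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    qus_stop(sprintf("cannot create output directory: %s", out_dir),
             "qus_param_error")
  }
  cohort$seed <- derive_seed(seed, "scores")
  scores <- simulate_scores(cohort)
  n <- nrow(scores)

  # feasibility floors for the moment matching (see moment_match_mixture)
  floor_t <- texture$speckle_sd + 0.25
  floor_l <- sqrt(texture$speckle_sd^2 + texture$band_amplitude^2 / 2) + 0.25

  subjects <- withr::with_seed(derive_seed(seed, "subjects"), {
    out <- scores
    out$sex <- NA_character_
    out$age <- out$weight_kg <- out$height_cm <- out$duration_wk <- NA_real_
    out$t_mean_target <- out$l_mean_target <- NA_real_
    for (i in seq_len(n)) {
      g <- STUDY_DEMOGRAPHICS[[out$reference_label[i]]]
      mt <- STUDY_MEAN_TARGETS[[out$reference_label[i]]]
      out$sex[i] <- if (stats::runif(1) < g$p_male) "M" else "F"
      out$age[i] <- max(18, stats::rnorm(1, g$age[1], g$age[2]))
      out$weight_kg[i] <- max(30, stats::rnorm(1, g$weight[1], g$weight[2]))
      out$height_cm[i] <- max(120, stats::rnorm(1, g$height[1], g$height[2]))
      out$duration_wk[i] <- max(0.5, stats::rnorm(1, g$duration[1], g$duration[2]))
      out$t_mean_target[i] <- min(185, max(60, stats::rnorm(1, mt$transverse[1], mt$transverse[2])))
      out$l_mean_target[i] <- min(185, max(60, stats::rnorm(1, mt$longitudinal[1], mt$longitudinal[2])))
    }
    out
  })
  subjects$t_sd <- pmax(subjects$t_sd, floor_t)
  subjects$l_sd <- pmax(subjects$l_sd, floor_l)

  crit <- withr::with_seed(derive_seed(seed, "criteria"), {
    rows <- lapply(seq_len(n), function(i) {
      draw_criteria_fields(subjects$reference_label[i], subjects$sex[i])
    })
    do.call(rbind, lapply(rows, as.data.frame))
  })
  subjects <- cbind(subjects, crit)

  image_files <- character(0)
  for (i in seq_len(n)) {
    for (view in c("transverse", "longitudinal")) {
      target <- if (view == "transverse") {
        c(subjects$t_mean_target[i], subjects$t_sd[i])
      } else {
        c(subjects$l_mean_target[i], subjects$l_sd[i])
      }
      sim <- simulate_tendon_image(
        view = view, condition = subjects$reference_label[i], target = target,
        texture = texture, spacing_mm = spacing_mm, size_px = size_px,
        seed = derive_seed(seed, paste(subjects$subject_id[i], view)),
        subject_id = subjects$subject_id[i]
      )
      sim$image$sex <- subjects$sex[i]
      fn <- sprintf("%s_%s.png", subjects$subject_id[i], view)
      write_image(sim$image, file.path(out_dir, fn), roi = sim$roi)
      image_files <- c(image_files, fn)
    }
  }

  table_cols <- c("subject_id", "age", "sex", "weight_kg", "height_cm",
                  "duration_wk", "tear_or_rupture", "prior_injection",
                  "fracture_or_surgery", "reference_label",
                  "t_sheath_mm", "l_sheath_mm", "fluid_mm",
                  "fluid_displaceable", "fluid_compressible", "color_flow")
  subjects$tear_or_rupture <- FALSE
  subjects$prior_injection <- FALSE
  subjects$fracture_or_surgery <- FALSE
  write_subject_table(subjects[, table_cols], file.path(out_dir, "subjects.csv"))

  manifest <- list(
    seed = seed,
    cohort = unclass(cohort),
    texture = unclass(texture),
    spacing_mm = spacing_mm,
    size_px = size_px,
    files = list(subjects = "subjects.csv", images = image_files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(manifest)
}
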