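# Synthetic cohorts and B-mode-like tendon images. The generator's job is to
# realize the statistical structure the diagnostic method consumes --
# per-subject ROI-StdDev distributions per group and view, and images whose
# fixed-area ROI statistics reproduce those distributions -- not to model
# ultrasound physics. Speckle is a Gaussian first-two-moments proxy;
# heterogeneity comes from hypoechoic fluid blobs and hyperechoic streaks
# whose fractions are solved in closed form from the target moments.

#' Cohort parameters for score simulation
#'
#' Defaults are the published group distributions of the ROI StdDev statistic
#' (mean, SD) per view and the study's group sizes (136 tendinitis-positive,
#' 200 negative).
#'
#' @param transverse_pos,transverse_neg,longitudinal_pos,longitudinal_neg
#'   numeric `(mean, sd)` of the StdDev statistic for each group and view.
#' @param n_pos,n_neg group sizes.
#' @param seed RNG seed.
#' @return An object of class `qus_cohort_params`.
#' @export
cohort_params <- function(transverse_pos = c(30.1, 6.8),
                          transverse_neg = c(21.9, 4.1),
                          longitudinal_pos = c(26.5, 6.0),
                          longitudinal_neg = c(18.7, 4.7),
                          n_pos = 136, n_neg = 200, seed = 1L) {
  groups <- list(transverse_pos = transverse_pos, transverse_neg = transverse_neg,
                 longitudinal_pos = longitudinal_pos,
                 longitudinal_neg = longitudinal_neg)
  for (nm in names(groups)) {
    g <- groups[[nm]]
    if (!is.numeric(g) || length(g) != 2L || !all(is.finite(g)) || g[2] <= 0) {
      qus_stop(sprintf("`%s` must be (mean, sd) with sd > 0", nm),
               "qus_param_error")
    }
  }
  if (n_pos < 1 || n_neg < 1) {
    qus_stop("group sizes must be at least 1", "qus_param_error")
  }
  structure(c(groups, list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                           seed = as.integer(seed))),
            class = "qus_cohort_params")
}

#' Texture parameters for image simulation
#'
#' Component gray levels are anchored on the published cohort table: baseline
#' tendon echogenicity near the transverse ROI mean (112), hypoechoic fluid
#' near the positive-group minimum (45), hyperechoic condensed fibers near
#' the positive-group maximum (200). All three components share the speckle
#' SD; the longitudinal view additionally carries sinusoidal fibrillar bands.
#'
#' @param baseline_mean baseline tendon gray level.
#' @param speckle_sd per-component speckle standard deviation.
#' @param band_amplitude,band_period_mm fibrillar stripe modulation
#'   (longitudinal view only).
#' @param fluid_mean,hyper_mean component gray levels.
#' @param fluid_fraction,hyper_fraction default within-ROI fractions used when
#'   no moment matching is requested; both default 0.
#' @return An object of class `qus_texture_params`.
#' @export
texture_params <- function(baseline_mean = 112, speckle_sd = 10,
                           band_amplitude = 8, band_period_mm = 0.6,
                           fluid_mean = 45, hyper_mean = 200,
                           fluid_fraction = 0, hyper_fraction = 0) {
  for (v in c(baseline_mean, fluid_mean, hyper_mean)) {
    if (!is_scalar_number(v) || v < 0 || v > 255) {
      qus_stop("component gray levels must lie in [0, 255]", "qus_param_error")
    }
  }
  if (!is_scalar_number(speckle_sd) || speckle_sd <= 0) {
    qus_stop("`speckle_sd` must be positive", "qus_param_error")
  }
  if (band_amplitude < 0 || band_period_mm <= 0) {
    qus_stop("band modulation needs amplitude >= 0 and period > 0",
             "qus_param_error")
  }
  if (fluid_fraction < 0 || hyper_fraction < 0 ||
      fluid_fraction + hyper_fraction > 1) {
    qus_stop("fractions must be >= 0 with fluid + hyper <= 1", "qus_param_error")
  }
  structure(
    list(baseline_mean = baseline_mean, speckle_sd = speckle_sd,
         band_amplitude = band_amplitude, band_period_mm = band_period_mm,
         fluid_mean = fluid_mean, hyper_mean = hyper_mean,
         fluid_fraction = fluid_fraction, hyper_fraction = hyper_fraction),
    class = "qus_texture_params"
  )
}

rnorm_trunc <- function(n, mean, sd, lo = 0, hi = 255) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Simulate per-subject ROI StdDev scores
#'
#' Draws each subject's per-view StdDev score from the group normal
#' distributions of [cohort_params()], truncated to `[0, 255]` by redraw.
#' Deterministic given the seed.
#'
#' @param params a [cohort_params()].
#' @return Data frame with `subject_id`, `reference_label`, `t_sd`, `l_sd`.
#' @export
simulate_scores <- function(params = cohort_params()) {
  stopifnot(inherits(params, "qus_cohort_params"))
  withr::with_seed(params$seed, {
    n <- params$n_pos + params$n_neg
    lab <- rep(c("pos", "neg"), c(params$n_pos, params$n_neg))
    t_sd <- c(
      rnorm_trunc(params$n_pos, params$transverse_pos[1], params$transverse_pos[2]),
      rnorm_trunc(params$n_neg, params$transverse_neg[1], params$transverse_neg[2])
    )
    l_sd <- c(
      rnorm_trunc(params$n_pos, params$longitudinal_pos[1], params$longitudinal_pos[2]),
      rnorm_trunc(params$n_neg, params$longitudinal_neg[1], params$longitudinal_neg[2])
    )
    data.frame(subject_id = sprintf("S%04d", seq_len(n)),
               reference_label = lab, t_sd = t_sd, l_sd = l_sd,
               stringsAsFactors = FALSE)
  })
}

#' Solve mixture fractions that hit target ROI moments
#'
#' The ROI is a three-component per-pixel mixture (baseline speckle, fluid,
#' hyperechoic) with known component means and a shared component SD. Given a
#' target ROI mean and SD, the two mixture-moment equations -- mixture mean
#' `sum(f_i mu_i)` and mixture second moment `sum(f_i (sigma_i^2 + mu_i^2))`
#' with `f_base = 1 - f_fluid - f_hyper` -- are linear in the two unknown
#' fractions and solved in closed form. An unreachable target (a fraction
#' below 0 or a fraction sum above 1) raises an infeasibility error naming
#' the violated bound.
#'
#' @param target_mean,target_sd target ROI moments.
#' @param texture a [texture_params()]; supplies component means and the
#'   speckle SD.
#' @param baseline_sd effective SD of the baseline component; defaults to the
#'   speckle SD, and is raised to `sqrt(speckle_sd^2 + band_amplitude^2/2)`
#'   by the image simulator for the band-modulated longitudinal view.
#' @return Named list `fluid_fraction`, `hyper_fraction`.
#' @export
moment_match_mixture <- function(target_mean, target_sd,
                                 texture = texture_params(),
                                 baseline_sd = texture$speckle_sd) {
  stopifnot(inherits(texture, "qus_texture_params"))
  if (!is_scalar_number(target_mean) || !is_scalar_number(target_sd) ||
      target_sd < 0) {
    qus_stop("targets must be finite with target_sd >= 0", "qus_param_error")
  }
  mu_b <- texture$baseline_mean
  mu_f <- texture$fluid_mean
  mu_h <- texture$hyper_mean
  s2 <- texture$speckle_sd^2
  m2_b <- baseline_sd^2 + mu_b^2
  m2_f <- s2 + mu_f^2
  m2_h <- s2 + mu_h^2
  target_m2 <- target_sd^2 + target_mean^2
  A <- rbind(c(mu_f - mu_b, mu_h - mu_b),
             c(m2_f - m2_b, m2_h - m2_b))
  b <- c(target_mean - mu_b, target_m2 - m2_b)
  if (abs(det(A)) < 1e-9) {
    qus_stop("degenerate component configuration: moment system is singular",
             "qus_infeasible_error")
  }
  f <- drop(solve(A, b))
  f[abs(f) < 1e-12] <- 0
  if (f[1] < 0) {
    qus_stop(sprintf("infeasible target: fluid_fraction = %.4g < 0", f[1]),
             "qus_infeasible_error")
  }
  if (f[2] < 0) {
    qus_stop(sprintf("infeasible target: hyper_fraction = %.4g < 0", f[2]),
             "qus_infeasible_error")
  }
  if (sum(f) > 1 + 1e-12) {
    qus_stop(sprintf("infeasible target: fraction sum = %.4g > 1", sum(f)),
             "qus_infeasible_error")
  }
  list(fluid_fraction = f[1], hyper_fraction = f[2])
}

#' Simulate a B-mode-like tendon image with calibrated ROI statistics
#'
#' Builds a speckled image whose centered 2 mm^2 ROI (circle for the
#' transverse view, square for the longitudinal) realizes the target
#' `(mean, sd)` in expectation. Inside the ROI, pixels come from the
#' moment-matched three-component mixture: baseline Gaussian speckle anchored
#' at the target mean (with sinusoidal fibrillar bands on the longitudinal
#' view), a hypoechoic fluid component grouped into a contiguous blob at the
#' ROI margin, and a hyperechoic component laid down as a streak -- spatial
#' grouping rather than salt-and-pepper, so the picture resembles sheath
#' fluid abutting condensed fibers. Outside the ROI, baseline texture only.
#' Values are rounded and clipped to `[0, 255]`. Deterministic given the
#' seed.
#'
#' @param view `"transverse"` or `"longitudinal"`.
#' @param condition `"pos"` or `"neg"`; recorded as the image's group label.
#' @param target numeric `(mean, sd)` for the ROI statistics.
#' @param texture a [texture_params()].
#' @param spacing_mm `(row, col)` mm per pixel.
#' @param size_px image size `(rows, cols)`.
#' @param seed RNG seed.
#' @param subject_id recorded in the image metadata.
#' @param fractions optional `list(fluid_fraction, hyper_fraction)` to force
#'   instead of moment matching (e.g. both 0 for a pure-speckle baseline).
#' @return List with `image` (a [image_record()]), `roi` (the [roi_spec()]
#'   of the calibrated region) and `fractions` (the mixture fractions used).
#' @export
simulate_tendon_image <- function(view, condition = c("pos", "neg"), target,
                                  texture = texture_params(),
                                  spacing_mm = c(0.02, 0.02),
                                  size_px = c(120, 120), seed = 1L,
                                  subject_id = "synthetic",
                                  fractions = NULL) {
  view <- match_view(view)
  condition <- match.arg(condition)
  stopifnot(inherits(texture, "qus_texture_params"))
  if (!is.numeric(target) || length(target) != 2L || target[2] < 0) {
    qus_stop("`target` must be (mean, sd) with sd >= 0", "qus_param_error")
  }
  nr <- size_px[1]
  nc <- size_px[2]
  sp <- spacing_mm

  # anchor the speckle component at the target echogenicity so the two
  # solved fractions carry all the heterogeneity
  tex <- texture
  tex$baseline_mean <- target[1]
  base_sd_eff <- if (view == "longitudinal") {
    sqrt(texture$speckle_sd^2 + texture$band_amplitude^2 / 2)
  } else {
    texture$speckle_sd
  }
  fr <- fractions %||%
    moment_match_mixture(target[1], target[2], tex, baseline_sd = base_sd_eff)

  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  spec <- roi_spec(if (view == "transverse") "circle" else "square",
                   center = ctr, area_mm2 = 2)
  shell <- image_record(matrix(0L, nr, nc), sp, view,
                        subject_id = subject_id, group_label = condition)
  mask <- suppressWarnings(roi_pixel_mask(spec, shell))

  px <- withr::with_seed(seed, {
    field <- matrix(stats::rnorm(nr * nc, target[1], texture$speckle_sd), nr, nc)
    if (view == "longitudinal" && texture$band_amplitude > 0) {
      band <- texture$band_amplitude *
        sin(2 * pi * ((seq_len(nr) - 1) * sp[1]) / texture$band_period_mm)
      field <- field + band  # recycled down columns: stripes across depth
    }
    co <- mask$coords
    n <- nrow(co)
    n_f <- round(fr$fluid_fraction * n)
    n_h <- min(round(fr$hyper_fraction * n), n - n_f)
    if (n_f > 0) {
      theta <- stats::runif(1, 0, 2 * pi)
      r_mm <- sqrt(spec$area_mm2 / pi)
      anchor <- ctr + c(cos(theta) * r_mm / sp[1], sin(theta) * r_mm / sp[2])
      d2 <- (co[, 1] - anchor[1])^2 + (co[, 2] - anchor[2])^2
      fluid_idx <- order(d2)[seq_len(n_f)]
    } else {
      fluid_idx <- integer()
    }
    remaining <- setdiff(seq_len(n), fluid_idx)
    if (n_h > 0) {
      a_row <- co[remaining[sample.int(length(remaining), 1L)], 1]
      ord <- remaining[order(abs(co[remaining, 1] - a_row),
                             abs(co[remaining, 2] - ctr[2]))]
      hyper_idx <- ord[seq_len(n_h)]
    } else {
      hyper_idx <- integer()
    }
    if (length(fluid_idx)) {
      field[co[fluid_idx, , drop = FALSE]] <-
        stats::rnorm(length(fluid_idx), texture$fluid_mean, texture$speckle_sd)
    }
    if (length(hyper_idx)) {
      field[co[hyper_idx, , drop = FALSE]] <-
        stats::rnorm(length(hyper_idx), texture$hyper_mean, texture$speckle_sd)
    }
    matrix(as.integer(pmin(255, pmax(0, round(field)))), nr, nc)
  })

  img <- image_record(px, sp, view, subject_id = subject_id,
                      group_label = condition)
  list(image = img, roi = spec, fractions = fr)
}
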