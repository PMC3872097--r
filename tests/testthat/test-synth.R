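# Synthetic cohorts and images: determinism, moment matching, directionality.

test_that("simulated scores are deterministic and hit the group moments", {
  p <- cohort_params(n_pos = 10000, n_neg = 10000, seed = 77)
  s1 <- simulate_scores(p)
  s2 <- simulate_scores(p)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 20000L)
  # group sample means within 3 standard errors of the configured targets
  for (grp in c("pos", "neg")) {
    mu <- if (grp == "pos") c(30.1, 26.5) else c(21.9, 18.7)
    sd_ <- if (grp == "pos") c(6.8, 6.0) else c(4.1, 4.7)
    sub <- s1[s1$reference_label == grp, ]
    expect_lt(abs(mean(sub$t_sd) - mu[1]), 3 * sd_[1] / sqrt(1e4))
    expect_lt(abs(mean(sub$l_sd) - mu[2]), 3 * sd_[2] / sqrt(1e4))
  }
  expect_true(all(s1$t_sd >= 0 & s1$t_sd <= 255))
})

test_that("vanishing within-group spread gives a perfect classifier", {
  p <- cohort_params(transverse_pos = c(30.1, 1e-9),
                     transverse_neg = c(21.9, 1e-9),
                     n_pos = 50, n_neg = 50, seed = 5)
  s <- simulate_scores(p)
  ss <- sens_spec_at(s$t_sd, s$reference_label, 26)
  expect_equal(ss$sens, 1)
  expect_equal(ss$spec, 1)
})

test_that("moment matching is exact, identity at baseline, and bounded", {
  tex <- texture_params()
  # target equal to the baseline component: no admixture needed
  id <- moment_match_mixture(112, tex$speckle_sd, tex)
  expect_equal(id$fluid_fraction, 0)
  expect_equal(id$hyper_fraction, 0)

  # algebraic self-consistency: plug fractions back into the moment equations
  fr <- moment_match_mixture(112.4, 30.1, tex)
  f_base <- 1 - fr$fluid_fraction - fr$hyper_fraction
  mus <- c(tex$baseline_mean, tex$fluid_mean, tex$hyper_mean)
  fs <- c(f_base, fr$fluid_fraction, fr$hyper_fraction)
  mix_mean <- sum(fs * mus)
  mix_m2 <- sum(fs * (tex$speckle_sd^2 + mus^2))
  expect_equal(mix_mean, 112.4, tolerance = 1e-9)
  expect_equal(sqrt(mix_m2 - mix_mean^2), 30.1, tolerance = 1e-9)

  # a target SD below the speckle floor is infeasible and says so
  expect_error(moment_match_mixture(112, tex$speckle_sd / 2, tex),
               class = "qus_infeasible_error")
  # a mean beyond both extreme components is infeasible
  expect_error(moment_match_mixture(240, 30, tex),
               class = "qus_infeasible_error")
})

test_that("generated images realize their target ROI moments (median over seeds)", {
  targets <- list(
    list(view = "transverse", cond = "neg", t = c(111.8, 21.9)),
    list(view = "transverse", cond = "pos", t = c(112.4, 30.1)),
    list(view = "longitudinal", cond = "neg", t = c(94.2, 18.7)),
    list(view = "longitudinal", cond = "pos", t = c(102.9, 26.5))
  )
  for (tg in targets) {
    stats <- vapply(1:50, function(s) {
      sim <- simulate_tendon_image(tg$view, tg$cond, tg$t, seed = s)
      st <- roi_stats(sim$image, roi_pixel_mask(sim$roi, sim$image))
      c(st$mean, st$stddev)
    }, numeric(2))
    expect_lt(abs(median(stats[1, ]) - tg$t[1]), 1.0)   # mean within +/-1.0
    expect_lt(abs(median(stats[2, ]) - tg$t[2]), 1.5)   # StdDev within +/-1.5
    expect_lt(abs(median(stats[2, ]) - tg$t[2]) / tg$t[2], 0.05)
  }
})

test_that("tendinitis images show the max-up/min-down directionality", {
  per_condition <- function(cond, target) {
    vapply(1:30, function(s) {
      sim <- simulate_tendon_image("transverse", cond, target, seed = 100 + s)
      st <- roi_stats(sim$image, roi_pixel_mask(sim$roi, sim$image))
      c(st$min, st$max)
    }, numeric(2))
  }
  pos <- per_condition("pos", c(112.4, 30.1))
  neg <- per_condition("neg", c(111.8, 21.9))
  expect_gt(median(pos[2, ]), median(neg[2, ]))  # max rises with tendinitis
  expect_lt(median(pos[1, ]), median(neg[1, ]))  # min falls with tendinitis
})

test_that("forcing zero fractions leaves pure speckle at the baseline SD", {
  tex <- texture_params()
  sim <- simulate_tendon_image("transverse", "neg", c(112, tex$speckle_sd),
                               texture = tex, seed = 9,
                               fractions = list(fluid_fraction = 0,
                                                hyper_fraction = 0))
  st <- roi_stats(sim$image, roi_pixel_mask(sim$roi, sim$image))
  expect_lt(abs(st$stddev - tex$speckle_sd), 0.5)
  expect_lt(abs(st$mean - 112), 1.0)
})

test_that("increasing the fluid fraction inflates SD and drags the minimum down", {
  grid <- c(0, 0.05, 0.10, 0.15)
  med <- vapply(grid, function(f) {
    res <- vapply(1:20, function(s) {
      sim <- simulate_tendon_image("transverse", "pos", c(112, 15), seed = 200 + s,
                                   fractions = list(fluid_fraction = f,
                                                    hyper_fraction = 0))
      st <- roi_stats(sim$image, roi_pixel_mask(sim$roi, sim$image))
      c(st$stddev, st$min)
    }, numeric(2))
    c(median(res[1, ]), median(res[2, ]))
  }, numeric(2))
  expect_true(all(diff(med[1, ]) > 0))
  expect_true(all(diff(med[2, ]) <= 0))
})

test_that("generated images satisfy the container invariants at default spacing", {
  for (view in c("transverse", "longitudinal")) {
    sim <- simulate_tendon_image(view, "pos",
                                 if (view == "transverse") c(112.4, 30.1)
                                 else c(102.9, 26.5), seed = 17)
    px <- sim$image$pixels
    expect_true(all(px >= 0 & px <= 255))
    expect_true(is.integer(px))
    mask <- roi_pixel_mask(sim$roi, sim$image)
    expect_gt(mask$n_pixels, 2000)
    expect_length(validate_roi(mask), 0L)
  }
})

test_that("a small study writes the expected files, deterministically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cohort <- cohort_params(n_pos = 5, n_neg = 5)
  m1 <- simulate_study(cohort, out_dir = dir1, seed = 42)
  m2 <- simulate_study(cohort, out_dir = dir2, seed = 42)

  expect_length(m1$files$images, 20L)  # 2 views x 10 subjects
  expect_true(file.exists(file.path(dir1, "subjects.csv")))
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  expect_length(list.files(dir1, pattern = "\\.png$"), 20L)

  # byte-identical outputs from the same seed
  for (f in c(m1$files$images, "subjects.csv", "manifest.json")) {
    expect_identical(readBin(file.path(dir1, f), "raw", file.size(file.path(dir1, f))),
                     readBin(file.path(dir2, f), "raw", file.size(file.path(dir2, f))),
                     label = f)
  }
})

test_that("study criteria fields mostly reproduce the intended labels", {
  dir <- withr::local_tempdir()
  simulate_study(cohort_params(n_pos = 40, n_neg = 40), out_dir = dir, seed = 7)
  subjects <- read_subject_table(file.path(dir, "subjects.csv"))
  relabeled <- vapply(seq_len(nrow(subjects)), function(i) {
    criteria_label(sheath_measurements(
      transverse_sheath_mm = subjects$t_sheath_mm[i],
      longitudinal_sheath_mm = subjects$l_sheath_mm[i],
      fluid_depth_mm = subjects$fluid_mm[i],
      fluid_displaceable = subjects$fluid_displaceable[i],
      fluid_compressible = subjects$fluid_compressible[i],
      color_flow_increased = subjects$color_flow[i],
      sex = subjects$sex[i]
    ))
  }, character(1))
  agreement <- mean(relabeled == subjects$reference_label)
  # designed agreement 95%; allow binomial noise at n = 80
  expect_gte(agreement, 0.85)
  expect_lte(agreement, 1.0)
})
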