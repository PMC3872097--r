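# Independent oracles: deliberately naive implementations (loops, exhaustive
# scans, closed forms) against which the package's vectorized code is tested.

# Brute-force count of lattice pixel centers within a closed disk.
oracle_circle_pixels <- function(center, radius_mm, spacing, nr, nc) {
  hits <- matrix(numeric(0), ncol = 2)
  for (r in seq_len(nr)) {
    for (cl in seq_len(nc)) {
      d <- sqrt(((r - center[1]) * spacing[1])^2 +
                  ((cl - center[2]) * spacing[2])^2)
      if (d <= radius_mm) hits <- rbind(hits, c(r, cl))
    }
  }
  hits
}

# Loop-based first-order statistics with the population SD convention.
oracle_roi_stats <- function(px) {
  n <- length(px)
  s <- 0
  for (v in px) s <- s + v
  m <- s / n
  ss <- 0
  for (v in px) ss <- ss + (v - m)^2
  list(min = min(px), max = max(px), mean = m, stddev = sqrt(ss / n))
}

# Exhaustive threshold scan for the best Youden index (strict > positivity).
oracle_best_j <- function(scores, labels) {
  pos <- labels == "pos"
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1, u)  # include observed scores for good measure
  best <- -Inf
  for (thr in cand) {
    j <- mean(scores[pos] > thr) + mean(scores[!pos] <= thr) - 1
    if (j > best) best <- j
  }
  best
}

# Closed-form binormal AUROC.
binormal_auc <- function(mu_pos, sd_pos, mu_neg, sd_neg) {
  pnorm((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))
}

# Density-equality Youden-optimal threshold for two normals (the root
# between the means of the quadratic phi1(x)/s1 = phi0(x)/s0).
binormal_youden_cutoff <- function(mu_pos, sd_pos, mu_neg, sd_neg) {
  a <- 1 / sd_neg^2 - 1 / sd_pos^2
  b <- -2 * (mu_neg / sd_neg^2 - mu_pos / sd_pos^2)
  cc <- mu_neg^2 / sd_neg^2 - mu_pos^2 / sd_pos^2 - 2 * log(sd_pos / sd_neg)
  if (abs(a) < 1e-12) return(-cc / b)
  roots <- (-b + c(-1, 1) * sqrt(b^2 - 4 * a * cc)) / (2 * a)
  roots[roots > min(mu_neg, mu_pos) & roots < max(mu_neg, mu_pos)][1]
}

# Random small two-class score instance (sometimes tied) for property tests.
random_instance <- function(n_max = 50) {
  n_pos <- sample(2:(n_max / 2), 1)
  n_neg <- sample(2:(n_max / 2), 1)
  scores <- c(rnorm(n_pos, 1), rnorm(n_neg))
  if (runif(1) < 0.3) scores <- round(scores)  # force ties sometimes
  list(scores = scores, labels = rep(c("pos", "neg"), c(n_pos, n_neg)))
}

# Flat test image with every pixel at `value`.
uniform_image <- function(value = 128L, n = 64L, spacing = c(0.02, 0.02),
                          view = "transverse") {
  image_record(matrix(as.integer(value), n, n), spacing, view)
}

# A tiny image holding arbitrary pixel values with a mask covering them all.
image_with_pixels <- function(values, view = "transverse") {
  n <- ceiling(sqrt(length(values)))
  px <- matrix(0L, n, n)
  px[seq_along(values)] <- as.integer(values)
  img <- image_record(px, c(0.02, 0.02), view)
  coords <- cbind(row = ((seq_along(values) - 1) %% n) + 1,
                  col = ((seq_along(values) - 1) %/% n) + 1)
  storage.mode(coords) <- "integer"
  mask <- structure(list(coords = coords, n_pixels = nrow(coords),
                         achieved_area_mm2 = nrow(coords) * 0.02 * 0.02,
                         spacing_mm = c(0.02, 0.02)),
                    class = "qus_mask")
  list(image = img, mask = mask)
}

# Roster emulating the study's enrolment accounting: n subjects with
# disjoint exclusion flags in the stated order.
make_roster <- function(n = 379, n_tear = 17, n_inject = 16, n_fracture = 10) {
  df <- data.frame(
    subject_id = sprintf("P%03d", seq_len(n)),
    age = 50, sex = "F", weight_kg = 60, height_cm = 160, duration_wk = 10,
    tear_or_rupture = FALSE, prior_injection = FALSE,
    fracture_or_surgery = FALSE, reference_label = "unknown",
    stringsAsFactors = FALSE
  )
  df$tear_or_rupture[seq_len(n_tear)] <- TRUE
  df$prior_injection[n_tear + seq_len(n_inject)] <- TRUE
  df$fracture_or_surgery[n_tear + n_inject + seq_len(n_fracture)] <- TRUE
  df
}
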