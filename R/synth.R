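#' Synthetic vessel-network slab with known ground truth
#'
#' Renders a branching curvilinear vessel network as an en-face angiography
#' slab and returns the exact foreground mask, the summed centerline length
#' and the achieved vessel area fraction. Strokes are random smooth walks
#' seeded inside the foveal measurement disc, stamped with a circular brush
#' of per-stroke width; the generator keeps adding strokes (with adaptively
#' shortened lengths) until the mask's area fraction *inside the centered
#' foveal ROI* is within ±0.02 of the target — the region where perfusion
#' density is measured. Rendering adds a slight blur (optical point-spread)
#' and multiplicative speckle; a generous signal-to-background separation
#' emulates a good-quality OCTA acquisition.
#'
#' Identical specs (seed included) produce identical output; the session RNG
#' is untouched.
#'
#' @param side_px Image side in pixels (default 304, a 3 mm scan).
#' @param area_fraction Target vessel area fraction in `[0, 0.6)` inside the
#'   ROI; 0 gives a blank slab.
#' @param n_branches Number of primary strokes before adaptive top-up.
#' @param width_range_px Min/max stroke width in pixels.
#' @param seed Integer RNG seed.
#' @param scan_width_mm Physical field width (default 3).
#' @param roi_radius_mm Radius of the measurement disc used for the target
#'   fraction (default 1.5).
#' @return A list: `slab` ([en_face_slab()]), `truth_mask`
#'   (`octa_binary_mask`), `centerline_length_px`, `area_fraction`
#'   (achieved, inside the ROI), `n_strokes`.
#' @export
generate_vessel_slab <- function(side_px = 304, area_fraction = 0.2,
                                 n_branches = 10,
                                 width_range_px = c(3, 9), seed = 1,
                                 scan_width_mm = 3, roi_radius_mm = 1.5) {
  if (area_fraction < 0 || area_fraction >= 0.6) {
    abort("`area_fraction` must lie in [0, 0.6).")
  }
  if (length(width_range_px) != 2 || any(width_range_px < 1) ||
      width_range_px[1] > width_range_px[2]) {
    abort("`width_range_px` must be an increasing pair of widths >= 1.")
  }
  ctr <- (side_px - 1) / 2
  pitch <- scan_width_mm / side_px
  radius_px <- roi_radius_mm / pitch
  rows <- matrix(0:(side_px - 1), side_px, side_px)
  cols <- matrix(0:(side_px - 1), side_px, side_px, byrow = TRUE)
  roi_mask <- (rows - ctr)^2 + (cols - ctr)^2 <= radius_px^2
  n_roi <- sum(roi_mask)

  res <- with_local_seed(seed, {
    mask <- matrix(FALSE, side_px, side_px)
    total_len <- 0
    n_strokes <- 0L
    frac <- 0
    max_strokes <- max(n_branches, 50L) * 10L
    while (frac < area_fraction - 0.005 && n_strokes < max_strokes) {
      w <- runif(1, width_range_px[1], width_range_px[2])
      deficit_px <- (area_fraction - frac) * n_roi
      # primary strokes span the field; top-up strokes (and any stroke whose
      # full span would overshoot) are sized to the remaining deficit
      cap <- max(15L, min(3L * side_px, round(1.1 * deficit_px / w)))
      len <- if (n_strokes < n_branches) {
        min(round(runif(1, 0.8, 1.6) * side_px), cap)
      } else {
        cap
      }
      stroke <- draw_stroke(side_px, ctr, radius_px, len, w)
      mask <- mask | stroke$mask
      total_len <- total_len + stroke$length_px
      n_strokes <- n_strokes + 1L
      frac <- sum(mask & roi_mask) / n_roi
    }
    if (area_fraction > 0 && abs(frac - area_fraction) > 0.02) {
      abort(sprintf(
        "Could not reach area fraction %.3f (got %.3f after %d strokes); widen the stroke constraints.",
        area_fraction, frac, n_strokes))
    }
    base <- 0.10 + 0.75 * mask
    img <- gaussian_blur(base, 0.7)
    img <- img * (1 + 0.08 * matrix(rnorm(side_px^2), side_px, side_px))
    list(mask = mask, img = clamp01(img), total_len = total_len,
         frac = frac, n_strokes = n_strokes)
  })

  list(
    slab = en_face_slab(res$img, "SCP", scan_width_mm = scan_width_mm),
    truth_mask = new_binary_mask(res$mask,
                                 list(method = "synthetic-ground-truth")),
    centerline_length_px = res$total_len,
    area_fraction = res$frac,
    n_strokes = res$n_strokes
  )
}

# One smooth random-walk stroke stamped with a circular brush of width w.
# Returns its mask and centerline length in px (unit steps).
draw_stroke <- function(side_px, ctr, radius_px, len, w) {
  theta <- runif(1, 0, 2 * pi)
  r0 <- radius_px * sqrt(runif(1)) * 0.95
  a0 <- runif(1, 0, 2 * pi)
  pos <- c(ctr + r0 * sin(a0), ctr + r0 * cos(a0))
  turns <- rnorm(len, 0, 0.06)
  pr <- numeric(len + 1); pc <- numeric(len + 1)
  pr[1] <- pos[1]; pc[1] <- pos[2]
  n_pts <- 1L
  for (i in seq_len(len)) {
    theta <- theta + turns[i]
    pos <- pos + c(sin(theta), cos(theta))
    if (any(pos < 0) || any(pos > side_px - 1)) break
    n_pts <- n_pts + 1L
    pr[n_pts] <- pos[1]; pc[n_pts] <- pos[2]
  }
  pr <- pr[seq_len(n_pts)]; pc <- pc[seq_len(n_pts)]
  brush_r <- w / 2
  br <- ceiling(brush_r)
  offs <- expand.grid(dr = -br:br, dc = -br:br)
  offs <- offs[offs$dr^2 + offs$dc^2 <= brush_r^2, ]
  rr <- round(rep(pr, each = nrow(offs)) + offs$dr) + 1L
  cc <- round(rep(pc, each = nrow(offs)) + offs$dc) + 1L
  ok <- rr >= 1 & rr <= side_px & cc >= 1 & cc <= side_px
  mask <- matrix(FALSE, side_px, side_px)
  mask[cbind(rr[ok], cc[ok])] <- TRUE
  list(mask = mask, length_px = n_pts - 1L)
}

#' Synthetic choriocapillaris texture with known flow voids
#'
#' Emulates the granular choriocapillaris en-face signal: a fine-scale
#' smoothed-noise granule field with darker flow-void blobs occupying a
#' stated fraction of the image. The void mask is the exact ground truth
#' (blobs are a smooth random field thresholded at the requested quantile).
#' `contrast` scales how much darker voids are (1 = black voids).
#'
#' @param side_px Image side in pixels.
#' @param void_fraction Fraction of pixels inside flow voids, in (0, 0.9).
#' @param granule_scale_px Correlation length of the granules (> 0.5 px).
#' @param contrast Void darkening factor in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @param scan_width_mm Physical field width.
#' @return A list: `slab` (CC [en_face_slab()]), `void_mask` (logical
#'   matrix, `TRUE` inside voids), `void_fraction` (achieved).
#' @export
generate_cc_texture <- function(side_px = 304, void_fraction = 0.3,
                                granule_scale_px = 4, contrast = 0.6,
                                seed = 1, scan_width_mm = 3) {
  if (void_fraction <= 0 || void_fraction >= 0.9) {
    abort("`void_fraction` must lie in (0, 0.9).")
  }
  if (granule_scale_px <= 0.5) abort("Degenerate `granule_scale_px`.")
  if (contrast < 0 || contrast > 1) abort("`contrast` must lie in [0, 1].")
  res <- with_local_seed(seed, {
    g <- gaussian_blur(matrix(rnorm(side_px^2), side_px, side_px),
                       granule_scale_px / 2)
    g <- (g - mean(g)) / sd(g)
    base <- clamp01(0.60 + 0.10 * g)
    v <- gaussian_blur(matrix(rnorm(side_px^2), side_px, side_px),
                       granule_scale_px * 4)
    void <- v <= quantile(v, void_fraction)
    img <- base
    img[void] <- img[void] * (1 - contrast)
    list(img = clamp01(img), void = void)
  })
  list(
    slab = en_face_slab(res$img, "CC", scan_width_mm = scan_width_mm),
    void_mask = res$void,
    void_fraction = mean(res$void)
  )
}

#' Synthetic EZ reflectance scene with shared illumination gain
#'
#' Generates the three slabs the reflectivity normalization needs — EZ,
#' vitreous (dark) reference and RNFL (bright) reference — as flat
#' reflectance levels modulated by one shared smooth multiplicative gain
#' field (the acquisition disturbance the normalization exists to cancel)
#' plus independent additive Gaussian noise. The true normalized
#' reflectivity is `(base_ez - dark_level) / (bright_level - dark_level)`
#' by construction.
#'
#' @param base_ez True EZ reflectance level.
#' @param dark_level,bright_level Reference reflectance levels
#'   (`bright_level > dark_level`).
#' @param gain_amplitude Peak relative amplitude of the gain field in
#'   `[0, 1)`; gain lies in `[1 - a, 1 + a]`.
#' @param noise_sd Additive noise SD (>= 0).
#' @param side_px Image side in pixels.
#' @param seed Integer RNG seed.
#' @param scan_width_mm Physical field width.
#' @return A list: `ez`, `dark_ref`, `bright_ref` ([en_face_slab()]s),
#'   `true_ez_norm`, `gain_field` (matrix).
#' @export
generate_reflectance_scene <- function(base_ez = 0.40, dark_level = 0.10,
                                       bright_level = 0.75,
                                       gain_amplitude = 0.2, noise_sd = 0.02,
                                       side_px = 304, seed = 1,
                                       scan_width_mm = 3) {
  if (bright_level <= dark_level) {
    abort("`bright_level` must exceed `dark_level`.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (gain_amplitude < 0 || gain_amplitude >= 1) {
    abort("`gain_amplitude` must lie in [0, 1).")
  }
  res <- with_local_seed(seed, {
    gain <- if (gain_amplitude > 0) {
      g <- gaussian_blur(matrix(rnorm(side_px^2), side_px, side_px),
                         side_px / 8)
      1 + gain_amplitude * g / max(abs(g))
    } else {
      matrix(1, side_px, side_px)
    }
    render <- function(level) {
      img <- level * gain
      if (noise_sd > 0) {
        img <- img + matrix(rnorm(side_px^2, 0, noise_sd), side_px, side_px)
      }
      clamp01(img)
    }
    list(gain = gain, ez = render(base_ez), dark = render(dark_level),
         bright = render(bright_level))
  })
  list(
    ez = en_face_slab(res$ez, "EZ", scan_width_mm = scan_width_mm),
    dark_ref = en_face_slab(res$dark, "VITREOUS_REF",
                            scan_width_mm = scan_width_mm),
    bright_ref = en_face_slab(res$bright, "RNFL_REF",
                              scan_width_mm = scan_width_mm),
    true_ez_norm = (base_ez - dark_level) / (bright_level - dark_level),
    gain_field = res$gain
  )
}

#' Default per-metric cohort parameters
#'
#' Mean and SD of each quantified metric for the study (macula-on) and
#' fellow eyes of a typical macula-on retinal-detachment cohort; these are
#' the defaults [generate_cohort()] draws from.
#'
#' @return A tibble: `metric`, `study_mean`, `study_sd`, `fellow_mean`,
#'   `fellow_sd`.
#' @export
default_cohort_params <- function() {
  tibble(
    metric      = cohort_metric_names(),
    study_mean  = c(17.26, 2.69, 6.45, 15.69, 2.82, 5.67, 50.21, 0.31),
    study_sd    = c(3.34, 0.59, 0.36, 3.34, 0.80, 0.62, 6.20, 0.09),
    fellow_mean = c(20.56, 3.36, 6.16, 17.12, 2.93, 5.88, 57.43, 0.42),
    fellow_sd   = c(3.62, 0.70, 0.32, 3.97, 0.75, 0.33, 6.20, 0.15)
  )
}

#' Synthetic paired-eye cohort
#'
#' Draws, per subject and per metric, a correlated bivariate-normal
#' (study, fellow) pair with the requested means, SDs and within-pair
#' correlation, and returns a per-eye cohort table ready for
#' [summarize_cohort()]. The within-pair correlation default (0.5) reflects
#' the typical inter-eye correlation of healthy paired organs; it is a free
#' parameter of the simulation.
#'
#' @param n_subjects Number of subjects (default 21).
#' @param params Per-metric parameter tibble as in [default_cohort_params()].
#' @param rho Within-pair correlation, in (-1, 1).
#' @param seed Integer RNG seed.
#' @return A tibble with `2 * n_subjects` rows: `subject_id`, `eye` and one
#'   column per metric.
#' @export
generate_cohort <- function(n_subjects = 21, params = default_cohort_params(),
                            rho = 0.5, seed = 1) {
  if (n_subjects < 2) abort("`n_subjects` must be >= 2.")
  if (rho <= -1 || rho >= 1) abort("`rho` must lie in (-1, 1).")
  params <- as_tibble(params)
  need <- c("metric", "study_mean", "study_sd", "fellow_mean", "fellow_sd")
  if (!all(need %in% names(params))) {
    abort(paste0("`params` needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(params$study_sd <= 0) || any(params$fellow_sd <= 0)) {
    abort("All SDs must be positive.")
  }
  draws <- with_local_seed(seed, {
    purrr::pmap(params, function(metric, study_mean, study_sd,
                                 fellow_mean, fellow_sd) {
      sigma <- matrix(c(study_sd^2, rho * study_sd * fellow_sd,
                        rho * study_sd * fellow_sd, fellow_sd^2), 2, 2)
      ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
      if (any(ev <= 0)) {
        abort(sprintf("Implied covariance for '%s' is not positive definite.",
                      metric))
      }
      xy <- MASS::mvrnorm(n_subjects, c(study_mean, fellow_mean), sigma)
      tibble(study = xy[, 1], fellow = xy[, 2])
    })
  })
  names(draws) <- params$metric
  ids <- sprintf("S%03d", seq_len(n_subjects))
  per_eye <- function(eye) {
    out <- tibble(subject_id = ids, eye = eye)
    for (mname in params$metric) out[[mname]] <- draws[[mname]][[eye]]
    out
  }
  dplyr::bind_rows(per_eye("study"), per_eye("fellow")) |>
    dplyr::arrange(.data$subject_id, dplyr::desc(.data$eye))
}
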