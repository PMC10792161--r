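test_that("generators are pure functions of their spec (seed included)", {
  a <- generate_vessel_slab(side_px = 128, area_fraction = 0.15, seed = 5,
                            n_branches = 5, scan_width_mm = 3 * 128 / 304,
                            roi_radius_mm = 0.55)
  b <- generate_vessel_slab(side_px = 128, area_fraction = 0.15, seed = 5,
                            n_branches = 5, scan_width_mm = 3 * 128 / 304,
                            roi_radius_mm = 0.55)
  expect_identical(a$slab$image, b$slab$image)
  expect_identical(a$truth_mask$mask, b$truth_mask$mask)

  t1 <- generate_cc_texture(side_px = 96, seed = 8,
                            scan_width_mm = 3 * 96 / 304)
  t2 <- generate_cc_texture(side_px = 96, seed = 8,
                            scan_width_mm = 3 * 96 / 304)
  expect_identical(t1$slab$image, t2$slab$image)

  c1 <- generate_cohort(n_subjects = 8, seed = 4)
  c2 <- generate_cohort(n_subjects = 8, seed = 4)
  expect_identical(c1, c2)

  # generators never disturb the session RNG
  set.seed(123); before <- .Random.seed
  invisible(generate_cohort(n_subjects = 3, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("vessel generator hits its target area fraction inside the ROI", {
  for (seed in 1:5) {
    g <- generate_vessel_slab(side_px = 200, area_fraction = 0.2, seed = seed,
                              scan_width_mm = 3 * 200 / 304,
                              roi_radius_mm = 0.9)
    expect_lte(abs(g$area_fraction - 0.2), 0.02)
    # PD computed on the ground-truth mask equals the achieved fraction exactly
    roi <- make_roi(g$slab, 0.9)
    pd <- 100 * sum(g$truth_mask$mask & roi$mask) / roi$n_px
    expect_equal(pd, 100 * g$area_fraction)
    expect_gt(g$centerline_length_px, 0)
  }
  # f = 0 edge: blank slab, empty mask
  g0 <- generate_vessel_slab(side_px = 128, area_fraction = 0, seed = 1,
                             scan_width_mm = 3 * 128 / 304,
                             roi_radius_mm = 0.55)
  expect_false(any(g0$truth_mask$mask))
  expect_equal(g0$n_strokes, 0)
  expect_error(generate_vessel_slab(area_fraction = 0.7), "0, 0.6")
})

test_that("pipeline PD on rendered vessel slabs recovers the target fraction", {
  errs <- vapply(1:10, function(seed) {
    g <- generate_vessel_slab(side_px = 200, area_fraction = 0.2, seed = seed,
                              scan_width_mm = 3 * 200 / 304,
                              roi_radius_mm = 0.9)
    quantify_slab(g$slab, radius_mm = 0.9)$pd_percent - 20
  }, numeric(1))
  expect_lt(max(abs(errs)), 2)
})

test_that("cc texture reports its exact void mask and plausible PDCC", {
  # the study's measurement geometry: 3 mm / 304 px scan, 1.5 mm ROI
  tx <- generate_cc_texture(side_px = 304, void_fraction = 0.5,
                            contrast = 0.9, seed = 2)
  expect_equal(tx$void_fraction, 0.5, tolerance = 0.01)
  roi <- make_roi(tx$slab, 1.5)
  pdcc <- compute_pdcc(binarize_phansalkar(tx$slab, roi), roi)
  expect_gte(pdcc, 40)
  expect_lte(pdcc, 60)
  expect_error(generate_cc_texture(void_fraction = 0.95), "0, 0.9")
  expect_error(generate_cc_texture(granule_scale_px = 0.1), "Degenerate")
})

test_that("zero-contrast voids are indistinguishable from no-void texture", {
  pdcc_at <- function(contrast, seed) {
    tx <- generate_cc_texture(side_px = 128, void_fraction = 0.4,
                              contrast = contrast, seed = seed,
                              scan_width_mm = 3 * 128 / 304)
    roi <- make_roi(tx$slab, 0.55)
    compute_pdcc(binarize_phansalkar(tx$slab, roi,
                                     phansalkar_params(10)), roi)
  }
  zero <- vapply(1:10, function(s) pdcc_at(0, s), numeric(1))
  high <- vapply(1:10, function(s) pdcc_at(0.9, s), numeric(1))
  # contrast 0 leaves the granule field untouched: PDCC stays high and the
  # two-sample comparison against dark voids is decisive
  expect_gt(t.test(zero, high)$statistic, 5)
  expect_gt(mean(zero) - mean(high), 20)
})

test_that("reflectance scenes cancel a shared gain and bound the noise error", {
  # noiseless, gain-free: pipeline value is exact
  sc0 <- generate_reflectance_scene(base_ez = 0.425, gain_amplitude = 0,
                                    noise_sd = 0, side_px = 96, seed = 1,
                                    scan_width_mm = 3 * 96 / 304)
  roi <- make_roi(sc0$ez, 0.4)
  expect_equal(sc0$true_ez_norm, 0.5)
  expect_equal(normalized_reflectivity(sc0$ez, sc0$dark_ref, sc0$bright_ref,
                                       roi, "roi")$ez_norm, 0.5)

  # shared gain field, no noise: error stays within 0.02 across seeds
  errs <- vapply(1:20, function(s) {
    sc <- generate_reflectance_scene(gain_amplitude = 0.3, noise_sd = 0,
                                     side_px = 96, seed = s,
                                     scan_width_mm = 3 * 96 / 304)
    r <- make_roi(sc$ez, 0.4)
    abs(normalized_reflectivity(sc$ez, sc$dark_ref, sc$bright_ref,
                                r, "roi")$ez_norm - sc$true_ez_norm)
  }, numeric(1))
  expect_lt(max(errs), 0.02)

  # additive noise: mean absolute error bounded
  nerrs <- vapply(1:100, function(s) {
    sc <- generate_reflectance_scene(gain_amplitude = 0.1, noise_sd = 0.05,
                                     side_px = 96, seed = s,
                                     scan_width_mm = 3 * 96 / 304)
    r <- make_roi(sc$ez, 0.4)
    abs(normalized_reflectivity(sc$ez, sc$dark_ref, sc$bright_ref,
                                r, "roi")$ez_norm - sc$true_ez_norm)
  }, numeric(1))
  expect_lt(mean(nerrs), 0.03)
  expect_error(generate_reflectance_scene(bright_level = 0.1,
                                          dark_level = 0.2), "exceed")
})

test_that("cohort generator honors its mean/SD/correlation structure", {
  # law of large numbers on the means
  big <- generate_cohort(n_subjects = 10000, rho = 0, seed = 12)
  pars <- default_cohort_params()
  for (i in c(1, 7, 8)) {
    m <- pars$metric[i]
    sv <- big[[m]][big$eye == "study"]
    se <- pars$study_sd[i] / sqrt(10000)
    expect_lt(abs(mean(sv) - pars$study_mean[i]), 2 * se * 1.5)
  }
  # within-pair correlation close to its target
  wide <- tidyr::pivot_wider(big[, c("subject_id", "eye", "scp_pd")],
                             names_from = "eye", values_from = "scp_pd")
  big5 <- generate_cohort(n_subjects = 10000, rho = 0.5, seed = 13)
  wide5 <- tidyr::pivot_wider(big5[, c("subject_id", "eye", "scp_pd")],
                              names_from = "eye", values_from = "scp_pd")
  expect_lt(abs(cor(wide$study, wide$fellow)), 0.05)
  expect_equal(cor(wide5$study, wide5$fellow), 0.5, tolerance = 0.05)
  # near-zero SDs collapse onto the specified means
  tiny <- default_cohort_params()
  tiny$study_sd <- tiny$fellow_sd <- rep(1e-9, 8)
  coll <- generate_cohort(n_subjects = 5, params = tiny, seed = 1)
  expect_equal(coll$scp_pd[coll$eye == "study"], rep(17.26, 5),
               tolerance = 1e-6)
  expect_error(generate_cohort(rho = 1), "-1, 1")
})
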