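test_that("thinning leaves 1-px structures alone and empties empty masks", {
  m <- matrix(FALSE, 64, 64)
  m[30, 5:54] <- TRUE  # 1-px horizontal line of length 50
  sk <- skeletonize(mk_mask(m))
  expect_identical(sk$mask, m)
  expect_false(any(skeletonize(mk_mask(matrix(FALSE, 64, 64)))$mask))
})

test_that("a filled bar thins to a single midline with bounded endpoint erosion", {
  m <- matrix(FALSE, 64, 64)
  m[20:26, 10:30] <- TRUE  # 21 x 7 bar
  sk <- skeletonize(mk_mask(m))
  expect_true(all(m[sk$mask]))                      # subset of source
  expect_equal(oracle_n_components(sk$mask), 1)     # still one component
  # thinning erodes each rounded end by at most (width - 1) / 2 px; the
  # reference Zhang-Suen implementations give 15-17 px for this bar
  expect_gte(sum(sk$mask), 21 - 6)
  expect_lte(sum(sk$mask), 21)
  expect_true(all(which(sk$mask, arr.ind = TRUE)[, 1] == 23))  # midline row
})

test_that("thinning preserves the 8-connected component count", {
  for (seed in 1:5) {
    # random blobs: threshold smoothed noise
    img <- withr::with_seed(seed, matrix(rnorm(64 * 64), 64, 64))
    sm <- octaquant:::gaussian_blur(img, 2.5)
    m <- sm > quantile(sm, 0.75)
    sk <- skeletonize(mk_mask(m))
    expect_true(all(m[sk$mask]))
    expect_equal(oracle_n_components(sk$mask), oracle_n_components(m))
  }
})

test_that("plexus metrics implement their ROI-fraction definitions", {
  slab <- en_face_slab(matrix(0.5, 304, 304), "SCP")
  roi <- make_roi(slab, 1.5)
  # mask covering the whole ROI -> PD = 100
  full <- mk_mask(roi$mask)
  sk <- skeletonize(full, roi)
  met <- compute_plexus_metrics(full, sk, roi, "SCP")
  expect_equal(met$pd_percent, 100)
  expect_equal(met$pd_percent, met$vdi * met$vld_percent, tolerance = 1e-6)

  # a 7 x 100 bar inside the ROI: VDI close to the bar width
  m <- matrix(FALSE, 304, 304)
  m[148:154, 102:201] <- TRUE
  bar <- mk_mask(m)
  skb <- skeletonize(bar, roi)
  mb <- compute_plexus_metrics(bar, skb, roi, "SCP")
  expect_gte(mb$vdi, 6.3)
  expect_lte(mb$vdi, 7.7)
  expect_equal(mb$pd_percent, 100 * 700 / roi$n_px)

  # empty skeleton with non-empty mask -> VDI flagged NA
  dot <- matrix(FALSE, 304, 304)
  dot[152, 152] <- TRUE
  expect_warning(
    mna <- compute_plexus_metrics(mk_mask(dot),
                                  structure(list(mask = matrix(FALSE, 304, 304),
                                                 provenance = list()),
                                            class = "octa_skeleton"),
                                  roi),
    "undefined")
  expect_true(is.na(mna$vdi))
})

test_that("the PD = VDI x VLD identity holds on binarized synthetic slabs", {
  for (seed in 1:5) {
    g <- generate_vessel_slab(side_px = 160, area_fraction = 0.18,
                              n_branches = 6, seed = seed,
                              scan_width_mm = 3 * 160 / 304,
                              roi_radius_mm = 0.7)
    roi <- make_roi(g$slab, 0.7)
    bm <- binarize_global(g$slab, roi, "otsu")
    sk <- skeletonize(bm, roi)
    met <- compute_plexus_metrics(bm, sk, roi)
    expect_equal(met$pd_percent, met$vdi * met$vld_percent, tolerance = 1e-6)
    expect_lte(met$vld_percent, met$pd_percent)
    expect_gte(met$vdi, 1)
  }
})

test_that("PD is monotone non-decreasing under dilation of the mask", {
  g <- generate_vessel_slab(side_px = 160, area_fraction = 0.15,
                            n_branches = 6, seed = 3,
                            scan_width_mm = 3 * 160 / 304,
                            roi_radius_mm = 0.7)
  roi <- make_roi(g$slab, 0.7)
  m <- g$truth_mask$mask
  dil <- EBImage::dilate(EBImage::Image(m * 1), EBImage::makeBrush(5, "disc"))
  dmask <- mk_mask(EBImage::imageData(dil) > 0)
  pd0 <- 100 * sum(m & roi$mask) / roi$n_px
  sk0 <- skeletonize(mk_mask(m), roi)
  pd1 <- compute_plexus_metrics(dmask, skeletonize(dmask, roi), roi)$pd_percent
  expect_gte(pd1, pd0)
})

test_that("PDCC is the ROI foreground percentage", {
  slab <- en_face_slab(matrix(0.5, 304, 304), "CC")
  roi <- make_roi(slab, 1.5)
  expect_equal(compute_pdcc(mk_mask(roi$mask), roi), 100)
  expect_equal(compute_pdcc(mk_mask(matrix(FALSE, 304, 304)), roi), 0)
  # agreement with an oracle-computed Phansalkar mask on a small texture
  tx <- generate_cc_texture(side_px = 64, void_fraction = 0.4,
                            contrast = 0.8, seed = 6,
                            scan_width_mm = 3 * 64 / 304)
  troi <- inscribed_roi(tx$slab)
  pp <- phansalkar_params(window_radius_px = 4)
  pdcc <- compute_pdcc(binarize_phansalkar(tx$slab, troi, pp), troi)
  omask <- oracle_phansalkar(tx$slab$image, troi$mask, 4)
  expect_equal(pdcc, 100 * sum(omask & troi$mask) / troi$n_px)
})

test_that("quantify_slab routes SCP/DCP and CC through the right binarizers", {
  g <- generate_vessel_slab(side_px = 160, area_fraction = 0.2, seed = 2,
                            n_branches = 6, scan_width_mm = 3 * 160 / 304,
                            roi_radius_mm = 0.7)
  row <- quantify_slab(g$slab, radius_mm = 0.7)
  expect_equal(row$method, "otsu")
  expect_false(is.na(row$vdi))
  tx <- generate_cc_texture(side_px = 160, seed = 2,
                            scan_width_mm = 3 * 160 / 304)
  ccslab <- tx$slab
  rowcc <- quantify_slab(ccslab, radius_mm = 0.7)
  expect_equal(rowcc$method, "phansalkar")
  expect_true(is.na(rowcc$vdi))
  ez <- en_face_slab(matrix(0.5, 160, 160), "EZ",
                     scan_width_mm = 3 * 160 / 304)
  expect_error(quantify_slab(ez, 0.7), "SCP/DCP/CC")
})
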