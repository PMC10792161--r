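#' Perfusion metrics of a binarized plexus inside the ROI
#'
#' Computes the three standard OCTA capillary metrics over the foveal ROI:
#'
#' * **PD** (perfusion density, %): foreground-pixel fraction of the ROI
#'   times 100.
#' * **VLD** (vessel length density, %): skeleton-pixel fraction of the ROI
#'   times 100.
#' * **VDI** (vessel diameter index): foreground pixel count divided by
#'   skeleton pixel count — a dimensionless surrogate for mean vessel
#'   caliber (roughly the average vessel width in pixels). `NA` with a
#'   warning when the skeleton is empty.
#'
#' All three are pixel-count ratios, so the physical pixel pitch cancels;
#' the identity `pd_percent == vdi * vld_percent` holds whenever VDI is
#' defined.
#'
#' @param mask An `octa_binary_mask`.
#' @param skeleton An `octa_skeleton` derived from `mask` (same shape,
#'   subset of its foreground).
#' @param roi A [make_roi()] result of the same shape.
#' @param slab_kind Optional slab label carried into the output.
#' @return A one-row tibble: `slab_kind`, `pd_percent`, `vld_percent`,
#'   `vdi`, `n_roi_px`, `method`.
#' @export
compute_plexus_metrics <- function(mask, skeleton, roi, slab_kind = NA_character_) {
  stopifnot(inherits(mask, "octa_binary_mask"),
            inherits(skeleton, "octa_skeleton"),
            inherits(roi, "circular_roi"))
  if (!identical(dim(mask$mask), dim(roi$mask)) ||
      !identical(dim(skeleton$mask), dim(roi$mask))) {
    abort("`mask`, `skeleton` and `roi` must share one shape.")
  }
  if (any(skeleton$mask & !mask$mask)) {
    abort("`skeleton` is not a subset of `mask` foreground.")
  }
  n_roi <- sum(roi$mask)
  if (n_roi == 0) abort("Empty ROI.")
  n_fg <- sum(mask$mask & roi$mask)
  n_sk <- sum(skeleton$mask & roi$mask)
  vdi <- if (n_sk > 0) n_fg / n_sk else NA_real_
  if (n_sk == 0 && n_fg > 0) {
    warn("Empty skeleton with non-empty mask: VDI undefined (NA).")
  }
  tibble(
    slab_kind = slab_kind,
    pd_percent = 100 * n_fg / n_roi,
    vld_percent = 100 * n_sk / n_roi,
    vdi = vdi,
    n_roi_px = n_roi,
    method = mask$provenance$method %||% NA_character_
  )
}

#' Choriocapillaris perfusion density
#'
#' Foreground fraction of the ROI, in percent, for a Phansalkar-binarized
#' choriocapillaris slab.
#'
#' @param mask An `octa_binary_mask` from [binarize_phansalkar()].
#' @param roi A [make_roi()] result of the same shape.
#' @return A single number in `[0, 100]`.
#' @export
compute_pdcc <- function(mask, roi) {
  stopifnot(inherits(mask, "octa_binary_mask"), inherits(roi, "circular_roi"))
  if (!identical(dim(mask$mask), dim(roi$mask))) {
    abort("`mask` and `roi` shapes differ.")
  }
  n_roi <- sum(roi$mask)
  if (n_roi == 0) abort("Empty ROI.")
  100 * sum(mask$mask & roi$mask) / n_roi
}

#' Quantify one plexus slab end to end
#'
#' Convenience wrapper: ROI construction, binarization (global for SCP/DCP,
#' Phansalkar for CC), skeletonization (SCP/DCP only) and metric
#' computation.
#'
#' @param slab An [en_face_slab()] of kind SCP, DCP or CC.
#' @param radius_mm ROI radius in mm.
#' @param method Global thresholder for SCP/DCP.
#' @param params Phansalkar parameters for CC.
#' @return A one-row tibble (see [compute_plexus_metrics()]); for CC the
#'   skeleton metrics are `NA` and `pd_percent` is the PDCC.
#' @export
quantify_slab <- function(slab, radius_mm = 1.5, method = c("otsu", "mean"),
                          params = phansalkar_params()) {
  stopifnot(inherits(slab, "en_face_slab"))
  method <- match.arg(method)
  roi <- make_roi(slab, radius_mm)
  if (slab$slab_kind == "CC") {
    mask <- binarize_phansalkar(slab, roi, params)
    return(tibble(slab_kind = "CC",
                  pd_percent = compute_pdcc(mask, roi),
                  vld_percent = NA_real_, vdi = NA_real_,
                  n_roi_px = roi$n_px, method = "phansalkar"))
  }
  if (!slab$slab_kind %in% c("SCP", "DCP")) {
    abort(sprintf("quantify_slab() handles SCP/DCP/CC, not %s.", slab$slab_kind))
  }
  mask <- binarize_global(slab, roi, method)
  skel <- skeletonize(mask, roi)
  compute_plexus_metrics(mask, skel, roi, slab_kind = slab$slab_kind)
}
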