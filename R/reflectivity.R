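#' Normalized ellipsoid-zone reflectivity
#'
#' Rescales the mean EZ en-face brightness between a dark reference (the
#' vitreous) and a bright reference (the retinal nerve fiber layer):
#' \deqn{EZ_{norm} = \frac{\bar I_{EZ} - \bar I_{dark}}{\bar I_{bright} - \bar I_{dark}}}
#' The two-point normalization cancels any global affine change of the
#' acquisition intensity scale (gain and offset) applied jointly to the
#' three structures — its entire purpose is to make reflectivity comparable
#' across subjects and devices. Values are typically in `[0, 1]` but are
#' deliberately not clamped: out-of-range values are a diagnostic that the
#' references do not bracket the EZ signal.
#'
#' The EZ mean is always taken inside the foveal ROI. Reference means are
#' taken over the full reference slabs by default (`reference_scope =
#' "full"`); `"roi"` restricts them to the same ROI, which makes a shared
#' spatially varying illumination gain cancel exactly since all three means
#' then weight the gain field identically.
#'
#' @param ez,dark_ref,bright_ref [en_face_slab()] objects from the same eye,
#'   same shape (EZ, vitreous reference, RNFL reference).
#' @param roi A [make_roi()] result for the EZ slab.
#' @param reference_scope `"full"` (default) or `"roi"`.
#' @return A one-row tibble: `mean_ez`, `mean_dark`, `mean_bright`,
#'   `ez_norm`, `reference_scope`.
#' @export
#' @examples
#' base <- matrix(0.45, 64, 64); dark <- matrix(0.10, 64, 64)
#' bright <- matrix(0.80, 64, 64)
#' ez <- en_face_slab(base, "EZ"); d <- en_face_slab(dark, "VITREOUS_REF")
#' b <- en_face_slab(bright, "RNFL_REF")
#' normalized_reflectivity(ez, d, b, make_roi(ez, 0.9))  # ez_norm = 0.5
normalized_reflectivity <- function(ez, dark_ref, bright_ref, roi,
                                    reference_scope = c("full", "roi")) {
  stopifnot(inherits(ez, "en_face_slab"), inherits(dark_ref, "en_face_slab"),
            inherits(bright_ref, "en_face_slab"), inherits(roi, "circular_roi"))
  reference_scope <- match.arg(reference_scope)
  if (!identical(dim(ez$image), dim(dark_ref$image)) ||
      !identical(dim(ez$image), dim(bright_ref$image))) {
    abort("EZ and reference slabs must share one shape.")
  }
  if (!identical(dim(ez$image), dim(roi$mask))) {
    abort("`roi` does not match the EZ slab shape.")
  }
  ref_vals <- function(slab) {
    v <- if (reference_scope == "roi") slab$image[roi$mask] else slab$image
    if (length(v) == 0) abort("Empty reference region.")
    v
  }
  mean_ez <- mean(ez$image[roi$mask])
  mean_dark <- mean(ref_vals(dark_ref))
  mean_bright <- mean(ref_vals(bright_ref))
  if (mean_bright <= mean_dark) {
    abort(sprintf(
      "Bright reference mean (%.4f) must exceed dark reference mean (%.4f): references inverted or degenerate.",
      mean_bright, mean_dark))
  }
  tibble(mean_ez = mean_ez, mean_dark = mean_dark,
         mean_bright = mean_bright,
         ez_norm = (mean_ez - mean_dark) / (mean_bright - mean_dark),
         reference_scope = reference_scope)
}

#' Check affine invariance of the normalized reflectivity
#'
#' Applies the intensity transform `a * I + b` (gain `a > 0`, offset `b`)
#' jointly to the EZ slab and both references, recomputes the normalized
#' reflectivity without clamping, and compares with the original. The
#' normalization is algebraically invariant to such transforms; this
#' verifies it numerically.
#'
#' @inheritParams normalized_reflectivity
#' @param a Gain, must be positive.
#' @param b Offset.
#' @param tol Tolerance for declaring invariance (default `1e-10`).
#' @return A one-row tibble: `ez_norm`, `ez_norm_transformed`, `deviation`,
#'   `invariant`.
#' @export
check_affine_invariance <- function(ez, dark_ref, bright_ref, roi,
                                    a = 1, b = 0, tol = 1e-10,
                                    reference_scope = c("full", "roi")) {
  if (!is.numeric(a) || length(a) != 1 || a <= 0) {
    abort("Gain `a` must be a single positive number.")
  }
  reference_scope <- match.arg(reference_scope)
  orig <- normalized_reflectivity(ez, dark_ref, bright_ref, roi,
                                  reference_scope)
  tf <- function(slab) {
    new_en_face_slab(a * slab$image + b, slab$slab_kind, slab$scan_width_mm,
                     slab$fovea_center_px, slab$ssi, slab$eye_label,
                     slab$subject_id)
  }
  trans <- normalized_reflectivity(tf(ez), tf(dark_ref), tf(bright_ref), roi,
                                   reference_scope)
  dev <- abs(trans$ez_norm - orig$ez_norm)
  tibble(ez_norm = orig$ez_norm, ez_norm_transformed = trans$ez_norm,
         deviation = dev, invariant = dev <= tol)
}
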