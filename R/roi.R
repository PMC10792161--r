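#' Foveal circular region of interest
#'
#' Builds the circular measurement region centered on the fovea. The default
#' radius is 1.5 mm, a choice driven by the limited lateral resolution of
#' en-face OCTA images. The radius is converted to pixels through the pixel
#' pitch (`scan_width_mm / ncol`), and a pixel belongs to the ROI when its
#' *center* lies within `radius_px` of the fovea center (0-based pixel-center
#' geometry).
#'
#' The disc must lie fully inside the physical image area, which spans
#' `[-0.5, n - 0.5]` in each pixel dimension; a fovea center too close to an
#' edge is rejected rather than producing a truncated ROI.
#'
#' @param slab An [en_face_slab()] with its fovea center set.
#' @param radius_mm ROI radius in millimetres (default 1.5).
#' @return An object of class `circular_roi` with fields `center_px`
#'   (0-based row, col), `radius_mm`, `radius_px`, `mask` (logical matrix,
#'   same shape as the slab) and `n_px` (pixel count).
#' @export
#' @examples
#' slab <- en_face_slab(matrix(runif(304^2), 304, 304), "SCP")
#' roi <- make_roi(slab, radius_mm = 1.5)
#' roi$radius_px   # 152 for a 3 mm / 304 px scan
make_roi <- function(slab, radius_mm = 1.5) {
  stopifnot(inherits(slab, "en_face_slab"))
  if (!is.numeric(radius_mm) || length(radius_mm) != 1 || radius_mm <= 0) {
    abort("`radius_mm` must be a single positive number.")
  }
  pitch <- pixel_pitch_mm(slab)
  radius_px <- radius_mm / pitch
  ctr <- slab$fovea_center_px  # 0-based (row, col)
  nr <- nrow(slab$image); nc <- ncol(slab$image)
  # Disc must fit inside the physical image extent [-0.5, n - 0.5].
  if (ctr[1] - radius_px < -0.5 || ctr[1] + radius_px > nr - 0.5 ||
      ctr[2] - radius_px < -0.5 || ctr[2] + radius_px > nc - 0.5) {
    abort(sprintf(
      "ROI of radius %.1f px around (%.1f, %.1f) extends outside the %d x %d image.",
      radius_px, ctr[1], ctr[2], nr, nc))
  }
  rows <- matrix(0:(nr - 1), nr, nc)
  cols <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  mask <- (rows - ctr[1])^2 + (cols - ctr[2])^2 <= radius_px^2
  if (!any(mask)) abort("ROI contains no pixel centers; radius too small.")
  structure(
    list(center_px = ctr, radius_mm = radius_mm, radius_px = radius_px,
         mask = mask, n_px = sum(mask)),
    class = "circular_roi"
  )
}

#' @export
print.circular_roi <- function(x, ...) {
  cat(sprintf(
    "<circular_roi> radius %.2f mm = %.1f px, center (%.1f, %.1f), %d px\n",
    x$radius_mm, x$radius_px, x$center_px[1], x$center_px[2], x$n_px))
  invisible(x)
}
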