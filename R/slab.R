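#' En-face slab objects
#'
#' An `en_face_slab` wraps one grayscale en-face image (a numeric matrix of
#' intensities in `[0, 1]`, rows = image rows) together with the acquisition
#' metadata the quantification pipeline needs: which anatomical slab it is,
#' the physical width of the square scan field, the fovea center in pixel
#' coordinates, the device-reported signal strength index (SSI), and the
#' eye/subject labels.
#'
#' Pixel coordinates are 0-based `(row, col)` and refer to pixel centers, so
#' the first pixel center is `(0, 0)` and the image physically spans
#' `[-0.5, ncol - 0.5]` in each direction. The pixel pitch (mm per pixel) is
#' `scan_width_mm / ncol(image)`.
#'
#' @param image Numeric matrix, intensities in `[0, 1]`, at least 64 px per
#'   side.
#' @param slab_kind One of `"SCP"`, `"DCP"`, `"CC"`, `"EZ"`,
#'   `"VITREOUS_REF"`, `"RNFL_REF"`.
#' @param scan_width_mm Physical width of the square field in mm (default 3).
#' @param fovea_center_px Numeric length-2, 0-based `(row, col)` of the fovea
#'   center. Defaults to the image center. Supplied by the operator; the
#'   package never localizes the fovea itself.
#' @param ssi Signal strength index on a 0-10 scale (`NA` if unknown).
#' @param eye_label `"study"` or `"fellow"` (`NA` if not applicable).
#' @param subject_id Opaque subject identifier string.
#'
#' @return An object of class `en_face_slab`.
#' @export
#' @examples
#' img <- matrix(runif(64 * 64), 64, 64)
#' slab <- en_face_slab(img, "SCP", scan_width_mm = 3, ssi = 9)
#' slab
en_face_slab <- function(image, slab_kind,
                         scan_width_mm = 3,
                         fovea_center_px = NULL,
                         ssi = NA_real_,
                         eye_label = NA_character_,
                         subject_id = NA_character_) {
  slab_kind <- match.arg(slab_kind, slab_kinds())
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a numeric matrix.")
  }
  if (min(dim(image)) < 64) {
    abort(sprintf("`image` must have >= 64 px per side, got %d x %d.",
                  nrow(image), ncol(image)))
  }
  if (anyNA(image) || min(image) < 0 || max(image) > 1) {
    abort("`image` intensities must all lie in [0, 1].")
  }
  new_en_face_slab(image, slab_kind, scan_width_mm, fovea_center_px, ssi,
                   eye_label, subject_id)
}

# Internal constructor: trusts `image` (used for affine-invariance checks
# where intensities are deliberately pushed outside [0, 1]).
new_en_face_slab <- function(image, slab_kind, scan_width_mm = 3,
                             fovea_center_px = NULL, ssi = NA_real_,
                             eye_label = NA_character_,
                             subject_id = NA_character_) {
  if (!is.numeric(scan_width_mm) || length(scan_width_mm) != 1 ||
      !is.finite(scan_width_mm) || scan_width_mm <= 0) {
    abort("`scan_width_mm` must be a single positive number.")
  }
  if (is.null(fovea_center_px)) {
    fovea_center_px <- c((nrow(image) - 1) / 2, (ncol(image) - 1) / 2)
  }
  if (length(fovea_center_px) != 2 || anyNA(fovea_center_px)) {
    abort("`fovea_center_px` must be a finite (row, col) pair.")
  }
  if (!is.na(ssi) && (ssi < 0 || ssi > 10)) {
    abort("`ssi` must lie in [0, 10].")
  }
  if (!is.na(eye_label)) {
    eye_label <- match.arg(eye_label, c("study", "fellow"))
  }
  structure(
    list(
      image = image,
      slab_kind = slab_kind,
      scan_width_mm = scan_width_mm,
      fovea_center_px = as.numeric(fovea_center_px),
      ssi = as.numeric(ssi),
      eye_label = eye_label,
      subject_id = subject_id
    ),
    class = "en_face_slab"
  )
}

slab_kinds <- function() c("SCP", "DCP", "CC", "EZ", "VITREOUS_REF", "RNFL_REF")

#' @export
print.en_face_slab <- function(x, ...) {
  cat(sprintf("<en_face_slab> %s  %d x %d px  %.2f mm field (%.4f mm/px)\n",
              x$slab_kind, nrow(x$image), ncol(x$image), x$scan_width_mm,
              pixel_pitch_mm(x)))
  cat(sprintf("  fovea (row, col) = (%.1f, %.1f)  SSI = %s  eye = %s  subject = %s\n",
              x$fovea_center_px[1], x$fovea_center_px[2],
              format(x$ssi), format(x$eye_label), format(x$subject_id)))
  invisible(x)
}

#' Pixel pitch of a slab
#'
#' Millimetres per pixel: `scan_width_mm / ncol(image)`.
#'
#' @param slab An [en_face_slab()].
#' @return A single positive number (mm / px).
#' @export
pixel_pitch_mm <- function(slab) {
  stopifnot(inherits(slab, "en_face_slab"))
  slab$scan_width_mm / ncol(slab$image)
}

#' Read an en-face slab image from disk
#'
#' Reads a single-channel 8- or 16-bit TIFF or PNG and rescales intensities
#' to `[0, 1]` by dividing by the bit-depth maximum (255 or 65535), so all
#' downstream arithmetic is bit-depth independent. Acquisition metadata is
#' attached unmodified.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @inheritParams en_face_slab
#' @return An [en_face_slab()].
#' @export
read_slab <- function(path, slab_kind,
                      scan_width_mm = 3,
                      fovea_center_px = NULL,
                      ssi = NA_real_,
                      eye_label = NA_character_,
                      subject_id = NA_character_) {
  if (!file.exists(path)) {
    abort(sprintf("Cannot read slab image: file not found: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tryCatch(tiff::readTIFF(path),
                    error = function(e) abort(sprintf(
                      "Unreadable TIFF: %s (%s)", path, conditionMessage(e)))),
    png = tryCatch(png::readPNG(path),
                   error = function(e) abort(sprintf(
                     "Unreadable PNG: %s (%s)", path, conditionMessage(e)))),
    abort(sprintf("Unsupported image format '%s': %s", ext, path))
  )
  if (length(dim(img)) == 3) {
    abort(sprintf("Multi-channel image not supported (%d channels): %s",
                  dim(img)[3], path))
  }
  if (length(img) == 0 || min(dim(img)) == 0) {
    abort(sprintf("Zero-size image: %s", path))
  }
  # readTIFF/readPNG already divide by the bit-depth maximum.
  en_face_slab(img, slab_kind, scan_width_mm, fovea_center_px, ssi,
               eye_label, subject_id)
}

#' Write an en-face slab image to disk
#'
#' Quantizes intensities to the requested bit depth and writes a
#' single-channel TIFF or PNG. A slab whose intensities are exact multiples
#' of `1 / (2^bits - 1)` round-trips losslessly through [read_slab()].
#'
#' @param slab An [en_face_slab()].
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @param bits Bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_slab <- function(slab, path, bits = 8) {
  stopifnot(inherits(slab, "en_face_slab"), bits %in% c(8, 16))
  ext <- tolower(tools::file_ext(path))
  img <- slab$image
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = bits)
  } else if (ext == "png") {
    if (bits != 8) abort("PNG output is written at 8 bits; use TIFF for 16.")
    png::writePNG(img, path)
  } else {
    abort(sprintf("Unsupported image format '%s': %s", ext, path))
  }
  invisible(path)
}
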