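#' Binary vessel masks
#'
#' Thresholding converts an en-face slab into a logical foreground mask of
#' the same shape, restricted to the ROI: a pixel outside the ROI is never
#' foreground. Every mask carries provenance (thresholder name and
#' parameters) so results are traceable. Ties go to background: foreground
#' always means intensity strictly greater than the threshold.
#'
#' @name binary-masks
NULL

new_binary_mask <- function(mask, provenance) {
  structure(list(mask = mask, provenance = provenance),
            class = "octa_binary_mask")
}

#' @export
print.octa_binary_mask <- function(x, ...) {
  cat(sprintf("<octa_binary_mask> %d x %d, %d foreground px, method = %s\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              x$provenance$method))
  invisible(x)
}

# Otsu's threshold on a vector of [0,1] intensities: 256-bin histogram,
# exhaustive maximization of between-class variance over the bin edges.
# Returns NA when the criterion is degenerate (constant input).
otsu_threshold <- function(v, n_bins = 256) {
  bins <- pmin(floor(v * n_bins) + 1L, n_bins)
  counts <- tabulate(bins, n_bins)
  n <- length(v)
  level_means <- (seq_len(n_bins) - 0.5) / n_bins
  w0 <- cumsum(counts) / n                    # class <= candidate edge
  mu0 <- cumsum(counts * level_means) / n
  mu_t <- mu0[n_bins]
  w1 <- 1 - w0
  # between-class variance at each candidate edge k/n_bins, k = 1..n_bins-1
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- (mu_t * w0[valid] - mu0[valid])^2 / (w0[valid] * w1[valid])
  if (!any(is.finite(bcv))) return(NA_real_)
  k <- which.max(bcv)
  k / n_bins
}

#' Global binarization of a plexus slab inside the ROI
#'
#' Computes a single threshold from the intensities *inside* the ROI
#' (Otsu's between-class-variance criterion by default, or the ROI mean) and
#' marks as foreground the ROI pixels strictly above it. Intended for the
#' superficial and deep capillary plexus slabs.
#'
#' A constant image inside the ROI has no separable classes: the result is
#' an all-background mask with a warning rather than an arbitrary split.
#'
#' @param slab An [en_face_slab()] (SCP or DCP).
#' @param roi A [make_roi()] result of the same shape.
#' @param method `"otsu"` (default) or `"mean"`.
#' @return An `octa_binary_mask` whose provenance records method and
#'   threshold.
#' @export
binarize_global <- function(slab, roi, method = c("otsu", "mean")) {
  stopifnot(inherits(slab, "en_face_slab"), inherits(roi, "circular_roi"))
  method <- match.arg(method)
  if (!identical(dim(slab$image), dim(roi$mask))) {
    abort("`slab` and `roi` shapes differ.")
  }
  v <- slab$image[roi$mask]
  if (max(v) == min(v)) {
    warn("Constant intensities inside the ROI; threshold is degenerate, returning all-background mask.")
    thr <- NA_real_
    mask <- matrix(FALSE, nrow(slab$image), ncol(slab$image))
  } else {
    thr <- switch(method, otsu = otsu_threshold(v), mean = mean(v))
    mask <- slab$image > thr & roi$mask
  }
  new_binary_mask(mask, list(method = method, threshold = thr,
                             roi_radius_mm = roi$radius_mm))
}

#' Phansalkar local-threshold parameters
#'
#' The Phansalkar threshold is a local adaptive rule designed for
#' low-contrast images. With `m` and `s` the mean and (population) standard
#' deviation of the intensities in a circular window around the pixel, the
#' local threshold is
#' \deqn{T = m (1 + p e^{-q m} + k (s / r - 1))}
#' and the pixel is foreground iff its intensity exceeds `T`. Defaults
#' follow the de-facto standard implementation: window radius 15 px,
#' `k = 0.25`, `r = 0.5`, `p = 2`, `q = 10`.
#'
#' @param window_radius_px Circular window radius in pixels (>= 1).
#' @param k,r,p,q Scalar parameters of the threshold formula; `r > 0`.
#' @return A `phansalkar_params` list.
#' @export
phansalkar_params <- function(window_radius_px = 15, k = 0.25, r = 0.5,
                              p = 2, q = 10) {
  if (window_radius_px < 1) abort("`window_radius_px` must be >= 1.")
  if (r <= 0) abort("`r` must be positive.")
  structure(list(window_radius_px = window_radius_px, k = k, r = r,
                 p = p, q = q),
            class = "phansalkar_params")
}

#' Phansalkar local thresholding of a choriocapillaris slab
#'
#' Binarizes a CC slab with the Phansalkar local threshold (see
#' [phansalkar_params()]) evaluated per ROI pixel over a circular window.
#' At image borders the window is truncated to in-bounds pixels; the local
#' standard deviation is the population SD. Ties go to background and
#' outside-ROI pixels are background.
#'
#' @param slab An [en_face_slab()] (CC), intensities in `[0, 1]`.
#' @param roi A [make_roi()] result.
#' @param params A [phansalkar_params()] object.
#' @return An `octa_binary_mask`.
#' @export
binarize_phansalkar <- function(slab, roi, params = phansalkar_params()) {
  stopifnot(inherits(slab, "en_face_slab"), inherits(roi, "circular_roi"),
            inherits(params, "phansalkar_params"))
  img <- slab$image
  if (!identical(dim(img), dim(roi$mask))) abort("`slab` and `roi` shapes differ.")
  w <- params$window_radius_px
  if (2 * w >= min(dim(img))) {
    abort(sprintf("Window radius %g px too large for a %d x %d image.",
                  w, nrow(img), ncol(img)))
  }
  # Circular window offsets; accumulate truncated-window sums by shifting.
  offs <- expand.grid(dr = -w:w, dc = -w:w)
  offs <- offs[offs$dr^2 + offs$dc^2 <= w^2, ]
  s1 <- matrix(0, nrow(img), ncol(img))
  s2 <- matrix(0, nrow(img), ncol(img))
  cnt <- matrix(0, nrow(img), ncol(img))
  ones <- matrix(1, nrow(img), ncol(img))
  for (i in seq_len(nrow(offs))) {
    sh <- shift_matrix(img, offs$dr[i], offs$dc[i], fill = 0)
    inb <- shift_matrix(ones, offs$dr[i], offs$dc[i], fill = 0)
    s1 <- s1 + sh
    s2 <- s2 + sh * sh
    cnt <- cnt + inb
  }
  m <- s1 / cnt
  s <- sqrt(pmax(s2 / cnt - m^2, 0))
  thr <- m * (1 + params$p * exp(-params$q * m) + params$k * (s / params$r - 1))
  mask <- img > thr & roi$mask
  new_binary_mask(mask, c(list(method = "phansalkar",
                               roi_radius_mm = roi$radius_mm),
                          unclass(params)))
}
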