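# Small fixture builders shared across test files.

# A 64x64 (or larger) slab from a plain matrix, defaulting to a centered
# fovea and a 3 mm field scaled to keep pixel pitch constant.
mk_slab <- function(img, kind = "SCP", ...) {
  en_face_slab(img, kind, scan_width_mm = 3 * ncol(img) / 304, ...)
}

# Uniform-noise slab of a given side, deterministic per seed.
rand_slab <- function(side = 64, kind = "SCP", seed = 1) {
  img <- withr::with_seed(seed, matrix(runif(side * side), side, side))
  mk_slab(img, kind)
}

# Full-frame ROI substitute: a disc inscribed in the image.
inscribed_roi <- function(slab) {
  make_roi(slab, radius_mm = pixel_pitch_mm(slab) * (ncol(slab$image) / 2 - 1))
}

# Wrap a logical matrix as a binary mask like the binarizers produce.
mk_mask <- function(m, method = "test") {
  octaquant:::new_binary_mask(m, list(method = method))
}
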