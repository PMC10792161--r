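# Internal helpers shared across modules.

# Run `code` under a temporary RNG seed, restoring the caller's global RNG
# state afterwards. Every generator routes its randomness through this so
# identical specs give identical output and nothing leaks into the session.
with_local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Shift a matrix by (dr, dc) so that out[i, j] = m[i + dr, j + dc], padding
# out-of-bounds positions with `fill`. Used by the thinning and local
# thresholding kernels.
shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- (1 + max(0, dr)):(nr + min(0, dr))
  src_c <- (1 + max(0, dc)):(nc + min(0, dc))
  if (length(src_r) < 1 || length(src_c) < 1) return(out)
  dst_r <- src_r - dr
  dst_c <- src_c - dc
  out[dst_r, dst_c] <- m[src_r, src_c]
  out
}

# Separable Gaussian blur with truncated (renormalized) borders; kernel
# extends to 3 sigma. Exact direct convolution -- image sides here are a few
# hundred pixels at most.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  conv1 <- function(x) {
    n <- length(x)
    acc <- numeric(n)
    wt <- numeric(n)
    for (i in seq_along(k)) {
      off <- i - half - 1L
      lo <- max(1L, 1L - off); hi <- min(n, n - off)
      if (lo > hi) next
      acc[lo:hi] <- acc[lo:hi] + k[i] * x[(lo + off):(hi + off)]
      wt[lo:hi] <- wt[lo:hi] + k[i]
    }
    acc / wt
  }
  m <- apply(m, 2, conv1)
  t(apply(t(m), 2, conv1))
}

clamp01 <- function(m) {
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

# 8-connected component labelling by flood fill; small images only (tests,
# topology checks). Returns an integer matrix of labels, 0 = background.
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% nr) + 1L
      c <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        q <- (cc - 1L) * nr + rr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}
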