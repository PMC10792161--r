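# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

# Per-pixel Phansalkar: recompute window mean / population SD / threshold by
# direct summation over the circular window, truncated at borders.
oracle_phansalkar <- function(img, roi_mask, w, k = 0.25, r = 0.5,
                              p = 2, q = 10) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!roi_mask[i, j]) next
      acc <- 0; acc2 <- 0; cnt <- 0L
      for (di in -w:w) {
        for (dj in -w:w) {
          if (di * di + dj * dj > w * w) next
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
          acc <- acc + img[ii, jj]
          acc2 <- acc2 + img[ii, jj]^2
          cnt <- cnt + 1L
        }
      }
      m <- acc / cnt
      s <- sqrt(max(acc2 / cnt - m^2, 0))
      thr <- m * (1 + p * exp(-q * m) + k * (s / r - 1))
      out[i, j] <- img[i, j] > thr
    }
  }
  out
}

# Exhaustive Otsu: for each of 256 candidate levels, split the raw values and
# maximize between-class variance computed from the raw group means.
oracle_otsu <- function(v, n_levels = 256) {
  cands <- (seq_len(n_levels) - 1) / (n_levels - 1)
  best <- -Inf; best_t <- NA_real_
  for (t in cands) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; best_t <- t }
  }
  best_t
}

# Two-sided paired-t p-value by numerical integration of the t density.
oracle_paired_p <- function(study, fellow) {
  d <- study - fellow
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  df <- n - 1
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  tail <- integrate(dens, abs(tstat), Inf, rel.tol = 1e-12)$value
  list(t = tstat, p = 2 * tail)
}

# 8-connected component count (flood fill on small masks).
oracle_n_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc); cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start; lab[start] <- cur
    while (length(queue)) {
      pp <- queue[length(queue)]; queue <- queue[-length(queue)]
      rr <- ((pp - 1L) %% nr) + 1L; cc <- ((pp - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- rr + dr; c2 <- cc + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        qq <- (c2 - 1L) * nr + r2
        if (mask[qq] && lab[qq] == 0L) { lab[qq] <- cur; queue <- c(queue, qq) }
      }
    }
  }
  cur
}
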