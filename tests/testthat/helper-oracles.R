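# Independent brute-force oracles used across the test files. These are
# deliberately naive pixel-loop implementations, kept separate from the
# package's vectorized code paths.

# plain Gaussian convolution with replicated borders (no brightness term)
oracle_gaussian_conv <- function(m, sigma_s, radius) {
  h <- nrow(m); w <- ncol(m)
  d <- (-radius):radius
  g <- exp(-d^2 / (2 * sigma_s^2))
  K <- outer(g, g); K <- K / sum(K)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (di in d) for (dj in d) {
      ii <- min(max(i + di, 1L), h); jj <- min(max(j + dj, 1L), w)
      acc <- acc + K[di + radius + 1L, dj + radius + 1L] * m[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# full adaptive filter evaluated pixel by pixel straight from its definition
oracle_adaptive_denoise <- function(m, sigma_s, sigma_b, radius, cutoff = Inf) {
  h <- nrow(m); w <- ncol(m)
  d <- (-radius):radius
  g <- exp(-d^2 / (2 * sigma_s^2))
  Ks <- outer(g, g) / (2 * pi * sigma_s^2)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    num <- 0; den <- 0
    for (di in d) for (dj in d) {
      ii <- min(max(i + di, 1L), h); jj <- min(max(j + dj, 1L), w)
      diff <- m[ii, jj] - m[i, j]
      wgt <- Ks[di + radius + 1L, dj + radius + 1L] *
        exp(-diff^2 / (2 * sigma_b^2))
      if (is.finite(cutoff) && abs(diff) > cutoff) wgt <- 0
      num <- num + wgt * m[ii, jj]; den <- den + wgt
    }
    out[i, j] <- if (den > 0) num / den else m[i, j]
  }
  out
}

# phase-1 segmentation path written as explicit pixel loops
oracle_phase1 <- function(img, w1 = 0.4, w2 = 0.6,
                          min_window = 3L, max_window = 7L) {
  h <- dim(img)[1]; w <- dim(img)[2]
  gray <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    gray[i, j] <- (img[i, j, 1] * img[i, j, 2] * img[i, j, 3])^(1 / 3)
  gamma <- (min(gray) * w1 + max(gray) * w2) / (w1 + w2)
  m <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    m[i, j] <- if (gray[i, j] < gamma) 255 else 0
  rank <- function(mask, win, f) {
    r <- (win - 1L) %/% 2L
    out <- mask
    for (i in seq_len(h)) for (j in seq_len(w)) {
      vals <- c()
      for (di in -r:r) for (dj in -r:r) {
        ii <- min(max(i + di, 1L), h); jj <- min(max(j + dj, 1L), w)
        vals <- c(vals, mask[ii, jj])
      }
      out[i, j] <- f(vals)
    }
    out
  }
  m <- rank(m, min_window, min)
  m <- rank(m, max_window, max)
  list(gray = gray, gamma = gamma, mask = m)
}

# classification metrics recomputed directly from two masks
oracle_metrics_from_masks <- function(pred, truth) {
  p <- pred > 0; t <- truth > 0
  tp <- sum(p & t); fn <- sum(!p & t); fp <- sum(p & !t); tn <- sum(!p & !t)
  list(
    sn = tp / (tp + fn), sp = tn / (tn + fp),
    dice = 2 * tp / (2 * tp + fp + fn), jaccard = tp / (tp + fn + fp),
    accuracy = (tp + tn) / (tp + fn + fp + tn),
    precision = tp / (tp + fp),
    mcc = (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
}

# count 8-connected strands of a mask: grow by one pixel (strokes are kept
# at least three pixels apart by the generator) and count 4-connected
# components of the grown mask
count_strands <- function(mask) {
  m <- mask > 0
  grown <- m
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    h <- nrow(m); w <- ncol(m)
    ri <- pmin(pmax(seq_len(h) + di, 1L), h)
    ci <- pmin(pmax(seq_len(w) + dj, 1L), w)
    grown <- grown | m[ri, ci]
  }
  max(EBImage::bwlabel(grown * 1))
}

# small random RGB test image
random_rgb <- function(h, w, seed) {
  set.seed(seed)
  array(runif(h * w * 3, 0, 255), c(h, w, 3))
}
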