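# Adaptive edge-preserving denoising ----------------------------------------
#
# The filter combines a spatial Gaussian kernel with a brightness kernel
# (Gaussian in the intensity difference to the centre pixel), normalized so
# the weights sum to one, plus a hard range cutoff that zeroes the weight of
# any neighbour whose intensity differs from the centre by more than
# `range_cutoff` — this is what preserves lesion edges that plain Gaussian
# smoothing would blur away.

#' Denoising configuration
#'
#' @param sigma_s spatial standard deviation in pixels (> 0).
#' @param sigma_b brightness standard deviation in intensity units (> 0).
#' @param radius kernel half-width in pixels; defaults to `ceiling(2 * sigma_s)`.
#' @param range_cutoff intensity difference beyond which a neighbour's
#'   weight is forced to zero; defaults to `3 * sigma_b`. Use `Inf` to
#'   disable the cutoff.
#' @return object of class `denoise_config`.
#' @export
denoise_config <- function(sigma_s = 2, sigma_b = 30,
                           radius = ceiling(2 * sigma_s),
                           range_cutoff = 3 * sigma_b) {
  if (!is.finite(sigma_s) || sigma_s <= 0) stop("sigma_s must be > 0")
  if (!is.finite(sigma_b) || sigma_b <= 0) stop("sigma_b must be > 0")
  if (radius < 1) stop("radius must be >= 1")
  if (range_cutoff <= 0) stop("range_cutoff must be > 0")
  structure(list(sigma_s = sigma_s, sigma_b = sigma_b,
                 radius = as.integer(radius), range_cutoff = range_cutoff),
            class = "denoise_config")
}

#' Spatial Gaussian kernel
#'
#' The isotropic 2-D Gaussian \eqn{n_{\sigma_s}(x, y) =
#' \frac{1}{2\pi\sigma_s^2} e^{-\frac{x^2 + y^2}{2\sigma_s^2}}} sampled on
#' the integer grid \eqn{[-r, r]^2}.
#'
#' @param cfg a [denoise_config] (or a positive `sigma_s` scalar).
#' @param radius kernel half-width; taken from `cfg` when omitted.
#' @return a `(2 radius + 1)` square matrix of weights.
#' @export
spatial_kernel <- function(cfg, radius = NULL) {
  if (is.numeric(cfg)) cfg <- denoise_config(sigma_s = cfg)
  r <- if (is.null(radius)) cfg$radius else as.integer(radius)
  d <- (-r):r
  g <- exp(-d^2 / (2 * cfg$sigma_s^2))
  outer(g, g) / (2 * pi * cfg$sigma_s^2)
}

#' Edge-preserving adaptive denoise
#'
#' Each output pixel is the normalized sum of its neighbours weighted by
#' the spatial kernel times a brightness Gaussian
#' \eqn{e^{-\Delta^2 / (2\sigma_b^2)}} in the intensity difference
#' \eqn{\Delta}; neighbours with \eqn{|\Delta|} beyond the range cutoff get
#' weight zero. Exact on constant images; converges to plain Gaussian
#' smoothing as `sigma_b` grows with the cutoff disabled. Borders are
#' handled by edge replication. RGB input is filtered per channel.
#'
#' @param img gray matrix or RGB array on [0, 255].
#' @param cfg a [denoise_config].
#' @return denoised image of the same kind, on [0, 255].
#' @export
denoise <- function(img, cfg = denoise_config()) {
  if (is.matrix(img)) return(.denoise_channel(img, cfg))
  assert_rgb(img)
  out <- img
  for (ch in 1:3) out[, , ch] <- .denoise_channel(img[, , ch], cfg)
  out
}

.denoise_channel <- function(m, cfg) {
  r <- cfg$radius
  sk <- spatial_kernel(cfg)
  two_sb2 <- 2 * cfg$sigma_b^2
  num <- m * sk[r + 1L, r + 1L]        # centre term: diff 0, brightness wt 1
  den <- matrix(sk[r + 1L, r + 1L], nrow(m), ncol(m))
  for (di in -r:r) for (dj in -r:r) {
    if (di == 0L && dj == 0L) next
    neigh <- shift_replicate(m, di, dj)
    d <- neigh - m
    w <- sk[di + r + 1L, dj + r + 1L] * exp(-d^2 / two_sb2)
    if (is.finite(cfg$range_cutoff)) w[abs(d) > cfg$range_cutoff] <- 0
    num <- num + w * neigh
    den <- den + w
  }
  out <- num / den
  bad <- !is.finite(out)               # pathological cutoff: keep the pixel
  if (any(bad)) out[bad] <- m[bad]
  clip255(out)
}
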