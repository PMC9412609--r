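# Two-phase lesion segmentation ----------------------------------------------
#
# Phase 1: unify the channels by geometric mean, threshold at the weighted
# combination of the intensity extremes (the lesion is the darker side),
# clean the mask with a 3x3 sliding minimum then a 7x7 sliding maximum and
# keep the largest component. Phase 2: the pixels in a band around the
# phase-1 boundary are ambiguous; their darkness is normalized over the
# band and each is kept or discarded against the pentagonal-neutrosophic
# threshold.

#' Unify the three channels into one
#'
#' Per-pixel cube root of the product of the channel values, on [0, 255].
#'
#' @param img RGB array on [0, 255].
#' @return gray matrix on [0, 255].
#' @examples
#' unify_channels(array(c(64, 125, 216), c(1, 1, 3))) # 120
#' @export
unify_channels <- function(img) geom_mean_channels(img)

#' Weighted global threshold
#'
#' \eqn{\gamma = (I_{min} w_1 + I_{max} w_2) / (w_1 + w_2)} over the image
#' intensity extremes; with the default weights 0.4 and 0.6 the threshold
#' sits 60% of the way from the minimum to the maximum.
#'
#' @param gray non-empty gray matrix.
#' @param w1 weight on the minimum (default 0.4).
#' @param w2 weight on the maximum (default 0.6).
#' @return the threshold, a scalar within \[Imin, Imax\].
#' @export
global_threshold <- function(gray, w1 = 0.4, w2 = 0.6) {
  assert_gray(gray)
  if (length(gray) == 0) stop("empty image", call. = FALSE)
  if (w1 <= 0 || w2 <= 0) stop("weights must be positive", call. = FALSE)
  (min(gray) * w1 + max(gray) * w2) / (w1 + w2)
}

#' Initial (phase-1) mask from the global threshold
#'
#' The lesion is darker than the surrounding skin, so a pixel joins the
#' mask when its unified intensity is strictly below the threshold.
#'
#' @param gray gray matrix.
#' @param gamma finite threshold.
#' @return binary mask (0/255).
#' @export
initial_mask <- function(gray, gamma) {
  if (!is.finite(gamma)) stop("gamma must be finite", call. = FALSE)
  (gray < gamma) * 255
}

#' Sliding-minimum pass over a binary mask
#'
#' Dense window minimum (binary erosion with the full square window),
#' borders replicated; removes isolated foreground speckle.
#'
#' @param mask binary mask (0/255).
#' @param window odd window size (default 3).
#' @return binary mask.
#' @export
min_pass <- function(mask, window = 3L) {
  assert_mask(mask)
  rank_filter(mask, window, "min")
}

#' Sliding-maximum pass over a binary mask
#'
#' Dense window maximum (binary dilation with the full square window),
#' borders replicated; restores and consolidates the eroded lesion body.
#'
#' @param mask binary mask (0/255).
#' @param window odd window size (default 7).
#' @return binary mask.
#' @export
max_pass <- function(mask, window = 7L) {
  assert_mask(mask)
  rank_filter(mask, window, "max")
}

#' Boundary band of a mask
#'
#' The ring of pixels within `width` (Chebyshev distance) of the mask's
#' inner boundary — the 8-connected foreground pixels adjacent to
#' background. For this purpose the image is treated as surrounded by
#' background, so a full-image mask yields a band along the image border.
#' These are the ambiguous pixels handed to phase 2.
#'
#' @param mask binary mask (0/255).
#' @param width band half-width in pixels (>= 1).
#' @return binary mask of the band.
#' @export
boundary_band <- function(mask, width = 5L) {
  assert_mask(mask)
  if (width < 1L) stop("width must be >= 1", call. = FALSE)
  fg <- mask > 0
  if (!any(fg)) return(mask * 0)
  # erosion with background padding: a border pixel always has an outside
  # neighbour, so it belongs to the boundary
  h <- nrow(fg); w <- ncol(fg)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- fg
  er <- pad[2:(h + 1L), 2:(w + 1L)]
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    er <- er & pad[2:(h + 1L) + di, 2:(w + 1L) + dj]
  }
  band <- fg & !er
  if (width > 1L) {
    b <- band * 1
    r <- width - 1L
    for (di in -r:r) for (dj in -r:r) {
      if (di == 0L && dj == 0L) next
      b <- pmax(b, shift_replicate(band * 1, di, dj))
    }
    band <- b > 0
  }
  band * 255
}

#' Phase-2 pentagonal-neutrosophic refinement
#'
#' Pixels outside the band keep their phase-1 label. Band pixel
#' intensities are normalized to a darkness score
#' `(band_max - intensity) / (band_max - band_min)` in \[0, 1\] (so dark,
#' lesion-like pixels score high); a band pixel is kept iff its score is
#' at least the pentagonal threshold. When no explicit quintuple is given
#' the five components default to the 10/30/50/70/90th percentiles of the
#' band's own darkness distribution — a data-adaptive, generally
#' asymmetric pentagon. A degenerate band (all equal intensity) keeps its
#' phase-1 labels.
#'
#' @param gray unified gray image.
#' @param phase1 phase-1 binary mask.
#' @param band boundary-band binary mask.
#' @param spec a [pnn_spec], a linguistic term (string), or `NULL` for the
#'   percentile default.
#' @param pi_deg,sigma_deg,mu_deg degrees used when `spec` is `NULL` or a
#'   linguistic term.
#' @return binary mask with attributes `theta` (the threshold used, on the
#'   normalized darkness scale) and `band_pixels`.
#' @export
refine <- function(gray, phase1, band, spec = NULL,
                   pi_deg = 0.9, sigma_deg = 0.3, mu_deg = 0.2) {
  stopifnot(all(dim(gray) == dim(phase1)), all(dim(gray) == dim(band)))
  out <- phase1
  idx <- band > 0
  nb <- sum(idx)
  if (nb == 0L) {
    attr(out, "theta") <- NA_real_; attr(out, "band_pixels") <- 0L
    return(out)
  }
  v <- gray[idx]
  rng <- range(v)
  if (diff(rng) == 0) {                    # degenerate band
    attr(out, "theta") <- NA_real_; attr(out, "band_pixels") <- nb
    return(out)
  }
  darkness <- (rng[2] - v) / (rng[2] - rng[1])
  if (is.null(spec)) {
    m <- unname(quantile(darkness, c(.1, .3, .5, .7, .9), type = 7))
    spec <- pnn_spec(m, pi_deg, sigma_deg, mu_deg)
  } else if (is.character(spec)) {
    spec <- linguistic_to_pnn(spec, pi_deg = pi_deg, sigma_deg = sigma_deg,
                              mu_deg = mu_deg)
  }
  theta <- pnn_threshold(spec)
  out[idx] <- ifelse(darkness >= theta, 255, 0)
  attr(out, "theta") <- theta
  attr(out, "band_pixels") <- nb
  out
}

#' Segmentation configuration
#'
#' @param w1,w2 weights of the global threshold (defaults 0.4 and 0.6).
#' @param band_width boundary-band half-width in pixels (default 5).
#' @param pnn `NULL` (data-adaptive percentile pentagon), a linguistic
#'   term, or a [pnn_spec].
#' @param min_window,max_window odd windows of the two morphological
#'   passes (defaults 3 and 7).
#' @param keep_largest keep only the largest connected foreground
#'   component after the maximum pass (default TRUE).
#' @param pi_deg,sigma_deg,mu_deg degrees of the pentagonal threshold.
#' @return object of class `seg_config`.
#' @export
seg_config <- function(w1 = 0.4, w2 = 0.6, band_width = 5L, pnn = NULL,
                       min_window = 3L, max_window = 7L,
                       keep_largest = TRUE,
                       pi_deg = 0.9, sigma_deg = 0.3, mu_deg = 0.2) {
  if (w1 <= 0 || w2 <= 0) stop("weights must be positive")
  if (band_width < 1) stop("band_width must be >= 1")
  if (min_window %% 2 != 1 || max_window %% 2 != 1)
    stop("windows must be odd")
  structure(list(w1 = w1, w2 = w2, band_width = as.integer(band_width),
                 pnn = pnn, min_window = as.integer(min_window),
                 max_window = as.integer(max_window),
                 keep_largest = keep_largest, pi_deg = pi_deg,
                 sigma_deg = sigma_deg, mu_deg = mu_deg),
            class = "seg_config")
}

#' Two-phase lesion segmentation
#'
#' Orchestrates channel unification, the weighted global threshold, the
#' initial mask, the 3x3 minimum and 7x7 maximum passes (plus the
#' largest-component filter), the boundary band, and the
#' pentagonal-neutrosophic refinement. Deterministic for a fixed
#' configuration.
#'
#' @param img pre-processed RGB array on [0, 255].
#' @param cfg a [seg_config].
#' @return object of class `derm_segmentation` with elements
#'   `phase1_mask`, `final_mask`, `band` (all 0/255), `gamma` (global
#'   threshold, intensity units), `theta` (pentagonal threshold on the
#'   normalized band-darkness scale; `NA` for an empty/degenerate band),
#'   `band_pixels`, and `config`.
#' @export
segment <- function(img, cfg = seg_config()) {
  assert_rgb(img)
  gray <- unify_channels(img)
  gamma <- global_threshold(gray, cfg$w1, cfg$w2)
  m <- initial_mask(gray, gamma)
  m <- min_pass(m, cfg$min_window)
  m <- max_pass(m, cfg$max_window)
  if (cfg$keep_largest && any(m > 0)) {
    lab <- EBImage::bwlabel((m > 0) * 1)
    areas <- tabulate(lab[lab > 0])
    m <- (matrix(lab == which.max(areas), nrow(m), ncol(m))) * 255
  }
  band <- boundary_band(m, cfg$band_width)
  final <- refine(gray, m, band, spec = cfg$pnn, pi_deg = cfg$pi_deg,
                  sigma_deg = cfg$sigma_deg, mu_deg = cfg$mu_deg)
  theta <- attr(final, "theta"); nb <- attr(final, "band_pixels")
  attributes(final) <- list(dim = dim(final))
  structure(list(phase1_mask = m, final_mask = final, band = band,
                 gamma = gamma, theta = theta, band_pixels = nb,
                 config = cfg),
            class = "derm_segmentation")
}

#' @export
print.derm_segmentation <- function(x, ...) {
  cat("Two-phase dermoscopic lesion segmentation\n")
  cat(sprintf("  image: %d x %d px\n", nrow(x$final_mask), ncol(x$final_mask)))
  cat(sprintf("  global threshold gamma: %.2f (intensity units)\n", x$gamma))
  if (is.na(x$theta))
    cat("  pentagonal threshold theta: not applied (empty/degenerate band)\n")
  else
    cat(sprintf("  pentagonal threshold theta: %.4f (normalized darkness)\n",
                x$theta))
  cat(sprintf("  boundary band: %d px\n", x$band_pixels))
  cat(sprintf("  lesion area: %d px (%.2f%% of image)\n",
              sum(x$final_mask > 0), 100 * mean(x$final_mask > 0)))
  invisible(x)
}

#' @export
summary.derm_segmentation <- function(object, truth = NULL, ...) {
  res <- list(gamma = object$gamma, theta = object$theta,
              band_pixels = object$band_pixels,
              phase1_area = sum(object$phase1_mask > 0),
              final_area = sum(object$final_mask > 0))
  if (!is.null(truth)) {
    cc <- confusion_from_masks(object$final_mask, truth)
    res$metrics <- classification_metrics(cc)
  }
  structure(res, class = "summary.derm_segmentation")
}

#' @export
print.summary.derm_segmentation <- function(x, ...) {
  cat(sprintf("gamma = %.2f, theta = %s, band = %d px\n", x$gamma,
              ifelse(is.na(x$theta), "NA", sprintf("%.4f", x$theta)),
              x$band_pixels))
  cat(sprintf("phase-1 area = %d px, final area = %d px\n",
              x$phase1_area, x$final_area))
  if (!is.null(x$metrics)) {
    p <- x$metrics$percent
    cat(sprintf("vs truth: Dice %.2f%%, Jaccard %.2f%%, Sn %.2f%%, Sp %.2f%%\n",
                p[["dice"]], p[["jaccard"]], p[["sn"]], p[["sp"]]))
  }
  invisible(x)
}

#' Plot a segmentation result
#'
#' Renders the image (or unified gray channel) with the final mask
#' contour overlaid.
#'
#' @param x a `derm_segmentation`.
#' @param img optional RGB array to draw under the contour.
#' @param ... ignored.
#' @export
plot.derm_segmentation <- function(x, img = NULL, ...) {
  mask <- x$final_mask
  h <- nrow(mask); w <- ncol(mask)
  op <- par(mar = c(1, 1, 2, 1)); on.exit(par(op))
  plot(0, 0, type = "n", xlim = c(0, w), ylim = c(0, h), asp = 1,
       axes = FALSE, xlab = "", ylab = "",
       main = "lesion segmentation")
  if (!is.null(img)) {
    rasterImage(clip255(img) / 255, 0, 0, w, h)
  }
  edge <- boundary_band(mask, 1L)
  ij <- which(edge > 0, arr.ind = TRUE)
  if (nrow(ij)) points(ij[, 2], h - ij[, 1] + 1, pch = ".", col = "red")
  invisible(x)
}
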