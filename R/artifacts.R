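# Digital artifact removal ---------------------------------------------------
#
# Hair strands, dermoscopic ruler ticks and dark frames are dark,
# curvilinear or border-hugging structures on a lighter background. They
# are picked up by a morphological black-hat transform on the monochrome
# image, filtered by a thinness test that relegates compact blobs (the
# lesion itself) to background, grown to full strand width by alternating
# dilation and smoothing, and finally painted over from the surrounding
# skin by distance-weighted inpainting.

#' Convert an RGB image to monochrome
#'
#' Per-pixel geometric mean of the three channels — the same channel
#' unification rule the segmentation phase uses, kept identical across the
#' pipeline for consistency.
#'
#' @param img RGB array on [0, 255].
#' @return gray matrix on [0, 255].
#' @examples
#' to_monochrome(array(c(64, 125, 216), c(1, 1, 3))) # 120
#' @export
to_monochrome <- function(img) geom_mean_channels(img)

#' Detect hair, ruler and frame artifacts
#'
#' The monochrome image is binarized against a local-contrast criterion
#' (black-hat response above mean + 2 sd); connected components survive
#' only if thin and elongated (`area >= 4 * width^2` with the width read
#' off the distance transform, at least `min_area` pixels, and at most
#' `max_area_frac` of the image) — compact regular blocks are background.
#' The surviving mask is alternately dilated (3x3 cross) and mean-smoothed
#' to cover full strand width. Dark regions touching the image border
#' (frames, corner vignettes) are flagged separately.
#'
#' @param img RGB array on [0, 255].
#' @param se_size black-hat structuring-element size (odd; should exceed
#'   the widest strand).
#' @param rounds dilate/smooth rounds applied to the surviving mask.
#' @param min_area minimum component area in pixels.
#' @param max_area_frac maximum component area as a fraction of the image.
#' @param dark_level intensity below which border-touching regions count
#'   as frame.
#' @param min_contrast absolute black-hat floor in intensity units: a
#'   candidate pixel must sit at least this far below its morphological
#'   closing, so the adaptive threshold cannot collapse onto noise on an
#'   already-clean image.
#' @return binary mask (0/255), 255 = artifact pixel; empty on clean images.
#' @export
detect_artifacts <- function(img, se_size = 11L, rounds = 2L,
                             min_area = 25L, max_area_frac = 0.05,
                             dark_level = 60, min_contrast = 10) {
  g <- to_monochrome(img)
  npix <- length(g)

  # black-hat: closing minus image highlights dark structures thinner
  # than the structuring element
  closed <- rank_filter(rank_filter(g, se_size, "max"), se_size, "min")
  bh <- closed - g
  s <- sd(bh)
  thr <- max(mean(bh) + 2 * s, min_contrast)
  cand <- bh > thr

  keep <- matrix(FALSE, nrow(g), ncol(g))
  if (any(cand)) {
    lab <- .label8(cand)
    dm <- EBImage::distmap(cand * 1)
    areas <- tabulate(lab[lab > 0])
    width_est <- vapply(seq_along(areas), function(k) {
      2 * max(dm[lab == k]) - 1
    }, numeric(1))
    ok <- areas >= min_area & areas <= max_area_frac * npix &
      areas >= 4 * width_est^2
    keep <- matrix(lab %in% which(ok), nrow(g), ncol(g))
    # hysteresis: a strand stays continuous even where its contrast drops
    # (e.g. crossing the dark lesion), so extend every surviving strong
    # component through the connected weak black-hat response
    if (any(keep)) {
      weak <- (bh > max(mean(bh) + 0.5 * s, min_contrast / 2)) | keep
      labw <- .label8(weak)
      areasw <- tabulate(labw[labw > 0])
      hit <- unique(labw[keep])
      hit <- hit[hit > 0 & areasw[hit] <= max_area_frac * npix]
      if (length(hit))
        keep <- keep | matrix(labw %in% hit, nrow(g), ncol(g))
    }
  }

  # frame / border-touching dark bands: dark pixels inside a border zone
  # whose connected component actually reaches the image border (keeps a
  # dark lesion that merely extends towards the edge out of the frame mask)
  margin <- max(2L, floor(0.15 * min(dim(g))))
  zone <- matrix(FALSE, nrow(g), ncol(g))
  zone[c(seq_len(margin), nrow(g) - seq_len(margin) + 1L), ] <- TRUE
  zone[, c(seq_len(margin), ncol(g) - seq_len(margin) + 1L)] <- TRUE
  dark <- (g < dark_level) & zone
  if (any(dark)) {
    labd <- .label8(dark)
    border_ids <- unique(c(labd[1, ], labd[nrow(g), ], labd[, 1], labd[, ncol(g)]))
    border_ids <- setdiff(border_ids, 0)
    if (length(border_ids)) {
      areasd <- tabulate(labd[labd > 0])
      big <- border_ids[areasd[border_ids] >= 0.002 * npix]
      if (length(big)) keep <- keep | matrix(labd %in% big, nrow(g), ncol(g))
    }
  }

  # alternate dilation (cross) and mean smoothing to full strand width
  m <- keep * 1
  if (any(m > 0)) {
    for (i in seq_len(rounds)) {
      m <- pmax(m, shift_replicate(m, 1L, 0L), shift_replicate(m, -1L, 0L),
                shift_replicate(m, 0L, 1L), shift_replicate(m, 0L, -1L))
      sm <- (m + shift_replicate(m, 1L, 0L) + shift_replicate(m, -1L, 0L) +
               shift_replicate(m, 0L, 1L) + shift_replicate(m, 0L, -1L) +
               shift_replicate(m, 1L, 1L) + shift_replicate(m, 1L, -1L) +
               shift_replicate(m, -1L, 1L) + shift_replicate(m, -1L, -1L)) / 9
      m <- (sm >= 0.5) * 1
    }
  }
  m * 255
}

#' Inpaint masked pixels from their surroundings
#'
#' Every flagged pixel is replaced by an inverse-distance-weighted average
#' of nearby non-flagged pixels, searched over expanding radii (up to
#' `max_radius`); only original, unflagged pixels contribute. Pixels a
#' large mask leaves unreached are filled by iterative propagation from
#' already-inpainted neighbours. Unflagged pixels are returned unchanged.
#'
#' @param img RGB array (or gray matrix) on [0, 255].
#' @param mask binary mask (0/255) of pixels to replace.
#' @param max_radius largest search radius in pixels.
#' @return image of the same kind with flagged pixels filled.
#' @export
inpaint <- function(img, mask, max_radius = 15L) {
  gray_in <- is.matrix(img)
  if (gray_in) img <- array(rep(img, 3L), c(dim(img), 3L))
  assert_rgb(img)
  if (!all(dim(mask) == dim(img)[1:2])) stop("mask shape mismatch", call. = FALSE)
  flagged <- mask > 0
  if (!any(flagged)) return(if (gray_in) img[, , 1L] else img)
  if (all(flagged)) stop("mask covers the whole image; nothing to inpaint from",
                         call. = FALSE)
  known <- (!flagged) * 1
  out <- img
  unfilled <- flagged
  for (r in unique(pmin(c(3L, 7L, max_radius), max_radius))) {
    if (!any(unfilled)) break
    K <- .ring_kernel(r)
    den <- EBImage::filter2(known, K, boundary = "replicate")
    fill <- unfilled & den > 1e-8
    if (any(fill)) {
      for (ch in 1:3) {
        num <- EBImage::filter2(img[, , ch] * known, K, boundary = "replicate")
        v <- out[, , ch]; v[fill] <- num[fill] / den[fill]; out[, , ch] <- v
      }
      unfilled <- unfilled & !fill
    }
  }
  # propagate into any remaining deep interior from already-filled pixels
  guard <- 0L
  K <- .ring_kernel(max_radius)
  while (any(unfilled) && guard < 100L) {
    guard <- guard + 1L
    kn <- (!unfilled) * 1
    den <- EBImage::filter2(kn, K, boundary = "replicate")
    fill <- unfilled & den > 1e-8
    if (!any(fill)) break
    for (ch in 1:3) {
      num <- EBImage::filter2(out[, , ch] * kn, K, boundary = "replicate")
      v <- out[, , ch]; v[fill] <- num[fill] / den[fill]; out[, , ch] <- v
    }
    unfilled <- unfilled & !fill
  }
  out <- clip255(out)
  if (gray_in) out[, , 1L] else out
}

# 8-connected component labels: label the 1-px-grown mask (which joins
# diagonal chains) and keep labels on the original pixels only
.label8 <- function(mask) {
  grown <- mask
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    grown <- grown | shift_replicate(mask, di, dj)
  }
  lab <- EBImage::bwlabel(grown * 1)
  lab[!mask] <- 0
  lab
}

# inverse-Euclidean-distance kernel of radius r, zero centre
.ring_kernel <- function(r) {
  d <- (-r):r
  dist <- sqrt(outer(d^2, d^2, "+"))
  K <- ifelse(dist > 0 & dist <= r, 1 / dist, 0)
  K
}
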