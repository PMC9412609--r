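# Synthetic dermoscopy scenes -------------------------------------------------
#
# Seeded generator of dermoscopy-like scenes with paired ground truth: a
# darker, ameboid lesion (concentric shade bands from dark centre to
# lighter rim) on lighter skin, optional hair strands (random cubic Bezier
# strokes), ruler tick marks, a dark circular frame, and additive Gaussian
# noise. Every stage of the pipeline is testable against these scenes
# without any external dataset.

#' Scene specification for the synthetic generator
#'
#' @param size image edge length in pixels.
#' @param skin_tone RGB triple of the background skin.
#' @param lesion_shades matrix (k x 3, 2-5 rows) of RGB shades from the
#'   lesion centre (row 1, darkest) outwards; every shade must be darker
#'   (lower geometric-mean intensity) than the skin.
#' @param lesion_radius_frac lesion radius as a fraction of `size`, in
#'   (0, 0.45].
#' @param boundary_irregularity amplitude of the radial perturbation, in
#'   \[0, 1).
#' @param n_hairs number of hair strands (>= 0).
#' @param ruler draw ruler tick marks along the top edge.
#' @param frame draw a dark circular frame (corner vignette).
#' @param noise_sigma standard deviation of the additive Gaussian noise in
#'   intensity units (>= 0).
#' @param seed integer seed; the scene is fully determined by it.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(size = 512L,
                       skin_tone = c(205, 165, 145),
                       lesion_shades = default_lesion_shades(),
                       lesion_radius_frac = 0.25,
                       boundary_irregularity = 0.15,
                       n_hairs = 0L, ruler = FALSE, frame = FALSE,
                       noise_sigma = 0, seed = 1L) {
  lesion_shades <- rbind(lesion_shades)
  if (nrow(lesion_shades) < 2L || nrow(lesion_shades) > 5L)
    stop("lesion_shades must have 2-5 rows", call. = FALSE)
  gm <- function(v) prod(v)^(1 / 3)
  if (any(apply(lesion_shades, 1, gm) >= gm(skin_tone)))
    stop("every lesion shade must be darker than the skin tone", call. = FALSE)
  if (lesion_radius_frac <= 0 || lesion_radius_frac > 0.45)
    stop("lesion_radius_frac must lie in (0, 0.45]", call. = FALSE)
  if (boundary_irregularity < 0 || boundary_irregularity >= 1)
    stop("boundary_irregularity must lie in [0, 1)", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(list(size = as.integer(size), skin_tone = skin_tone,
                 lesion_shades = lesion_shades,
                 lesion_radius_frac = lesion_radius_frac,
                 boundary_irregularity = boundary_irregularity,
                 n_hairs = as.integer(n_hairs), ruler = isTRUE(ruler),
                 frame = isTRUE(frame), noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Default lesion shade palette
#'
#' Five shades spanning dark brown (centre) to bluish grey (rim), all
#' darker than typical skin.
#'
#' @return 5 x 3 matrix of RGB values.
#' @export
default_lesion_shades <- function() {
  rbind(c(55, 42, 52),     # darkest, bluish-brown centre
        c(72, 52, 55),
        c(88, 64, 62),
        c(105, 78, 72),
        c(122, 95, 92))    # lightest rim, still well below skin
}

#' Generate a synthetic dermoscopy scene
#'
#' The lesion boundary is a circle radially perturbed by a low-order
#' random Fourier series scaled by the irregularity amplitude; the
#' interior is filled with concentric shade bands. Hairs are random cubic
#' Bezier strokes of width 1-5 px (rejection-sampled so strands do not
#' touch each other); ruler ticks are evenly spaced dark marks along the
#' top edge; the frame is a dark circular vignette. Gaussian noise is
#' added last and the image clipped to \[0, 255\] and rounded to 8-bit
#' levels. Fully determined by the spec's seed.
#'
#' @param spec a [scene_spec].
#' @return object of class `lesion_sample`: list with `image` (RGB, with
#'   artifacts and noise), `clean` (RGB, lesion + skin only),
#'   `lesion_mask`, `hair_mask`, `artifact_mask` (hair, ruler and frame
#'   combined; all masks 0/255), and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  n <- spec$size
  cx <- (n + 1) / 2; cy <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  dx <- rows - cx; dy <- cols - cy
  dist <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)

  # ameboid boundary: low-order Fourier perturbation of the radius
  r0 <- spec$lesion_radius_frac * n
  if (spec$boundary_irregularity > 0) {
    amp <- rnorm(4)
    amp <- amp / sum(abs(amp))                 # total perturbation <= 1
    phase <- runif(4, 0, 2 * pi)
    pert <- Reduce(`+`, lapply(1:4, function(k)
      amp[k] * cos((k + 1) * theta + phase[k])))
    rtheta <- r0 * (1 + spec$boundary_irregularity * pert)
  } else {
    rtheta <- matrix(r0, n, n)
  }
  rtheta <- pmin(pmax(rtheta, 0.4 * r0), 0.45 * n)
  lesion <- dist < rtheta

  # concentric shade bands, darkest at the centre
  k <- nrow(spec$lesion_shades)
  img <- array(0, c(n, n, 3L))
  for (ch in 1:3) img[, , ch] <- spec$skin_tone[ch]
  frac <- dist / rtheta
  band <- pmin(floor(frac * k) + 1L, k)
  for (ch in 1:3) {
    v <- img[, , ch]
    v[lesion] <- spec$lesion_shades[band[lesion], ch]
    img[, , ch] <- v
  }
  clean <- img

  hair_mask <- matrix(FALSE, n, n)
  if (spec$n_hairs > 0L) {
    placed <- 0L; tries <- 0L
    # strands of one scene share a growth direction (as real hair does)
    # and must stay clearly apart: demand a 3-px gap to placed ones
    angle0 <- runif(1, 0, pi)
    while (placed < spec$n_hairs && tries < 200L) {
      tries <- tries + 1L
      stroke <- .bezier_stroke(n, width = sample(1:5, 1L), angle = angle0)
      grown <- .grow_mask(stroke, 3L)
      if (!any(grown & hair_mask)) {
        hair_mask <- hair_mask | stroke
        shade <- runif(1, 12, 35)
        for (ch in 1:3) {
          v <- img[, , ch]; v[stroke] <- shade * runif(1, 0.9, 1.1)
          img[, , ch] <- v
        }
        placed <- placed + 1L
      }
    }
    if (placed < spec$n_hairs)
      warning("placed only ", placed, " of ", spec$n_hairs, " hair strands")
  }

  ruler_mask <- matrix(FALSE, n, n)
  if (spec$ruler) {
    xs <- seq(24L, n - 24L, by = 16L)
    for (x in xs) {
      ruler_mask[6:20, x + (0:1)] <- TRUE
    }
    for (ch in 1:3) {
      v <- img[, , ch]; v[ruler_mask] <- 18; img[, , ch] <- v
    }
  }

  frame_mask <- matrix(FALSE, n, n)
  if (spec$frame) {
    frame_mask <- dist > 0.52 * n
    for (ch in 1:3) {
      v <- img[, , ch]; v[frame_mask] <- 10; img[, , ch] <- v
    }
  }

  if (spec$noise_sigma > 0) {
    img <- img + array(rnorm(length(img), 0, spec$noise_sigma), dim(img))
  }
  img <- round(clip255(img))

  structure(list(image = img, clean = clean,
                 lesion_mask = lesion * 255,
                 hair_mask = hair_mask * 255,
                 artifact_mask = (hair_mask | ruler_mask | frame_mask) * 255,
                 spec = spec),
            class = "lesion_sample")
}

# one cubic Bezier stroke rasterized onto an n x n logical matrix; the
# stroke runs roughly along `angle` with a random lateral offset and
# gently jittered control points
.bezier_stroke <- function(n, width = 2L, angle = runif(1, 0, pi)) {
  dir <- c(cos(angle), sin(angle))
  perp <- c(-dir[2], dir[1])
  centre <- (n + 1) / 2 + perp * runif(1, -0.38, 0.38) * n +
    dir * runif(1, -0.1, 0.1) * n
  half <- runif(1, 0.35, 0.55) * n
  p <- rbind(centre - dir * half,
             centre - dir * half / 3 + perp * runif(1, -.08, .08) * n,
             centre + dir * half / 3 + perp * runif(1, -.08, .08) * n,
             centre + dir * half)
  p <- pmin(pmax(p, 0.02 * n), 0.98 * n)
  t <- seq(0, 1, length.out = 4L * n)
  b <- outer((1 - t)^3, p[1, ]) + outer(3 * (1 - t)^2 * t, p[2, ]) +
    outer(3 * (1 - t) * t^2, p[3, ]) + outer(t^3, p[4, ])
  m <- matrix(FALSE, n, n)
  r <- max(0L, floor((width - 1L) / 2L))
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 <= (width / 2)^2 | (offs$di == 0 & offs$dj == 0), ]
  ri <- round(b[, 1]); ci <- round(b[, 2])
  for (o in seq_len(nrow(offs))) {
    rr <- ri + offs$di[o]; cc <- ci + offs$dj[o]
    ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
    m[cbind(rr[ok], cc[ok])] <- TRUE
  }
  m
}

.grow_mask <- function(m, r) {
  out <- m
  for (di in -r:r) for (dj in -r:r) {
    if (di == 0L && dj == 0L) next
    out <- out | shift_replicate(m, di, dj)
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Rotate a sample by an exact multiple of 90 degrees
#'
#' Image and all masks are co-rotated on the pixel grid (no
#' interpolation), so mask cardinality is preserved exactly.
#'
#' @param sample a `lesion_sample`.
#' @param k quarter turns.
#' @return rotated `lesion_sample`.
#' @export
rotate_sample <- function(sample, k = 1L) {
  out <- sample
  for (f in c("image", "clean")) out[[f]] <- rotate90(sample[[f]], k)
  for (f in c("lesion_mask", "hair_mask", "artifact_mask"))
    out[[f]] <- rotate90(sample[[f]], k)
  out
}

#' Augmented training-set size under the rotation scheme
#'
#' Each image contributes itself plus its 90/180/270-degree rotations, so
#' the training count quadruples (e.g. 25881 becomes 103524).
#'
#' @param n original image count.
#' @return augmented count, `4 * n`.
#' @export
augmented_count <- function(n) 4L * as.integer(n)

#' Augment a set of samples by 90-degree rotations
#'
#' Returns the originals followed by their three rotations (output length
#' is four times the input length), with masks co-rotated. Additive
#' Gaussian noise of `noise_sigma` intensity units is injected into the
#' rotated copies (seeded from each sample's own seed, so the result is
#' reproducible); set it to 0 for pure rotation.
#'
#' @param samples non-empty list of `lesion_sample` objects.
#' @param noise_sigma noise injected into rotated copies.
#' @return list of `4 * length(samples)` samples.
#' @export
augment <- function(samples, noise_sigma = 8) {
  if (!length(samples)) stop("empty input", call. = FALSE)
  out <- vector("list", 4L * length(samples))
  i <- 1L
  for (s in samples) {
    out[[i]] <- s; i <- i + 1L
    for (k in 1:3) {
      r <- rotate_sample(s, k)
      if (noise_sigma > 0) {
        old <- .Random.seed_save()
        set.seed((s$spec$seed * 7L + k) %% .Machine$integer.max)
        r$image <- round(clip255(r$image +
          array(rnorm(length(r$image), 0, noise_sigma), dim(r$image))))
        .Random.seed_restore(old)
      }
      out[[i]] <- r; i <- i + 1L
    }
  }
  out
}

#' Default synthetic evaluation suite
#'
#' `n` scenes spanning a fixed difficulty grid (boundary irregularity x
#' artifact load x noise level x lesion size), reproducible from the
#' master seed. The grid always includes at least one artifact-free scene
#' and one scene carrying hairs, ruler and frame together.
#'
#' @param n number of scenes (>= 1).
#' @param master_seed integer master seed; per-scene seeds are derived
#'   from (master seed, scene index) so the suite is stable under
#'   reordering.
#' @return list of `lesion_sample` objects.
#' @export
default_suite <- function(n = 20L, master_seed = 42L) {
  stopifnot(n >= 1)
  irr <- c(0, 0.15, 0.3)
  art <- 0:2                 # none; hairs; hairs + ruler + frame
  noi <- c(0, 6)
  rad <- c(0.18, 0.25, 0.32)
  grid <- expand.grid(irr = irr, art = art, noi = noi)
  lapply(seq_len(n), function(i) {
    g <- grid[(i - 1L) %% nrow(grid) + 1L, ]
    sd_i <- (master_seed * 7919L + i * 104729L) %% 2147483647L
    spec <- scene_spec(
      size = 512L,
      lesion_radius_frac = rad[(i - 1L) %% 3L + 1L],
      boundary_irregularity = g$irr,
      n_hairs = if (g$art >= 1) 3L + (i %% 3L) else 0L,
      ruler = g$art == 2, frame = g$art == 2,
      noise_sigma = g$noi, seed = sd_i)
    generate_scene(spec)
  })
}

#' Write a suite of scenes to disk
#'
#' Writes `scene_####.png`, `scene_####_mask.png`, `scene_####_hair.png`
#' per scene plus a `manifest.csv` echoing every spec field.
#'
#' @param samples list of `lesion_sample` objects.
#' @param dir output directory (created if missing).
#' @return the manifest data frame, invisibly.
#' @export
write_suite <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    stem <- sprintf("scene_%04d", i)
    write_image(s$image, file.path(dir, paste0(stem, ".png")))
    write_image(s$lesion_mask, file.path(dir, paste0(stem, "_mask.png")))
    write_image(s$hair_mask, file.path(dir, paste0(stem, "_hair.png")))
    sp <- s$spec
    data.frame(scene = stem, size = sp$size,
               lesion_radius_frac = sp$lesion_radius_frac,
               boundary_irregularity = sp$boundary_irregularity,
               n_hairs = sp$n_hairs, ruler = sp$ruler, frame = sp$frame,
               noise_sigma = sp$noise_sigma, seed = sp$seed)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
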