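#' @importFrom EBImage bwlabel distmap filter2 resize readImage imageData
#' @importFrom stats quantile rnorm runif sd
#' @importFrom graphics par rasterImage points
#' @importFrom utils write.csv
NULL

# Raster conventions used throughout the package:
#  * grayscale image: numeric H x W matrix on [0, 255]
#  * RGB image:       numeric H x W x 3 array on [0, 255], channels R,G,B
#  * binary mask:     numeric H x W matrix with values in {0, 255}, 255 = fg
# Row 1 is the top image row; indices are 1-based (R convention).

#' Validate an RGB image array
#'
#' @param img object to check.
#' @return `img`, invisibly; errors if not an H x W x 3 numeric array.
#' @keywords internal
assert_rgb <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected an H x W x 3 RGB array", call. = FALSE)
  invisible(img)
}

assert_gray <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("expected a numeric H x W matrix", call. = FALSE)
  invisible(img)
}

assert_mask <- function(mask) {
  assert_gray(mask)
  if (!all(mask %in% c(0, 255)))
    stop("mask values must be 0 or 255", call. = FALSE)
  invisible(mask)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Shift a matrix with edge replication
#'
#' Returns the matrix whose (i, j) entry is `m[i + di, j + dj]`, with
#' out-of-range indices clamped to the nearest valid row/column
#' (replicated borders).
#'
#' @param m numeric matrix.
#' @param di,dj integer row/column offsets.
#' @return matrix of the same dimension.
#' @keywords internal
shift_replicate <- function(m, di, dj) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + di, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dj, 1L), w)
  m[ri, ci, drop = FALSE]
}

#' Sliding-window rank filter (min or max) with replicated borders
#'
#' Dense rank filtering over a full odd square window; the workhorse behind
#' the morphological passes and the black-hat transform.
#'
#' @param m numeric matrix.
#' @param window odd window size.
#' @param what `"min"` or `"max"`.
#' @return filtered matrix, same dimension.
#' @export
rank_filter <- function(m, window, what = c("min", "max")) {
  what <- match.arg(what)
  assert_gray(m)
  if (window %% 2L != 1L || window < 1L) stop("window must be odd and >= 1")
  r <- (window - 1L) %/% 2L
  out <- m
  acc <- if (what == "min") pmin else pmax
  for (di in -r:r) for (dj in -r:r) {
    if (di == 0L && dj == 0L) next
    out <- acc(out, shift_replicate(m, di, dj))
  }
  out
}

#' Read an 8-bit image file as a 0-255 array
#'
#' PNG is read via the png package; JPEG and TIFF via EBImage. Grayscale
#' files come back as a matrix, colour files as an H x W x 3 array (any
#' alpha channel is dropped).
#'
#' @param path file path.
#' @return numeric matrix or H x W x 3 array on [0, 255].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else {
    img <- EBImage::readImage(path)
    a <- EBImage::imageData(img)
    # EBImage stores x (column) as the first dimension; transpose back
    a <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
  }
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L) a <- a[, , 1:3, drop = FALSE] else a <- a[, , 1L]
  }
  a * 255
}

#' Write an image or mask as PNG
#'
#' @param img matrix (gray/mask) or H x W x 3 array on [0, 255].
#' @param path output path (PNG).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(clip255(img) / 255, path)
  invisible(path)
}

#' Resize an image to a square target with bilinear interpolation
#'
#' @param img gray matrix or RGB array on [0, 255].
#' @param size target edge length in pixels.
#' @return resized image of the same kind.
#' @export
resize_image <- function(img, size = 512L) {
  rs <- function(m) EBImage::resize(m, w = size, h = size, filter = "bilinear")
  if (is.matrix(img)) return(rs(img))
  assert_rgb(img)
  out <- array(0, c(size, size, 3L))
  for (ch in 1:3) out[, , ch] <- rs(img[, , ch])
  out
}

#' Rotate an image or mask by an exact multiple of 90 degrees
#'
#' Grid rotation without interpolation, so mask cardinality is preserved.
#' Positive `k` rotates counter-clockwise by `k * 90` degrees.
#'
#' @param img matrix or H x W x 3 array.
#' @param k integer number of quarter turns.
#' @return rotated raster.
#' @export
rotate90 <- function(img, k = 1L) {
  k <- ((k %% 4L) + 4L) %% 4L
  rot1 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  f <- function(m) { for (i in seq_len(k)) m <- rot1(m); m }
  if (is.matrix(img)) return(f(img))
  assert_rgb(img)
  ch1 <- f(img[, , 1L])
  out <- array(0, c(dim(ch1), 3L))
  out[, , 1L] <- ch1
  out[, , 2L] <- f(img[, , 2L])
  out[, , 3L] <- f(img[, , 3L])
  out
}

# Geometric mean of the three channels, the single-channel unification rule
# used both for monochrome conversion and for segmentation.
geom_mean_channels <- function(img) {
  assert_rgb(img)
  out <- (img[, , 1L] * img[, , 2L] * img[, , 3L])^(1 / 3)
  if (!is.matrix(out)) out <- matrix(out, dim(img)[1], dim(img)[2])
  out
}
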