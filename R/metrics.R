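# Evaluation metrics ----------------------------------------------------------
#
# Image-quality metrics (MSE/RMSE/PSNR/UIQI), confusion-matrix metrics for
# localization, segmentation and classification, bounding-box IoU, mean
# average precision, and first-order image statistics. Ratios with a zero
# denominator are reported as NA (an explicit undefined sentinel), never
# silently as 0.

#' Round half-up to a number of decimals
#'
#' Plain half-up rounding (0.005 -> 0.01), the convention used for
#' percentage reporting; base `round()` rounds half-to-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Mean and root-mean-square error between two images
#'
#' @param reference,processed same-shape gray matrices or RGB arrays on
#'   [0, 255]; channels are pooled.
#' @return named list with `mse` and `rmse`.
#' @export
mse_rmse <- function(reference, processed) {
  if (!all(dim(reference) == dim(processed)))
    stop("shape mismatch", call. = FALSE)
  mse <- mean((as.numeric(processed) - as.numeric(reference))^2)
  list(mse = mse, rmse = sqrt(mse))
}

#' Peak signal-to-noise ratio in dB
#'
#' \eqn{PSNR = 20 \log_{10}(I_{max} / RMSE)} with \eqn{I_{max} = 255} for
#' 8-bit images. Identical images give `Inf`.
#'
#' @inheritParams mse_rmse
#' @param i_max peak intensity (255 for 8-bit data).
#' @return PSNR in decibels.
#' @export
psnr <- function(reference, processed, i_max = 255) {
  e <- mse_rmse(reference, processed)
  if (e$mse == 0) return(Inf)
  20 * log10(i_max / e$rmse)
}

#' Universal image quality index
#'
#' \deqn{UIQI = \frac{4\,\sigma_{xy}\,\bar x\,\bar y}
#'   {(\sigma_x^2 + \sigma_y^2)(\bar x^2 + \bar y^2)}}
#' computed globally; combines correlation, luminance and contrast
#' agreement and lies in \[-1, 1\], with 1 for identical non-constant
#' images.
#'
#' @inheritParams mse_rmse
#' @return the index; errors if the denominator is zero (e.g. two
#'   constant images).
#' @export
uiqi <- function(reference, processed) {
  if (!all(dim(reference) == dim(processed)))
    stop("shape mismatch", call. = FALSE)
  x <- as.numeric(reference); y <- as.numeric(processed)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y); cxy <- stats::cov(x, y)
  den <- (vx + vy) * (mx^2 + my^2)
  if (den == 0) stop("UIQI undefined: zero denominator", call. = FALSE)
  4 * cxy * mx * my / den
}

#' Image quality report
#'
#' Convenience wrapper bundling MSE, RMSE, PSNR and UIQI.
#'
#' @inheritParams mse_rmse
#' @return list with `mse`, `rmse`, `psnr_db`, `uiqi`.
#' @export
quality_report <- function(reference, processed) {
  e <- mse_rmse(reference, processed)
  q <- tryCatch(uiqi(reference, processed), error = function(e) NA_real_)
  list(mse = e$mse, rmse = e$rmse,
       psnr_db = psnr(reference, processed), uiqi = q)
}

#' Confusion counts from a pair of binary masks
#'
#' Pixel-wise true/false positive/negative counts, with 255 = foreground
#' in both masks.
#'
#' @param pred,truth same-shape binary masks (0/255).
#' @return object of class `confusion_counts`: list with `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
confusion_from_masks <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch", call. = FALSE)
  p <- pred > 0; t <- truth > 0
  confusion_counts(tp = sum(p & t), fn = sum(!p & t),
                   fp = sum(p & !t), tn = sum(!p & !t))
}

#' Construct confusion counts
#'
#' @param tp,fn,fp,tn non-negative integer counts.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  v <- c(tp, fn, fp, tn)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(list(tp = as.numeric(tp), fn = as.numeric(fn),
                 fp = as.numeric(fp), tn = as.numeric(tn)),
            class = "confusion_counts")
}

#' Reconstruct confusion counts from class sizes and printed rates
#'
#' Given the positive/negative class sizes and sensitivity/specificity in
#' percent, counts are recovered by nearest-integer rounding of
#' rate x class size — the inverse of how such tables are printed.
#'
#' @param n_pos,n_neg class sizes.
#' @param sn_pct,sp_pct sensitivity and specificity in percent.
#' @return object of class `confusion_counts`.
#' @export
confusion_from_rates <- function(n_pos, n_neg, sn_pct, sp_pct) {
  tp <- round(sn_pct / 100 * n_pos)
  tn <- round(sp_pct / 100 * n_neg)
  confusion_counts(tp = tp, fn = n_pos - tp, fp = n_neg - tn, tn = tn)
}

#' Classification / segmentation metrics from confusion counts
#'
#' Computes sensitivity (= recall), specificity, Dice, Jaccard, accuracy,
#' AUC as the two-point formula (Sn + Sp) / 2, precision, F1 (harmonic
#' mean of precision and recall) and the Matthews correlation coefficient.
#' Each metric with a zero denominator is `NA`.
#'
#' @param c a [confusion_counts] object.
#' @return list of class `classification_metrics` with the metrics on the
#'   \[0, 1\] scale (`mcc` in \[-1, 1\]) and a `percent` element: the same
#'   values x 100, rounded half-up to 2 decimals.
#' @export
classification_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  tp <- c$tp; fn <- c$fn; fp <- c$fp; tn <- c$tn
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  sn <- sdiv(tp, tp + fn)
  sp <- sdiv(tn, tn + fp)
  dice <- sdiv(2 * tp, 2 * tp + fp + fn)
  jac <- sdiv(tp, tp + fn + fp)
  acc <- sdiv(tp + tn, tp + fn + fp + tn)
  auc <- if (is.na(sn) || is.na(sp)) NA_real_ else (sn + sp) / 2
  prec <- sdiv(tp, tp + fp)
  rec <- sn
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_ else
    2 * prec * rec / (prec + rec)
  mden <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mden == 0) NA_real_ else (tp * tn - fp * fn) / sqrt(mden)
  vals <- list(sn = sn, sp = sp, dice = dice, jaccard = jac, accuracy = acc,
               auc = auc, precision = prec, recall = rec, f1 = f1, mcc = mcc)
  pct <- vapply(vals, function(v) round_half_up(v * 100, 2), numeric(1))
  structure(c(vals, list(percent = pct)), class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  p <- x$percent
  cat("classification metrics (%):\n")
  for (nm in names(p))
    cat(sprintf("  %-9s %s\n", nm,
                ifelse(is.na(p[[nm]]), "NA", sprintf("%6.2f", p[[nm]]))))
  invisible(x)
}

#' Dice coefficient implied by a Jaccard index
#'
#' The exact identity `Dc = 2 Js / (1 + Js)` linking the two overlap
#' measures.
#'
#' @param js Jaccard index on \[0, 1\].
#' @return Dice coefficient on \[0, 1\].
#' @export
dice_from_jaccard <- function(js) 2 * js / (1 + js)

#' Bounding box (half-open pixel intervals)
#'
#' @param row_min,col_min,row_max,col_max pixel indices with
#'   `max > min` on both axes; the box covers `[min, max)`.
#' @return object of class `bounding_box`.
#' @export
bounding_box <- function(row_min, col_min, row_max, col_max) {
  if (row_max <= row_min || col_max <= col_min)
    stop("box must have positive extent", call. = FALSE)
  structure(list(row_min = row_min, col_min = col_min,
                 row_max = row_max, col_max = col_max),
            class = "bounding_box")
}

#' Intersection-over-union of two bounding boxes
#'
#' True IoU (overlap area divided by union area) in \[0, 1\]; disjoint
#' boxes give 0.
#'
#' @param a,b [bounding_box] objects.
#' @return IoU scalar.
#' @export
box_iou <- function(a, b) {
  ih <- max(0, min(a$row_max, b$row_max) - max(a$row_min, b$row_min))
  iw <- max(0, min(a$col_max, b$col_max) - max(a$col_min, b$col_min))
  inter <- ih * iw
  area <- function(x) (x$row_max - x$row_min) * (x$col_max - x$col_min)
  un <- area(a) + area(b) - inter
  inter / un
}

#' Mean average precision over per-image confusion counts
#'
#' Mean of per-image precision TP / (TP + FP); images where precision is
#' undefined are skipped and counted in the `n_undefined` attribute. `NA`
#' when every entry is undefined.
#'
#' @param per_image non-empty list of [confusion_counts].
#' @return mAP scalar with attribute `n_undefined`.
#' @export
mean_average_precision <- function(per_image) {
  if (!length(per_image)) stop("empty list", call. = FALSE)
  prec <- vapply(per_image, function(c) {
    if (c$tp + c$fp == 0) NA_real_ else c$tp / (c$tp + c$fp)
  }, numeric(1))
  n_und <- sum(is.na(prec))
  if (n_und == length(prec)) {
    out <- NA_real_
  } else {
    if (n_und > 0) warning(n_und, " image(s) with undefined precision skipped")
    out <- mean(prec, na.rm = TRUE)
  }
  attr(out, "n_undefined") <- n_und
  out
}

#' First-order image statistics
#'
#' Population mean, standardized skewness (third moment over sigma^3) and
#' non-excess kurtosis (fourth moment over sigma^4; a Gaussian scores 3).
#' Skewness and kurtosis are `NA` for a constant image.
#'
#' @param img gray matrix (any numeric raster works).
#' @return list with `mean`, `skewness`, `kurtosis`.
#' @export
image_stats <- function(img) {
  x <- as.numeric(img)
  if (!length(x)) stop("empty image", call. = FALSE)
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  if (s2 == 0)
    return(list(mean = mu, skewness = NA_real_, kurtosis = NA_real_))
  list(mean = mu,
       skewness = mean((x - mu)^3) / s2^1.5,
       kurtosis = mean((x - mu)^4) / s2^2)
}
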