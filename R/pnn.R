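# Pentagonal neutrosophic numbers ------------------------------------------
#
# A single-valued pentagonal neutrosophic number (SVPNN) carries three
# piecewise-linear membership profiles over five ordered support points:
# truth (peak pi at the core), hesitation and falsity (valleys reaching
# their degree at the core, 1 outside the support). The score-style
# threshold derived from a pentagonal quintuple drives phase two of the
# lesion segmentation.

#' Construct a single-valued pentagonal neutrosophic number
#'
#' @param truth,hesitation,falsity numeric length-5, non-decreasing support
#'   points of the respective membership profile.
#' @param pi_deg truth degree in \[0, 1\] (peak of the truth profile).
#' @param rho_deg hesitation degree in \[0, 1\] (valley floor of hesitation).
#' @param sigma_deg falsity degree in \[0, 1\] (valley floor of falsity).
#' @return object of class `svpnn`.
#' @examples
#' n <- svpnn(c(.1, .2, .3, .4, .5), c(.1, .2, .3, .4, .5),
#'            c(.1, .2, .3, .4, .5), 1, 0, 0)
#' validate_svpnn(n)
#' @export
svpnn <- function(truth, hesitation = truth, falsity = truth,
                  pi_deg = 1, rho_deg = 0, sigma_deg = 0) {
  out <- structure(
    list(truth = as.numeric(truth), hesitation = as.numeric(hesitation),
         falsity = as.numeric(falsity), pi = pi_deg, rho = rho_deg,
         sigma = sigma_deg),
    class = "svpnn")
  out
}

#' Validate an SVPNN
#'
#' Checks the three defining invariants: each support quintuple is
#' non-decreasing, the three degrees lie in \[0, 1\], and the sum of the
#' suprema of the three memberships stays within \[0, 3\].
#'
#' @param n an [svpnn] object.
#' @return `TRUE` or `FALSE`; never raises.
#' @export
validate_svpnn <- function(n) {
  if (!inherits(n, "svpnn")) return(FALSE)
  parts <- list(n$truth, n$hesitation, n$falsity)
  ok_len <- all(vapply(parts, length, 1L) == 5L) &&
    all(vapply(parts, function(p) all(is.finite(p)), TRUE))
  if (!ok_len) return(FALSE)
  ordered <- all(vapply(parts, function(p) !is.unsorted(p), TRUE))
  degs <- c(n$pi, n$rho, n$sigma)
  deg_ok <- all(is.finite(degs)) && all(degs >= 0) && all(degs <= 1)
  # supremum bound: sup(truth) = pi, sup(hesitation) = sup(falsity) = 1
  sup_ok <- deg_ok && (n$pi + 1 + 1 >= 0) && (n$pi + 1 + 1 <= 3)
  isTRUE(ordered && deg_ok && sup_ok)
}

# Evaluate one rising linear branch v0 -> v1 over [x0, x1); a zero-width
# branch is treated as a jump evaluated by right-continuity (returns v1).
.lin <- function(x, x0, x1, v0, v1) {
  if (x1 == x0) return(v1)
  v0 + (v1 - v0) * (x - x0) / (x1 - x0)
}

#' Truth membership of an SVPNN
#'
#' Piecewise-linear pentagonal profile: zero outside the support, each of
#' the two rising pieces climbs from 0 to the truth degree, the peak value
#' `pi` is attained at the core point, and the two falling pieces mirror
#' the rise.
#'
#' @param x evaluation point (scalar or vector).
#' @param n a valid [svpnn].
#' @return membership value(s) in \[0, pi\].
#' @export
truth_membership <- function(x, n) {
  if (!validate_svpnn(n)) stop("invalid svpnn", call. = FALSE)
  p <- n$truth; pi_ <- n$pi
  one <- function(x) {
    if (x < p[1] || x > p[5]) return(0)
    if (x == p[3]) return(pi_)
    if (x < p[2]) return(.lin(x, p[1], p[2], 0, pi_))
    if (x < p[3]) return(.lin(x, p[2], p[3], 0, pi_))
    if (x < p[4]) return(.lin(x, p[4], p[3], 0, pi_))
    .lin(x, p[5], p[4], 0, pi_)
  }
  vapply(x, one, numeric(1))
}

# Shared valley profile for hesitation/falsity: 1 outside the support,
# each piece interpolating between 1 and the degree `deg`, with the core
# point evaluating exactly to `deg`.
.valley_membership <- function(x, p, deg) {
  one <- function(x) {
    if (x < p[1] || x > p[5]) return(1)
    if (x == p[3]) return(deg)
    if (x < p[2]) return(.lin(x, p[1], p[2], 1, deg))
    if (x < p[3]) return(.lin(x, p[2], p[3], 1, deg))
    if (x < p[4]) return(.lin(x, p[4], p[3], 1, deg))
    .lin(x, p[5], p[4], 1, deg)
  }
  vapply(x, one, numeric(1))
}

#' Hesitation membership of an SVPNN
#'
#' Valley-shaped profile: equals 1 outside the support and attains the
#' hesitation degree `rho` at the core point.
#'
#' @inheritParams truth_membership
#' @return membership value(s) in \[rho, 1\].
#' @export
hesitation_membership <- function(x, n) {
  if (!validate_svpnn(n)) stop("invalid svpnn", call. = FALSE)
  .valley_membership(x, n$hesitation, n$rho)
}

#' Falsity membership of an SVPNN
#'
#' @inheritParams truth_membership
#' @return membership value(s) in \[sigma, 1\].
#' @export
falsity_membership <- function(x, n) {
  if (!validate_svpnn(n)) stop("invalid svpnn", call. = FALSE)
  .valley_membership(x, n$falsity, n$sigma)
}

# Pentagonal threshold specification ----------------------------------------

#' Pentagonal threshold specification
#'
#' Holds the five pentagonal components on the normalized intensity axis
#' together with the truth, indeterminacy and falsity degrees entering the
#' score-based threshold.
#'
#' @param m numeric length-5, non-decreasing, each in \[0, 1\].
#' @param pi_deg truth part, in \[0, 1\].
#' @param sigma_deg indeterminacy part, in \[0, 1\].
#' @param mu_deg falsity part, in \[0, 1\].
#' @return object of class `pnn_spec`.
#' @export
pnn_spec <- function(m, pi_deg = 0.9, sigma_deg = 0.3, mu_deg = 0.2) {
  m <- as.numeric(m)
  if (length(m) != 5L || any(!is.finite(m)))
    stop("m must be five finite numbers", call. = FALSE)
  if (is.unsorted(m)) stop("m must be non-decreasing", call. = FALSE)
  if (any(m < 0 | m > 1)) stop("m components must lie in [0, 1]", call. = FALSE)
  degs <- c(pi_deg, sigma_deg, mu_deg)
  if (any(!is.finite(degs) | degs < 0 | degs > 1))
    stop("degrees must lie in [0, 1]", call. = FALSE)
  structure(list(m = m, pi = pi_deg, sigma = sigma_deg, mu = mu_deg),
            class = "pnn_spec")
}

#' Pentagonal-neutrosophic threshold
#'
#' Score-style scalar reduction of a pentagonal quintuple:
#' \deqn{\vartheta = \frac{1}{15}(m_1+m_2+m_3+m_4+m_5)(2 + \pi - \sigma - \mu)}
#' With full truth and no indeterminacy or falsity (pi = 1, sigma = mu = 0)
#' this reduces exactly to the arithmetic mean of the five components.
#'
#' @param spec a [pnn_spec].
#' @return the threshold, a scalar in \[0, sum(m)/5\].
#' @examples
#' pnn_threshold(pnn_spec(c(.2, .3, .4, .5, .6), 1, 0, 0)) # 0.4, the mean
#' @export
pnn_threshold <- function(spec) {
  if (!inherits(spec, "pnn_spec")) spec <- do.call(pnn_spec, as.list(spec))
  sum(spec$m) / 15 * (2 + spec$pi - spec$sigma - spec$mu)
}

# Linguistic grades -----------------------------------------------------------

# Default anchor table on the normalized intensity axis: core values at
# 0.1, 0.3, 0.5, 0.7, 0.9 (uniform partition) with symmetric +/-0.2 spread,
# clipped to [0, 1].
.pnn_terms <- c("VeryLow", "Low", "Median", "High", "VeryHigh")

.default_anchors <- function() {
  cores <- c(VeryLow = 0.1, Low = 0.3, Median = 0.5, High = 0.7, VeryHigh = 0.9)
  lapply(cores, function(cc) pmin(pmax(cc + c(-.2, -.1, 0, .1, .2), 0), 1))
}

#' Map a linguistic grade to a pentagonal threshold specification
#'
#' The five-term vocabulary (VeryLow, Low, Median, High, VeryHigh) is
#' anchored on the normalized intensity axis at cores 0.1 ... 0.9 with a
#' symmetric 0.2 spread clipped to \[0, 1\]; e.g. Median maps to
#' (0.3, 0.4, 0.5, 0.6, 0.7). The anchor table and default degrees can be
#' overridden, including from a flat key=value config file via
#' [read_pnn_config()].
#'
#' @param term one of `"VeryLow"`, `"Low"`, `"Median"`, `"High"`,
#'   `"VeryHigh"` (case-insensitive; `"very low"`/`"very_low"` accepted).
#' @param anchors optional named list of quintuples overriding the table.
#' @param pi_deg,sigma_deg,mu_deg degrees passed to [pnn_spec()].
#' @return a [pnn_spec].
#' @export
linguistic_to_pnn <- function(term, anchors = NULL,
                              pi_deg = 0.9, sigma_deg = 0.3, mu_deg = 0.2) {
  key <- gsub("[ _]", "", tolower(term))
  tab <- .default_anchors()
  if (!is.null(anchors)) {
    names(anchors) <- gsub("[ _]", "", tolower(names(anchors)))
    for (nm in names(anchors)) tab[[.match_term(nm)]] <- anchors[[nm]]
  }
  hit <- .match_term(key)
  pnn_spec(tab[[hit]], pi_deg, sigma_deg, mu_deg)
}

.match_term <- function(key) {
  idx <- match(gsub("[ _]", "", tolower(key)), tolower(.pnn_terms))
  if (is.na(idx))
    stop("unknown linguistic term: must be one of ",
         paste(.pnn_terms, collapse = ", "), call. = FALSE)
  .pnn_terms[idx]
}

#' Read a flat key=value config for the pentagonal threshold
#'
#' Lines look like `median = 0.3,0.4,0.5,0.6,0.7` (anchor override) or
#' `pi = 0.9` / `sigma = 0.3` / `mu = 0.2` (default degrees). Blank lines
#' and `#` comments are ignored.
#'
#' @param path path to the config file.
#' @return list with elements `anchors` (named list, possibly empty) and
#'   `pi`, `sigma`, `mu`.
#' @export
read_pnn_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list(anchors = list(), pi = 0.9, sigma = 0.3, mu = 0.2)
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- as.numeric(strsplit(trimws(kv[2]), ",")[[1]])
    lk <- gsub("[ _]", "", tolower(key))
    if (lk %in% c("pi", "sigma", "mu")) out[[lk]] <- val
    else out$anchors[[.match_term(lk)]] <- val
  }
  out
}
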