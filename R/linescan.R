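# Line-scan enrichment: a 1D intensity profile across the nucleus through
# the enriched region, and the peak / minimum enrichment ratio.

# Bilinear interpolation of matrix m (rows = y, cols = x) at real
# coordinates (y, x); coordinates clamped to the grid. When a logical
# `mask` is given, interpolation weights are restricted to mask pixels
# (renormalized), so samples near the mask boundary never blend in
# intensities from outside it; interior samples are plain bilinear.
bilinear <- function(m, y, x, mask = NULL) {
  ny <- nrow(m); nx <- ncol(m)
  y <- pmin(pmax(y, 1), ny); x <- pmin(pmax(x, 1), nx)
  y0 <- pmin(floor(y), ny - 1L); x0 <- pmin(floor(x), nx - 1L)
  fy <- y - y0; fx <- x - x0
  w <- cbind((1 - fy) * (1 - fx), fy * (1 - fx), (1 - fy) * fx, fy * fx)
  idx <- list(cbind(y0, x0), cbind(y0 + 1, x0),
              cbind(y0, x0 + 1), cbind(y0 + 1, x0 + 1))
  vals <- sapply(idx, function(ii) m[ii])
  vals <- matrix(vals, nrow = length(y))
  if (!is.null(mask)) {
    inm <- matrix(sapply(idx, function(ii) as.numeric(mask[ii])), nrow = length(y))
    w <- w * inm
    tot <- rowSums(w)
    w <- w / ifelse(tot > 0, tot, 1)
  }
  rowSums(vals * w)
}

#' Intensity profile along a line across the nucleus
#'
#' The line passes through the nucleus centroid in the direction of the
#' intensity-weighted signal centroid, so it crosses the enriched region.
#' When the signal mask is empty or its centroid coincides with the nucleus
#' centroid, the nucleus major axis is used instead — a deterministic
#' stand-in for drawing an arbitrary line when no enrichment is visible.
#' Endpoints are clipped to the nucleus boundary; intensities are sampled
#' by bilinear interpolation at unit-pixel steps, with interpolation
#' weights restricted to nucleus pixels so boundary samples never mix in
#' extranuclear background.
#'
#' @param plane numeric 2D intensity matrix (one z-slice).
#' @param nucleus_slice logical 2D nucleus mask for that slice.
#' @param signal_slice optional logical 2D signal mask.
#' @return A `LineProfile`: list with `distance` (strictly increasing, px),
#'   `intensity`, and `endpoints` (2 x 2 matrix of (y, x) rows).
#' @export
line_scan <- function(plane, nucleus_slice, signal_slice = NULL) {
  stopifnot(is.matrix(plane), is.logical(nucleus_slice))
  check_congruent(plane, nucleus_slice, "plane and nucleus slice")
  if (!any(nucleus_slice)) stop("empty nucleus slice")
  idx <- which(nucleus_slice, arr.ind = TRUE)
  cen <- c(mean(idx[, 1]), mean(idx[, 2]))          # (y, x)

  dir <- NULL
  if (!is.null(signal_slice) && any(signal_slice)) {
    sidx <- which(signal_slice, arr.ind = TRUE)
    w <- plane[signal_slice]
    if (sum(w) <= 0) w <- rep(1, nrow(sidx))
    scen <- c(sum(sidx[, 1] * w), sum(sidx[, 2] * w)) / sum(w)
    d <- scen - cen
    if (sqrt(sum(d^2)) > 1e-6) dir <- d / sqrt(sum(d^2))
  }
  if (is.null(dir)) {
    ell <- fit_ellipse(nucleus_slice)
    dir <- c(sin(ell$theta), cos(ell$theta))        # (y, x) of major axis
  }

  # walk outward from the centroid to the mask boundary (nearest-pixel test)
  inside <- function(t) {
    p <- cen + t * dir
    i <- round(p[1]); j <- round(p[2])
    i >= 1 && i <= nrow(plane) && j >= 1 && j <= ncol(plane) &&
      nucleus_slice[i, j]
  }
  walk <- function(step) {
    t <- 0
    while (inside(t + step)) t <- t + step
    t
  }
  t_hi <- walk(0.25); t_lo <- walk(-0.25)
  if (t_hi - t_lo < 1) stop("nucleus chord shorter than one pixel")

  dist <- seq(0, t_hi - t_lo, by = 1)
  pts_y <- cen[1] + (t_lo + dist) * dir[1]
  pts_x <- cen[2] + (t_lo + dist) * dir[2]
  structure(list(distance = dist,
                 intensity = bilinear(plane, pts_y, pts_x, mask = nucleus_slice),
                 endpoints = rbind(c(pts_y[1], pts_x[1]),
                                   c(pts_y[length(dist)], pts_x[length(dist)]))),
            class = "LineProfile")
}

#' Line-scan enrichment ratio
#'
#' Peak intensity along the profile divided by the lowest intensity,
#' measuring how strongly the stain is enriched on the territory relative
#' to the rest of the nucleus. A centered 3-point moving average (edges
#' replicated) is applied first by default to suppress single-pixel noise;
#' intensities are floored at `1e-6 * max` before the ratio.
#'
#' @param profile a [line_scan()] result, or a numeric vector of samples.
#' @param smooth logical; apply the moving average (default `TRUE`).
#' @return Enrichment ratio E >= 1.
#' @examples
#' enrichment_ratio(c(50, 200, 75), smooth = FALSE)  # 4
#' @export
enrichment_ratio <- function(profile, smooth = TRUE) {
  v <- if (inherits(profile, "LineProfile")) profile$intensity else as.numeric(profile)
  if (length(v) < 2) stop("profile needs >= 2 samples")
  if (smooth && length(v) >= 3) {
    padded <- c(v[1], v, v[length(v)])
    v <- (padded[1:length(v)] + padded[2:(length(v) + 1)] +
            padded[3:(length(v) + 2)]) / 3
  }
  mx <- max(v)
  if (mx <= 0) stop("profile minimum <= 0 after flooring")
  v <- pmax(v, 1e-6 * mx)
  mx / min(v)
}
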