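# The three-zone radial assay: mid-slice selection, ellipse fitting,
# equal-area concentric zones, and signal zone fractions.

#' Select the in-focus middle slice
#'
#' Among the middle third of nucleus-containing z-planes, returns the plane
#' maximizing a focus score: the normalized variance (variance / mean^2) of
#' the signal channel within the nucleus. Ties go to the lowest z.
#'
#' @param signal_stack a [voxel_stack()] of the signal channel.
#' @param nucleus logical 3D nucleus mask.
#' @return 1-based z index.
#' @export
select_mid_slice <- function(signal_stack, nucleus) {
  stopifnot(inherits(signal_stack, "VoxelStack"), is.logical(nucleus))
  check_congruent(signal_stack, nucleus, "signal stack and nucleus mask")
  zs <- which(apply(nucleus, 1, any))
  if (length(zs) < 3) stop("nucleus spans fewer than 3 planes")
  n <- length(zs)
  mid <- zs[(floor(n / 3) + 1):ceiling(2 * n / 3)]
  score <- vapply(mid, function(z) {
    v <- signal_stack$data[z, , ][nucleus[z, , ]]
    m <- mean(v)
    if (m <= 0) 0 else var(v) / m^2
  }, numeric(1))
  mid[which.max(score)]   # which.max returns the first (lowest z) on ties
}

#' Fit an ellipse to a 2D mask by image moments
#'
#' Center from the first moments, orientation and axis ratio from the
#' eigendecomposition of the second central moments (for a filled ellipse
#' the eigenvalues are a^2/4 and b^2/4), then both semi-axes rescaled so
#' the ellipse area equals the mask pixel count.
#'
#' @param mask logical 2D mask (rows = y, cols = x).
#' @return An `Ellipse2D`: list with `center` `(cy, cx)` in pixel
#'   coordinates, semi-axes `a >= b > 0` in pixels, orientation `theta`
#'   (radians, major axis relative to +x).
#' @export
fit_ellipse <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 2L)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  yy <- idx[, 1]; xx <- idx[, 2]
  cy <- mean(yy); cx <- mean(xx)
  n <- nrow(idx)
  syy <- sum((yy - cy)^2) / n
  sxx <- sum((xx - cx)^2) / n
  sxy <- sum((xx - cx) * (yy - cy)) / n
  if (sxx * syy - sxy^2 <= 1e-12)
    stop("degenerate mask: pixels are collinear")
  # +1/12 per axis accounts for the unit pixel extent
  cov <- matrix(c(sxx + 1 / 12, sxy, sxy, syy + 1 / 12), 2, 2)
  eg <- eigen(cov, symmetric = TRUE)
  a <- 2 * sqrt(eg$values[1]); b <- 2 * sqrt(eg$values[2])
  s <- sqrt(n / (pi * a * b))    # area match
  v <- eg$vectors[, 1]           # (x, y) components of the major axis
  structure(list(center = c(cy = cy, cx = cx), a = a * s, b = b * s,
                 theta = atan2(v[2], v[1])),
            class = "Ellipse2D")
}

# Rasterize (a scaled copy of) an ellipse on a pixel grid by center-point
# membership.
ellipse_mask <- function(ellipse, shape, scale = 1) {
  stopifnot(inherits(ellipse, "Ellipse2D"), length(shape) == 2L)
  ny <- shape[1]; nx <- shape[2]
  dx <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - ellipse$center[["cx"]]
  dy <- matrix(seq_len(ny), ny, nx) - ellipse$center[["cy"]]
  ct <- cos(ellipse$theta); st <- sin(ellipse$theta)
  u <- ct * dx + st * dy
  w <- -st * dx + ct * dy
  (u / (scale * ellipse$a))^2 + (w / (scale * ellipse$b))^2 <= 1
}

#' Ellipticity quality-control gate
#'
#' Jaccard overlap between the mask and the interior of its fitted ellipse;
#' nuclei whose cross-section is not smooth and elliptical fail the gate and
#' are excluded from the zone assay.
#'
#' @param mask logical 2D nuclear slice mask.
#' @param ellipse the fitted [fit_ellipse()] result.
#' @param min_overlap pass threshold on the Jaccard score (default 0.90).
#' @return list with `pass` (logical) and `score` (Jaccard in \[0, 1\]).
#' @export
check_ellipticity <- function(mask, ellipse, min_overlap = 0.90) {
  stopifnot(is.logical(mask), inherits(ellipse, "Ellipse2D"))
  em <- ellipse_mask(ellipse, dim(mask))
  score <- sum(mask & em) / sum(mask | em)
  list(pass = score >= min_overlap, score = score)
}

#' Build three equal-area concentric zones
#'
#' The zone boundaries are the concentric ellipses sharing the fitted
#' ellipse's center and orientation with semi-axes scaled by `sqrt(1/3)`
#' and `sqrt(2/3)` — the contours at which the enclosed area is one and two
#' thirds of the total. On the pixel grid, each pixel inside the outer
#' ellipse is assigned by its squared elliptical radius: pixels are ranked
#' by that radius (deterministic lexicographic tie-break) and cut into
#' three equal-count groups, so the discrete zone areas agree to within one
#' pixel whatever the ellipse size.
#'
#' @param ellipse an [fit_ellipse()] result (the outer boundary).
#' @param shape `(ny, nx)` of the target grid.
#' @return A `ZoneSet`: list of logical masks `central`, `intermediate`,
#'   `peripheral` (pairwise disjoint) plus the `ellipse`.
#' @export
make_zones <- function(ellipse, shape) {
  stopifnot(inherits(ellipse, "Ellipse2D"))
  if (ellipse$a < 1 || ellipse$b < 1)
    stop("ellipse too small to partition into zones")
  cy <- ellipse$center[["cy"]]; cx <- ellipse$center[["cx"]]
  if (cx - ellipse$a < 0.5 || cx + ellipse$a > shape[2] + 0.5 ||
      cy - ellipse$a < 0.5 || cy + ellipse$a > shape[1] + 0.5)
    warning("ellipse extends beyond the grid; zones are clipped")
  ny <- shape[1]; nx <- shape[2]
  dx <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - cx
  dy <- matrix(seq_len(ny), ny, nx) - cy
  ct <- cos(ellipse$theta); st <- sin(ellipse$theta)
  u <- ct * dx + st * dy
  w <- -st * dx + ct * dy
  rho2 <- (u / ellipse$a)^2 + (w / ellipse$b)^2   # area grows linearly in rho2
  inside <- which(rho2 <= 1)
  n <- length(inside)
  if (n < 3) stop("degenerate ellipse: fewer than 3 pixels inside")
  ord <- inside[order(rho2[inside], inside)]
  k1 <- round(n / 3); k2 <- round(2 * n / 3)
  zone_of <- function(ix) {
    m <- matrix(FALSE, ny, nx); m[ix] <- TRUE; m
  }
  zones <- list(central = zone_of(ord[seq_len(k1)]),
                intermediate = zone_of(ord[(k1 + 1):k2]),
                peripheral = zone_of(ord[(k2 + 1):n]),
                ellipse = ellipse)
  structure(zones, class = "ZoneSet")
}

#' Signal fraction in each radial zone
#'
#' Fraction of the thresholded signal pixels falling in the central,
#' intermediate and peripheral zone, relative to the signal within the zone
#' union; the three fractions sum to 1.
#'
#' @param signal_mask logical 2D signal mask for the same slice.
#' @param zones a [make_zones()] result.
#' @param weights optional numeric 2D intensity matrix: when given, zone
#'   overlap is weighted by intensity instead of counting pixels.
#' @return Named numeric vector `(p_central, p_mid, p_periph)`.
#' @export
zone_fractions <- function(signal_mask, zones, weights = NULL) {
  stopifnot(is.logical(signal_mask), inherits(zones, "ZoneSet"))
  check_congruent(signal_mask, zones$central, "signal mask and zones")
  amount <- function(m) {
    if (is.null(weights)) sum(m) else sum(weights[m])
  }
  counts <- c(p_central = amount(signal_mask & zones$central),
              p_mid = amount(signal_mask & zones$intermediate),
              p_periph = amount(signal_mask & zones$peripheral))
  tot <- sum(counts)
  if (tot == 0) stop("no signal in nucleus (zone union)")
  counts / tot
}
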