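#' Territory volume fraction
#'
#' Fraction of the nuclear volume occupied by the signal territory, counted
#' in voxels: `|signal AND nucleus| / |nucleus|`. Pure voxel counting — the
#' result does not depend on the physical voxel spacing, since grid
#' anisotropy biases numerator and denominator identically.
#'
#' @param signal logical 3D signal (territory) mask.
#' @param nucleus logical 3D nucleus mask, congruent with `signal`.
#' @return Volume fraction in \[0, 1\].
#' @examples
#' nuc <- array(TRUE, c(2, 4, 4))
#' volume_fraction(nuc, nuc)  # 1
#' @export
volume_fraction <- function(signal, nucleus) {
  stopifnot(is.logical(signal), is.logical(nucleus))
  check_congruent(signal, nucleus, "signal and nucleus masks")
  n <- sum(nucleus)
  if (n == 0) stop("empty nucleus mask")
  sum(signal & nucleus) / n
}

#' Normalized mean nuclear intensity
#'
#' Mean intensity inside the nucleus mask divided by the mean intensity of a
#' background region of the same stack. When no background region is given,
#' the background is every voxel outside the nucleus mask dilated by 3
#' voxels (the dilation keeps the bright rim around an imperfect mask out of
#' the background estimate).
#'
#' @param stack a [voxel_stack()].
#' @param nucleus logical 3D nucleus mask.
#' @param background optional logical 3D background mask, non-empty and
#'   disjoint from `nucleus`.
#' @return Intensity ratio I > 0.
#' @export
mean_intensity_ratio <- function(stack, nucleus, background = NULL) {
  stopifnot(inherits(stack, "VoxelStack"), is.logical(nucleus))
  check_congruent(stack, nucleus, "stack and nucleus mask")
  if (!any(nucleus)) stop("empty nucleus mask")
  if (is.null(background)) {
    background <- !dilate_mask_3d(nucleus, 3L)
  } else {
    check_congruent(stack, background, "stack and background mask")
    if (any(background & nucleus)) stop("background region overlaps the nucleus")
  }
  if (!any(background)) stop("background region is empty")
  bg_mean <- mean(stack$data[background])
  if (bg_mean <= 0) stop("background mean is zero")
  mean(stack$data[nucleus]) / bg_mean
}
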