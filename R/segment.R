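# Nucleus and signal segmentation on 3D stacks.

# Otsu threshold of a numeric vector via EBImage's histogram criterion.
otsu_threshold <- function(values, levels = 4096L) {
  rng <- range(values)
  if (diff(rng) == 0) stop("cannot threshold constant values")
  img <- EBImage::Image(matrix(values, ncol = 1L))
  EBImage::otsu(img, range = rng, levels = levels)
}

# Label connected components of a logical 3D array (26-connectivity).
# Frontier BFS over linear indices; returns an integer array (0 = background).
label_components_3d <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  lab <- array(0L, d)
  remaining <- which(mask)
  comp <- 0L
  while (length(remaining) > 0) {
    comp <- comp + 1L
    frontier <- remaining[1]
    lab[frontier] <- comp
    while (length(frontier) > 0) {
      co <- arrayInd(frontier, d)
      n_off <- nrow(off)
      cand <- co[rep(seq_len(nrow(co)), each = n_off), , drop = FALSE] +
        off[rep(seq_len(n_off), times = nrow(co)), , drop = FALSE]
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
            cand[, 2] >= 1 & cand[, 2] <= d[2] &
            cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      ci <- cand[, 1] + d[1] * ((cand[, 2] - 1L) + d[2] * (cand[, 3] - 1L))
      ci <- unique(ci[mask[ci] & lab[ci] == 0L])
      lab[ci] <- comp
      frontier <- ci
    }
    remaining <- remaining[lab[remaining] == 0L]
  }
  lab
}

# Fill internal holes of a logical 3D mask, plane by plane.
fill_holes_per_plane <- function(mask) {
  for (z in seq_len(dim(mask)[1])) {
    plane <- mask[z, , ]
    if (!any(plane)) next
    filled <- EBImage::fillHull(EBImage::Image(plane * 1))
    mask[z, , ] <- as.matrix(filled) > 0
  }
  mask
}

# Binary dilation of a 3D mask by `iter` steps of 6-connectivity.
dilate_mask_3d <- function(mask, iter = 3L) {
  d <- dim(mask)
  shift_or <- function(m, axis, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[axis]
    if (by > 0) { idx_src[[axis]] <- 1:(n - 1); idx_dst[[axis]] <- 2:n }
    else { idx_src[[axis]] <- 2:n; idx_dst[[axis]] <- 1:(n - 1) }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (i in seq_len(iter)) {
    grown <- mask
    for (axis in 1:3) {
      grown <- grown | shift_or(mask, axis, 1L) | shift_or(mask, axis, -1L)
    }
    mask <- grown
  }
  mask
}

#' Segment the nucleus from a DNA-stain stack
#'
#' Global threshold on the pooled stack histogram (Otsu's criterion by
#' default), followed by keeping the largest 3D connected component
#' (26-connectivity) and filling internal holes plane by plane. Dissected
#' nuclei are imaged one per field, so the largest component is the nucleus.
#'
#' @param stack a [voxel_stack()] of the nuclear stain.
#' @param method `"otsu"`, or a numeric threshold to use directly.
#' @return Logical 3D array (the nucleus mask) with attribute
#'   `threshold`.
#' @export
segment_nucleus <- function(stack, method = "otsu") {
  stopifnot(inherits(stack, "VoxelStack"))
  v <- stack$data
  if (diff(range(v)) == 0) stop("no foreground: stack is constant")
  thr <- if (is.numeric(method)) method else switch(method,
    otsu = otsu_threshold(as.numeric(v)),
    stop("unknown threshold method: ", method))
  mask <- v > thr
  if (!any(mask)) stop("no foreground above threshold")
  lab <- label_components_3d(mask)
  sizes <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(sizes)
  mask <- fill_holes_per_plane(mask)
  attr(mask, "threshold") <- thr
  mask
}

#' Segment the signal channel inside the nucleus
#'
#' Thresholds the signal channel (Otsu restricted to voxels inside the
#' nucleus mask by default) and intersects the result with the nucleus
#' mask, so non-specific staining outside the nucleus never contributes.
#' No largest-component filter is applied: a chromosome territory may
#' legitimately fragment across planes.
#'
#' @param stack a [voxel_stack()] of the signal channel.
#' @param nucleus logical 3D nucleus mask congruent with `stack`.
#' @param method `"otsu"`, or a numeric threshold.
#' @return Logical 3D array, a subset of `nucleus`, with attributes
#'   `threshold` and `empty` (`TRUE` when no voxel passed — flagged, not an
#'   error).
#' @export
segment_signal <- function(stack, nucleus, method = "otsu") {
  stopifnot(inherits(stack, "VoxelStack"), is.logical(nucleus))
  check_congruent(stack, nucleus, "signal stack and nucleus mask")
  if (!any(nucleus)) stop("empty nucleus mask")
  inside <- stack$data[nucleus]
  if (diff(range(inside)) == 0) {
    # constant signal inside the nucleus: nothing to threshold. A uniformly
    # bright nucleus IS all signal; a uniformly dark one has none (flagged).
    mask <- if (inside[1] > 0) nucleus else array(FALSE, dim(stack$data))
    attr(mask, "threshold") <- NA_real_
    attr(mask, "empty") <- !any(mask)
    return(mask)
  }
  thr <- if (is.numeric(method)) method else switch(method,
    otsu = otsu_threshold(inside),
    stop("unknown threshold method: ", method))
  mask <- (stack$data > thr) & nucleus
  attr(mask, "threshold") <- thr
  attr(mask, "empty") <- !any(mask)
  mask
}
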