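#' Single-channel 3D intensity stack
#'
#' A `VoxelStack` holds one channel of a 3D image as a numeric array indexed
#' `[z, y, x]` together with its physical voxel spacing in micrometers.
#' Values are non-negative intensities; the grid is typically anisotropic
#' (z-spacing coarser than xy), matching confocal/widefield stacks acquired
#' with 0.2 um z-steps and ~0.1 um pixels.
#'
#' @param data numeric array with dim `(nz, ny, nx)`, all values >= 0.
#'   A matrix is promoted to a single-plane stack.
#' @param spacing numeric length-3 vector `(dz, dy, dx)` in micrometers.
#' @param channel character scalar channel label (e.g. `"dapi"`, `"signal"`).
#'
#' @return An object of class `VoxelStack`: a list with elements `data`,
#'   `spacing`, `channel`.
#' @examples
#' vs <- voxel_stack(array(1, c(3, 8, 8)), spacing = c(0.2, 0.1, 0.1))
#' dim(vs)
#' @export
voxel_stack <- function(data, spacing = c(0.2, 0.1, 0.1), channel = "unknown") {
  if (is.matrix(data)) data <- array(data, c(1L, nrow(data), ncol(data)))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (any(!is.finite(data))) stop("stack contains non-finite values")
  if (any(data < 0)) stop("stack intensities must be >= 0")
  if (dim(data)[1] < 1L) stop("stack needs nz >= 1")
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(list(data = data, spacing = spacing, channel = as.character(channel)),
            class = "VoxelStack")
}

#' @export
dim.VoxelStack <- function(x) dim(x$data)

#' @export
print.VoxelStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<VoxelStack '%s'> %d x %d x %d (z,y,x), spacing %.3g/%.3g/%.3g um, range [%.4g, %.4g]\n",
              x$channel, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Extract one z-plane of a stack as a matrix
#'
#' @param stack a [voxel_stack()].
#' @param z 1-based plane index.
#' @return numeric `(ny, nx)` matrix.
#' @export
stack_plane <- function(stack, z) {
  stopifnot(inherits(stack, "VoxelStack"))
  z <- as.integer(z)
  if (z < 1L || z > dim(stack$data)[1]) stop("plane index out of range")
  stack$data[z, , ]
}

check_congruent <- function(a, b, what = "objects") {
  da <- if (inherits(a, "VoxelStack")) dim(a$data) else dim(a)
  db <- if (inherits(b, "VoxelStack")) dim(b$data) else dim(b)
  if (!identical(da, db)) stop(sprintf("%s are not congruent: %s vs %s",
                                       what, paste(da, collapse = "x"),
                                       paste(db, collapse = "x")))
  invisible(TRUE)
}

#' Read a multi-page TIFF as a VoxelStack
#'
#' Pages become z-planes. Multi-sample (RGB) pages are reduced by the
#' `channel_index`-th sample. Intensities are kept on the scale returned by
#' [tiff::readTIFF()] (0-1 for integer TIFFs unless `as.is`).
#'
#' @param path TIFF file path.
#' @param spacing voxel spacing `(dz, dy, dx)` in um.
#' @param channel channel label to attach.
#' @param channel_index sample index for multi-sample pages.
#' @param as.is passed to [tiff::readTIFF()] for integer TIFFs; `TRUE`
#'   keeps raw integer counts. 32-bit float pages (as written by
#'   [write_stack_tiff()]) are multiplied by 65535, undoing the fixed
#'   16-bit-equivalent storage scale.
#' @return a [voxel_stack()].
#' @export
read_stack_tiff <- function(path, spacing = c(0.2, 0.1, 0.1),
                            channel = "unknown", channel_index = 1L,
                            as.is = TRUE) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  is_float <- identical(attr(pages[[1]], "bits.per.sample"), 32L)
  if (!is_float && as.is) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  planes <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , channel_index] else p
  })
  arr <- array(0, c(length(planes), nrow(planes[[1]]), ncol(planes[[1]])))
  for (i in seq_along(planes)) arr[i, , ] <- planes[[i]]
  if (is_float) arr <- arr * 65535
  voxel_stack(arr, spacing = spacing, channel = channel)
}

#' Write a VoxelStack (or binary mask) as a multi-page TIFF
#'
#' Intensity stacks are written as 32-bit float pages in units of 1/65535
#' (the 16-bit-equivalent scale, since TIFF float storage is defined on
#' \[0, 1\]); [read_stack_tiff()] restores original intensities, which must
#' therefore not exceed 65535. Logical masks are written as 8-bit pages.
#'
#' @param x a [voxel_stack()] or a logical 3D array.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(x, path) {
  if (inherits(x, "VoxelStack")) {
    arr <- x$data
    if (max(arr) > 65535)
      stop("intensities exceed 65535; rescale before writing")
    pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else if (is.logical(x) && length(dim(x)) == 3L) {
    pages <- lapply(seq_len(dim(x)[1]), function(z) {
      m <- matrix(0, dim(x)[2], dim(x)[3])
      m[x[z, , ]] <- 1
      m
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else stop("x must be a VoxelStack or a logical 3D array")
  invisible(path)
}

#' Write a flat key=value sidecar file
#'
#' Used for simulation truth records and parameters next to image files.
#'
#' @param x named list of scalars.
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)))
  lines <- vapply(names(x), function(k) {
    v <- x[[k]]
    paste0(k, "=", paste(format(v, digits = 15, scientific = FALSE, trim = TRUE),
                         collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key=value sidecar file
#' @param path text file written by [write_sidecar()].
#' @return named list of character vectors (numeric where parseable).
#' @export
read_sidecar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  out <- lapply(kv, function(p) {
    vals <- strsplit(p[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(vals))
    if (!anyNA(num)) num else vals
  })
  names(out) <- vapply(kv, `[`, character(1), 1)
  out
}
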