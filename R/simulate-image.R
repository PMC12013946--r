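#' Parameters for the synthetic nucleus image generator
#'
#' Describes one simulated dissected nucleus: a solid ellipsoid of DNA stain
#' containing a single chromosome-territory blob of controllable relative
#' volume, radial position and stain enrichment, rendered onto an anisotropic
#' voxel grid in physical (micrometer) coordinates.
#'
#' All geometry uses the `(z, y, x)` axis order throughout.
#'
#' @param shape integer `(nz, ny, nx)` voxel counts; `nz >= 10`.
#' @param spacing voxel spacing `(dz, dy, dx)` in um; default `0.2/0.1/0.1`,
#'   the usual anisotropic z-step vs camera pixel size.
#' @param semi_axes nucleus semi-axes `(sz, sy, sx)` in um; the ellipsoid must
#'   fit inside the grid.
#' @param f_true territory volume fraction in (0, 1]; the territory occupies
#'   this fraction of the nuclear volume. Compact (wild-type-like) X
#'   territories sit near 0.12, decondensed ones near 0.20.
#' @param r_true radial position of the territory center in \[0, 1\]:
#'   0 = nuclear centroid, 1 = as far toward the boundary as the territory
#'   fits, measured along a seeded random direction in the xy mid-plane.
#' @param k_true stain enrichment (>= 1): territory mean intensity divided by
#'   the non-territory nuclear mean in the signal channel.
#' @param base_intensity nuclear baseline intensity (arbitrary counts).
#' @param bg_level extranuclear background intensity.
#' @param gradient_amp amplitude of an optional additive linear background
#'   gradient across x (0 disables).
#' @param noise_scale noise magnitude: each voxel receives Gaussian noise with
#'   standard deviation `noise_scale * sqrt(intensity + 1)` (a Poisson-like
#'   variance scaling plus read-noise floor); 0 yields noise-free intensities.
#' @param irregular logical; if `TRUE` the territory boundary is perturbed
#'   with smoothed noise instead of being a perfect sphere.
#' @param seed integer RNG seed; the generator is bit-reproducible given
#'   `(params, seed)`.
#'
#' @return An object of class `ImageSimParams` (a validated list).
#' @seealso [image_sim_preset()], [generate_nucleus_stack()]
#' @export
image_sim_params <- function(shape = c(32L, 72L, 72L),
                             spacing = c(0.2, 0.1, 0.1),
                             semi_axes = c(2.4, 3.2, 3.2),
                             f_true = 0.125,
                             r_true = 0.6,
                             k_true = 4,
                             base_intensity = 100,
                             bg_level = 20,
                             gradient_amp = 0,
                             noise_scale = 1,
                             irregular = FALSE,
                             seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(spacing) == 3L, all(spacing > 0),
            length(semi_axes) == 3L, all(semi_axes > 0))
  if (shape[1] < 10L) stop("nz must be >= 10")
  if (!(f_true > 0 && f_true <= 1)) stop("f_true must be in (0, 1]")
  if (r_true < 0 || r_true > 1) stop("r_true must be in [0, 1]")
  if (k_true < 1) stop("k_true must be >= 1")
  if (base_intensity <= 0 || bg_level < 0) stop("invalid intensity levels")
  if (noise_scale < 0 || gradient_amp < 0) stop("noise/gradient must be >= 0")
  half <- shape * spacing / 2
  if (any(semi_axes > half))
    stop(sprintf("nucleus semi-axes (%s um) do not fit inside the grid half-extent (%s um)",
                 paste(signif(semi_axes, 3), collapse = ", "),
                 paste(signif(half, 3), collapse = ", ")))
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 semi_axes = as.numeric(semi_axes), f_true = f_true,
                 r_true = r_true, k_true = k_true,
                 base_intensity = base_intensity, bg_level = bg_level,
                 gradient_amp = gradient_amp, noise_scale = noise_scale,
                 irregular = isTRUE(irregular), seed = as.integer(seed)),
            class = "ImageSimParams")
}

#' Named presets for the image simulator
#'
#' `"wt-like"` emulates a compact, peripheral territory (volume fraction
#' 0.125, radial position 0.6); `"decondensed-like"` a decondensed, more
#' central one (volume fraction 0.20, radial position 0.3). Presets are
#' conveniences for batch simulations, not claims about any particular
#' dataset.
#'
#' @param name `"wt-like"` or `"decondensed-like"`.
#' @param ... overrides passed on to [image_sim_params()].
#' @return An `ImageSimParams` object.
#' @export
image_sim_preset <- function(name = c("wt-like", "decondensed-like"), ...) {
  name <- match.arg(name)
  base <- switch(name,
                 "wt-like" = list(f_true = 0.125, r_true = 0.6),
                 "decondensed-like" = list(f_true = 0.20, r_true = 0.3))
  do.call(image_sim_params, utils::modifyList(base, list(...)))
}

# Smooth 3D noise field in [-1, 1]-ish range: white noise blurred in-plane
# (Gaussian) and box-averaged along z.
smooth_noise_field <- function(shape, sigma = 4) {
  arr <- array(rnorm(prod(shape)), shape)
  for (z in seq_len(shape[1])) {
    arr[z, , ] <- as.matrix(EBImage::gblur(EBImage::Image(arr[z, , ]), sigma = sigma))
  }
  out <- arr
  for (z in seq_len(shape[1])) {
    zz <- max(1L, z - 1L):min(shape[1], z + 1L)
    out[z, , ] <- apply(arr[zz, , , drop = FALSE], c(2, 3), mean)
  }
  out / max(abs(out))
}

#' Simulate a two-channel nucleus stack with ground truth
#'
#' Renders a solid ellipsoidal nucleus and a single territory blob in
#' physical (um) coordinates onto the anisotropic voxel grid (voxel
#' membership by center-point test), then builds two intensity channels:
#'
#' * nuclear stain: `base_intensity` inside the nucleus, `bg_level` outside;
#' * signal stain: `k_true * base_intensity` inside the territory,
#'   `base_intensity` elsewhere in the nucleus, `bg_level` outside.
#'
#' An optional linear gradient and Poisson-Gaussian noise are added to both
#' channels; the returned truth masks are noise-free.
#'
#' The territory is a sphere holding the requested fraction `f_true` of the
#' nuclear volume, centered `r_true` of the way toward the boundary along a
#' seeded random direction in the xy mid-plane, and constrained to fit
#' entirely inside the nucleus. `f_true = 1` returns the nucleus itself as
#' the territory.
#'
#' @param params an [image_sim_params()] object.
#' @return A list with elements
#'   \describe{
#'     \item{dapi, signal}{[voxel_stack()] objects (nuclear stain, signal).}
#'     \item{truth}{list: `nucleus_mask`, `territory_mask` (logical arrays),
#'       `realized_fraction` (territory voxels / nucleus voxels),
#'       `mid_slice` (z index of the nucleus center plane),
#'       `zone_fractions` (territory zone fractions at that plane computed
#'       from the noise-free masks, when the fit is defined),
#'       `k_true`, `seed`.}
#'   }
#' @examples
#' sim <- generate_nucleus_stack(image_sim_params(noise_scale = 0, seed = 3))
#' sim$truth$realized_fraction
#' @export
generate_nucleus_stack <- function(params) {
  stopifnot(inherits(params, "ImageSimParams"))
  with_seed(params$seed, {
    shp <- params$shape; sp <- params$spacing; ax <- params$semi_axes
    cz <- shp[1] * sp[1] / 2; cy <- shp[2] * sp[2] / 2; cx <- shp[3] * sp[3] / 2
    z <- axis_coords(shp[1], sp[1]); y <- axis_coords(shp[2], sp[2])
    x <- axis_coords(shp[3], sp[3])
    # normalized squared ellipsoid coordinate per axis, broadcast over grid
    ez <- ((z - cz) / ax[1])^2
    ey <- ((y - cy) / ax[2])^2
    ex <- ((x - cx) / ax[3])^2
    quad <- outer(outer(ez, ey, `+`), ex, `+`)      # (nz, ny, nx)
    nucleus <- quad <= 1

    if (params$f_true >= 1) {
      territory <- nucleus
      t_center <- c(cz, cy, cx)
    } else {
      # sphere radius giving the requested fraction of the ellipsoid volume
      rt <- (params$f_true * prod(ax))^(1 / 3)
      inner <- ax - rt   # conservative inner ellipsoid for a guaranteed fit
      if (any(inner <= 0))
        stop(sprintf(
          "territory cannot fit: sphere radius %.3g um for f_true=%.3g exceeds a nucleus semi-axis (%s um)",
          rt, params$f_true, paste(signif(ax, 3), collapse = ", ")))
      phi <- runif(1, 0, 2 * pi)             # random direction, xy mid-plane
      u <- c(0, sin(phi), cos(phi))          # (z, y, x)
      dmax <- 1 / sqrt((u[2] / inner[2])^2 + (u[3] / inner[3])^2)
      t_center <- c(cz, cy, cx) + params$r_true * dmax * u
      d2 <- outer(outer((z - t_center[1])^2, (y - t_center[2])^2, `+`),
                  (x - t_center[3])^2, `+`)
      if (params$irregular) {
        g <- smooth_noise_field(shp)
        territory <- (sqrt(d2) <= rt * (1 + 0.15 * g)) & nucleus
      } else {
        territory <- (d2 <= rt^2) & nucleus
      }
    }

    base <- params$base_intensity
    dapi_int <- array(params$bg_level, shp)
    dapi_int[nucleus] <- base
    sig_int <- array(params$bg_level, shp)
    sig_int[nucleus] <- base
    sig_int[territory] <- params$k_true * base

    if (params$gradient_amp > 0) {
      ramp <- params$gradient_amp * (seq_len(shp[3]) - 1) / max(1L, shp[3] - 1L)
      grad <- aperm(array(ramp, c(shp[3], shp[1], shp[2])), c(2, 3, 1))
      dapi_int <- dapi_int + grad
      sig_int <- sig_int + grad
    }

    add_noise <- function(intensity) {
      if (params$noise_scale == 0) return(intensity)
      noisy <- intensity +
        rnorm(length(intensity), sd = params$noise_scale * sqrt(intensity + 1))
      pmax(array(noisy, dim(intensity)), 0)
    }
    dapi <- voxel_stack(add_noise(dapi_int), spacing = sp, channel = "dapi")
    sig <- voxel_stack(add_noise(sig_int), spacing = sp, channel = "signal")

    mid <- which.min(abs(z - cz))
    zf <- tryCatch({
      ell <- fit_ellipse(nucleus[mid, , ])
      zones <- make_zones(ell, shp[2:3])
      zone_fractions(territory[mid, , ], zones)
    }, error = function(e) NULL)

    truth <- list(nucleus_mask = nucleus, territory_mask = territory,
                  realized_fraction = sum(territory) / sum(nucleus),
                  mid_slice = mid, zone_fractions = zf,
                  territory_center = t_center,
                  k_true = params$k_true, seed = params$seed)
    list(dapi = dapi, signal = sig, truth = truth)
  })
}

#' Write a simulated nucleus to disk
#'
#' Writes the two channels as 32-bit float multi-page TIFFs
#' (`<prefix>_dapi.tif`, `<prefix>_sig.tif`), the truth masks as 8-bit TIFFs
#' (`<prefix>_nucleus_mask.tif`, `<prefix>_territory_mask.tif`) and the
#' parameters plus realized truth as a `key=value` sidecar
#' (`<prefix>_truth.txt`).
#'
#' @param sim result of [generate_nucleus_stack()].
#' @param prefix output path prefix (directories must exist).
#' @param params the [image_sim_params()] used (recorded in the sidecar).
#' @return Named character vector of the files written, invisibly.
#' @export
write_nucleus_sim <- function(sim, prefix, params = NULL) {
  files <- c(dapi = paste0(prefix, "_dapi.tif"),
             sig = paste0(prefix, "_sig.tif"),
             nucleus_mask = paste0(prefix, "_nucleus_mask.tif"),
             territory_mask = paste0(prefix, "_territory_mask.tif"),
             truth = paste0(prefix, "_truth.txt"))
  write_stack_tiff(sim$dapi, files[["dapi"]])
  write_stack_tiff(sim$signal, files[["sig"]])
  write_stack_tiff(sim$truth$nucleus_mask, files[["nucleus_mask"]])
  write_stack_tiff(sim$truth$territory_mask, files[["territory_mask"]])
  rec <- list(realized_fraction = sim$truth$realized_fraction,
              mid_slice = sim$truth$mid_slice,
              k_true = sim$truth$k_true, seed = sim$truth$seed)
  if (!is.null(sim$truth$zone_fractions))
    rec$zone_fractions <- unname(unlist(sim$truth$zone_fractions))
  if (!is.null(params))
    rec <- c(rec, params[c("shape", "spacing", "semi_axes", "f_true", "r_true",
                           "k_true", "base_intensity", "bg_level",
                           "gradient_amp", "noise_scale")])
  write_sidecar(rec, files[["truth"]])
  invisible(files)
}
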