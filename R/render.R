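#' Construct an image stack
#'
#' A thin container: a 3D numeric array in (z, y, x) order carrying its
#' physical voxel size and channel name as attributes. Voxel centres follow
#' the half-voxel convention: the centre of 0-based voxel `i` sits at
#' `(i + 0.5) * voxel_size`.
#'
#' @param voxels 3D numeric array `(z, y, x)`.
#' @param voxel_size Named numeric `c(xy = , z = )` in nm.
#' @param channel Channel name.
#' @return An `image_stack` object.
#' @export
image_stack <- function(voxels, voxel_size = c(xy = 107.5, z = 200),
                        channel = "unknown") {
  stopifnot(length(dim(voxels)) == 3)
  if (any(voxel_size <= 0)) abort("voxel_size must be strictly positive")
  if (any(!is.finite(voxels)) || any(voxels < 0)) {
    abort("intensities must be finite and >= 0")
  }
  structure(voxels, voxel_size = voxel_size, channel = channel,
            class = c("image_stack", "array"))
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_stack %s> %d x %d x %d (z,y,x), voxel %g/%g nm\n",
              attr(x, "channel"), d[1], d[2], d[3],
              attr(x, "voxel_size")[["xy"]], attr(x, "voxel_size")[["z"]]))
  invisible(x)
}

voxel_size_of <- function(stack) {
  attr(stack, "voxel_size") %||% c(xy = 107.5, z = 200)
}

# Separable 3D Gaussian blur: EBImage::gblur slice-wise in xy when the
# kernel fits the slice, otherwise (and always along z) a 1D weighted sum
# of shifted slabs with replicate edges. Sigmas in voxels.
blur3d <- function(arr, sigma_xy, sigma_z) {
  d <- dim(arr)
  out <- arr
  if (sigma_xy > 0) {
    brush <- 2 * ceiling(3 * sigma_xy) + 1
    if (brush <= min(d[2], d[3])) {
      for (k in seq_len(d[1])) {
        out[k, , ] <- imageData(gblur(Image(out[k, , ]), sigma = sigma_xy))
      }
    } else {
      out <- blur_axis(blur_axis(out, 2, sigma_xy), 3, sigma_xy)
    }
  }
  if (sigma_z > 0 && d[1] > 1) {
    out <- blur_axis(out, 1, sigma_z)
  }
  out
}

# 1D Gaussian convolution along one axis of a 3D array, replicate padding
blur_axis <- function(arr, axis, sigma) {
  d <- dim(arr)
  n <- d[axis]
  half <- min(max(1L, ceiling(3 * sigma)), n - 1L)
  w <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  w <- w / sum(w)
  acc <- array(0, d)
  for (j in seq(-half, half)) {
    src <- pmin(pmax(seq_len(n) + j, 1L), n)
    acc <- acc + w[j + half + 1] * switch(axis,
      arr[src, , , drop = FALSE],
      arr[, src, , drop = FALSE],
      arr[, , src, drop = FALSE])
  }
  acc
}

# Add one Gaussian spot to `arr` in place-ish (returns modified array).
# Positions in nm; amplitude scaled so the voxel sum approximates
# `intensity` (integral of the continuous Gaussian / voxel volume).
render_spot <- function(arr, z_nm, y_nm, x_nm, intensity, vox, psf) {
  d <- dim(arr)
  sxy <- psf[["xy"]]; sz <- psf[["z"]]
  amp <- intensity * (vox[["xy"]]^2 * vox[["z"]]) /
    ((2 * pi)^1.5 * sxy^2 * sz)
  # window of +-4 sigma around the spot, clipped to the field
  cz <- z_nm / vox[["z"]] + 0.5; cy <- y_nm / vox[["xy"]] + 0.5
  cx <- x_nm / vox[["xy"]] + 0.5  # 1-based voxel-centre coordinates
  rz <- ceiling(4 * sz / vox[["z"]]); rxy <- ceiling(4 * sxy / vox[["xy"]])
  iz <- max(1, floor(cz - rz)):min(d[1], ceiling(cz + rz))
  iy <- max(1, floor(cy - rxy)):min(d[2], ceiling(cy + rxy))
  ix <- max(1, floor(cx - rxy)):min(d[3], ceiling(cx + rxy))
  if (length(iz) == 0 || length(iy) == 0 || length(ix) == 0) return(arr)
  gz <- exp(-((iz - cz) * vox[["z"]])^2 / (2 * sz^2))
  gy <- exp(-((iy - cy) * vox[["xy"]])^2 / (2 * sxy^2))
  gx <- exp(-((ix - cx) * vox[["xy"]])^2 / (2 * sxy^2))
  arr[iz, iy, ix] <- arr[iz, iy, ix] +
    amp * (gz %o% gy %o% gx)
  arr
}

#' Render simulated ground truth into per-channel 3D image stacks
#'
#' Each spot becomes an anisotropic 3D Gaussian (PSF widths from
#' `config$psf_sigma_nm`) whose voxel sum equals its true intensity. The DAPI
#' channel renders filled nuclei and the `background` channel a diffuse
#' cytoplasmic haze (the probe background used for cell outlining). Poisson
#' shot noise is applied first, then additive Gaussian read noise.
#' Per-channel drift is applied to spot coordinates before rendering. Spots
#' outside the field are clipped with a warning.
#'
#' @param sim Result of [simulate_cells()].
#' @param config The [sim_config()] in use.
#' @param channels Channels to render (subset of
#'   `c("mrna", "fluc", "suntag", "ago", "dapi", "background")`).
#' @param noise Apply the configured noise model (set `FALSE` for noiseless
#'   renders).
#' @return Named list of [image_stack()] objects.
#' @export
render_field <- function(sim, config = sim_config(),
                         channels = c("mrna", "suntag", "ago", "dapi",
                                      "background"),
                         noise = TRUE) {
  d <- unname(config$field_shape[c("z", "y", "x")])
  vox <- config$voxel_size
  fy <- d[2] * vox[["xy"]]; fx <- d[3] * vox[["xy"]]; fz <- d[1] * vox[["z"]]

  channel_of <- c(reporter_mRNA = "mrna", fluc_mRNA = "fluc",
                  suntag_on_mRNA = "suntag", suntag_free = "suntag",
                  ago_on_mRNA = "ago", ago_free = "ago")
  truth <- sim$truth
  truth$channel <- unname(channel_of[truth$species])

  out_of_field <- truth$x_nm < 0 | truth$x_nm > fx |
    truth$y_nm < 0 | truth$y_nm > fy | truth$z_nm < 0 | truth$z_nm > fz
  if (any(out_of_field)) {
    warn(sprintf("%d spot(s) fall outside the field and were clipped",
                 sum(out_of_field)))
    truth <- truth[!out_of_field, ]
  }

  set.seed(cell_seed(config$seed, -2L) + 1)
  out <- list()
  for (ch in channels) {
    arr <- array(0, d)
    if (ch %in% c("dapi", "background")) {
      yy <- (seq_len(d[2]) - 0.5) * vox[["xy"]]
      xx <- (seq_len(d[3]) - 0.5) * vox[["xy"]]
      mask <- matrix(0, d[2], d[3])
      for (k in seq_len(nrow(sim$geometry))) {
        g <- sim$geometry[k, ]
        if (ch == "dapi") {
          m <- outer(yy, xx, function(y, x)
            in_ellipse(x, y, g$nuc_x_nm, g$nuc_y_nm, g$nuc_a_nm, g$nuc_b_nm))
        } else {
          m <- outer(yy, xx, function(y, x)
            in_ellipse(x, y, g$center_x_nm, g$center_y_nm,
                       g$cell_a_nm, g$cell_b_nm))
        }
        mask <- pmax(mask, m * 1)
      }
      level <- if (ch == "dapi") 400 else 60
      slab <- imageData(gblur(Image(mask * level), sigma = 3))
      for (k in seq_len(d[1])) arr[k, , ] <- slab
    } else {
      sp <- truth[truth$channel == ch, ]
      dr <- config$drift_nm[[ch]] %||% c(0, 0, 0)
      for (i in seq_len(nrow(sp))) {
        arr <- render_spot(arr, sp$z_nm[i] + dr[[1]], sp$y_nm[i] + dr[[2]],
                           sp$x_nm[i] + dr[[3]], sp$intensity[i], vox,
                           config$psf_sigma_nm)
      }
    }
    arr <- arr + config$bg_offset
    if (noise) {
      if (config$noise[["shot"]] > 0) {
        s <- config$noise[["shot"]]
        arr <- array(rpois(length(arr), pmax(arr, 0) * s) / s, d)
      }
      if (config$noise[["read"]] > 0) {
        arr <- arr + array(rnorm(length(arr), 0, config$noise[["read"]]), d)
      }
      arr <- pmax(arr, 0)
    }
    out[[ch]] <- image_stack(arr, vox, ch)
  }
  out
}
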