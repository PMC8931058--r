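#' Subtract the smooth background of a stack
#'
#' Removes the low-frequency component by subtracting a large-sigma Gaussian
#' blur of the stack from itself; negative residuals are clamped to zero.
#'
#' @param stack An [image_stack()].
#' @param sigma_nm Named `c(xy = , z = )` blur widths in nm (default 10x a
#'   typical PSF laterally).
#' @return Background-subtracted [image_stack()].
#' @export
subtract_background <- function(stack, sigma_nm = c(xy = 1500, z = 1200)) {
  vox <- voxel_size_of(stack)
  bg <- blur3d(unclass(stack), sigma_nm[["xy"]] / vox[["xy"]],
               sigma_nm[["z"]] / vox[["z"]])
  image_stack(pmax(unclass(stack) - bg, 0), vox, attr(stack, "channel"))
}

# strict 26-neighbourhood local maxima of a 3D array (out-of-field
# neighbours count as -Inf, so border voxels can still qualify)
local_maxima_3d <- function(arr) {
  d <- dim(arr)
  shift_arr <- function(a, dz, dy, dx) {
    out <- array(-Inf, d)
    zs <- max(1, 1 + dz):min(d[1], d[1] + dz)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    xs <- max(1, 1 + dx):min(d[3], d[3] + dx)
    out[zs, ys, xs] <- a[zs - dz, ys - dy, xs - dx, drop = FALSE]
    out
  }
  is_max <- array(TRUE, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    is_max <- is_max & (arr > shift_arr(arr, dz, dy, dx))
  }
  which(is_max, arr.ind = TRUE)
}

#' Detect candidate spot positions
#'
#' Difference-of-Gaussians band-pass at the expected PSF scale, strict
#' 26-neighbourhood local maxima, thresholded at
#' `mean + threshold_sigmas * sd` of the filter response.
#'
#' @param stack Background-subtracted [image_stack()].
#' @param threshold_sigmas Detection threshold in response s.d. units
#'   (default 5).
#' @param psf_sigma_nm Expected PSF widths `c(xy = , z = )` in nm.
#' @return Tibble of 1-based integer voxel seeds (`vz`, `vy`, `vx`) with the
#'   filter `response`, strongest first.
#' @export
detect_candidates <- function(stack, threshold_sigmas = 5,
                              psf_sigma_nm = c(xy = 150, z = 300)) {
  vox <- voxel_size_of(stack)
  s_xy <- psf_sigma_nm[["xy"]] / vox[["xy"]]
  s_z <- psf_sigma_nm[["z"]] / vox[["z"]]
  a <- unclass(stack)
  resp <- blur3d(a, s_xy, s_z) - blur3d(a, 1.6 * s_xy, 1.6 * s_z)
  thr <- mean(resp) + threshold_sigmas * sd(resp)
  mx <- local_maxima_3d(resp)
  vals <- resp[mx]
  keep <- vals > thr
  tibble(vz = mx[keep, 1], vy = mx[keep, 2], vx = mx[keep, 3],
         response = vals[keep]) |>
    arrange(desc(.data$response))
}

#' Fit a 3D Gaussian to one spot
#'
#' Least-squares fit of an elliptical Gaussian
#' `A * exp(-((dx^2 + dy^2) / (2 s_xy^2) + dz^2 / (2 s_z^2))) + b` over a
#' window around a seed voxel. Positions are reported in nm under the
#' half-voxel centre convention. The integrated intensity is the analytic
#' Gaussian integral expressed in voxel-sum units:
#' `A * (2*pi)^{3/2} * s_xy^2 * s_z / voxel volume`.
#'
#' @param stack [image_stack()] (background need not be subtracted; a local
#'   offset is fit).
#' @param seed Integer vector `c(vz, vy, vx)` (1-based voxel indices).
#' @param window Odd window extents `c(z = 5, y = 9, x = 9)` in voxels;
#'   shrunk at stack boundaries.
#' @param sigma_start PSF width starting values in nm.
#' @return One-row tibble: positions in nm, `amplitude`, `background`,
#'   `sigma_xy_nm`, `sigma_z_nm`, `integrated_intensity`, normalized
#'   `residual`, `valid` flag.
#' @export
fit_spot_3d <- function(stack, seed, window = c(z = 5, y = 9, x = 9),
                        sigma_start = c(xy = 150, z = 300)) {
  vox <- voxel_size_of(stack)
  d <- dim(stack)
  hz <- (window[["z"]] - 1) %/% 2
  hy <- (window[["y"]] - 1) %/% 2
  hx <- (window[["x"]] - 1) %/% 2
  iz <- max(1, seed[1] - hz):min(d[1], seed[1] + hz)
  iy <- max(1, seed[2] - hy):min(d[2], seed[2] + hy)
  ix <- max(1, seed[3] - hx):min(d[3], seed[3] + hx)
  w <- unclass(stack)[iz, iy, ix, drop = FALSE]

  zc <- (iz - 0.5) * vox[["z"]]
  yc <- (iy - 0.5) * vox[["xy"]]
  xc <- (ix - 0.5) * vox[["xy"]]
  grid <- expand.grid(z = zc, y = yc, x = xc)
  v <- as.vector(w)

  b0 <- min(v); a0 <- max(v) - b0
  wt <- pmax(v - b0, 0)
  if (sum(wt) == 0) wt <- rep(1, length(v))
  z0 <- sum(grid$z * wt) / sum(wt)
  y0 <- sum(grid$y * wt) / sum(wt)
  x0 <- sum(grid$x * wt) / sum(wt)

  # parameters: log A, b, z0, y0, x0, log s_xy, log s_z
  obj <- function(p) {
    A <- exp(p[1]); sxy <- exp(p[6]); sz <- exp(p[7])
    mu <- A * exp(-(((grid$x - p[5])^2 + (grid$y - p[4])^2) / (2 * sxy^2) +
                      (grid$z - p[3])^2 / (2 * sz^2))) + p[2]
    sum((v - mu)^2)
  }
  p0 <- c(log(max(a0, 1e-6)), b0, z0, y0, x0,
          log(sigma_start[["xy"]]), log(sigma_start[["z"]]))
  fit <- tryCatch(
    optim(p0, obj, method = "BFGS",
          control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL
  )
  bad <- is.null(fit)
  if (!bad) {
    p <- fit$par
    A <- exp(p[1]); b <- p[2]; sxy <- exp(p[6]); sz <- exp(p[7])
    inside <- p[3] >= min(zc) - vox[["z"]] && p[3] <= max(zc) + vox[["z"]] &&
      p[4] >= min(yc) - vox[["xy"]] && p[4] <= max(yc) + vox[["xy"]] &&
      p[5] >= min(xc) - vox[["xy"]] && p[5] <= max(xc) + vox[["xy"]]
    resid <- sqrt(fit$value / length(v)) / max(A, 1e-12)
    tibble(
      z_nm = p[3], y_nm = p[4], x_nm = p[5],
      amplitude = A, background = b,
      sigma_xy_nm = sxy, sigma_z_nm = sz,
      integrated_intensity = A * (2 * pi)^1.5 * sxy^2 * sz /
        (vox[["xy"]]^2 * vox[["z"]]),
      residual = resid,
      valid = inside && A > 0 && fit$convergence == 0
    )
  } else {
    tibble(z_nm = NA_real_, y_nm = NA_real_, x_nm = NA_real_,
           amplitude = NA_real_, background = NA_real_,
           sigma_xy_nm = NA_real_, sigma_z_nm = NA_real_,
           integrated_intensity = NA_real_, residual = NA_real_,
           valid = FALSE)
  }
}

#' Quality-filter fitted spots
#'
#' Drops invalid fits, fits whose width, amplitude or residual falls outside
#' the configured physical bounds, and duplicate fits that converged to
#' within one voxel of a brighter spot (the brighter one is kept).
#'
#' @param spots Tibble of [fit_spot_3d()] rows.
#' @param voxel_size Voxel size `c(xy = , z = )` in nm (for the 1-voxel
#'   duplicate radius).
#' @param sigma_xy_bounds,sigma_z_bounds Allowed PSF-width ranges in nm.
#' @param max_residual Maximum normalized fit residual.
#' @return Filtered tibble with an `intensity` column set to the integrated
#'   intensity (the quantity used by all downstream metrics).
#' @export
filter_spots <- function(spots, voxel_size = c(xy = 107.5, z = 200),
                         sigma_xy_bounds = c(50, 400),
                         sigma_z_bounds = c(100, 800),
                         max_residual = 1) {
  if (nrow(spots) == 0) {
    return(mutate(spots, intensity = numeric(0)))
  }
  ok <- spots |>
    filter(.data$valid,
           .data$amplitude > 0,
           .data$sigma_xy_nm >= sigma_xy_bounds[1],
           .data$sigma_xy_nm <= sigma_xy_bounds[2],
           .data$sigma_z_nm >= sigma_z_bounds[1],
           .data$sigma_z_nm <= sigma_z_bounds[2],
           .data$residual <= max_residual) |>
    arrange(desc(.data$integrated_intensity))
  keep <- rep(TRUE, nrow(ok))
  if (nrow(ok) > 1) {
    for (i in 2:nrow(ok)) {
      j <- which(keep[seq_len(i - 1)])
      dup <- abs(ok$z_nm[j] - ok$z_nm[i]) < voxel_size[["z"]] &
        abs(ok$y_nm[j] - ok$y_nm[i]) < voxel_size[["xy"]] &
        abs(ok$x_nm[j] - ok$x_nm[i]) < voxel_size[["xy"]]
      if (any(dup)) keep[i] <- FALSE
    }
  }
  ok[keep, ] |>
    mutate(intensity = .data$integrated_intensity)
}

#' Detect, fit and filter spots in one call
#'
#' Runs [subtract_background()], [detect_candidates()], [fit_spot_3d()] per
#' seed and [filter_spots()].
#'
#' @inheritParams detect_candidates
#' @inheritParams fit_spot_3d
#' @param channel Channel label attached to the output.
#' @param ... Passed to [filter_spots()].
#' @return Spot tibble (`spot_id`, `channel`, positions in nm, `amplitude`,
#'   `integrated_intensity`, `intensity`, sigmas, `background`, `residual`).
#' @export
detect_spots <- function(stack, threshold_sigmas = 5,
                         psf_sigma_nm = c(xy = 150, z = 300),
                         window = c(z = 5, y = 9, x = 9),
                         channel = attr(stack, "channel"), ...) {
  bs <- subtract_background(stack)
  cand <- detect_candidates(bs, threshold_sigmas, psf_sigma_nm)
  if (nrow(cand) == 0) {
    return(tibble(spot_id = integer(0), channel = character(0),
                  z_nm = numeric(0), y_nm = numeric(0), x_nm = numeric(0),
                  amplitude = numeric(0), background = numeric(0),
                  sigma_xy_nm = numeric(0), sigma_z_nm = numeric(0),
                  integrated_intensity = numeric(0), residual = numeric(0),
                  valid = logical(0), intensity = numeric(0)))
  }
  fits <- map(seq_len(nrow(cand)), function(i) {
    fit_spot_3d(bs, c(cand$vz[i], cand$vy[i], cand$vx[i]), window,
                sigma_start = psf_sigma_nm)
  }) |> list_rbind()
  out <- filter_spots(fits, voxel_size = voxel_size_of(stack), ...)
  out |>
    mutate(spot_id = seq_len(nrow(out)), channel = channel, .before = 1)
}
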