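# Internal helpers shared across modules.

# Deterministic per-cell seed derived from the global seed, so that single
# cells can be regenerated without replaying the whole field. Kept < 2^31.
cell_seed <- function(seed, cell_id) {
  (as.numeric(seed) * 7919 + as.numeric(cell_id) * 104729) %% 2147483647
}

# Anisotropic squared Euclidean distance in nm between two spot tables
# (row-wise cross product), returned as a dense matrix. Inputs must carry
# z_nm / y_nm / x_nm columns. Intended for per-cell blocks (<= few thousand
# rows each).
cross_dist <- function(a, b) {
  dz <- outer(a$z_nm, b$z_nm, "-")
  dy <- outer(a$y_nm, b$y_nm, "-")
  dx <- outer(a$x_nm, b$x_nm, "-")
  sqrt(dz^2 + dy^2 + dx^2)
}

check_spot_table <- function(x, arg = deparse(substitute(x))) {
  need <- c("z_nm", "y_nm", "x_nm")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with z_nm, y_nm, x_nm columns", arg))
  }
  invisible(x)
}

# Uniform sample inside a 2D ellipse (axis-aligned), returned in nm.
sample_ellipse <- function(n, cx, cy, a, b) {
  r <- sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  tibble(x_nm = cx + a * r * cos(th), y_nm = cy + b * r * sin(th))
}

in_ellipse <- function(x, y, cx, cy, a, b) {
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

# Uniform sample in the cytoplasmic annulus (cell ellipse minus nucleus
# ellipse) by rejection from the cell ellipse.
sample_cytoplasm <- function(n, geom) {
  out <- tibble(x_nm = numeric(0), y_nm = numeric(0))
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    p <- sample_ellipse(m, geom$center_x_nm, geom$center_y_nm,
                        geom$cell_a_nm, geom$cell_b_nm)
    keep <- !in_ellipse(p$x_nm, p$y_nm, geom$nuc_x_nm, geom$nuc_y_nm,
                        geom$nuc_a_nm, geom$nuc_b_nm)
    out <- bind_rows(out, p[keep, ])
  }
  out[seq_len(n), ]
}

# Isotropic 3D Gaussian jitter truncated so the displaced point stays within
# `max_r` nm of the origin spot (partners must colocalize by construction).
truncated_jitter <- function(n, sigma, max_r) {
  dz <- rnorm(n, 0, sigma); dy <- rnorm(n, 0, sigma); dx <- rnorm(n, 0, sigma)
  bad <- which(dz^2 + dy^2 + dx^2 > max_r^2)
  while (length(bad) > 0) {
    dz[bad] <- rnorm(length(bad), 0, sigma)
    dy[bad] <- rnorm(length(bad), 0, sigma)
    dx[bad] <- rnorm(length(bad), 0, sigma)
    bad <- bad[dz[bad]^2 + dy[bad]^2 + dx[bad]^2 > max_r^2]
  }
  tibble(dz = dz, dy = dy, dx = dx)
}

signif_band <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.05 ~ "*", TRUE ~ "n.s.")
}
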