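#' Segment nuclei from the DAPI channel
#'
#' Maximum-intensity projection, Gaussian smoothing, global Otsu threshold,
#' hole filling, and a distance-transform watershed to split touching
#' nuclei; objects below a minimum area are removed.
#'
#' @param dapi DAPI [image_stack()] (or a 2D matrix already projected).
#' @param sigma_px Smoothing sigma in pixels.
#' @param min_area_um2 Minimum nucleus area in square micrometres.
#' @param threshold Absolute threshold overriding Otsu (optional).
#' @return Integer label matrix (y, x); 0 is background.
#' @export
segment_nuclei <- function(dapi, sigma_px = 3, min_area_um2 = 10,
                           threshold = NULL) {
  vox <- voxel_size_of(dapi)
  proj <- project_max(dapi)
  if (max(proj) == 0) return(matrix(0L, nrow(proj), ncol(proj)))
  sm <- imageData(gblur(Image(proj / max(proj)), sigma = sigma_px))
  thr <- threshold %||% otsu(Image(sm), range = c(0, 1))
  mask <- sm > thr
  if (!any(mask)) return(matrix(0L, nrow(proj), ncol(proj)))
  mask <- imageData(fillHull(Image(mask * 1))) > 0
  dm <- distmap(Image(mask * 1))
  labels <- imageData(watershed(dm, tolerance = 1))
  min_px <- min_area_um2 * 1e6 / vox[["xy"]]^2
  tab <- table(labels[labels > 0])
  small <- as.integer(names(tab)[tab < min_px])
  labels[labels %in% small] <- 0L
  relabel(labels)
}

#' Segment cell outlines seeded by nuclei
#'
#' Seeded region growing (CellProfiler-style propagation) on the smoothed
#' probe-background projection: each nucleus label expands into the
#' thresholded haze, so every cell contains exactly its seed nucleus and
#' touching cells are partitioned along intensity ridges.
#'
#' @param background Probe-background [image_stack()] (the non-specific
#'   smFISH haze that outlines cells).
#' @param nuclei Label matrix from [segment_nuclei()].
#' @param sigma_px Smoothing sigma in pixels.
#' @param threshold Absolute threshold overriding Otsu (optional).
#' @return Integer label matrix of cells, labels matching the seed nuclei.
#' @export
segment_cells <- function(background, nuclei, sigma_px = 3,
                          threshold = NULL) {
  if (is.null(background)) {
    abort(paste("background channel missing: cell outlines need the probe",
                "haze; use spots-only mode instead"))
  }
  proj <- project_max(background)
  sm <- imageData(gblur(Image(proj / max(proj)), sigma = sigma_px))
  thr <- threshold %||% otsu(Image(sm), range = c(0, 1))
  mask <- sm > thr | nuclei > 0
  labels <- imageData(propagate(Image(sm), Image(nuclei), mask = mask,
                                lambda = 1e-4))
  storage.mode(labels) <- "integer"
  labels
}

project_max <- function(stack) {
  if (is.matrix(stack)) return(stack)
  apply(unclass(stack), c(2, 3), max)
}

relabel <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (i in seq_along(u)) out[labels == u[i]] <- i
  out
}

#' Build per-cell geometry from label masks
#'
#' @param nuclei,cells Label matrices from [segment_nuclei()] /
#'   [segment_cells()].
#' @param voxel_size Voxel size `c(xy = , z = )` in nm.
#' @return A `cell_geometry_masks` list: the two label matrices, the pixel
#'   size, and a tibble with `cell_id`, `nucleus_area_um2`,
#'   `touches_border`.
#' @export
geometry_from_masks <- function(nuclei, cells,
                                voxel_size = c(xy = 107.5, z = 200)) {
  ids <- sort(unique(cells[cells > 0]))
  border <- unique(c(cells[1, ], cells[nrow(cells), ],
                     cells[, 1], cells[, ncol(cells)]))
  tab <- tibble(
    cell_id = as.integer(ids),
    nucleus_area_um2 = map_dbl_int(ids, function(i)
      sum(nuclei == i) * voxel_size[["xy"]]^2 / 1e6),
    touches_border = ids %in% border
  )
  structure(list(nuclei = nuclei, cells = cells, voxel_size = voxel_size,
                 table = tab),
            class = "cell_geometry_masks")
}

map_dbl_int <- function(x, f) vapply(x, f, numeric(1))

#' Assign spots to cells and compartments
#'
#' Each spot is assigned by its (y, x) position only (outlines are 2D
#' projections): nuclear if it falls inside a nucleus, cytoplasmic if inside
#' a cell but outside its nucleus, `unassigned` (and excluded downstream)
#' otherwise. Accepts either mask-based geometry from
#' [geometry_from_masks()] or the parametric ellipse geometry emitted by
#' [simulate_cells()].
#'
#' @param spots Spot tibble with `y_nm`, `x_nm`.
#' @param geometry `cell_geometry_masks` or the simulator geometry tibble.
#' @return `spots` with `cell_id` and `compartment` columns replaced.
#' @export
assign_compartment <- function(spots, geometry) {
  check_spot_table(spots)
  if (inherits(geometry, "cell_geometry_masks")) {
    px <- geometry$voxel_size[["xy"]]
    iy <- pmin(pmax(ceiling(spots$y_nm / px), 1L), nrow(geometry$cells))
    ix <- pmin(pmax(ceiling(spots$x_nm / px), 1L), ncol(geometry$cells))
    lin <- cbind(iy, ix)
    cell <- geometry$cells[lin]
    nuc <- geometry$nuclei[lin]
    spots$cell_id <- ifelse(cell > 0, as.integer(cell), NA_integer_)
    spots$compartment <- case_when(
      nuc > 0 ~ "nuclear",
      cell > 0 ~ "cytoplasmic",
      TRUE ~ "unassigned"
    )
  } else {
    g <- geometry
    cell_id <- rep(NA_integer_, nrow(spots))
    comp <- rep("unassigned", nrow(spots))
    for (k in seq_len(nrow(g))) {
      innuc <- in_ellipse(spots$x_nm, spots$y_nm, g$nuc_x_nm[k],
                          g$nuc_y_nm[k], g$nuc_a_nm[k], g$nuc_b_nm[k])
      incell <- in_ellipse(spots$x_nm, spots$y_nm, g$center_x_nm[k],
                           g$center_y_nm[k], g$cell_a_nm[k], g$cell_b_nm[k])
      hit <- is.na(cell_id) & (innuc | incell)
      cell_id[hit] <- g$cell_id[k]
      comp[hit] <- ifelse(innuc[hit], "nuclear", "cytoplasmic")
    }
    spots$cell_id <- cell_id
    spots$compartment <- comp
  }
  spots
}
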