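# Dataset layout on disk:
#   <run>/<condition>/<time>/spots_<channel>.csv  + geometry.csv + meta.yaml
# or, in image mode,
#   <run>/<condition>/<time>/cellXX_<channel>.tif + meta.yaml
# Channels are resolved by name, never by position.

#' Write a spots-only dataset to disk
#'
#' @param tables Named list of spot tibbles (from [emit_spot_tables()] or
#'   [detect_spots()]).
#' @param geometry Geometry tibble.
#' @param dir Output directory (created).
#' @param voxel_size Voxel size recorded in `meta.yaml`.
#' @return `dir`, invisibly.
#' @export
write_spot_dataset <- function(tables, geometry, dir,
                               voxel_size = c(xy = 107.5, z = 200)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in names(tables)) {
    write_csv(tables[[ch]], file.path(dir, paste0("spots_", ch, ".csv")))
  }
  write_csv(geometry, file.path(dir, "geometry.csv"))
  write_yaml(list(voxel_size = as.list(voxel_size)),
             file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a dataset directory
#'
#' Loads spot-table CSVs (resolved by channel name) and geometry, and
#' validates the recorded voxel size against the supplied configuration,
#' warning on mismatch.
#'
#' @param dir Dataset directory.
#' @param config Optional [sim_config()] whose voxel size is checked
#'   against the dataset metadata.
#' @return List with `tables` (named by channel), `geometry`,
#'   `voxel_size`.
#' @export
read_spot_dataset <- function(dir, config = NULL) {
  files <- list.files(dir, pattern = "^spots_.*\\.csv$", full.names = TRUE)
  if (length(files) == 0) {
    abort(sprintf("no spot tables (spots_<channel>.csv) found in %s", dir))
  }
  chans <- sub("^spots_(.*)\\.csv$", "\\1", basename(files))
  tables <- setNames(lapply(files, read_csv, show_col_types = FALSE), chans)
  geom_path <- file.path(dir, "geometry.csv")
  geometry <- if (file.exists(geom_path)) {
    read_csv(geom_path, show_col_types = FALSE)
  } else {
    NULL
  }
  meta_path <- file.path(dir, "meta.yaml")
  voxel_size <- NULL
  if (file.exists(meta_path)) {
    voxel_size <- unlist(read_yaml(meta_path)$voxel_size)
  }
  if (!is.null(config) && !is.null(voxel_size) &&
      any(abs(voxel_size - config$voxel_size[names(voxel_size)]) > 1e-6)) {
    warn(sprintf(
      "dataset voxel size (%s) differs from configured (%s)",
      paste(voxel_size, collapse = "/"),
      paste(config$voxel_size, collapse = "/")))
  }
  list(tables = tables, geometry = geometry, voxel_size = voxel_size)
}

#' Write and read image stacks as TIFF
#'
#' Stacks are stored one file per channel in ZYX slice order, values scaled
#' to the 16-bit range on write.
#'
#' @param stack An [image_stack()].
#' @param path Output .tif path.
#' @param scale Divisor mapping intensities to `[0, 1]` for TIFF storage
#'   (default: stack maximum).
#' @return `write_stack()`: `path` invisibly (with the scale recorded in a
#'   sidecar yaml); `read_stack()`: an [image_stack()].
#' @export
write_stack <- function(stack, path, scale = NULL) {
  scale <- scale %||% max(stack)
  if (scale <= 0) scale <- 1
  d <- dim(stack)
  slices <- lapply(seq_len(d[1]), function(k)
    pmin(unclass(stack)[k, , ] / scale, 1))
  writeTIFF(slices, path, bits.per.sample = 16L)
  write_yaml(list(scale = scale,
                  voxel_size = as.list(voxel_size_of(stack)),
                  channel = attr(stack, "channel")),
             paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  slices <- readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".yaml")
  meta <- if (file.exists(meta_path)) read_yaml(meta_path) else list()
  scale <- meta$scale %||% 1
  vox <- unlist(meta$voxel_size %||% list(xy = 107.5, z = 200))
  d <- c(length(slices), dim(slices[[1]]))
  arr <- array(0, d)
  for (k in seq_along(slices)) arr[k, , ] <- slices[[k]] * scale
  image_stack(arr, vox, meta$channel %||% "unknown")
}

#' Save the result bundle of an experiment
#'
#' Writes `metrics_per_cell.csv`, `metrics_bulk.json`, `classes.csv`,
#' `stats.csv` and `manifest.json` under `dir`.
#'
#' @param experiment A `silence_experiment` from [run_experiment()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_csv(experiment$per_cell, file.path(dir, "metrics_per_cell.csv"))
  write_json(experiment$bulk, file.path(dir, "metrics_bulk.json"),
             dataframe = "rows", auto_unbox = TRUE, digits = NA)
  write_csv(experiment$classes, file.path(dir, "classes.csv"))
  stats_tab <- tidy(experiment)
  if (nrow(stats_tab) > 0) {
    write_csv(stats_tab, file.path(dir, "stats.csv"))
  }
  write_json(experiment$manifest, file.path(dir, "manifest.json"),
             auto_unbox = TRUE)
  invisible(dir)
}
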