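#' Per-cell silencing metrics
#'
#' Computes, for each cell, the count and intensity ingredients and the six
#' per-cell ratios of the single-cell analysis:
#' * `S = M_sun_cyto / M_fluc_cyto` (mRNA stability),
#' * `T_eff = I_sun_coloc_cyto / M_sun_cyto` (translational efficiency),
#' * `T_fra = M_sun_coloc_cyto / M_sun_cyto` (fraction translated),
#' * `A_eff = I_ago_coloc_cyto / M_sun_cyto` (RISC-binding efficiency),
#' * `A_fra = M_ago_coloc_cyto / M_sun_cyto` (fraction RISC-positive),
#' * `E = M_sun_cyto / M_sun_nuc` (export efficiency).
#' A ratio whose denominator is zero is `NA` (the cell is excluded from that
#' metric, not an error). Cells flagged `touches_border` in `geometry` are
#' dropped.
#'
#' @param classified A `classified_mrnas` tibble from [classify_mrnas()].
#' @param fluc Optional Fluc (internal control) spot tibble with `cell_id`
#'   and `compartment`.
#' @param geometry Optional geometry table (simulator tibble or the `table`
#'   element of [geometry_from_masks()]) supplying `nucleus_area_um2` and
#'   `touches_border`.
#' @return Tibble with one row per cell.
#' @export
per_cell_metrics <- function(classified, fluc = NULL, geometry = NULL) {
  cells <- classified |>
    filter(!is.na(.data$cell_id)) |>
    group_by(.data$cell_id) |>
    summarise(
      M_sun_cyto = sum(.data$compartment == "cytoplasmic"),
      M_sun_nuc = sum(.data$compartment == "nuclear"),
      M_sun_coloc_cyto = sum(.data$translated &
                               .data$compartment == "cytoplasmic"),
      M_ago_coloc_cyto = sum(.data$risc_positive &
                               .data$compartment == "cytoplasmic"),
      I_sun_coloc_cyto = sum(.data$suntag_intensity[.data$translated &
        .data$compartment == "cytoplasmic"], na.rm = TRUE),
      I_ago_coloc_cyto = sum(.data$ago_intensity[.data$risc_positive &
        .data$compartment == "cytoplasmic"], na.rm = TRUE),
      .groups = "drop"
    )
  if (!is.null(fluc)) {
    fl <- fluc |>
      filter(!is.na(.data$cell_id)) |>
      group_by(.data$cell_id) |>
      summarise(M_fluc_cyto = sum(.data$compartment == "cytoplasmic"),
                .groups = "drop")
    cells <- left_join(cells, fl, by = "cell_id") |>
      mutate(M_fluc_cyto = replace_na(.data$M_fluc_cyto, 0L))
  } else {
    cells$M_fluc_cyto <- NA_integer_
  }
  safe_ratio <- function(num, den) ifelse(!is.na(den) & den > 0,
                                          num / den, NA_real_)
  cells <- cells |>
    mutate(
      S = safe_ratio(.data$M_sun_cyto, .data$M_fluc_cyto),
      T_eff = safe_ratio(.data$I_sun_coloc_cyto, .data$M_sun_cyto),
      T_fra = safe_ratio(.data$M_sun_coloc_cyto, .data$M_sun_cyto),
      A_eff = safe_ratio(.data$I_ago_coloc_cyto, .data$M_sun_cyto),
      A_fra = safe_ratio(.data$M_ago_coloc_cyto, .data$M_sun_cyto),
      E = safe_ratio(.data$M_sun_cyto, .data$M_sun_nuc)
    )
  if (!is.null(geometry)) {
    gt <- if (inherits(geometry, "cell_geometry_masks")) geometry$table
          else geometry
    cells <- cells |>
      left_join(gt |> select("cell_id", "nucleus_area_um2",
                             "touches_border"),
                by = "cell_id") |>
      filter(!.data$touches_border | is.na(.data$touches_border))
  }
  cells
}

#' Bulk (pooled) silencing metrics
#'
#' Ratio-of-sums over all included cells -- not the mean of per-cell
#' ratios: `S_bulk = sum(M_sun_cyto) / sum(M_fluc_cyto)`,
#' `T_eff_bulk = sum(I_sun_coloc_cyto) / sum(M_sun_cyto)`,
#' `A_eff_bulk = sum(I_ago_coloc_cyto) / sum(M_sun_cyto)`.
#'
#' @param cells Per-cell metrics from [per_cell_metrics()].
#' @return One-row tibble `S_bulk`, `T_eff_bulk`, `A_eff_bulk`, `n_cells`.
#' @export
bulk_metrics <- function(cells) {
  if (nrow(cells) < 1) abort("bulk metrics need at least one cell")
  pooled_ratio <- function(num, den) {
    if (all(is.na(den))) return(NA_real_)
    dsum <- sum(den, na.rm = TRUE)
    if (dsum == 0) abort("pooled denominator is zero")
    sum(num, na.rm = TRUE) / dsum
  }
  tibble(
    S_bulk = pooled_ratio(cells$M_sun_cyto, cells$M_fluc_cyto),
    T_eff_bulk = pooled_ratio(cells$I_sun_coloc_cyto, cells$M_sun_cyto),
    A_eff_bulk = pooled_ratio(cells$I_ago_coloc_cyto, cells$M_sun_cyto),
    n_cells = nrow(cells)
  )
}

#' Ribosome-number estimates for SunTag spots on mRNAs
#'
#' Each on-mRNA SunTag intensity is divided by the median intensity of free
#' SunTag spots (single released peptides -- the one-peptide calibration
#' unit): `R = i_spot / median(i_free)`. The free-spot median is taken per
#' cell when the cell has at least `min_free` free spots, otherwise the
#' pooled-population median is used. Only cytoplasmic spots enter. Note the
#' estimate is a lower bound: bright spots also contain nascent partial
#' peptides, so the true ribosome number is larger.
#'
#' @param suntag_on On-mRNA SunTag spot tibble (`cell_id`, `compartment`,
#'   `intensity`).
#' @param suntag_free Free SunTag spot tibble.
#' @param min_free Minimum free spots per cell before falling back to the
#'   pooled median (default 10).
#' @return `suntag_on` (cytoplasmic rows) with `ribosomes` and the
#'   `unit_intensity` used.
#' @export
ribosome_counts <- function(suntag_on, suntag_free, min_free = 10) {
  free <- suntag_free[suntag_free$compartment == "cytoplasmic", ]
  if (nrow(free) == 0) abort("no free SunTag spots: cannot calibrate")
  pooled <- median(free$intensity)
  per_cell <- free |>
    group_by(.data$cell_id) |>
    summarise(unit_intensity = if (n() >= min_free)
      median(.data$intensity) else pooled, .groups = "drop")
  suntag_on |>
    filter(.data$compartment == "cytoplasmic") |>
    left_join(per_cell, by = "cell_id") |>
    mutate(unit_intensity = replace_na(.data$unit_intensity, pooled),
           ribosomes = .data$intensity / .data$unit_intensity)
}

#' Normalize per-cell stability to a negative control
#'
#' `S_norm(k) = S(k) / S_bulk(control)`; time-course runs normalize within
#' each time point against the matched control.
#'
#' @param cells Per-cell metrics of the condition of interest.
#' @param control_bulk [bulk_metrics()] of the matched negative control.
#' @return `cells` with an `S_norm` column.
#' @export
normalize_to_control <- function(cells, control_bulk) {
  s0 <- control_bulk$S_bulk
  if (is.na(s0) || s0 == 0) abort("control S_bulk is zero or undefined")
  mutate(cells, S_norm = .data$S / s0)
}

#' Back-of-envelope abundance of miR-21-loaded RISC
#'
#' Multiplies the AGO copy number per cell by the relative miR-21 occupancy
#' and rounds to one significant figure: with ~15,000 AGO copies and ~25%
#' occupancy in U2OS cells this gives ~4000 loaded RISC per cell, the
#' abundance that motivates keeping reporter expression at or below ~100
#' mRNAs per cell.
#'
#' @param ago_copies_per_cell AGO protein copies per cell.
#' @param mir21_occupancy Fraction of miRNA reads that are miR-21.
#' @param digits Significant digits for rounding (default 1).
#' @return Estimated loaded-RISC copies per cell.
#' @export
risc_copies <- function(ago_copies_per_cell = 15000, mir21_occupancy = 0.25,
                        digits = 1) {
  stopifnot(ago_copies_per_cell >= 0,
            mir21_occupancy >= 0, mir21_occupancy <= 1)
  signif(ago_copies_per_cell * mir21_occupancy, digits)
}
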