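#' Configuration for the synthetic microscopy generator
#'
#' Builds the parameter set that drives [simulate_cells()], [emit_spot_tables()]
#' and [render_field()]. Defaults emulate the pulse-chase reporter system in
#' U2OS cells: reporter expression minimized to a median of ~40 (max ~100)
#' mRNAs per cell, ~250 SunTag IF spots and ~2000 AGO IF spots per cell,
#' nuclear export unfolding over the 0/30/60 min chase, RISC binding from the
#' earliest time point, a step change to translational repression at 30 min,
#' and a single survival fraction for mRNA decay from 60 min.
#'
#' @param n_cells Number of cells to simulate (default 50, one analysis batch).
#' @param field_shape Integer vector `c(z, y, x)` of the rendered field in
#'   voxels.
#' @param voxel_size Named numeric `c(xy = , z = )` voxel size in nm.
#' @param mrna_nb Named numeric `c(size = , mu = )` negative-binomial law for
#'   reporter mRNAs per cell; truncated at `mrna_max`. The default
#'   (size 6, mu 42, cap 100) has median exactly 40.
#' @param mrna_max Upper truncation for mRNA counts per cell.
#' @param fluc_nb Negative-binomial law for the internal-control Fluc mRNAs.
#' @param time_min Chase time in minutes (0, 30 or 60).
#' @param time_offset_min Minutes of effective export time already elapsed at
#'   chase time 0 (the transcription pulse itself lasts 30 min, so some mRNAs
#'   are cytoplasmic at t = 0).
#' @param k_export Nuclear-export rate per minute;
#'   `P(cytoplasmic) = 1 - exp(-k_export * (time_min + time_offset_min))`.
#' @param p_risc_bind Probability that a cytoplasmic reporter mRNA is
#'   RISC-bound in the miR-21 condition.
#' @param p_risc_false Same probability for the mutant-site condition
#'   (default 0; apparent RISC-positives in the mutant then arise only from
#'   chance colocalization with the dense free-AGO background).
#' @param repression_onset_min Minutes after which RISC-bound mRNAs are
#'   translationally repressed (step model).
#' @param decay_onset_min Minutes after which the decay reporter is degraded.
#' @param decay_survival Fraction of cytoplasmic reporter mRNAs surviving
#'   decay at `time_min >= decay_onset_min` (miR-21 condition, decay design).
#' @param p_translated_active,p_translated_repressed Probability that a
#'   cytoplasmic mRNA is translated before/after repression applies to it.
#' @param ribosome_mean_active,ribosome_mean_repressed Mean ribosome load of
#'   translated mRNAs (Poisson above a floor of 1).
#' @param risc_extra_mean With eight sites per reporter, a bound mRNA carries
#'   `1 + Poisson(risc_extra_mean)` RISC.
#' @param n_free_suntag Free single SunTag peptides per cell (together with
#'   on-mRNA spots this yields ~250 SunTag spots/cell).
#' @param n_ago_spots Free AGO spots per cell (~2000).
#' @param suntag_unit,ago_unit,mrna_intensity Named `c(meanlog = , sdlog = )`
#'   lognormal intensity laws (a.u.); `suntag_unit` is the single-peptide
#'   unit, `ago_unit` the single-RISC unit.
#' @param partner_jitter_nm Named `c(suntag = , ago = )` s.d. of the isotropic
#'   displacement of on-mRNA partner spots from their mRNA, truncated at the
#'   colocalization gate minus `jitter_margin_nm`.
#' @param jitter_margin_nm Safety margin kept between partner displacement and
#'   the gate.
#' @param gates_nm Named `c(suntag = 500, ago = 250)` colocalization gates.
#' @param drift_nm Named list of per-channel 3-vectors `c(z, y, x)` nm drift
#'   relative to the mRNA channel.
#' @param loc_sd_nm Localization noise s.d. per axis for spot-table emission.
#' @param intensity_cv Multiplicative (lognormal) intensity noise for
#'   spot-table emission.
#' @param psf_sigma_nm Named `c(xy = , z = )` Gaussian PSF widths for
#'   rendering.
#' @param noise Named `c(shot = , read = )`: Poisson shot-noise scale
#'   (photons per a.u.; 0 disables) and additive read-noise s.d.
#' @param bg_offset Constant camera/background offset added before shot noise.
#' @param cell_axes_um,nucleus_axes_um Named `c(a = , b = )` ellipse semi-axes
#'   in micrometres.
#' @param z_depth_um Axial extent of the cell in micrometres.
#' @param seed Integer seed; identical config + seed gives identical output.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 50,
                       field_shape = c(z = 15, y = 256, x = 256),
                       voxel_size = c(xy = 107.5, z = 200),
                       mrna_nb = c(size = 6, mu = 42),
                       mrna_max = 100,
                       fluc_nb = c(size = 6, mu = 42),
                       time_min = 0,
                       time_offset_min = 10,
                       k_export = 0.03,
                       p_risc_bind = 0.35,
                       p_risc_false = 0,
                       repression_onset_min = 30,
                       decay_onset_min = 60,
                       decay_survival = 0.5,
                       p_translated_active = 0.6,
                       p_translated_repressed = 0.15,
                       ribosome_mean_active = 8,
                       ribosome_mean_repressed = 2,
                       risc_extra_mean = 0.8,
                       n_free_suntag = 220,
                       n_ago_spots = 2000,
                       suntag_unit = c(meanlog = log(1500), sdlog = 0.3),
                       ago_unit = c(meanlog = log(1500), sdlog = 0.3),
                       mrna_intensity = c(meanlog = log(5000), sdlog = 0.25),
                       partner_jitter_nm = c(suntag = 60, ago = 60),
                       jitter_margin_nm = 50,
                       gates_nm = c(suntag = 500, ago = 250),
                       drift_nm = list(),
                       loc_sd_nm = 20,
                       intensity_cv = 0.1,
                       psf_sigma_nm = c(xy = 150, z = 300),
                       noise = c(shot = 1, read = 2),
                       bg_offset = 100,
                       cell_axes_um = c(a = 11, b = 9),
                       nucleus_axes_um = c(a = 4.5, b = 3.5),
                       z_depth_um = 3,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$p_risc_bind, cfg$p_risc_false, cfg$decay_survival,
             cfg$p_translated_active, cfg$p_translated_repressed)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities and survival fractions must lie in [0, 1]")
  }
  nonneg <- c(cfg$k_export, cfg$n_free_suntag, cfg$n_ago_spots,
              cfg$ribosome_mean_active, cfg$ribosome_mean_repressed,
              cfg$loc_sd_nm, cfg$intensity_cv, cfg$psf_sigma_nm, cfg$noise,
              cfg$partner_jitter_nm, cfg$risc_extra_mean)
  if (any(nonneg < 0)) abort("rates, counts and sigmas must be >= 0")
  if (any(cfg$voxel_size <= 0)) abort("voxel sizes must be positive")
  if (cfg$nucleus_axes_um[["a"]] >= cfg$cell_axes_um[["a"]] ||
      cfg$nucleus_axes_um[["b"]] >= cfg$cell_axes_um[["b"]]) {
    abort("non-physical geometry: nucleus must fit inside the cell")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_cells, "cells, t =", x$time_min, "min, seed",
      x$seed, "\n")
  invisible(x)
}

#' Read or write a simulation configuration as YAML
#'
#' The YAML mirrors [sim_config()] field for field; absent fields take their
#' defaults.
#'
#' @param path File path.
#' @param config A `sim_config` object (for writing).
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- read_yaml(path)
  raw <- lapply(raw, function(v) if (is.list(v)) unlist(v) else v)
  if (!is.null(raw$drift_nm)) {
    raw$drift_nm <- lapply(read_yaml(path)$drift_nm, unlist)
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  flat <- lapply(unclass(config), function(v) {
    if (is.numeric(v) && (length(v) > 1 || !is.null(names(v)))) as.list(v)
    else v
  })
  write_yaml(flat, path)
  invisible(path)
}
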