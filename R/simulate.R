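#' Simulate a ground-truthed cell population
#'
#' Draws cell geometries and molecular ground truth from the generative model
#' of the reporter system: mRNA counts per cell, nuclear/cytoplasmic
#' compartment via the export model
#' `P(cyto) = 1 - exp(-k_export * (t + offset))`, RISC binding of cytoplasmic
#' reporters, a step change to translational repression after
#' `repression_onset_min` for bound mRNAs, ribosome loads, decay thinning of
#' the decay reporter from `decay_onset_min`, on-mRNA SunTag/AGO partner
#' spots jittered within the colocalization gates, and dense free SunTag/AGO
#' spots scattered through the cytoplasm.
#'
#' @param config A [sim_config()] object.
#' @param condition `"miR21"` (functional sites) or `"mutant"` (mutated seed
#'   and supplemental pairing; the negative control).
#' @param design Which reporter/channel set to emulate: `"triple"`
#'   (mRNA + SunTag + AGO, anti-decay element present), `"translation"`
#'   (mRNA + SunTag), `"risc"` (mRNA + AGO), or `"decay"` (mRNA + Fluc
#'   internal control, no anti-decay element, so decay applies).
#'
#' @return A list with `geometry` (one row per cell: centres and ellipse
#'   semi-axes in nm, nucleus area in um^2, `touches_border`) and `truth`
#'   (one row per molecule/spot: `spot_id`, `cell_id`, `species`, positions
#'   in nm, `intensity`, `compartment`, `linked_mrna_id`, `ribosome_count`,
#'   and for reporter rows the `translated` / `risc_bound` flags).
#' @export
simulate_cells <- function(config = sim_config(),
                           condition = c("miR21", "mutant"),
                           design = c("triple", "translation", "risc", "decay")) {
  condition <- arg_match(condition)
  design <- arg_match(design)
  stopifnot(inherits(config, "sim_config"))

  geometry <- layout_cells(config)
  truth <- map(seq_len(config$n_cells), function(k) {
    set.seed(cell_seed(config$seed, k))
    simulate_one_cell(geometry[k, ], config, condition, design)
  }) |> list_rbind()
  truth$spot_id <- seq_len(nrow(truth))
  # re-link partner rows now that ids are global
  truth <- relink_partners(truth)
  list(geometry = geometry, truth = truth,
       condition = condition, design = design)
}

# Cells are placed on a fixed-pitch grid (pitch = one cell diameter + 2 um);
# spots-only analyses never consult absolute positions across cells, and
# render_field() checks containment in the requested field.
layout_cells <- function(config) {
  a <- config$cell_axes_um[["a"]] * 1000
  b <- config$cell_axes_um[["b"]] * 1000
  na <- config$nucleus_axes_um[["a"]] * 1000
  nb <- config$nucleus_axes_um[["b"]] * 1000
  pitch <- 2 * max(a, b) + 2000
  ncol <- ceiling(sqrt(config$n_cells))
  idx <- seq_len(config$n_cells) - 1L
  set.seed(cell_seed(config$seed, 0L))
  tibble(
    cell_id = seq_len(config$n_cells),
    center_x_nm = (idx %% ncol + 0.5) * pitch,
    center_y_nm = (idx %/% ncol + 0.5) * pitch,
    cell_a_nm = a, cell_b_nm = b,
    nuc_x_nm = .data$center_x_nm + runif(config$n_cells, -0.1, 0.1) * a,
    nuc_y_nm = .data$center_y_nm + runif(config$n_cells, -0.1, 0.1) * b,
    nuc_a_nm = na, nuc_b_nm = nb,
    nucleus_area_um2 = pi * (na / 1000) * (nb / 1000),
    touches_border = FALSE
  )
}

rtrunc_nbinom <- function(n, law, cap) {
  x <- rnbinom(n, size = law[["size"]], mu = law[["mu"]])
  while (any(x > cap)) {
    i <- x > cap
    x[i] <- rnbinom(sum(i), size = law[["size"]], mu = law[["mu"]])
  }
  x
}

sample_z <- function(n, config) {
  depth <- config$z_depth_um * 1000
  runif(n, 300, depth - 300)
}

simulate_one_cell <- function(geom, config, condition, design) {
  t_eff <- config$time_min + config$time_offset_min
  p_cyto <- 1 - exp(-config$k_export * t_eff)

  n_mrna <- rtrunc_nbinom(1, config$mrna_nb, config$mrna_max)
  cyto <- runif(n_mrna) < p_cyto

  # decay thins cytoplasmic copies of the decay reporter (no anti-decay
  # element) in the miR-21 condition once decay has set in
  if (design == "decay" && condition == "miR21" &&
      config$time_min >= config$decay_onset_min) {
    keep <- !cyto | runif(n_mrna) < config$decay_survival
    cyto <- cyto[keep]
    n_mrna <- length(cyto)
  }

  pos_nuc <- sample_ellipse(sum(!cyto), geom$nuc_x_nm, geom$nuc_y_nm,
                            geom$nuc_a_nm, geom$nuc_b_nm)
  pos_cyt <- sample_cytoplasm(sum(cyto), geom)
  pos <- tibble(x_nm = numeric(n_mrna), y_nm = numeric(n_mrna))
  pos[!cyto, ] <- pos_nuc[, c("x_nm", "y_nm")]
  pos[cyto, ] <- pos_cyt[, c("x_nm", "y_nm")]

  p_bind <- if (condition == "miR21") config$p_risc_bind else config$p_risc_false
  bound <- cyto & runif(n_mrna) < p_bind

  repressed <- bound & config$time_min >= config$repression_onset_min
  p_tr <- ifelse(repressed, config$p_translated_repressed,
                 config$p_translated_active)
  translated <- cyto & runif(n_mrna) < p_tr

  ribo_mean <- ifelse(repressed, config$ribosome_mean_repressed,
                      config$ribosome_mean_active)
  ribo <- ifelse(translated, 1 + rpois(n_mrna, pmax(ribo_mean - 1, 0)), NA_real_)

  mrna <- tibble(
    cell_id = geom$cell_id,
    species = "reporter_mRNA",
    z_nm = sample_z(n_mrna, config),
    y_nm = pos$y_nm, x_nm = pos$x_nm,
    intensity = rlnorm(n_mrna, config$mrna_intensity[["meanlog"]],
                       config$mrna_intensity[["sdlog"]]),
    compartment = ifelse(cyto, "cytoplasmic", "nuclear"),
    linked_mrna_id = NA_integer_,
    ribosome_count = ribo,
    translated = translated,
    risc_bound = bound,
    local_id = seq_len(n_mrna)
  )

  parts <- list(mrna)

  if (design %in% c("triple", "translation")) {
    sel <- which(translated)
    if (length(sel) > 0) {
      j <- truncated_jitter(length(sel), config$partner_jitter_nm[["suntag"]],
                            config$gates_nm[["suntag"]] - config$jitter_margin_nm)
      parts <- c(parts, list(tibble(
        cell_id = geom$cell_id, species = "suntag_on_mRNA",
        z_nm = mrna$z_nm[sel] + j$dz, y_nm = mrna$y_nm[sel] + j$dy,
        x_nm = mrna$x_nm[sel] + j$dx,
        intensity = mrna$ribosome_count[sel] *
          rlnorm(length(sel), config$suntag_unit[["meanlog"]],
                 config$suntag_unit[["sdlog"]]),
        compartment = "cytoplasmic", linked_mrna_id = sel,
        ribosome_count = mrna$ribosome_count[sel],
        translated = NA, risc_bound = NA, local_id = NA_integer_
      )))
    }
    n_free <- rpois(1, config$n_free_suntag)
    pf <- sample_cytoplasm(n_free, geom)
    parts <- c(parts, list(tibble(
      cell_id = geom$cell_id, species = "suntag_free",
      z_nm = sample_z(n_free, config), y_nm = pf$y_nm, x_nm = pf$x_nm,
      intensity = rlnorm(n_free, config$suntag_unit[["meanlog"]],
                         config$suntag_unit[["sdlog"]]),
      compartment = "cytoplasmic", linked_mrna_id = NA_integer_,
      ribosome_count = NA_real_, translated = NA, risc_bound = NA,
      local_id = NA_integer_
    )))
  }

  if (design %in% c("triple", "risc")) {
    sel <- which(bound)
    if (length(sel) > 0) {
      j <- truncated_jitter(length(sel), config$partner_jitter_nm[["ago"]],
                            config$gates_nm[["ago"]] - config$jitter_margin_nm)
      n_risc <- 1 + rpois(length(sel), config$risc_extra_mean)
      parts <- c(parts, list(tibble(
        cell_id = geom$cell_id, species = "ago_on_mRNA",
        z_nm = mrna$z_nm[sel] + j$dz, y_nm = mrna$y_nm[sel] + j$dy,
        x_nm = mrna$x_nm[sel] + j$dx,
        intensity = n_risc * rlnorm(length(sel), config$ago_unit[["meanlog"]],
                                    config$ago_unit[["sdlog"]]),
        compartment = "cytoplasmic", linked_mrna_id = sel,
        ribosome_count = NA_real_, translated = NA, risc_bound = NA,
        local_id = NA_integer_
      )))
    }
    n_free <- rpois(1, config$n_ago_spots)
    pf <- sample_cytoplasm(n_free, geom)
    parts <- c(parts, list(tibble(
      cell_id = geom$cell_id, species = "ago_free",
      z_nm = sample_z(n_free, config), y_nm = pf$y_nm, x_nm = pf$x_nm,
      intensity = rlnorm(n_free, config$ago_unit[["meanlog"]],
                         config$ago_unit[["sdlog"]]),
      compartment = "cytoplasmic", linked_mrna_id = NA_integer_,
      ribosome_count = NA_real_, translated = NA, risc_bound = NA,
      local_id = NA_integer_
    )))
  }

  if (design == "decay") {
    n_fluc <- rtrunc_nbinom(1, config$fluc_nb, config$mrna_max)
    fc <- runif(n_fluc) < p_cyto
    pn <- sample_ellipse(sum(!fc), geom$nuc_x_nm, geom$nuc_y_nm,
                         geom$nuc_a_nm, geom$nuc_b_nm)
    pc <- sample_cytoplasm(sum(fc), geom)
    fp <- tibble(x_nm = numeric(n_fluc), y_nm = numeric(n_fluc))
    fp[!fc, ] <- pn[, c("x_nm", "y_nm")]
    fp[fc, ] <- pc[, c("x_nm", "y_nm")]
    parts <- c(parts, list(tibble(
      cell_id = geom$cell_id, species = "fluc_mRNA",
      z_nm = sample_z(n_fluc, config), y_nm = fp$y_nm, x_nm = fp$x_nm,
      intensity = rlnorm(n_fluc, config$mrna_intensity[["meanlog"]],
                         config$mrna_intensity[["sdlog"]]),
      compartment = ifelse(fc, "cytoplasmic", "nuclear"),
      linked_mrna_id = NA_integer_, ribosome_count = NA_real_,
      translated = NA, risc_bound = NA, local_id = NA_integer_
    )))
  }

  list_rbind(parts)
}

# partner rows are generated with linked_mrna_id = per-cell local index of
# their mRNA; rewrite to global spot ids once those exist
relink_partners <- function(truth) {
  key <- truth |>
    filter(.data$species == "reporter_mRNA") |>
    select("cell_id", "local_id", mrna_spot_id = "spot_id")
  truth |>
    left_join(key, by = c("cell_id", "linked_mrna_id" = "local_id")) |>
    mutate(linked_mrna_id = .data$mrna_spot_id) |>
    select(-"mrna_spot_id", -"local_id")
}

#' Emit noisy per-channel spot tables from simulated ground truth
#'
#' Fast path that bypasses image rendering and detection: ground-truth spots
#' are perturbed by localization noise, shifted by per-channel drift, and
#' their intensities perturbed multiplicatively, yielding tables in the same
#' shape as [detect_spots()] output so downstream stages are agnostic to the
#' path taken.
#'
#' @param sim Result of [simulate_cells()].
#' @param config The [sim_config()] used (its `loc_sd_nm`, `intensity_cv`,
#'   `drift_nm` fields drive the perturbations).
#' @return Named list of tibbles (`mrna`, and depending on the design
#'   `suntag`, `ago`, `fluc`), each with `spot_id`, `channel`, `cell_id`,
#'   `compartment`, `z_nm`, `y_nm`, `x_nm`, `intensity`.
#' @export
emit_spot_tables <- function(sim, config = sim_config()) {
  truth <- sim$truth
  set.seed(cell_seed(config$seed, -1L) + 1)
  channel_of <- c(reporter_mRNA = "mrna", fluc_mRNA = "fluc",
                  suntag_on_mRNA = "suntag", suntag_free = "suntag",
                  ago_on_mRNA = "ago", ago_free = "ago")
  truth$channel <- unname(channel_of[truth$species])
  out <- truth |>
    mutate(
      z_nm = .data$z_nm + rnorm(n(), 0, config$loc_sd_nm),
      y_nm = .data$y_nm + rnorm(n(), 0, config$loc_sd_nm),
      x_nm = .data$x_nm + rnorm(n(), 0, config$loc_sd_nm),
      intensity = .data$intensity *
        exp(rnorm(n(), 0, config$intensity_cv))
    )
  split(out, out$channel) |>
    imap(function(tab, ch) {
      d <- config$drift_nm[[ch]] %||% c(0, 0, 0)
      tab |>
        mutate(z_nm = .data$z_nm + d[[1]], y_nm = .data$y_nm + d[[2]],
               x_nm = .data$x_nm + d[[3]]) |>
        select("spot_id", "channel", "cell_id", "compartment",
               "z_nm", "y_nm", "x_nm", "intensity")
    })
}
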