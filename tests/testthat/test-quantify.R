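fake_classified <- function(df) {
  class(df) <- c("classified_mrnas", class(df))
  df
}

# hand-built cell: counts chosen so every ratio is forced by its definition
one_cell_classified <- function(cell_id = 1L, n_cyto, n_nuc = 0,
                                n_translated = 0, n_risc = 0,
                                i_sun = 0, i_ago = 0) {
  n <- n_cyto + n_nuc
  tr <- c(rep(TRUE, n_translated), rep(FALSE, n_cyto - n_translated),
          rep(FALSE, n_nuc))
  rp <- c(rep(TRUE, n_risc), rep(FALSE, n_cyto - n_risc), rep(FALSE, n_nuc))
  fake_classified(tibble::tibble(
    mrna_spot_id = seq_len(n), cell_id = cell_id,
    compartment = c(rep("cytoplasmic", n_cyto), rep("nuclear", n_nuc)),
    translated = tr, risc_positive = rp,
    suntag_intensity = ifelse(tr, i_sun / max(n_translated, 1), NA_real_),
    ago_intensity = ifelse(rp, i_ago / max(n_risc, 1), NA_real_)
  ))
}

test_that("per-cell ratios follow their defining equations", {
  # S = 20 / 40
  cl <- one_cell_classified(n_cyto = 20)
  fluc <- tibble::tibble(cell_id = 1L, compartment = rep("cytoplasmic", 40))
  m <- per_cell_metrics(cl, fluc = fluc)
  expect_equal(m$S, 0.5)

  # T_eff = 5000 / 40 = 125, T_fra = 10 / 40
  cl <- one_cell_classified(n_cyto = 40, n_translated = 10, i_sun = 5000)
  m <- per_cell_metrics(cl)
  expect_equal(m$T_eff, 125)
  expect_equal(m$T_fra, 0.25)

  # E = 30 / 10
  cl <- one_cell_classified(n_cyto = 30, n_nuc = 10)
  m <- per_cell_metrics(cl)
  expect_equal(m$E, 3.0)

  # A_eff, A_fra
  cl <- one_cell_classified(n_cyto = 40, n_risc = 12, i_ago = 6000)
  m <- per_cell_metrics(cl)
  expect_equal(m$A_eff, 150)
  expect_equal(m$A_fra, 0.3)
})

test_that("zero denominators flag the ratio as undefined, not an error", {
  cl <- one_cell_classified(n_cyto = 0, n_nuc = 5)
  m <- per_cell_metrics(cl, fluc = tibble::tibble(cell_id = 1L,
                                                  compartment = "nuclear"))
  expect_true(is.na(m$S))
  expect_true(is.na(m$T_eff))
  expect_equal(m$E, 0)
})

test_that("bulk metrics are ratios of sums, not means of ratios", {
  cells <- tibble::tibble(
    cell_id = 1:2,
    M_sun_cyto = c(10L, 30L), M_fluc_cyto = c(40L, 10L),
    M_sun_nuc = 0L, M_sun_coloc_cyto = 0L, M_ago_coloc_cyto = 0L,
    I_sun_coloc_cyto = 0, I_ago_coloc_cyto = 0,
    S = c(10 / 40, 30 / 10)
  )
  b <- bulk_metrics(cells)
  expect_equal(b$S_bulk, 40 / 50) # = 0.8
  expect_false(isTRUE(all.equal(b$S_bulk, mean(cells$S)))) # mean = 1.625
  expect_equal(mean(cells$S), 1.625)

  one <- cells[1, ]
  expect_equal(bulk_metrics(one)$S_bulk, one$S)

  same <- cells[c(1, 1, 1), ]
  expect_equal(bulk_metrics(same)$S_bulk, cells$S[1])

  zero <- dplyr::mutate(cells, M_fluc_cyto = 0L)
  expect_error(bulk_metrics(zero), "zero")
  expect_error(bulk_metrics(cells[0, ]), "at least one")
})

test_that("ribosome counts are intensities in free-SunTag median units", {
  on <- tibble::tibble(spot_id = 1:2, cell_id = 1L,
                       compartment = "cytoplasmic",
                       intensity = c(3000, 600))
  free <- tibble::tibble(spot_id = 3:13, cell_id = 1L,
                         compartment = "cytoplasmic",
                         intensity = rep(600, 11))
  r <- ribosome_counts(on, free)
  expect_equal(r$ribosomes, c(5, 1))

  # under min_free per-cell spots, the pooled median is the fallback
  free2 <- free
  free2$cell_id <- c(1L, rep(2L, 10))
  r2 <- ribosome_counts(on, free2, min_free = 10)
  expect_equal(r2$ribosomes, c(5, 1))

  expect_error(ribosome_counts(on, free[0, ]), "free SunTag")
})

test_that("simulated ribosome loads are recovered within one ribosome", {
  cfg <- sim_config(n_cells = 30, time_min = 0, k_export = 10,
                    ribosome_mean_active = 8, loc_sd_nm = 0,
                    intensity_cv = 0, n_ago_spots = 0, seed = 71)
  sim <- simulate_cells(cfg, "mutant", "translation")
  on <- sim$truth[sim$truth$species == "suntag_on_mRNA", ]
  free <- sim$truth[sim$truth$species == "suntag_free", ]
  on$spot_id <- seq_len(nrow(on))
  free$spot_id <- seq_len(nrow(free))
  r <- ribosome_counts(on, free)
  expect_gt(nrow(r), 400)
  expect_lt(abs(median(r$ribosomes) - 8), 1)
})

test_that("normalization to the control rescales stability", {
  cells <- tibble::tibble(S = c(1, 2), M_sun_cyto = c(10L, 20L),
                          M_fluc_cyto = c(10L, 10L),
                          I_sun_coloc_cyto = 0, I_ago_coloc_cyto = 0)
  ctrl <- tibble::tibble(S_bulk = 2)
  out <- normalize_to_control(cells, ctrl)
  expect_equal(out$S_norm, c(0.5, 1))

  self_bulk <- bulk_metrics(cells)
  self_norm <- normalize_to_control(cells, self_bulk)
  expect_equal(sum(self_norm$M_sun_cyto) /
                 sum(self_norm$M_fluc_cyto) / self_bulk$S_bulk, 1)

  expect_error(normalize_to_control(cells, tibble::tibble(S_bulk = 0)),
               "control")
})

test_that("loaded-RISC abundance arithmetic gives ~4000 copies per cell", {
  expect_equal(risc_copies(15000, 0.25), 4000)
  expect_equal(risc_copies(15000, 0.25, digits = 3), 3750)
})

test_that("noiseless spots-only metrics equal ground-truth metrics", {
  cfg <- sim_config(n_cells = 10, loc_sd_nm = 0, intensity_cv = 0,
                    n_free_suntag = 0, n_ago_spots = 0, time_min = 30,
                    p_risc_bind = 0.5, seed = 72)
  sim <- simulate_cells(cfg, "miR21", "triple")
  tabs <- emit_spot_tables(sim, cfg)
  cl <- classify_mrnas(tabs$mrna, tabs$suntag, tabs$ago)
  m <- per_cell_metrics(cl)

  truth <- sim$truth
  rep_t <- truth[truth$species == "reporter_mRNA", ]
  for (k in m$cell_id) {
    tk <- rep_t[rep_t$cell_id == k, ]
    cyto <- tk$compartment == "cytoplasmic"
    expect_equal(m$M_sun_cyto[m$cell_id == k], sum(cyto))
    expect_equal(m$M_sun_nuc[m$cell_id == k], sum(!cyto))
    expect_equal(m$M_sun_coloc_cyto[m$cell_id == k],
                 sum(tk$translated & cyto))
    expect_equal(m$M_ago_coloc_cyto[m$cell_id == k],
                 sum(tk$risc_bound & cyto))
    i_sun_truth <- sum(truth$intensity[truth$species == "suntag_on_mRNA" &
                                         truth$cell_id == k])
    expect_equal(m$I_sun_coloc_cyto[m$cell_id == k], i_sun_truth,
                 tolerance = 1e-9)
  }
})

test_that("pooled translated fraction recovers the generator parameter", {
  cfg <- sim_config(n_cells = 50, p_translated_active = 0.6, k_export = 10,
                    time_min = 0, n_free_suntag = 0, n_ago_spots = 0,
                    loc_sd_nm = 0, intensity_cv = 0, seed = 73)
  sim <- simulate_cells(cfg, "mutant", "translation")
  tabs <- emit_spot_tables(sim, cfg)
  cl <- classify_mrnas(tabs$mrna, suntag = tabs$suntag)
  cyto <- cl[cl$compartment == "cytoplasmic", ]
  expect_gt(nrow(cyto), 1500)
  expect_lt(abs(mean(cyto$translated) - 0.6), 0.03)
})

test_that("export efficiency increases with chase time", {
  med_E <- vapply(c(0, 30, 60), function(t) {
    cfg <- sim_config(n_cells = 25, time_min = t, seed = 74,
                      n_ago_spots = 0, n_free_suntag = 0)
    sim <- simulate_cells(cfg, "mutant", "translation")
    tabs <- emit_spot_tables(sim, cfg)
    cl <- classify_mrnas(tabs$mrna, suntag = tabs$suntag)
    m <- per_cell_metrics(cl)
    median(m$E, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med_E) > 0))
})
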