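test_that("config validation rejects non-physical settings", {
  expect_error(sim_config(p_risc_bind = 1.2), "probabilities")
  expect_error(sim_config(k_export = -1), ">= 0")
  expect_error(sim_config(nucleus_axes_um = c(a = 12, b = 10)),
               "nucleus must fit")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("zero export rate keeps every mRNA nuclear", {
  cfg <- sim_config(n_cells = 5, k_export = 0, time_min = 60, seed = 7)
  sim <- simulate_cells(cfg, "miR21", "triple")
  rep <- sim$truth[sim$truth$species == "reporter_mRNA", ]
  expect_true(all(rep$compartment == "nuclear"))
})

test_that("certain RISC binding links every cytoplasmic reporter to an AGO spot", {
  cfg <- sim_config(n_cells = 5, p_risc_bind = 1, time_min = 0, seed = 11)
  sim <- simulate_cells(cfg, "miR21", "triple")
  rep <- sim$truth[sim$truth$species == "reporter_mRNA" &
                     sim$truth$compartment == "cytoplasmic", ]
  ago_on <- sim$truth[sim$truth$species == "ago_on_mRNA", ]
  expect_setequal(ago_on$linked_mrna_id, rep$spot_id)
  expect_true(all(ago_on$linked_mrna_id %in%
                    sim$truth$spot_id[sim$truth$species == "reporter_mRNA"]))
})

test_that("RISC-bound fraction matches the binomial law", {
  # ~2000 cytoplasmic reporters at p = 0.5; 3 binomial s.d. tolerance
  cfg <- sim_config(n_cells = 50, p_risc_bind = 0.5, k_export = 10,
                    time_min = 0, n_ago_spots = 0, n_free_suntag = 0,
                    seed = 123)
  sim <- simulate_cells(cfg, "miR21", "triple")
  rep <- sim$truth[sim$truth$species == "reporter_mRNA" &
                     sim$truth$compartment == "cytoplasmic", ]
  expect_gt(nrow(rep), 1500)
  frac <- mean(rep$risc_bound)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(rep)))
})

test_that("mRNA counts per cell honour the configured distribution", {
  cfg <- sim_config(n_cells = 200, seed = 5)
  sim <- simulate_cells(cfg, "mutant", "triple")
  counts <- table(factor(
    sim$truth$cell_id[sim$truth$species == "reporter_mRNA"],
    levels = seq_len(200)))
  expect_lte(max(counts), 100)
  expect_lt(abs(median(counts) - 40), 6)
})

test_that("truth classes partition the reporter population", {
  cfg <- sim_config(n_cells = 10, seed = 2)
  sim <- simulate_cells(cfg, "miR21", "triple")
  rep <- sim$truth[sim$truth$species == "reporter_mRNA", ]
  by_class <- table(rep$translated, rep$risc_bound, rep$compartment)
  expect_equal(sum(by_class), nrow(rep))
})

test_that("identical config and seed reproduce the truth bit-for-bit", {
  cfg <- sim_config(n_cells = 4, seed = 99)
  a <- simulate_cells(cfg, "miR21", "triple")
  b <- simulate_cells(cfg, "miR21", "triple")
  expect_identical(a$truth, b$truth)
  cfg2 <- sim_config(n_cells = 4, seed = 100)
  c <- simulate_cells(cfg2, "miR21", "triple")
  expect_false(identical(a$truth, c$truth))
})

test_that("on-mRNA partners stay inside their colocalization gate", {
  cfg <- sim_config(n_cells = 20, p_risc_bind = 0.8, time_min = 0, seed = 3)
  sim <- simulate_cells(cfg, "miR21", "triple")
  tr <- sim$truth
  mrna <- tr[tr$species == "reporter_mRNA", ]
  for (sp in c("suntag_on_mRNA", "ago_on_mRNA")) {
    gate <- if (sp == "suntag_on_mRNA") 500 else 250
    on <- tr[tr$species == sp, ]
    i <- match(on$linked_mrna_id, mrna$spot_id)
    d <- sqrt((on$z_nm - mrna$z_nm[i])^2 + (on$y_nm - mrna$y_nm[i])^2 +
                (on$x_nm - mrna$x_nm[i])^2)
    expect_true(all(d <= gate - 50))
  }
})

test_that("noiseless emission reproduces truth positions exactly", {
  cfg <- sim_config(n_cells = 3, loc_sd_nm = 0, intensity_cv = 0, seed = 8)
  sim <- simulate_cells(cfg, "miR21", "triple")
  tabs <- emit_spot_tables(sim, cfg)
  all_spots <- dplyr::bind_rows(tabs) |> dplyr::arrange(spot_id)
  truth <- sim$truth |> dplyr::arrange(spot_id)
  expect_equal(all_spots$z_nm, truth$z_nm)
  expect_equal(all_spots$y_nm, truth$y_nm)
  expect_equal(all_spots$x_nm, truth$x_nm)
  expect_equal(all_spots$intensity, truth$intensity)
})

test_that("per-channel drift shifts emitted spots by the configured vector", {
  cfg <- sim_config(n_cells = 5, loc_sd_nm = 0, intensity_cv = 0,
                    drift_nm = list(ago = c(50, -30, 20)), seed = 21)
  sim <- simulate_cells(cfg, "miR21", "triple")
  tabs <- emit_spot_tables(sim, cfg)
  truth_ago <- sim$truth[sim$truth$species %in%
                           c("ago_on_mRNA", "ago_free"), ]
  obs <- tabs$ago[match(truth_ago$spot_id, tabs$ago$spot_id), ]
  expect_equal(mean(obs$z_nm - truth_ago$z_nm), 50)
  expect_equal(mean(obs$y_nm - truth_ago$y_nm), -30)
  expect_equal(mean(obs$x_nm - truth_ago$x_nm), 20)
})

test_that("localization noise has the configured RMS magnitude", {
  cfg <- sim_config(n_cells = 10, loc_sd_nm = 30, intensity_cv = 0,
                    seed = 31)
  sim <- simulate_cells(cfg, "miR21", "triple")
  tabs <- emit_spot_tables(sim, cfg)
  all_spots <- dplyr::bind_rows(tabs)
  truth <- sim$truth
  i <- match(all_spots$spot_id, truth$spot_id)
  err <- sqrt((all_spots$z_nm - truth$z_nm[i])^2 +
                (all_spots$y_nm - truth$y_nm[i])^2 +
                (all_spots$x_nm - truth$x_nm[i])^2)
  expect_gt(length(err), 1000)
  rms <- sqrt(mean(err^2))
  expect_lt(abs(rms - 30 * sqrt(3)) / (30 * sqrt(3)), 0.1)
})

test_that("decay thins the cytoplasmic decay reporter only after onset", {
  base <- function(t, cond) {
    cfg <- sim_config(n_cells = 40, time_min = t, k_export = 10,
                      decay_survival = 0.5, seed = 77)
    sim <- simulate_cells(cfg, cond, "decay")
    sum(sim$truth$species == "reporter_mRNA")
  }
  n30 <- base(30, "miR21")
  n60 <- base(60, "miR21")
  n60_mut <- base(60, "mutant")
  # same seed; only the decay branch differs
  expect_lt(n60 / n30, 0.65)
  expect_gt(n60_mut / n30, 0.9)
})

test_that("config YAML round trip preserves the configuration", {
  cfg <- sim_config(n_cells = 7, p_risc_bind = 0.42,
                    drift_nm = list(ago = c(10, 20, 30)), seed = 13)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-6)
})
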