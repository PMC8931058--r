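test_that("drift estimation recovers a constant shift", {
  set.seed(61)
  ref <- random_spot_table(200)
  shift <- c(50, -30, 20)
  moving <- ref
  moving$z_nm <- moving$z_nm + shift[1]
  moving$y_nm <- moving$y_nm + shift[2]
  moving$x_nm <- moving$x_nm + shift[3]

  d0 <- estimate_drift(ref, ref)
  expect_equal(unname(d0$offset_nm), c(0, 0, 0))

  d <- estimate_drift(ref, moving)
  expect_lt(max(abs(d$offset_nm - c(z = 50, y = -30, x = 20))), 1)
})

test_that("drift survives a tenfold excess of distractor spots", {
  set.seed(62)
  ref <- random_spot_table(100, extent_nm = 20000)
  moving <- ref
  moving$z_nm <- moving$z_nm + 50 + rnorm(100, 0, 10)
  moving$y_nm <- moving$y_nm - 30 + rnorm(100, 0, 10)
  moving$x_nm <- moving$x_nm + 20 + rnorm(100, 0, 10)
  distract <- random_spot_table(1000, extent_nm = 20000)
  distract$spot_id <- 1000 + distract$spot_id
  moving_all <- dplyr::bind_rows(moving, distract)
  d <- estimate_drift(ref, moving_all)
  expect_lt(sqrt(sum((d$offset_nm - c(50, -30, 20))^2)), 20)
})

test_that("drift estimation fails loudly with too few pairs", {
  a <- random_spot_table(3)
  b <- a
  expect_error(estimate_drift(a, b, min_pairs = 10), "pairs")
  expect_error(estimate_drift(a[0, ], b), "nonempty")
})

test_that("matching honours the distance gate", {
  m <- tibble::tibble(spot_id = 1L, z_nm = 0, y_nm = 0, x_nm = 0)
  p200 <- tibble::tibble(spot_id = 1L, z_nm = 0, y_nm = 0, x_nm = 200)
  p300 <- tibble::tibble(spot_id = 1L, z_nm = 0, y_nm = 0, x_nm = 300)
  expect_equal(nrow(match_spots(m, p200, 250)), 1)
  expect_equal(nrow(match_spots(m, p300, 250)), 0)
  expect_error(match_spots(m, p200, -1), "non-negative")
})

test_that("greedy matching assigns a shared partner to the nearer mRNA", {
  m <- tibble::tibble(spot_id = c(1L, 2L), z_nm = 0, y_nm = 0,
                      x_nm = c(0, 400))
  p <- tibble::tibble(spot_id = 1L, z_nm = 0, y_nm = 0, x_nm = 100)
  pairs <- match_spots(m, p, 500)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$mrna_spot_id, 1L)
})

test_that("greedy matching equals the brute-force oracle", {
  set.seed(63)
  for (i in 1:50) {
    n1 <- sample(2:60, 1); n2 <- sample(2:60, 1)
    m <- random_spot_table(n1, extent_nm = 3000)
    p <- random_spot_table(n2, extent_nm = 3000)
    gate <- runif(1, 200, 1200)
    got <- match_spots(m, p, gate)
    want <- brute_force_match(m, p, gate)
    expect_equal(got[order(got$mrna_spot_id), ],
                 want[order(want$mrna_spot_id), ],
                 tolerance = 1e-12)
  }
})

test_that("colocalized fraction is monotone in the gate", {
  set.seed(64)
  m <- random_spot_table(80, extent_nm = 4000)
  p <- random_spot_table(300, extent_nm = 4000)
  fracs <- vapply(c(100, 250, 500, 750, 1000), function(g)
    nrow(match_spots(m, p, g)) / nrow(m), numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("pair assignments are invariant under drift plus re-estimation", {
  set.seed(65)
  m <- random_spot_table(150, extent_nm = 10000)
  # partner channel: the same physical spots re-localized with 30 nm noise
  p <- m
  p$z_nm <- p$z_nm + rnorm(150, 0, 30)
  p$y_nm <- p$y_nm + rnorm(150, 0, 30)
  p$x_nm <- p$x_nm + rnorm(150, 0, 30)
  base_drift <- estimate_drift(m, p, search_radius_nm = 2000,
                               min_pairs = 5)
  base <- match_spots(m, p, 500, base_drift)
  shifted <- p
  shifted$z_nm <- shifted$z_nm + 120
  shifted$y_nm <- shifted$y_nm - 80
  shifted$x_nm <- shifted$x_nm + 60
  d <- estimate_drift(m, shifted, search_radius_nm = 2000, min_pairs = 5)
  again <- match_spots(m, shifted, 500, d)
  expect_equal(base$mrna_spot_id, again$mrna_spot_id)
  expect_equal(base$partner_spot_id, again$partner_spot_id)
  expect_equal(base$distance_nm, again$distance_nm, tolerance = 1e-6)
})

test_that("classification recovers ground-truth classes without noise", {
  cfg <- sim_config(n_cells = 8, loc_sd_nm = 0, intensity_cv = 0,
                    n_free_suntag = 0, n_ago_spots = 0,
                    p_risc_bind = 0.5, time_min = 30, seed = 66)
  sim <- simulate_cells(cfg, "miR21", "triple")
  tabs <- emit_spot_tables(sim, cfg)
  cl <- classify_mrnas(tabs$mrna, tabs$suntag, tabs$ago)
  truth <- sim$truth[sim$truth$species == "reporter_mRNA", ]
  i <- match(cl$mrna_spot_id, truth$spot_id)
  expect_equal(cl$translated, truth$translated[i])
  expect_equal(cl$risc_positive, truth$risc_bound[i])
})

test_that("partner spots partition exactly into on-mRNA and free", {
  set.seed(67)
  m <- random_spot_table(100, extent_nm = 20000)
  p <- random_spot_table(1000, extent_nm = 20000)
  pairs <- match_spots(m, p, 400)
  parts <- partition_free_spots(p, pairs)
  expect_equal(nrow(parts$on_mrna), nrow(pairs))
  expect_equal(nrow(parts$on_mrna) + nrow(parts$free), nrow(p))
  expect_length(intersect(parts$on_mrna$spot_id, parts$free$spot_id), 0)

  none <- partition_free_spots(p, pairs[0, ])
  expect_equal(nrow(none$free), nrow(p))
})

test_that("the mutant condition shows a nonzero chance-colocalization baseline", {
  cfg <- sim_config(n_cells = 15, seed = 68, time_min = 30)
  sim <- simulate_cells(cfg, "mutant", "triple")
  tabs <- emit_spot_tables(sim, cfg)
  cl <- classify_mrnas(tabs$mrna, tabs$suntag, tabs$ago)
  cyto <- cl[cl$compartment == "cytoplasmic", ]
  frac <- mean(cyto$risc_positive)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.35)
})
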