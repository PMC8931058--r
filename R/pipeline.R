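#' Run a complete in-silico silencing experiment
#'
#' Orchestrates simulate -> (emit spot tables | render + detect) ->
#' compartment assignment -> drift correction -> classification ->
#' per-cell/bulk metrics -> statistics, for every condition x time-point
#' combination of one of the three experiment shapes:
#' * `"decay"` -- SunTag reporter vs Fluc internal control; stability `S`,
#'   normalized to the mutant control within each time point;
#' * `"translation"` -- mRNA + SunTag; `T_eff`, `T_fra`;
#' * `"triple"` -- mRNA + SunTag + AGO; all metrics.
#'
#' Condition comparisons use one-tailed Mann-Whitney tests with the
#' direction each hypothesis implies (miR-21 reduces `S`, `T_eff`, `T_fra`
#' and increases `A_eff`, `A_fra`); time courses additionally run Dunn's
#' multiple comparisons of miR-21 vs mutant within each time point across
#' the pooled condition x time groups.
#'
#' @param design `"triple"`, `"translation"`, `"risc"` or `"decay"`.
#' @param config Base [sim_config()]; `time_min` and `seed` are varied per
#'   condition/time internally (derived deterministically from
#'   `config$seed`).
#' @param conditions Conditions to simulate.
#' @param time_points_min Subset of `c(0, 30, 60)`.
#' @param mode `"spots"` (noisy spot tables, fast) or `"images"` (render
#'   stacks and run detection; slow, small fields recommended).
#' @param gates_nm Colocalization gates.
#' @return A `silence_experiment` list: `per_cell`, `bulk`, `classes`,
#'   `tests_mw`, `tests_dunn`, `manifest`.
#' @export
run_experiment <- function(design = c("triple", "translation", "risc",
                                      "decay"),
                           config = sim_config(),
                           conditions = c("miR21", "mutant"),
                           time_points_min = 0,
                           mode = c("spots", "images"),
                           gates_nm = c(suntag = 500, ago = 250)) {
  design <- arg_match(design)
  mode <- arg_match(mode)
  stopifnot(all(time_points_min %in% c(0, 30, 60)))

  runs <- expand.grid(condition = conditions, time_min = time_points_min,
                      stringsAsFactors = FALSE)
  res <- map(seq_len(nrow(runs)), function(i) {
    cond <- runs$condition[i]; tmin <- runs$time_min[i]
    cfg <- config
    cfg$time_min <- tmin
    cfg$seed <- (config$seed + 7717 * match(cond, c("miR21", "mutant")) +
                   131 * tmin) %% 2147483647
    run_one_condition(design, cfg, cond, mode, gates_nm)
  })

  per_cell <- map2(res, seq_len(nrow(runs)), function(r, i) {
    r$cells |> mutate(condition = runs$condition[i],
                      time_min = runs$time_min[i])
  }) |> list_rbind()
  classes <- map2(res, seq_len(nrow(runs)), function(r, i) {
    as_tibble(r$classified) |> mutate(condition = runs$condition[i],
                                      time_min = runs$time_min[i])
  }) |> list_rbind()

  # normalize stability to the mutant control within each time point
  if (design == "decay" && "mutant" %in% conditions) {
    per_cell <- per_cell |>
      group_by(.data$time_min) |>
      group_modify(function(df, key) {
        ctrl <- bulk_metrics(filter(df, .data$condition == "mutant"))
        normalize_to_control(df, ctrl)
      }) |>
      ungroup()
  }

  bulk <- per_cell |>
    group_by(.data$condition, .data$time_min) |>
    group_modify(function(df, key) bulk_metrics(df)) |>
    ungroup()

  tests_mw <- condition_tests(per_cell, design)
  tests_dunn <- if (length(time_points_min) > 1 && length(conditions) == 2) {
    timecourse_tests(per_cell, design)
  } else {
    NULL
  }

  manifest <- list(
    package_version = as.character(packageVersion("silencescope")),
    design = design, mode = mode,
    conditions = conditions, time_points_min = time_points_min,
    gates_nm = as.list(gates_nm),
    seed = config$seed,
    config_json = as.character(toJSON(unclass(config), auto_unbox = TRUE,
                                      digits = NA))
  )
  structure(list(per_cell = per_cell, bulk = bulk, classes = classes,
                 tests_mw = tests_mw, tests_dunn = tests_dunn,
                 manifest = manifest),
            class = "silence_experiment")
}

design_channels <- function(design) {
  switch(design,
         triple = c("mrna", "suntag", "ago"),
         translation = c("mrna", "suntag"),
         risc = c("mrna", "ago"),
         decay = c("mrna", "fluc"))
}

run_one_condition <- function(design, cfg, condition, mode, gates_nm) {
  sim <- simulate_cells(cfg, condition = condition, design = design)
  chans <- design_channels(design)
  if (mode == "spots") {
    tabs <- emit_spot_tables(sim, cfg)
  } else {
    stacks <- render_field(sim, cfg, channels = c(chans, "dapi",
                                                  "background"))
    nuclei <- segment_nuclei(stacks$dapi)
    cells <- segment_cells(stacks$background, nuclei)
    geom <- geometry_from_masks(nuclei, cells, cfg$voxel_size)
    tabs <- map(stacks[chans], detect_spots)
    tabs <- map(tabs, assign_compartment, geometry = geom)
  }
  for (ch in chans) {
    if (is.null(tabs[[ch]])) {
      abort(sprintf("design '%s' needs the '%s' channel but it is missing",
                    design, ch))
    }
  }
  drifts <- list()
  for (ch in intersect(c("suntag", "ago", "fluc"), chans)) {
    drifts[[ch]] <- tryCatch(
      estimate_drift(tabs$mrna, tabs[[ch]]),
      error = function(e) zero_drift()
    )
  }
  classified <- classify_mrnas(
    tabs$mrna,
    suntag = tabs$suntag, ago = tabs$ago,
    drifts = drifts, gates_nm = gates_nm
  )
  cells <- per_cell_metrics(classified, fluc = tabs$fluc,
                            geometry = sim$geometry)
  list(sim = sim, tables = tabs, drifts = drifts, classified = classified,
       cells = cells)
}

# one-tailed condition comparisons per metric and time point; directions
# encode the silencing hypotheses (miR-21 lowers S / T_eff / T_fra, raises
# A_eff / A_fra)
metric_directions <- c(S = "less", S_norm = "less", T_eff = "less",
                       T_fra = "less", A_eff = "greater", A_fra = "greater")

condition_tests <- function(per_cell, design) {
  metrics <- intersect(names(metric_directions), names(per_cell))
  metrics <- metrics[vapply(metrics, function(m)
    any(is.finite(per_cell[[m]])), logical(1))]
  if (!all(c("miR21", "mutant") %in% per_cell$condition) ||
      length(metrics) == 0) {
    return(NULL)
  }
  out <- map(metrics, function(m) {
    per_cell |>
      group_by(.data$time_min) |>
      group_modify(function(df, key) {
        a <- df[[m]][df$condition == "miR21"]
        b <- df[[m]][df$condition == "mutant"]
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        if (length(a) == 0 || length(b) == 0) return(tibble())
        mann_whitney(a, b, alternative = metric_directions[[m]]) |>
          mutate(metric = m, .before = 1)
      }) |>
      ungroup()
  }) |> list_rbind()
  class(out) <- c("silence_test", class(out))
  out
}

timecourse_tests <- function(per_cell, design) {
  metrics <- intersect(names(metric_directions), names(per_cell))
  metrics <- metrics[vapply(metrics, function(m)
    any(is.finite(per_cell[[m]])), logical(1))]
  times <- sort(unique(per_cell$time_min))
  comparisons <- lapply(times, function(t)
    c(paste0("miR21_", t), paste0("mutant_", t)))
  out <- map(metrics, function(m) {
    df <- per_cell |>
      mutate(grp = paste0(.data$condition, "_", .data$time_min)) |>
      filter(is.finite(.data[[m]]))
    dunn_test(df, m, "grp", comparisons = comparisons) |>
      mutate(metric = m,
             time_min = as.numeric(sub(".*_", "", .data$group1)),
             .before = 1)
  }) |> list_rbind()
  class(out) <- c("silence_test", class(out))
  out
}

#' @export
print.silence_experiment <- function(x, ...) {
  cat("<silence_experiment>", x$manifest$design, "design,",
      paste(x$manifest$conditions, collapse = "/"), "at",
      paste(x$manifest$time_points_min, collapse = "/"), "min\n")
  print(x$bulk)
  invisible(x)
}

#' @rdname run_experiment
#' @param x A `silence_experiment` (for `glance`).
#' @param ... Unused.
#' @export
glance.silence_experiment <- function(x, ...) x$bulk

#' @rdname run_experiment
#' @export
tidy.silence_experiment <- function(x, ...) {
  bind_rows(
    if (!is.null(x$tests_mw)) as_tibble(x$tests_mw),
    if (!is.null(x$tests_dunn)) as_tibble(x$tests_dunn)
  )
}
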