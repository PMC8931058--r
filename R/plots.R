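# ggplot2 views of the result tables; styling mirrors the field's
# single-cell scatter-with-median convention.

#' Per-cell metric scatter with medians
#'
#' One jittered point per cell, grouped by condition (and faceted by time
#' point when present), with a median crossbar -- the standard single-cell
#' presentation for these metrics.
#'
#' @param per_cell Per-cell metrics tibble (from [per_cell_metrics()] or a
#'   `silence_experiment`).
#' @param metric Metric column name (e.g. `"T_eff"`, `"A_fra"`,
#'   `"S_norm"`).
#' @return A ggplot.
#' @export
plot_metric <- function(per_cell, metric = "T_eff") {
  if (inherits(per_cell, "silence_experiment")) per_cell <- per_cell$per_cell
  df <- per_cell |> filter(is.finite(.data[[metric]]))
  if (!"condition" %in% names(df)) df$condition <- "all"
  p <- ggplot(df, aes(x = .data$condition, y = .data[[metric]],
                      colour = .data$condition)) +
    geom_jitter(width = 0.15, alpha = 0.6, size = 1.4) +
    stat_summary(fun = median, geom = "crossbar", width = 0.4,
                 colour = "red", linewidth = 0.3) +
    labs(x = NULL, y = metric) +
    theme_classic() +
    theme(legend.position = "none")
  if ("time_min" %in% names(df) && length(unique(df$time_min)) > 1) {
    p <- p + facet_wrap(~time_min, labeller = label_both)
  }
  p
}

#' Stacked four-class composition of mRNAs
#'
#' Fractions of RISC-negative/positive x untranslated/translated
#' cytoplasmic mRNAs per condition (and time point).
#'
#' @param classes Classified-mRNA tibble (or a `silence_experiment`).
#' @return A ggplot.
#' @export
plot_classes <- function(classes) {
  if (inherits(classes, "silence_experiment")) classes <- classes$classes
  df <- classes |> filter(.data$compartment == "cytoplasmic")
  if (!"condition" %in% names(df)) df$condition <- "all"
  grp <- intersect(c("condition", "time_min"), names(df))
  df <- df |>
    group_by(across(all_of(c(grp, "class")))) |>
    summarise(n = n(), .groups = "drop_last") |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()
  p <- ggplot(df, aes(x = .data$condition, y = .data$fraction,
                      fill = .data$class)) +
    geom_col(position = "stack") +
    labs(x = NULL, y = "fraction of cytoplasmic mRNAs", fill = NULL) +
    theme_classic()
  if ("time_min" %in% names(df) && length(unique(df$time_min)) > 1) {
    p <- p + facet_wrap(~time_min, labeller = label_both)
  }
  p
}

#' @export
autoplot.silence_experiment <- function(object, metric = NULL, ...) {
  metric <- metric %||% switch(object$manifest$design,
                               decay = if ("S_norm" %in%
                                 names(object$per_cell)) "S_norm" else "S",
                               translation = "T_eff",
                               risc = "A_eff",
                               triple = "A_eff")
  plot_metric(object, metric)
}

#' @export
autoplot.classified_mrnas <- function(object, ...) plot_classes(object)
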