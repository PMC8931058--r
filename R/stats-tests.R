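#' One-tailed Mann-Whitney U test
#'
#' Rank-sum test comparing two independent samples. The p-value is exact
#' (full enumeration of rank assignments) when the pooled size is at most 20
#' and the data are tie-free; otherwise the normal approximation with tie
#' correction and continuity correction is used. `alternative = "greater"`
#' tests the hypothesis that `x` is stochastically greater than `y` (same
#' convention as [stats::wilcox.test()]).
#'
#' @param x,y Numeric samples (each nonempty).
#' @param alternative `"greater"`, `"less"` or `"two_sided"`.
#' @param exact_max Largest pooled size for which the exact path is used.
#' @return A one-row `silence_test` tibble: `statistic` (U of `x`),
#'   `p_value`, `n1`, `n2`, `alternative`, `exact`, `method`, `band`.
#' @export
mann_whitney <- function(x, y,
                         alternative = c("greater", "less", "two_sided"),
                         exact_max = 20) {
  alternative <- arg_match(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) abort("both samples must be nonempty")
  m <- length(x); n <- length(y); N <- m + n
  pooled <- c(x, y)
  r <- rank(pooled)
  ties <- any(duplicated(pooled))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2  # = #{x_i > y_j} (+0.5/tie)

  if (N <= exact_max && !ties) {
    # enumerate all C(N, m) equally likely rank assignments of the x-sample
    combos <- utils::combn(N, m)
    u_all <- colSums(combos) - m * (m + 1) / 2
    p <- switch(alternative,
      greater = mean(u_all >= U),
      less = mean(u_all <= U),
      two_sided = min(1, 2 * min(mean(u_all >= U), mean(u_all <= U)))
    )
    exact <- TRUE
  } else {
    mu <- m * n / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sig <- sqrt(m * n / 12 * ((N + 1) - tie_term))
    p_greater <- pnorm((U - mu - 0.5) / sig, lower.tail = FALSE)
    p_less <- pnorm((U - mu + 0.5) / sig)
    p <- switch(alternative,
      greater = p_greater,
      less = p_less,
      two_sided = min(1, 2 * min(p_greater, p_less))
    )
    exact <- FALSE
  }
  out <- tibble(
    method = "Mann-Whitney U",
    statistic = U, p_value = p, p_adjusted = NA_real_,
    n1 = m, n2 = n, alternative = alternative, exact = exact,
    band = signif_band(p)
  )
  class(out) <- c("silence_test", class(out))
  out
}

#' Dunn's multiple-comparisons test
#'
#' Kruskal-Wallis-style post hoc: all observations are ranked together and
#' each requested pair of groups is compared with
#' `z = (meanrank_i - meanrank_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))`
#' where the tie term is `T = sum(t^3 - t) / (12 (N - 1))`. Two-sided
#' p-values come from the standard normal; the adjusted p is Bonferroni over
#' the comparisons actually performed (`p_adj = min(1, m p)`).
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the response and the
#'   grouping factor.
#' @param comparisons `NULL` for all pairs, or a list of length-2 character
#'   vectors naming the group pairs to test.
#' @return A `silence_test` tibble with one row per comparison.
#' @export
dunn_test <- function(data, value, group, comparisons = NULL) {
  v <- data[[value]]; g <- as.character(data[[group]])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  sizes <- table(g)
  if (any(sizes == 0) || length(v) == 0) abort("every group must be nonempty")
  if (length(sizes) < 3) warn("Dunn's test with fewer than 3 groups")
  N <- length(v)
  r <- rank(v)
  mean_rank <- tapply(r, g, mean)
  tie_tab <- table(v)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  groups <- names(sizes)
  if (is.null(comparisons)) {
    comparisons <- utils::combn(groups, 2, simplify = FALSE)
  }
  m_comp <- length(comparisons)
  rows <- map(comparisons, function(pr) {
    if (!all(pr %in% groups)) abort(sprintf("unknown group in comparison: %s",
                                            paste(pr, collapse = " vs ")))
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / sizes[[pr[1]]] + 1 / sizes[[pr[2]]]))
    z <- (mean_rank[[pr[1]]] - mean_rank[[pr[2]]]) / se
    p <- 2 * pnorm(-abs(z))
    tibble(method = "Dunn", comparison = paste(pr, collapse = " vs "),
           group1 = pr[1], group2 = pr[2],
           statistic = z, p_value = p,
           p_adjusted = min(1, m_comp * p),
           n1 = as.integer(sizes[[pr[1]]]), n2 = as.integer(sizes[[pr[2]]]))
  })
  out <- list_rbind(rows) |>
    mutate(band = signif_band(.data$p_adjusted))
  class(out) <- c("silence_test", class(out))
  out
}

#' Pearson correlation with simple linear regression
#'
#' @param x,y Numeric vectors (n >= 3, finite).
#' @return One-row tibble: `r`, `slope`, `intercept`, `n`.
#' @export
pearson_with_fit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need at least 3 finite (x, y) pairs")
  if (sd(x) == 0) abort("x has zero variance")
  fit <- lm(y ~ x)
  tibble(r = cor(x, y), slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]), n = length(x))
}

#' @export
print.silence_test <- function(x, ...) {
  label <- if ("method" %in% names(x)) x$method[1] else "statistical"
  cat("<", label, "test results >\n", sep = " ")
  print(as_tibble(x), ...)
  invisible(x)
}

#' @rdname mann_whitney
#' @param x A `silence_test` object (for `tidy`).
#' @param ... Unused.
#' @export
tidy.silence_test <- function(x, ...) as_tibble(x)
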