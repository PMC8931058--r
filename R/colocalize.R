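#' Estimate the average inter-channel drift
#'
#' Pairs spots of two channels by mutual nearest neighbour within a search
#' radius, takes the mean displacement (moving minus reference) as the drift
#' vector, and refines once after applying the offset. When both tables
#' carry `cell_id`, pairing is restricted to within-cell candidates.
#'
#' @param ref,moving Spot tibbles (`z_nm`, `y_nm`, `x_nm`, optional
#'   `cell_id`).
#' @param search_radius_nm Pairing radius (default 500 nm).
#' @param min_pairs Minimum mutual pairs required (default 10).
#' @return A `drift_vector`: list with `offset_nm` (named z/y/x) and
#'   `n_pairs`.
#' @export
estimate_drift <- function(ref, moving, search_radius_nm = 500,
                           min_pairs = 10) {
  check_spot_table(ref); check_spot_table(moving)
  if (nrow(ref) == 0 || nrow(moving) == 0) {
    abort("both spot tables must be nonempty to estimate drift")
  }
  one_pass <- function(offset) {
    mv <- moving
    mv$z_nm <- mv$z_nm - offset[1]
    mv$y_nm <- mv$y_nm - offset[2]
    mv$x_nm <- mv$x_nm - offset[3]
    pairs <- mutual_nn(ref, mv, search_radius_nm)
    if (nrow(pairs) == 0) return(NULL)
    disp <- cbind(moving$z_nm[pairs$j] - ref$z_nm[pairs$i],
                  moving$y_nm[pairs$j] - ref$y_nm[pairs$i],
                  moving$x_nm[pairs$j] - ref$x_nm[pairs$i])
    list(offset = colMeans(disp), n = nrow(pairs))
  }
  first <- one_pass(c(0, 0, 0))
  if (is.null(first) || first$n < min_pairs) {
    abort(sprintf("drift estimation found %d mutual pairs (< %d required)",
                  if (is.null(first)) 0L else first$n, min_pairs))
  }
  second <- one_pass(first$offset)
  off <- if (!is.null(second)) second$offset else first$offset
  n <- if (!is.null(second)) second$n else first$n
  structure(list(offset_nm = setNames(off, c("z", "y", "x")),
                 n_pairs = n),
            class = "drift_vector")
}

#' @export
print.drift_vector <- function(x, ...) {
  cat(sprintf("<drift_vector> (z %.1f, y %.1f, x %.1f) nm from %d pairs\n",
              x$offset_nm[["z"]], x$offset_nm[["y"]], x$offset_nm[["x"]],
              x$n_pairs))
  invisible(x)
}

zero_drift <- function() {
  structure(list(offset_nm = c(z = 0, y = 0, x = 0), n_pairs = 0L),
            class = "drift_vector")
}

# mutual nearest neighbours within `radius`, blockwise by cell_id when
# available; returns tibble(i = row in a, j = row in b, dist)
mutual_nn <- function(a, b, radius) {
  blocks <- if ("cell_id" %in% names(a) && "cell_id" %in% names(b)) {
    ids <- intersect(unique(a$cell_id), unique(b$cell_id))
    lapply(ids, function(id) list(i = which(a$cell_id %in% id),
                                  j = which(b$cell_id %in% id)))
  } else {
    list(list(i = seq_len(nrow(a)), j = seq_len(nrow(b))))
  }
  out <- map(blocks, function(bl) {
    if (length(bl$i) == 0 || length(bl$j) == 0) return(NULL)
    dm <- cross_dist(a[bl$i, ], b[bl$j, ])
    nn_ab <- apply(dm, 1, which.min)
    nn_ba <- apply(dm, 2, which.min)
    ii <- seq_along(bl$i)
    mut <- nn_ba[nn_ab] == ii
    d <- dm[cbind(ii, nn_ab)]
    keep <- mut & d <= radius
    tibble(i = bl$i[keep], j = bl$j[nn_ab[keep]], dist = d[keep])
  })
  list_rbind(keep(out, Negate(is.null)))
}

#' Match mRNA spots to partner spots under a distance gate
#'
#' Applies the drift correction to the partner channel, enumerates all
#' candidate pairs with 3D Euclidean distance at or below the gate, and
#' accepts them greedily in ascending distance order (ties broken by lower
#' spot id), so that every spot takes part in at most one pair. When both
#' tables carry `cell_id`, only within-cell pairs are considered.
#'
#' @param mrnas,partners Spot tibbles with `spot_id` and positions in nm.
#' @param max_dist_nm Colocalization gate in nm (500 for mRNA-SunTag, 250
#'   for mRNA-AGO).
#' @param drift A `drift_vector` for the partner channel, or `NULL` for
#'   zero drift.
#' @return Tibble `mrna_spot_id`, `partner_spot_id`, `distance_nm`.
#' @export
match_spots <- function(mrnas, partners, max_dist_nm, drift = NULL) {
  check_spot_table(mrnas); check_spot_table(partners)
  if (max_dist_nm < 0) abort("max_dist_nm must be non-negative")
  empty <- tibble(mrna_spot_id = integer(0), partner_spot_id = integer(0),
                  distance_nm = numeric(0))
  if (nrow(mrnas) == 0 || nrow(partners) == 0) return(empty)
  off <- if (is.null(drift)) c(z = 0, y = 0, x = 0) else drift$offset_nm
  p <- partners
  p$z_nm <- p$z_nm - off[["z"]]
  p$y_nm <- p$y_nm - off[["y"]]
  p$x_nm <- p$x_nm - off[["x"]]

  blocks <- if ("cell_id" %in% names(mrnas) && "cell_id" %in% names(p)) {
    ids <- intersect(unique(mrnas$cell_id), unique(p$cell_id))
    lapply(ids, function(id) list(i = which(mrnas$cell_id %in% id),
                                  j = which(p$cell_id %in% id)))
  } else {
    list(list(i = seq_len(nrow(mrnas)), j = seq_len(nrow(p))))
  }
  cand <- map(blocks, function(bl) {
    if (length(bl$i) == 0 || length(bl$j) == 0) return(NULL)
    dm <- cross_dist(mrnas[bl$i, ], p[bl$j, ])
    hit <- which(dm <= max_dist_nm, arr.ind = TRUE)
    if (nrow(hit) == 0) return(NULL)
    tibble(mrna_row = bl$i[hit[, 1]], partner_row = bl$j[hit[, 2]],
           distance_nm = dm[hit])
  }) |> keep(Negate(is.null)) |> list_rbind()
  if (is.null(cand) || nrow(cand) == 0) return(empty)

  cand <- cand |>
    mutate(mrna_spot_id = mrnas$spot_id[.data$mrna_row],
           partner_spot_id = partners$spot_id[.data$partner_row]) |>
    arrange(.data$distance_nm, .data$mrna_spot_id, .data$partner_spot_id)
  used_m <- integer(0); used_p <- integer(0)
  take <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (!(cand$mrna_spot_id[r] %in% used_m) &&
        !(cand$partner_spot_id[r] %in% used_p)) {
      take[r] <- TRUE
      used_m <- c(used_m, cand$mrna_spot_id[r])
      used_p <- c(used_p, cand$partner_spot_id[r])
    }
  }
  cand[take, c("mrna_spot_id", "partner_spot_id", "distance_nm")]
}

#' Classify mRNAs by translation and RISC binding
#'
#' Matches mRNA spots against SunTag spots (500 nm gate) and AGO spots
#' (250 nm gate) after drift correction, then assigns every mRNA to one of
#' the four classes of the 2x2 translated-by-RISC table. Matching is
#' restricted to cytoplasmic spots; nuclear mRNAs are retained with both
#' flags `FALSE` so they remain available for export counting.
#'
#' @param mrnas mRNA spot tibble (`spot_id`, `cell_id`, `compartment`,
#'   positions, `intensity`).
#' @param suntag,ago Partner spot tibbles, or `NULL` when the channel was
#'   not imaged.
#' @param drifts Named list of `drift_vector`s (`suntag`, `ago`).
#' @param gates_nm Named gates `c(suntag = 500, ago = 250)`.
#' @return A `classified_mrnas` tibble: ids, cell, compartment, `translated`
#'   and `risc_positive` flags, partner ids, distances and partner
#'   intensities, and the combined `class` label.
#' @export
classify_mrnas <- function(mrnas, suntag = NULL, ago = NULL,
                           drifts = list(),
                           gates_nm = c(suntag = 500, ago = 250)) {
  out <- mrnas |>
    select("spot_id", "cell_id", "compartment", "z_nm", "y_nm", "x_nm",
           mrna_intensity = "intensity") |>
    rename(mrna_spot_id = "spot_id") |>
    mutate(translated = FALSE, risc_positive = FALSE,
           suntag_partner_id = NA_integer_, suntag_dist_nm = NA_real_,
           suntag_intensity = NA_real_,
           ago_partner_id = NA_integer_, ago_dist_nm = NA_real_,
           ago_intensity = NA_real_)
  cyto <- mrnas[mrnas$compartment == "cytoplasmic", ]
  attach_partner <- function(out, partners, gate, drift, prefix) {
    pc <- partners[partners$compartment == "cytoplasmic", ]
    pairs <- match_spots(cyto, pc, gate, drift)
    if (nrow(pairs) > 0) {
      i <- match(pairs$mrna_spot_id, out$mrna_spot_id)
      out[[paste0(prefix, "_partner_id")]][i] <- pairs$partner_spot_id
      out[[paste0(prefix, "_dist_nm")]][i] <- pairs$distance_nm
      out[[paste0(prefix, "_intensity")]][i] <-
        partners$intensity[match(pairs$partner_spot_id, partners$spot_id)]
    }
    out
  }
  if (!is.null(suntag)) {
    out <- attach_partner(out, suntag, gates_nm[["suntag"]],
                          drifts$suntag, "suntag")
    out$translated <- !is.na(out$suntag_partner_id)
  }
  if (!is.null(ago)) {
    out <- attach_partner(out, ago, gates_nm[["ago"]], drifts$ago, "ago")
    out$risc_positive <- !is.na(out$ago_partner_id)
  }
  out$class <- paste0(
    ifelse(out$risc_positive, "RISC-positive ", "RISC-negative "),
    ifelse(out$translated, "translated", "untranslated")
  )
  class(out) <- c("classified_mrnas", class(out))
  out
}

#' Split partner spots into on-mRNA and free populations
#'
#' @param partners Partner spot tibble.
#' @param pairs Pair table from [match_spots()] (or a `classified_mrnas`
#'   table, from which the relevant partner ids are pulled).
#' @param which For a `classified_mrnas` input, which partner column to use
#'   (`"suntag"` or `"ago"`).
#' @return List with `on_mrna` and `free` tibbles (disjoint, exhaustive).
#' @export
partition_free_spots <- function(partners, pairs, which = c("suntag", "ago")) {
  ids <- if (inherits(pairs, "classified_mrnas")) {
    which <- arg_match(which)
    col <- paste0(which, "_partner_id")
    pairs[[col]][!is.na(pairs[[col]])]
  } else {
    pairs$partner_spot_id
  }
  on <- partners$spot_id %in% ids
  list(on_mrna = partners[on, ], free = partners[!on, ])
}
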