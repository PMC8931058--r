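# Independent oracles and small fixture builders used across tests.

# Brute-force greedy matcher: repeatedly accept the globally smallest
# remaining distance <= gate from the full distance matrix (ties by lower
# mrna id then partner id). Same rule as match_spots(), implemented over
# the dense matrix so the two can be compared.
brute_force_match <- function(mrnas, partners, gate) {
  if (nrow(mrnas) == 0 || nrow(partners) == 0) {
    return(tibble::tibble(mrna_spot_id = integer(0),
                          partner_spot_id = integer(0),
                          distance_nm = numeric(0)))
  }
  dm <- sqrt(outer(mrnas$z_nm, partners$z_nm, "-")^2 +
               outer(mrnas$y_nm, partners$y_nm, "-")^2 +
               outer(mrnas$x_nm, partners$x_nm, "-")^2)
  out <- list()
  repeat {
    ok <- which(dm <= gate, arr.ind = TRUE)
    if (nrow(ok) == 0) break
    d <- dm[ok]
    cand <- data.frame(i = ok[, 1], j = ok[, 2], d = d,
                       mid = mrnas$spot_id[ok[, 1]],
                       pid = partners$spot_id[ok[, 2]])
    cand <- cand[order(cand$d, cand$mid, cand$pid), ]
    top <- cand[1, ]
    out[[length(out) + 1]] <- top
    dm[top$i, ] <- Inf
    dm[, top$j] <- Inf
  }
  if (length(out) == 0) {
    return(tibble::tibble(mrna_spot_id = integer(0),
                          partner_spot_id = integer(0),
                          distance_nm = numeric(0)))
  }
  res <- do.call(rbind, out)
  tibble::tibble(mrna_spot_id = res$mid, partner_spot_id = res$pid,
                 distance_nm = res$d)
}

random_spot_table <- function(n, extent_nm = 5000) {
  tibble::tibble(
    spot_id = seq_len(n),
    z_nm = runif(n, 0, extent_nm / 2),
    y_nm = runif(n, 0, extent_nm),
    x_nm = runif(n, 0, extent_nm)
  )
}

# Naive O(L * m) site-scanner oracle: slide every site string over every
# UTR position, then apply the same longest-type-wins rule keyed on the
# seed hexamer position.
naive_scan <- function(utr, mirnas) {
  rows <- list()
  for (i in seq_len(nrow(mirnas))) {
    sm <- silencescope::seed_match_strings(mirnas$sequence[i])
    found <- list()
    for (type in names(sm)) {
      pat <- sm[[type]]
      k <- nchar(pat)
      for (s in 0:(nchar(utr) - k)) {
        if (substr(utr, s + 1, s + k) == pat) {
          found[[length(found) + 1]] <-
            data.frame(mirna = mirnas$name[i], site_type = type,
                       start = s, seq = pat)
        }
      }
    }
    if (length(found) == 0) next
    tab <- do.call(rbind, found)
    tab$hex <- tab$start + ifelse(tab$site_type %in% c("8mer", "7mer-m8"),
                                  1L, 0L)
    tab$pri <- match(tab$site_type, c("8mer", "7mer-m8", "7mer-A1", "6mer"))
    keep <- do.call(rbind, lapply(split(tab, tab$hex), function(g)
      g[which.min(g$pri), ]))
    rows[[length(rows) + 1]] <- keep[, c("mirna", "site_type", "start",
                                         "seq")]
  }
  if (length(rows) == 0) {
    return(tibble::tibble(mirna = character(0), site_type = character(0),
                          start = integer(0), seq = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$mirna), ]
  tibble::as_tibble(out)
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# render a single Gaussian spot into a fresh stack (no noise, no offset)
render_single_spot <- function(z_nm, y_nm, x_nm, intensity,
                               dim = c(15, 32, 32),
                               vox = c(xy = 107.5, z = 200),
                               psf = c(xy = 150, z = 300), offset = 0) {
  cfg <- sim_config(n_cells = 1, field_shape = c(z = dim[1], y = dim[2],
                                                 x = dim[3]),
                    voxel_size = vox, psf_sigma_nm = psf,
                    noise = c(shot = 0, read = 0), bg_offset = offset)
  geom <- tibble::tibble(cell_id = 1L, center_x_nm = 0, center_y_nm = 0,
                         cell_a_nm = 1, cell_b_nm = 1, nuc_x_nm = 0,
                         nuc_y_nm = 0, nuc_a_nm = 0.5, nuc_b_nm = 0.5,
                         nucleus_area_um2 = 0, touches_border = FALSE)
  truth <- tibble::tibble(cell_id = 1L, species = "reporter_mRNA",
                          z_nm = z_nm, y_nm = y_nm, x_nm = x_nm,
                          intensity = intensity,
                          compartment = "cytoplasmic",
                          linked_mrna_id = NA_integer_,
                          ribosome_count = NA_real_, translated = NA,
                          risc_bound = NA, spot_id = 1L)
  sim <- list(truth = truth, geometry = geom)
  render_field(sim, cfg, channels = "mrna", noise = FALSE)$mrna
}

mir21 <- "UAGCUUAUCAGACUGAUGUUGA"

# Detection benchmark fixture: n spots with a minimum pairwise separation
# (resolvable single emitters), uniform in the field, lognormal intensities.
min_sep_truth <- function(n, min_sep_nm = 1000,
                          y_range = c(1000, 26500),
                          x_range = c(1000, 26500),
                          z_range = c(400, 2600),
                          meanlog = log(8000), sdlog = 0.25) {
  pts <- matrix(numeric(0), 0, 3)
  while (nrow(pts) < n) {
    cand <- c(runif(1, z_range[1], z_range[2]),
              runif(1, y_range[1], y_range[2]),
              runif(1, x_range[1], x_range[2]))
    if (nrow(pts) == 0 ||
        min(sqrt(colSums((t(pts) - cand)^2))) >= min_sep_nm) {
      pts <- rbind(pts, cand)
    }
  }
  tibble::tibble(
    spot_id = seq_len(n), cell_id = 1L, species = "reporter_mRNA",
    z_nm = pts[, 1], y_nm = pts[, 2], x_nm = pts[, 3],
    intensity = rlnorm(n, meanlog, sdlog), compartment = "cytoplasmic",
    linked_mrna_id = NA_integer_, ribosome_count = NA_real_,
    translated = NA, risc_bound = NA
  )
}
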