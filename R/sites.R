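# Canonical miRNA seed-site scanning. Coordinates are 0-based offsets on
# the forward strand of the given UTR. Site classes follow the canonical
# convention: the seed is miRNA nt 2-7/2-8, an A opposite position 1
# upgrades a site, pairing at nt 8 extends it.

rna_complement <- function(s) chartr("ACGU", "UGCA", s)

reverse_string <- function(s) {
  vapply(strsplit(s, NULL), function(ch) paste(rev(ch), collapse = ""), "")
}

rc_rna <- function(s) reverse_string(rna_complement(s))

check_rna <- function(s, arg = "sequence") {
  s <- toupper(s)
  if (grepl("T", s)) {
    warn(sprintf("`%s` contains T; converting to U", arg))
    s <- gsub("T", "U", s)
  }
  if (grepl("[^ACGU]", s)) {
    abort(sprintf("`%s` contains characters outside {A, C, G, U}", arg))
  }
  s
}

#' Target substrings matched by each canonical site type
#'
#' For a miRNA given 5'->3', the target-space (5'->3') matches are:
#' 6mer = reverse complement of nt 2-7; 7mer-m8 = rc(nt 2-8);
#' 7mer-A1 = rc(nt 2-7) followed by A; 8mer = rc(nt 2-8) followed by A.
#'
#' @param mirna_seq miRNA sequence, 5'->3' RNA.
#' @return Named character vector over the four site types.
#' @export
seed_match_strings <- function(mirna_seq) {
  s <- check_rna(mirna_seq, "mirna_seq")
  if (nchar(s) < 8) abort("miRNA sequence too short (need at least 8 nt)")
  seed27 <- substr(s, 2, 7)
  seed28 <- substr(s, 2, 8)
  c(`8mer` = paste0(rc_rna(seed28), "A"),
    `7mer-m8` = rc_rna(seed28),
    `7mer-A1` = paste0(rc_rna(seed27), "A"),
    `6mer` = rc_rna(seed27))
}

#' Scan a 3' UTR for canonical miRNA sites
#'
#' Reports all occurrences of the 8mer, 7mer-m8, 7mer-A1 and 6mer matches of
#' each miRNA. Overlapping occurrences of the same seed are deduplicated so
#' that the longest type wins (an 8mer suppresses the 7mer/6mer matches it
#' contains). Output is sorted by position.
#'
#' @param utr UTR sequence 5'->3' (RNA; T is auto-converted with a warning).
#' @param mirnas A data frame with `name` and `sequence` columns, or a named
#'   character vector of miRNA sequences.
#' @return Tibble `mirna`, `site_type`, `start` (0-based), `seq`.
#' @export
scan_utr <- function(utr, mirnas) {
  if (is.character(mirnas)) {
    mirnas <- tibble(name = names(mirnas) %||%
                       paste0("mir", seq_along(mirnas)),
                     sequence = unname(mirnas))
  }
  empty <- tibble(mirna = character(0), site_type = character(0),
                  start = integer(0), seq = character(0))
  if (nchar(utr) == 0) return(empty)
  utr <- check_rna(utr, "utr")

  hits <- map(seq_len(nrow(mirnas)), function(i) {
    sm <- seed_match_strings(mirnas$sequence[i])
    per_type <- imap(sm, function(pat, type) {
      starts <- find_all(utr, pat)
      if (length(starts) == 0) return(NULL)
      tibble(mirna = mirnas$name[i], site_type = type,
             start = starts, seq = pat)
    })
    tab <- list_rbind(keep(per_type, Negate(is.null)))
    if (is.null(tab) || nrow(tab) == 0) return(NULL)
    dedupe_sites(tab)
  })
  out <- list_rbind(keep(hits, Negate(is.null)))
  if (is.null(out) || nrow(out) == 0) return(empty)
  arrange(out, .data$start, .data$mirna)
}

# all 0-based start offsets of fixed pattern `pat` in `s`, overlaps included
find_all <- function(s, pat) {
  n <- nchar(s); k <- nchar(pat)
  if (k > n) return(integer(0))
  starts <- integer(0)
  from <- 1L
  repeat {
    hit <- regexpr(pat, substr(s, from, n), fixed = TRUE)
    if (hit == -1) break
    pos <- from + as.integer(hit) - 1L
    starts <- c(starts, pos - 1L)
    from <- pos + 1L
    if (from > n - k + 1L) break
  }
  starts
}

# Same-miRNA deduplication: occurrences sharing the position of the core
# seed hexamer keep only the longest type. For a site string starting at s
# (0-based), the hexamer rc(nt 2-7) sits at s+1 for 8mer and 7mer-m8 and at
# s for 7mer-A1 and 6mer.
dedupe_sites <- function(tab) {
  priority <- c(`8mer` = 1L, `7mer-m8` = 2L, `7mer-A1` = 3L, `6mer` = 4L)
  tab |>
    mutate(hex = .data$start +
             ifelse(.data$site_type %in% c("8mer", "7mer-m8"), 1L, 0L),
           pri = priority[.data$site_type]) |>
    group_by(.data$hex) |>
    slice_min(.data$pri, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select(-"hex", -"pri")
}

#' Verify designed-site pairing against seed and 3' supplemental regions
#'
#' Checks a designed target site (given 5'->3' with its 3' end opposite
#' miRNA nt 1) for perfect Watson-Crick complementarity opposite the seed
#' (nt 2-8) and opposite the 3' supplemental region (nt 13-16) at the
#' canonical register.
#'
#' @param site_seq Target site sequence, long enough to span positions
#'   opposite miRNA nt 1-16.
#' @param mirna_seq miRNA sequence 5'->3' (>= 16 nt).
#' @return Named logical vector `c(seed_paired = , supplemental_paired = )`.
#' @export
verify_site_pairing <- function(site_seq, mirna_seq) {
  site <- check_rna(site_seq, "site_seq")
  mir <- check_rna(mirna_seq, "mirna_seq")
  if (nchar(mir) < 16) abort("miRNA must be at least 16 nt")
  L <- nchar(site)
  if (L < 16) abort("site must span positions opposite miRNA nt 1-16")
  site_ch <- strsplit(site, NULL)[[1]]
  mir_ch <- strsplit(mir, NULL)[[1]]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  # site position L - k + 1 lies opposite miRNA nt k
  paired <- function(k) site_ch[L - k + 1] == comp[mir_ch[k]]
  c(seed_paired = all(vapply(2:8, paired, logical(1))),
    supplemental_paired = all(vapply(13:16, paired, logical(1))))
}

#' Audit a "cleaned" UTR against a miRNA list
#'
#' A reporter UTR intended to carry no canonical sites for the given miRNAs
#' (e.g. the 30 most abundant in the cell line) is scanned; any residual
#' sites are reported.
#'
#' @inheritParams scan_utr
#' @return List: `sites` (residual-site tibble), `clean` (logical),
#'   `n_residual`.
#' @export
audit_clean_utr <- function(utr, mirnas) {
  sites <- scan_utr(utr, mirnas)
  list(sites = sites, clean = nrow(sites) == 0, n_residual = nrow(sites))
}
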