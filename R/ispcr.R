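#' Find primer binding sites on a template
#'
#' Reports every position where the primer (plus strand) or its reverse
#' complement (minus strand) matches with at most `max_mismatch`
#' substitutions, requiring the `anchor` bases at the primer's 3' end to
#' match exactly (extension fails without an annealed 3' terminus). No
#' thermodynamics are modelled; matching is purely sequence-based.
#'
#' @param template template DNA string.
#' @param primer primer DNA string, written 5'->3'.
#' @param max_mismatch maximum substitutions outside the 3' anchor.
#' @param anchor number of exact-match bases at the 3' end (default 5).
#' @return tibble `position` (1-based start of the matched window on the
#'   plus strand), `strand`.
#' @export
find_primer_sites <- function(template, primer, max_mismatch = 2,
                              anchor = 5) {
  assert_dna(template, "template"); assert_dna(primer, "primer")
  if (nchar(primer) > nchar(template)) {
    return(tibble(position = integer(0), strand = character(0)))
  }
  plus <- .primer_scan_cpp(template, primer, as.integer(max_mismatch),
                           as.integer(anchor))
  # minus strand: the reverse complement anneals on the plus-strand text,
  # with the primer's 3' end at the window's left edge
  rc <- revcomp(primer)
  minus <- .primer_scan_anchor_left(template, rc, max_mismatch, anchor)
  bind_rows(
    tibble(position = as.integer(plus), strand = "+"),
    tibble(position = as.integer(minus), strand = "-")
  ) |> arrange(.data$position)
}

# anchor at the LEFT edge of the window: scan the reversed problem with the
# right-anchored C++ kernel
.primer_scan_anchor_left <- function(template, pattern, max_mismatch,
                                     anchor) {
  rev_chars <- function(s) {
    paste(rev(strsplit(s, NULL)[[1]]), collapse = "")
  }
  hits <- .primer_scan_cpp(rev_chars(template), rev_chars(pattern),
                           as.integer(max_mismatch), as.integer(anchor))
  if (length(hits) == 0) return(integer(0))
  sort(nchar(template) - nchar(pattern) - hits + 2L)
}

#' Predict the PCR amplicon ladder on a tandem-array template
#'
#' Enumerates all products between a forward-primer site on the plus strand
#' and a reverse-primer site on the minus strand whose 3' end lies
#' downstream of the forward 3' end, up to `max_len`. On a tandem array with
#' one site pair per unit this yields the monomer/dimer/multimer ladder; band
#' sizes within 1 bp are collapsed to one band.
#'
#' @param template template DNA string (e.g. several tandem units).
#' @param pair list or one-row tibble with `forward` and `reverse` primers
#'   (5'->3').
#' @param max_len maximum product size in bp (default 3000).
#' @param max_mismatch,anchor see [find_primer_sites()].
#' @return an `amplicon_ladder` tibble: `band_bp`, `fwd_site`, `rev_site`
#'   (1-based plus-strand starts), sorted by size.
#' @export
predict_amplicons <- function(template, pair, max_len = 3000,
                              max_mismatch = 2, anchor = 5) {
  assert_dna(template, "template")
  fwd <- pair$forward[[1]]
  rev_p <- pair$reverse[[1]]
  if (nchar(fwd) < 15 || nchar(fwd) > 30 ||
      nchar(rev_p) < 15 || nchar(rev_p) > 30) {
    abort("primer lengths must be 15-30 nt")
  }
  f_sites <- find_primer_sites(template, fwd, max_mismatch, anchor)
  f_sites <- f_sites[f_sites$strand == "+", , drop = FALSE]
  r_sites <- find_primer_sites(template, rev_p, max_mismatch, anchor)
  r_sites <- r_sites[r_sites$strand == "-", , drop = FALSE]
  empty <- tibble(band_bp = integer(0), fwd_site = integer(0),
                  rev_site = integer(0))
  if (nrow(f_sites) == 0 || nrow(r_sites) == 0) {
    return(structure(empty, class = c("amplicon_ladder", class(empty))))
  }
  combos <- tidyr::expand_grid(fwd_site = f_sites$position,
                               rev_site = r_sites$position)
  combos$band_bp <- combos$rev_site + nchar(rev_p) - combos$fwd_site
  combos <- combos |>
    filter(.data$rev_site >= .data$fwd_site + nchar(fwd),
           .data$band_bp <= max_len) |>
    arrange(.data$band_bp)
  # collapse bands within 1 bp of each other
  if (nrow(combos) > 0) {
    keep <- c(TRUE, diff(combos$band_bp) > 1)
    combos <- combos[keep, , drop = FALSE]
  }
  out <- combos[, c("band_bp", "fwd_site", "rev_site")]
  class(out) <- c("amplicon_ladder", class(out))
  out
}

#' Annotate an amplicon ladder with multimer labels
#'
#' Labels each band monomer/dimer/`k`-mer when its size is within 10% of
#' `k` times the unit length; bands off the unit ladder are flagged
#' `variant` (as seen when variant repeat units are present in the
#' germline arrays).
#'
#' @param ladder an `amplicon_ladder` from [predict_amplicons()].
#' @param unit_length repeat unit length in bp (> 0).
#' @return tibble `band_bp`, `n_units` (NA for variants), `label`.
#' @export
ladder_report <- function(ladder, unit_length) {
  if (unit_length <= 0) abort("unit_length must be > 0")
  if (nrow(ladder) == 0) {
    return(tibble(band_bp = integer(0), n_units = integer(0),
                  label = character(0)))
  }
  ordinal <- function(k) {
    if (k == 1) return("monomer")
    if (k == 2) return("dimer")
    if (k == 3) return("trimer")
    paste0(k, "-mer")
  }
  k_near <- round(ladder$band_bp / unit_length)
  on_ladder <- k_near >= 1 &
    abs(ladder$band_bp - k_near * unit_length) <= 0.1 * k_near * unit_length
  tibble(
    band_bp = ladder$band_bp,
    n_units = ifelse(on_ladder, as.integer(k_near), NA_integer_),
    label = ifelse(on_ladder, vapply(pmax(k_near, 1), ordinal, character(1)),
                   "variant")
  )
}
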