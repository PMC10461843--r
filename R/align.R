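star_scoring <- function() {
  list(match = 1, mismatch = -1, gap_opening = 2, gap_extension = 0.5)
}

pairwise_global <- function(a, b, scoring = star_scoring()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = scoring$gap_opening, gapExtension = scoring$gap_extension)
}

# Merge one (centroid, clone) pairwise alignment into a growing star
# alignment. `master` is the centroid row with the union gap pattern; `rows`
# are the already-merged rows. All are character vectors of single
# characters.
merge_into_star <- function(master, rows, cent_aln, clone_aln) {
  n <- length(master); m <- length(cent_aln)
  i <- 1L; j <- 1L
  new_master <- character(0)
  new_rows <- vector("list", length(rows))
  for (r in seq_along(rows)) new_rows[[r]] <- character(0)
  new_clone <- character(0)
  emit <- function(mi, ji) {
    new_master <<- c(new_master, if (!is.na(mi)) master[mi] else "-")
    for (r in seq_along(rows)) {
      new_rows[[r]] <<- c(new_rows[[r]],
                          if (!is.na(mi)) rows[[r]][mi] else "-")
    }
    new_clone <<- c(new_clone, if (!is.na(ji)) clone_aln[ji] else "-")
  }
  while (i <= n || j <= m) {
    mi_gap <- i <= n && master[i] == "-"
    ji_gap <- j <= m && cent_aln[j] == "-"
    if (i <= n && j <= m && !mi_gap && !ji_gap) {
      emit(i, j); i <- i + 1L; j <- j + 1L
    } else if (i <= n && j <= m && mi_gap && ji_gap) {
      emit(i, j); i <- i + 1L; j <- j + 1L
    } else if (i <= n && mi_gap) {
      emit(i, NA); i <- i + 1L
    } else if (j <= m && ji_gap) {
      emit(NA, j); j <- j + 1L
    } else if (i <= n) {
      emit(i, NA); i <- i + 1L
    } else {
      emit(NA, j); j <- j + 1L
    }
  }
  list(master = new_master, rows = c(new_rows, list(new_clone)))
}

#' Align cloned repeat copies (star alignment)
#'
#' Aligns each clone globally to a centroid clone — the clone with minimal
#' summed edit distance to all others — with affine-gap scoring (match +1,
#' mismatch -1, gap opening -2, extension -0.5, overridable), then merges
#' the pairwise alignments column-wise into one multiple alignment.
#' Substitution-only clone sets align without gaps.
#'
#' @param clones a `clone_set` (from [sample_clones()]) or tibble with
#'   `clone` and `sequence` columns, or a named character vector.
#' @param scoring list with `match`, `mismatch`, `gap_opening`,
#'   `gap_extension`.
#' @return an `alignment`: tibble with `clone` and `aligned` (equal-length
#'   gapped strings); attribute `centroid`.
#' @export
align_clones <- function(clones, scoring = star_scoring()) {
  if (is.character(clones)) {
    clones <- tibble(clone = names(clones) %||%
                       paste0("clone_", seq_along(clones)),
                     sequence = unname(clones))
  }
  seqs <- clones$sequence
  labels <- clones$clone
  if (length(seqs) < 2) abort("invalid-input: need >= 2 clones")

  d <- utils::adist(seqs)
  centroid_idx <- which.min(rowSums(d))
  centroid <- seqs[centroid_idx]

  master <- strsplit(centroid, NULL)[[1]]
  order_idx <- c(centroid_idx, setdiff(seq_along(seqs), centroid_idx))
  rows <- list(master)  # centroid row itself
  for (idx in order_idx[-1]) {
    if (seqs[idx] == centroid) {
      # identical clone: merge with a gap-free self-alignment
      res <- merge_into_star(master, rows, strsplit(centroid, NULL)[[1]],
                             strsplit(centroid, NULL)[[1]])
    } else {
      pa <- pairwise_global(centroid, seqs[idx], scoring)
      cent_aln <- strsplit(as.character(Biostrings::alignedPattern(pa)),
                           NULL)[[1]]
      clone_aln <- strsplit(as.character(Biostrings::alignedSubject(pa)),
                            NULL)[[1]]
      res <- merge_into_star(master, rows, cent_aln, clone_aln)
    }
    master <- res$master
    rows <- res$rows
  }

  aligned <- vapply(rows, paste, character(1), collapse = "")
  out <- tibble(clone = labels[order_idx], aligned = aligned)
  # drop all-gap columns, should any arise from merging
  chars <- do.call(rbind, strsplit(out$aligned, NULL))
  keep <- colSums(chars != "-") > 0
  if (!all(keep)) {
    out$aligned <- apply(chars[, keep, drop = FALSE], 1, paste,
                         collapse = "")
  }
  out <- out[match(labels, out$clone), , drop = FALSE]
  attr(out, "centroid") <- labels[centroid_idx]
  class(out) <- c("alignment", class(out))
  out
}

alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$aligned, NULL))
}

#' Majority-rule consensus of an alignment
#'
#' Per column, the most frequent base among non-gap symbols, ties broken
#' alphabetically (A < C < G < T); columns in which the gap is the most
#' frequent symbol overall are dropped, so the consensus is gap-free.
#'
#' @param aln an `alignment` from [align_clones()].
#' @return consensus DNA string.
#' @export
call_consensus <- function(aln) {
  chars <- alignment_matrix(aln)
  cons <- apply(chars, 2, function(col) {
    n_gap <- sum(col == "-")
    counts <- table(factor(col[col != "-"], levels = dna_alphabet))
    if (n_gap > max(counts)) return(NA_character_)
    names(counts)[which.max(counts)]  # which.max takes the first = A<C<G<T
  })
  paste(cons[!is.na(cons)], collapse = "")
}

#' Mean pairwise divergence of aligned clones (gap sites excluded)
#'
#' Intraspecific sequence diversity: for every unordered pair of rows, the
#' proportion of mismatching columns among columns where both rows have a
#' base; columns with a gap in either row are excluded for that pair. The
#' reported value is the mean over pairs, in percent. Pairs with no
#' comparable columns are skipped; if all pairs are skipped the result is a
#' no-call (`NA`).
#'
#' @param aln an `alignment`.
#' @return mean pairwise divergence in percent.
#' @export
pairwise_divergence <- function(aln) {
  chars <- alignment_matrix(aln)
  n <- nrow(chars)
  if (n < 2) abort("invalid-input: need >= 2 rows")
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- chars[i, ] != "-" & chars[j, ] != "-"
      if (!any(ok)) next
      vals <- c(vals, mean(chars[i, ok] != chars[j, ok]))
    }
  }
  if (length(vals) == 0) {
    warning("no comparable column in any pair: no-call")
    return(NA_real_)
  }
  100 * mean(vals)
}
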