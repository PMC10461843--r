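#' GC content in percent
#'
#' `100 * (#G + #C) / length`, reported to one decimal, rounded half up
#' (matching the reporting convention for repeat consensus sequences).
#'
#' @param seq non-empty A/C/G/T string.
#' @return numeric percent with one decimal.
#' @export
#' @examples
#' gc_content("GGCC")  # 100
gc_content <- function(seq) {
  assert_dna(seq, "seq")
  round_half_up(100 * gc_fraction(seq), 1)
}

#' Count substitutions between two consensus sequences of one family
#'
#' The two monomers are first rotation-aligned — the rotation of `b` (over
#' both strands) maximizing matches against `a` is chosen, since tandem
#' monomers have no natural origin — then globally aligned; the number of
#' mismatch columns is returned. Indel columns are recorded in the
#' `"indel_columns"` attribute, not counted as substitutions. Symmetric in
#' its arguments.
#'
#' @param a,b consensus DNA strings whose lengths differ by at most 2-fold.
#' @return integer substitution count (attribute `indel_columns`).
#' @export
#' @examples
#' count_substitutions("ACGT", "ACGA")  # 1
count_substitutions <- function(a, b) {
  assert_dna(a, "a"); assert_dna(b, "b")
  ratio <- nchar(a) / nchar(b)
  if (ratio < 0.5 || ratio > 2) abort("invalid-pair: length ratio outside [0.5, 2]")

  rotations <- function(s) {
    n <- nchar(s)
    doubled <- paste0(s, s)
    vapply(seq_len(n), function(i) substr(doubled, i, i + n - 1L),
           character(1))
  }
  cands <- c(rotations(b), rotations(revcomp(b)))

  if (nchar(a) == nchar(b)) {
    a_chars <- strsplit(a, NULL)[[1]]
    matches <- vapply(cands, function(s) {
      sum(strsplit(s, NULL)[[1]] == a_chars)
    }, numeric(1), USE.NAMES = FALSE)
    best <- cands[which.max(matches)]
  } else {
    scores <- vapply(cands, function(s) {
      Biostrings::score(pairwise_global(a, s))
    }, numeric(1), USE.NAMES = FALSE)
    best <- cands[which.max(scores)]
  }

  pa <- pairwise_global(a, best)
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), NULL)[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), NULL)[[1]]
  both <- pat != "-" & sub != "-"
  n_sub <- sum(pat[both] != sub[both])
  structure(as.integer(n_sub), indel_columns = sum(!both))
}

#' Find pairs of direct repeats in a monomer
#'
#' Maximal exact substrings of length >= `min_len` occurring at two or more
#' non-overlapping positions on the same strand. A candidate is suppressed
#' when it is contained in a longer repeated substring (so e.g. a
#' homopolymer run yields no pairs: every short word in it extends to a
#' longer repeated word whose occurrences overlap). Each surviving repeat is
#' reported once, with its first two non-overlapping occurrences.
#'
#' @param seq DNA string.
#' @param min_len minimum repeat length (default 8).
#' @param max_pairs report at most this many pairs, longest first.
#' @return tibble `substring`, `pos1`, `pos2` (1-based starts), `length`.
#' @export
find_direct_repeats <- function(seq, min_len = 8, max_pairs = 10) {
  assert_dna(seq, "seq")
  n <- nchar(seq)
  out <- list()
  if (n < 2 * min_len) {
    return(tibble(substring = character(0), pos1 = integer(0),
                  pos2 = integer(0), length = integer(0)))
  }
  repeated_at <- function(len) {
    if (len > n - 1) return(character(0))
    subs <- substring(seq, seq_len(n - len + 1), seq_len(n - len + 1) + len - 1)
    unique(subs[duplicated(subs)])
  }
  for (len in seq(n - 1, min_len)) {
    reps <- repeated_at(len)
    if (length(reps) == 0) next
    longer <- repeated_at(len + 1)
    for (w in reps) {
      # suppressed if contained in a longer repeated substring
      if (length(longer) > 0 &&
          any(vapply(longer, function(x) grepl(w, x, fixed = TRUE),
                     logical(1)))) {
        next
      }
      occ <- gregexpr(w, seq, fixed = TRUE)[[1]]
      if (occ[1] == -1 || length(occ) < 2) next
      p1 <- occ[1]
      p2 <- occ[occ >= p1 + len][1]
      if (is.na(p2)) next
      out[[length(out) + 1]] <- tibble(substring = w, pos1 = as.integer(p1),
                                       pos2 = as.integer(p2),
                                       length = as.integer(len))
    }
  }
  if (length(out) == 0) {
    return(tibble(substring = character(0), pos1 = integer(0),
                  pos2 = integer(0), length = integer(0)))
  }
  res <- list_rbind(out) |>
    arrange(dplyr::desc(.data$length), .data$pos1)
  head(res, max_pairs)
}

#' Scan a tandem monomer for open reading frames
#'
#' Scans all six frames of the doubled sequence (a tandem repeat has no
#' natural start, and an ORF may wrap around the unit boundary) for
#' ATG-to-stop spans of at least `min_aa` codons; hits are reported modulo
#' the unit length and de-duplicated.
#'
#' @param seq monomer DNA string.
#' @param min_aa minimum ORF length in codons, ATG included (default 30).
#' @return tibble `start` (1-based, within the unit), `length_codons`,
#'   `frame` (1-3), `strand` (+/-).
#' @export
find_orfs <- function(seq, min_aa = 30) {
  assert_dna(seq, "seq")
  L <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  scan_strand <- function(s, strand) {
    doubled <- paste0(s, s)
    hits <- list()
    for (frame in 1:3) {
      starts <- seq(frame, nchar(doubled) - 2, by = 3)
      codons <- substring(doubled, starts, starts + 2)
      i <- 1
      while (i <= length(codons)) {
        if (codons[i] == "ATG") {
          j <- i
          while (j <= length(codons) && !(codons[j] %in% stops)) j <- j + 1
          if (j <= length(codons)) {       # found a stop
            n_codons <- j - i
            if (n_codons >= min_aa && starts[i] <= L) {
              hits[[length(hits) + 1]] <- tibble(
                start = as.integer((starts[i] - 1L) %% L + 1L),
                length_codons = as.integer(n_codons),
                frame = as.integer(frame), strand = strand)
            }
            i <- j + 1
            next
          }
        }
        i <- i + 1
      }
    }
    hits
  }
  res <- c(scan_strand(seq, "+"), scan_strand(revcomp(seq), "-"))
  if (length(res) == 0) {
    return(tibble(start = integer(0), length_codons = integer(0),
                  frame = integer(0), strand = character(0)))
  }
  distinct(list_rbind(res))
}

#' Characterize a repeat family from a clone set
#'
#' One-stop report: aligns the clones, calls the consensus and computes
#' divergence, GC, direct repeats and ORFs.
#'
#' @param clones a `clone_set`.
#' @param min_repeat_len minimum direct-repeat length.
#' @param min_orf_aa minimum ORF length in codons.
#' @return a `consensus_report` list: `family`, `source`, `n_clones`,
#'   `consensus`, `divergence_pct`, `gc_pct`, `direct_repeats` (tibble),
#'   `orfs` (tibble), `alignment`.
#' @export
characterize_clones <- function(clones, min_repeat_len = 8, min_orf_aa = 30) {
  aln <- align_clones(clones)
  consensus <- call_consensus(aln)
  out <- list(
    family = clones$family[1],
    source = clones$source[1],
    n_clones = nrow(clones),
    consensus = consensus,
    divergence_pct = round_half_up(pairwise_divergence(aln), 1),
    gc_pct = gc_content(consensus),
    direct_repeats = find_direct_repeats(consensus, min_repeat_len),
    orfs = find_orfs(consensus, min_orf_aa),
    alignment = aln
  )
  class(out) <- "consensus_report"
  out
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf(
    "%s (%s): %d clones, unit %d bp, divergence %.1f%%, GC %.1f%%, %d direct-repeat pair(s), %d ORF(s)\n",
    x$family, x$source, x$n_clones, nchar(x$consensus), x$divergence_pct,
    x$gc_pct, nrow(x$direct_repeats), nrow(x$orfs)))
  invisible(x)
}

#' @rdname characterize_clones
#' @param x a `consensus_report`.
#' @param ... unused.
#' @export
tidy.consensus_report <- function(x, ...) {
  tibble(
    family = x$family, source = x$source, n_clones = x$n_clones,
    unit_length = nchar(x$consensus),
    divergence_pct = x$divergence_pct, gc_pct = x$gc_pct,
    n_direct_repeat_pairs = nrow(x$direct_repeats),
    n_orfs = nrow(x$orfs), consensus = x$consensus
  )
}
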