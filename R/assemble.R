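utils::globalVariables(".")

dna_alphabet <- c("A", "C", "G", "T")

canonical_kmer <- function(x) pmin(x, revcomp(x))

#' Assemble enriched k-mers into repeat contigs
#'
#' Greedy unique-extension unitigging over the (k-1)-overlap graph of the
#' enriched canonical k-mer set. Extension proceeds while the current
#' k-mer has exactly one member successor and that successor has exactly one
#' member predecessor; it stops at branches and dead ends. A unitig whose
#' end re-enters its own start via a (k-1)-overlap is marked circular — the
#' expected shape for a tandem-repeat monomer, whose k-mers form a simple
#' cycle. Re-entry is detected either directly (the walk returns to its
#' starting k-mer) or, when junction k-mers at array boundaries cut the
#' cycle, by checking that every wraparound k-mer of the unitig's own
#' circularisation is a member of the enriched set. Each member
#' k-mer is assigned to at most one contig. The method is built for tandem
#' satellites; it does no bubble popping or tip clipping and is not a
#' general-purpose assembler.
#'
#' @param enriched an `enriched_kmers` tibble (or tibble with `kmer` and
#'   optionally `germ_count` columns, plus a `k` attribute).
#' @return tibble of contigs: `contig`, `sequence`, `circular`, `length`,
#'   `n_kmers`, `mean_kmer_count`, `member_kmers` (list column).
#' @export
assemble_enriched <- function(enriched) {
  k <- attr(enriched, "k")
  members <- enriched$kmer
  if (length(members) == 0) {
    return(tibble(contig = character(0), sequence = character(0),
                  circular = logical(0), length = integer(0),
                  n_kmers = integer(0), mean_kmer_count = numeric(0),
                  member_kmers = list()))
  }
  counts <- if ("germ_count" %in% names(enriched)) {
    stats::setNames(enriched$germ_count, members)
  } else {
    stats::setNames(rep(NA_real_, length(members)), members)
  }
  member_env <- new.env(parent = emptyenv())
  for (m in members) assign(m, TRUE, envir = member_env)
  is_member <- function(x) {
    vapply(x, function(v) exists(v, envir = member_env, inherits = FALSE),
           logical(1), USE.NAMES = FALSE)
  }

  successors <- function(w) {
    cand <- paste0(substr(w, 2, k), dna_alphabet)
    cand[is_member(canonical_kmer(cand))]
  }
  predecessors <- function(w) {
    cand <- paste0(dna_alphabet, substr(w, 1, k - 1))
    cand[is_member(canonical_kmer(cand))]
  }

  used <- new.env(parent = emptyenv())
  contigs <- list()

  walk_right <- function(start) {
    path <- start
    in_path <- new.env(parent = emptyenv())
    assign(canonical_kmer(start), TRUE, envir = in_path)
    circular <- FALSE
    w <- start
    repeat {
      succ <- successors(w)
      if (length(succ) != 1) break
      v <- succ
      if (length(predecessors(v)) != 1) break
      if (v == start) { circular <- TRUE; break }
      vc <- canonical_kmer(v)
      if (exists(vc, envir = in_path, inherits = FALSE)) break
      if (exists(vc, envir = used, inherits = FALSE)) break
      path <- c(path, v)
      assign(vc, TRUE, envir = in_path)
      w <- v
    }
    list(path = path, circular = circular)
  }

  for (m in members) {
    if (exists(m, envir = used, inherits = FALSE)) next
    right <- walk_right(m)
    path <- right$path
    circular <- right$circular
    if (!circular) {
      # extend leftwards by walking right from the reverse complement
      left <- walk_right(revcomp(m))
      if (length(left$path) > 1) {
        ext <- rev(vapply(left$path[-1], revcomp, character(1)))
        # guard against re-using k-mers already on the right-hand path
        ext_c <- vapply(ext, canonical_kmer, character(1))
        keep <- !ext_c %in% vapply(path, canonical_kmer, character(1))
        path <- c(ext[keep], path)
      }
    }
    # Array-junction k-mers cut a monomer cycle at two nodes (the branch
    # out of the unit's last base and the branch into its first), so no
    # single unique-extension walk can traverse the whole cycle. A walk
    # between the cuts still spells the cycle, possibly with a few bases
    # duplicated at both ends. Detect re-entry by trying each end overlap
    # d = k-1 .. 0: the unitig closes into a cycle of length n-d when its
    # d-base prefix equals its suffix and every k-mer spanning the joint of
    # that cycle is a member. d = k-1 is the fully traversed cycle; smaller
    # d covers cycles whose wraparound nodes were claimed by the cuts.
    cycle_seq <- NULL
    if (!circular && length(path) > 1) {
      lin <- paste0(path[1], paste(substr(path[-1], k, k), collapse = ""))
      n_lin <- nchar(lin)
      for (d in (k - 1):0) {
        c_len <- n_lin - d
        if (c_len < 2 * (k - 1)) next
        if (d > 0 &&
            substr(lin, 1, d) != substr(lin, n_lin - d + 1, n_lin)) next
        if (d < k - 1) {
          circ_seq <- paste0(substr(lin, 1, c_len), substr(lin, 1, k - 1))
          joint <- substring(circ_seq, (c_len - k + 2):c_len,
                             (c_len - k + 2):c_len + k - 1)
          if (!all(is_member(canonical_kmer(joint)))) next
        }
        circular <- TRUE
        cycle_seq <- substr(lin, 1, c_len)
        break
      }
    }
    canon <- vapply(path, canonical_kmer, character(1))
    for (x in canon) assign(x, TRUE, envir = used)
    spelled <- paste0(path[1],
                      paste(substr(path[-1], k, k), collapse = ""))
    if (circular) {
      spelled <- if (!is.null(cycle_seq)) cycle_seq else
        substr(spelled, 1, length(path))
    }
    contigs[[length(contigs) + 1]] <- tibble(
      sequence = spelled,
      circular = circular,
      length = nchar(spelled),
      n_kmers = length(path),
      mean_kmer_count = mean(counts[canon]),
      member_kmers = list(canon)
    )
  }
  out <- list_rbind(contigs)
  out <- out[order(-out$length), , drop = FALSE]
  out$contig <- sprintf("contig_%03d", seq_len(nrow(out)))
  out[, c("contig", "sequence", "circular", "length", "n_kmers",
          "mean_kmer_count", "member_kmers")]
}

#' Infer the tandem monomer of a repeat contig
#'
#' For a circular contig the unit length is the smallest rotation period of
#' the circular sequence; for a linear contig the smallest period is accepted
#' only if the contig spans at least two full units. The reported monomer is
#' strand- and rotation-canonical (lexicographically minimal rotation over
#' both strands), so calls are invariant to input rotation and to
#' reverse-complementing the reads.
#'
#' @param contig one contig row from [assemble_enriched()], or a list/tibble
#'   with `sequence` and `circular`.
#' @return one-row tibble: `unit_length`, `canonical_monomer`, `no_call`
#'   (TRUE when a linear contig shows no repetition).
#' @export
infer_monomer <- function(contig) {
  s <- contig$sequence[[1]]
  circular <- isTRUE(contig$circular[[1]])
  if (circular) {
    p <- circular_period(s)
  } else {
    p <- smallest_period(s)
    if (nchar(s) < 2 * p) {
      return(tibble(unit_length = NA_integer_,
                    canonical_monomer = NA_character_, no_call = TRUE))
    }
  }
  monomer <- substr(s, 1, p)
  tibble(unit_length = as.integer(p),
         canonical_monomer = canonical_monomer(monomer),
         no_call = FALSE)
}

#' Estimate tandem copy number from k-mer depth
#'
#' Median germline count of the monomer's k-mers divided by the effective
#' k-mer coverage: a k-mer occurring once per repeat unit is seen by the
#' reads that fully contain it, `copies x coverage x (R - k + 1) / R` times
#' in expectation for read length `R`. When `read_length` is omitted the
#' edge factor is skipped and the estimate is biased low by `(R - k + 1)/R`.
#'
#' @param monomer monomer DNA string (treated as circular).
#' @param enriched an `enriched_kmers` (or `kmer_tab`) tibble to look counts
#'   up in; k-mers absent from the table count 0.
#' @param per_base_coverage germline fold coverage (> 0).
#' @param read_length read length used for the edge correction (optional).
#' @return numeric copy-number estimate.
#' @export
estimate_copy_number <- function(monomer, enriched, per_base_coverage,
                                 read_length = NULL) {
  if (per_base_coverage <= 0) {
    abort("invalid-parameter: per_base_coverage must be > 0")
  }
  k <- attr(enriched, "k")
  if (!is.null(read_length)) {
    if (read_length <= k) abort("invalid-parameter: read_length must exceed k")
    per_base_coverage <- per_base_coverage * (read_length - k + 1) / read_length
  }
  circ <- paste0(monomer, substr(monomer, 1, k - 1))
  kmers <- unique(canonical_kmer(
    substring(circ, seq_len(nchar(monomer)), seq_len(nchar(monomer)) + k - 1)
  ))
  count_col <- if ("germ_count" %in% names(enriched)) "germ_count" else "count"
  counts <- enriched[[count_col]][match(kmers, enriched$kmer)]
  counts[is.na(counts)] <- 0
  stats::median(counts) / per_base_coverage
}

#' Write contigs as FASTA
#'
#' Headers carry the circular flag and mean k-mer count.
#'
#' @param contigs contig tibble from [assemble_enriched()].
#' @param path output path.
#' @export
write_contigs_fasta <- function(contigs, path) {
  seqs <- Biostrings::DNAStringSet(contigs$sequence)
  names(seqs) <- sprintf("%s circular=%d mean_count=%.1f",
                         contigs$contig, as.integer(contigs$circular),
                         contigs$mean_kmer_count)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
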