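#' Count canonical k-mers in a read set
#'
#' Counts every length-`k` substring of every read under canonical form (the
#' lexicographically smaller of a k-mer and its reverse complement), so a
#' read and its reverse complement give identical tables. k-mers containing
#' non-ACGT characters are skipped. Odd `k` avoids self-reverse-complement
#' k-mers.
#'
#' @param reads a `read_set`, or a character vector of sequences.
#' @param k odd integer, 11 <= k <= 31.
#' @return a `kmer_tab` tibble with columns `kmer`, `count` (sorted by
#'   k-mer) and attributes `k` and `total_kmers`.
#' @export
#' @examples
#' count_kmers(c("ACGTACGT"), k = 11)  # too short: empty table
count_kmers <- function(reads, k = 21) {
  if (k %% 2 == 0) abort("invalid-parameter: k must be odd")
  if (k < 11 || k > 31) abort("invalid-parameter: k must be in [11, 31]")
  seqs <- if (inherits(reads, "read_set")) reads$reads$sequence else reads
  if (length(seqs) == 0) abort("reads must be non-empty")
  res <- .count_kmers_cpp(seqs, as.integer(k))
  out <- tibble(kmer = res$kmer, count = res$count)
  attr(out, "k") <- as.integer(k)
  attr(out, "total_kmers") <- res$total
  class(out) <- c("kmer_tab", class(out))
  out
}

#' @export
print.kmer_tab <- function(x, ...) {
  cat(sprintf("kmer_tab: %d distinct canonical %d-mers, %.0f total\n",
              nrow(x), attr(x, "k"), attr(x, "total_kmers")))
  NextMethod()
}

#' Filter k-mers enriched in the germline over the soma
#'
#' The discovery criterion for germline-restricted repeats: keep canonical
#' k-mers whose germline frequency is at least `ratio_threshold` times the
#' somatic frequency. Somatic counts are scaled to the germline table total
#' before the ratio, and a pseudocount on the somatic side keeps the ratio
#' finite:
#' `ratio = germ_count / (soma_count * germ_total / soma_total + pseudocount)`.
#' A raw germline count floor suppresses sequencing-error k-mers.
#'
#' @param germ,soma `kmer_tab` tables with equal `k`.
#' @param ratio_threshold minimum germline/somatic frequency ratio
#'   (default 100).
#' @param min_germline_count minimum raw germline count (default 10).
#' @param pseudocount added to the scaled somatic count (default 1).
#' @return an `enriched_kmers` tibble: `kmer`, `germ_count`, `soma_count`,
#'   `ratio`, with the filter parameters as attributes.
#' @export
enrichment_filter <- function(germ, soma, ratio_threshold = 100,
                              min_germline_count = 10, pseudocount = 1) {
  if (!identical(attr(germ, "k"), attr(soma, "k"))) {
    abort("invalid-input: k-mer tables have different k")
  }
  scale <- attr(germ, "total_kmers") / attr(soma, "total_kmers")
  g <- tibble(kmer = germ$kmer, germ_count = germ$count)
  s <- tibble(kmer = soma$kmer, soma_count = soma$count)
  out <- g |>
    left_join(s, by = "kmer") |>
    mutate(
      soma_count = dplyr::coalesce(.data$soma_count, 0),
      ratio = .data$germ_count / (.data$soma_count * scale + pseudocount)
    ) |>
    filter(.data$ratio >= ratio_threshold,
           .data$germ_count >= min_germline_count) |>
    arrange(.data$kmer)
  attr(out, "k") <- attr(germ, "k")
  attr(out, "ratio_threshold") <- ratio_threshold
  attr(out, "min_germline_count") <- min_germline_count
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("enriched_kmers", class(out))
  out
}

#' @export
print.enriched_kmers <- function(x, ...) {
  cat(sprintf(
    "enriched_kmers: %d canonical %d-mers (ratio >= %g, germ count >= %g)\n",
    nrow(x), attr(x, "k"), attr(x, "ratio_threshold"),
    attr(x, "min_germline_count")))
  NextMethod()
}

#' Write enriched k-mers as TSV
#' @param enriched an `enriched_kmers` tibble.
#' @param path output path.
#' @export
write_enriched_tsv <- function(enriched, path) {
  readr::write_tsv(enriched, path, progress = FALSE)
  invisible(path)
}
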