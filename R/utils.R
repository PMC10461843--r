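#' Round half up to a fixed number of decimals
#'
#' Percentages in reports are rounded half up (so 0.15 -> 0.2 at one decimal),
#' unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half up.
#' @export
#' @examples
#' round_half_up(2.25, 1)  # 2.3
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of A/C/G/T strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence with an exact G+C count
#'
#' Draws a uniform random arrangement of `n_gc` G/C bases (each G or C with
#' equal probability) and `length - n_gc` A/T bases.
#'
#' @param length sequence length in bp.
#' @param n_gc exact number of G+C bases.
#' @return a single DNA string.
#' @keywords internal
random_dna <- function(length, n_gc) {
  stopifnot(n_gc >= 0, n_gc <= length)
  is_gc <- rep(FALSE, length)
  is_gc[sample.int(length, n_gc)] <- TRUE
  bases <- character(length)
  bases[is_gc] <- sample(c("G", "C"), n_gc, replace = TRUE)
  bases[!is_gc] <- sample(c("A", "T"), length - n_gc, replace = TRUE)
  paste(bases, collapse = "")
}

#' Uniform random DNA
#' @param length sequence length in bp.
#' @return a single DNA string with each base uniform on A/C/G/T.
#' @keywords internal
random_dna_uniform <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

assert_dna <- function(x, what = "sequence") {
  if (length(x) != 1 || is.na(x) || !nzchar(x) ||
      grepl("[^ACGT]", x)) {
    abort(sprintf("%s must be a non-empty A/C/G/T string", what))
  }
  invisible(x)
}

#' Smallest period of a string
#'
#' The smallest `p` such that `s[i] == s[i + p]` for all valid `i`
#' (Knuth-Morris-Pratt border analysis). For a tandem monomer repeated in a
#' string this is the unit length.
#'
#' @param s a single string.
#' @return integer smallest period.
#' @export
#' @examples
#' smallest_period("ACGACGACG")  # 3
smallest_period <- function(s) {
  ch <- strsplit(s, NULL)[[1]]
  n <- length(ch)
  fail <- integer(n)
  k <- 0L
  for (i in seq_len(n)[-1]) {
    while (k > 0L && ch[k + 1L] != ch[i]) k <- fail[k]
    if (ch[k + 1L] == ch[i]) k <- k + 1L
    fail[i] <- k
  }
  n - fail[n]
}

# Smallest rotation period: smallest divisor d of nchar(s) such that s is the
# d-prefix repeated. This is the unit length of a circular sequence.
circular_period <- function(s) {
  n <- nchar(s)
  for (d in seq_len(n)) {
    if (n %% d != 0L) next
    unit <- substr(s, 1L, d)
    if (strrep(unit, n %/% d) == s) return(d)
  }
  n
}

#' Lexicographically minimal rotation of a string
#'
#' Used to put tandem-repeat monomers into a canonical rotation so calls are
#' comparable across runs. Monomers are short (tens to hundreds of bp), so
#' the minimum is taken directly over all rotations.
#'
#' @param s a character vector; each element is rotated independently.
#' @return the minimal rotation of each element of `s`.
#' @export
#' @examples
#' minimal_rotation("GTAC")  # "ACGT"
minimal_rotation <- function(s) {
  vapply(s, function(x) {
    n <- nchar(x)
    if (n <= 1) return(x)
    doubled <- paste0(x, x)
    min(vapply(seq_len(n), function(i) substr(doubled, i, i + n - 1L),
               character(1)))
  }, character(1), USE.NAMES = FALSE)
}

#' Canonical monomer: minimal rotation over both strands
#'
#' @param s a character vector of DNA strings (monomers, treated as
#'   circular); each element is canonicalized independently.
#' @return per element, the lexicographically smaller of the minimal
#'   rotations of the sequence and its reverse complement.
#' @export
canonical_monomer <- function(s) {
  pmin(minimal_rotation(s), minimal_rotation(revcomp(s)))
}

# Derive a reproducible child seed from a master seed and a stage label.
# Keeps results independent across stages while everything flows from one
# seed; result is kept below 2^31.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.numeric(seed) * 10007 + h) %% 2147483647
}

#' GC content of a DNA string (fraction)
#' @param x character vector of DNA strings.
#' @return numeric vector of G+C fractions.
#' @keywords internal
gc_fraction <- function(x) {
  vapply(x, function(s) {
    n <- nchar(s)
    gc <- nchar(gsub("[^GCgc]", "", s))
    gc / n
  }, numeric(1), USE.NAMES = FALSE)
}
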