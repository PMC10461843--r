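#' Build a germline genome with planted tandem-repeat arrays
#'
#' Constructs the diploid germline karyotype: E-chromosomes carry the tandem
#' arrays of `placement`; somatically retained chromosomes are random
#' background. Families flagged `dispersed` additionally receive low-density
#' single-copy insertions on *all* chromosomes (Poisson number, one expected
#' copy per `dispersed_spacing` bp), emulating a repeat shared between
#' E-chromosomes and the retained complement. The full placement, including
#' those insertions, is retained as ground truth.
#'
#' @param config a [karyotype_config()].
#' @param families family panel tibble.
#' @param placement array placement tibble (see [default_placement()]);
#'   0-based half-open coordinates on E-chromosomes.
#' @param seed integer seed.
#' @param dispersed_spacing expected bp between dispersed single-copy
#'   insertions (default one per 10 kb).
#' @return a `genome` object: list with `chromosomes` tibble (`id`,
#'   `pair_id`, `is_eliminated`, `length`, `sequence`), `placement`,
#'   `config`, `families`.
#' @export
build_germline_genome <- function(config = karyotype_config(),
                                  families = default_families(),
                                  placement = default_placement(config,
                                                                families),
                                  seed = 1,
                                  dispersed_spacing = 10000) {
  set.seed(child_seed(seed, "genome"))
  unknown <- setdiff(placement$family, families$name)
  if (length(unknown) > 0) {
    abort(paste("invalid-placement: unknown families:",
                paste(unknown, collapse = ", ")))
  }
  validate_placement(placement)

  e_pairs <- sort(unique(placement$pair_id))
  n_e <- config$e_chromosome_count
  if (length(e_pairs) * 2 != n_e) {
    abort("placement must cover every E-chromosome pair")
  }
  n_ret_pairs <- config$somatic_2n / 2
  chrom <- bind_rows(
    tibble(
      id = paste0(rep(e_pairs, each = 2), c("a", "b")),
      pair_id = rep(e_pairs, each = 2),
      is_eliminated = TRUE,
      length = config$e_length
    ),
    tibble(
      id = paste0(rep(sprintf("S%02d", seq_len(n_ret_pairs)), each = 2),
                  c("a", "b")),
      pair_id = rep(sprintf("S%02d", seq_len(n_ret_pairs)), each = 2),
      is_eliminated = FALSE,
      length = config$retained_length
    )
  )

  # dispersed single-copy insertions on every chromosome, avoiding the
  # designed arrays
  disp_fams <- families[families$dispersed, , drop = FALSE]
  disp_rows <- NULL
  if (nrow(disp_fams) > 0 && dispersed_spacing > 0) {
    disp_rows <- purrr::pmap(chrom, function(id, pair_id, is_eliminated,
                                             length) {
      taken <- placement[placement$chromosome_id == id,
                         c("start", "end"), drop = FALSE]
      rows <- purrr::pmap(disp_fams[, c("name", "unit_length")],
                          function(name, unit_length) {
        n_ins <- rpois(1, length / dispersed_spacing)
        if (n_ins == 0) return(NULL)
        starts <- integer(0)
        tries <- 0
        while (length(starts) < n_ins && tries < 200) {
          cand <- sample.int(length - unit_length, 1) - 1L
          clash <- any(cand < taken$end & cand + unit_length > taken$start)
          if (!clash) {
            starts <- c(starts, cand)
            taken <<- bind_rows(taken,
                                tibble(start = cand,
                                       end = cand + unit_length))
          }
          tries <- tries + 1
        }
        if (length(starts) == 0) return(NULL)
        tibble(
          chromosome_id = id, pair_id = pair_id, family = name,
          start = as.integer(starts),
          end = as.integer(starts + unit_length), copies = 1L,
          orientation = sample(c("+", "-"), length(starts), replace = TRUE),
          kind = "dispersed", pattern = NA_integer_
        )
      })
      list_rbind(purrr::compact(rows))
    }) |> purrr::compact() |> list_rbind()
  }
  full_placement <- bind_rows(placement, disp_rows) |>
    arrange(.data$chromosome_id, .data$start)
  # dispersed single-copy insertions are random per chromosome and need not
  # land on both homologs of a pair, so only interval validity is re-checked
  validate_placement(full_placement, check_pairs = FALSE)

  monomers <- stats::setNames(families$monomer, families$name)
  chrom$sequence <- purrr::pmap_chr(chrom, function(id, pair_id,
                                                    is_eliminated, length) {
    rows <- full_placement[full_placement$chromosome_id == id, ,
                           drop = FALSE]
    assemble_chromosome(length, rows, monomers)
  })

  structure(
    list(chromosomes = as_tibble(chrom), placement = full_placement,
         config = config, families = families, seed = seed),
    class = "genome"
  )
}

# Splice tandem arrays into a random background sequence. `rows` are sorted,
# non-overlapping 0-based half-open intervals.
assemble_chromosome <- function(length, rows, monomers) {
  if (nrow(rows) == 0) return(random_dna_uniform(length))
  pieces <- character(2 * nrow(rows) + 1)
  pos <- 0L
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    if (r$start > pos) {
      pieces[2 * i - 1] <- random_dna_uniform(r$start - pos)
    }
    arr <- strrep(monomers[[r$family]], r$copies)
    if (r$orientation == "-") arr <- revcomp(arr)
    stopifnot(nchar(arr) == r$end - r$start)
    pieces[2 * i] <- arr
    pos <- r$end
  }
  if (pos < length) pieces[2 * nrow(rows) + 1] <- random_dna_uniform(length - pos)
  paste(pieces, collapse = "")
}

#' Derive the somatic genome by dropping eliminated chromosomes
#'
#' The somatic genome is the germline genome minus its E-chromosomes;
#' retained chromosomes are byte-identical. Idempotent: applying it to a
#' genome without eliminated chromosomes returns an unchanged copy.
#'
#' @param germline a `genome`.
#' @return a `genome` with only non-eliminated chromosomes.
#' @export
derive_somatic_genome <- function(germline) {
  stopifnot(inherits(germline, "genome"))
  keep <- !germline$chromosomes$is_eliminated
  out <- germline
  out$chromosomes <- germline$chromosomes[keep, , drop = FALSE]
  out$placement <- germline$placement[
    germline$placement$chromosome_id %in% out$chromosomes$id, , drop = FALSE]
  out
}

#' @export
print.genome <- function(x, ...) {
  n_e <- sum(x$chromosomes$is_eliminated)
  cat(sprintf("genome: %d chromosomes (%d eliminated), %.2f Mb total\n",
              nrow(x$chromosomes), n_e,
              sum(x$chromosomes$length) / 1e6))
  invisible(x)
}

#' Total genome size in bp
#' @param genome a `genome`.
#' @return integer total length.
#' @export
genome_size <- function(genome) sum(genome$chromosomes$length)

#' Write a genome to FASTA
#'
#' One record per chromosome; the header encodes the pair and elimination
#' flag (`<id> pair=<pair> eliminated=<0/1>`).
#'
#' @param genome a `genome`.
#' @param path output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- Biostrings::DNAStringSet(genome$chromosomes$sequence)
  names(seqs) <- sprintf("%s pair=%s eliminated=%d",
                         genome$chromosomes$id,
                         genome$chromosomes$pair_id,
                         as.integer(genome$chromosomes$is_eliminated))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a placement map as BED-like TSV
#'
#' 0-based half-open, columns chrom/start/end/family/copies/strand.
#'
#' @param placement placement tibble.
#' @param path output path.
#' @export
write_placement_bed <- function(placement, path) {
  readr::write_tsv(
    placement[, c("chromosome_id", "start", "end", "family", "copies",
                  "orientation")],
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Simulate shotgun reads from a genome
#'
#' Uniform start positions on both strands, fixed read length, independent
#' per-base substitution errors. The number of reads is
#' `round(coverage * genome size / read_length)`, so total bases match the
#' requested coverage to within one read.
#'
#' @param genome a `genome`.
#' @param coverage fold coverage (> 0).
#' @param read_length read length in bp (must not exceed the shortest
#'   chromosome).
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return a `read_set`: list with `reads` tibble (`id`, `sequence`,
#'   `quality`) and the simulation parameters.
#' @export
simulate_reads <- function(genome, coverage, read_length = 100,
                           error_rate = 0, seed = 1) {
  if (coverage <= 0) abort("invalid-parameter: coverage must be > 0")
  if (read_length > min(genome$chromosomes$length)) {
    abort("invalid-parameter: read_length exceeds shortest chromosome")
  }
  set.seed(child_seed(seed, "reads"))
  total <- genome_size(genome)
  n_reads <- round(coverage * total / read_length)
  # apportion reads to chromosomes by length (largest-remainder rounding)
  share <- n_reads * genome$chromosomes$length / total
  n_i <- floor(share)
  rem <- n_reads - sum(n_i)
  if (rem > 0) {
    extra <- order(share - n_i, decreasing = TRUE)[seq_len(rem)]
    n_i[extra] <- n_i[extra] + 1
  }

  seqs <- purrr::map(seq_len(nrow(genome$chromosomes)), function(i) {
    n <- n_i[i]
    if (n == 0) return(character(0))
    L <- genome$chromosomes$length[i]
    starts <- sample.int(L - read_length + 1L, n, replace = TRUE)
    reads <- substring(genome$chromosomes$sequence[i], starts,
                       starts + read_length - 1L)
    minus <- runif(n) < 0.5
    if (any(minus)) reads[minus] <- revcomp(reads[minus])
    reads
  })
  reads <- unlist(seqs)

  if (error_rate > 0) {
    n_err <- rbinom(length(reads), read_length, error_rate)
    idx <- which(n_err > 0)
    for (i in idx) {
      pos <- sample.int(read_length, n_err[i])
      ch <- strsplit(reads[i], NULL)[[1]]
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      reads[i] <- paste(ch, collapse = "")
    }
  }

  out <- list(
    reads = tibble(
      id = sprintf("read_%07d", seq_along(reads)),
      sequence = reads,
      quality = strrep("I", read_length)
    ),
    read_length = read_length, coverage = coverage,
    error_rate = error_rate, seed = seed
  )
  class(out) <- "read_set"
  out
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads x %d bp (%.1fx requested, error %.3g)\n",
              nrow(x$reads), x$read_length, x$coverage, x$error_rate))
  invisible(x)
}

#' Write reads as FASTQ (Sanger qualities)
#' @param read_set a `read_set`.
#' @param path output FASTQ path.
#' @export
write_fastq <- function(read_set, path) {
  seqs <- Biostrings::DNAStringSet(read_set$reads$sequence)
  names(seqs) <- read_set$reads$id
  qual <- Biostrings::BStringSet(read_set$reads$quality)
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a read_set
#' @param path FASTQ path.
#' @return a `read_set`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  out <- list(
    reads = tibble(
      id = names(x) %||% sprintf("read_%07d", seq_along(x)),
      sequence = unname(as.character(x)),
      quality = unname(as.character(S4Vectors::mcols(x)$qualities))
    ),
    read_length = if (length(x)) max(Biostrings::width(x)) else 0L,
    coverage = NA_real_, error_rate = NA_real_, seed = NA_integer_
  )
  class(out) <- "read_set"
  out
}
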