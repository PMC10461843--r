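#' Generate a random tandem-repeat monomer family
#'
#' Draws a random monomer of exactly `unit_length` bp whose realized G+C count
#' is `round(target_gc * unit_length)` (so realized GC is within 0.5/unit of
#' the target). The monomer is guaranteed primitive (its smallest period is
#' its full length), i.e. it is not itself a tandem repeat of a shorter word.
#'
#' Fixed subsequences can be spliced in with `embed` (used e.g. to plant
#' primer-binding sites); the G+C budget of the free positions is adjusted so
#' the whole monomer still meets the target where feasible.
#'
#' @param name family label.
#' @param unit_length monomer length in bp (>= 10).
#' @param target_gc target G+C fraction in `[0, 1]`.
#' @param seed integer seed; same arguments and seed give the same monomer.
#' @param embed optional named list of DNA strings; names are 1-based start
#'   positions at which each string is placed verbatim.
#' @return a one-row tibble with columns `name`, `monomer`, `unit_length`,
#'   `target_gc` and realized `gc`.
#' @export
#' @examples
#' make_repeat_family("fam38", 47, 0.39, seed = 1)
make_repeat_family <- function(name, unit_length, target_gc, seed = NULL,
                               embed = NULL) {
  if (!is.numeric(unit_length) || unit_length < 10) {
    abort("unit_length must be >= 10")
  }
  if (target_gc < 0 || target_gc > 1) abort("target_gc must be in [0, 1]")
  unit_length <- as.integer(unit_length)
  if (!is.null(seed)) set.seed(seed)

  fixed <- rep(NA_character_, unit_length)
  if (!is.null(embed)) {
    for (pos in names(embed)) {
      s <- embed[[pos]]
      assert_dna(s, "embedded segment")
      at <- as.integer(pos)
      if (at < 1 || at + nchar(s) - 1L > unit_length) {
        abort("embedded segment outside monomer bounds")
      }
      fixed[at:(at + nchar(s) - 1L)] <- strsplit(s, NULL)[[1]]
    }
  }
  n_free <- sum(is.na(fixed))
  gc_fixed <- sum(fixed %in% c("G", "C"))
  n_gc_total <- round(target_gc * unit_length)
  n_gc_free <- min(max(n_gc_total - gc_fixed, 0L), n_free)

  repeat {
    bases <- fixed
    if (n_free > 0) {
      free_seq <- strsplit(random_dna(n_free, n_gc_free), NULL)[[1]]
      bases[is.na(fixed)] <- free_seq
    }
    monomer <- paste(bases, collapse = "")
    # primitive = not an exact tandem of a shorter word (divisor periods only;
    # a mere shared prefix/suffix border is fine)
    if (circular_period(monomer) == unit_length) break
  }

  tibble(
    name = name,
    monomer = monomer,
    unit_length = unit_length,
    target_gc = target_gc,
    gc = gc_fraction(monomer)
  )
}

#' Apply a fixed number of substitutions to a monomer
#'
#' Each substituted site is changed to a uniformly random different base.
#' Positions listed in `protect` (e.g. primer-binding sites) are never
#' touched.
#'
#' @param monomer DNA string.
#' @param n_subs number of substituted sites.
#' @param protect optional integer vector of 1-based protected positions.
#' @return the mutated monomer.
#' @export
mutate_monomer <- function(monomer, n_subs, protect = integer()) {
  ch <- strsplit(monomer, NULL)[[1]]
  candidates <- setdiff(seq_along(ch), protect)
  if (n_subs > length(candidates)) abort("more substitutions than free sites")
  pos <- sample(candidates, n_subs)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

#' Packaged PCR primer pairs
#'
#' The four primer pairs used for the novel repeat families (forward and
#' reverse written 5'->3'), shipped as a plain-text fixture, with the unit
#' length of the family each pair amplifies.
#'
#' @return tibble with columns `name`, `forward`, `reverse`, `unit_length`.
#' @export
default_primer_pairs <- function() {
  path <- system.file("extdata", "primers.tsv", package = "elimrep")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Default repeat-family panel
#'
#' Builds the ten-family panel the simulator plants on eliminated (E-)
#' chromosomes, emulating the EEEb1-EEEb10 satellite families of the Japanese
#' hagfish germline genome. The four families characterized by cloning carry
#' their reported unit lengths (360, 47, 84 and 120 bp for EEEb7/8/9/10, the
#' "family 0/38/10/5" clones) and GC targets; each of the four embeds its
#' primer-binding sites (forward at the unit start, reverse flush with the
#' unit end) so in-silico PCR reproduces the monomer/dimer ladder in exact
#' unit multiples; EEEb10 is flagged dispersed (present at low density
#' on somatically retained chromosomes as well). Unit lengths for EEEb1-6 are
#' not reported and use typical satellite values. All monomers are synthetic
#' sequences, not the deposited clones.
#'
#' Somatic-variant monomers (`somatic_monomer`) differ from the germline
#' monomer by the reported consensus substitution counts: 3 for the EEEb7
#' analogue, 5 for EEEb9, 0 for EEEb8 and EEEb10 (other families reuse the
#' germline monomer).
#'
#' @param seed integer seed.
#' @return tibble with one row per family: `name`, `monomer`,
#'   `somatic_monomer`, `unit_length`, `target_gc`, `gc`, `dispersed`,
#'   `is_reference`, `clone_n_germ`, `clone_n_soma`, `clone_rate_germ`,
#'   `clone_rate_soma`, `planted_substitutions`.
#' @export
default_families <- function(seed = 1) {
  set.seed(child_seed(seed, "families"))
  primers <- default_primer_pairs()
  primer_map <- c(EEEb7 = "family0", EEEb8 = "family38",
                  EEEb9 = "family10", EEEb10 = "family5")

  spec <- tibble(
    name = paste0("EEEb", 1:10),
    unit_length = c(180L, 150L, 210L, 90L, 300L, 60L, 360L, 47L, 84L, 120L),
    target_gc = c(0.35, 0.38, 0.33, 0.41, 0.36, 0.40, 0.408, 0.392, 0.393,
                  0.298),
    dispersed = c(rep(FALSE, 9), TRUE),
    is_reference = c(TRUE, rep(FALSE, 9))
  )

  fams <- purrr::pmap(spec, function(name, unit_length, target_gc, dispersed,
                                     is_reference) {
    embed <- NULL
    if (name %in% names(primer_map)) {
      # forward site at the unit start, reverse site flush with the unit end:
      # amplicons then come in exact unit-length multiples (monomer, dimer, ...)
      p <- primers[primers$name == primer_map[[name]], ]
      rc <- revcomp(p$reverse)
      embed <- stats::setNames(
        list(p$forward, rc),
        c("1", as.character(unit_length - nchar(rc) + 1L))
      )
    }
    fam <- make_repeat_family(name, unit_length, target_gc, embed = embed)
    fam$dispersed <- dispersed
    fam$is_reference <- is_reference
    fam
  }) |>
    list_rbind()

  # germline vs somatic consensus substitutions reported for the cloned
  # families: 3 (family 0 / EEEb7), 0 (family 38 / EEEb8), 5 (family 10 /
  # EEEb9), 0 (family 5 / EEEb10)
  fams$planted_substitutions <- c(rep(0L, 6), 3L, 0L, 5L, 0L)
  # substitutions never fall on primer-binding sites, so in-silico PCR works
  # on germline and somatic templates alike
  protect_sites <- function(i) {
    p <- primers[primers$name == primer_map[[fams$name[i]]], ]
    L <- fams$unit_length[i]
    c(seq_len(nchar(p$forward)), (L - nchar(p$reverse) + 1L):L)
  }
  fams$somatic_monomer <- fams$monomer
  fams$somatic_monomer[7] <- mutate_monomer(fams$monomer[7], 3L,
                                            protect_sites(7))
  fams$somatic_monomer[9] <- mutate_monomer(fams$monomer[9], 5L,
                                            protect_sites(9))

  # clone-set sizes reported for the four cloned families; per-site clone
  # mutation rates chosen so intraspecific divergence is of the reported
  # magnitude (approx 2p for small p)
  fams$clone_n_germ <- c(rep(20L, 6), 16L, 40L, 34L, 12L)
  fams$clone_n_soma <- c(rep(20L, 6), 10L, 50L, 21L, 22L)
  fams$clone_rate_germ <- c(rep(0.02, 6), 0.023, 0.038, 0.100, 0.011)
  fams$clone_rate_soma <- c(rep(0.02, 6), 0.027, 0.036, 0.057, 0.002)
  fams
}

#' Sample cloned copies of a repeat monomer
#'
#' Emulates sequencing cloned PCR products of one repeat family: each clone
#' is the family monomer with independent per-site substitutions, each to a
#' uniformly random different base.
#'
#' @param family one-row family tibble (from [make_repeat_family()] or one
#'   row of [default_families()]).
#' @param source `"germline"` or `"somatic"`; with the default-family panel
#'   the somatic monomer carries the planted consensus substitutions.
#' @param n number of clones.
#' @param mutation_rate per-site substitution probability in `[0, 0.25)`.
#' @param seed integer seed.
#' @param indel_rate optional per-site indel probability (default 0). When
#'   positive, each indel site receives a deletion or insertion of geometric
#'   length (mean 1.5); modelling clones with occasional gaps.
#' @return a `clone_set`: tibble with columns `clone`, `family`, `source`,
#'   `sequence`, plus attributes `monomer` and `mutation_rate`.
#' @export
sample_clones <- function(family, source = c("germline", "somatic"), n,
                          mutation_rate, seed = NULL, indel_rate = 0) {
  source <- match.arg(source)
  if (mutation_rate < 0 || mutation_rate >= 0.25) {
    abort("mutation_rate must be in [0, 0.25)")
  }
  if (!is.null(seed)) set.seed(seed)
  monomer <- if (source == "somatic" && "somatic_monomer" %in% names(family)) {
    family$somatic_monomer[1]
  } else {
    family$monomer[1]
  }
  L <- nchar(monomer)
  base_chars <- strsplit(monomer, NULL)[[1]]
  seqs <- vapply(seq_len(n), function(i) {
    ch <- base_chars
    nmut <- rbinom(1, L, mutation_rate)
    if (nmut > 0) {
      pos <- sample.int(L, nmut)
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
    if (indel_rate > 0) {
      nind <- rbinom(1, L, indel_rate)
      if (nind > 0) {
        for (p in sort(sample.int(length(ch), nind), decreasing = TRUE)) {
          len <- 1L + stats::rgeom(1, 1 / 1.5)
          if (runif(1) < 0.5) {
            ch <- ch[-(p:min(p + len - 1L, length(ch)))]
          } else {
            ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
            ch <- append(ch, ins, after = p)
          }
        }
      }
    }
    paste(ch, collapse = "")
  }, character(1))

  out <- tibble(
    clone = sprintf("%s_%s_%02d", family$name[1],
                    if (source == "germline") "G" else "S", seq_len(n)),
    family = family$name[1],
    source = source,
    sequence = seqs
  )
  attr(out, "monomer") <- monomer
  attr(out, "mutation_rate") <- mutation_rate
  class(out) <- c("clone_set", class(out))
  out
}
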