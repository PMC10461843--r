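#' Karyotype configuration for a germline/somatic genome pair
#'
#' Describes a diploid karyotype in which a fixed set of chromosomes
#' (E-chromosomes) is present in germ cells but eliminated from somatic
#' cells: germline 2n = 52 and somatic 2n = 36 by default, i.e. 16
#' E-chromosomes. Chromosome lengths are scaled down to desk size; the
#' eliminated fraction implied by the lengths is reported, not enforced.
#'
#' @param germline_2n diploid chromosome number in germ cells (even).
#' @param somatic_2n diploid chromosome number in somatic cells (even).
#' @param e_length E-chromosome length in bp.
#' @param retained_length somatically retained chromosome length in bp.
#' @param eliminated_fraction_target nominal fraction of germline DNA
#'   eliminated (recorded in the manifest; approximately 21%).
#' @return a `karyotype_config` list.
#' @export
#' @examples
#' cfg <- karyotype_config()
#' cfg$e_chromosome_count  # 16
karyotype_config <- function(germline_2n = 52, somatic_2n = 36,
                             e_length = 50000, retained_length = 100000,
                             eliminated_fraction_target = 0.21) {
  if (germline_2n %% 2 != 0 || somatic_2n %% 2 != 0) {
    abort("diploid counts must be even")
  }
  if (germline_2n <= somatic_2n) {
    abort("germline_2n must exceed somatic_2n")
  }
  e_count <- germline_2n - somatic_2n
  structure(
    list(
      germline_2n = as.integer(germline_2n),
      somatic_2n = as.integer(somatic_2n),
      e_chromosome_count = as.integer(e_count),
      e_length = as.integer(e_length),
      retained_length = as.integer(retained_length),
      eliminated_fraction_target = eliminated_fraction_target,
      eliminated_fraction_realized =
        e_count * e_length /
          (e_count * e_length + somatic_2n * retained_length)
    ),
    class = "karyotype_config"
  )
}

#' @export
print.karyotype_config <- function(x, ...) {
  cat(sprintf(
    "karyotype: germline 2n=%d, somatic 2n=%d, %d E-chromosomes\n",
    x$germline_2n, x$somatic_2n, x$e_chromosome_count
  ))
  cat(sprintf(
    "lengths: E %d bp, retained %d bp (eliminated fraction %.1f%%, target %.0f%%)\n",
    x$e_length, x$retained_length, 100 * x$eliminated_fraction_realized,
    100 * x$eliminated_fraction_target
  ))
  invisible(x)
}

# One tiling block: `copies` tandem copies of `family`'s monomer.
blk <- function(family, copies) list(family = family, copies = copies)

# Block sequences defining the six karyogram pattern templates. Within the
# terminal (reference-positive) region, blocks of the reference family EEEb1
# alternate with blocks of the co-localizing families, emulating the
# interspersion seen on chromatin fibers; the adjacent region holds the
# families that map next to, rather than inside, the reference clusters.
# Share of each family's mass inside the reference region sets its
# co-localization class. Patterns differ from the base template in single,
# documented features; patterns 1 and 2 are each used by two chromosome
# pairs.
pattern_templates <- function() {
  e1 <- blk("EEEb1", 2)
  base_T <- list(
    e1, blk("EEEb8", 9), e1, blk("EEEb2", 3), e1, blk("EEEb4", 4), e1,
    blk("EEEb7", 1), e1, blk("EEEb7", 1), e1, blk("EEEb7", 1), e1,
    blk("EEEb7", 1), e1, blk("EEEb6", 5), e1, blk("EEEb9", 5), e1
  )
  base_A <- list(
    blk("EEEb2", 1), blk("EEEb3", 2), blk("EEEb5", 2), blk("EEEb9", 5),
    blk("EEEb10", 3), blk("EEEb4", 2), blk("EEEb3", 2), blk("EEEb6", 5),
    blk("EEEb5", 1), blk("EEEb7", 2), blk("EEEb3", 2), blk("EEEb5", 1),
    blk("EEEb10", 3)
  )
  drop_family <- function(blocks, fam) {
    purrr::keep(blocks, ~ .x$family != fam)
  }
  p3_T <- purrr::list_flatten(purrr::map(base_T, function(b) {
    if (b$family == "EEEb6") {
      list(blk("EEEb6", 7), e1, blk("EEEb6", 7), e1, blk("EEEb6", 7))
    } else {
      list(b)
    }
  }))
  p4_T <- purrr::list_flatten(purrr::map(base_T, function(b) {
    if (b$family == "EEEb9") list(b, e1, blk("EEEb9", 5)) else list(b)
  }))
  list(
    `1` = list(T = base_T, A = base_A, M = NULL, two_sided = TRUE),
    `2` = list(T = base_T, A = drop_family(base_A, "EEEb3"), M = NULL,
               two_sided = TRUE),
    `3` = list(T = p3_T, A = base_A, M = list(blk("EEEb6", 16)),
               two_sided = TRUE),
    `4` = list(T = p4_T, A = drop_family(base_A, "EEEb9"), M = NULL,
               two_sided = TRUE),
    `5` = list(T = drop_family(base_T, "EEEb2"),
               A = drop_family(base_A, "EEEb2"), M = NULL, two_sided = TRUE),
    `6` = list(T = base_T, A = base_A, M = NULL, two_sided = FALSE)
  )
}

# E-pair -> pattern assignment: patterns 1 and 2 each cover two pairs.
default_pattern_assignment <- function() {
  tibble(
    pair_id = paste0("E", 1:8),
    pattern = c(1L, 1L, 2L, 2L, 3L, 4L, 5L, 6L)
  )
}

place_blocks <- function(blocks, start, families, reverse = FALSE) {
  if (length(blocks) == 0) return(NULL)
  if (reverse) blocks <- rev(blocks)
  fam_len <- stats::setNames(families$unit_length, families$name)
  lens <- vapply(blocks, function(b) fam_len[[b$family]] * b$copies,
                 numeric(1))
  starts <- start + cumsum(c(0, head(lens, -1)))
  tibble(
    family = vapply(blocks, `[[`, character(1), "family"),
    start = as.integer(starts),
    end = as.integer(starts + lens),
    copies = vapply(blocks, function(b) as.integer(b$copies), integer(1))
  )
}

#' Default placement map: six-pattern layout over eight E-pairs
#'
#' Places tandem arrays of the family panel on the 16 E-chromosomes (8 pairs,
#' two identical homologs each) following six pattern templates; patterns 1
#' and 2 are each used for two pairs, so signature-based classification of
#' the karyogram recovers exactly six patterns. Patterns 1-5 are
#' mirror-symmetric about the chromosome centre (isochromosome-like);
#' pattern 6 carries a single terminal cluster region and is asymmetric.
#' Coordinates are 0-based half-open.
#'
#' @param config a [karyotype_config()].
#' @param families family panel tibble (see [default_families()]).
#' @param seed integer seed (orientations are drawn per block).
#' @return placement tibble: `chromosome_id`, `pair_id`, `family`, `start`,
#'   `end`, `copies`, `orientation`, `kind` (= "array"), `pattern`.
#' @export
default_placement <- function(config = karyotype_config(),
                              families = default_families(), seed = 1) {
  set.seed(child_seed(seed, "placement"))
  L <- config$e_length
  a_offset <- 9000L
  m_offset <- 20000L
  tpl <- pattern_templates()
  assign <- default_pattern_assignment()

  per_pattern <- purrr::imap(tpl, function(t, pid) {
    left_T <- place_blocks(t$T, 0L, families)
    left_A <- place_blocks(t$A, a_offset, families)
    left_M <- place_blocks(t$M, m_offset, families)
    left <- bind_rows(left_T, left_A, left_M)
    stopifnot(max(left$end) <= L / 2)
    rows <- left
    if (t$two_sided) {
      span <- function(df) if (is.null(df)) 0L else sum(df$end - df$start)
      right_T <- place_blocks(t$T, L - span(left_T), families,
                              reverse = TRUE)
      right_A <- place_blocks(t$A, L - a_offset - span(left_A), families,
                              reverse = TRUE)
      right_M <- if (is.null(t$M)) NULL else {
        place_blocks(t$M, L - m_offset - span(left_M), families,
                     reverse = TRUE)
      }
      rows <- bind_rows(rows, right_T, right_A, right_M)
    }
    rows$pattern <- as.integer(pid)
    rows
  })

  out <- purrr::pmap(assign, function(pair_id, pattern) {
    rows <- per_pattern[[as.character(pattern)]]
    purrr::map(c("a", "b"), function(h) {
      r <- rows
      r$chromosome_id <- paste0(pair_id, h)
      r$pair_id <- pair_id
      r
    }) |> list_rbind()
  }) |> list_rbind()

  out$orientation <- sample(c("+", "-"), nrow(out), replace = TRUE)
  out$kind <- "array"
  out <- out[, c("chromosome_id", "pair_id", "family", "start", "end",
                 "copies", "orientation", "kind", "pattern")]
  validate_placement(out)
  as_tibble(out)
}

# Placement sanity: within-chromosome intervals must not overlap and every
# E-pair must appear as two homologs.
validate_placement <- function(placement, check_pairs = TRUE) {
  bad <- placement |>
    group_by(.data$chromosome_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(overlap = any(head(.data$end, -1) > tail(.data$start, -1)),
              .groups = "drop")
  if (any(bad$overlap)) abort("invalid-placement: overlapping intervals")
  if (check_pairs) {
    homologs <- placement |>
      distinct(.data$pair_id, .data$chromosome_id) |>
      dplyr::count(.data$pair_id)
    if (any(homologs$n != 2)) {
      abort("invalid-placement: each pair needs exactly two homologs")
    }
  }
  invisible(placement)
}
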