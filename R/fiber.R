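#' Interspersion of probe signals along a chromatin fiber
#'
#' Formalizes the qualitative fiber-FISH observation that different repeat
#' families are entwined along one fiber rather than blocked. The observed
#' segment labels, ordered along the fiber, give
#' `index = (# adjacent segment pairs with different labels) / (S - 1)`
#' for `S` segments — 1 for perfect alternation, approaching 0 for fully
#' blocked layouts. The p-value is the permutation probability (label order
#' shuffled) of an index at least as large, with the add-one estimator.
#' This statistic is this package's formalization of a qualitative
#' observation, not a published quantity.
#'
#' Probes with fewer than 2 segments on the fiber are excluded; if fewer
#' than 2 probes remain the result is a no-call.
#'
#' @param segments tibble with `probe`, `start`, `end` (segments along one
#'   fiber), or a named list of logical masks on a common bin grid.
#' @param n_permutations number of label permutations (default 1000).
#' @param seed integer seed for the permutation draw.
#' @return list: `index`, `p_value`, `n_segments`, `n_probes`, `labels`;
#'   `index` is `NA` for a no-call.
#' @export
fiber_interspersion <- function(segments, n_permutations = 1000, seed = 1) {
  if (is.list(segments) && !is.data.frame(segments)) {
    segments <- purrr::imap(segments, function(mask, probe) {
      r <- rle(as.logical(mask))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      tibble(probe = probe, start = starts[r$values], end = ends[r$values])
    }) |> list_rbind()
  }
  counts <- table(segments$probe)
  keep <- names(counts)[counts >= 2]
  segments <- segments[segments$probe %in% keep, , drop = FALSE]
  if (length(keep) < 2) {
    return(list(index = NA_real_, p_value = NA_real_,
                n_segments = nrow(segments), n_probes = length(keep),
                labels = character(0)))
  }
  labels <- segments$probe[order(segments$start)]
  S <- length(labels)
  alternation <- function(l) sum(l[-1] != l[-length(l)]) / (length(l) - 1)
  obs <- alternation(labels)
  set.seed(child_seed(seed, "fiber"))
  perm <- vapply(seq_len(n_permutations),
                 function(i) alternation(sample(labels)), numeric(1))
  p <- (1 + sum(perm >= obs - 1e-12)) / (n_permutations + 1)
  list(index = obs, p_value = p, n_segments = S, n_probes = length(keep),
       labels = labels)
}
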