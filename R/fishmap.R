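#' Segment a chromosome intensity profile into signal and background
#'
#' A bin is signal-positive when its intensity reaches the background median
#' plus 3 background MADs, where the background is the set of bins at or
#' below the profile's 75th percentile. When that threshold is exactly zero
#' (clean zero-background profiles), a bin is positive iff its intensity is
#' positive. Isolated positive runs shorter than 2 bins are removed.
#'
#' @param intensities numeric vector (>= 10 bins).
#' @param min_run minimum run length kept (default 2).
#' @return list with `mask` (logical vector), `threshold`, `runs` (tibble of
#'   positive runs with `start_bin`, `end_bin`).
#' @export
segment_signal <- function(intensities, min_run = 2) {
  if (length(intensities) < 10) abort("need >= 10 bins")
  if (any(intensities < 0)) abort("intensities must be >= 0")
  bg <- intensities[intensities <= quantile(intensities, 0.75)]
  thr <- median(bg) + 3 * mad(bg)
  mask <- if (thr > 0) intensities >= thr else intensities > 0
  # drop runs shorter than min_run
  r <- rle(mask)
  r$values[r$values & r$lengths < min_run] <- FALSE
  mask <- inverse.rle(r)
  r2 <- rle(mask)
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1
  runs <- tibble(start_bin = starts[r2$values], end_bin = ends[r2$values])
  list(mask = mask, threshold = thr, runs = runs)
}

#' Fraction of a probe's intensity inside a reference mask
#'
#' @param target numeric intensity vector.
#' @param reference_mask logical vector on the same bin grid.
#' @return sum of target intensity inside the mask divided by total target
#'   intensity; 0 when the target is empty.
#' @export
overlap_fraction <- function(target, reference_mask) {
  if (length(target) != length(reference_mask)) {
    abort("invalid-input: bin grids differ")
  }
  tot <- sum(target)
  if (tot == 0) return(0)
  sum(target[reference_mask]) / tot
}

#' Co-localization cut-offs
#'
#' Numeric boundaries for the qualitative signal-distribution groups:
#' fully aligned (coincident), largely overlapping, half overlapping, and
#' peripheral; plus the dispersed-signal and detection-floor rules.
#'
#' @param coincident,largely,half lower overlap-fraction bounds (inclusive).
#' @param dispersed_bin_fraction minimum positive-bin fraction for a
#'   dispersed call.
#' @param dispersed_max_rel maximum peak intensity relative to the
#'   segmentation threshold for a dispersed call.
#' @param detection_floor minimum target total intensity, as a fraction of
#'   the reference total, below which the probe is called absent.
#' @return named list of cut-offs.
#' @export
localization_cutoffs <- function(coincident = 0.90, largely = 0.60,
                                 half = 0.35, dispersed_bin_fraction = 0.5,
                                 dispersed_max_rel = 2,
                                 detection_floor = 0.05) {
  list(coincident = coincident, largely = largely, half = half,
       dispersed_bin_fraction = dispersed_bin_fraction,
       dispersed_max_rel = dispersed_max_rel,
       detection_floor = detection_floor)
}

#' Classify a probe's localization relative to a reference probe
#'
#' Applies, in order: an absence floor (target total below
#' `detection_floor` of the reference total); a dispersed test (more than
#' half the bins positive but no bin reaching twice the segmentation
#' threshold — a weak genome-wide scatter); then the overlap-fraction
#' classes `coincident` (>= 0.90), `largely_overlapping` (>= 0.60),
#' `half_overlapping` (>= 0.35) and `peripheral` (below). The overlap is
#' computed on the above-threshold part of the target profile
#' (intensity minus the segmentation threshold, clamped at zero), which
#' equals the raw profile for clean zero-background input but keeps additive
#' background from diluting the fraction.
#'
#' @param target numeric target-probe intensity vector.
#' @param reference numeric reference-probe intensity vector (same grid).
#' @param cutoffs see [localization_cutoffs()].
#' @return one-row tibble: `call` (factor), `overlap`, `target_total`.
#' @export
classify_localization <- function(target, reference,
                                  cutoffs = localization_cutoffs()) {
  if (length(target) != length(reference)) {
    abort("invalid-input: bin grids differ")
  }
  levels <- c("coincident", "largely_overlapping", "half_overlapping",
              "peripheral", "dispersed", "absent")
  result <- function(call, overlap) {
    tibble(call = factor(call, levels = levels), overlap = overlap,
           target_total = sum(target))
  }
  if (sum(target) < cutoffs$detection_floor * sum(reference)) {
    return(result("absent", NA_real_))
  }
  seg_t <- segment_signal(target)
  if (seg_t$threshold > 0 &&
      mean(target >= seg_t$threshold) > cutoffs$dispersed_bin_fraction &&
      max(target) < cutoffs$dispersed_max_rel * seg_t$threshold) {
    return(result("dispersed", NA_real_))
  }
  seg_r <- segment_signal(reference)
  net <- pmax(target - seg_t$threshold, 0)
  frac <- overlap_fraction(net, seg_r$mask)
  call <- if (frac >= cutoffs$coincident) {
    "coincident"
  } else if (frac >= cutoffs$largely) {
    "largely_overlapping"
  } else if (frac >= cutoffs$half) {
    "half_overlapping"
  } else {
    "peripheral"
  }
  result(call, frac)
}

#' Symmetry score of a profile
#'
#' Pearson correlation between a profile and its reversal: 1 for a
#' mirror-symmetric (isochromosome-like) signal distribution, negative for
#' one-sided distributions. Zero-variance profiles score 0.
#'
#' @param intensities numeric vector.
#' @return numeric in `[-1, 1]`.
#' @export
symmetry_score <- function(intensities) {
  if (stats::sd(intensities) == 0) return(0)
  cor(intensities, rev(intensities))
}

#' Number of signal clusters in a profile
#'
#' @param intensities numeric vector.
#' @return integer count of positive runs after segmentation.
#' @export
cluster_count <- function(intensities) {
  nrow(segment_signal(intensities)$runs)
}

# orient a homolog so the reference-probe intensity centroid lies in the
# first half, then average the pair's homologs
orient_and_average <- function(wide, reference_probe) {
  ref <- wide[[reference_probe]]
  mid <- (length(ref) + 1) / 2
  centroid <- sum(seq_along(ref) * ref) / max(sum(ref), .Machine$double.eps)
  if (centroid > mid) wide <- wide[rev(seq_len(nrow(wide))), , drop = FALSE]
  wide
}

#' Build a karyogram: partition E-chromosome pairs into patterns
#'
#' For every E-chromosome pair, homolog profiles are oriented (reference
#' centroid in the first half) and averaged; each probe then receives a
#' localization call against the reference probe, a symmetry flag
#' (symmetry score >= `symmetry_min`) and a cluster count. Pairs with
#' identical signatures share a pattern id; `n_patterns` is the number of
#' distinct signatures.
#'
#' @param profiles a `profile_set` (see [render_fish_profiles()]); only
#'   eliminated chromosomes enter the karyogram.
#' @param reference_probe reference family (default `"EEEb1"`).
#' @param cutoffs see [localization_cutoffs()].
#' @param symmetry_min symmetric-flag threshold on the symmetry score.
#' @return a `karyogram` list: `calls` tibble (pair x probe:
#'   `pair`, `probe`, `call`, `overlap`, `symmetric`, `clusters`),
#'   `patterns` tibble (`pair`, `pattern`), `n_patterns`.
#' @export
build_karyogram <- function(profiles, reference_probe = "EEEb1",
                            cutoffs = localization_cutoffs(),
                            symmetry_min = 0.80) {
  probes <- sort(unique(profiles$probe))
  if (!reference_probe %in% probes) {
    abort("invalid-input: reference probe missing from profiles")
  }
  e_prof <- profiles[profiles$is_eliminated, , drop = FALSE]
  if (nrow(e_prof) == 0) abort("invalid-input: no eliminated chromosomes")
  missing <- e_prof |>
    group_by(.data$chromosome) |>
    summarise(ok = all(probes %in% .data$probe), .groups = "drop")
  if (!all(missing$ok)) {
    abort("invalid-input: every E-chromosome needs every probe")
  }

  pair_profiles <- e_prof |>
    arrange(.data$pair, .data$chromosome, .data$probe, .data$bin) |>
    group_by(.data$pair) |>
    dplyr::group_map(function(df, key) {
      homologs <- split(df, df$chromosome)
      wides <- purrr::map(homologs, function(h) {
        w <- tidyr::pivot_wider(h[, c("bin", "probe", "intensity")],
                                names_from = "probe",
                                values_from = "intensity") |>
          arrange(.data$bin)
        orient_and_average(w[, probes, drop = FALSE], reference_probe)
      })
      avg <- Reduce(`+`, purrr::map(wides, as.matrix)) / length(wides)
      list(pair = key$pair, profile = avg)
    })

  calls <- purrr::map(pair_profiles, function(p) {
    ref <- p$profile[, reference_probe]
    purrr::map(probes, function(pr) {
      x <- p$profile[, pr]
      cl <- classify_localization(x, ref, cutoffs)
      tibble(
        pair = p$pair, probe = pr, call = cl$call, overlap = cl$overlap,
        symmetric = symmetry_score(x) >= symmetry_min,
        clusters = cluster_count(x)
      )
    }) |> list_rbind()
  }) |> list_rbind()

  signatures <- calls |>
    arrange(.data$pair, .data$probe) |>
    group_by(.data$pair) |>
    summarise(signature = paste(.data$probe, .data$call, .data$symmetric,
                                .data$clusters, sep = ":", collapse = "|"),
              .groups = "drop")
  sig_ids <- signatures |>
    arrange(.data$pair) |>
    mutate(pattern = match(.data$signature, unique(.data$signature)))
  out <- list(
    calls = calls,
    patterns = sig_ids[, c("pair", "pattern")],
    n_patterns = length(unique(sig_ids$pattern)),
    reference_probe = reference_probe
  )
  class(out) <- "karyogram"
  out
}

#' @export
print.karyogram <- function(x, ...) {
  cat(sprintf("karyogram: %d pairs in %d patterns (reference %s)\n",
              nrow(x$patterns), x$n_patterns, x$reference_probe))
  print(x$patterns)
  invisible(x)
}

#' @rdname build_karyogram
#' @param x a `karyogram`.
#' @param ... unused.
#' @export
tidy.karyogram <- function(x, ...) {
  left_join(x$calls, x$patterns, by = "pair")
}

#' @rdname build_karyogram
#' @export
glance.karyogram <- function(x, ...) {
  tibble(n_pairs = nrow(x$patterns), n_patterns = x$n_patterns,
         n_probes = length(unique(x$calls$probe)),
         reference_probe = x$reference_probe)
}
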