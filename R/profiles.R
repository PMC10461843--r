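#' Render per-chromosome probe intensity profiles
#'
#' Emulates quantified hybridization signal along each chromosome: per-bin
#' intensity is (placed bases of the probe's family in the bin) / bin width,
#' plus a constant background and Gaussian noise truncated at zero.
#' Single-copy dispersed insertions (placement `kind == "dispersed"`) are
#' below the emulated optical resolution and are rendered as a uniform haze
#' carrying the same total mass, rather than as discrete one-bin spikes; with
#' zero noise and background the summed intensity times bin width therefore
#' still equals the family's total placed bases.
#'
#' @param genome a `genome` (its placement supplies the ground truth).
#' @param probes family names to render (default: all families).
#' @param bin_bp bin width in bp (>= 1).
#' @param background_level constant background intensity.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer seed.
#' @return a `profile_set` tibble: `chromosome`, `pair`, `is_eliminated`,
#'   `probe`, `bin` (1-based), `start` (0-based bp), `intensity`; attribute
#'   `bin_bp`.
#' @export
render_fish_profiles <- function(genome, probes = NULL, bin_bp = 500,
                                 background_level = 0, noise_sd = 0,
                                 seed = 1) {
  if (bin_bp < 1) abort("invalid-parameter: bin_bp must be >= 1")
  probes <- probes %||% genome$families$name
  unknown <- setdiff(probes, genome$families$name)
  if (length(unknown) > 0) {
    abort(paste("invalid-probe:", paste(unknown, collapse = ", ")))
  }
  set.seed(child_seed(seed, "profiles"))

  out <- purrr::pmap(genome$chromosomes[, c("id", "pair_id", "is_eliminated",
                                            "length")],
                     function(id, pair_id, is_eliminated, length) {
    n_bins <- ceiling(length / bin_bp)
    widths <- rep(bin_bp, n_bins)
    widths[n_bins] <- length - (n_bins - 1) * bin_bp
    rows <- genome$placement[genome$placement$chromosome_id == id, ,
                             drop = FALSE]
    purrr::map(probes, function(p) {
      fam_rows <- rows[rows$family == p, , drop = FALSE]
      arr <- fam_rows[fam_rows$kind != "dispersed", , drop = FALSE]
      disp <- fam_rows[fam_rows$kind == "dispersed", , drop = FALSE]
      base <- numeric(n_bins)
      if (nrow(arr) > 0) {
        for (i in seq_len(nrow(arr))) {
          b0 <- arr$start[i] %/% bin_bp + 1L
          b1 <- (arr$end[i] - 1L) %/% bin_bp + 1L
          for (b in b0:b1) {
            lo <- (b - 1L) * bin_bp
            base[b] <- base[b] +
              min(arr$end[i], lo + bin_bp) - max(arr$start[i], lo)
          }
        }
      }
      haze_total <- sum(disp$end - disp$start)
      intensity <- base / widths + haze_total * (widths / length) / widths +
        background_level
      if (noise_sd > 0) {
        intensity <- pmax(intensity + stats::rnorm(n_bins, 0, noise_sd), 0)
      }
      tibble(
        chromosome = id, pair = pair_id, is_eliminated = is_eliminated,
        probe = p, bin = seq_len(n_bins), start = (seq_len(n_bins) - 1L) * bin_bp,
        intensity = intensity
      )
    }) |> list_rbind()
  }) |> list_rbind()

  attr(out, "bin_bp") <- bin_bp
  class(out) <- c("profile_set", class(out))
  out
}

#' Write a profile set as TSV
#' @param profiles a `profile_set`.
#' @param path output path.
#' @export
write_profiles_tsv <- function(profiles, path) {
  readr::write_tsv(
    profiles[, c("chromosome", "probe", "bin", "intensity")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Read a profile TSV
#'
#' Expects columns `chromosome`, `probe`, `bin`, `intensity`; `pair` and
#' `is_eliminated` are reconstructed from the id convention
#' (`E<pair><homolog>` / `S<pair><homolog>`) when absent.
#'
#' @param path TSV path.
#' @param bin_bp bin width in bp.
#' @return a `profile_set`.
#' @export
read_profiles_tsv <- function(path, bin_bp = 500) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"pair" %in% names(x)) {
    x$pair <- sub("[ab]$", "", x$chromosome)
  }
  if (!"is_eliminated" %in% names(x)) {
    x$is_eliminated <- startsWith(x$chromosome, "E")
  }
  if (!"start" %in% names(x)) x$start <- (x$bin - 1L) * bin_bp
  attr(x, "bin_bp") <- bin_bp
  class(x) <- c("profile_set", class(x))
  x
}

#' Extract fiber segments from a placement map
#'
#' A chromatin fiber is a window of one chromosome; its probe signal
#' segments are simply the placed blocks inside the window, in linear order.
#' Used to feed [fiber_interspersion()].
#'
#' @param genome a `genome`.
#' @param chromosome chromosome id.
#' @param from,to window in bp (0-based half-open).
#' @param probes families to keep (default all).
#' @return tibble `probe`, `start`, `end` ordered along the fiber.
#' @export
fiber_segments <- function(genome, chromosome, from = 0,
                           to = NULL, probes = NULL) {
  rows <- genome$placement[genome$placement$chromosome_id == chromosome, ,
                           drop = FALSE]
  to <- to %||% genome$chromosomes$length[
    genome$chromosomes$id == chromosome]
  rows <- rows[rows$start >= from & rows$end <= to, , drop = FALSE]
  if (!is.null(probes)) rows <- rows[rows$family %in% probes, , drop = FALSE]
  rows <- rows[order(rows$start), , drop = FALSE]
  tibble(probe = rows$family, start = rows$start, end = rows$end)
}
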