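#' Plot probe intensity profiles
#'
#' One panel per chromosome, one colored line per probe, intensity against
#' chromosome position.
#'
#' @param object a `profile_set` (see [render_fish_profiles()]).
#' @param chromosomes optional chromosome ids to keep (default: all
#'   eliminated chromosomes).
#' @param probes optional probe names to keep.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.profile_set <- function(object, chromosomes = NULL, probes = NULL,
                                 ...) {
  df <- as_tibble(object)
  if (is.null(chromosomes)) {
    chromosomes <- unique(df$chromosome[df$is_eliminated])
    if (length(chromosomes) == 0) chromosomes <- unique(df$chromosome)
  }
  df <- df[df$chromosome %in% chromosomes, , drop = FALSE]
  if (!is.null(probes)) df <- df[df$probe %in% probes, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start / 1000,
                                   y = .data$intensity,
                                   colour = .data$probe)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$chromosome)) +
    ggplot2::labs(x = "position (kb)", y = "intensity", colour = "probe") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.profile_set
#' @param x a `profile_set`.
#' @export
plot_profiles <- function(x, chromosomes = NULL, probes = NULL) {
  autoplot.profile_set(x, chromosomes = chromosomes, probes = probes)
}

#' Plot a karyogram as a call matrix
#'
#' Tile plot of localization calls, one row per probe and one column per
#' E-chromosome pair, pairs grouped by their pattern id.
#'
#' @param object a `karyogram` (see [build_karyogram()]).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.karyogram <- function(object, ...) {
  df <- tidy(object)
  df$pair <- factor(df$pair, levels = unique(df$pair[order(df$pattern)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$probe,
                                   fill = .data$call)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$pattern),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "chromosome pair (grouped by pattern)", y = "probe",
                  fill = "localization") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.karyogram
#' @param x a `karyogram`.
#' @export
plot_karyogram <- function(x) autoplot.karyogram(x)

#' Plot an amplicon ladder as a virtual gel lane
#'
#' Band sizes on a log scale, as on an electrophoresis gel.
#'
#' @param object an `amplicon_ladder` (see [predict_amplicons()]), or the
#'   annotated tibble from [ladder_report()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.amplicon_ladder <- function(object, ...) {
  df <- as_tibble(object)
  df$lane <- if ("family" %in% names(df)) df$family else "template"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lane, y = .data$band_bp)) +
    ggplot2::geom_tile(width = 0.6, height = 0.015 * df$band_bp) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "product size (bp)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.amplicon_ladder
#' @param x an `amplicon_ladder` or annotated ladder tibble.
#' @export
plot_ladder <- function(x) autoplot.amplicon_ladder(x)
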