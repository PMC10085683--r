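#' Plot a contact-probability curve
#'
#' @param object A `contact_curve`.
#' @param ... Unused.
#' @return A ggplot: P(s) on log-log axes.
#' @export
autoplot.contact_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$p) & df$p > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s_mid, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10(labels = function(x) x / 1e6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "genomic separation s (Mb)",
                  y = expression(P[C](s))) +
    ggplot2::theme_minimal()
}

#' Plot a turn-length profile along chromosomes
#'
#' @param object A `turn_length_profile`.
#' @param ... Unused.
#' @return A ggplot: turn length (Mb) per region, coloured by artifact flag,
#'   one facet per chromosome.
#' @export
autoplot.turn_length_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mid_mb <- (df$start + df$end) / 2 / 1e6
  df$turn_mb <- df$turn_length / 1e6
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_mb, y = .data$turn_mb)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$artifact_flag)) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(T[l] ~ "(Mb)"),
                  colour = "flag") +
    ggplot2::theme_minimal()
}

#' Plot a helical path
#'
#' @param object A `helical_path`.
#' @param ... Unused.
#' @return A ggplot: side (x-z) projection of the path, coloured by the local
#'   turn length.
#' @export
autoplot.helical_path <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                   colour = .data$l_bp / 1e6)) +
    ggplot2::geom_path() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (nm)", y = "z (nm)", colour = expression(T[l] ~ "(Mb)")) +
    ggplot2::theme_minimal()
}

#' Plot a conformation
#'
#' @param object A `conformation`.
#' @param ... Unused.
#' @return A ggplot: x-z projection of the beads, coloured by genomic
#'   position.
#' @export
autoplot.conformation <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                   colour = .data$bp / 1e6)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (nm)", y = "z (nm)", colour = "Mb") +
    ggplot2::theme_minimal()
}

#' Plot SCE segment geometry against the chromonema constraints
#'
#' @param segments Output of [classify_sce_segments()].
#' @param thickness_band Height band drawn as guides (nm).
#' @return A ggplot of height versus width fraction, coloured by class.
#' @export
plot_sce_segments <- function(segments, thickness_band = c(300, 550)) {
  df <- tibble::as_tibble(segments)
  df$width_frac <- df$width / df$chromatid_width
  ggplot2::ggplot(df, ggplot2::aes(x = .data$width_frac, y = .data$height,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = thickness_band, linetype = "dashed") +
    ggplot2::labs(x = "width / chromatid width", y = "height (nm)",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
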