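#' Tidy an exponential-plus-Gaussian fit
#'
#' @param x An `exp_gauss_fit` from [fit_exp_gauss()].
#' @param ... Unused.
#' @return A tibble with one row per model parameter (`term`, `estimate`).
#' @export
tidy.exp_gauss_fit <- function(x, ...) {
  tibble::tibble(
    term = c("amp_exp", "scale_exp", "amp_gauss", "mu", "sigma"),
    estimate = c(x$amp_exp, x$scale_exp, x$amp_gauss, x$mu, x$sigma)
  )
}

#' One-row summary of an exponential-plus-Gaussian fit
#'
#' @param x An `exp_gauss_fit` from [fit_exp_gauss()].
#' @param ... Unused.
#' @return A one-row tibble with `turn_length`, `sigma`, `gauss_share`,
#'   `gauss_detected`, `rss`, `converged`, `n_pairs`.
#' @export
glance.exp_gauss_fit <- function(x, ...) {
  tibble::tibble(
    turn_length = x$mu, sigma = x$sigma, gauss_share = x$gauss_share,
    gauss_detected = x$gauss_detected, rss = x$rss, converged = x$converged,
    n_pairs = x$n_pairs
  )
}

#' Per-block convergence history of a simulation
#'
#' @param x A `chromonema_sim` from [simulate_chromonema()].
#' @param ... Unused.
#' @return The per-block tibble (`block`, `steps`, `max_dlog10`).
#' @export
tidy.chromonema_sim <- function(x, ...) x$blocks

#' One-row summary of a simulation
#'
#' @param x A `chromonema_sim` from [simulate_chromonema()].
#' @param ... Unused.
#' @return A one-row tibble with bead count, blocks run, total steps,
#'   convergence flag and the confinement radius in use.
#' @export
glance.chromonema_sim <- function(x, ...) {
  tibble::tibble(
    n_beads = nrow(x$conformation),
    blocks = nrow(x$blocks),
    steps = if (nrow(x$blocks) > 0) max(x$blocks$steps) else 0L,
    converged = x$converged,
    cylinder_radius = x$cylinder_radius
  )
}

#' Per-bin divergence of a model/Hi-C comparison
#' @param x A `curve_divergence` from [compare_to_hic()].
#' @param ... Unused.
#' @return The per-bin tibble (`s_mid`, `log10_ratio`).
#' @export
tidy.curve_divergence <- function(x, ...) x$per_bin

#' One-row summary of a model/Hi-C comparison
#' @param x A `curve_divergence` from [compare_to_hic()].
#' @param ... Unused.
#' @return A one-row tibble (`n_bins`, `max_abs_log10`, `rms_log10`).
#' @export
glance.curve_divergence <- function(x, ...) {
  tibble::tibble(
    n_bins = x$n_bins, max_abs_log10 = x$max_abs_log10,
    rms_log10 = x$rms_log10
  )
}
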