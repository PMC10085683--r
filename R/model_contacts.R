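conformation_contacts_matrix <- function(coords, contact_radius) {
  if (any(!is.finite(coords))) rlang::abort("non-finite coordinates")
  m <- .contacts_within(coords, contact_radius)
  tibble::tibble(i = m[, 1], j = m[, 2])
}

#' Spatial contacts of a simulated conformation
#'
#' Returns every unordered bead pair whose centre-to-centre distance is at
#' most `contact_radius`, found with a cell-list neighbour search that agrees
#' exactly with the all-pairs computation.
#'
#' @param conf A `conformation` tibble (or anything with x, y, z columns).
#' @param contact_radius Contact threshold in nm (default 51).
#' @return A tibble with integer columns `i`, `j` (`i < j`).
#' @export
conformation_contacts <- function(conf, contact_radius = 51) {
  coords <- as.matrix(tibble::as_tibble(conf)[, c("x", "y", "z")])
  out <- conformation_contacts_matrix(coords, contact_radius)
  out[order(out$i, out$j), ]
}

#' Contact-probability curve of simulated conformations
#'
#' Groups contacts by genomic separation `|i - j| * bp_per_monomer`, divides
#' observed contacts per bin by all possible monomer pairs at those
#' separations (summed over pooled conformations), and normalizes the curve
#' to 1 at the 100 kb point so it is directly comparable with Hi-C curves.
#' When beads are coarser than 100 kb the smallest separation bin is used
#' instead, with a warning.
#'
#' @param contacts A contact tibble from [conformation_contacts()], or a list
#'   of them (replicates are pooled before normalization).
#' @param n_monomers Number of beads per conformation.
#' @param bp_per_monomer Genomic size of one bead (bp).
#' @param bins Distance bins; defaults to log-spaced bins at 10 per decade
#'   from `max(100 kb, bp_per_monomer)` to the conformation span.
#' @param normalize_at Normalization point in bp (default 100 kb).
#' @param quiet Suppress the empty-contacts / fallback warnings.
#' @return A `contact_curve` tibble.
#' @export
model_contact_probability <- function(contacts, n_monomers, bp_per_monomer,
                                      bins = NULL, normalize_at = 1e5,
                                      quiet = FALSE) {
  if (!is.data.frame(contacts)) {
    n_conf <- length(contacts)
    contacts <- dplyr::bind_rows(contacts)
  } else {
    n_conf <- 1L
  }
  if (is.null(bins)) {
    lo <- max(1e5, bp_per_monomer)
    hi <- n_monomers * bp_per_monomer
    bins <- log_distance_bins(lo, hi, bins_per_decade = 10)
  }

  # separations below one monomer are meaningless; |i - j| >= 1 by design
  s <- abs(contacts$j - contacts$i) * bp_per_monomer
  idx <- bin_index(s, bins)
  n_obs <- tabulate(idx[!is.na(idx)], nbins = nrow(bins))

  k <- seq_len(n_monomers - 1)
  kidx <- bin_index(k * bp_per_monomer, bins)
  keep <- !is.na(kidx)
  n_possible <- numeric(nrow(bins))
  if (any(keep)) {
    tab <- vapply(split(n_monomers - k[keep], kidx[keep]), sum, numeric(1))
    at <- as.integer(names(tab))
    n_possible[at] <- n_possible[at] + tab
  }
  n_possible <- n_possible * n_conf

  p <- ifelse(n_possible > 0, n_obs / n_possible, NA_real_)
  curve <- new_contact_curve(tibble::tibble(
    s_lo = bins$s_lo, s_hi = bins$s_hi, s_mid = bins$s_mid,
    n_obs = n_obs, n_possible = n_possible, p = p
  ))

  if (nrow(contacts) == 0) {
    if (!quiet) rlang::warn("no contacts; returning an all-zero curve")
    return(curve)
  }
  at <- normalize_at
  if (bp_per_monomer > normalize_at) {
    at <- curve$s_mid[which(curve$n_possible > 0)[1]]
    if (!quiet) {
      rlang::warn(sprintf(
        "beads are coarser than %g bp; normalizing at the smallest separation bin (%g bp)",
        normalize_at, at
      ))
    }
  }
  ref_i <- bin_index(at, bins)
  if (is.na(ref_i) || is.na(curve$p[ref_i]) || curve$p[ref_i] <= 0) {
    if (!quiet) rlang::warn("curve undefined at the normalization point; returned unnormalized")
    return(curve)
  }
  normalize_curve(curve, at)
}

#' Compare a model contact curve with a Hi-C curve
#'
#' Matches bins of the two curves (both must be normalized at the same
#' point), and reports the per-bin log10 ratio together with its maximum
#' absolute value and root-mean-square over overlapping defined bins.
#'
#' @param model,hic Two normalized `contact_curve`s on a shared log grid
#'   (the model curve may cover a narrower separation range).
#' @return A list of class `curve_divergence` with `per_bin` (tibble of
#'   `s_mid`, `log10_ratio`), `max_abs_log10` and `rms_log10`.
#' @export
compare_to_hic <- function(model, hic) {
  if (is.null(attr(model, "normalized_at")) || is.null(attr(hic, "normalized_at"))) {
    rlang::abort("both curves must be normalized (see normalize_curve) before comparison")
  }
  mb <- tibble::as_tibble(model)
  hb <- tibble::as_tibble(hic)
  # match bins by their log-position with a tight relative tolerance
  key <- function(v) round(log10(v) * 1e6)
  merged <- dplyr::inner_join(
    dplyr::mutate(mb, .key = key(.data$s_lo)),
    dplyr::mutate(hb, .key = key(.data$s_lo)),
    by = ".key", suffix = c("_model", "_hic")
  )
  ok <- !is.na(merged$p_model) & merged$p_model > 0 &
    !is.na(merged$p_hic) & merged$p_hic > 0
  if (!any(ok)) rlang::abort("no overlapping defined bins between the curves")
  lr <- log10(merged$p_model[ok] / merged$p_hic[ok])
  structure(list(
    per_bin = tibble::tibble(s_mid = merged$s_mid_model[ok], log10_ratio = lr),
    max_abs_log10 = max(abs(lr)),
    rms_log10 = sqrt(mean(lr^2)),
    n_bins = sum(ok)
  ), class = "curve_divergence")
}

#' @export
print.curve_divergence <- function(x, ...) {
  cat(sprintf(
    "curve divergence over %d bins: max |log10 ratio| = %.4f, RMS = %.4f\n",
    x$n_bins, x$max_abs_log10, x$rms_log10
  ))
  invisible(x)
}
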