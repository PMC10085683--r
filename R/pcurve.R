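#' Logarithmically spaced genomic distance bins
#'
#' Bin edges form an exact geometric sequence from `lo` to `hi`; the number of
#' bins is `round(bins_per_decade * log10(hi / lo))`, so the first and last
#' edges hit `lo` and `hi` exactly and the edge ratio is constant.
#'
#' @param lo,hi Range of genomic separations covered (bp).
#' @param bins_per_decade Approximate bin density on the log10 axis.
#' @return A tibble of class `distance_bins` with columns `s_lo`, `s_hi`
#'   (half-open bins `[s_lo, s_hi)`) and the geometric midpoint `s_mid`.
#' @export
log_distance_bins <- function(lo = 1e5, hi = 1e9, bins_per_decade = 10) {
  stopifnot(lo > 0, hi > lo, bins_per_decade > 0)
  n <- max(1L, as.integer(round(bins_per_decade * log10(hi / lo))))
  edges <- lo * (hi / lo)^(seq(0, n) / n)
  edges[1] <- lo
  edges[n + 1] <- hi
  out <- tibble::tibble(
    s_lo = edges[-(n + 1)],
    s_hi = edges[-1],
    s_mid = sqrt(edges[-(n + 1)] * edges[-1])
  )
  class(out) <- c("distance_bins", class(out))
  out
}

bin_edges <- function(bins) c(bins$s_lo, bins$s_hi[nrow(bins)])

# index of the half-open bin [s_lo, s_hi) containing each separation; NA outside
bin_index <- function(s, bins) {
  edges <- bin_edges(bins)
  idx <- findInterval(s, edges, rightmost.closed = FALSE)
  idx[idx < 1 | idx > nrow(bins)] <- NA_integer_
  idx
}

same_bins <- function(a, b) {
  nrow(a) == nrow(b) &&
    isTRUE(all.equal(a$s_lo, b$s_lo, tolerance = 1e-12)) &&
    isTRUE(all.equal(a$s_hi, b$s_hi, tolerance = 1e-12))
}

new_contact_curve <- function(df, normalized_at = NULL) {
  out <- tibble::as_tibble(df)
  attr(out, "normalized_at") <- normalized_at
  class(out) <- c("contact_curve", class(tibble::tibble()))
  out
}

curve_bins <- function(curve) {
  out <- tibble::tibble(
    s_lo = curve$s_lo, s_hi = curve$s_hi, s_mid = curve$s_mid
  )
  class(out) <- c("distance_bins", class(out))
  out
}

#' Contact probability as a function of genomic separation
#'
#' Counts intra-chromosomal contact pairs per log-spaced separation bin and
#' divides by the number of possible locus pairs at that separation, where
#' loci are non-overlapping `bin_size` tiles of each chromosome (summed over
#' chromosomes). Bins with no possible locus pair get `p = NA` (undefined),
#' not zero.
#'
#' @param pairs A [contact_pairs] tibble.
#' @param bins Distance bins from [log_distance_bins()].
#' @param bin_size Locus tile size (bp) used for the denominator.
#' @return A `contact_curve` tibble with columns `s_lo`, `s_hi`, `s_mid`,
#'   `n_obs`, `n_possible`, `p`.
#' @export
contact_probability <- function(pairs, bins = log_distance_bins(),
                                bin_size = 1e5) {
  stopifnot(bin_size > 0)
  cs <- chrom_sizes(pairs)
  intra <- pairs[pairs$intra, , drop = FALSE]
  if (nrow(intra) == 0) rlang::abort("no usable contacts (no intra-chromosomal pairs)")

  s <- abs(intra$pos1 - intra$pos2)
  idx <- bin_index(s, bins)
  n_obs <- tabulate(idx[!is.na(idx)], nbins = nrow(bins))

  n_possible <- numeric(nrow(bins))
  for (L in cs) {
    n_loci <- floor(L / bin_size)
    if (n_loci < 2) next
    k <- seq_len(n_loci - 1)
    sep <- k * bin_size
    kidx <- bin_index(sep, bins)
    keep <- !is.na(kidx)
    if (any(keep)) {
      tab <- vapply(split(n_loci - k[keep], kidx[keep]), sum, numeric(1))
      at <- as.integer(names(tab))
      n_possible[at] <- n_possible[at] + tab
    }
  }

  p <- ifelse(n_possible > 0, n_obs / n_possible, NA_real_)
  new_contact_curve(tibble::tibble(
    s_lo = bins$s_lo, s_hi = bins$s_hi, s_mid = bins$s_mid,
    n_obs = n_obs, n_possible = n_possible, p = p
  ))
}

#' Normalize a contact curve at a reference separation
#'
#' Rescales `p` so that the bin containing `at` equals exactly 1. Normalizing
#' an already-normalized curve at the same point is a no-op.
#'
#' @param curve A `contact_curve`.
#' @param at Reference separation in bp (default 100 kb, the first bin edge of
#'   the default binning).
#' @return The rescaled `contact_curve` with attribute `normalized_at`.
#' @export
normalize_curve <- function(curve, at = 1e5) {
  i <- bin_index(at, curve_bins(curve))
  if (is.na(i)) rlang::abort("normalization point lies outside the binned range")
  ref <- curve$p[i]
  if (is.na(ref) || ref <= 0) {
    rlang::abort("curve is undefined or zero at the normalization point")
  }
  curve$p <- curve$p / ref
  curve$p[i] <- 1
  attr(curve, "normalized_at") <- at
  curve
}

#' Log-log derivative of a contact curve
#'
#' Computes d log10(p) / d log10(s) at the bin midpoints by central
#' differences (one-sided at the ends). Bins where `p` is undefined or
#' non-positive propagate as `NA`.
#'
#' @param curve A `contact_curve`.
#' @return A tibble with columns `s_mid` and `dlog_p`.
#' @export
log_derivative <- function(curve) {
  ok <- !is.na(curve$p) & curve$p > 0
  if (sum(ok) < 3) rlang::abort("need at least 3 bins with defined positive p")
  lp <- ifelse(ok, log10(curve$p), NA_real_)
  ls <- log10(curve$s_mid)
  n <- length(lp)
  d <- rep(NA_real_, n)
  if (n >= 2) {
    d[1] <- (lp[2] - lp[1]) / (ls[2] - ls[1])
    d[n] <- (lp[n] - lp[n - 1]) / (ls[n] - ls[n - 1])
  }
  if (n >= 3) {
    i <- 2:(n - 1)
    d[i] <- (lp[i + 1] - lp[i - 1]) / (ls[i + 1] - ls[i - 1])
  }
  tibble::tibble(s_mid = curve$s_mid, dlog_p = d)
}

#' Ratio of two contact curves (e.g. metaphase over interphase)
#'
#' @param meta,inter Two `contact_curve`s on identical bins.
#' @return A tibble with columns `s_mid` and `ratio`; bins where the
#'   denominator is zero or undefined are `NA`.
#' @export
ratio_curve <- function(meta, inter) {
  if (!same_bins(curve_bins(meta), curve_bins(inter))) {
    rlang::abort("curves are binned differently; rebin before taking a ratio")
  }
  den <- inter$p
  ratio <- ifelse(!is.na(den) & den > 0 & !is.na(meta$p), meta$p / den, NA_real_)
  tibble::tibble(s_mid = meta$s_mid, ratio = ratio)
}

#' Write a contact curve as TSV
#' @param curve A `contact_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  readr::write_tsv(tibble::as_tibble(curve), path)
  invisible(path)
}

#' Locate the interior local maximum of a contact curve
#'
#' Finds bins whose `p` exceeds both neighbours, restricted to separations at
#' least `s_min` (to skip the loop-scale shoulder), and returns the location
#' of the highest such bump — the helical full-turn peak in a metaphase-like
#' curve.
#'
#' @param curve A `contact_curve`.
#' @param s_min Smallest separation considered (bp).
#' @return A one-row tibble (`s_mid`, `s_lo`, `s_hi`, `p`) or a zero-row
#'   tibble when no interior maximum exists.
#' @export
find_pc_peak <- function(curve, s_min = 5e5) {
  p <- curve$p
  n <- length(p)
  is_peak <- rep(FALSE, n)
  if (n >= 3) for (i in 2:(n - 1)) {
    if (is.na(p[i])) next
    left <- p[i - 1]
    right <- p[i + 1]
    if (!is.na(left) && !is.na(right) && p[i] > left && p[i] > right) {
      is_peak[i] <- TRUE
    }
  }
  is_peak <- is_peak & curve$s_mid >= s_min
  if (!any(is_peak)) {
    return(tibble::tibble(
      s_mid = numeric(), s_lo = numeric(), s_hi = numeric(), p = numeric()
    ))
  }
  i <- which(is_peak)[which.max(p[is_peak])]
  tibble::tibble(
    s_mid = curve$s_mid[i], s_lo = curve$s_lo[i], s_hi = curve$s_hi[i],
    p = p[i]
  )
}
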