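#' Contact-distance histogram for a chromosomal region
#'
#' Counts intra-chromosomal pairs attributable to a region: a pair qualifies
#' when at least one endpoint falls inside `[start, end)` or when the pair
#' spans the region entirely (left endpoint before `start`, right endpoint at
#' or beyond `end`). Each qualifying pair is counted exactly once, binned by
#' its genomic separation.
#'
#' @param pairs A [contact_pairs] tibble.
#' @param chrom Chromosome id of the region.
#' @param start,end Region bounds (bp, half-open).
#' @param bins Distance bins; defaults to log-spaced bins from 100 kb to the
#'   chromosome length at 30 bins per decade (finer than the genome-wide P(s)
#'   binning so the Gaussian bump is resolved).
#' @return A tibble of class `regional_histogram` with columns `s_lo`, `s_hi`,
#'   `s_mid`, `count`, plus region coordinates in attributes.
#' @export
regional_histogram <- function(pairs, chrom, start, end, bins = NULL) {
  cs <- chrom_sizes(pairs)
  if (!chrom %in% names(cs)) rlang::abort(paste0("unknown chromosome: ", chrom))
  L <- cs[[chrom]]
  if (start < 0 || end > L || start >= end) {
    rlang::abort("region lies outside the chromosome")
  }
  if (is.null(bins)) bins <- log_distance_bins(1e5, L, bins_per_decade = 30)

  on_chrom <- pairs$intra & pairs$chrom1 == chrom
  a <- pmin(pairs$pos1[on_chrom], pairs$pos2[on_chrom])
  b <- pmax(pairs$pos1[on_chrom], pairs$pos2[on_chrom])
  inside <- (a >= start & a < end) | (b >= start & b < end)
  spanning <- a < start & b >= end
  s <- (b - a)[inside | spanning]

  idx <- bin_index(s, bins)
  count <- tabulate(idx[!is.na(idx)], nbins = nrow(bins))
  out <- tibble::tibble(
    s_lo = bins$s_lo, s_hi = bins$s_hi, s_mid = bins$s_mid, count = count
  )
  attr(out, "region") <- list(chrom = chrom, start = start, end = end)
  class(out) <- c("regional_histogram", class(tibble::tibble()))
  out
}

#' Fit an exponential-plus-Gaussian model to a contact-distance histogram
#'
#' Models the pair-distance density as
#' `A * exp(-s / lambda) + B * exp(-(s - mu)^2 / (2 * sigma^2))`:
#' an exponential decay from loop-scale contacts plus a Gaussian bump whose
#' centre `mu` is the helical turn length of the region. The fit is weighted
#' least squares on the per-bp density of the log-spaced histogram, with
#' Poisson (`sqrt(count)`) weighting.
#'
#' @param hist A [regional_histogram()].
#' @param mu_bounds Allowed turn-length window (bp).
#' @param min_counts Minimum total pair count required to attempt a fit.
#' @param detect_threshold Minimum share of the fitted signal integral carried
#'   by the Gaussian component for `gauss_detected` to be `TRUE`.
#' @return An object of class `exp_gauss_fit`: a list with `amp_exp`,
#'   `scale_exp`, `amp_gauss`, `mu`, `sigma` (density-scale amplitudes, bp
#'   scales), `rss`, `converged`, `gauss_detected`, and `gauss_share`.
#' @export
fit_exp_gauss <- function(hist, mu_bounds = c(1e7, 6e7), min_counts = 1000,
                          detect_threshold = 0.05) {
  total <- sum(hist$count)
  if (total < min_counts) {
    rlang::abort(paste0(
      "region underpowered: ", total, " pairs (< ", min_counts, ")"
    ))
  }
  width <- hist$s_hi - hist$s_lo
  dens <- hist$count / width
  # Poisson: var(count) ~ count, so var(dens) ~ count / width^2
  w <- width^2 / pmax(hist$count, 1)

  # deterministic initialization
  s <- hist$s_mid
  first_dec <- which(s <= min(s) * 10 & hist$count > 0)
  lam0 <- 5e6
  if (length(first_dec) >= 3) {
    sl <- stats::coef(stats::lm(log(dens[first_dec]) ~ s[first_dec]))[2]
    if (is.finite(sl) && sl < 0) lam0 <- min(max(-1 / sl, 1e5), 5e7)
  }
  in_win <- which(s >= mu_bounds[1] & s <= mu_bounds[2])
  sm <- as.numeric(stats::filter(dens, rep(1 / 3, 3), sides = 2))
  mu0 <- if (length(in_win) > 0) {
    s[in_win][which.max(ifelse(is.na(sm[in_win]), dens[in_win], sm[in_win]))]
  } else mean(mu_bounds)
  sig0 <- 5e6
  A0 <- max(dens[1], 1e-12)
  d_mu0 <- dens[which.min(abs(s - mu0))]

  fail <- function() {
    structure(list(
      amp_exp = NA_real_, scale_exp = NA_real_, amp_gauss = NA_real_,
      mu = NA_real_, sigma = NA_real_, rss = NA_real_,
      converged = FALSE, gauss_detected = FALSE, gauss_share = NA_real_,
      n_pairs = total
    ), class = "exp_gauss_fit")
  }

  # a degenerate start (e.g. near-zero Gaussian amplitude) makes the initial
  # gradient singular; walk a small deterministic ladder of starts
  starts <- list(
    list(A = A0, lam = lam0,
         B = max(d_mu0 - A0 * exp(-mu0 / lam0), 0.1 * d_mu0),
         mu = mu0, sig = sig0),
    list(A = A0, lam = 3e6, B = max(0.3 * d_mu0, 1e-12), mu = mu0, sig = sig0),
    list(A = A0, lam = 1e7, B = max(0.3 * d_mu0, 1e-12),
         mu = mean(mu_bounds), sig = sig0)
  )
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        dens ~ A * exp(-s / lam) + B * exp(-(s - mu)^2 / (2 * sig^2)),
        start = st,
        lower = c(A = 0, lam = 1e4, B = 0, mu = mu_bounds[1], sig = 1e5),
        upper = c(A = Inf, lam = 1e9, B = Inf, mu = mu_bounds[2], sig = 5e7),
        weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(fail())

  cf <- stats::coef(fit)
  exp_int <- cf[["A"]] * cf[["lam"]]
  gauss_int <- cf[["B"]] * cf[["sig"]] * sqrt(2 * pi)
  share <- gauss_int / (exp_int + gauss_int)
  structure(list(
    amp_exp = unname(cf[["A"]]), scale_exp = unname(cf[["lam"]]),
    amp_gauss = unname(cf[["B"]]), mu = unname(cf[["mu"]]),
    sigma = unname(cf[["sig"]]),
    rss = sum(stats::residuals(fit)^2 * w),
    converged = TRUE,
    gauss_detected = is.finite(share) && share >= detect_threshold,
    gauss_share = unname(share),
    n_pairs = total
  ), class = "exp_gauss_fit")
}

#' @export
print.exp_gauss_fit <- function(x, ...) {
  cat("exp+Gaussian contact-distance fit\n")
  if (x$converged) {
    cat(sprintf(
      "  mu = %.2f Mb, sigma = %.2f Mb, exp scale = %.2f Mb\n",
      x$mu / 1e6, x$sigma / 1e6, x$scale_exp / 1e6
    ))
    cat(sprintf(
      "  Gaussian share = %.1f%% (detected: %s)\n",
      100 * x$gauss_share, x$gauss_detected
    ))
  } else {
    cat("  fit did not converge\n")
  }
  invisible(x)
}

region_table <- function(L, region_size) {
  n_full <- floor(L / region_size)
  if (n_full < 1) return(NULL)
  start <- (seq_len(n_full) - 1) * region_size
  end <- start + region_size
  end[n_full] <- L  # terminal remainder merged into the last full region
  tibble::tibble(start = start, end = end)
}

#' Helical turn-length profile along chromosomes
#'
#' Tiles each chromosome into non-overlapping `region_size` regions (a
#' terminal remainder shorter than `region_size` is merged into the last full
#' region), fits the exponential-plus-Gaussian model to each region's
#' contact-distance histogram, and reports the Gaussian centre as the region's
#' helical turn length. Regions overlapping a mask, underpowered regions and
#' regions without a detected Gaussian are flagged `no_signal`; regions whose
#' turn length jumps by more than `jump_factor` relative to both neighbours
#' are flagged `abrupt_peak` (a typical signature of assembly errors). Flags
#' annotate entries only; they never alter the fitted values.
#'
#' @param pairs A [contact_pairs] tibble.
#' @param region_size Region length in bp (default 5 Mb).
#' @param masks Optional data frame (`chrom`, `start`, `end`) of regions to
#'   exclude, e.g. centromeres and nucleolus organizers.
#' @param mu_bounds,min_counts,detect_threshold Passed to [fit_exp_gauss()].
#' @param jump_factor Fold-change versus both neighbours beyond which a region
#'   is flagged `abrupt_peak`.
#' @return A tibble of class `turn_length_profile`: one row per region with
#'   `chrom`, `start`, `end`, `turn_length` (bp; `NA` when `no_signal`),
#'   `artifact_flag` and fit diagnostics (`sigma`, `gauss_share`, `rss`,
#'   `converged`, `n_pairs`), plus the full fit objects in the list column
#'   `fit`.
#' @export
turn_length_profile <- function(pairs, region_size = 5e6, masks = NULL,
                                mu_bounds = c(1e7, 6e7), min_counts = 1000,
                                detect_threshold = 0.05, jump_factor = 1.5) {
  cs <- chrom_sizes(pairs)
  if (all(cs < region_size)) {
    rlang::abort("every chromosome is shorter than `region_size`")
  }
  res <- purrr::map(names(cs)[cs >= region_size], function(ch) {
    regs <- region_table(cs[[ch]], region_size)
    bins <- log_distance_bins(1e5, cs[[ch]], bins_per_decade = 30)
    purrr::pmap(regs, function(start, end) {
      masked <- !is.null(masks) && any(
        masks$chrom == ch & masks$start < end & masks$end > start
      )
      fit <- NULL
      flag <- "ok"
      tl <- NA_real_
      if (masked) {
        flag <- "no_signal"
      } else {
        h <- regional_histogram(pairs, ch, start, end, bins = bins)
        fit <- tryCatch(
          fit_exp_gauss(h, mu_bounds, min_counts, detect_threshold),
          error = function(e) NULL
        )
        if (is.null(fit) || !fit$converged || !fit$gauss_detected) {
          flag <- "no_signal"
        } else {
          tl <- fit$mu
        }
      }
      tibble::tibble(
        chrom = ch, start = start, end = end, turn_length = tl,
        artifact_flag = flag,
        sigma = if (is.null(fit)) NA_real_ else fit$sigma,
        gauss_share = if (is.null(fit)) NA_real_ else fit$gauss_share,
        rss = if (is.null(fit)) NA_real_ else fit$rss,
        converged = if (is.null(fit)) FALSE else fit$converged,
        n_pairs = if (is.null(fit)) NA_real_ else fit$n_pairs,
        fit = list(fit)
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  # abrupt-peak annotation: mu deviating >jump_factor from both neighbours
  res <- res |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      .prev = dplyr::lag(.data$turn_length),
      .next = dplyr::lead(.data$turn_length),
      artifact_flag = dplyr::if_else(
        .data$artifact_flag == "ok" &
          !is.na(.data$.prev) & !is.na(.data$.next) &
          ((.data$turn_length > jump_factor * .data$.prev &
              .data$turn_length > jump_factor * .data$.next) |
             (.data$turn_length * jump_factor < .data$.prev &
                .data$turn_length * jump_factor < .data$.next)),
        "abrupt_peak", .data$artifact_flag
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".prev", -".next")

  attr(res, "chrom_sizes") <- cs
  attr(res, "region_size") <- region_size
  class(res) <- c("turn_length_profile", class(tibble::tibble()))
  res
}

#' Write a turn-length profile as BEDGRAPH
#' @param profile A [turn_length_profile()].
#' @param path Output path; regions without a turn length are skipped.
#' @return `path`, invisibly.
#' @export
write_profile_bedgraph <- function(profile, path) {
  keep <- !is.na(profile$turn_length)
  lines <- sprintf(
    "%s\t%d\t%d\t%g",
    profile$chrom[keep], as.integer(profile$start[keep]),
    as.integer(profile$end[keep]), profile$turn_length[keep]
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a turn-length profile from BEDGRAPH
#' @param path A 4-column BEDGRAPH (chrom, start, end, turn_length_bp).
#' @return A tibble with columns `chrom`, `start`, `end`, `turn_length`.
#' @export
read_profile_bedgraph <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "turn_length"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), turn_length = readr::col_double()
    ),
    comment = "#"
  )
}
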