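#' Specification of a synthetic helical Hi-C signal
#'
#' Describes metaphase-like contact pairs whose separation distribution is a
#' mixture of an exponential decay (loop-scale contacts) and a Gaussian bump
#' centred at the helical turn length.
#'
#' @param chrom_length Chromosome length in bp.
#' @param turn_length Bump centre in bp: a single constant, or a data frame
#'   (`start`, `end`, `turn_length`) giving a piecewise/gradient track along
#'   the chromosome.
#' @param exp_scale Scale of the exponential component (bp).
#' @param bump_sigma Width of the Gaussian bump (bp).
#' @param bump_weight Mixture weight of the Gaussian component (0 to 1).
#' @param n_pairs Number of contact pairs to draw.
#' @param chrom Chromosome name used in the output.
#' @param seed Integer seed.
#' @return A list of class `helical_signal_spec`.
#' @export
helical_signal_spec <- function(chrom_length, turn_length = 30e6,
                                exp_scale = 5e6, bump_sigma = 5e6,
                                bump_weight = 0.3, n_pairs = 1e5,
                                chrom = "chrS", seed = 1) {
  stopifnot(chrom_length > 0, exp_scale > 0, bump_sigma > 0,
            bump_weight >= 0, bump_weight <= 1, n_pairs >= 0)
  tl_values <- if (is.numeric(turn_length)) turn_length else turn_length$turn_length
  if (any(tl_values <= 0 | tl_values >= chrom_length)) {
    rlang::abort("turn lengths must lie strictly inside (0, chrom_length)")
  }
  structure(list(
    chrom_length = chrom_length, turn_length = turn_length,
    exp_scale = exp_scale, bump_sigma = bump_sigma,
    bump_weight = bump_weight, n_pairs = n_pairs, chrom = chrom, seed = seed
  ), class = "helical_signal_spec")
}

local_turn_length <- function(pos, turn_length, chrom_length) {
  if (is.numeric(turn_length)) return(rep(turn_length, length(pos)))
  prof <- turn_length[order(turn_length$start), , drop = FALSE]
  i <- findInterval(pos, c(prof$start, chrom_length), rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(prof))
  prof$turn_length[i]
}

#' Generate metaphase-like contact pairs with a helical bump
#'
#' For each pair a left endpoint is drawn uniformly on the chromosome and a
#' separation from the mixture
#' `(1 - w) * Exp(exp_scale) + w * Normal(turn_length(left), bump_sigma)`;
#' draws whose right endpoint falls off the chromosome (or whose separation
#' is non-positive) are redrawn, so the bump is undistorted away from the
#' chromosome ends. Byte-identical output for a fixed seed.
#'
#' @param spec A [helical_signal_spec()].
#' @return A [contact_pairs] tibble.
#' @export
generate_helical_pairs <- function(spec) {
  stopifnot(inherits(spec, "helical_signal_spec"))
  cs <- stats::setNames(spec$chrom_length, spec$chrom)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  n <- spec$n_pairs
  pos1 <- numeric(0)
  sep <- numeric(0)
  while (length(pos1) < n) {
    todo <- n - length(pos1)
    draw <- ceiling(todo * 1.4) + 16
    p1 <- floor(stats::runif(draw, 0, spec$chrom_length))
    bump <- stats::runif(draw) < spec$bump_weight
    d <- ifelse(
      bump,
      stats::rnorm(draw, local_turn_length(p1, spec$turn_length, spec$chrom_length),
                   spec$bump_sigma),
      stats::rexp(draw, rate = 1 / spec$exp_scale)
    )
    keep <- d >= 1 & (p1 + d) < spec$chrom_length
    pos1 <- c(pos1, p1[keep])
    sep <- c(sep, d[keep])
  }
  pos1 <- pos1[seq_len(n)]
  sep <- floor(sep[seq_len(n)])

  recs <- tibble::tibble(
    readID = sprintf("synth%08d", seq_len(n)),
    chrom1 = spec$chrom, pos1 = pos1,
    chrom2 = spec$chrom, pos2 = pos1 + sep,
    strand1 = "+", strand2 = "-"
  )
  contact_pairs(recs, cs)
}

#' Generate interphase-like contact pairs (pure power-law decay)
#'
#' Separations follow a truncated power law `s^exponent` on
#' `[100 kb, chrom_length)` (drawn by inverse-CDF sampling), with uniform
#' left endpoints and off-chromosome redraws. No helical bump.
#'
#' @param chrom_length Chromosome length (bp).
#' @param exponent Power-law exponent; must be negative.
#' @param n_pairs Number of pairs.
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @param s_min Lower truncation of the separation distribution (bp).
#' @return A [contact_pairs] tibble.
#' @export
generate_interphase_pairs <- function(chrom_length, exponent = -0.7,
                                      n_pairs = 1e5, chrom = "chrS",
                                      seed = 1, s_min = 1e5) {
  if (exponent >= 0) rlang::abort("power-law exponent must be negative")
  cs <- stats::setNames(chrom_length, chrom)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  a <- exponent + 1
  smax <- chrom_length
  rpow <- function(k) {
    u <- stats::runif(k)
    if (abs(a) < 1e-12) {
      exp(log(s_min) + u * (log(smax) - log(s_min)))
    } else {
      (s_min^a + u * (smax^a - s_min^a))^(1 / a)
    }
  }
  pos1 <- numeric(0)
  sep <- numeric(0)
  while (length(pos1) < n_pairs) {
    todo <- n_pairs - length(pos1)
    draw <- ceiling(todo * 1.4) + 16
    p1 <- floor(stats::runif(draw, 0, chrom_length))
    d <- rpow(draw)
    keep <- (p1 + d) < chrom_length
    pos1 <- c(pos1, p1[keep])
    sep <- c(sep, d[keep])
  }
  pos1 <- pos1[seq_len(n_pairs)]
  sep <- floor(sep[seq_len(n_pairs)])
  recs <- tibble::tibble(
    readID = sprintf("synth%08d", seq_len(n_pairs)),
    chrom1 = chrom, pos1 = pos1, chrom2 = chrom, pos2 = pos1 + sep,
    strand1 = "+", strand2 = "-"
  )
  contact_pairs(recs, cs)
}

#' Ideal helical conformation with optional loop blur
#'
#' Places beads exactly on the analytic helical path of the given geometry
#' and adds isotropic Gaussian displacements of scale `loop_blur_nm`,
#' mimicking the stochastic positioning of chromatin loops around the axis.
#'
#' @param turn_length_bp Genomic turn length (bp).
#' @param n_turns Number of turns to build.
#' @param params A [helix_params()]; `m * l0` sets the bp per bead.
#' @param loop_blur_nm Standard deviation of the isotropic blur (nm).
#' @param seed Integer seed for the blur.
#' @return A `conformation` tibble.
#' @export
generate_ideal_helix_conformation <- function(turn_length_bp, n_turns,
                                              params = helix_params(),
                                              loop_blur_nm = 0, seed = 1) {
  path <- build_helical_path(turn_length_bp, params,
                             span_bp = n_turns * turn_length_bp)
  coords <- as.matrix(path[, c("x", "y", "z")])
  if (loop_blur_nm > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    coords <- coords + matrix(stats::rnorm(length(coords), sd = loop_blur_nm),
                              ncol = 3)
  }
  new_conformation(coords, params$m * params$l0)
}
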