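# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's optimized code paths.

# exhaustive P(s): enumerate every ordered locus pair per chromosome and every
# observed pair, bin both by separation
oracle_pcurve <- function(pairs, bins, bin_size) {
  cs <- chrom_sizes(pairs)
  edges <- c(bins$s_lo, bins$s_hi[nrow(bins)])
  nb <- nrow(bins)
  assign_bin <- function(s) {
    i <- findInterval(s, edges)
    ifelse(i < 1 | i > nb, NA_integer_, i)
  }
  n_obs <- integer(nb)
  intra <- pairs[pairs$intra, ]
  if (nrow(intra) > 0) {
    for (r in seq_len(nrow(intra))) {
      b <- assign_bin(abs(intra$pos1[r] - intra$pos2[r]))
      if (!is.na(b)) n_obs[b] <- n_obs[b] + 1L
    }
  }
  n_possible <- numeric(nb)
  for (L in cs) {
    n_loci <- floor(L / bin_size)
    if (n_loci < 2) next
    for (i in seq_len(n_loci - 1)) {
      for (j in seq(i + 1, n_loci)) {
        b <- assign_bin((j - i) * bin_size)
        if (!is.na(b)) n_possible[b] <- n_possible[b] + 1
      }
    }
  }
  list(n_obs = n_obs, n_possible = n_possible,
       p = ifelse(n_possible > 0, n_obs / n_possible, NA_real_))
}

# all-pairs contact search
oracle_contacts <- function(coords, radius) {
  n <- nrow(coords)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= radius) {
        out[[length(out) + 1]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0) return(matrix(integer(), 0, 2))
  do.call(rbind, out)
}

# count cos(theta) cycles by positive-going zero crossings plus fractional
# remainder; independent of the cumulative-angle bookkeeping
oracle_cos_cycles <- function(theta_deg) {
  th <- theta_deg * pi / 180
  fine <- approx(seq_along(th), th, n = length(th) * 50)$y
  s <- sin(fine)
  crossings <- sum(s[-length(s)] < 0 & s[-1] >= 0 & diff(fine) > 0)
  # remainder beyond the last full cycle
  crossings + (fine[length(fine)] - 2 * pi * crossings) / (2 * pi)
}

toy_pairs <- function(pos1, pos2, chrom = "chr1", L = 2e7,
                      chrom2 = chrom) {
  contact_pairs(
    tibble::tibble(chrom1 = chrom, pos1 = pos1, chrom2 = chrom2, pos2 = pos2),
    stats::setNames(rep(L, length(unique(c(chrom, chrom2)))),
                    unique(c(chrom, chrom2)))
  )
}

# generative model of sister-chromatid exchanges on a helical chromonema:
# sub-turn exchanges are one chromonema thickness high with partial width,
# exchanges of >= 1 turn stack whole turns and span the chromatid
gen_sce_segments <- function(n, seed, thickness = 400, chromatid_width = 800) {
  set.seed(seed)
  turns <- runif(n, 0.05, 3)
  sub <- turns < 1
  height <- ifelse(
    sub,
    runif(n, 320, 520),
    thickness * floor(turns + runif(n)) * runif(n, 0.95, 1.2)
  )
  height <- pmax(height, 310)
  width_frac <- ifelse(sub, runif(n, 0.25, 0.85), runif(n, 0.92, 1))
  tibble::tibble(
    height = height,
    width = width_frac * chromatid_width,
    chromatid_width = chromatid_width
  )
}

# small bottle-brush used by several simulation tests (1000 beads, loop and
# turn geometry consistent so the tether carries no built-in strain)
small_brush <- function(seed = 3) {
  arch <- sample_loop_architecture(
    1e6, m = 1000, major_mean_bp = 2e4, minor_mean_bp = 2e3, seed = seed
  )
  conf <- init_conformation(
    arch, turn_length_bp = 2e5, n_turns = 5, turn_height = 100,
    path_radius = 100, seed = seed
  )
  list(arch = arch, conf = conf)
}
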