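test_that("regional pair attribution follows the endpoint-or-spanning rule", {
  # 20 Mb chromosome, region [5, 10) Mb, 8 hand-placed pairs
  pos1 <- c(6e6, 4e6, 1e6, 9.9e6, 4.5e6, 12e6, 5e6, 3e6)
  pos2 <- c(8e6, 12e6, 3e6, 15e6, 5.5e6, 18e6, 9.999e6, 4.9e6)
  pr <- toy_pairs(pos1, pos2, L = 2e7)
  h <- regional_histogram(pr, "chr1", 5e6, 1e7,
                          bins = log_distance_bins(1e5, 2e7, 10))
  # exhaustive rule evaluation
  a <- pmin(pos1, pos2); b <- pmax(pos1, pos2)
  qualifies <- (a >= 5e6 & a < 1e7) | (b >= 5e6 & b < 1e7) | (a < 5e6 & b >= 1e7)
  expect_equal(sum(h$count), sum(qualifies & (b - a) >= 1e5))
  # the spanning pair (4, 12) counts, the distal (1, 3) does not
  expect_true(qualifies[2])
  expect_false(qualifies[3])
})

test_that("empty regions give all-zero histograms and pairs are never double-counted", {
  pr <- toy_pairs(numeric(), numeric(), L = 2e7)
  h <- regional_histogram(pr, "chr1", 5e6, 1e7)
  expect_true(all(h$count == 0))

  # both ends inside the region: exactly one count
  pr2 <- toy_pairs(6e6, 8e6, L = 2e7)
  h2 <- regional_histogram(pr2, "chr1", 5e6, 1e7)
  expect_equal(sum(h2$count), 1)

  expect_error(regional_histogram(pr2, "chr1", 1.9e7, 2.5e7), "outside")
})

test_that("every intra pair is attributed to at least one region", {
  set.seed(12)
  L <- 5e7
  p1 <- sample.int(L - 2e5, 200) - 1
  sep <- sample.int(2e7, 200)
  pr <- toy_pairs(p1, pmin(p1 + sep, L - 1), L = L)
  regs <- seq(0, L - 5e6, by = 5e6)
  a <- pmin(pr$pos1, pr$pos2); b <- pmax(pr$pos1, pr$pos2)
  covered <- rep(FALSE, nrow(pr))
  for (st in regs) {
    en <- st + 5e6
    covered <- covered |
      (a >= st & a < en) | (b >= st & b < en) | (a < st & b >= en)
  }
  expect_true(all(covered))
})

test_that("the exp+Gaussian fitter recovers mixture parameters", {
  set.seed(21)
  n <- 2e5
  bump <- runif(n) < 0.3
  s <- ifelse(bump, rnorm(n, 3e7, 5e6), rexp(n, 1 / 5e6))
  s <- s[s >= 1e5 & s < 2e8]
  bins <- log_distance_bins(1e5, 2e8, 30)
  idx <- findInterval(s, c(bins$s_lo, bins$s_hi[nrow(bins)]))
  h <- tibble::tibble(
    s_lo = bins$s_lo, s_hi = bins$s_hi, s_mid = bins$s_mid,
    count = tabulate(idx, nbins = nrow(bins))
  )
  fit <- fit_exp_gauss(h)
  expect_true(fit$converged)
  expect_true(fit$gauss_detected)
  expect_lt(abs(fit$mu - 3e7), 1e6)

  # glance/tidy expose the fit tabularly
  g <- glance(fit)
  expect_equal(g$turn_length, fit$mu)
  expect_equal(nrow(tidy(fit)), 5)
})

test_that("a pure exponential yields no detected Gaussian", {
  set.seed(22)
  s <- rexp(2e5, 1 / 5e6)
  s <- s[s >= 1e5]
  bins <- log_distance_bins(1e5, 2e8, 30)
  idx <- findInterval(s, c(bins$s_lo, bins$s_hi[nrow(bins)]))
  h <- tibble::tibble(
    s_lo = bins$s_lo, s_hi = bins$s_hi, s_mid = bins$s_mid,
    count = tabulate(idx, nbins = nrow(bins))
  )
  fit <- fit_exp_gauss(h)
  expect_false(fit$gauss_detected)
})

test_that("underpowered regions are refused", {
  bins <- log_distance_bins(1e5, 1e8, 10)
  h <- tibble::tibble(s_lo = bins$s_lo, s_hi = bins$s_hi, s_mid = bins$s_mid,
                      count = c(10, rep(0, nrow(bins) - 1)))
  expect_error(fit_exp_gauss(h), "underpowered")
})

test_that("profiles recover a constant turn length and tile the chromosome", {
  sp <- helical_signal_spec(1e8, turn_length = 3e7, n_pairs = 20 * 2e4, seed = 31)
  pr <- generate_helical_pairs(sp)
  prof <- turn_length_profile(pr)
  expect_s3_class(prof, "turn_length_profile")
  # tiling: contiguous regions covering [0, L)
  expect_equal(prof$start, seq(0, 9.5e7, by = 5e6))
  expect_equal(prof$end[-nrow(prof)], prof$start[-1])
  expect_equal(prof$end[nrow(prof)], 1e8)
  ok <- prof$artifact_flag == "ok"
  interior <- prof$start >= 1e7 & prof$end <= 9e7
  expect_gt(sum(ok & interior), 10)
  expect_lt(median(abs(prof$turn_length[ok & interior] - 3e7)), 2e6)
})

test_that("a turn-length gradient is recovered monotonically after smoothing", {
  track <- tibble::tibble(
    start = seq(0, 1.45e8, by = 5e6),
    end = seq(5e6, 1.5e8, by = 5e6),
    turn_length = seq(2e7, 3.8e7, length.out = 30)
  )
  sp <- helical_signal_spec(1.5e8, turn_length = track, n_pairs = 30 * 3e4,
                            seed = 32)
  pr <- generate_helical_pairs(sp)
  prof <- turn_length_profile(pr)
  interior <- which(prof$start >= 1e7 & prof$end <= 1.4e8 &
                      !is.na(prof$turn_length))
  sm <- stats::filter(prof$turn_length[interior], rep(1 / 3, 3), sides = 2)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) > -1e6))
  expect_gt(sm[length(sm)], sm[1])
})

test_that("masked and signal-free regions are flagged without disturbing neighbours", {
  # turn length close to twice the region size, so neighbours of a disrupted
  # region keep the bump carried by their own endpoint-attributed pairs
  sp <- helical_signal_spec(6e7, turn_length = 1.2e7, exp_scale = 3e6,
                            bump_sigma = 2e6, n_pairs = 2e5, seed = 33)
  pr <- generate_helical_pairs(sp)

  masked <- turn_length_profile(
    pr, masks = tibble::tibble(chrom = "chrS", start = 2.5e7, end = 3e7),
    mu_bounds = c(1e7, 4e7)
  )
  expect_equal(masked$artifact_flag[masked$start == 2.5e7], "no_signal")
  expect_true(is.na(masked$turn_length[masked$start == 2.5e7]))

  # replace one region's pairs by pure-exponential noise
  target <- c(2.5e7, 3e7)
  a <- pmin(pr$pos1, pr$pos2); b <- pmax(pr$pos1, pr$pos2)
  in_target <- (a >= target[1] & a < target[2]) |
    (b >= target[1] & b < target[2]) | (a < target[1] & b >= target[2])
  noise <- generate_helical_pairs(helical_signal_spec(
    6e7, turn_length = 1.2e7, exp_scale = 3e6, bump_weight = 0,
    n_pairs = 2e5, seed = 34
  ))
  na <- pmin(noise$pos1, noise$pos2); nb <- pmax(noise$pos1, noise$pos2)
  n_in <- (na >= target[1] & na < target[2]) |
    (nb >= target[1] & nb < target[2]) | (na < target[1] & nb >= target[2])
  mixed <- contact_pairs(
    dplyr::bind_rows(tibble::as_tibble(pr)[!in_target, ],
                     tibble::as_tibble(noise)[n_in, ]),
    chrom_sizes(pr)
  )
  prof <- turn_length_profile(mixed, mu_bounds = c(1e7, 4e7))
  expect_equal(prof$artifact_flag[prof$start == 2.5e7], "no_signal")
  neighbours <- prof$artifact_flag[prof$start %in% c(2e7, 3e7)]
  expect_true(all(neighbours == "ok"))
})

test_that("flags annotate but never alter fitted turn lengths", {
  sp <- helical_signal_spec(6e7, turn_length = 2e7, exp_scale = 3e6,
                            bump_sigma = 3e6, n_pairs = 1e5, seed = 35)
  pr <- generate_helical_pairs(sp)
  p1 <- turn_length_profile(pr, mu_bounds = c(1e7, 4e7), jump_factor = 1.5)
  p2 <- turn_length_profile(pr, mu_bounds = c(1e7, 4e7), jump_factor = 1.01)
  expect_equal(p1$turn_length, p2$turn_length)
})

test_that("profiles refuse chromosomes shorter than the region size", {
  pr <- toy_pairs(1e5, 2e6, L = 3e6)
  expect_error(turn_length_profile(pr, region_size = 5e6), "shorter")
})
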