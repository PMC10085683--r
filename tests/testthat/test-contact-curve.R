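test_that("log bins hit their endpoints with a constant edge ratio", {
  b <- log_distance_bins(1e5, 1e9, 10)
  edges <- c(b$s_lo, b$s_hi[nrow(b)])
  expect_equal(edges[1], 1e5)
  expect_equal(edges[length(edges)], 1e9)
  ratios <- edges[-1] / edges[-length(edges)]
  expect_lt(diff(range(ratios)) / ratios[1], 1e-9)
  expect_equal(nrow(b), 40)
})

test_that("a single-separation toy puts all probability mass in one bin", {
  pr <- toy_pairs(pos1 = rep(0, 10) + seq(0, 9) * 1e4,
                  pos2 = rep(150000, 10) + seq(0, 9) * 1e4, L = 6e5)
  bins <- log_distance_bins(1e5, 6e5, 10)
  cv <- contact_probability(pr, bins, bin_size = 1e5)
  hit <- which(cv$s_lo <= 1.5e5 & cv$s_hi > 1.5e5)
  expect_true(all(cv$n_obs[-hit] == 0))
  expect_equal(sum(cv$n_obs), 10)
  expect_true(all(is.na(cv$p[cv$n_possible == 0])))
})

test_that("contact probability matches exhaustive enumeration on toy inputs", {
  # 6-locus toy: 600 kb chromosome, 100 kb loci, 5 hand-placed pairs
  pr <- toy_pairs(
    pos1 = c(50000, 50000, 120000, 200000, 10000),
    pos2 = c(151000, 360000, 520000, 310000, 590000),
    L = 6e5
  )
  bins <- log_distance_bins(1e5, 6e5, 10)
  cv <- contact_probability(pr, bins, bin_size = 1e5)
  orc <- oracle_pcurve(pr, bins, 1e5)
  expect_identical(cv$n_obs, as.integer(orc$n_obs))
  expect_equal(cv$n_possible, orc$n_possible)
  expect_equal(cv$p, orc$p)

  # property: random toys up to 200 loci agree bin-for-bin with enumeration
  set.seed(99)
  for (rep in 1:5) {
    L <- sample(5:20, 1) * 1e5
    n <- sample(20:60, 1)
    p1 <- sample.int(L - 1, n, replace = TRUE) - 1
    sep <- pmin(sample.int(L / 2, n, replace = TRUE), L - 1 - p1)
    pr <- toy_pairs(p1, p1 + sep, L = L)
    bins <- log_distance_bins(1e5, L, 8)
    cv <- contact_probability(pr, bins, bin_size = 1e5)
    orc <- oracle_pcurve(pr, bins, 1e5)
    expect_identical(cv$n_obs, as.integer(orc$n_obs))
    expect_equal(cv$n_possible, orc$n_possible)
  }
})

test_that("observed counts are conserved across bins", {
  sp <- helical_signal_spec(5e7, turn_length = 5e6, exp_scale = 2e6,
                            bump_sigma = 1e6, n_pairs = 2e4, seed = 8)
  pr <- generate_helical_pairs(sp)
  bins <- log_distance_bins(1e5, 5e7, 10)
  cv <- contact_probability(pr, bins)
  s <- abs(pr$pos1 - pr$pos2)
  expect_equal(sum(cv$n_obs), sum(s >= 1e5 & s < 5e7))
})

test_that("normalization pins the 100 kb bin to 1 and is idempotent", {
  sp <- helical_signal_spec(5e7, turn_length = 5e6, n_pairs = 2e4, seed = 8)
  cv <- contact_probability(generate_helical_pairs(sp),
                            log_distance_bins(1e5, 5e7, 10))
  n1 <- normalize_curve(cv, 1e5)
  expect_identical(n1$p[1], 1)
  n2 <- normalize_curve(n1, 1e5)
  expect_identical(n2$p, n1$p)
})

test_that("log derivative recovers power-law exponents exactly", {
  bins <- log_distance_bins(1e5, 1e9, 10)
  curve <- chromonema:::new_contact_curve(tibble::tibble(
    s_lo = bins$s_lo, s_hi = bins$s_hi, s_mid = bins$s_mid,
    n_obs = 1L, n_possible = 1, p = bins$s_mid^-0.5
  ))
  d <- log_derivative(curve)
  expect_true(all(abs(d$dlog_p + 0.5) < 1e-6))

  curve$p <- rep(0.3, nrow(curve))
  d0 <- log_derivative(curve)
  expect_true(all(abs(d0$dlog_p) < 1e-12))
})

test_that("the derivative of an exp+Gaussian curve crosses zero near the bump centre", {
  bins <- log_distance_bins(1e5, 1e9, 10)
  mu <- 3e7
  p <- exp(-bins$s_mid / 5e6) + 0.5 * exp(-(bins$s_mid - mu)^2 / (2 * 5e6^2))
  curve <- chromonema:::new_contact_curve(tibble::tibble(
    s_lo = bins$s_lo, s_hi = bins$s_hi, s_mid = bins$s_mid,
    n_obs = 1L, n_possible = 1, p = p
  ))
  d <- log_derivative(curve)
  # the sign change from rising bump to decay must happen within one bin of mu
  up <- which(d$dlog_p[-nrow(d)] > 0 & d$dlog_p[-1] <= 0 & d$s_mid[-nrow(d)] > 1e6)
  expect_gte(length(up), 1)
  cross <- d$s_mid[up[1] + 1]
  mu_bin <- which(bins$s_lo <= mu & bins$s_hi > mu)
  cross_bin <- which(bins$s_lo <= cross & bins$s_hi > cross)
  expect_lte(abs(cross_bin - mu_bin), 1)
})

test_that("log derivative needs three defined bins", {
  bins <- log_distance_bins(1e5, 1e6, 4)
  curve <- chromonema:::new_contact_curve(tibble::tibble(
    s_lo = bins$s_lo, s_hi = bins$s_hi, s_mid = bins$s_mid,
    n_obs = 0L, n_possible = 1, p = c(1, 2, NA, NA)[seq_len(nrow(bins))]
  ))
  expect_error(log_derivative(curve), "at least 3")
})

test_that("ratio curves divide bin-wise and mark undefined denominators", {
  bins <- log_distance_bins(1e5, 1e8, 10)
  base <- tibble::tibble(
    s_lo = bins$s_lo, s_hi = bins$s_hi, s_mid = bins$s_mid,
    n_obs = 1L, n_possible = 1, p = bins$s_mid^-0.6
  )
  a <- chromonema:::new_contact_curve(base)
  r <- ratio_curve(a, a)
  expect_true(all(abs(r$ratio - 1) < 1e-12))

  # metaphase-like bump over interphase-like power law peaks at the bump
  mu <- 3e7
  meta <- base
  meta$p <- bins$s_mid^-0.6 * (1 + 3 * exp(-(bins$s_mid - mu)^2 / (2 * 5e6^2)))
  m <- chromonema:::new_contact_curve(meta)
  r2 <- ratio_curve(m, a)
  peak_bin <- which.max(r2$ratio)
  mu_bin <- which(bins$s_lo <= mu & bins$s_hi > mu)
  expect_lte(abs(peak_bin - mu_bin), 1)

  # zero denominator propagates as NA, no error
  b0 <- base
  b0$p[5] <- 0
  r3 <- ratio_curve(m, chromonema:::new_contact_curve(b0))
  expect_true(is.na(r3$ratio[5]))

  bins2 <- log_distance_bins(1e5, 1e7, 10)
  other <- chromonema:::new_contact_curve(tibble::tibble(
    s_lo = bins2$s_lo, s_hi = bins2$s_hi, s_mid = bins2$s_mid,
    n_obs = 1L, n_possible = 1, p = 1
  ))
  expect_error(ratio_curve(a, other), "binned differently")
})

test_that("contact probability refuses inputs without intra pairs", {
  pr <- toy_pairs(100, 200, chrom = "chr1", chrom2 = "chr2", L = 1e6)
  expect_error(contact_probability(pr, log_distance_bins(1e5, 1e6, 4)),
               "no usable contacts")
})
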