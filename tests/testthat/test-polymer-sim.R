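test_that("loop architectures are reproducible and match their target means", {
  a1 <- sample_loop_architecture(1.5e8, m = 200, seed = 17)
  a2 <- sample_loop_architecture(1.5e8, m = 200, seed = 17)
  expect_identical(a1$major_bases, a2$major_bases)
  expect_identical(a1$minor_bases, a2$minor_bases)
  a3 <- sample_loop_architecture(1.5e8, m = 200, seed = 18)
  expect_false(identical(a1$major_bases, a3$major_bases))

  # ~50 major loops expected for 150 Mb at 3 Mb means; a 99% interval for a
  # count with Poisson-like dispersion around 50 is roughly 50 +/- 2.6*sqrt(50)
  n_major <- length(a1$major_bases)
  expect_gt(n_major, 50 - 2.6 * sqrt(50))
  expect_lt(n_major, 50 + 2.6 * sqrt(50))
  mean_major_bp <- 1.5e8 / n_major
  expect_lt(abs(mean_major_bp - 3e6) / 3e6, 0.15)

  expect_error(
    sample_loop_architecture(1.5e8, major_mean_bp = 3e6, minor_mean_bp = 4e6),
    "minor_mean_bp < major_mean_bp"
  )
})

test_that("architectures round-trip through JSON", {
  a <- sample_loop_architecture(5e6, m = 1000, major_mean_bp = 5e5,
                                minor_mean_bp = 1e5, seed = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_architecture_json(a, f)
  back <- read_architecture_json(f)
  expect_identical(back$major_bases, a$major_bases)
  expect_identical(back$minor_bases, a$minor_bases)
  expect_equal(tibble::as_tibble(back$loops), tibble::as_tibble(a$loops))
})

test_that("major loops partition the chain and minors nest inside them", {
  a <- sample_loop_architecture(5e7, m = 1000, major_mean_bp = 2e6,
                                minor_mean_bp = 4e5, seed = 5)
  majors <- a$loops[a$loops$level == "major", ]
  expect_equal(majors$start[1], 1L)
  expect_equal(majors$end[nrow(majors)], a$n_monomers)
  expect_equal(majors$start[-1], majors$end[-nrow(majors)] + 1L)
  # every minor base strictly inside one major loop (not at its start)
  owner <- findInterval(a$minor_bases, majors$start)
  expect_true(all(a$minor_bases > majors$start[owner] &
                    a$minor_bases <= majors$end[owner]))
})

test_that("initial conformations place loop bases on the analytic helix", {
  sb <- small_brush(seed = 7)
  conf <- sb$conf
  expect_equal(nrow(conf), 1e6 / 1000)
  anchors <- attr(conf, "anchors")
  ti <- attr(conf, "tether_idx")
  cm <- as.matrix(conf[, c("x", "y", "z")])
  expect_lt(max(abs(cm[ti, ] - anchors)), 1e-6)
  # no coincident beads
  expect_gt(min(dist(cm[sample(nrow(cm), 200), ])), 0)
  # loop apices sit farther from the axis than the bases
  arch <- sb$arch
  seg_end <- c(arch$major_bases[-1] - 1L, arch$n_monomers)
  apex <- floor((arch$major_bases + seg_end) / 2)
  rad <- function(i) sqrt(cm[i, 1]^2 + cm[i, 2]^2)
  expect_gt(mean(rad(apex)), mean(rad(arch$major_bases)))

  expect_error(
    init_conformation(sb$arch, turn_length_bp = 3e6, n_turns = 5),
    "spans"
  )
})

test_that("half-helical folding keeps |x| and brings opposite half-turns together", {
  arch <- sample_loop_architecture(1e6, m = 1000, major_mean_bp = 2e4,
                                   minor_mean_bp = 2e3, seed = 9)
  hel <- init_conformation(arch, turn_length_bp = 2e5, n_turns = 5,
                           turn_height = 100, path_radius = 100, seed = 9)
  hh <- init_conformation(arch, turn_length_bp = 2e5, n_turns = 5,
                          turn_height = 100, path_radius = 100,
                          variant = "half_helical", seed = 9)
  ah <- attr(hel, "anchors")
  af <- attr(hh, "anchors")
  expect_true(all(af[, 1] >= 0))
  expect_equal(af[, 2], ah[, 2])
  expect_equal(af[, 3], ah[, 3])
  expect_equal(af[, 1], abs(ah[, 1]))

  # anchors half a turn apart get closer once folded
  per_turn <- length(arch$major_bases) / 5
  half <- round(per_turn / 2)
  i <- 1:(nrow(ah) - half)
  d_hel <- sqrt(rowSums((ah[i, , drop = FALSE] - ah[i + half, , drop = FALSE])^2))
  d_half <- sqrt(rowSums((af[i, , drop = FALSE] - af[i + half, , drop = FALSE])^2))
  expect_lt(mean(d_half), mean(d_hel))
})

test_that("max_blocks = 0 returns the conformation unchanged", {
  sb <- small_brush(seed = 4)
  sim <- simulate_chromonema(sb$conf, max_blocks = 0, seed = 4)
  expect_equal(as.matrix(sim$conformation[, c("x", "y", "z")]),
               as.matrix(sb$conf[, c("x", "y", "z")]))
  expect_false(sim$converged)
  expect_null(sim$curve)
})

test_that("trajectories are reproducible per seed", {
  sb <- small_brush(seed = 6)
  s1 <- simulate_chromonema(sb$conf, max_blocks = 2, block_steps = 300, seed = 11)
  s2 <- simulate_chromonema(sb$conf, max_blocks = 2, block_steps = 300, seed = 11)
  expect_identical(as.matrix(s1$conformation[, c("x", "y", "z")]),
                   as.matrix(s2$conformation[, c("x", "y", "z")]))
  s3 <- simulate_chromonema(sb$conf, max_blocks = 2, block_steps = 300, seed = 12)
  expect_false(identical(as.matrix(s1$conformation[, c("x", "y", "z")]),
                         as.matrix(s3$conformation[, c("x", "y", "z")])))
})

test_that("equilibrated bonds and tethers match harmonic Boltzmann statistics", {
  # excluded volume off isolates the harmonic statistics the oracle describes
  sb <- small_brush(seed = 8)
  par <- sim_params(repulsion_trunc = 0, cylinder_radius = Inf)
  sim <- simulate_chromonema(sb$conf, par, max_blocks = 6, block_steps = 1500,
                             seed = 8)
  cm <- as.matrix(sim$conformation[, c("x", "y", "z")])

  # oracle: E[r] under p(r) ~ r^2 exp(-k (r - r0)^2 / 2), k = kBT/wiggle^2.
  # Bonds adjacent to loop anchors carry bridge strain (anchors are equally
  # spaced regardless of loop length), so the Boltzmann oracle applies to
  # the unstrained chain interior
  r <- seq(0, 25, by = 0.001)
  w <- r^2 * exp(-(r - 10)^2 / 2)
  e_bond <- sum(r * w) / sum(w)
  arch <- sb$arch
  anchors_all <- sort(unique(c(arch$major_bases, arch$minor_bases)))
  near <- (1:(nrow(cm) - 1)) %in% c(anchors_all, anchors_all - 1L)
  bonds <- sqrt(rowSums((cm[-1, ] - cm[-nrow(cm), ])^2))
  expect_lt(abs(mean(bonds[!near]) - e_bond) / e_bond, 0.02)

  # tethered beads flanked by loops of typical length (no bridge strain)
  # stay within 3*sqrt(kBT/k) of their anchors (RMS)
  anchors <- attr(sim$conformation, "anchors")
  ti <- attr(sim$conformation, "tether_idx")
  d <- sqrt(rowSums((cm[ti, ] - anchors)^2))
  loop_len <- diff(c(arch$major_bases, arch$n_monomers + 1L))
  unstrained <- loop_len >= 10 & dplyr::lag(loop_len, default = 100L) >= 10
  expect_gt(sum(unstrained), 5)
  expect_lt(sqrt(mean(d[unstrained]^2)), 3 * sqrt(1 / par$tether_k))
})

test_that("cylindrical confinement keeps beads inside the wall", {
  # derived radius packs volume_per_monomer per bead into the helix height
  dummy <- sim_params()
  expect_equal(chromonema:::confinement_radius(dummy, 3e6, 8000),
               sqrt(3e6 * 11^3 / (pi * 8000)))

  sb <- small_brush(seed = 10)
  par <- sim_params(cylinder_radius = 130)
  sim <- simulate_chromonema(sb$conf, par, max_blocks = 5,
                             block_steps = 1000, confine = TRUE, seed = 10)
  expect_equal(sim$cylinder_radius, 130)
  cm <- as.matrix(sim$conformation[, c("x", "y", "z")])
  rho <- sqrt(cm[, 1]^2 + cm[, 2]^2)
  frac_in <- mean(rho <= sim$cylinder_radius + 3 * sqrt(1 / 10))
  expect_gt(frac_in, 0.99)
})

test_that("unstable integration is reported as an error", {
  sb <- small_brush(seed = 13)
  expect_error(
    simulate_chromonema(sb$conf, sim_params(dt = 50), max_blocks = 1,
                        block_steps = 200, seed = 13),
    "unstable"
  )
})
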