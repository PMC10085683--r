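#' Simulation parameters for the bottle-brush polymer model
#'
#' All energies are in units of kBT and lengths in nm; temperature enters the
#' model only through the kBT scale, so equilibrium statistics match a 300 K
#' simulation with the same reduced constants. The bond spring constant is
#' derived from the thermal wiggle distance as `kBT / wiggle^2`.
#'
#' @param temperature Kelvin, informational (kBT = 1 internally).
#' @param collision_rate Langevin friction per reduced time unit; equilibrium
#'   averages do not depend on it, larger values thermalize faster.
#' @param bond_rest Rest length of chain and loop-anchor bonds (nm).
#' @param bond_wiggle Thermal standard deviation of the bond length (nm).
#' @param angle_k Chain bending stiffness (kBT/rad^2), rest angle straight.
#' @param repulsion_trunc Height of the excluded-volume barrier at zero
#'   separation (kBT); finite so fibres can cross (topoisomerase-permissive).
#'   1.5 by default, 2.5 for the 650 nm confinement variants.
#' @param repulsion_cutoff Range of the repulsion (nm, the bead diameter).
#' @param tether_k Stiffness tethering loop bases to the helical path
#'   (kBT/nm^2).
#' @param confinement_k Stiffness of the cylindrical wall (kBT/nm^2).
#' @param volume_per_monomer Target volume per bead (nm^3) used to size the
#'   confinement cylinder when no radius override is given.
#' @param cylinder_radius Optional explicit confinement radius (nm, e.g. the
#'   650 nm variant); `NA` derives the radius from `volume_per_monomer`;
#'   `Inf` disables confinement.
#' @param contact_radius Distance threshold defining a contact (nm).
#' @param dt Integration step in reduced time units.
#' @param equil_tolerance Convergence threshold: maximum absolute change of
#'   log10 P(s) between consecutive block curves.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(temperature = 300, collision_rate = 0.1,
                       bond_rest = 10, bond_wiggle = 1, angle_k = 1,
                       repulsion_trunc = 1.5, repulsion_cutoff = 10,
                       tether_k = 4, confinement_k = 10,
                       volume_per_monomer = 11^3, cylinder_radius = NA,
                       contact_radius = 51, dt = 0.08,
                       equil_tolerance = 0.05) {
  stopifnot(
    temperature > 0, collision_rate > 0, bond_rest > 0, bond_wiggle > 0,
    angle_k >= 0, repulsion_trunc >= 0, repulsion_cutoff > 0, tether_k >= 0,
    confinement_k >= 0, volume_per_monomer > 0, contact_radius > 0, dt > 0,
    equil_tolerance > 0
  )
  structure(list(
    temperature = temperature, collision_rate = collision_rate,
    bond_rest = bond_rest, bond_wiggle = bond_wiggle, angle_k = angle_k,
    repulsion_trunc = repulsion_trunc, repulsion_cutoff = repulsion_cutoff,
    tether_k = tether_k, confinement_k = confinement_k,
    volume_per_monomer = volume_per_monomer,
    cylinder_radius = cylinder_radius, contact_radius = contact_radius,
    dt = dt, equil_tolerance = equil_tolerance
  ), class = "sim_params")
}

# draw consecutive loop lengths (monomers) with exponential-distributed bp
# lengths around `mean_bp`, covering `n_monomers`; returns loop start indices
sample_loop_starts <- function(n_monomers, mean_bp, m) {
  starts <- integer(0)
  pos <- 1L
  while (pos <= n_monomers) {
    starts <- c(starts, pos)
    len <- max(1L, as.integer(round(stats::rexp(1, rate = 1 / mean_bp) / m)))
    pos <- pos + len
  }
  starts
}

#' Sample a nested major/minor loop architecture
#'
#' The chain of `genome_bp / m` monomers is partitioned into consecutive
#' major loops whose lengths are exponentially distributed around
#' `major_mean_bp` (truncated at one monomer); each major loop is further
#' partitioned into minor loops around `minor_mean_bp`. Loop bases are the
#' monomers at which loops anchor to the axis.
#'
#' @param genome_bp Modelled genomic span (bp).
#' @param m Monomer (bead) size in bp.
#' @param major_mean_bp,minor_mean_bp Mean loop lengths (bp).
#' @param seed Integer seed; the architecture is reproducible per seed.
#' @return A list of class `loop_architecture` with `n_monomers`,
#'   `major_bases`, `minor_bases` (interior minor anchors), `loops` (tibble of
#'   `level`, `start`, `end`), and the generating parameters.
#' @export
sample_loop_architecture <- function(genome_bp, m = 200, major_mean_bp = 3e6,
                                     minor_mean_bp = 5e5, seed = 1) {
  if (!(minor_mean_bp < major_mean_bp && major_mean_bp < genome_bp)) {
    rlang::abort("need minor_mean_bp < major_mean_bp < genome_bp")
  }
  n_monomers <- as.integer(floor(genome_bp / m))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  major_starts <- sample_loop_starts(n_monomers, major_mean_bp, m)
  major_ends <- c(major_starts[-1] - 1L, n_monomers)
  minor <- purrr::map2(major_starts, major_ends, function(s, e) {
    sub <- sample_loop_starts(e - s + 1L, minor_mean_bp, m) + s - 1L
    sub
  })
  minor_starts <- unlist(minor)
  minor_ends <- unlist(purrr::map2(minor, major_ends, function(st, e) {
    c(st[-1] - 1L, e)
  }))

  loops <- dplyr::bind_rows(
    tibble::tibble(level = "major", start = major_starts, end = major_ends),
    tibble::tibble(level = "minor", start = minor_starts, end = minor_ends)
  )
  structure(list(
    n_monomers = n_monomers,
    genome_bp = genome_bp,
    m = m,
    major_bases = major_starts,
    minor_bases = setdiff(minor_starts, major_starts),
    loops = loops,
    major_mean_bp = major_mean_bp,
    minor_mean_bp = minor_mean_bp,
    seed = seed
  ), class = "loop_architecture")
}

#' Write a loop architecture as JSON
#' @param arch A [sample_loop_architecture()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_architecture_json <- function(arch, path) {
  jsonlite::write_json(
    list(
      n_monomers = arch$n_monomers, genome_bp = arch$genome_bp, m = arch$m,
      major_bases = arch$major_bases, minor_bases = arch$minor_bases,
      major_mean_bp = arch$major_mean_bp, minor_mean_bp = arch$minor_mean_bp,
      seed = arch$seed,
      loops = arch$loops
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a loop architecture from JSON
#' @param path A file written by [write_architecture_json()].
#' @return A `loop_architecture` list.
#' @export
read_architecture_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$major_bases <- as.integer(x$major_bases)
  x$minor_bases <- as.integer(x$minor_bases)
  x$n_monomers <- as.integer(x$n_monomers)
  x$loops <- tibble::as_tibble(x$loops)
  x$loops$start <- as.integer(x$loops$start)
  x$loops$end <- as.integer(x$loops$end)
  structure(x[c("n_monomers", "genome_bp", "m", "major_bases", "minor_bases",
                "loops", "major_mean_bp", "minor_mean_bp", "seed")],
            class = "loop_architecture")
}

#' @export
print.loop_architecture <- function(x, ...) {
  cat("loop_architecture: ", x$n_monomers, " monomers (", x$m, " bp each), ",
      length(x$major_bases), " major / ",
      length(x$major_bases) + length(x$minor_bases), " minor loops\n", sep = "")
  invisible(x)
}

# stash/restore the global RNG state so seeded generators do not perturb it
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

new_conformation <- function(coords, bp_per_monomer, anchors = NULL,
                             tether_idx = NULL, arch = NULL, step_count = 0) {
  n <- nrow(coords)
  out <- tibble::tibble(
    bead = seq_len(n),
    bp = (seq_len(n) - 0.5) * bp_per_monomer,
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  )
  attr(out, "bp_per_monomer") <- bp_per_monomer
  attr(out, "anchors") <- anchors
  attr(out, "tether_idx") <- tether_idx
  attr(out, "architecture") <- arch
  attr(out, "step_count") <- step_count
  class(out) <- c("conformation", class(tibble::tibble()))
  out
}

coords_matrix <- function(conf) {
  as.matrix(tibble::as_tibble(conf)[, c("x", "y", "z")])
}

#' Fold helical anchors into the half-helical arrangement
#'
#' The half-helical comparison model reverses handedness every half turn; in
#' coordinates this amounts to keeping only the absolute value of the x
#' coordinate when converting the helical path from cylindrical to Cartesian
#' coordinates. Anchors half a turn apart, far apart on the helix, become
#' spatially close.
#'
#' @param anchors A matrix or data frame with columns x, y, z (nm).
#' @return The folded anchors (same shape); y and z are untouched.
#' @export
apply_half_helical <- function(anchors) {
  if (is.matrix(anchors)) {
    anchors[, 1] <- abs(anchors[, 1])
  } else {
    anchors$x <- abs(anchors$x)
  }
  anchors
}

#' Initial bottle-brush conformation on a helical path
#'
#' Places the major-loop base beads equally spaced on a helix with `n_turns`
#' turns of height `turn_height`, and the remaining beads of each loop on a
#' radial out-and-back excursion from their base (loops emerge radially). A
#' small seeded jitter keeps beads from coinciding.
#'
#' @param arch A [sample_loop_architecture()] result spanning
#'   `n_turns * turn_length_bp`.
#' @param turn_length_bp Genomic turn length (bp).
#' @param n_turns Number of helical turns.
#' @param turn_height Axial rise per turn (nm).
#' @param path_radius Helical path radius (nm); when `NULL` it follows from
#'   the Pythagorean relation with `d_sep`.
#' @param d_sep Along-path spacing of consecutive loop bases (nm); ignored
#'   when `path_radius` is given.
#' @param variant `"helical"` or `"half_helical"` (anchors folded to
#'   `|x|` before loops are attached).
#' @param seed Seed for the placement jitter.
#' @return A `conformation` tibble (bead, bp, x, y, z) carrying the anchor
#'   coordinates and tethered bead indices as attributes.
#' @export
init_conformation <- function(arch, turn_length_bp = 30e6, n_turns = 5,
                              turn_height = 400, path_radius = NULL,
                              d_sep = 50, variant = c("helical", "half_helical"),
                              seed = 1) {
  variant <- match.arg(variant)
  span <- n_turns * turn_length_bp
  if (abs(arch$genome_bp - span) > arch$major_mean_bp) {
    rlang::abort(sprintf(
      "architecture spans %.3g bp but n_turns * turn_length_bp = %.3g bp",
      arch$genome_bp, span
    ))
  }
  bases <- arch$major_bases
  K <- length(bases)
  per_turn <- K / n_turns
  if (is.null(path_radius)) {
    path_radius <- sqrt(pmax(0, (d_sep * per_turn)^2 - turn_height^2)) / (2 * pi)
  }
  k <- seq_len(K) - 1
  theta <- k * 2 * pi / per_turn
  anchors <- cbind(
    x = path_radius * cos(theta),
    y = path_radius * sin(theta),
    z = k * turn_height / per_turn
  )
  # intrinsic scaffold spacing between consecutive loop bases (helical
  # geometry); kept as the rest length of anchor-bridging bonds in both
  # variants so the tether geometry is force-free at initialization
  anchor_spacing <- sqrt(rowSums((anchors[-1, , drop = FALSE] -
                                    anchors[-K, , drop = FALSE])^2))
  if (variant == "half_helical") anchors <- apply_half_helical(anchors)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  n <- arch$n_monomers
  coords <- matrix(0, n, 3)
  step_out <- 5  # nm per bead along the excursion (half the bond rest length)
  seg_end <- c(bases[-1] - 1L, n)
  for (kk in seq_len(K)) {
    b <- bases[kk]
    e <- seg_end[kk]
    rho <- sqrt(sum(anchors[kk, 1:2]^2))
    dir_xy <- if (rho > 1e-9) anchors[kk, 1:2] / rho else c(1, 0)
    coords[b, ] <- anchors[kk, ]
    g <- e - b
    if (g > 0) {
      # loop beads ride a radial out-and-back excursion while drifting from
      # this anchor to the next so chain bonds stay near their rest length
      nxt <- if (kk < K) anchors[kk + 1, ] else anchors[kk, ]
      j <- seq_len(g)
      frac <- j / (g + 1)
      excursion <- step_out * pmin(j, g + 1 - j)
      coords[b + j, 1] <- anchors[kk, 1] + (nxt[1] - anchors[kk, 1]) * frac +
        dir_xy[1] * excursion
      coords[b + j, 2] <- anchors[kk, 2] + (nxt[2] - anchors[kk, 2]) * frac +
        dir_xy[2] * excursion
      coords[b + j, 3] <- anchors[kk, 3] + (nxt[3] - anchors[kk, 3]) * frac
    }
  }
  jitter <- matrix(stats::runif(3 * n, -0.5, 0.5), n, 3)
  jitter[bases, ] <- 0  # bases sit exactly on the analytic path
  coords <- coords + jitter

  conf <- new_conformation(coords, arch$m, anchors = anchors,
                           tether_idx = bases, arch = arch)
  attr(conf, "turn_length_bp") <- turn_length_bp
  attr(conf, "n_turns") <- n_turns
  attr(conf, "turn_height") <- turn_height
  attr(conf, "path_radius") <- path_radius
  attr(conf, "variant") <- variant
  attr(conf, "anchor_spacing") <- anchor_spacing
  conf
}

build_bond_table <- function(arch, params, anchor_spacing = NULL) {
  k_bond <- 1 / params$bond_wiggle^2  # kBT / wiggle^2
  n <- arch$n_monomers
  chain <- cbind(seq_len(n - 1L), seq(2L, n))
  loops <- arch$loops
  # side-by-side loops: consecutive anchors of each level are bridged,
  # pinching the intervening chain into a loop (condensin positions)
  anchor_bonds <- function(level) {
    st <- loops$start[loops$level == level]
    en <- loops$end[loops$level == level]
    cbind(st, pmin(en + 1L, n))
  }
  maj <- anchor_bonds("major")
  # major bridges rest at the scaffold spacing of consecutive loop bases so
  # the tethered geometry carries no built-in strain
  maj_r0 <- if (is.null(anchor_spacing)) {
    rep(params$bond_rest, nrow(maj))
  } else {
    c(anchor_spacing, params$bond_rest)[seq_len(nrow(maj))]
  }
  minr <- anchor_bonds("minor")
  # a major loop holding a single minor loop would duplicate the major
  # bridge with a short-rest minor bridge; keep only the major-level bridge
  dup <- minr[, 1] %in% arch$major_bases &
    (minr[, 2] %in% arch$major_bases | minr[, 2] == n)
  minr <- minr[!dup, , drop = FALSE]
  ab <- rbind(maj, minr)
  r0 <- c(maj_r0, rep(params$bond_rest, nrow(minr)))
  keep <- ab[, 1] != ab[, 2]
  bonds <- rbind(chain, ab[keep, , drop = FALSE])
  list(
    bonds = bonds,
    r0 = c(rep(params$bond_rest, nrow(chain)), r0[keep]),
    k = rep(k_bond, nrow(bonds))
  )
}

confinement_radius <- function(params, n_monomers, height) {
  cr <- params$cylinder_radius
  if (!is.null(cr) && length(cr) == 1 && !is.na(cr)) {
    return(if (is.infinite(cr)) -1 else cr)
  }
  sqrt(n_monomers * params$volume_per_monomer / (pi * height))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Langevin-dynamics simulation of the bottle-brush model
#'
#' Integrates the polymer in blocks of `block_steps` Langevin steps. After
#' each block the model contact-probability curve is computed; the run stops
#' when the maximum absolute change of log10 P(s) between consecutive block
#' curves drops below `equil_tolerance` (or when `max_blocks` is exhausted,
#' which is reported, not an error). Only loop-base beads feel the tether;
#' the excluded-volume barrier is finite so strands may cross.
#'
#' @param conf An [init_conformation()] result.
#' @param params A [sim_params()] list.
#' @param max_blocks Maximum number of blocks (0 returns the input unchanged).
#' @param block_steps Langevin steps per block.
#' @param confine Logical: apply the cylindrical confinement (radius from
#'   `params`, height from the helix extent).
#' @param seed Integer seed; trajectories are reproducible per seed.
#' @param curve_bins Optional distance bins for the convergence curve.
#' @return A list of class `chromonema_sim`: `conformation` (final),
#'   `blocks` (per-block convergence summary), `curve` (final normalized
#'   contact curve), `converged`, `params`.
#' @export
simulate_chromonema <- function(conf, params = sim_params(), max_blocks = 30,
                                block_steps = 2000, confine = TRUE, seed = 1,
                                curve_bins = NULL) {
  arch <- attr(conf, "architecture")
  if (is.null(arch)) rlang::abort("conformation carries no loop architecture")
  anchors <- attr(conf, "anchors")
  tether_idx <- attr(conf, "tether_idx")
  bt <- build_bond_table(arch, params, attr(conf, "anchor_spacing"))
  height <- (attr(conf, "n_turns") %||% 5) * (attr(conf, "turn_height") %||% 400)
  cyl_r <- if (confine) confinement_radius(params, arch$n_monomers, height) else -1

  coords <- coords_matrix(conf)
  bp <- attr(conf, "bp_per_monomer")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vel <- matrix(stats::rnorm(3 * nrow(coords)), ncol = 3)

  if (is.null(curve_bins)) {
    lo <- max(1e5, bp)
    hi <- arch$n_monomers * bp
    curve_bins <- log_distance_bins(lo, hi, bins_per_decade = 10)
  }

  block_curve <- function(cm) {
    contacts <- conformation_contacts_matrix(cm, params$contact_radius)
    model_contact_probability(
      contacts, n_monomers = arch$n_monomers, bp_per_monomer = bp,
      bins = curve_bins, normalize_at = 1e5, quiet = TRUE
    )
  }

  blocks <- tibble::tibble(
    block = integer(), steps = integer(), max_dlog10 = numeric()
  )
  converged <- FALSE
  prev_logp <- NULL
  steps_done <- attr(conf, "step_count") %||% 0
  if (max_blocks > 0) {
    for (b in seq_len(max_blocks)) {
      res <- .langevin_block(
        coords, vel, bt$bonds, bt$r0, bt$k, params$angle_k,
        as.integer(tether_idx), anchors[, 1:3, drop = FALSE], params$tether_k,
        params$repulsion_trunc, params$repulsion_cutoff,
        cyl_r, params$confinement_k, params$dt, params$collision_rate,
        as.integer(block_steps), abs(seed) * 1000003 + b
      )
      if (!res$finite) {
        rlang::abort("integration unstable (non-finite coordinates); reduce the step size")
      }
      coords <- res$coords
      vel <- res$vel
      steps_done <- steps_done + block_steps
      curve <- block_curve(coords)
      # convergence is judged on bins with enough contacts to be meaningful
      measured <- !is.na(curve$p) & curve$p > 0 & curve$n_obs >= 20
      logp <- ifelse(measured, log10(curve$p), NA_real_)
      dmax <- if (is.null(prev_logp)) NA_real_ else {
        both <- !is.na(logp) & !is.na(prev_logp)
        if (!any(both)) Inf else max(abs(logp[both] - prev_logp[both]))
      }
      blocks <- dplyr::bind_rows(blocks, tibble::tibble(
        block = b, steps = steps_done, max_dlog10 = dmax
      ))
      prev_logp <- logp
      if (!is.na(dmax) && dmax < params$equil_tolerance) {
        converged <- TRUE
        break
      }
    }
  }

  out_conf <- new_conformation(coords, bp, anchors = anchors,
                               tether_idx = tether_idx, arch = arch,
                               step_count = steps_done)
  for (a in c("turn_length_bp", "n_turns", "turn_height", "path_radius", "variant")) {
    attr(out_conf, a) <- attr(conf, a)
  }
  structure(list(
    conformation = out_conf,
    blocks = blocks,
    curve = if (max_blocks > 0) block_curve(coords) else NULL,
    converged = converged,
    params = params,
    cylinder_radius = cyl_r
  ), class = "chromonema_sim")
}

#' @export
print.chromonema_sim <- function(x, ...) {
  cat("chromonema_sim: ", nrow(x$conformation), " beads, ",
      nrow(x$blocks), " block(s), ",
      if (x$converged) "equilibrated" else "max_blocks reached", "\n", sep = "")
  invisible(x)
}

#' Write a conformation as CSV or XYZ
#' @param conf A `conformation`.
#' @param file Output path; `.xyz` writes an XYZ snapshot, anything else CSV.
#' @return `file`, invisibly.
#' @export
write_conformation <- function(conf, file) {
  if (grepl("\\.xyz$", file)) {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(c(as.character(nrow(conf)), "conformation (nm)"), con)
    writeLines(sprintf("C %.3f %.3f %.3f", conf$x, conf$y, conf$z), con)
  } else {
    readr::write_csv(tibble::as_tibble(conf)[, c("bead", "bp", "x", "y", "z")], file)
  }
  invisible(file)
}
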