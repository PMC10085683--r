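#' Helical path parameters
#'
#' @param m Monomer size in bp (default 200 bp, one nucleosome plus linker).
#' @param l0 Mean major-loop size in monomers (default 15000, i.e. 3 Mb
#'   loops at 200 bp monomers).
#' @param turn_height Axial rise per helical turn in nm (default 400).
#' @param d_sep Spatial spacing of consecutive path monomers along the helix
#'   in nm (default 50; 20 and 100 are the tested variants).
#' @return A list of class `helix_params`.
#' @export
helix_params <- function(m = 200, l0 = 15000, turn_height = 400, d_sep = 50) {
  stopifnot(m > 0, l0 > 0, turn_height > 0, d_sep > 0)
  structure(list(m = m, l0 = l0, turn_height = turn_height, d_sep = d_sep),
            class = "helix_params")
}

#' Path monomers fitting in one helical turn
#'
#' For a turn length `l_i` (bp), a monomer size `m` (bp) and an average major
#' loop of `l0` monomers, the number of path monomers (major-loop bases) per
#' turn is `l_i / m / l0`. With 1 Mb monomers and `l0 = 1` this counts whole
#' megabases per turn, the parameterization used for turn counting.
#'
#' @param l_i Turn length(s) in bp.
#' @param params A [helix_params()].
#' @return Real-valued monomer count(s); round only for reporting.
#' @export
monomers_per_turn <- function(l_i, params = helix_params()) {
  if (any(l_i <= 0)) rlang::abort("turn length must be positive")
  l_i / params$m / params$l0
}

#' Helical radius from monomers per turn
#'
#' One turn unrolls into a right triangle whose hypotenuse is the path length
#' `d_sep * n_i` and whose legs are the circumference `2*pi*r_i` and the turn
#' height, so `r_i = sqrt((d_sep * n_i)^2 - turn_height^2) / (2*pi)`.
#'
#' @param n_i Monomers per turn (real-valued).
#' @param params A [helix_params()].
#' @return Radius in nm (0 for the degenerate vertical path).
#' @export
turn_radius <- function(n_i, params = helix_params()) {
  hyp <- params$d_sep * n_i
  if (any(hyp < params$turn_height)) {
    rlang::abort("turn too short for pitch: d_sep * n_i < turn_height leaves no real radius")
  }
  sqrt(hyp^2 - params$turn_height^2) / (2 * pi)
}

# piecewise-constant turn-length lookup for monomer genomic midpoints;
# regions without a value are filled from the nearest informative region
lookup_turn_length <- function(mids, profile) {
  if (is.numeric(profile) && length(profile) == 1) {
    return(rep(profile, length(mids)))
  }
  prof <- tibble::as_tibble(profile)
  stopifnot(all(c("start", "end", "turn_length") %in% names(prof)))
  prof <- prof[order(prof$start), , drop = FALSE]
  tl <- prof$turn_length
  if (all(is.na(tl))) rlang::abort("profile has no usable turn-length values")
  # nearest-neighbour fill of no_signal regions
  idx_ok <- which(!is.na(tl))
  near <- vapply(seq_along(tl), function(i) {
    if (!is.na(tl[i])) return(tl[i])
    tl[idx_ok[which.min(abs(idx_ok - i))]]
  }, numeric(1))
  i <- findInterval(mids, c(prof$start, prof$end[nrow(prof)]),
                    rightmost.closed = TRUE)
  if (any(i < 1 | i > nrow(prof))) {
    rlang::abort("profile does not cover the modelled span")
  }
  near[i]
}

#' Build the variable-radius helical path
#'
#' Places one path monomer per `m * l0` bp. Each monomer `i` looks up the
#' turn length `l_i` of the profile region containing its genomic midpoint,
#' converts it to monomers-per-turn `n_i`, and advances the path by
#' `turn_height / n_i` in height and `360 / n_i` degrees in angle from the
#' origin `(z, theta) = (0, 0)`; the radius follows from the Pythagorean
#' relation of [turn_radius()]. Angles accumulate without wrapping so turn
#' counting is exact.
#'
#' @param profile A single turn length (bp), or a data frame with columns
#'   `start`, `end`, `turn_length` (e.g. a [turn_length_profile()] or a
#'   BEDGRAPH read with [read_profile_bedgraph()]); `NA` regions are filled
#'   from the nearest informative region.
#' @param params A [helix_params()].
#' @param span_bp Genomic span to model; defaults to the profile extent
#'   (required when `profile` is a single number).
#' @return A tibble of class `helical_path` with per-monomer columns
#'   `index`, `bp_mid`, `l_bp`, `n_i`, `theta_deg` (cumulative), `z_nm`,
#'   `r_nm`, `x`, `y`, `z`.
#' @export
build_helical_path <- function(profile, params = helix_params(),
                               span_bp = NULL) {
  bp_per_monomer <- params$m * params$l0
  if (is.null(span_bp)) {
    if (is.numeric(profile) && length(profile) == 1) {
      rlang::abort("`span_bp` is required when `profile` is a constant")
    }
    span_bp <- max(profile$end) - min(profile$start)
  }
  n_monomers <- floor(span_bp / bp_per_monomer)
  if (n_monomers < 1) rlang::abort("span shorter than one path monomer")
  offset <- if (is.numeric(profile) && length(profile) == 1) 0 else min(profile$start)
  mids <- offset + (seq_len(n_monomers) - 0.5) * bp_per_monomer
  l_bp <- lookup_turn_length(mids, profile)
  n_i <- monomers_per_turn(l_bp, params)
  if (any(params$d_sep * n_i < params$turn_height)) {
    bad <- which(params$d_sep * n_i < params$turn_height)[1]
    rlang::abort(sprintf(
      "turn too short for pitch at monomer %d (genomic midpoint %.0f bp): d_sep * n_i = %.1f nm < turn height %.0f nm",
      bad, mids[bad], params$d_sep * n_i[bad], params$turn_height
    ))
  }
  theta <- cumsum(360 / n_i)
  z <- cumsum(params$turn_height / n_i)
  r <- turn_radius(n_i, params)
  out <- tibble::tibble(
    index = seq_len(n_monomers), bp_mid = mids, l_bp = l_bp, n_i = n_i,
    theta_deg = theta, z_nm = z, r_nm = r,
    x = r * cos(theta * pi / 180), y = r * sin(theta * pi / 180), z = z
  )
  attr(out, "params") <- params
  attr(out, "bp_per_monomer") <- bp_per_monomer
  class(out) <- c("helical_path", class(tibble::tibble()))
  out
}

#' Count helical turns of a path
#'
#' The number of turns is the number of cycles of `cos(theta)` along the
#' path; with the cumulative (unwrapped) angle convention this equals the
#' total accumulated angle divided by 360 degrees, the fractional remainder
#' included.
#'
#' @param path A [build_helical_path()] result.
#' @return Real-valued turn count (round for reporting).
#' @export
count_turns <- function(path) {
  if (nrow(path) == 0) rlang::abort("empty path")
  path$theta_deg[nrow(path)] / 360
}

#' Extrapolate physical chromosome length from a turn count
#'
#' @param turns Number of helical turns.
#' @param per_turn_height_range Two ordered per-turn heights in nm bracketing
#'   the uncertainty (e.g. the measured mean band height and the inferred
#'   pitch).
#' @return Length range in micrometres (`low`, `high`).
#' @export
extrapolate_physical_length <- function(turns, per_turn_height_range) {
  stopifnot(turns > 0, length(per_turn_height_range) == 2)
  if (diff(per_turn_height_range) < 0) {
    rlang::abort("`per_turn_height_range` must be ordered low, high")
  }
  out <- turns * per_turn_height_range / 1000
  names(out) <- c("low", "high")
  out
}

#' Chromatin packing density
#'
#' @param volume Chromatid volume in cubic micrometres.
#' @param dna DNA content in Mb.
#' @return Density in um^3 per Mb.
#' @export
chromatin_density <- function(volume, dna) {
  if (any(volume <= 0) || any(dna <= 0)) {
    rlang::abort("volume and DNA content must be positive")
  }
  volume / dna
}

#' Classify sister-chromatid-exchange segments under the chromonema model
#'
#' A helically wound chromonema of ~400 nm thickness constrains how an
#' exchanged segment can look: a sub-turn exchange is about one chromonema
#' thickness high but need not span the chromatid width; an exchange of one
#' turn or more is at least one thickness high and spans the full width.
#' Segments taller than the thickness band yet narrower than the chromatid
#' violate the model, as do segments shorter than the 300 nm floor.
#'
#' @param segments A data frame with columns `height`, `width`,
#'   `chromatid_width` (all nm).
#' @param thickness_band Height band (nm) compatible with a single chromonema
#'   thickness; defaults to the observed 300-550 nm transition range.
#' @param width_tolerance Fraction of the chromatid width within which a
#'   segment counts as full-width.
#' @return The input tibble with an added factor column `class` with levels
#'   `subturn_consistent`, `multiturn_consistent`, `violation_tall_narrow`,
#'   `violation_too_short`.
#' @export
classify_sce_segments <- function(segments, thickness_band = c(300, 550),
                                  width_tolerance = 0.1) {
  seg <- tibble::as_tibble(segments)
  stopifnot(all(c("height", "width", "chromatid_width") %in% names(seg)))
  if (any(seg$height <= 0 | seg$width <= 0 | seg$chromatid_width <= 0)) {
    rlang::abort("segment dimensions must be positive")
  }
  if (any(seg$width > seg$chromatid_width)) {
    rlang::abort("segment width cannot exceed the chromatid width")
  }
  full <- seg$width >= (1 - width_tolerance) * seg$chromatid_width
  cls <- dplyr::case_when(
    seg$height < thickness_band[1] ~ "violation_too_short",
    full ~ "multiturn_consistent",
    seg$height <= thickness_band[2] ~ "subturn_consistent",
    TRUE ~ "violation_tall_narrow"
  )
  seg$class <- factor(cls, levels = c(
    "subturn_consistent", "multiturn_consistent",
    "violation_tall_narrow", "violation_too_short"
  ))
  seg
}

#' Export a helical path for 3D viewers
#' @param path A `helical_path`.
#' @param file Output path; `.xyz` writes an XYZ snapshot, anything else CSV.
#' @return `file`, invisibly.
#' @export
write_path <- function(path, file) {
  if (grepl("\\.xyz$", file)) {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(c(as.character(nrow(path)), "helical path (nm)"), con)
    writeLines(sprintf("C %.3f %.3f %.3f", path$x, path$y, path$z), con)
  } else {
    readr::write_csv(tibble::as_tibble(path), file)
  }
  invisible(file)
}
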