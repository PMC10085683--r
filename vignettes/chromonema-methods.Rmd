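---
title: "Inferring and modelling the helical coiling of metaphase chromatids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and modelling the helical coiling of metaphase chromatids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(chromonema)
library(dplyr)
```

## The scientific problem

During mitosis, chromatin condenses roughly a thousand-fold into rod-shaped
chromatids. In species with large chromosomes — barley, with ~0.5–0.7 Gb
chromosomes, is the motivating case — the condensed chromatin fibre (the
*chromonema*, a ~400 nm thick thread) winds into a helix. Each helical gyre
covers a genomic span called the **turn length** \(T_l\) (tens of Mb in
barley), and chromatin loops emanate radially from the helically wound loop
bases, giving a *bottle-brush* architecture: major loops (~3 Mb, attributed
to condensin II) subdivided into minor loops (~500 kb, condensin I).

A helix leaves a characteristic fingerprint in chromosome-conformation
capture (Hi-C) data: the contact probability \(P_C(s)\) as a function of
genomic separation \(s\) decays, then rises again into a local maximum
("bump") at \(s \approx T_l\), because loci one full turn apart are brought
back into spatial proximity. This package implements the complete
computational chain around that observation:

1. **`hic_contacts`-style analytics** — \(P_C(s)\) on log-spaced distance
   bins, its log-log derivative, and metaphase/interphase ratio tracks.
2. **Turn-length estimation** — regional exponential-plus-Gaussian fits
   whose Gaussian centre is the local turn length.
3. **Helix geometry** — the explicit variable-radius helical path implied by
   a turn-length profile, turn counting, physical-length extrapolation,
   chromatin density, and the sister-chromatid-exchange (SCE) geometry
   classifier.
4. **Polymer simulation** — a coarse-grained Langevin simulator of the
   bottle-brush model with helical and half-helical tether variants.
5. **Model read-out** — contact probabilities computed from simulated
   conformations, directly comparable with Hi-C curves.
6. **Synthetic data** — generators with known ground truth, so every stage
   is testable end to end without external downloads.

## Contact probability curves

All Hi-C analytics work on intra-chromosomal pair separations
\(s = |pos_1 - pos_2|\) (0-based positions), binned on an exact geometric
grid from 100 kb to 1 Gb by default (10 bins per decade; the bin count is
rounded so the first and last edges are hit exactly). The probability in a
bin is

\[ P_C(\text{bin}) = \frac{\#\{\text{observed pairs with } s \in \text{bin}\}}
   {\#\{\text{possible locus pairs with } s \in \text{bin}\}} \]

where the denominator counts ordered pairs of non-overlapping 100 kb locus
tiles, summed over chromosomes. Bins without any possible pair are marked
undefined (`NA`), never zero. Curves are routinely normalized to equal 1 at
the 100 kb point so that experimental and simulated curves share a scale.
The log-log derivative \(d\log_{10} P_C / d\log_{10} s\) uses central
differences at bin midpoints (one-sided at the ends); a helical bump appears
as a zero crossing from positive to negative near \(T_l\).

Design choices worth stating explicitly, since the underlying procedure
leaves them open:

* locus tiles for the denominator default to the 100 kb bin size, and the
  possible-pair sums are pooled over chromosomes;
* inter-chromosomal pairs are parsed and kept (flagged) but excluded from
  all \(P(s)\) analytics;
* the 100 kb normalization point is the first bin edge of the default grid.

## Regional turn-length estimation

Chromosomes are tiled into non-overlapping 5 Mb regions (a terminal
remainder is merged into the last full region). A pair belongs to a region
if at least one endpoint lies inside it, or if it spans the region entirely;
each qualifying pair is counted once. The contact-distance histogram of a
region is fitted, as a per-bp density on log-spaced bins (30 per decade),
with

\[ f(s) = A e^{-s/\lambda} + B e^{-(s-\mu)^2 / 2\sigma^2}, \]

an exponential decay from loop-scale contacts plus the Gaussian helical
bump. The fitted centre \(\mu\) is the region's turn length. The fit is
weighted least squares with Poisson (\(\sqrt{\text{count}}\)) weighting,
which stabilizes the sparse tail, and uses a deterministic initialization:
\(\lambda_0\) from the log-slope of the first decade, \(\mu_0\) at the
smoothed histogram maximum inside the allowed window, \(\sigma_0 = 5\) Mb.
Bounds default to \(\mu \in [10, 60]\) Mb, bracketing the 20–38 Mb range
observed in barley. A Gaussian is *detected* when its fitted integral
carries at least 5% of the total signal; regions failing that (or masked
regions — centromeres and nucleolus organizers hinder chromatin contacts and
are masked, not modelled), or with fewer than 1000 pairs, are flagged
`no_signal`. A region whose \(\mu\) exceeds 1.5× (or falls below 1/1.5×)
both neighbours is flagged `abrupt_peak`, the signature of an assembly
error; flags annotate and never alter fitted values. All of these constants
are exposed as arguments.

## Helix geometry

Given a turn length \(l_i\) (bp) at path monomer \(i\), a monomer size
\(m\) (bp) and a mean major-loop size \(l_0\) (monomers), the number of path
monomers per turn is

\[ n_i = l_i / m / l_0 , \]

each monomer advances the path by \(z_i - z_{i-1} = h / n_i\) and
\(\theta_i - \theta_{i-1} = 360^\circ / n_i\) (turn height \(h = 400\) nm),
and the radius follows from unrolling one turn into a right triangle:

\[ (d\, n_i)^2 = (2\pi r_i)^2 + h^2 , \]

with \(d\) the spatial spacing of consecutive path monomers (50 nm default;
20 and 100 nm variants). Angles are stored cumulatively (unwrapped), which
makes turn counting exact: the number of cycles of \(\cos\theta\) equals the
total accumulated angle over 360°. Per-monomer turn lengths are looked up
piecewise-constant from the region containing the monomer's genomic
midpoint; `no_signal` regions are filled from the nearest informative
region. With 1 Mb monomers and \(l_0 = 1\), turn counting reduces to
integrating \(1/T_l\) along the chromosome. Handedness is fixed
right-handed (+θ); only relative geometry matters for every quantity
computed here.

Physical predictions follow directly: chromosome length = turns × per-turn
height (the per-turn height range is an input, since measured band heights
(~380 nm) and the inferred pitch (~450 nm) bracket it), and chromatin
density = volume / DNA content.

The SCE classifier encodes the two observable constraints a helical
chromonema places on exchanged chromatid segments: a sub-turn exchange is
one chromonema thickness high (300–550 nm band) but need not span the
chromatid width, while an exchange of one or more turns spans the full
width. Segments taller than the band yet narrower than the chromatid
(`violation_tall_narrow`) and segments below the 300 nm floor
(`violation_too_short`) are inconsistent with the model. The band and the
10% full-width tolerance are configurable; the defaults encode the observed
transition range rather than a sharp cutoff.

## The polymer simulator

Chromatin is a beads-on-a-string homopolymer (one bead = 200 bp, one
nucleosome plus linker; a coarser `bp_per_monomer`, e.g. 1 kb, makes the
10 Mb comparison model runnable in minutes — the tests and the acceptance
script use that scale and say so). Five forces act, all in kBT/nm units:

1. harmonic bonds between consecutive beads, 10 nm rest, spring constant
   \(k_BT/\text{wiggle}^2\) with a 1 nm thermal wiggle;
2. a bending force with the stated 1 kBT/rad² stiffness and a straight rest
   angle, implemented in the cosine-harmonic form \(U = k(1+\cos\theta)\):
   it has exactly that curvature at the straight minimum but, unlike the
   plain harmonic angle, a bounded force when the chain folds back on
   itself — folded angles occur transiently in the radial loop
   initialization and would otherwise receive divergent force spikes;
3. a truncated polynomial repulsion
   \(U(r) = E_0 (1 - (r/r_c)^2)^3\), \(r_c = 10\) nm, with a finite barrier
   \(E_0 = 1.5\) kBT (2.5 in the 650 nm-confinement variants) at zero
   separation, so fibres may cross — a stand-in for topoisomerase II
   activity;
4. harmonic tethers (4 kBT/nm²) holding only the major-loop base beads to
   the helical path;
5. a harmonic cylindrical wall (10 kBT/nm²) whose radius packs 11³ nm³ per
   bead over the helix height, or an explicit 650 nm override, or none.

Loop architecture is sampled once per replicate: consecutive major-loop
lengths are exponential around 3 Mb (truncated at one monomer), minor loops
exponential around 500 kb nested inside each major loop. Loops are static —
consecutive loop anchors of each level are bridged by harmonic bonds, the
standard static-loop encoding of condensin positions; bridges between major
bases rest at their scaffold spacing so the tethered geometry is strain-free
at start, and a bridge that would duplicate a major-base bridge (a major
loop containing a single minor loop) is dropped. Because bases are placed
equally spaced along the path regardless of loop length, unusually short
major loops sit between anchors farther apart than their bridged contour
and are pulled off their tether anchors by that strain — a property of the
equal-spacing construction, visible as a displacement tail on the tether
residence distribution. The initial conformation places major-loop bases equally spaced on
the analytic helix (five turns by default) with loop beads on radial
out-and-back excursions drifting toward the next anchor. The half-helical
comparison model differs only in the anchor coordinates: \(x \mapsto |x|\)
when converting from cylindrical to Cartesian, which folds the helix so
that loci half a turn apart become neighbours.

Integration is fixed-step Langevin (BAOAB splitting), in reduced units:
kBT = 1, unit mass, nm lengths, step 0.08 reduced time units (resolving the
unit-frequency bond oscillation), friction 0.1 per reduced time. Because
all stated force constants are already in kBT units, equilibrium statistics
are independent of the friction coefficient and of the absolute temperature;
the friction default is chosen for efficient thermalization. The integrator
has its own deterministic RNG seeded per block, so trajectories are exactly
reproducible per seed. The run proceeds in blocks; after each block the
model \(P(s)\) is computed and the run stops when the maximum absolute
change of \(\log_{10} P(s)\) between consecutive block curves (over bins
with at least 20 contacts, so Poisson noise in near-empty bins does not
dominate) falls below 0.05 — the operational meaning of "equilibrated
contact probability". Hitting the block cap is reported, not an error.

## Reading contacts out of models

Two beads are in contact when their centres are within 51 nm. The search
uses a cell list that provably agrees with the all-pairs computation (a
property test enforces this). Contacts are grouped by genomic separation
\(|i-j| \cdot \text{bp per monomer}\), divided by the number of possible
pairs at that separation (replicates pooled before normalization), and
normalized at 100 kb like the Hi-C curves; separations below one monomer are
meaningless and excluded. `compare_to_hic()` reports per-bin log10 ratios
plus their max-abs and RMS over overlapping defined bins.

## What the synthetic generators emulate — and what they do not

`generate_helical_pairs()` draws a uniform left endpoint and a separation
from \((1-w)\,\mathrm{Exp}(\lambda) + w\,\mathcal N(T_l(\text{pos}),
\sigma)\), with defaults \(w = 0.3\), \(\lambda = 5\) Mb, \(\sigma = 5\) Mb
chosen to produce a metaphase-like curve with a clear helical bump; the
turn length may vary along the chromosome as a piecewise track. Off-ends
draws are rejected and redrawn rather than clipped, which keeps the bump
undistorted away from the chromosome ends (edge regions are excluded from
recovery assertions for this reason). `generate_interphase_pairs()` draws a
truncated power law with no bump. `generate_ideal_helix_conformation()`
puts beads on the analytic path with isotropic Gaussian blur standing in
for stochastic loop positioning.

These generators share the *model's* signal shape, not real data's
nuisances: no restriction-site or mappability bias, no duplicates, no
trans-contact noise, no assembly errors (except as injected by tests), and
the exp+Gaussian mixture is exactly the family the estimator fits. Passing
recovery tests therefore demonstrates correctness of the estimation
machinery under the stated signal model — not robustness to everything real
Hi-C can contain.

## Numerical choices and degenerate inputs

* Half-open bins \([e_i, e_{i+1})\) everywhere; geometric bin midpoints.
* Undefined bins (no possible pairs, zero denominators) propagate as `NA`
  through derivatives and ratios; they are never silently zeroed.
* The regional fitter returns `converged = FALSE` on optimizer failure
  instead of raising; underpowered regions (< 1000 pairs) are an error at
  the single-fit level and a `no_signal` flag at the profile level.
* `turn_radius()` refuses \(d\,n_i < h\) (no real radius) and returns the
  degenerate 0 radius at equality.
* Non-finite coordinates abort a simulation with advice to reduce the step.
* Every stochastic routine takes an explicit seed, restores the caller's
  RNG state, and is byte-reproducible.

## Problem sizes used by tests and the acceptance script

Turn-length recovery runs on a 200 Mb synthetic chromosome with 10⁵ pairs
per 5 Mb region and five seeds — enough for the median regional estimate to
sit well inside the ±2 Mb recovery band. The simulation checks use the
10 Mb comparison model (2 Mb turns, 100 nm height and path radius, 100 kb /
10 kb loops) at 1 kb per bead with three replicate seeds and 16 000 Langevin
steps per replicate, after which the full-turn peak of the helical model is
stable; these sizes were chosen as the smallest that give unambiguous
signals. The half-helical variant is run identically and contrasted
qualitatively, as the models' curves differ markedly rather than by a
single number.

## Known limitations

* Loop positions are static; condensin loop-extrusion kinetics and
  sister-chromatid cohesion are out of scope.
* Centromere and nucleolus-organizer interiors are masked, not modelled.
* The convergence rule judges equilibration of \(P(s)\) only; slower
  structural observables may still be relaxing when it triggers.
* Turn counting from a profile inherits the profile's 5 Mb resolution and
  the nearest-region fill of `no_signal` gaps.
* The 400 nm turn height of the geometric model and the ~450 nm pitch
  suggested by microscopy are both exposed as parameters; the package takes
  no side in that tension.
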