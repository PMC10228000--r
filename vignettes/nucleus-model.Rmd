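---
title: "A coarse-grained dynamic model of the fly interphase nucleus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained dynamic model of the fly interphase nucleus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flynuc)
```

## The model

`flynuc` simulates the entire *Drosophila melanogaster* female interphase
genome as a beads-on-a-string polymer at TAD resolution. Each bead represents
a pair of paired homologous TADs (~100 kb each); the 1169 TAD beads, 6
pericentromeric heterochromatin (HET) beads and 4 centromere (CEN) beads form
four chains — the paired chromosomes 2, 3, 4 and X — giving 1179 chain beads,
plus a nucleolus bead (0.333 um radius) restrained at half the nuclear
radius. Chromosomes 2 and 3 join their arms through a HET–CEN–HET triplet,
chromosome 4 starts with CEN–HET, and chromosome X ends with HET–CEN.

Bead size and mass derive from sequence length: the mass is
`m = 2 L (132500/200 + 660)` Da (DNA plus one nucleosome's protein complement
per 200 bp repeat, doubled for the homolog pair), and the bead radius is the
single-TAD "hard radius" scaled by 1.254031 so the bead volume doubles.
Across the genome the bead diameters span roughly 0.08–0.38 um with a 0.18 um
mean.

Every pair interaction is an LJ-cos potential: a 12-6 repulsive core up to
the minimum at `2^(1/6) sigma` (with `sigma = r_i + r_j`), a well of class-
dependent depth, and a `cos^2` taper that reaches exactly zero at
`2^(1/6) sigma + omega`. Four epigenetic bead classes (Active, Null, PcG,
HP1) carry the wild-type well depths 0.1, 1.5, 1.5 and 1.5 kT on the
diagonal and 0.5 kT for all unlike pairs, which satisfies the Flory–Huggins
phase-separation criterion `eps_AB < (eps_AA + eps_BB)/2` for every unlike
pair and produces A/B-like compartmentalization. A further 268 "specific"
long-range TAD pairs get extra wells with depths proportional to the
logarithm of their contact enrichment (`depth = a + b log E`, clamped to
[0, 6] kT).

The nuclear envelope is a spherical wall. TADs containing lamina-associated
domains (350 of the 1169 after mapping the 412 LADs onto TADs; "L-TADs")
feel an attractive LJ-cos well of depth `eps_L` at the wall, 4 kT in the
wild-type parameter set and 0.1 kT (essentially zero) in the Lamin-mutant
set that models lamin depletion; all other beads are repelled. The wall
contact scale is chosen so the well minimum sits exactly at a center-surface
distance equal to the bead radius — the bead touching the wall — which makes
the "at the NE" layer statistics (below) respond directly to binding.

## Dynamics and time calibration

The equation of motion is Langevin dynamics with mass-proportional friction,
`m_i r'' = -grad U - gamma m_i r' + L_i(t)`, integrated with a BAOAB
velocity-Verlet splitting at `dt = 0.01 tau`, where the LJ time
`tau = sigma_min sqrt(m_min / eps)` equals 136 ns for the LJ energy scale
`eps = 3 kT` (so `dt = 1.36 ns`). The friction presets are 1, 0.1 and
0.01 per tau; the low-friction production regime keeps bead inertia relevant
and speeds the exploration of configuration space by an order of magnitude,
and the thermostat remains exact as `gamma -> 0` because the stochastic
(O) step is an exact Ornstein–Uhlenbeck update. Noise amplitudes satisfy
fluctuation–dissipation per bead mass, so the stationary velocity
distribution is Maxwell–Boltzmann at the target temperature for every bead.

Simulation steps map onto biological time through the sub-diffusive law for
chromosomal loci, `MSD(dt) = 4 D_app (dt/lambda)^0.39` with
`4 D_app = 0.061 um^2` held fixed, fitted over the first 3e5 steps of the
radial MSD of nine non-LAD beads. The calibrated steps-per-second factors are
`lambda = 20e4, 2.8e4, 1e4 /s` for `gamma = 1, 0.1, 0.01 /tau`. The
production run of 400 million steps at `gamma = 0.01/tau` therefore spans

```{r timemap}
format_biotime(steps_to_biotime(400e6, gamma = 0.01))
```

about one G1 phase. The mapping is order-of-magnitude: a model "minute" is a
real minute, not an hour or a second, but no sub-second accuracy is claimed.

## Initial configurations and the ensemble

Interphase fly nuclei keep a Rabl-like, territorial arrangement. The five
large chromosome arms (2L, 2R, 3L, 3R, X) are generated as straight bead
strings parallel to the z-axis, each confined to its own 72-degree dihedral
wedge, polarized centromere-to-telomere; chromosome 4 sits at the North
pole. Four observed nucleus topologies are provided — CIS-X6S, CIS-X7N,
TRANS-X3S, TRANS-X4N — where CIS places the two R-arms (and the two L-arms)
of the autosomes in adjacent wedges and the X6S/X7N suffix gives the pole of
chromosome X. The exact azimuthal order of arms within a topology is not
fully constrained by the observations; the wedge tables used here satisfy
the CIS/TRANS adjacency relations and are configurable.

Each arm is collapsed into a compact globule by 1e5 Langevin steps under a
weak harmonic spring towards the nucleus center (equilibrium length 0.99 um,
spring constant 0.5 kT/um^2; removed afterwards) while the wedge restraints
(half-plane harmonic penalties, 10 kT/um^2) keep arms territorial. The arms
are then joined through the junction beads and a large repulsive sphere is
shrunk geometrically onto the chromosomes — 10 stages of 1e4 steps by
default; the schedule is a package choice, the procedure (a set of short
runs with decreasing restraining radius) is fixed — until the final nuclear
radius is reached.

The reference ensemble is 18 nuclei: the CIS topologies weighted twice
(CIS-X6S x2, CIS-X7N x2, TRANS-X3S, TRANS-X4N — the experimental CIS:TRANS
weight of 2) times three nuclear radii. The radii default to 1.8, 2.0 and
2.2 um with 2.0 um the reference size; the published analyses quote 2 um
nuclei and pool sizes on a relative radial axis, so the two flanking sizes
are a plausible spread, and they are configurable.

## Readouts

* **Contact maps** — two TADs are in contact when their centers are within
  `1.2 (r_i + r_j)` (the 1.2 factor is configurable and recorded in the map
  metadata). Per-snapshot indicators are averaged in 5-minute windows (3e6
  steps at the production calibration), then over windows and nuclei; the
  first window is discarded as burn-in by default. Maps are symmetric with
  unit diagonal by convention. `pearson_maps()` compares maps on the
  off-diagonal upper triangle and can stratify away reference entries below
  a threshold (e.g. 0.03) dominated by experimental noise.
* **Radial density profiles** — shell number densities, conserving the bead
  count exactly per snapshot, with ensemble mean and SD-of-mean error bars;
  a relative-radius axis supports pooling nuclei of different sizes.
* **NE layers** — occupancy of the 0.09 um layer (average bead radius, the
  "LAD fraction at the NE" criterion), the 0.2 um contact layer (average
  bead diameter, the LAD-mobility criterion), and the 0.4 um layer holding
  half the nuclear volume.
* **LAD mobility** — per-L-TAD contact probabilities, attachment and
  detachment events and dwell times from a single-nucleus trajectory; a
  statically anchored LAD would show probabilities of exactly 0 or 1, so
  interior values reject the static picture.
* **Class contact sums and difference maps** — e.g. the per-Null-TAD summed
  contact probability with Active TADs, whose mutant-vs-WT mean relative
  change quantifies the loss of A/B segregation after lamin depletion.
* **Per-TAD radial distributions** — with a dip-test bimodality heuristic:
  a distribution is called bi-modal when the wall peak and the interior
  maximum both exceed three times the density in the dip between them. The
  threshold 3 is a documented heuristic of this package, not a literature
  value.

## The synthetic genome

Real annotation inputs (TAD table with classes and hard radii, LAD
intervals, specific-pair enrichments) are distributed externally, so the
package ships a generator that emulates their statistics: exactly
494/492/131/52 TADs and 54/228/50/18 L-TADs per class (totals 1169 and 350),
log-normal TAD lengths clamped so bead diameters stay in 0.08–0.38 um with
0.18 um mean, and LAD placement by a two-state persistence process along
each arm followed by count-preserving boundary flips, giving exact totals
and clustered L-TADs. The persistence default 0.4 reproduces the observed
spread of the 17-TAD-window linear L-TAD density f_L (about 0.05–0.7 around
the genome mean 0.30 = 350/1169); `persistence = 0` reduces to independent
Bernoulli placement with binomial f_L variance. Class labels are drawn
independently of position given the L-TAD flag, so the synthetic genome does
not reproduce the real genome's class-level spatial autocorrelation along
the chain, nor its correlated size–class structure; tests passing on it show
the machinery and the LAD-driven physics, not fly-genome-specific detail.

## Numerical choices

* **Soft cores.** The 12-6 core is continued linearly (constant force) below
  the radius where it reaches 50 kT, so initialization overlaps relax
  instead of exploding; forces stay C0 and the potential C1 everywhere.
* **Taper width.** The supplementary constants of the published potentials
  are not reproduced in the available text, so `omega` is an explicit
  calibration knob. The default `omega = 0.25 sigma` was selected by the
  same model-development criteria the original selection used — the NE LAD
  fraction near 25% at `eps_L = 4 kT`, a wild-type chromatin density peak
  adjacent to the envelope that disappears in the Lamin mutant, and interior
  densification in the mutant. With `omega = 0.5 sigma` the longer-ranged
  cohesion over-condenses chromatin centrally and the wall peak never forms.
* **Repulsion amplitude** for purely repulsive pairs (and the wall) is the
  LJ energy scale, 3 kT. **Bonds** are harmonic with rest length `r_i + r_j`
  and stiffness `30 / sigma^2` kT/um^2 — stiff enough that bonds never
  stretch past 3x rest length in production, soft enough for the 0.01 tau
  step. **Bonded neighbours are excluded** from the non-bonded sums (the
  standard bead-spring convention; exposed as a flag because the original
  choice is not documented).
* **HET/CEN beads** have no measured sizes or interactions; they default to
  0.2 um radius, the mass of a 500-kb region, and cross-type-level (0.5 kT)
  attractions. Results-level statistics are insensitive to this choice
  because the junction beads are 10 of 1179 and carry no LADs.
* **Neighbour search** uses a cell list rebuilt every 20 steps with a
  0.15 um skin; at the maximal bead speeds observed this is a >10x safety
  margin against missed pairs.
* **Determinism.** All stochastic stages draw from R's RNG; a fixed seed
  makes genome generation, initialization and trajectories bit-reproducible
  in the single-threaded build.

## Scaled-down test conditions

The full published protocol — 18 nuclei x 400e6 steps at 1179 beads — is a
cluster-scale computation. The package's own test and acceptance suites
exercise the identical code paths at reduced size: a 120-TAD synthetic
genome (proportional class and L-TAD quotas, ~36 L-TADs) in a 1.0 um
nucleus, single nuclei per condition, preparations of 2e4 collapse steps
and 8 shrink stages, and productions of 0.6–1e6 steps at `gamma = 1/tau`.
These sizes were chosen so the qualitative contrasts of interest —
monotone growth of the NE LAD fraction with `eps_L`, the presence/absence
of the wall density peak, interior occupancy probabilities, decompaction
after envelope removal — are clearly resolved; absolute full-scale numbers
(e.g. the exact 94% peak position or the 22% Null–Active contact increase)
are not expected to transfer quantitatively across this size reduction and
are therefore not asserted at test scale.

## Known limitations

Homologous chromosomes are premerged into single beads (no pairing
dynamics); there is no loop extrusion, no electrostatics, no hydrodynamic
coupling, and the nucleolus is a passive excluded-volume sphere. The
time mapping inherits the uncertainty of the experimental sub-diffusion
exponent. The Pearson comparison against an experimental Hi-C map is
supported as a workflow (`pearson_maps()` with low-probability
stratification) but ships no experimental data.
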