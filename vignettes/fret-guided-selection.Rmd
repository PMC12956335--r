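---
title: "FRET-guided selection of RNA 3D structure collections: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FRET-guided selection of RNA 3D structure collections: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretsel)
```

`fretsel` selects, from a pool of predicted RNA 3D structures, the
sub-collection most consistent with a single-molecule FRET (smFRET)
experiment, subject to the structural constraint that a reference motif — a
kissing loop in the motivating application — is correctly folded. This
vignette documents the underlying models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic test system does and
does not establish about real data.

## The scientific setting

The construct of interest has two structured elements joined by a flexible
single-stranded linker; a donor and an acceptor dye sit on the two
elements. Because the linker is disordered, the molecule populates a broad
distribution of inter-dye distances, and the smFRET efficiency histogram is
the experimental fingerprint of that distribution. Structure predictors
emit static snapshots with no populations attached; the question the
package answers is *which snapshots, in which proportions, reproduce the
measured histogram* — after discarding snapshots whose reference motif is
misfolded, since those would fit the FRET coordinate for the wrong reason.

## Watson–Crick annotation and kissing-loop classification

Base pairs are classified purely geometrically, so the filter is explicit
and reproducible. A pair of complementary bases (A–U or G–C) is
`canonical_WC` iff

* both canonical edge hydrogen-bond heavy-atom distances (A:N1–U:N3 and
  A:N6–U:O4; G:N1–C:N3 and G:O6–C:N4) lie in **[2.4, 3.6] Å**,
* the inter-base-plane angle (between C2/C4/C6 ring normals, folded to
  [0°, 90°]) is **≤ 35°**, and
* the faces are oriented **cis**: the two C1′ atoms lie on the same side of
  the axis through the glycosidic nitrogens.

Candidate pairs are those with base-centroid distance ≤ 7 Å; residues
missing the ring atoms are skipped with a warning rather than failing the
model. The thresholds are parameters of `annotate_base_pairs()`; the
defaults above are deliberately permissive windows around textbook values,
because the filter's job is to detect *rearranged* pairing, not to grade
hydrogen-bond quality.

A `kl_reference` object carries the classification contract: the set of
residue pairs that must be canonical, one *variable pair* exempt from the
canonical requirement, the residue region for eRMSD, and the eRMSD
threshold. The variable pair accommodates a position that the reference
structure itself resolves without canonical geometry; the qualitative
requirement that it stay "in contact" is operationalized as
C1′–C1′ ≤ 12 Å (configurable, `proximity_max`) — the upper range of paired
C1′–C1′ distances (~10.4 Å) plus slack. Which base of that pair sits at
which position is left entirely to the configuration; the package imposes
no orientation.

## eRMSD

Pairing alone cannot detect backbone rearrangements that preserve contacts,
so the filter also computes the base-centric eRMSD against the reference.
Each base receives an orthonormal frame from its C2/C4/C6 ring atoms
(origin at their centroid, x toward C2, z along the ring normal). For every
ordered base pair (j, k) in the region, the displacement of k's center in
j's frame is anisotropically scaled — **5 Å** laterally, **3 Å** along the
normal, reflecting the different length scales of pairing and stacking —
and mapped to a smooth 4-component G-vector that vanishes beyond a cutoff
of **2.4** scaled units. The eRMSD is the root-mean-square G-vector
difference over all ordered pairs, normalized by the number of residues. It
is zero iff the two structures' local base arrangements coincide, and is
invariant under rigid transforms (asserted numerically in the tests, along
with agreement to an independently coded implementation of the formula at
10⁻⁶).

Models pass the filter iff the kissing loop is *preserved* **and**
eRMSD ≤ `ermsd_max`; the threshold default is **0.8**, and the comparison is
inclusive. The per-model audit table records status, eRMSD, and verdict so
losses at each stage can be accounted for.

## The accessible-contact-volume dye model

FRET efficiencies are predicted from sterically allowed dye positions
rather than from a single attachment-point distance. For each dye,
`compute_acv()` builds a cubic grid centered on the attachment atom with
half-width `linker_length + max(dye_radii)` and applies three rules:

1. **Steric exclusion** — a grid point is unusable if a dye sphere centered
   there overlaps any heavy atom (center distance < element vdW radius +
   dye radius; C 1.70, N 1.55, O 1.52, P 1.80 Å, 1.70 Å for anything else).
2. **Linker reachability** — the point must be reachable from the
   attachment atom along a shortest path through open grid cells (Dijkstra
   with Euclidean edge lengths) of length ≤ `linker_length`. For
   pathfinding, obstacles are dilated by `linker_width / 2`, modeling the
   linker as a tube; a sphere of radius `max(3 Å, linker_width)` around the
   attachment atom stays traversable, since the linker emerges from a
   covalent bond whose immediate neighborhood would otherwise be sealed by
   the dilation.
3. **Contact shell** — accessible points within `cv_thickness` of the
   molecular surface are labeled `contact` and together carry `cv_fraction`
   of the dye weight (the experimentally determined stacked-dye fraction,
   e.g. from time-resolved anisotropy); `free` points share the remainder
   uniformly. With three `dye_radii` the three accessible sets are unioned
   with equal weight.

**Path-graph neighborhood.** The classical 26-neighbor grid graph
overestimates shortest paths in off-axis directions by up to ~12%
(chamfer-metric distortion), which would shrink a free dye's accessible
region to ~78% of the analytic sphere volume. The package therefore uses a
neighborhood of radius **3** grid steps by default (primitive offsets only;
~97% of the analytic volume at spacing L/10, where discretization alone
accounts for ~0.5%), implemented in C++ with a binary-heap Dijkstra.
Multi-step edges additionally require every grid cell touched by the
straight segment to be open, so paths cannot tunnel through thin walls;
this touched-cell rule is symmetric under edge reversal. `nbr_radius = 1`
reproduces the literal 26-neighbor graph, and the tests pin both variants
against an independent shortest-path oracle.

**Efficiency.** `efficiency_from_acvs()` samples `n_pairs` independent
weight-proportional position pairs. The default mode applies the Förster
equation `E = 1/(1 + (R/R0)^6)` to the mean inter-dye distance
(`mean_distance`); the alternative `mean_efficiency` averages per-pair
efficiencies. Both are offered because ensemble practice varies and the two
differ systematically for broad position clouds (Jensen's inequality); the
default follows the convention of deriving `E` from the ACV mean distance.
The grid spacing default is **1.0 Å** (standard accessible-volume practice;
the sphere-volume oracle in the test suite pins the accuracy), with
**1.5 Å** used in the package's own pipeline examples for speed.

`compute_macv()` aggregates ACVs over several frames of one model by weight
union (each frame contributing equally); with a single frame it degenerates
to the plain ACV.

## Collection sizing by Kullback–Leibler convergence

How many structures are enough? `estimate_min_subset()` compares the
efficiency histogram `P` of the full collection (size N, bin width ΔE =
**0.05** by default, matching typical experimental accuracy of ±0.05) with
histograms `Q` of random subsets of size x drawn without replacement, via

D(P‖Q) = Σⱼ pⱼ ln(pⱼ/qⱼ)   (natural log, nats),

for x on the grid `size_step, 2·size_step, …, N − size_step` plus N itself.
Repetitions per x grow (doubling, from `repetition_floor` = 10 up to
`repetition_cap` = 10 000) until the **standard error of the mean KLD**
falls below `sd_tolerance` = 1% of the mean; points that hit the cap are
flagged `converged = FALSE` rather than silently accepted. The standard
error is the right reading of a "grow the repetitions until the sd is small"
rule: the population sd of KLD values across subsets does not shrink with
more repetitions, so no amount of repetition could ever satisfy a rule
stated on it.

**Zero-bin handling.** Small subsets leave bins empty with probability
near 1, and the bare formula then diverges. The default regularization
(`regularize = "reference"`) gives the subset histogram pseudo-counts of
total Jeffreys magnitude m/2 (m bins) distributed **proportionally to the
reference probabilities** — a Dirichlet prior centered on P. This choice is
the unique simple prior that keeps three exact identities: D = 0 for
identical histograms at any sample size, D = 0 at x = N (the subset is the
full set), and D ≡ 0 when every structure has the same efficiency. A strict
mode (`regularize = "none"`) evaluates the bare formula with a +Inf
sentinel. Because zero-bin handling and log base are conventions, absolute
KLD curve values are comparable only within one convention;
`min_subset_size()` therefore reports the first size at which the
antitonically smoothed curve (isotonic regression on the reversed series)
drops below a user-chosen level.

## Reweighting against the experimental histogram

Let `|B_i|` be the number of filtered structures in efficiency bin i and
`p_i` the experimental smFRET probability of that bin. The *unweighted*
selection takes every structure exactly once, so the predicted per-bin
frequency is `|B_i|/N`. The *weighted* selection matches the target:
target probabilities are restricted to populated bins (`|B_i| > 0`),
renormalized, and converted to integer per-bin quotas by largest-remainder
apportionment of `n_total` (ties toward lower bin index), which conserves
`Σ quotas = n_total` exactly. Within a bin, if the quota does not exceed
the population, that many distinct members are drawn without replacement;
otherwise every member is selected `floor(quota/|B_i|)` times and the
remainder is drawn without replacement from a random permutation of the
bin. Renormalization over populated bins is required for `n_total` to be
well-defined when target mass falls outside the collection's range; the
discarded mass is reported, and reweighting fails loudly when *no*
populated bin carries target mass — reweighting can only repopulate
conformations the collection already contains, never invent new ones.
`n_total` defaults to the filtered collection size. The per-bin quota
table is retained for audit, and `report_contributions()` summarizes
per-structure percentages and the unique-structure count.

## Photon-burst simulation

To compare predictions with experiment on equal terms, per-structure
efficiencies are pushed through a Monte-Carlo photon model. For each of
`n_bursts` bursts, a size n is drawn from the empirical burst-size table;
each photon is acceptor-type with probability `E_s + (1 − E_s)·d`, where
`d` is the direct-excitation probability and s the structure governing that
photon; the apparent efficiency is the γ-corrected ratio
`E_app = n_A / (n_A + γ·n_D)`. Three exchange regimes set how s is drawn:

* **fast** — fresh multiplicity-proportional draw per photon. Photons are
  then i.i.d. with the weight-averaged acceptor probability, so the
  acceptor count is drawn as a single binomial per burst — an exact
  distributional identity, not an approximation. Fast exchange time-averages
  structure within a burst, which narrows the apparent distribution.
* **static** — one structure per burst; structural heterogeneity survives
  as histogram multimodality.
* **trajectory** — consecutive frames of a time-ordered efficiency series,
  one frame per photon, with a uniformly chosen start (wrapping); this
  links photons within a burst the way a molecular-dynamics trajectory
  would.

Background and crosstalk are corrections applied to experimental data
before it enters the package; they are deliberately not part of the
generative model. Direct excitation is modeled per photon as the simplest
mechanism with the right marginal effect. The shot-noise limit is pinned by
tests: for a single state with γ = 1 and d = 0, `E_app` is exactly
Binomial(n, E)/n, verified by a chi-square goodness-of-fit.

## The synthetic test system

`generate_toy_construct()` emulates the geometry that makes the scientific
problem nontrivial — two rigid, ideally paired duplex blocks joined by a
flexible single-stranded poly(A) linker whose conformational breadth is
controlled by one `spread` parameter — with the smallest atom set the
pipeline exercises (ring atoms for eRMSD frames, WC-edge atoms, glycosidic
N, C1′, P, and a designated dye-attachment carbon per element). Nucleobases
are force-field-relaxed planar templates; the Watson–Crick pair geometry is
solved from standard hydrogen-bond and C1′–C1′ distances, and the duplex
stacks pairs at 2.81 Å rise / 32.7° twist. The linker is a virtual-bond
chain (5.9 Å per residue) whose bend angles receive Gaussian perturbations
of sd `spread × 40°`; models with heavy-atom contacts < 2 Å between
non-neighbor residues are rejected and redrawn. With `spread = 0` all
models are identical and fully extended. `generate_synthetic_smfret()`
draws a truncated Gaussian on [0, 1] by inverse-CDF sampling; its default
mean 0.32 and sd 0.14 mirror a typical experimental unbound-state
histogram. Every stochastic operation takes an explicit seed and restores
the ambient RNG state.

What passing tests on this system establishes: the annotation recovers
pairing known by construction; the filter's two criteria act independently;
ACV volumes and paths match analytic and brute-force oracles; reweighting
hits the target within the quantization bound 1/n_total per bin; burst
statistics match their closed-form limits; and the full pipeline is
deterministic given seeds. What it does **not** establish: predictive
accuracy on real RNA (the toy linker is not a thermodynamic ensemble, dye
photophysics beyond scalar γ/direct-excitation/CV-fraction parameters is
out of scope, and real collections have heterogeneous atom naming and
occasional malformed records that only the tolerant PDB reader addresses).

## Numerical choices and degenerate inputs

* Histogram bins are half-open `[l, u)` with the last bin closed, so
  E = 1 is counted; `1/bin_width` must be an integer.
* Largest-remainder ties break toward lower bin index — deterministic and
  total-conserving.
* KLD values within −10⁻⁹ of zero are clamped to zero (floating-point
  guard; the divergence is provably non-negative).
* Empty filtered collections, empty histograms, buried attachment atoms
  (no accessible grid point), and reweighting without bin overlap all fail
  with named errors rather than propagating NaNs; skipped residues and
  non-converged KLD points warn or flag but do not abort.
* Pipeline problem sizes in the package's own examples (100-model
  collections, 1.5 Å ACV grids, 10⁴ bursts, 2000-member KLD collections)
  were chosen so the complete suite exercises every stage at full fidelity
  while remaining comfortable to run interactively; all sizes scale up by
  configuration only.

## Known limitations

* The WC classifier covers canonical cis pairs only; it does not implement
  the full Leontis–Westhof family taxonomy, sugar/Hoogsteen edges, or
  stacking annotation.
* mmCIF input, protein residues, and alternate locations beyond the first
  are out of scope for the PDB reader.
* The dye model treats dye shape as one to three spheres and photophysics
  as three scalars (γ, direct excitation, CV fraction); κ² dynamics,
  blinking, and lifetime information are not modeled.
* Reweighting is single-coordinate (the FRET efficiency) and integer-count;
  continuous maximum-entropy weighting is deliberately not implemented.
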