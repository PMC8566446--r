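---
title: "touchnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{touchnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(touchnet)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic fixtures establish (and what they cannot), and the numerical and
design choices taken where the method itself leaves them open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The model

### Placement

Somas are placed one at a time with positions drawn uniformly from the
volume's bounding box expanded by `dMin`. A candidate closer than `dMin`
to any previously stored soma is rejected; a surviving candidate inside the
volume is accepted, while one outside is stored as a *padding* soma —
remembered for the distance constraint but not counted. Padding is what
keeps the accepted density flat up to the boundary: without it, positions
near the wall have fewer neighbours able to exclude them and the border
layer over-fills. The acceptance suite measures exactly this, comparing the
occupancy of a `dMin`-thick border shell against its volume fraction with
padding on (flat within 3 standard errors over 20 seeds) and off (the
artifact appears at a very large z-score).

Assumptions: uniform density (no gradients), isotropic random orientation
unless `rotationMode` says otherwise, hard-sphere exclusion only. A packing
feasibility guard refuses requests where the excluded volume
`N·(4π/3)(dMin/2)³` exceeds 30 % of the volume, and placement aborts after
10⁶ consecutive rejections; both bounds are engineering choices, stated
here once.

### Touch detection

Space is divided into cubic voxels, 3 µm by default — this is the maximal
axon–dendrite interaction distance, since contacts are only found within a
voxel. Every neurite segment marks the exact set of voxels it passes
through. We implement this as a parametric *supercover* traversal (all
plane-crossing parameters of the segment, voxel identity from interval
midpoints) rather than literal small steps: it is the limit of
infinitesimal stepping, exact and step-size free. The test suite checks
equivalence against a brute-force fine-stepping oracle at voxel/50
resolution; the only permitted discrepancies are corner slivers whose
in-voxel length is below the oracle's own step, verified analytically by
slab-clipping.

The soma is voxelized as a sphere (voxel centres within the radius) and
counts as a postsynaptic target; multi-point SWC somas are collapsed to a
centroid sphere whose radius covers all soma points. Whether axon–soma
appositions should form synapses is not settled by the method description
we follow; we include them, and flag the choice here.

A putative synapse is one (pre, post, voxel) triple with presynaptic axon
occupancy and postsynaptic dendrite/soma occupancy, type pair allowed, self
contacts excluded. Several co-occupied voxels for the same pair give
several synapses. When a voxel holds multiple dendritic segments of the
postsynaptic neuron, the most proximal one (smallest path distance) is
recorded — a deterministic tie-break. Gap junctions are dendrite–dendrite
co-occupancy of unordered pairs, stored once.

For scale, voxels group into hypervoxels (100³ voxels by default). Every
voxel is owned by exactly one hypervoxel (lattice floor division), so the
decomposition cannot double-count; neurons are assigned to all hypervoxels
their segment bounding boxes touch, hypervoxels are processed most-populated
first (load balance), and the per-hypervoxel function is pure, so a
parallel map is a drop-in replacement even though execution here is serial.
The suite asserts that the decomposed synapse set is identical to the
single-grid one.

If a reconstruction lacks an axon, `axon_density_touch()` substitutes an
axonal probability cloud: each dendrite-occupied voxel of an allowed target
receives a synapse with probability `min(1, density · voxel volume)`,
evaluated at the voxel centre relative to the presynaptic soma.

### Pruning

Putative synapses overestimate real connectivity; the cascade

\[
P_{keep} = P_{dist} \cdot f1 \cdot P_{SM} \cdot P_{mu} \cdot a3
\]

reduces them to match pairwise recording statistics. Stage order is
distance-dependent → `f1` → soft-max → `mu2` → `a3`:

1. **P_dist(d)** — per synapse, keep with a user-supplied probability of
   dendritic path distance to the soma (expression in `d`, micrometres).
2. **f1** — per synapse, keep a fixed fraction.
3. **soft-max** — per pair with `n` synapses entering the stage, keep each
   with `P_SM = 2·softMax/((1+e^{-(n-softMax)/5})·n)`, a soft cap: the
   expected surviving count `n·P_SM` never exceeds `2·softMax`.
4. **mu2** — per pair, keep *all* synapses with probability
   `P_mu = 1/(1+e^{-8/mu2·(n-mu2)})`, else remove all. `P_mu(n=mu2) = 1/2`.
5. **a3** — per pair, keep all with probability `a3`.

The placement of `a3` after `mu2` is our ordering decision; the stages are
described as a product and `a3` is a pure pair-level decimation, so its
position only matters for seeds, not expectations, and we pin it last and
regression-test the declared order.

`expected_kept()` is the analytic oracle: it propagates each pair's
synapse-count distribution exactly — Poisson-binomial convolution through
the per-synapse stages, a count-conditional binomial through soft-max,
`P_mu`/`a3` weighting per pair — and the suite requires 1000-seed
Monte-Carlo means from `prune()` to sit within 3 standard errors of it for
every parameter set in the worked-example grid (f1 ∈ {0.5, 0.25}, mu2 = 3,
softMax ∈ {1, 2, 3}, a3 ∈ {0.5, 0.25}, and combinations).

**A deliberate design choice.** Read per synapse, the soft-max stage can
disconnect a pair entirely (probability `(1−P_SM)^n`), which a strict
"soft-max never disconnects" reading forbids. Conditioning on at least one
survivor, however, shifts the expectation: at `softMax = 1` on the
100-pair × 4 fixture it would yield ≈ 150 kept synapses where the plain
binomial reading yields ≈ 129 — and 129 is what the published expectations
for this rule arithmetic out to (`400 · P_SM(4; 1)`). We therefore make the
plain per-synapse rule the default and expose the conditioned variant as
`keep_connected = TRUE` in both `prune()` and `expected_kept()`, tested in
its own right. Users who need the never-disconnect contract opt in and
accept the (documented) bias.

**Randomness.** Pruning draws come from one seeded stream after the synapse
table is brought into canonical (pre, post, position) order, making the
result a pure function of (table contents, parameters, seed) and
independent of row order. Per-pair keyed substreams would give the same
guarantees; the canonical-order stream vectorises far better in R, which is
what keeps the 1000-seed acceptance runs cheap.

Population units: neurons join unit *u* of their type with the configured
fraction, remainder in unit 0 ("no unit"). A connection's `pruning` block
applies when both endpoints share a non-zero unit, `pruningOther` otherwise
(falling back to `pruning` when absent).

### External input

Spike trains are piecewise-homogeneous Poisson: within each
`[start, end)` interval the configured rate applies, zero elsewhere. For a
population correlation `C`, each of `k` trains keeps every spike of one
shared mother train with probability `P = √C` and merges an independent
Poisson train of rate `(1−P)·f(t)`. The marginal rate is then
`P·f + (1−P)·f = f` regardless of `C`, and the pairwise spike-count
correlation is `P² = C`. The method description fixes the inclusion
probabilities but not the mother rate; choosing the mother rate equal to
the target rate is our decision, and it is the one that preserves both the
marginal rate and the correlation simultaneously. Correlation is *defined*
here on spike counts in 100 ms bins (the definition needs a bin; ours is
configurable in `train_count_correlation()`).

Input synapses go onto the dendrites with linear density proportional to
`synapseDensity(d)` (uniform if absent). `nInputs` fixes the count exactly
with the density acting as a shape; a density alone draws a Poisson count
with mean `∫ density dl`. Target blocks are resolved most-specific-first:
neuron id beats morphology key beats neuron type, one block per neuron, all
channels within it applied.

### Morphology curation

Reconstructions from public repositories carry systematic artefacts; the
curation module repairs them while preserving what matters for the
electrical model — cable length.

* **z-jumps**: a parent→child step with `|Δz|` above threshold *and*
  larger than the lateral step (our detection criterion; the phenomenon is
  a depth-axis registration error, so the jump must be z-dominated).
  Default threshold 3 µm. Four repairs: `align` (rigid shift of the
  downstream subtree), `split` (absorb the offset linearly in path length
  along the remainder of the section), `tilt` (rigid rotation about the
  parent so the jump node returns to the parent's z level — an isometry),
  `join` (subdivide only the jump segment into sub-threshold steps; ids are
  renumbered and the repaired node returned as an attribute).
* **cut neurites**: leaves coincident with the extreme z plane of the
  reconstruction. A face qualifies only when ≥ 2 leaves lie on it within
  tolerance — a slice cut clips several neurites at one plane, whereas the
  single most extreme leaf of an intact cell is just its natural extent.
  Repair grafts a copy of a randomly chosen intact donor branch of the same
  centrifugal order, rotated to continue the cut branch and mirrored across
  the cut face so it grows back into the tissue.
* **shrinkage**: xy scaling and z expansion; `unravel()` re-lays each
  dendritic section along sliding-window principal axes, preserving every
  segment length exactly while increasing end-to-end extent.
* **variability**: `twist`/`rotate` rigidly rotate subtrees at dendritic
  bifurcations (about the parent-branch axis or a random axis) — exact
  isometries; `jitter` displaces nodes and restores each segment length;
  `scale3d` scales coordinates and radii by a random factor. The suite
  verifies cable-length conservation, subtree isometry, and that pooling
  nine π-amplitude twists of a deliberately asymmetric tree reduces the
  anisotropy (largest/smallest covariance eigenvalue) of its termination
  cloud — the symmetry-restoration property that motivates the method.

## 2. Parameters that matter

| parameter | unit | default | rationale |
|---|---|---|---|
| voxel size | m | 3 µm | sets the maximal touch distance |
| hypervoxel extent | voxels | 100³ | work unit for decomposition |
| `dMin` | m | 15 µm | striatal soma-separation scale; satisfies the packing guard at 10,062 neurons in a 0.5 mm cube |
| reference density | m⁻³ | 8.0496·10¹³ | 10,062 neurons per (0.5 mm)³ |
| z-jump threshold | m | 3 µm | "a few micrometres" artefact scale |
| cut-face tolerance / min leaves | m / – | 1 µm / 2 | see curation notes |
| correlation bin | s | 0.1 | definition of the count correlation |
| `f1`, `a3` | – | none | per-synapse / per-pair keep fractions in [0,1] |
| `softMax`, `mu2` | synapses | none | soft cap scale; sigmoid midpoint |
| distance expressions | `d` in µm | none | written against published distance axes |

Internally everything is SI metres; SWC files (µm) convert at I/O, with
6-significant-digit decimal output so write→read→write is bit-stable.

## 3. What the synthetic fixtures do and do not establish

`make_grid_fixture(P, k)` builds `P` disjoint pre/post ball-and-stick pairs
whose axon and dendrite share exactly `k` voxels, every coordinate on the
voxel-centre lattice. It gives touch detection a known answer (`k` per
directed pair, nothing else, invariant under whole-voxel translation) and
pruning a clean 100 × 4 pair histogram. `make_distance_ladder()` crosses
one presynaptic axon per requested distance over parallel straight
dendrites, realising synapses within half a voxel of each printed path
distance. The broken-morphology generators record their own ground truth
(jump node, removed cable, cut leaves).

A green suite therefore establishes: the detector finds exactly the
constructed contacts; the pruning cascade's sampled behaviour matches its
analytic expectation; the input generator hits its rate and correlation
targets; repairs restore the recorded damage. It does **not** establish
realism of striatal connectivity: the fixtures have straight neurites,
no tortuosity, no reconstructed axonal arbors, and the full-scale results
(hundreds of millions of synapses, benchmark timings, population-level
distance curves from real morphologies) need the original morphology
dataset and cluster resources. Those are replaced, deliberately, by the
property checks listed in the acceptance suite plus the density arithmetic
`469·10⁶ / 6.2 mm³ = 75.6·10⁶ mm⁻³`.

## 4. Numerical choices and degenerate inputs

* Voxel indices are `floor((p − origin)/size)`; boundary points belong to
  the higher-index voxel, consistently everywhere.
* Zero-length segments mark one voxel; somas smaller than half a voxel mark
  their containing voxel.
* The mesh inside/outside grid labels surface-sampled cells `border` and
  resolves border queries by ray parity with a fixed irrational-direction
  ray; volume estimates count border cells at half weight. Non-watertight
  meshes are refused unless `allow_open = TRUE`.
* Rotation sampling uses uniform unit quaternions; uniformity is tested by
  the mean image of a fixed vector.
* Truncated-normal conductances resample negative draws (exact mean when
  sd = 0).
* `prune()` on an empty table, `repair_cut()` with no cuts, `scale3d` with
  amplitude 0, identity transforms — all are exact identities and tested.
* The pipeline container is a plain-text directory (TSV at 17 significant
  digits + JSON metadata) with a version field, provenance (config hash,
  all stage seeds) and cross-table integrity checks. A hierarchical binary
  container would serve large networks better; at the scales this package
  targets in R, text wins on portability and diffability, and the layout is
  pinned by round-trip tests.

## 5. Known limitations

* Serial execution; the hypervoxel decomposition is parallel-ready but no
  scheduler is shipped.
* Touch distance is bounded by one voxel; no spine modelling.
* No density gradients or orientation fields in placement.
* Distance-dependent pruning curves must be supplied by the user; none are
  built in.
* The soft-max `keep_connected` variant biases expectations upward (see
  §1); it is off by default.
* Cut-point detection assumes slice faces are perpendicular to z and that
  at least two neurites were clipped.
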