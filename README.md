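# touchnet

Predicting synaptic connectivity for microcircuit models by touch
detection.

Building a biophysically detailed network model of a brain region — the
dorsal striatum is the motivating case — needs a wiring diagram long before
any simulation can run. `touchnet` implements the anatomy-constrained
pipeline that produces one: place neuron somas in a bounded 3D volume at
realistic density, overlay reconstructed SWC morphologies, find every
location where an axon comes close enough to a dendrite to form a synapse,
and then prune those *putative* synapses stochastically until the surviving
connectivity matches what pairwise patch recordings report. The same
machinery generates correlated Poisson background input for the resulting
network and repairs the raw SWC reconstructions (slice cuts, z-jumps,
shrinkage) that real morphology databases deliver.

It is aimed at computational neuroscientists who need a reproducible,
scriptable wiring generator in R, and at method developers who want the
pruning rules and their analytic expectations available as plain functions.

## The model

**Placement.** Somas are rejection-sampled uniformly inside a mesh- or
cube-bounded volume under a hard minimum separation `dMin`; candidates that
land outside the volume but respect `dMin` are kept as invisible "padding"
so the density stays flat right up to the border.

**Touch detection.** Neurites are rasterized into cubic voxels (3 µm side
by default) with an exact supercover line traversal; the soma sphere is
voxelized as a postsynaptic target. A voxel containing the axon of neuron
*i* and a dendrite (or soma) of neuron *j* yields one putative synapse
*i → j*, provided the type pair is allowed. Voxels group into 100³-voxel
hypervoxels that tile space and can be processed independently;
dendrite–dendrite co-occupancy gives gap junctions.

**Pruning.** The probability of keeping a putative synapse is the product
of five stages,

    P_keep = P_dist · f1 · P_SM · P_mu · a3

applied in the order distance-dependent → f1 → soft-max → mu2 → a3, where
for a pair connected by *n* synapses entering the stage

    P_mu = 1 / (1 + exp(-8/mu2 · (n − mu2)))          (all-or-none, per pair)
    P_SM = 2·softMax / ((1 + exp(-(n − softMax)/5)) · n)   (per synapse)

`f1` keeps a fixed fraction of synapses, `a3` a fixed fraction of connected
pairs, and `P_dist(d)` is any user expression of dendritic path distance
`d` (µm). `expected_kept()` propagates a pair-count histogram through the
cascade exactly and serves as the independent oracle for the stochastic
`prune()`.

**Input.** External drive is piecewise-rate Poisson. Correlated ensembles
are built from a shared mother train thinned per child with probability
`P = √C`, merged with an independent train at rate `(1 − P)·f`, which keeps
the marginal rate at `f` and the pairwise spike-count correlation at `C`.

**Curation.** `detect_zjumps()` / `repair_zjump()` (align, split, tilt,
join), `detect_cut_points()` / `repair_cut()` (grafting intact donor
branches of the same centrifugal order), `shrinkage_correct()`,
`unravel()`, and length-preserving `randomize()` (jitter / twist / rotate,
plus random 3D scaling).

## Worked example

One hundred disjoint ball-and-stick neuron pairs are arranged so touch
detection finds exactly four putative synapses per directed pair, then the
`f1 = 0.5`, `mu2 = 3` cascade is applied:

```r
library(touchnet)

fx  <- make_grid_fixture(pairs = 100, syn_per_pair = 4)
det <- detect_network(fx$placement, fx$morphologies, fx$allowed_pairs)
nrow(det$synapses)
#> putative synapses: 400

params <- pruning_parameters(f1 = 0.5, mu2 = 3)
expected_kept(rep(4, 100), params)
#> analytic expectation: 65.9

kept <- vapply(1:1000, function(s) nrow(prune(det$synapses, params, s)),
               numeric(1))
mean(kept)
#> Monte-Carlo mean (1000 seeds): 65.6 +/- 0.42

synapses_per_pair_histogram(prune(det$synapses, params, 1))
#>  2  3  4
#>  4 14  9
```

400 putative synapses enter; `f1` halves them per synapse and the `mu2`
sigmoid then removes *all* synapses of weakly connected pairs, so on
average 65.9 survive — the Monte-Carlo mean agrees within its standard
error, and the surviving pairs keep 2–4 synapses each.

The full pipeline is also scriptable per network directory:

```r
cli(c("init",   "mysim", "--size", "10062", "--seed", "1234"))
cli(c("place",  "mysim"))
cli(c("detect", "mysim"))
cli(c("prune",  "mysim"))
cli(c("input",  "mysim", "--time", "10"))
```

(`init --size 10062` builds a 0.5 mm cube at the reference striatal
density.) A shell wrapper lives at `inst/scripts/touchnet.R`.

## Documentation

The methods vignette (`vignettes/touchnet-methods.Rmd`) describes the
model, the numerical choices, what the synthetic fixtures do and do not
establish, and known limitations. Function documentation is in the roxygen
comments in `R/`.
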