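---
title: "Subnetwork voting for functional brain networks: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subnetwork voting for functional brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvnet)
```

## The problem

Resting-state functional connectivity studies summarize each subject's brain
as a graph: regions are nodes, and two regions are joined when their activity
time courses are sufficiently correlated.  The conventional ("classic")
construction computes one Pearson correlation matrix over the whole series
and keeps the strongest `ND`% of pairs as edges.  Group comparisons of the
resulting graph properties are notoriously inconsistent across studies: the
correlation of a full-length, noisy series is easily inflated by transient
artifacts (scanner drift, physiological noise), so spurious edges enter
different subjects' networks in different places, widening within-group
variance and masking genuine between-group differences.

## The subnetwork-voting (SNV) construction

`snv_construct()` replaces the single full-length correlation with an
ensemble vote:

1. Slide a window of width `W` over the length-`L` series with stride 1,
   giving `K = L − W + 1` windowed subseries (identical boundaries for all
   regions).
2. In each window `i`, compute the Pearson matrix `C_i` and binarize it at
   the target density `ND`% by ranking absolute correlations — the binary
   subnetwork `S_i`.
3. Sum the subnetworks into the voting matrix `S = Σ S_i`, whose entries
   count, between 0 and `K`, how many windows selected each pair.
4. Threshold `S` itself at `ND`% to obtain the final network.  When several
   pairs share the marginal vote count `T`, the accumulated correlation
   magnitude `C = Σ |C_i|` breaks the tie in favour of the more strongly
   correlated pair; any residual tie falls back to ascending (row, column)
   index so the output is fully deterministic.

An edge must therefore be supported in many windows, not just on average
over the whole series; a transient artifact that dominates a few windows
contributes only a few votes.  With `W = L` there is a single window and
the construction reduces — bit for bit, which the test suite asserts — to
the classic method.

Both constructions realize their density exactly:
`target_edges(N, ND) = round(ND/100 · N(N−1)/2)`, rounded half-up so the
realized density is as close as possible to nominal.  Thresholding,
tie-breaking and the vote bound `0 ≤ S ≤ K` are checked against an
independently coded step-by-step oracle in the tests.

## Parameters that matter

* **Density `ND`** (percent of possible edges, default grid 8–16%): the
  customary range in which binary brain graphs stay sparse yet connected
  enough for meaningful topology.  All group analyses run across the grid
  rather than at one value.
* **Window width `W`** (time points, `3 ≤ W ≤ L`): the central trade-off.
  Narrow windows make per-window correlations unreliable; windows close to
  `L` leave too few subnetworks (`K` small) for the vote to matter.  For the
  reference series length `L = 128`, widths of 90–100 keep `K ≥ 25`
  subnetworks while each window still spans several minutes of scan time;
  `sweep_window_widths()` reproduces this diagnostic on any cohort.  A
  useful rule of thumb is `W ≈ 0.7·L`.
* **Long-edge threshold** (mm, default 75): an edge is "long" when its
  endpoint centroids are farther apart than the threshold.  There is no
  canonical anatomical cut-off, so the value is an explicit, recorded
  parameter rather than a constant.
* **Null-model size `n_null`** (default 100): the small-world value
  `σ = (C/C_rand)/(Λ/Λ_rand)` normalizes clustering and path length by
  means over degree-preserving surrogates (double-edge swaps, `10·m`
  attempts).  `σ` is deterministic given `(net, n_null, seed)`.  On very
  sparse small graphs every surrogate can be triangle-free, making
  `C_rand = 0`; this is reported as an error suggesting a larger ensemble
  rather than returning an infinite σ.

## Statistics and classification

Group differences are assessed per (property, density, window) cell with a
pooled-variance two-sample t-test (`--welch` switches to the unequal
variance form).  Degenerate cells are resolved explicitly: two constant
equal samples give `p = 1`, constant unequal samples `p → 0`.
Benjamini–Hochberg FDR control is applied across a method's full cell
family; uncorrected p-values are kept alongside the flags because raw
profiles are what the method comparison consumes.

The comparison between construction methods uses a paired sign-flip
permutation test on per-cell p-value differences, pairing classic and SNV
cells by (property, density) and treating window widths as additional SNV
cells.  The pairing unit and the sign-flip scheme are this package's
explicit encoding of an otherwise under-specified "permutation test";
the one-sided p uses the add-one rule `(1 + #{null ≥ obs})/(1 + n_perm)`
and is validated against exact enumeration of all `2^9` sign patterns in
the tests.  For classification scores the same machinery runs with the
orientation reversed (scores are higher-is-better).

Classification uses a linear SVM (cost 1, no class weighting) under paired
K-fold cross-validation: each fold holds one subject per group, so every
training set stays balanced.  Two feature sets are supported: the five
global properties, and an "optimized" set that drops the small-world value
and appends the degrees of nodes whose group difference survives FDR — with
the selection recomputed inside every training split, never on held-out
subjects (a leakage check in the suite perturbs test subjects and asserts
the selected nodes and scaling bounds are unchanged).  Features are min–max
scaled to [0, 1] with training-fold bounds; test values are clipped and a
constant training feature maps to the neutral 0.5.  Sensitivity counts the
second group (`B`) as positive — a convention, configurable via
`positive =`.  With balanced folds, accuracy equals
(sensitivity + specificity)/2, which the suite asserts.

## What the synthetic cohort emulates — and what it does not

Because the original imaging cohort is not redistributable, every
experiment runs on seeded synthetic data.  Signals are zero-mean Gaussian
with covariance `Σ = I + c·A`, where `A` is a planted ground-truth network
and `c` the coupling strength, so a planted edge appears as a population
correlation of about `c/(1 + noise_sd²)` after independent observation
noise.  Pearson correlation is the only statistic either construction
consumes, so matching second moments is sufficient and exactly
controllable; `Σ` is repaired by eigenvalue flooring at 1e−6 if a dense
`A` at high coupling pushes it indefinite.  Nonstationarity is modelled as
bursts: short windows in which a random half of the regions share one
strong noise sequence, creating exactly the transient spurious
correlations that motivate voting.

Two study designs are fixed in the acceptance suite:

* **Edge recovery**: N = 20 regions, L = 60 time points, truth density
  12%, coupling 0.6, noise sd 0.3, two bursts of 6 points at sd 3;
  W = 42 ≈ 0.7·L; 50 replicates.  Mean Jaccard overlap between recovered
  and planted edges is at least as high for SNV as for the classic
  construction.
* **Group comparison**: a 14+14 cohort at the reference series length
  L = 128 with W = 90 (K = 39 subnetworks), N = 30 regions, group A drawn
  from an integrated random truth and group B from a lattice-like
  (ring + 5% rewiring) truth — high clustering, low efficiency — with
  coupling 0.6 and bursts of 13 points.  The planted contrast is detected,
  and SNV grids flag at least as many significant (property, density)
  cells as classic grids.

These scales were chosen so the full suite and the acceptance script run
in minutes on one CPU; they are stated here because conclusions should be
read at that scale.  An instructive observation from these experiments: at
L = 128 the voting construction does *not* improve single-subject edge
recovery over the classic method, yet it markedly sharpens group
discrimination — the vote suppresses the idiosyncratic (burst-driven)
edges that differ across subjects, shrinking within-group variance even
when per-subject accuracy is unchanged.  That is the mechanism the method
claims, and it is the property a user should expect on real data:
better group-level consistency, not better individual networks.

The generator does not attempt hemodynamics, autocorrelated BOLD dynamics,
head motion, or parcellation effects.  Passing tests therefore demonstrate
the algorithmic claims (exact density, degeneracy to the classic method,
vote bounds, calibrated statistics, leak-free classification) and the
noise-burst mechanism — not performance on any particular scanner or
population.

## Numerical choices and degenerate inputs

* Constant (zero-variance) regions are rejected at load; inside a windowed
  subseries the check happens at correlation time so the error can name the
  subject, window and region.
* Correlations are clamped to [−1, 1] and symmetrized against floating
  drift before ranking.
* All tie-breaks are deterministic (weights, then ascending indices); two
  runs on the same input are bit-identical, and every stochastic routine
  (surrogates, permutations, simulation, fold assignment) takes an explicit
  seed.
* Disconnected pairs contribute 0 to efficiency (1/∞) and are excluded
  from the characteristic path length, keeping both finite at 8% density
  where fragmentation is common.
* Nodes of degree < 2 contribute clustering 0 and stay in the mean over
  all nodes.

## A small worked example

```{r example, eval = FALSE}
gt <- make_ground_truth(20, 12, "random", seed = 5)
spec <- synthetic_spec(gt, n_timepoints = 60, coupling_strength = 0.6,
                       noise_sd = 0.3,
                       burst = list(n_bursts = 2, burst_length = 6,
                                    burst_sd = 3), seed = 3)
tc <- simulate_subject(spec, "demo")
net_classic <- classic_construct(tc, density_pct = 12)
net_snv     <- snv_construct(tc, window_width = 42, density_pct = 12)
edge_recovery_score(net_classic, gt)
edge_recovery_score(net_snv, gt)
voting_state(net_snv)$window_count   # 19 subnetworks voted
```

## Known limitations

The method applies only to data with a temporal dimension; single-number
per-region measures cannot be windowed.  The per-window density equals the
final density by construction — the two are not independently tunable.
Window width selection remains a rule-of-thumb diagnostic
(`sweep_window_widths()`), not a data-driven estimator.  The permutation
scheme for method comparison is an interpretation (sign-flip on paired
cells) and is labelled as such wherever it is reported.
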