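---
title: "Methods: annotation-driven cell population discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation-driven cell population discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phenoforest)
```

# The problem

High-dimensional cytometry measures tens of protein markers on up to
millions of cells per sample. Identifying cell subpopulations by manual
gating is biased toward populations the analyst thought to look for, while
generic clustering methods return arbitrary numeric labels that are hard to
match across samples and harder still to interpret. `phenoforest`
implements an annotation-driven alternative: every discovered population is
named by where it falls relative to data-driven, per-marker expression
thresholds (for example `CD8+ PD-1dim CD28+`), and populations are matched
across samples *by that name*, never by a distance metric in marker space.

The method's key assumption is that biologically distinct populations
separate into modal groups along at least some measured markers. All of the
machinery is one-dimensional and nonparametric: multimodality is detected
with the dip test, and gates are placed at antimodes of a taut-string
density estimate. No distributional form is assumed for marker expression.

# The pipeline

The analysis of one experiment proceeds in two phases.

**Phase 1 — standardized thresholds.**

1. *Marker bounds.* For each marker the 1st and 99th expression percentiles
   are computed per sample; the 5th percentile of the 1st percentiles and
   the 95th percentile of the 99th percentiles become the marker's bounds.
   Events outside the bounds (debris and doublet pile-ups at the edges of
   the scale) are kept, but flagged and excluded from all density
   estimation; the count of interior events is the marker's *effective
   sample size*. A fluorescence-minus-one control can replace a lower
   bound via `pf_config(boundary_overrides=)`.
2. *Annotation forest* (`grow_annotation_forest`). Per experimental unit,
   the exhaustive collection of gating strategies of depth at most 3: at a
   node, every active marker not already on the path whose dip p-value
   falls below 0.25 is gated at the antimode midpoints of its taut-string
   density (at most 4 gates; more means the marker is treated as
   non-gateable there). Children are event subsets between consecutive
   gates; nodes below 500 events are not gated further.
3. *Depth scores* (`depth_scores`). Each gating record contributes
   `omega = Q * P * D`: `Q` is the product of `1 - p` over the dip
   p-values along its strategy (a grandchild whose three ancestral
   p-values all equal 0.25 scores `0.75^3 = 27/64`), `P` is the node's
   effective size relative to the marker's effective root size, and
   `D = 1/d_i` penalizes depth `i` by the number of gatings at that depth
   (the factorial growth of strategy space is why depth stops at 3 —
   deeper markers are dominated after normalization). Scores are
   normalized per unit so the best marker scores 1.
4. *Marker selection* (`select_markers`). A marker is kept when the median
   (configurable quantile) of its normalized depth scores across units
   exceeds 0.01 (configurable threshold).
5. *Boundary estimation and standardization* (`estimate_unit_boundaries`,
   `standardize_all`). Per unit and marker, the gate count with the
   largest total omega mass wins, and boundaries are omega-weighted
   averages of gate locations. Across units the standard count is a
   majority vote (ties toward the smaller count); standard locations are
   rank-wise medians over conforming units. Non-conforming units are
   reconciled by greedy nearest-distance matching: surplus boundaries
   farthest from the standards are deleted, unmatched standards imputed.
   An imputation hierarchy restricts pass 1 of this process to units
   sharing a class label (e.g. tissue vs blood), with a second global pass
   for anything still missing.

**Phase 2 — discovery and counting.**

6. *Discovery forests* (`discover_unit`). Randomized partition trees with
   no depth limit and a 25-event leaf floor: at each node one marker is
   drawn uniformly from the multimodal candidates. The random marker
   choice is what makes trees diverse; with the panel's markers removed
   along each path, trees terminate after at most one split per marker.
7. *Leaf scoring and selection.* Each leaf scores
   `n * prod_m [p_dip,m * exp(-|tau3,m|) * exp(-|tau4,m - 0.1226|)]` over
   the selected markers, with `tau3`, `tau4` the trimmed (trim = 1) sample
   L-skewness and L-kurtosis of the leaf margin; 0.1226 anchors the
   kurtosis term at the Gaussian reference value, so homogeneous,
   symmetric, unimodal margins score highest. A disjoint set of leaves is
   chosen greedily by score across all trees.
8. *Annotation.* Selected leaves are annotated by comparing margin medians
   with the unit's reconciled thresholds (a median exactly on a boundary
   takes the lower level); one boundary yields `-`/`+`, two yield
   `-`/`dim`/`bright`, three and four extend the ordinal scale.
   Independently, *every cell of every sample* is annotated by direct
   thresholding — this per-cell labeling is what the count matrix uses, so
   targeted extraction on new data is well defined.
9. *Down-selection and counting.* Phenotypes are matched across units by
   exact annotation-string equality; with more than 4 samples, the
   occurrence threshold is the elbow of the greatest convex minorant of
   the occurrence distribution restricted to `[max(2, 0.05 n), min(n - 1,
   0.95 n)]` (vertical distance to the chord), otherwise every phenotype
   is kept. The primary output is the sample-by-phenotype count matrix of
   exact cell counts.

# The nonparametric primitives

Both one-dimensional primitives are implemented in compiled code inside
the package and validated in the test suite against independent oracles.

**Dip statistic.** The dip is the smallest sup-norm distance between the
empirical CDF and any unimodal CDF. The implementation iteratively shrinks
a candidate modal interval between the greatest convex minorant and least
concave majorant of the empirical CDF, accumulating the staircase
deviations outside it; the tests verify it to 1e-7 against a brute-force
binary search on the distance whose feasibility check is an exact
convex/concave tube argument. P-values are calibrated against the uniform
null: a Monte-Carlo quantile table (10,000 replicates per tabulated sample
size down to 2,000 at the largest sizes, fixed seeds) ships as plain text
and is interpolated on the `sqrt(n) * dip` scale in `log n`; sample sizes
outside the table trigger a seeded on-the-fly simulation. The uniform
null is the natural reference here because the dip of a sample is
invariant under monotone transformation of an atomless null.

**Taut-string density.** The estimate is the derivative of the shortest
path through a tube of radius `r` around the empirical CDF, computed by
divide and conquer (the string must touch the most-violated tube bound of
any chord; recurse on both sides). The number of modes is the minimal
number consistent with the tube, which is exactly the parsimony wanted for
gating. The tube radius is a single global `r = c / sqrt(n)` — a
Kolmogorov-type band — rather than a locally adaptive multiresolution
radius; a global band is simpler, deterministic, and sufficient for gating
because the dip test (not the taut string) is the arbiter of whether a
marker is multimodal. The default `c = 0.4` was calibrated once so that a
single Gaussian sample of n = 1000 is estimated unimodal in at least 99%
of seeded trials while keeping sensitivity to minority mixture components;
it is exposed as `ts_scale` in `pf_config()`.

# Tuning parameters

| parameter | default | role |
|---|---|---|
| `dip_threshold` | 0.25 | dip p-value below which unimodality is rejected; deliberately liberal so that gating is driven by density shape, with the depth score absorbing noise |
| `min_events` | 500 | smallest population gated in the annotation forest; keeps Q/P/D well defined |
| `min_leaf` | 25 | discovery-tree leaf floor = smallest discoverable population |
| `max_depth` | 3 | markers per gating strategy (factorial-cost argument above) |
| `max_gates` | 4 | at most 5 expression categories per marker |
| `ts_scale` | 0.4 | taut-string band scale factor (calibration above) |
| `score_quantile` | 0.5 | cross-unit depth-score quantile used for selection |
| `score_threshold` | 0.01 | depth-score selection threshold |
| `occurrence_threshold` | `"auto"` | GCM elbow (above) or a fixed integer |
| `n_trees` | 100 | discovery trees per unit; more trees explore more partitions at linear cost |

All randomness (discovery forests, tie-breaking jitter, embedding noise)
is seeded from `pf_config(seed=)`; per-unit seeds are derived
deterministically, so a run is reproducible from its configuration alone.

# What the synthetic generator emulates

`simulate_gaussian_experiment` reproduces the benchmark design the method
is evaluated on: 10-dimensional Gaussian mixtures whose component means
have entries 0 ("not expressed") or 8 ("expressed"), variances uniform
between 1 and 2 with random correlation redrawn per sample and component,
mixture weights taken from a fixed reference vector (0.1425 down to
0.002226562 in powers of two of multiplicity) renormalized uniformly, and
per-sample batch effects as integer-rounded N(0, 1/2²) mean shifts.
`simulate_responder_experiment` fixes the printed 125-component weight
vectors in which component 120's weight doubles from 0.0011 to 0.0022 in
responders — a perfect single-component predictor of a binary outcome.
`transform_nongaussian` applies `gamma(1 + |x/4|)` columnwise, producing
the heavy, asymmetric margins typical of randomized mass-cytometry data.

What this emulates well: marker panels where populations are modal groups,
sample-to-sample location shifts, non-Gaussian margins, rare predictive
populations (~27 cells per 25,000). What it does not emulate: spillover
and compensation artifacts, batch-varying staining efficiency,
doublets/debris (the marker-bound machinery is exercised only lightly),
marker correlation structures specific to real panels, and technical
dropout. Passing the benchmarks therefore demonstrates correct recovery of
modal structure, not robustness to every cytometry artifact.

# Numerical choices and degenerate inputs

* Tied values (common after integer-valued transforms) are broken by
  deterministic rank-preserving jitter of magnitude 1e-9 times the data
  range before density estimation.
* A marker constant across all samples makes its default bounds collapse
  and is reported as an error instructing its exclusion.
* Dip on fewer than 4 events is an error that callers treat as
  "unimodal"; taut strings require 25 events — below that a node is
  simply a leaf.
* Depth-score ties (two markers sharing the maximum) both receive score 1;
  reporting order is panel order.
* Gate-count votes tie toward the smaller count; boundary-mass ties in a
  unit likewise take the smaller gate count.
* Imputed boundaries sit at the standard location shifted by the unit's
  mean signed offset between its matched boundaries and their standards,
  preserving unit-specific location shifts; if reconciliation ever yields
  non-increasing locations they are re-sorted and separated by 1e-9 times
  the marker range.
* In `pfda_test` the cluster factor uses a reference-level
  parameterization; the tested contrast (responder effect averaged over
  clusters) is constructed from the coefficient covariance so its value is
  invariant to which cluster is the reference.
* GLMM fits that fail to converge are flagged and reported with `NA`
  p-values; a beta-binomial fixed-effect fallback (glmmTMB) is attempted
  and flagged distinctly. Exact numerical parity with any particular
  mixed-model backend is not promised; the contract, enforced by
  simulation tests, is distributional correctness (near-nominal type-I
  error) under the null.

# Design choices where the design was open

* *Shape score functional form.* The ingredients (margin dip p-values and
  trimmed L-moments) are fixed by the method; the multiplicative
  combination with the Gaussian L-kurtosis anchor 0.1226 is this
  package's concrete choice, covered by direct arithmetic tests and
  treated as replaceable.
* *Discovery-tree randomization.* Exhaustive unconstrained branching is
  computationally infeasible; drawing the split marker uniformly from the
  multimodal candidates generates forest diversity at bounded cost.
* *Leaf selection.* Greedy weighted set packing ordered by score (ties:
  larger leaf, then earlier tree) rather than optimal packing; the toy
  tests show greedy attains the optimum on small instances, and
  disjointness is asserted on every run.
* *Occurrence curve.* The "distribution of occurrences" is read as the
  normalized count of phenotypes at each occurrence value, and the elbow
  uses vertical distance to the chord; the cumulative version can be
  obtained by thresholding manually.
* *Boundary-estimation weights.* The omega weights from depth scoring are
  reused for boundary estimation rather than recomputed per gate-count
  class.
* *Targeted level coarsening* (e.g. treating `dim` and `bright` as `+`
  when a validation dataset yields a single threshold) is expressed
  explicitly in the target's accepted-level sets; nothing is inferred
  automatically.

# Problem sizes used by the tests and acceptance script

The shipped checks run the clustering benchmark at 2 replicates of
3 samples x 10,000 cells for 5 and for 45 mixture components (both raw and
gamma-transformed), with 25 discovery trees per unit, and the responder
benchmark at 2 iterations of the full 20-sample x 25,000-cell design with
10 trees per unit. These sizes keep a complete run on a single CPU
comfortable while leaving the generating process exactly as specified;
`n_trees` trades computation for partition diversity and can be raised
freely for real analyses.

# Known limitations

* Only one-dimensional structure is detected: a population separable
  solely by a rotated linear combination of markers, with unimodal
  margins, is invisible.
* Markers expressed on rare subsets can score low depth and be dropped;
  the supervised boundary list and FMO-informed bounds exist precisely to
  rescue such markers.
* Annotation strings are matched exactly; a marker whose standard gate
  count differs between two datasets must be reconciled through explicit
  level coarsening in targeted extraction.
* The FCS reader covers list-mode FCS 3.0/3.1 with float, double, or
  fixed-width integer data — the subset needed to ingest typical modern
  exports; compensation, transformation, and FCS writing are out of
  scope, and inputs are assumed pre-gated and pre-transformed upstream.
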