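---
title: "Representational topology analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representational topology analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rta)
```

## The problem

Representational similarity analysis (RSA) compares two measurement systems
— brain regions, subjects, species, network layers — through their
representational dissimilarity matrices (RDMs): for each pair of stimuli
(or time points), the dissimilarity between the evoked response patterns.
Two systems are judged similar when their RDMs correlate (a "second-order
isomorphism", conventionally Spearman over the lower triangle).

That judgement is blind to global shape. A set of points on a torus and the
same points projected onto the annulus beneath it produce RDMs that
correlate near 1, yet the two spaces host different numbers of periodic
structures (two independent loops versus one), which implies different
underlying computations. Likewise a Gaussian cluster and the same cluster
with a small hole punched in its centre have nearly identical covariance —
and hence nearly identical linear summaries — while being topologically a
blob and a ring. `torus_annulus_experiment()` reproduces the first failure
case end to end:

```{r, eval = FALSE}
ex <- torus_annulus_experiment(n = 1000, R = 2, r = 1, seed = 1)
ex$spearman # ~0.98: RSA equates the two spaces
```

This package analyses the *topology* of an RDM directly, via persistent
homology, and provides the statistical machinery to threshold, compare and
visualize the result.

## Persistent homology of an RDM

A Vietoris–Rips complex at linkage radius $\varepsilon$ connects every set
of items that are pairwise within $\varepsilon$. Sweeping $\varepsilon$
from 0 upward, topological features — connected components ($H_0$), loops
($H_1$), voids ($H_2$) — appear and disappear; each feature's birth and
death radii form a point in the persistence diagram, and
$\text{persistence} = \text{death} - \text{birth}$ measures how robust a
feature is. `build_vr_filtration()` + `compute_persistence()` (or the
`rips_diagram()` shortcut) implement the standard boundary-matrix reduction
over $\mathbb{F}_2$:

* **Coefficients.** $\mathbb{F}_2$, the universal convention for Rips
  persistence.
* **Cutoff.** The default `max_radius` is the maximum RDM entry, at which
  scale the complex is a single component. Features still alive at the
  cutoff are reported with `death = max_radius` and `death_capped = TRUE`,
  so downstream distances treat them as finite while the flag preserves the
  distinction.
* **Zero-persistence features are dropped.** They are invisible in the
  diagram and meaningless for thresholding; duplicated items therefore
  contribute nothing beyond one $H_0$ feature.
* **Determinism.** Simplices are ordered by (value, dimension,
  lexicographic vertex tuple). Reduction, pairing, and representative
  cycles are pure functions of that order, so reruns are bit-identical.
  The `twist` (clearing) optimization is the default and is tested to give
  pairings identical to plain reduction.
* **Representative cycles.** For a paired loop, the reduced column of its
  killing triangle at pairing time — a set of edges, each entering at or
  before the loop's birth, with every vertex of even degree. For a loop
  that survives to the cutoff, the accumulated chain of its birth column.
  Like any homology generator, the cycle is one representative of its
  class, not a unique object.

`max_dim` defaults to 1 because loops carry the analyses this package
targets; `max_dim = 2` (voids, e.g. for torus-versus-sphere questions) is
available at substantially higher cost, since the filtration must then
enumerate 3-simplices.

## Comparing diagrams: exact bottleneck distance

All inference rests on the bottleneck distance: the smallest $c$ such that
the two diagrams can be matched feature-to-feature (or feature-to-diagonal
at cost persistence/2) with every match within $L_\infty$ cost $c$.
`bottleneck_distance()` computes it **exactly**: the optimum is always one
of the finitely many candidate costs (half-persistences and pairwise
$L_\infty$ costs), so a binary search with a bipartite-matching feasibility
check at each candidate terminates at the true value. Exactness matters
because permutation p-values below compare sums of these values; an
approximate distance would make the test's ties and orderings
implementation-dependent. The feasibility check only needs to cover
features with persistence $> 2c$ on either side, which keeps the matchings
small; the one-sided matchings combine by the Mendelsohn–Dulmage theorem.

## Separating signal from noise: bootstrap thresholding

`bootstrap_threshold()` implements the resampling band: resample the items
with replacement `n_boot` times, compute each resample's diagram at the
full RDM's cap, record its bottleneck distance to the full diagram per
dimension, and take the $(1-\alpha)$ quantile $c$ of those distances.
Features with persistence above $2c$ are significant. Defaults are
`n_boot = 30` and `alpha = 0.1` — thirty samples being the usual minimum
for a stable empirical quantile, and 0.1 avoiding over-thresholding of
moderately persistent structure. Resampled index multisets are
deduplicated before building the sub-RDM (duplicates only add
zero-persistence features) and redrawn in the degenerate case of fewer
than three distinct items.

Operating characteristics at the package's reference conditions (checked in
the test suite): a noiseless 60-point circle keeps exactly one significant
loop, and a 60-point 2D Gaussian cluster (sd 1) keeps none, in at least 95%
of 100 seeds each.

## Adjudicating models: the paired-bootstrap permutation test

Given a target RDM $T$ and candidate model RDMs $M_i$ with item
correspondence, `adjudicate()` (or the lower-level
`paired_bootstrap_diagrams()` / `permutation_test()` /
`distance_confidence_interval()`) asks which model's topology is closest
to the target's:

1. Draw `n_boot` shared item resamples; for each, compute the diagrams of
   the target and model sub-RDMs. Sharing the resample across the pair is
   what makes the procedure paired; both diagrams use a shared cap equal to
   the joint maximum dissimilarity of the two RDMs so capped deaths are
   comparable.
2. The observed statistic is the within-group sum of pairwise bottleneck
   distances (both groups, upper triangles) — a topological sum of squared
   errors. Distinct topologies make each group internally coherent and the
   statistic small relative to its permutation distribution.
3. Each permutation independently swaps each pair's two diagrams with
   probability 1/2. With `n_perm` permutations,
   $p = (1 + \#\{S_{perm} \le S_{obs}\})/(1 + n_perm)$.
4. The 2.5% and 97.5% percentiles (linear interpolation) of the
   within-pair distances give a 95% confidence interval for the
   target-model topological distance. Among models *not* significantly
   different from the target, a model whose interval lies entirely below
   another's is the better model; `bonferroni = TRUE` divides the
   threshold by the number of models.

Defaults are `n_boot = 100` and `n_perm = 1000`. Design choices that the
procedure's loose verbal description leaves open, fixed here once:

* The +1 permutation correction (p can never be 0, and identical spaces
  give exactly p = 1).
* "Less than" is implemented as $\le$, so the degenerate all-zero case —
  target identical to model — yields p = 1 rather than a spurious
  rejection.
* The paired shuffle is an independent within-pair swap, the standard
  exchangeability move for paired two-group designs.
* The loss statistic is the plain unnormalized sum of the upper triangle;
  no group-size normalization is applied (group sizes are equal by
  construction here, so normalization would only rescale).
* All pairwise distances among the $2N$ diagrams are computed once and
  cached; permutations are then index shuffles over the cached matrix.

At the package's reference conditions (test suite): 60 points shared
between a torus ($R = 2$, $r = 1$) and its annulus projection are declared
topologically different at $p \le 0.05$ in essentially every one of 50
seeds (`n_boot = 50`, `n_perm = 500`) — power against a genuine
topological difference that second-order correlation cannot see.

**Calibration caveat.** The permutation test is exactly the classical
two-group diagram test, and in the setting that test was built for —
groups of diagrams from *independent* replicates (subjects, runs, sessions)
— it is well calibrated: in the suite's simulation, iid groups of
noisy-circle diagrams reject at close to the nominal 10% rate. Feeding it
*bootstrap* groups derived from two fixed RDMs is a different situation:
all diagrams in a group share one underlying RDM, so within-group
(resampling) variability is small compared to any fixed difference between
the two RDMs, and the test will, given enough bootstrap replicates, flag
*any* discrepancy — including pure measurement noise. In our simulations,
two independently noise-perturbed copies of the same 60-point circle are
declared different in the large majority of seeds, and shrinking the noise
does not restore calibration, because the bootstrap variability shrinks
with it. Independent within-pair swaps do not preserve the joint law of
diagrams that share an RDM; only the full swap of all pairs does. A small
p-value from the bootstrap-paired pipeline should therefore be read as
"these two specific RDMs differ topologically beyond resampling
variability", not as evidence that the underlying representational
processes differ; for process-level claims, build the groups from
independent replicates and use the same `permutation_test()` on them. The
confidence intervals, which compare the *magnitudes* of target-model
distances across candidate models, are the more informative adjudication
output.

## Proximity-labeled Rips graphs

A PLRG overlays geometry on topology: take the Rips graph at the birth
scale of the most persistent loop, keep the connected component containing
the loop's representative cycle (isolated vertices and unrelated clumps
are uninformative at that scale), lay it out with Fruchterman–Reingold
(seed fixed at 42, 500 iterations, recorded in the object), and colour
each node by its classical-MDS coordinates: pink-to-green along the first
axis, blue-to-orange along the second, averaged channel-wise in RGB (the
top-right corner is the green/orange average, a brown). Where the colour
gradient sweeps smoothly around the graph, MDS geometry and Rips topology
agree; colour discontinuities across adjacent nodes mark structure that
the linear projection collapsed.

Choices made here: axis values are min-max normalized (a symmetric-about-0
normalization would tie colours to the MDS origin, which is arbitrary);
MDS is computed on the full RDM by default with `mds = "component"`
offered for component-restricted embeddings; the MDS reflection ambiguity
is fixed by making each column's largest-magnitude coordinate positive;
endpoint RGB values are configurable with defaults pink (255,105,180),
green (0,128,0), blue (0,0,255), orange (255,165,0). Cycle nodes are
emphasized with deeper (darkened) fills and larger markers.

`classical_mds()` wraps `stats::cmdscale`; columns with non-positive
eigenvalues are zeroed with a warning rather than dropped, so the
embedding always has the requested width.

## The correlation-to-distance transform

Correlation similarity matrices are converted by
`cor_to_rdm(mode = "linear")`: $\rho \mapsto 2(1-\rho)$, entries in
$[0, 4]$. This linear rescaling is the package default. It is not a metric
in general; `mode = "sqrt"` ($\sqrt{2(1-\rho)}$, the Euclidean distance
between standardized patterns) is provided for users who need the triangle
inequality, and the tests verify it holds. Rips filtration values are
entry-wise maxima, so any monotone transform of the entries reparametrizes
the filtration axis without changing which features exist or their order —
the choice mainly affects the scale on which persistence is measured.

## Synthetic generators and what they do (not) show

All generators are pure functions of (parameters, seed): `sample_torus`
(default $R = 2$, $r = 1$), `project_to_annulus`, `sample_circle`,
`sample_gaussian_clusters`, `sample_punctured_gaussian`, and the bundled
`torus_annulus_experiment`. Torus sampling draws both angles uniformly by
default (`angle_uniform`); `area_uniform` rejection-samples the minor
angle against $R + r\cos\theta$ for the uniform surface measure. The
defaults are the reference conditions used throughout the tests: 1,000
points for the RDM-correlation demonstration, 60 points for the
thresholding and adjudication characteristics, noise sd 0.1 on unit-radius
circles for null calibration, a 0.5-sd hole for the punctured-cluster
contrast (covariance compared at $n = 200$, thresholded loop counts at
$n = 120$).

These clouds emulate the *topology* of representational spaces with
controllable noise; they do not emulate fMRI measurement processes —
spatial autocorrelation, hemodynamics, inter-subject variability, or
correlation-derived (rather than Euclidean) dissimilarities. Passing tests
therefore certify the machinery (the homology, the distances, the
calibration of the inference under i.i.d. geometric noise), not the
field-validity of any particular neuroimaging conclusion.

## Numerical conventions and limitations

* RDM validation: symmetry within $10^{-12}$ accepted silently; asymmetry
  up to $10^{-8}$ (floating-point I/O noise) symmetrized with a warning;
  larger asymmetry rejected. Diagonal must be zero to $10^{-12}$.
* Percentiles use linear interpolation between order statistics
  (`stats::quantile` type 7) everywhere.
* Tie-breaks: equally persistent features resolve to the earlier birth,
  then to diagram order, with a warning on exact ties — in noisy data the
  ordering of near-tied loops is itself noise.
* Runtime scales steeply with item count (the filtration holds
  $O(n^3)$ triangles at `max_dim = 1`): diagrams are instant below
  $n \approx 100$, seconds at $n \approx 120$ and tens of seconds at
  $n \approx 200$. The resampling procedures multiply that by `n_boot`.
  Diagrams of RDMs with more than a few hundred items are out of this
  package's intended range.
* Comparing diagrams from RDMs of very different sizes is not supported
  conceptually: diagram size confounds distance calculations, and the
  adjudication procedure requires identical item correspondence.
* Homology above dimension 2, approximate/sparse filtrations, kernel
  similarities between diagrams, and Mapper/UMAP/Isomap-style graph
  layouts are out of scope.
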