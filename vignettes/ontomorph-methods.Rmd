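---
title: "Quantifying cranial ontogeny and heterochrony with ontomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cranial ontogeny and heterochrony with ontomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontomorph)
```

## The problem

Heterochrony — evolutionary change in the timing or rate of development —
is inferred in fossil lineages by comparing ontogenetic trajectories of
descendants with those of their ancestors. For taxa known only from
skeletal material the trajectory is reduced to a size–shape path: a
juvenile and an adult skull, each captured as a 2D landmark configuration,
connected by an allometric growth vector. Ancestral trajectories are not
observable; they are reconstructed on a time-calibrated phylogeny from the
juvenile and adult shapes of the sampled taxa. A descendant adult whose
shape sits at significantly *lower* allometric shape values than its
reconstructed ancestor's adult retains juvenile characteristics
(paedomorphosis); significantly *higher* values indicate development
beyond the ancestral adult condition (peramorphosis). Without individual
age data, allometric comparisons support only these two categories — not
the underlying processes (progenesis, neoteny, acceleration,
hypermorphosis), which require growth timing.

`ontomorph` implements this workflow end to end: Procrustes
superimposition, ordination, allometric regression, time calibration,
ancestral state reconstruction, phylogenetic signal testing, trajectory
quantification, and the paedomorphosis/peramorphosis classifier, plus a
fully synthetic data generator so that every stage is testable against a
known ground truth.

## Superimposition

`gpa()` performs generalized Procrustes analysis: configurations are
centered, scaled to unit centroid size, and iteratively rotated onto the
evolving mean shape until the consensus moves less than `tol` (default
1e-10, at most 200 sweeps). Numerical choices:

* **Scaling.** The default (`scale_method = "unit"`) keeps every aligned
  configuration at exactly unit centroid size before tangent projection.
  A full-Procrustes variant (`"full"`), which additionally shrinks each
  specimen by the cosine of its Procrustes angle from the consensus, is
  available behind the flag; at the shape distances typical of skull data
  the two differ at the fourth decimal.
* **Reflections** are forbidden (rotations restricted to determinant +1):
  all specimens must be digitized facing the same direction, because no
  superimposition can repair a mirrored specimen once reflection is
  excluded. `allow_reflection = TRUE` exists for synthetic tests only.
* **Semilandmarks** are treated exactly like landmarks and are never
  slid. Sliding is deliberately not implemented: for outline-dominated
  skull data, sliding can introduce large artificial deformation, and the
  equal-weighting convention keeps the analysis reproducible without a
  bending-energy implementation.
* **Tangent projection** (default on) orthogonally projects the aligned
  shapes onto the tangent plane at the consensus. It is toggleable so its
  effect can be quantified; on realistic shape variance it moves PC
  variance shares by well under half a percentage point.
* **Canonical orientation.** After convergence the consensus is rotated
  onto its principal axes (major axis along x, the farthest landmark at
  positive x). Without this step the output frame would depend on the
  arbitrary orientation of the input, and superimposing rotated copies of
  a data set would not reproduce the same coordinates.

`centroid_size()` is the usual square root of summed squared distances of
landmarks to their centroid; log centroid size uses the natural log (the
base only rescales regression slopes by a constant).

## Ordination and component selection

`shape_pca()` eigendecomposes the sample covariance matrix (divisor
n − 1) of the Procrustes coordinates. GPA leaves four near-null
dimensions (two translations, rotation, scale); eigenvalues below 1e-12
of the largest are excluded before variance fractions are formed, so the
broken-stick baseline is computed over the genuinely non-degenerate
components. Component signs are fixed by making the largest-magnitude
loading positive, so stored results are stable across platforms.

`broken_stick_significant()` retains the initial run of components whose
variance fraction exceeds the broken-stick expectation
$b_i = \frac{1}{p}\sum_{j=i}^{p} 1/j$. With a single nonzero component
the stick is degenerate ($b_1 = 1$) and the component is retained.

## Allometric regression and scalar shape variables

`regress_shape_on_size()` fits the multivariate regression of shape on
log centroid size. The pooled within-group variant centers *both* shape
and size within groups (the standard construction; the non-pooled variant
is what reproduces a whole-sample allometry estimate). The amount of
shape variation explained is `percent_predicted` = 100 × predicted SS /
total SS, tested by randomly permuting the size values against the shapes
(default 10,000 permutations, p = (b + 1)/(n + 1) so p is never zero).

Two scalar shape variables express each specimen's position along the
allometric axis:

* the **regression score**, the projection of (shape − grand mean) onto
  the unit-normalized coefficient vector — unit normalization keeps the
  score in Procrustes units, commensurable with distances; and
* the **Euclidean distance** from a reference specimen (by default the
  smallest specimen of the sample, whose value is set to zero), an
  axis-free check on the regression score.

## Time calibration and ancestral states

`calibrate_branch_lengths()` assigns each internal node the age of its
oldest descendant tip (tip ages are midpoints of stratigraphic
intervals), adds 1 Myr to the root, and removes the resulting zero-length
branches by sharing the duration of the nearest strictly older ancestor
branch equally along each zero-length chain. Chains are resolved deepest
first; note that a zero-length internal chain always terminates in the
tip that pinned the ages, so the shared chain includes that terminal
branch (a 6-Myr branch over two zero internal branches and the pinning
tip branch yields four branches of 1.5 Myr).

`ancestral_states_scp()` reconstructs ancestral states by weighted
squared-change parsimony: minimize
$\sum_{\text{branches}} \lVert x_{child} - x_{parent}\rVert^2 / \ell$.
Setting the gradient to zero gives a sparse linear system in the internal
states, solved exactly per coordinate — no iterative pruning
approximation. The minimizer coincides with the maximum-likelihood
ancestral states under Brownian motion, which the test suite verifies
against an independent implementation to 1e-8. The minimized objective is
the *weighted tree length*, the statistic of the permutation signal test:
states are shuffled across tips and p is the fraction of permuted tree
lengths at or below the observed one (short = strong signal).

`k_mult()` implements the multivariate K statistic: the ratio of mean
squared deviations from the phylogenetic (GLS) mean in the original
versus phylogenetically whitened space, scaled by its Brownian
expectation $(\mathrm{tr}\,C - n/\mathbf{1}^{\top}C^{-1}\mathbf{1})/(n-1)$
with C the shared-branch-length covariance in Myr. K = 1 under Brownian
motion (the suite confirms a replicate mean within 0.1 of 1 on a 64-tip
tree); for one trait it reduces exactly to Blomberg's K.

## Trajectories and the heterochrony classifier

A trajectory is the juvenile→adult pair of one taxon (or reconstructed
ancestor). Change vectors point from juvenile to adult: published
notation for the two-stage change vector is ambiguous about subscript
order, and figures in this literature draw arrows toward the adult, so
the juvenile→adult orientation is adopted and applied consistently
(angles between trajectories are unaffected as long as one convention is
used throughout). Angles use the dot-product formula in an atan2 form
that is exact at 0°, 90° and 180°; lengths are Euclidean norms.

Ancestral trajectories pair the adult states reconstructed on the full
tree with the juvenile states reconstructed on the tree pruned to the
juvenile-bearing taxa (pruning preserves the original calibration by
summing the removed branch durations).

The classifier compares adult stages of an ancestor–descendant pair on
both shape variables. The significance threshold is 1.5 × CI, where CI is
the half-width of the t-based 95% confidence interval of the *mean*
branch-wise difference of the variable over all 2n − 2 branches of the
adult supertree — the only quantity in the analysis with that
cardinality. Because the published description does not pin down "the CI
value", an empirical-quantile alternative (half the central 95% range of
the branch differences, roughly 1.96 branch SDs) is available via
`ci_threshold(method = "quantile")`. Both deltas significant and negative
→ paedomorphosis; both significant and positive → peramorphosis;
anything else → undetermined. Requiring agreement of both variables
matches how every published case in this workflow is argued.

## The synthetic study

`fixture_study()` generates the package's reference data set: 12 taxa on
a calibrated supertree spanning the late Triassic to Late Cretaceous
(root ~206 Myr), five of them with juvenile stages, all sharing one
allometric axis. Its conditions are fixed once and documented here:

* **Base shape**: a deterministic schematic saurischian skull in lateral
  view, 20 fixed landmarks and 51 semilandmarks on the outline, naris,
  antorbital fenestra, orbit and infratemporal fenestra.
* **Allometric axis**: a unit vector orthogonal to the similarity null
  directions, slope 0.05 Procrustes units per unit log CS; log CS runs
  from 0.5 (juvenile) to 2 (adult), giving ontogenetic trajectories of
  ~0.075 Procrustes units — comparable to interspecific distances, as in
  real saurischian samples.
* **Digitization noise**: isotropic Gaussian displacement per landmark
  with SD 0.5% of centroid size, the order of careful manual digitizing
  error.
* **Brownian drift of shape**: rate 1e-8 per coordinate per Myr, kept
  below the noise floor deliberately. Baseline drift *along the
  allometric axis* is mathematically indistinguishable from heterochrony,
  so a generator meant to provide unambiguous ground truth must keep
  undirected drift small and inject directed shifts explicitly.
* **Heterochronic shifts**: signed displacements along the allometric
  axis attached to named branches (default ±0.02 on five branches,
  mirroring a study with paedomorphic and peramorphic episodes and three
  unshifted comparisons). Shifts are applied to the lineage mean, so both
  stages of a shifted taxon move together, and descendants inherit them.
* **Adult size drift**: log CS Brownian rate 2e-3 per Myr by default.
  For *null* (zero-effect) simulations this is switched off, because
  size evolution along a shared allometric line is itself
  allometric-scaling signal — a larger descendant genuinely extends the
  ancestral ontogeny — and counting it as a "false" call would misstate
  the classifier's error rate.
* **Tree ages**: nested clades are progressively younger so that no
  internal node used in a comparison collapses onto a single tip through
  near-zero branches. One exception is unavoidable: the root is always
  pinned to the oldest tip by the max-age calibration rule, so the oldest
  tip is a background taxon that carries neither a juvenile series nor a
  shift.

The generator is seed-deterministic, and `write_fixture_bundle()` emits
the whole study as TPS + CSV + NEXUS + JSON configuration files.

What passing tests on these data do and do not show: they demonstrate
that each operator implements its definition exactly (oracle tests), that
the pipeline is deterministic and invariant where it must be, and that
the classifier recovers injected shifts of the study's magnitude with
high probability. They do not show that real skull data satisfy the
generator's assumptions (a single shared allometric axis, isotropic
noise, two clean stages per taxon), nor do they validate the biological
interpretation of any call.

## Known limitations

* **The 1.5 × CI rule is anticonservative for single comparisons.** The
  threshold is a standard error of the *mean* branch difference
  (≈ 0.24–0.66 of one branch-difference SD, depending on the branch
  count), applied to individual differences whose null variation is of
  the same order as a branch difference. Terminal comparisons, which
  inherit a single specimen's digitization noise undamped, therefore
  produce frequent spurious significance under a pure null; in
  simulations at the package's study conditions roughly a third of
  zero-effect calls come out classified. The quantile CI variant is the
  conservative alternative. This liberality is a property of the
  published decision rule, reproduced faithfully, and is the reason the
  package reports both shape variables and flags disagreement as
  "undetermined".
* **The Euclidean-distance variable is norm-biased.** A noisy specimen's
  distance from the reference exceeds that of a noise-free shape by about
  $\sigma^2 d / (2\lVert x - ref\rVert)$; reconstructed ancestors are
  smoothed and carry less noise than tips, so tip-versus-ancestor ED
  differences carry a systematic positive offset. At 0.5% digitization
  noise this bias (~0.01 Procrustes units) exceeds a 3-SD heterochronic
  shift, which pushes small terminal paedomorphic shifts toward
  "undetermined"; shifts at the study's designed magnitude (0.02) are
  recovered reliably.
* **Two-stage trajectories.** Length, slope and angle of a trajectory
  built from one juvenile and one adult are sensitive to the juvenile's
  ontogenetic stage; multi-stage trajectories can bend in ways a
  two-stage vector cannot capture.
* **Reconstruction dependence.** Ancestral calls depend on the topology,
  the calibration algorithm and squared-change parsimony's homogeneous-
  rate assumption; near-zero branches pin reconstructions to single
  specimens.

## Problem sizes

The test suite and the acceptance script run the full pipeline on the
12-taxon miniature study (17 specimens × 71 landmarks), use 200
replicates for each operating-characteristic simulation (K calibration on
a 64-tip balanced tree, permutation-test size on a 16-tip tree,
classifier recovery and false-call rates), and 10,000 permutations for
the single showcase run — sizes chosen so the whole suite completes in a
few minutes on one CPU while keeping Monte-Carlo error a small fraction
of every asserted margin.
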