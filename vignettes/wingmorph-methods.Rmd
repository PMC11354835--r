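---
title: "Methods: wing geometric morphometrics for honey bee identification"
author: "wingmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wing geometric morphometrics for honey bee identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingmorph)
```

# The problem

Africanized honey bees are hybrids carrying *Apis mellifera scutellata*
(lineage A) genes; in managed highland populations the degree of
Africanization is commonly assessed from the venation geometry of the left
forewing. Nineteen homologous landmarks at vein intersections are digitized
per wing, and specimens are compared with reference wings of documented
pure subspecies (*A. m. carnica*, *A. m. ligustica*, *A. m. mellifera*,
*A. m. scutellata*). wingmorph implements that identification pipeline
end-to-end, together with a synthetic-data generator that reproduces the
statistical structure of such a survey, and a minimal mitochondrial
companion assigning tRNALeu-COII sequences to reference haplotypes.

# Superimposition and tangent coordinates

`gpa_align()` performs generalized Procrustes analysis. Each configuration
is centered, scaled to unit centroid size (partial Procrustes; the
unit-size constraint is the convention of the morphometric software bee
studies typically use, and it keeps the invariants simple), and rotated to
the current consensus by the rotation-only solution of the orthogonal
Procrustes problem (SVD of the cross-covariance with the determinant
constrained to +1 — reflections are disallowed because all wings are
digitized on the same side). The consensus is re-estimated as the unit-size
arithmetic mean until it moves less than `tol` (default 1e-10 in
root-sum-of-squares; the iteration typically converges in well under ten
steps on wing-like data, and hitting `max_iter = 100` yields a warning, not
an error). Two determinism devices matter for reproducibility:

- the final configuration is rotated so the consensus lies on its
  principal axes, with eigenvector signs fixed deterministically, so output
  orientation does not depend on platform eigen-solvers;
- the initial consensus is the mean pre-shape when digitizing orientations
  are coherent (mean pre-shape norm at least 0.2), falling back to the
  first specimen otherwise. Starting from the mean makes a second run of
  GPA on already-aligned shapes an immediate fixpoint (idempotence), while
  the fallback covers raw data whose random orientations cancel the mean.

Aligned shapes are projected orthogonally into the tangent space at the
consensus (`tangent_project()`): the flattened shape's component along the
unit consensus vector is removed. The consensus maps to the zero vector,
every tangent vector is orthogonal to the consensus, and because each
shape is also optimally rotated, the tangent data of n specimens have rank
at most min(n − 1, 2k − 4). For shape scatter of the magnitude seen in
wing data the tangent coordinates agree with the raw Procrustes residuals
up to a quadratic curvature term.

An important assumption: GPA presumes *concentrated* shape variation. For
clouds spread over a large part of shape space the mean shape is not
unique and the superimposition becomes initialization-dependent; the
package's property tests therefore exercise invariance on realistic
scatter (isotropic landmark noise a few percent of centroid size), which is
also the only regime in which tangent-space statistics are meaningful.

Centroid sizes are always taken from the raw coordinates before unit
scaling — otherwise every specimen would have size 1 and the size–altitude
correlation would be undefined. For the same reason `read_tps()` applies
`SCALE=` factors by default (`scale_policy = "apply"`), keeping sizes
comparable across images; the policy is exposed because digitizing
protocols differ in whether scales were set.

# Ordination, Mahalanobis distances and tests

`shape_pca()` is the spectral decomposition of the tangent covariance with
a deterministic sign convention (largest-magnitude loading element
positive).

`cva()` first reduces the tangent data to the leading principal components
capturing `var_retain` (default 0.99) of total variance, capped at n − g
components and at the numerical rank. This regularization is necessary
because 2k = 38 shape variables typically exceed the within-group degrees
of freedom of a 50-wing reference group; the retained fraction is exposed
because no single value is canonical. Within that subspace the canonical
axes solve the W⁻¹B eigenproblem through a Cholesky reformulation
(numerically symmetric), and scores are scaled so the pooled within-group
variance along each axis is 1. In that metric, Euclidean distances between
group means are exactly the Mahalanobis distances
D = sqrt((mᵢ − mⱼ)ᵀ W⁻¹ (mᵢ − mⱼ)); the package computes D both ways and
refuses to return if the two routes disagree beyond 1e-8. Distances are
reported as `D` with `D²` alongside, explicitly labelled, because published
tables are inconsistent about which scale "Mahalanobis distance" means and
both conventions must be reproducible.

`permutation_test()` uses the Mahalanobis distance between two group means
as its statistic, shuffles labels between the two groups only, refits means
and pooled covariance per permutation in a fixed PCA subspace of the two
groups' data (the subspace is label-independent, so holding it fixed biases
nothing), and reports the add-one p-value
p = (1 + #{perm ≥ observed}) / (1 + n_perm), which can never be zero. The
default `n_perm = 1000` balances grid resolution against cost; all
permutation machinery is seeded.

`size_covariate_correlation()` is the Pearson correlation with the
two-sided t test on n − 2 degrees of freedom, via `stats::cor.test()`.

# Classification

`train_lda()` fits the linear discriminant
score(x) = mᵀW⁻¹x − ½mᵀW⁻¹m + log(prior) in the same reduced subspace as
the CVA. Priors default to equal because reference panels are balanced by
design (50 wings per subspecies); proportional priors are available.
Classification (`classify()`) takes the argmax, breaking exact ties toward
the lexicographically first group name with a warning. Reference and query
specimens must be superimposed *jointly* — a discriminant trained in one
tangent basis is meaningless in another — so models fitted from a
`wing_gpa` object carry the consensus shape and refuse queries from a
different superimposition.

`loocv_accuracy()` refits the discriminant — including the subspace
reduction — for every held-out specimen, but does not refit the
superimposition: removing one wing from a GPA of hundreds changes the
consensus negligibly, and refitting it would strand the held-out specimen
in a different coordinate system. This is a deliberate, documented
approximation, and it follows the cross-validation convention of the
morphometric software this field uses.

The reporting layer mirrors the tables such surveys publish:
`frequency_report()` gives the percentage of each query population
assigned to each reference (rows sum to 100), and `africanization_table()`
collapses assignments into an Africanized/European dichotomy per
altitudinal floor, where "Africanized" means assignment to the
*scutellata*-like reference or to a hybrid reference class when one was
trained. The survey's three floors are closed bands on integer-rounded
altitude — 2600–2800, 2801–3000, 3001–3274 m a.s.l. — which tile the range
exactly (`altitude_floor()`).

Whether the hybrid class of such surveys was operationalized as a fifth
training class or a post-hoc threshold is not decidable from published
descriptions; the package defaults to plain argmax over whatever reference
groups are supplied (a fifth class trained from study wings can simply be
labelled in the metadata), which keeps both modes expressible without
asserting either as *the* published one.

# Clustering

`upgma()` implements the standard unweighted pair-group method: merge the
closest pair at height d/2, with inter-cluster distances equal to
size-weighted averages — equivalently, average linkage on the original
dissimilarities. Ties are broken toward the lexicographically smallest
pair of cluster labels, making merge order deterministic. The placebo
outgroup gets no special treatment: it attaches last purely because its
distances are large. Trees serialize to Newick with branch lengths that
reproduce merge heights exactly (`to_newick()`, `as.phylo()`).

# Haplotype assignment

`global_alignment()` is Needleman–Wunsch with linear gap penalty
(defaults match = 1, mismatch = 0, gap = −1). Identity is
100 · matches / aligned columns with gapped columns counted in the
denominator — the conservative "global identity" convention, stated
explicitly because published identity tables rarely say which denominator
they used. `N` matches nothing by default (even another `N`); set
`n_policy = "literal"` for verbatim matching. Because different
score-optimal alignments can contain different numbers of matches, the
traceback canonicalizes: among score-optimal alignments it selects one
maximizing matches, then aligned pairs (folded into the dynamic program
with dominance weights), which makes the reported identity well defined
and symmetric in the two sequences. `assign_haplotype()` reports the best
hit, its lineage, the runner-up and the margin, warning below 0.5
percentage points of margin; exact ties go to the lexicographically first
haplotype name. The panel is a local FASTA plus haplotype/lineage table —
assignment is deterministic and needs no network.

# The synthetic generator

`simulate_study()` emulates the statistical structure of a highland
survey, not bee biology:

- **Design:** 15 apiary populations × 5 colonies × 10 wings (750 study
  wings) spanning 2600–3274 m a.s.l. (apiaries evenly spaced), plus 4
  reference groups of 50 wings, plus an optional small placebo population
  far from all references.
- **Shapes:** reference means are a ring-like base wing outline plus
  random tangent offsets of norm `separation` (default 0.08); specimens
  add isotropic Gaussian tangent noise of SD `sigma_w` (default 0.01, i.e.
  1% of centroid size — the magnitude at which wing-shape scatter sits);
  study populations are a single hybrid morphotype mixing
  `lambda` = 0.8 toward the *scutellata*-like mean and the remainder
  equally over the European means, so they overlap *scutellata* the way
  Africanized study wings do.
- **Size:** centroid size follows CS = β₀ + β₁·altitude + ε with β₁
  calibrated against the realized altitude spread so the population
  correlation equals `rho` (default −0.32, the size–altitude gradient such
  surveys report), around a mean of 400 image units with SD 20 (5%
  coefficient of variation). The coupling is on size only; shape–altitude
  coupling is deliberately absent by default so size and shape effects
  stay separable.
- **Nuisance:** every specimen is emitted under a random rotation,
  translation and its own scale, so the pipeline must genuinely undo the
  similarity transforms.

Everything is driven by one seed, and `save_simulation()` writes the TPS
file, metadata CSV and a YAML sidecar recording the generating parameters.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: correlated landmark noise along vein structures,
digitizing error that varies by landmark, colony-level random effects,
shape allometry, or real subspecies mean shapes. Tests on simulated data
validate the *machinery* (invariances, optimality, calibration, recovery),
not biological effect sizes.

# Problem sizes and numerical choices

The test suite and the acceptance script run the survey-scale simulation
(950–960 wings, 19 landmarks), 500-replicate null calibration of the
permutation test at n_perm = 199, 200-replicate checks of the
size–altitude correlation at n = 750, exhaustive brute-force comparison of
UPGMA on 4–6-leaf matrices, and 1000 mutated queries against a 5-haplotype
panel — sizes chosen so every property is measured at the design's own
scale. Key tolerances: GPA convergence 1e-10; the internal
CVA-versus-quadratic-form cross-check 1e-8; ultrametricity of trees 1e-9;
TPS round-trips exact to 6 significant digits. Degenerate inputs
(coincident landmarks, zero-variance covariates, singular pooled
covariances, empty sequences, asymmetric distance matrices) raise errors
rather than propagating NaNs.

# Limitations

Two-dimensional landmarks only; no semilandmarks, no thin-plate-spline
deformation displays, no quadratic discriminants or non-parametric
classifiers, no neighbor-joining or bootstrap on the morphometric tree,
and no BLAST-style database search — haplotype assignment is against a
user-supplied local panel, so identity values depend on that panel's
composition. The LOO approximation (superimposition not refit) is
standard but slightly optimistic in principle.
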