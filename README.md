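# wingmorph

Landmark-based wing geometric morphometrics for identifying honey bee
(*Apis mellifera*) populations and quantifying Africanization — the
introgression of *A. m. scutellata*-derived (lineage A) phenotypes into
managed colonies. The package is aimed at bee morphometrists and population
biologists who digitize forewing vein intersections (typically 19 landmarks
per left forewing with the tps software family) and want to re-run a full
identification analysis: superimposition, ordination, classification
against pure-subspecies references, and clustering of populations — plus a
minimal mitochondrial companion that assigns tRNALeu-COII amplicon
sequences to reference haplotypes by percent identity.

## What it computes

Given raw landmark configurations **X**₁..**X**ₙ (k × 2 each):

- **Generalized Procrustes analysis.** Each configuration is centered,
  scaled to unit centroid size CS = √Σᵢ‖xᵢ − x̄‖², and rotated (rotations
  only — all wings are digitized on the same side) to minimize summed
  squared landmark distances to an iteratively re-estimated consensus; the
  aligned shapes are orthogonally projected into the tangent space at the
  consensus, giving 2k shape variables per specimen.
- **Ordination.** PCA of the tangent coordinates (exploratory), and
  canonical variate analysis across groups: eigenvectors of W⁻¹B with W
  the pooled within-group covariance, scores scaled to unit within-group
  variance, pairwise Mahalanobis distances
  D = √((mᵢ − mⱼ)ᵀ W⁻¹ (mᵢ − mⱼ)) with permutation tests (labels shuffled
  within each pair, add-one p-values), and the Pearson correlation between
  centroid size and altitude.
- **Classification.** Linear discriminant against reference groups
  (score = mᵀW⁻¹x − ½mᵀW⁻¹m + log prior), resubstitution and leave-one-out
  cross-validated accuracy, per-population identification tables and an
  Africanized/European breakdown by altitudinal floor (2600–2800,
  2801–3000, 3001–3274 m a.s.l.).
- **Clustering.** UPGMA on the population Mahalanobis matrix, exported as
  an ultrametric Newick tree.
- **Haplotypes.** Needleman–Wunsch global alignment percent identity
  (gap-inclusive denominator) against a user-supplied haplotype panel,
  best-hit assignment with margins.
- **Simulation.** A seeded generator emulating a highland survey (15
  apiaries × 5 colonies × 10 wings, 4 reference groups of 50, a hybrid
  morphotype leaning toward *scutellata*, and a negative altitude–size
  correlation), so the whole pipeline is testable without data downloads.

## Worked example

```r
library(wingmorph)
sim <- simulate_study(seed = 42, placebo = TRUE)   # 950 wings + placebo
res <- run_pipeline(sim, seed = 42)

res$size_correlation
#> Pearson correlation, centroid_size ~ altitude_masl:
#>   r = -0.321, n = 750, two-sided p = <2e-16

round(res$frequency$combined, 1)
#>            carnica ligustica mellifera scutellata
#> carnica      100.0         0         0        0.0
#> ligustica      0.0       100         0        0.0
#> mellifera      0.0         0       100        0.0
#> scutellata     0.0         0         0      100.0
#> AB             0.1         0         0       99.9

round(res$cva_subspecies$D2["study", ], 2)
#>    carnica  ligustica  mellifera scutellata      study
#>      69.18     112.31     136.47       4.24       0.00
```

The correlation row says wings get smaller with altitude exactly as the
generator was told (target r = −0.32). The identification table has one row
per known population and one column per reference subspecies; the `AB` row
is the 750 study wings, almost all assigned to the *scutellata*-like
reference — the hybrid morphotype the generator produces (mixing weight
0.8). The Mahalanobis row shows the study morphotype sitting a short
distance (D² ≈ 4) from *scutellata* and far from the European references.
`res$newick` holds the 20-leaf UPGMA tree (15 apiaries, 4 references,
placebo outgroup attaching last), and `res$accuracy` the resubstitution and
leave-one-out accuracy of the reference discriminant (both 1.0 at the
generator's default separation).

Real TPS data run through the same entry point:

```r
res <- run_pipeline("wings.tps", metadata = "metadata.csv", out_dir = "results")
```

or from the shell via the wrapper in `inst/cli/wingmorph.R`.

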