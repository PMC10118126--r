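# brainsig

Anatomic and cell-type transcriptomic signatures of brain diseases.

Genes that carry risk for a brain disease are not expressed uniformly across
the brain: averaged over a disease's gene set, regional expression forms a
reproducible anatomic signature, and single-nucleus data resolves the same
gene sets into cell-type signatures. `brainsig` implements the statistics
needed to build, compare, and validate such signatures — for researchers who
want to classify diseases by where and in which cells their risk genes act,
rather than by clinical phenotype alone.

## What it computes

Given (i) a gene–disease association table with evidence counts, (ii)
per-subject structure × gene expression matrices over a brain-structure
ontology, (iii) cell-type × gene mean expression (CPM) for one or two
species, and (iv) a set of canonical module eigengenes, the package
computes:

- **Anatomic disease profiles** — per-disease mean expression across
  structures, averaged over subjects and z-scored, optionally weighted by a
  literature-evidence GDA score
  `C(N1) + M(N2) + I(N3) + L(N4)` with `C ∈ {0, 0.3, 0.5, 0.6}`,
  `M = 0.2·[N2>0]`, `I = 0.1·[N3>0]`, `L = min(0.01·N4, 0.1)`.
- **Anatomic disease groups (ADG)** — agglomerative clustering with Ward
  linkage (ward.D2) on the distance `1 − ρ` (Pearson between profiles),
  plus per-structure ANOVA / pairwise t tests with Benjamini–Hochberg FDR,
  co-clustering stability under gene-set downsampling, and agreement
  between labelings as the fraction of concordant disease pairs.
- **Cross-subject identifiability** — how often a disease's signature in
  one subject finds the *same* disease (or the same ADG / phenotypic GBD
  class) as its nearest neighbour in every other subject, by Pearson or
  Euclidean proximity; rank signatures at a structure are encoded by
  prime factorization (`2^r1·3^r2·5^r3·7^r4·11^r5`).
- **Differential stability (DS)** — the mean Pearson correlation of a
  gene's regional profile over all subject pairs (15 pairs for 6 brains),
  computed on structures observed in both members of each pair.
- **Module association** — gene-to-eigengene correlations per subject,
  Fisher r-to-z, averaged across subjects, standardized per module, and
  averaged over disease gene sets.
- **Cell-type statistics** — tau specificity
  `τ = Σᵢ (1 − xᵢ/max x) / (N−1)`; disease × cell-type matrices clustered
  into cell-type groups (CTG); expression-weighted cell-type enrichment
  (EWCE) by permutation against same-size random background sets excluding
  the disease genes; cosine covariation maps over disease-unique genes
  thresholded at mean + 1.5 σ; consensus matrices and a within/between
  GBD-class distance ratio in a 2-D embedding.
- **Cross-species comparison** — signature alignment through a homologous
  cell-type map, joint clustering, the fraction of diseases whose nearest
  cross-species signature is themselves, and two-sample Kolmogorov–Smirnov
  comparisons.

A seeded synthetic-data generator (`synth_config()`,
`synth_subject_expression()`, `synth_cell_expression()`, `synth_gda()`)
emulates the statistical structure of all inputs — planted modules with
per-subject noise, planted cell-type markers with a specificity gradient,
disease gene sets drawn from planted groups — so the full pipeline runs and
is testable end to end without any external data.

## Worked example

```r
library(brainsig)

cfg  <- synth_config(seed = 1)             # 6 subjects x 104 structures,
sim  <- synth_subject_expression(cfg)      # 32 modules, 40 diseases
gda  <- synth_gda(cfg, sim$truth)
sets <- filter_associations(gda, min_curated = 1, min_genes = 10)
prof <- disease_profile(sim$expr, sets)
adg  <- cluster_profiles(prof, k = 5)
id   <- crosssubject_identity(prof, adg = adg$labels, gbd = sets$classes)
print(sets); print(adg); print(id)
```

```
Disease gene sets: 40 diseases, 442 genes in union
  filters dropped 0 records (evidence), 0 diseases (size)
Cluster result: 40 entities in 5 groups (Ward.D2, 1-Pearson)

1 2 3 4 5
8 8 8 8 8
Cross-subject identity (pearson): mean exact match 0.960
  mean same-ADG frequency: 1.000
  mean same-GBD frequency: 1.000
```

The five recovered clusters are the five planted disease groups (adjusted
Rand index 1.0 against the generator's truth map). The identity summary
says that in 96% of subject-to-subject comparisons a disease's anatomic
signature is closest to the *same disease* in the other subject, and always
to a disease of the same group. Differential stability separates planted
module genes (mean DS 0.918 at noise sd 0.3) from planted unstable genes
(mean DS 0.001).

The same stages run as one configured pipeline with logged artifacts and
checksums:

```r
manifest <- run_pipeline(list(seed = 1, out_dir = "run1"))
```

or from a shell via `inst/cli/brainsig run --config config.yaml`.

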