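# tripathotype

Early rheumatoid arthritis synovium is not one disease tissue. Biopsies
stratify histologically into three **pathotypes** — *lympho-myeloid* (B-cell
aggregates and diverse immune infiltrate), *diffuse-myeloid*
(macrophage-rich but B-cell poor), and *pauci-immune fibroid* (little
immune infiltrate) — and bulk RNA-seq of synovium and blood differs
systematically across them. `tripathotype` implements the complete
computational chain for this kind of pathotype-stratified transcriptomics
study, for bioinformaticians and computational rheumatologists who want
the method as reusable, tested functions rather than a one-off script
collection:

* **Histology classification** — the semiquantitative IHC score rules
  (CD3, CD20, CD68 lining/sublining, CD138, CD20+ aggregate grade) that
  call each biopsy lymphoid / myeloid / fibroid / ungraded, plus
  pathotype-shift vs clinical-response statistics over follow-up biopsies.
* **Cell-lineage gene modules** — derivation of marker gene sets from a
  reference expression atlas (genes x tissues) by tissue-specificity
  criteria: cross-tissue Z > 5 in the target tissue, expression rank <= 3,
  and a specificity score (number of tissues with Z > 3) below 10.
* **SVD module scoring** — one eigengene-style score per sample from the
  first right-singular vector of the row-centred module submatrix.
* **Three-way differential expression** — median-of-ratios normalisation,
  per-gene negative-binomial GLMs with a likelihood-ratio test across the
  three groups plus pairwise tests, BH FDR, and a six-way colour-class
  assignment (one group up: blue/red/green; two groups up:
  purple/yellow/cyan; else gray).
* **Polar "three-way volcano" projection** — the three group means (L, M,
  F) collapse to the plane by

  ```
  x = sqrt(3)/2 * (M - F)
  y = L - (M + F)/2
  theta = atan2(y, x),  r = sqrt(x^2 + y^2)
  ```

  (analogous to an RGB→HSV hue conversion), with the L/M/F axes at
  90°/330°/210° and `-log10` LRT p as the cylinder height; serializable 2D
  and 3D plot payloads are emitted as JSON.
* **Association statistics** — Spearman module-trait correlations with
  per-family FDR, synovium/blood concordance labels, hypergeometric
  cell-type annotation of modules, and binary group comparisons of module
  scores.
* **A synthetic-cohort generator** — every input above can be simulated
  with planted ground truth (markers, DE classes, module activities,
  trait correlations, response relations), so the whole chain is testable
  end to end without any external download.

## Worked example

```r
library(tripathotype)

# 1. reference atlas with planted markers; derive four lineage modules
atlas   <- generate_atlas(atlas_spec(seed = 1))
zatlas  <- zscore_tissues(atlas$atlas)
modules <- derive_modules(zatlas, c("T001", "T002", "T003", "T004"))

# 2. synthetic cohort (30/20/15 samples; 300 planted DE genes; one
#    planted module-trait correlation) and histology classification
spec <- cohort_spec(seed = 1,
  clinical_effect_map = data.frame(module = "T001", trait = "CCP_titer",
                                   rho = 0.5))
cohort <- generate_cohort(spec, modules)
table(classify_pathotype(cohort$histology)$pathotype)
#>  fibroid lymphoid  myeloid ungraded
#>       15       27       20        3

# 3. three-way differential expression and colour classes
de <- run_threeway_de(cohort$counts, cohort$annotations$pathotype)
table(de$color_class)
#>   blue   cyan   gray  green purple    red yellow
#>     54     51   1688     55     51     50     51

# 4. polar projection: genes up in the lymphoid group sit near 90 deg
payload <- build_payload(de, radial_mode = "zscore")
head(subset(payload$genes, color_class == "blue",
            select = c(gene_id, theta_deg, r, z_height)), 3)
#>    gene_id theta_deg        r  z_height
#> 5   g00005  41.93595 1.062782  2.874496
#> 12  g00012  92.14395 1.748769 19.252735
#> 28  g00028  88.51496 1.737020 21.794208

# 5. module scores against a clinical trait (planted Spearman rho = 0.5)
scores <- score_modules(rle_transform(cohort$counts), modules)
assoc  <- spearman_module_trait(scores, cohort$clinical, traits = "CCP_titer")
assoc[, c("module", "trait", "n", "rho", "p", "q")]
#>   module     trait  n      rho        p        q
#> 1   T001 CCP_titer 65  0.50039 2.19e-05 8.76e-05
#> 2   T002 CCP_titer 65  0.12614 3.17e-01 4.91e-01
#> 3   T003 CCP_titer 65 -0.11342 3.68e-01 4.91e-01
#> 4   T004 CCP_titer 65 -0.00415 9.74e-01 9.74e-01

# 6. pathotype shift at 6 months against change in DAS28
fu <- generate_followup(cohort$histology, response_strength = 1, seed = 1)
sr <- shift_vs_response(classify_pathotype(cohort$histology),
                        fu$calls, fu$delta_das28)
#> pathotype shift vs delta-DAS28: r = 0.62, p = 6.3e-08, n = 62
```

The planted CCP correlation is recovered at the module whose activity
drove it (rho = 0.50, q < 1e-4) and at no other module; biopsies that
shift to a less inflammatory pathotype show larger DAS28 improvements.

`run_all(pipeline_config(...))` chains every stage — simulate, classify,
derive modules, score, differential expression, polar payloads,
associations, annotation — writing TSV/CSV/GMT/JSON outputs plus a run
manifest; reruns with the same configuration reproduce byte-identical
tables.

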