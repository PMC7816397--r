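# allomix

Does pooling PBMCs from unrelated donors during multiplexed single-cell
RNA-seq sample preparation trigger a detectable allogeneic transcriptional
response? HLA-mismatched PBMCs can activate each other within hours of
co-culture, so the brief co-incubation used by donor-multiplexing protocols
(≈30 min at 4 °C before droplet emulsion) is a potential confounder for any
cross-sectional immunology study that pools samples. `allomix` implements
the analysis that answers this question and the synthetic data needed to
validate it, for computational biologists building or auditing multiplexed
scRNA-seq pipelines.

The core design keeps one donor (A) in every condition: an unmixed lane, a
lane mixed with 3 donors, a lane mixed with 7, and an unmixed technical
replicate. A mixing effect must make mixed-vs-unmixed donor A cells more
dissimilar than the technical replicates are to each other. Dissimilarity
between donor/lane groups is measured per cell type by the Jensen–Shannon
divergence between kernel density estimates of group cells on a shared 2-D
expression embedding,

    JSD(P, Q) = ½·KL(P‖M) + ½·KL(Q‖M),   M = (P+Q)/2,  log base 2,

computed on balanced subsamples (equal cells per group; CD4 T cells also
balanced by naive/memory/activated subtype), min–max scaled per iteration,
and averaged over repeated subsampling. Significance comes from a
donor-label permutation null: the observed differential
(mean mixing JSD − mean technical JSD) is called significant only if it
exceeds the permuted mixing-score mean + 1 SD.

The package also provides:

- a **synthetic multi-donor PBMC generator** (negative-binomial counts,
  marker structure, donor offsets, sample-tag counts with per-cell-type
  capture efficiency, full ground truth) with a controllable injected
  alloreactivity effect (IFNG/CD40LG up, DUSP1/FOS down in mixed-lane CD4
  T cells) as a positive control;
- **sample-tag demultiplexing**: Hamming-corrected barcode counting,
  per-tag threshold classification into donor/Doublet/Negative,
  concordance statistics against an external reference, and per-cell-type
  classification-bias tables;
- **QC, annotation, and composition tests**: the standard UMI filters,
  median-depth log2 normalization, marker-rule cell-type and CD4-subtype
  annotation, and pairwise proportion tests across donor/lane groups.

## Worked example

```r
library(allomix)

cfg <- generator_config(cells_per_donor_per_lane = 400, seed = 42)
sim <- generate_counts(cfg)

# demultiplex the sample tags and benchmark against ground truth
cls <- classify_cells(sim$tags)
concordance(cls, setNames(sim$truth$cells$donor, sim$truth$cells$cell))
#> $pct_unclassified
#> [1] 0
#> $pct_donor_match
#> [1] 100

# JSD mixing-effect test on the comparison groups
ann <- subset(sim$truth$cells,
              group %in% c("A1","A2","A3","A4","B2","B3","C2","C3"))
mt <- mixing_test(sim$counts[, ann$cell], ann,
                  jsd_params(n_iterations = 20, n_permutations = 20,
                             seed = 42, celltypes = c("CD4 T", "CD14 Mono")))
mt$jsd
#>  celltype  comparison       mean          sd n_iterations
#>     CD4 T inter_donor 0.91513941 0.014186031           20
#>     CD4 T      mixing 0.01904498 0.006342977           20
#>     CD4 T   technical 0.01117474 0.007964959           20
#> CD14 Mono inter_donor 0.85902052 0.017470654           20
#> CD14 Mono      mixing 0.03723934 0.007344327           20
#> CD14 Mono   technical 0.01476686 0.013159430           20
mt$null
#>  celltype observed_differential permuted_mixing_mean permuted_mixing_sd significant
#>     CD4 T            0.00787024           0.01651602        0.007289920       FALSE
#> CD14 Mono            0.02247247           0.02630843        0.008768161       FALSE
```

Read: donors differ strongly (inter-donor JSD ≈ 0.9 on the 0–1 scale),
while mixed and unmixed donor A cells differ no more than technical
replicates do (differential within the permutation noise) — no mixing
effect, as expected for this no-effect simulation. Re-running with
`generator_config(allo_effect = allo_effect_spec(...))` injects a CD4
alloreactivity signature and flips the CD4 verdict to significant.

End-to-end runners are available as `run_null_experiment()` (simulate →
demultiplex → QC → annotate → composition + JSD, with a provenance block)
and `run_real_data()` (same chain from 10x-style MTX/TSV files, a tag-count
CSV, a lane table, and optional external reference calls).

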