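# myoinfil

Bulk expression profiles of inflamed tissue confound two signals:
transcripts genuinely re-regulated inside the tissue, and transcripts
that merely track the changing proportion of infiltrating leukocytes.
In inflammatory myopathies (dermatomyositis, polymyositis, inclusion
body myositis, necrotizing myopathy) the infiltrate can dominate the
biopsy, and most apparent "over-expression" versus normal muscle is
cell-composition artifact.

`myoinfil` quantifies that infiltration directly from the expression
matrix and removes it.  It is aimed at analysts working with bulk
mRNA/miRNA profiles of heterogeneous tissue who need to know, per
transcript, whether a change survives accounting for cell composition.

## The model

Bulk signal is a linear mixture over compartments.  With baseline
leukocyte fraction *p₀* scaled per sample by an infiltration ratio
*rₛ*:

```
b_gs = rs·p0·x_g,leu + (1 − rs·p0)·x_g,mus
```

Under this *invasion model*, a strictly leukocyte-specific transcript
has bulk fold change versus normal controls exactly equal to *rₛ*, and
all such transcripts are coherently over-expressed.  The pipeline
therefore:

1. calls differential expression against normal controls
   (FC > 4, Benjamini–Hochberg *p* < 0.05; pooled or moderated t);
2. consensus-clusters the 200 most variable up-regulated genes
   (agglomerative/divisive hierarchical, k-means, k-medoids; 100
   bootstrap subsamples; membership robustness cutoff 0.6);
3. turns each cluster with ≥ 5 robust members into a signature scored
   as the **median fold change** of its robust members per sample;
4. designates a pan-leukocyte signature as the **leukocyte
   infiltration index** (an estimator of *rₛ*);
5. divides the matrix by the index and re-applies the thresholds to
   find over-expression *not* attributable to infiltration; and
6. validates the index against histology grades, the first principal
   component, and compartment-specific miRNAs (anti-correlation
   screen).

A ground-truth mixture-cohort simulator (`simulate_cohort()`) emulating
a 36-biopsy myositis study design makes every stage testable end to
end.

## Worked example

```r
library(myoinfil)
run <- run_pipeline(list(seed = 1))
print(run)
#> myoinfil pipeline run
#>   DE: 188 up / 0 down of 400 tested
#>   consensus: k = 5, 5 eligible signature cluster(s)
#>   index signature: E
#>   surviving over-expression after adjustment: 0/188 (0.0%)
```

400 simulated transcripts yield 188 up-calls — the five planted
leukocyte gene modules — which consensus clustering resolves at k = 5.
The largest cluster (signature E, the pan-leukocyte module) becomes the
index.  After dividing the matrix by the index, **none** of the 188
originally over-expressed transcripts remain over-expressed — the
correct answer, because every up-call in this cohort is
cell-composition artifact (the default design's muscle-intrinsic
induction touches only four samples and never passes the original
4-fold threshold).  Cohorts with planted cohort-wide intrinsic
regulation retain a small surviving fraction instead, all of it truly
intrinsic (see the vignette's scenario configurations).

```r
head(run$index, 3)
#>   sample_id index log2_index
#> 1 S01       0.895    -0.160
#> 2 S02       0.955    -0.0660
#> 3 S03       1.15      0.201
```

Normal controls (S01–S05) sit at index ≈ 1, i.e. baseline composition;
disease samples range up to ~16-fold infiltration.  The index tracks
the simulator's true per-sample ratio with Pearson r ≈ 0.999 (log2
scale) and ~3% median relative error, explains the H&E grade with
R² ≈ 0.88, and aligns with PC1 of the differential transcripts
(R² ≈ 0.98; PC1 carries ~88% of the variance).

```r
head(run$associations$anticorrelation, 3)
#>   mrna_id mirna_id         r        p    p_adj
#> 1 MUS_010 MIR-LEU_006 -0.932 1.48e-16 2.76e-15
#> 2 MUS_010 MIR-LEU_007 -0.911 1.19e-14 1.32e-13
#> 3 MUS_060 MIR-LEU_004 -0.907 2.73e-14 2.77e-13
```

The strongest anti-correlated mRNA:miRNA pairs are muscle transcripts
against leukocyte miRNAs — dilution of the muscle compartment moving
opposite to the infiltrate, exactly the direction structure the
invasion model predicts.

Real data enter through `input` paths (TSV expression matrix +
annotation table, optional miRNA matrix) instead of `simulate`; see
`?run_pipeline` and the vignette in `vignettes/` for the model,
parameter meanings, and design choices.

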