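# decurve

Analysis of matched RNA and protein expression time courses across a
starvation / stationary-phase transition: error-scaled piecewise curve
fitting by differential evolution, ensemble-based behavioral
classification, and the proportional-vs-integral framework for relating
protein dynamics to transcript dynamics.  A ground-truth synthetic-data
generator emulating the study design (nine log-spaced time points from 3 h
to two weeks, three biological replicates, negative-binomial counts,
operon-shared transcription) makes every stage testable without external
data.

The package is aimed at computational biologists analyzing bulk
time-course expression data — especially matched transcriptome/proteome
designs in bacteria — and at methodologists who want a fully simulated,
seeded benchmark for profile-classification pipelines.

## The model

Every trajectory is fit with a continuous seven-parameter piecewise curve
(plateau — ramp — plateau — ramp — plateau; durations *t*₁..*t*₄,
amplitudes *A*₁..*A*₃), scored against the replicate mean *d* by the
error-scaled cost

&nbsp;&nbsp;&nbsp;&nbsp;*F* = Σⱼ (*d*ⱼ − *s*ⱼ)² / σⱼ²,

minimized by a differential-evolution optimizer (15 agents, crossover
0.75, mixing 0.6, greedy selection, 20 pooled restarts).  Members of the
pooled population within one average SD of the data ("good fits") vote on
the gene's behavior — up, down, transiently up, transiently down, flat —
and the agreement fraction qualifies the call.

Protein–transcript coupling is probed through the kinetics
*dp/dt* = *k*ₛ·*m*(*t*) − *k*_d·*p*: Spearman correlations of the protein
profile with the transcript (*ρ*_prop, the fast-degradation limit) and
with the transcript's running trapezoidal integral (*ρ*_int, the
no-degradation limit) classify each gene as proportional, integral or
intermediate at the *ρ* > 0.70 threshold.  Operon co-expression coherence
(mean pairwise Spearman within operons), inter-gene-distance trends,
k-means profile clustering and RNA class fractions complete the toolkit.

## Worked example

```r
library(decurve)

cfg <- synthetic_config(n_genes = 300, seed = 42)
ds  <- simulate_dataset(cfg)
ds
#> synthetic_dataset: 300 genes, 9 time points, 3 replicates (seed 42 )
#>
#>           down           flat transient_down   transient_up             up
#>            141             61             17             55             26

# preprocessing ladder: low-count filter, depth normalization,
# replicate averaging (mean + floored SD), max normalization
rna <- max_normalize(average_replicates(depth_normalize(
         filter_low_counts(ds$rna))))

# fit one shut-off gene and classify it
fit <- fit_profile_de(rna$d["g5", ], rna$sigma["g5", ], rna$time_h, seed = 1)
fit
#> DE fit ensemble: 300 members, 20 restarts
#> best cost: 2.464906
#> best params:
#>          t1          t2          t3          t4          A1          A2
#>  20.6626646   0.3388266 143.9048219   0.3628776   0.8397439   0.2969058
#>          A3
#>   0.1341487
call_gene_behavior(fit)
#> behavior: down (agreement 1.00, delta 0.0669)
```

The best member says the transcript sat near its initial level for ~21 h,
dropped to ~30% of maximum, and decayed further to ~13% — and all 300
pooled ensemble members agree the gene is down-regulated (`agreement
1.00`); `delta` is the noise-derived change threshold on the normalized
scale.

```r
prot <- max_normalize(average_replicates(depth_normalize(
          filter_low_counts(ds$protein))))
reg <- regulation_calls(prot, rna)
head(subset(reg, !is.na(label)), 4)
#>   gene   rho_prop     rho_int        label
#> 1   g1  0.7333333  0.46666667 proportional
#> 2   g2  0.7666667 -0.01666667 proportional
#> 3   g3 -0.0500000 -0.26666667 intermediate
#> 4   g4 -0.3166667 -0.55000000 intermediate
```

Each row gives the two rank correlations — protein vs transcript and
protein vs transcript integral — and the resulting regulation label at
the 0.70 threshold.

The full pipeline (preprocessing, fitting, classification, regulation,
operons, clustering, fractions, enrichment, with a JSON run manifest and
byte-reproducible outputs) runs from one configuration object:

```r
res <- run_pipeline(run_config(synthetic = synthetic_config(seed = 1),
                               outdir = "run1", seed = 1))
```

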