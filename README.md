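# breedtrace

Genomic diversity and breed traceability from SNP array genotypes.

`breedtrace` is an R package for the standard analysis battery applied when
a local livestock breed (goat, sheep, cattle) is characterised from
medium-density chip data — typically to decide whether it is a distinct
genetic pool worth a conservation programme, and whether animals can be
traced back to it:

* **PLINK I/O and QC** — text (`.ped`/`.map`) and binary
  (`.bed`/`.bim`/`.fam`, v1.00 SNP-major, bit-exact on write) dialects,
  dataset merging with allele reconciliation, and the standard filters
  (autosomes only; SNP call rate > 95%; sample missingness < 10%).
* **Runs of homozygosity** — the consecutive scan (default: ≥ 15 SNPs,
  ≥ 1 Mbp, one heterozygote tolerated), five length classes
  (0–2, 2–4, 4–8, 8–16, > 16 Mbp), per-breed/per-chromosome summaries,
  shared ROH islands (regions covered in ≥ 45% of a breed), and the
  genomic inbreeding coefficient
  *F*<sub>ROH</sub> = Σ run lengths / autosomal map length.
* **Population structure** — genotype PCA by singular value decomposition
  and maximum-likelihood admixture (genotypes binomial in
  *p<sub>ij</sub>* = Σ<sub>k</sub> *q<sub>ik</sub> f<sub>kj</sub>*) fitted
  by EM, with the number of ancestries K chosen by 10-fold
  genotype-entry-masking cross-validation.
* **DAPC traceability** — PCA followed by regularized linear discriminant
  analysis, the retained-PC count chosen by repeated stratified
  cross-validation, evaluated under three audit scenarios: supervised
  (train on everything), semi-supervised (hold out animals of a target
  breed), and unsupervised / leave-breed-out (the target breed never enters
  training and must be attributed to the remaining breeds).
* **A multi-breed simulator** — Balding–Nichols drift from a shared
  ancestral pool, optional admixed ancestry per animal, planted autozygous
  segments and per-call missingness, with full ground truth returned for
  recovery testing.

## Worked example

Simulate a four-breed panel with 10% planted autozygosity, run QC, ROH,
admixture and the supervised traceability scenario:

```r
library(breedtrace)

cfg <- sim_config(n_breeds = 4, samples_per_breed = 20, n_chromosomes = 6,
                  snps_per_chromosome = 500, chromosome_length_bp = 1e8,
                  ancestral_freq_range = c(0.2, 0.8), drift = 0.08,
                  autozygosity = list(fraction = 0.10,
                                      length_range_bp = c(2e6, 6e6)),
                  missing_rate = 0.002, seed = 42)
sim <- simulate_breed_panel(cfg)
ds  <- apply_qc(sim$dataset, autosomes = as.character(1:6))$dataset
ds
#> geno_dataset: 80 samples x 3000 SNPs
#>   chromosomes: 6 | breeds: 4
#>   missing calls: 0.192%

segs <- detect_roh(ds)                      # consecutive method, defaults
froh <- compute_froh(segs, ds)
aggregate(froh ~ breed, froh$genome, function(x) round(mean(x), 3))
#>   breed  froh
#> 1   B01 0.124
#> 2   B02 0.120
#> 3   B03 0.125
#> 4   B04 0.125

fit <- admixture_fit(ds$calls, 4, seed = 1, n_restarts = 2)
fit
#> admixture fit: K = 4 | loglik = -274707 | 361 iterations (converged)
round(breed_mean_q(fit, ds$fam$breed)[, -1], 2)
#>     K1   K2   K3   K4
#> 1 0.09 0.01 0.85 0.04
#> 2 0.03 0.05 0.06 0.86
#> 3 0.04 0.85 0.06 0.05
#> 4 0.87 0.06 0.02 0.05

scenario_supervised(ds, seed = 1, folds = 5, repetitions = 2,
                    grid = c(10, 20, 30))
#> DAPC scenario 1 (supervised): 10 PCs, overall training success 100.0%,
#> CV success 100.0%
```

Reading the output: mean *F*<sub>ROH</sub> per breed sits at ≈ 0.12 — the
10% planted autozygosity plus a small background from drifted allele
frequencies. Each breed draws ≈ 85% of its ancestry from its own
admixture component (drift 0.08 leaves some shared ancestral signal), and
with 10 principal components the discriminant model assigns every animal
to its breed both on training data and under cross-validation.

The same workflow runs end to end from one configuration object via
`run_pipeline(pipeline_config(...))`, which writes TSV/JSON tables
(QC report, ROH segments/islands/length classes, *F*<sub>ROH</sub>,
admixture Q/P matrices, per-scenario assignment tables) plus a checksummed
manifest under `out/{qc,roh,structure,dapc}`; a thin wrapper lives at
`inst/cli/breedtrace-pipeline.R`.

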