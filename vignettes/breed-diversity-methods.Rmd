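---
title: "Methods: ROH, admixture and DAPC breed traceability in breedtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH, admixture and DAPC breed traceability in breedtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedtrace)
```

`breedtrace` implements an integrated workflow for breed-diversity studies
on medium-density SNP array data, of the kind used to characterise local
livestock breeds and decide whether they merit conservation as distinct
genetic pools. Three complementary analyses share one genotype container:
runs of homozygosity (ROH) quantify recent inbreeding within a breed,
model-based admixture quantifies shared ancestry between breeds, and
discriminant analysis of principal components (DAPC) asks whether an
animal's breed of origin can be recovered from its genotype alone
(traceability). A Balding–Nichols simulator with planted ground truth makes
every stage testable without external data.

## Genotype container and PLINK dialects

All stages consume a `geno_dataset`: an $n \times m$ integer matrix of
allele-1 dosages (0, 1, 2, `NA` for a missing call), a SNP map sorted by
chromosome and position, and a sample table whose breed label lives in the
PLINK family-ID field. Both PLINK dialects are supported. The binary codec
(v1.00 SNP-major `.bed`) is bit-exact on write: pad bits are zeroed, so a
write–read–write cycle reproduces the file byte for byte. The text dialect
carries no allele-order metadata, so the reader fixes the counted allele as
the alphabetically first observed allele; loci that are monomorphic in the
data are read with an unknown counted allele (dosage 0 throughout),
mirroring PLINK's minor-allele semantics. Datasets are merged over the
intersection of SNP ids; dosages are flipped ($d \mapsto 2-d$) when the two
inputs counted opposite alleles, and palindromic A/T–C/G swaps are rejected
rather than guessed, because a strand flip cannot be distinguished from an
allele swap at such loci.

Quality control applies the standard chip filters in a fixed order —
autosomes only, then SNP call rate, then sample missingness — with strict
boundaries (call rate must exceed the threshold, missingness must stay
below it). The order matters when a high-missingness sample drags SNP call
rates down; computing SNP call rate before removing samples matches the
common single-invocation PLINK workflow. The order is nevertheless a
configuration option (`filter_order`) for sensitivity checks, because
reasonable pipelines disagree on it.

## Runs of homozygosity

Detection uses the consecutive method: SNPs are scanned in map order and
the current run is extended while its cumulative heterozygous calls stay
within `max_het`, cumulative missing calls within `max_miss`, and each
inter-SNP gap within `max_gap_bp`. A closed run is reported when it
contains at least `min_snp` SNPs and spans at least `min_length_bp`, with
the span measured between its first and last SNP positions (so `length_bp =
end_bp - start_bp`). Defaults — 15 SNPs, 1 Mbp, one tolerated heterozygote —
are the usual 50k-chip settings; the heterozygote allowance absorbs
genotyping errors. The missing-call allowance (default 1) and the gap limit
(default 1 Mbp, `NULL` to disable) are not fixed by convention and are
exposed as parameters.

Two details of the scan are deliberate and encoded identically in the
test-suite's independent brute-force oracle. First, when a closed candidate
fails the minimum-SNP/length filters, the scan restarts just after the
candidate's *first* heterozygous or missing SNP rather than after the
violation, so a qualifying run that shares the candidate's tail is not
lost. Second, when the candidate *was* reported, the scan resumes past the
violating SNP instead; this keeps reported segments of one individual
non-overlapping and prevents a run from starting on the SNP that closed its
predecessor. One consequence worth knowing: loosening `max_het` does not
necessarily increase the segment count, because neighbouring runs merge; it
either extends the covered length or reduces the count, and the property
tests assert exactly that.

Reported segments feed four summaries: the five length classes (0–2, 2–4,
4–8, 8–16, >16 Mbp, left-open/right-closed so they partition $(0,\infty)$);
per-breed and per-chromosome counts; the per-SNP ROH frequency within a
breed, whose maximal stretches above a threshold (default 45% of the
breed's animals) become ROH islands — candidate selection or drift
signatures; and the genomic inbreeding coefficient
$F_{ROH} = \sum_i L_i / L_{auto}$, the summed run length over the total
autosomal length. The denominator defaults to the SNP-covered map length
(per chromosome, last minus first SNP position) because that is what the
data can see; assembly chromosome lengths can be supplied instead, which
yields slightly smaller coefficients. Island bounds use SNP positions, not
midpoints between flanking SNPs. A breeds-by-chromosomes matrix of mean ROH
counts can be decomposed by PCA (`roh_profile_pca`, a centred SVD via
`prcomp`) to place breeds by the genomic distribution of their runs.

## Admixture

The admixture model treats each genome as a mixture over $K$ ancestral
populations: individual $i$ has ancestry proportions $q_{ik}$ (rows of $Q$
on the simplex) and population $k$ has allele frequencies $f_{kj}$, so a
genotype is $g_{ij} \sim \mathrm{Binomial}(2, \sum_k q_{ik} f_{kj})$ and
the log-likelihood is

$$\ell(Q,F) = \sum_{ij} \left[ g_{ij}\log p_{ij} + (2-g_{ij})\log(1-p_{ij}) \right],
\qquad p_{ij} = \sum_k q_{ik} f_{kj},$$

with missing entries skipped. The optimizer is plain
expectation–maximization with alternating multiplicative updates of $Q$ and
$F$ — chosen over quasi-Newton acceleration because each sweep provably
never decreases $\ell$, which the tests assert on random instances, and
because desk-scale panels converge in hundreds of sweeps anyway. Random
restarts (seeded) mitigate local optima. Frequencies are clamped to
$[10^{-6}, 1-10^{-6}]$; iteration stops when the relative log-likelihood
gain drops below `tol` ($10^{-6}$ by default, looser inside
cross-validation where only the error surface matters) or at `max_iter`.
Non-convergence is reported via the `converged` flag, never an exception.
At $K=1$ a single sweep lands on the closed-form maximum-likelihood
solution ($f_j$ = observed allele frequency), which the tests use as an
exactness check.

The number of ancestries is chosen by entry-masking cross-validation:
non-missing genotype *entries* are partitioned into 10 folds; each fold is
masked in turn, the model refit, and the fold error is the mean squared
difference between the held-out genotype and its expected dosage
$2\sum_k \hat q_{ik}\hat f_{kj}$. The $K$ with the smallest mean error is
selected, ties going to the smallest $K$ (parsimony). Because the
likelihood is invariant to relabelling the $K$ components, estimated $Q$
matrices are compared to ground truth only after exhaustive permutation
alignment (`match_ancestry_labels`).

## DAPC and the three traceability scenarios

DAPC is the two-step classifier: a PCA on the centred dosage matrix
(missing calls imputed at the per-SNP training mean) reduces the genotypes
to `n_pc` components, and a linear discriminant classifier with a pooled
within-class covariance operates in that reduced space. The pooled
covariance is regularized by `ridge` (default $10^{-6}$) times its mean
diagonal — the reference tools handle near-singularity silently; here it is
explicit and a singular fit at `ridge = 0` is an error that suggests the
remedy. Class priors are proportional to training class sizes, posterior
ties break alphabetically, and a test sample without a single overlapping
non-missing call receives the priors as its posterior (the no-information
limit). Everything needed to project new samples — training means, loadings,
class means, covariance inverse — is stored in the model, and prediction
*always* centres new data with the training means; a regression test feeds
the model a test batch identical to one training class, which would be
zeroed out (and misassigned) if test-side statistics leaked in.

`n_pc` is selected by repeated stratified 10-fold cross-validation: one PCA
per training fold at the largest candidate, every candidate evaluated by
truncation, and the candidate with the highest mean held-out assignment
success selected (smallest on ties). The default candidate grid steps by 10
up to 259 components; a full grid is available but rarely changes the
outcome, because success curves plateau. Stratification matters: unstratified
folds can drop a small breed from training entirely, and classes smaller
than the fold count degrade gracefully with a warning.

The three validation scenarios mirror how a traceability claim would
actually be audited:

1. **Supervised** — select `n_pc` and fit on all animals; report per-breed
   training success, cross-validated success and the variance share of the
   retained PCs.
2. **Semi-supervised** — hold out a few animals (default 5) of a target
   breed, reselect and refit on the remainder (the target breed keeps its
   other animals), classify the holdouts, repeat (default 10 times) and
   average. PC selection is redone in every repetition rather than reusing
   the scenario-1 choice, so the reported success never peeks at held-out
   animals.
3. **Unsupervised / leave-breed-out** — the target breed never enters
   training; a fraction of each other breed (20%–90%) trains the model and
   80% of the target is classified among the remaining breeds. This turns
   the classifier into a similarity probe: an admixed target should land on
   its source breeds, and more training data should never hurt source
   attribution.

All scenarios are bit-for-bit reproducible given a seed.

## The simulator: what it emulates and what it does not

`simulate_breed_panel` draws ancestral frequencies uniformly on a
configurable range, breed frequencies from the Balding–Nichols Beta
distribution (mean $p_j$, variance $c_k\,p_j(1-p_j)$, with the drift $c_k$
approximately the breed's FST against the ancestral pool — the tests verify
this with a Hudson-type estimator), and genotypes binomially given each
animal's true ancestry row, which may be admixed. Positions are uniform,
sorted and unique. `plant_autozygosity` forces non-overlapping intervals to
be homozygous by drawing one allele from the animal's own expected
frequency and doubling it — the unphased analogue of inheriting the same
haplotype twice — clipping the final interval so the realized fraction
tracks the target; `apply_missingness` masks calls independently. The
defaults (10 breeds × 25 animals, 29 chromosomes of 100 Mbp, ~5,000 SNPs,
drift 0.1, 0.2% missing calls) are a desk-scale portrait of a multi-breed
50k-chip panel.

The simulator is deliberately simple: no linkage disequilibrium, no
recombination-map structure, no ascertainment beyond the frequency range,
no pedigree. Passing tests therefore demonstrate that the *algorithms*
recover what was planted under the model's own assumptions — they do not
certify performance on real chip data, where LD inflates chance
homozygosity runs and family structure adds relatedness the admixture model
ignores. Two consequences guided the validation choices below.

## Validation conditions and numerical choices

The test suite validates each stage against an independent oracle or
planted truth at fixed, documented sizes:

* **ROH scan**: exact agreement with a brute-force maximal-window oracle on
  1,000 random 300-SNP chromosomes across 20 parameter settings.
* **F_ROH recovery**: planted fractions 0, 0.05 and 0.20 with 2–8 Mbp
  segments on 50 animals, using 4 × 100 Mbp chromosomes at one SNP per
  50 kb (real chip density) and an ancestral frequency range of 0.2–0.8.
  The narrowed range emulates the common-variant ascertainment of
  commercial chips; it keeps background heterozygosity near 0.4, which
  caps chance (unplanted) run coverage below ~0.005 — without LD, a wider
  frequency range would produce rare-allele deserts that masquerade as
  ROH. Recovery is required within ±0.02.
* **Admixture**: exact K=1 closed form; EM ascent on 100 random instances;
  mean $|\hat Q - Q| \le 0.05$ after label alignment and CV selection of
  $K=3$ in at least 8 of 10 seeded runs on 3-breed panels (120 animals,
  1,000 SNPs, drift 0.2).
* **DAPC**: posterior agreement to $10^{-8}$ with a full-density Gaussian
  oracle; ≥99% cross-validated success on the 10-breed default panel and
  ≥95% back-assignment of held-out target animals; on a target simulated
  as a 50/50 mixture of two source breeds (plus a drift-0.3 outgroup),
  ≥95% of leave-breed-out assignments land on a source breed at training
  fraction 0.9, with attribution non-decreasing in training fraction.
* **I/O**: byte-identical binary round trips and exact QC counts at the
  strict 95%/10% boundaries.

Cross-validation repetition counts inside the scenario tests are reduced
(1–3 instead of 30) relative to the interactive defaults; they average a
quantity whose per-repetition variance is already small at these panel
sizes, and the package treats the repetition count as a parameter, not a
constant. PCA inside cross-validation loops uses an eigendecomposition of
the smaller Gram-matrix side (exactly equivalent to the thin SVD, at
$10^{-6}$-scale numerical agreement), while the user-facing
`genotype_pca` uses LAPACK's SVD directly and is tested to $10^{-8}$
against dense reconstructions.

## Known limitations

* No LD-aware ROH correction: on real data the 15-SNP/1-Mbp thresholds are
  doing the work that an LD model would; very dense or pruned panels need
  re-tuned thresholds.
* The admixture EM is first-order: for panels orders of magnitude larger
  than the desk scale, quasi-Newton implementations converge in far fewer
  sweeps.
* The F_ROH denominator is the SNP-covered map length; comparisons against
  coefficients computed over assembly lengths need the `chrom_lengths`
  override.
* Scenario-3 percentages are distributions over the *available* breeds; if
  the true source population is absent from the panel entirely, the
  assignment mass moves to the nearest available breeds by construction.
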