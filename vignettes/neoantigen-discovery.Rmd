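---
title: "Neoantigen discovery and expression analysis with neoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neoantigen discovery and expression analysis with neoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoscreen)
```

## The problem

Tumors accumulate somatic mutations, and a nonsynonymous single-nucleotide
variant (nsSNV) changes one amino acid of one protein. Short peptides
spanning that altered residue can be presented on MHC class I molecules and
recognized by CD8+ T cells as *neoantigens* — tumor-specific targets for
checkpoint-blockade response and for therapeutic vaccination. The
computational task is a funnel: from a variant list, enumerate every mutant
peptide window a given MHC allele could present, predict each window's
binding affinity, rank by affinity, remove candidates whose gene is not
expressed in the tumor, and design a vaccine-ready synthetic long peptide
(SLP) around the best candidates. `neoscreen` implements this funnel for
missense variants, together with the bulk RNA-seq statistics used to
characterize treatment-induced transcriptional changes in the same study
designs (TPM quantification, per-gene t-tests, Benjamini–Hochberg
correction, temporal induction summaries).

The motivating setting is the syngeneic mouse, where the class I alleles
are H-2Kb and H-2Db, but nothing in the pipeline is allele-specific beyond
its configuration.

## The binding model

Each predictor is an additive position-specific scoring matrix over the 20
residues: for a k-mer peptide $p_1 \ldots p_k$,

$$\log_{10} \mathrm{IC}_{50}(p) \;=\; b \;+\; \sum_{i=1}^{k} W[p_i, i],$$

with the result exponentiated to nM and clamped to $[10^{-2}, 10^{7}]$ so
the downstream affinity score can never divide by zero or overflow. This is
the stabilized-matrix-method family of models: IC50, the half-maximum
inhibitory concentration in a competition assay, is lower for stronger
binders, and the model is additive on the log scale where binding free
energies approximately add. Neural-network predictors are out of scope;
the adapter `merge_external_predictions()` lets externally computed IC50
tables join the consensus instead.

Multiple predictors are combined into a consensus IC50. Because IC50s span
five or more orders of magnitude and the matrix model is additive in log
space, the default consensus is the **geometric mean** (the arithmetic
mean of $\log_{10}$ IC50, exponentiated). An arithmetic-mean option exists
for sensitivity analysis; on the nM scale it is dominated by the weakest
predictor, which is rarely what a ranking should reflect. The consensus
always lies between the per-predictor minimum and maximum.

Ranking uses the affinity score

$$\mathrm{score} = \frac{1}{\mathrm{IC}_{50}} \times 100,$$

so a 50 nM binder scores 2 and a 500 nM binder 0.2. The score is a strictly
decreasing transform of IC50, so ranking by descending score and ascending
IC50 are the same ordering; the score exists for reporting and Manhattan
plots, not for changing the order. Candidate tiers use strict cutoffs
IC50 < 500, < 50 and < 25 nM — strict, so a candidate at exactly 500 nM is
excluded — and are nested by construction.

## Window enumeration and SLP design

For a missense change at protein position $m$ and an allele that presents
k-mers, every window $[s, s+k-1]$ with $s \le m \le s+k-1$ that lies inside
the protein is a candidate; near the termini fewer windows fit, and a
protein shorter than $k$ yields none. Default allele lengths are H-2Kb
{8, 9} and H-2Db {9, 10}, the canonical groove preferences of those
alleles; lengths are per-allele configuration, not hard-coded. Every mutant
window is paired with its wild-type counterpart (Hamming distance exactly
1), which downstream assays use as the control peptide.

The SLP designer places the mutant residue at offset
$\lceil L/2 \rceil$ of an $L$-mer (default $L = 28$, a common SLP length),
shifting the window only when a protein terminus forces it and truncating
only when the protein itself is shorter than $L$. Centering is a design
choice: published SLPs do not always state the epitope's register within
the long peptide, and a centered placement leaves maximal flanking context
on both sides for proteasomal processing.

## Expression evidence

A predicted binder whose transcript is not expressed cannot be presented.
The screen keeps a candidate when a binary evidence flag (the in-silico
stand-in for targeted PCR/Sanger confirmation) is `TRUE`, or when no flag
is present and the transcript's TPM is at least `min_tpm` (default 1.0, a
conventional detection floor; the threshold is a parameter because the
evidence the field actually uses is binary). Candidates are annotated and
partitioned, never silently dropped — rejects go to their own file. A
transcript absent from the expression table is an error by default
(`strict`), because silent identifier mismatches otherwise inflate
candidate lists; `lenient` mode marks such candidates unexpressed instead.

## Differential expression

Counts and per-gene effective lengths are converted to transcripts per
million:
$$\mathrm{TPM}_g = \frac{c_g / \ell_g}{\sum_j c_j / \ell_j} \times 10^6,$$
so every sample sums to $10^6$ exactly. Tests run on $\log_2(\mathrm{TPM} + 1)$
— the pseudocount of 1 keeps zeros finite while leaving well-expressed
genes on the log2 scale. The per-gene test is the two-sample **Welch**
t-test by default (pooled-variance optional): with 3–4 replicates per
group, assuming equal variances buys little and costs robustness. Genes
constant and equal in both groups are assigned $t = 0$, $p = 1$ rather
than dropped, so the Benjamini–Hochberg family size is always the full
gene count. BH adjustment is the standard step-up procedure; the volcano
table reports $-\log_{10} q$ with $q$ floored at machine epsilon, flagging
$q < 0.05$ (strict). The temporal profile compares treated-minus-control
mean log expression per study day, flags monotone increase across days and
reports the day of maximal difference.

Because TPM is compositional, strongly induced genes absorb library mass
and depress the apparent expression of null genes slightly; with the
default simulated designs this shift is an order of magnitude smaller than
the planted effects, but it is visible and users comparing fold changes
across very unequal libraries should keep it in mind.

## What the synthetic data emulates

`simulate_cohort()` generates every input the discovery pipeline consumes,
on a deliberately small scale (200 genes, 50 variants by default; real
tumors of this kind carry hundreds to thousands of nsSNVs, and the scale is
configurable):

* random proteins of 60–120 residues, generated **repeat-free at 8-mers**
  so that substring-uniqueness of enumerated windows is assertable;
* matched coding sequences (fixed codon per residue, terminal stop);
* a variant table with genomic coordinates for Manhattan layout;
* one **planted neoepitope**: a 9-mer on H-2Kb whose residue/position
  cells in a shared truth matrix are set so it scores at the target
  consensus IC50 (10 nM — comfortably inside the < 25 nM high-affinity
  tier); all other weights are background ($\mathcal{N}(0.35, 0.15^2)$ per
  cell with intercept 2, putting typical windows at $10^4$–$10^6$ nM,
  i.e. non-binders);
* five predictor matrices, each the truth matrix plus i.i.d.
  $\mathcal{N}(0, 0.05^2)$ cell noise — the consensus geometric mean is
  then a better estimate of the truth score than any single predictor;
* a log-normal expression table in which an exact fraction (default 20%)
  of variant transcripts is unexpressed, never including the planted one;
* truth files (`truth_*.tsv`) that record the planted peptide and the
  unexpressed set; the pipeline never reads them.

`simulate_expression()` generates grouped count matrices: per-gene
log-normal baselines ($\log_2$ baseline $\sim \mathcal{N}(5, 2^2)$),
effective lengths uniform on 500–3000 bp, replicate noise
$\mathcal{N}(0, 0.15^2)$ on the log2 scale, and a multiplicative treatment
effect on the planted genes that ramps linearly over the study days to its
full size at the last day. The default noise of 0.15 log2 units reflects
replicate variability typical of FACS-sorted, homogeneous immune
populations profiled in bulk; it was fixed by a design-time power analysis
so that the reference condition (two-fold induction, 4 vs 4 samples, 2,000
genes) is detectable at BH $q < 0.05$ with sensitivity well above 0.8.
Counts are rounded expression × length × depth, so Poisson shot noise is
*not* modeled — at the simulated depth (hundreds of counts for a typical
gene) shot noise would be dominated by the log-normal replicate noise, but
this is a simplification relative to real RNA-seq.

All generators pin the RNG (Mersenne-Twister / inversion / rejection
sampling) and are byte-reproducible for a given config and seed.

### What passing tests do and do not show

The planted-recovery test demonstrates that the pipeline's plumbing —
enumeration, scoring, consensus, expression screen, ranking — preserves a
strong signal end to end. It does not validate the biological accuracy of
any scoring matrix: matrices here are synthetic, and on real data
prediction quality is bounded by the predictors supplied. Likewise the DE
calibration shows the t-test/BH machinery is statistically sound under the
generator's log-normal noise; real RNA-seq has heavier-tailed,
mean-dependent variance that this generator intentionally does not
reproduce (count-model tools like DESeq2/edgeR address that regime).

## Numerical and degenerate-input choices

* IC50 clamp $[0.01, 10^7]$ nM; recorded in output metadata.
* Strict inequalities at all tier boundaries and at $q < 0.05$.
* Ranking ties broken by gene symbol then peptide lexicographically, so
  reports are deterministic.
* Mixed presence/absence of genomic coordinates in a Manhattan table
  falls back to index positions with a warning rather than guessing.
* An all-zero sample is an error in TPM computation (there is no sensible
  normalization), naming the sample.
* Zero-length proteins, non-missense CDS substitutions (synonymous or
  nonsense) and reference-residue mismatches are rejected with labelled
  errors; the pipeline analyzes missense variants only.

## Problem sizes

The shipped tests and the acceptance script use the default cohort
(200 genes, 50 variants, ~1,800 windows, 20 matrices) for 20 seeded
end-to-end runs, and 2,000-gene expression matrices at 3–4 samples per
group for the statistical checks. These sizes give stable stochastic
estimates (recovery counted over 20 runs; type-I error estimated from
2,000 null genes) while each run stays in the low seconds.

## Known limitations

* Missense variants only: no indels, frameshifts, splice products or
  fusion peptides.
* No proteasomal-processing or TAP-transport model, and no percentile-rank
  normalization; the ranking is IC50-based.
* No clonality/VAF weighting of candidates.
* TPM-level expression evidence only; no allele-specific expression or
  read-level support for the variant allele.
* The matrix predictors are file-driven; the package does not train them.

## A worked run

```{r, eval = FALSE}
dir <- tempfile("cohort_")
run_simulate(simulation_config(seed = 7), dir)

cfg <- run_config(
  proteome   = file.path(dir, "proteome.fasta"),
  variants   = file.path(dir, "variants.tsv"),
  matrix_dir = file.path(dir, "matrices"),
  expression = file.path(dir, "expression.tsv"),
  out_dir    = file.path(dir, "out"))
res <- run_discover(cfg)
head(res$ranked[, c("rank", "gene", "protein_change", "allele",
                    "mutant_peptide", "consensus_ic50_nM",
                    "affinity_score", "tier")])

study <- simulate_expression(de_params(), seed = 7)
de <- run_de(study$counts, study$effective_lengths, study$samples,
             out_dir = file.path(dir, "de"))
head(de$de[["17"]][order(de$de[["17"]]$q_value), ])
```
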