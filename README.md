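# neoscreen

Neoantigen discovery from somatic missense variants, with consensus MHC
class I binding prediction and an RNA-seq differential-expression stage.

## What it does and for whom

Tumor-specific mutant peptides (neoantigens) arise when a nonsynonymous
single-nucleotide variant changes one residue of a protein; those peptides
can be presented on MHC class I and recognized by CD8+ T cells. For
immunogenomics analysts working with variant calls from a tumor (the
motivating setting is syngeneic mouse models with the H-2Kb / H-2Db
alleles), `neoscreen` implements the standard discovery funnel:

1. **Enumerate** every 8–11-mer peptide window of the mutant protein that
   overlaps the altered residue, paired with its wild-type counterpart.
2. **Score** each window with additive position-specific scoring matrices
   predicting `log10 IC50(nM) = intercept + Σᵢ W[residueᵢ, i]`.
3. **Combine** several predictors into a consensus IC50 (geometric mean —
   the arithmetic mean of log10 IC50, exponentiated).
4. **Rank** by the affinity score `(1/IC50) × 100` and assign nested
   tiers at strict cutoffs IC50 < 500, < 50, < 25 nM.
5. **Screen** candidates for transcript expression (TPM threshold or a
   binary evidence flag), partitioning survivors from rejects.
6. **Design** a 28-residue synthetic long peptide (SLP) centered on the
   mutant residue for vaccine manufacture.

A companion stage implements the bulk RNA-seq statistics used alongside
such studies: TPM from counts and effective lengths
(`tpm_g = (c_g/l_g)/Σ(c_j/l_j) × 1e6`), Welch t-tests on `log2(TPM+1)`,
Benjamini–Hochberg correction, volcano tables and temporal-induction
profiles across study days. A seeded synthetic-data generator produces
every input the pipeline consumes — including a planted high-affinity
neoepitope — so the whole system is testable end to end without any
external download.

## Worked example

```r
library(neoscreen)

dir <- tempfile("cohort_")
run_simulate(simulation_config(seed = 7), dir)   # synthetic tumor inputs

cfg <- run_config(
  proteome   = file.path(dir, "proteome.fasta"),
  variants   = file.path(dir, "variants.tsv"),
  matrix_dir = file.path(dir, "matrices"),
  expression = file.path(dir, "expression.tsv"),
  out_dir    = file.path(dir, "out"))
res <- run_discover(cfg)
```

The run logs its candidate funnel to stderr:

```
[neoscreen] variants: 50
[neoscreen] enumerated windows: 1800
[neoscreen] predicted: 1800; lt500=1, lt50=1, lt25=1
[neoscreen] expressed: 1440 (rejected 360)
```

50 variants × 2 alleles × 2 window lengths each give 1,800 scored
windows; exactly one (the planted neoepitope) clears every affinity tier,
and 360 windows are rejected because their transcripts are unexpressed.
The top of the ranked report:

```
  rank    gene protein_change allele mutant_peptide consensus_ic50_nM affinity_score tier
1    1 GENE001           Q18A  H-2Kb      HCAGAIRRC             10.84        9.22934 lt25
2    2 GENE010           T31S  H-2Kb      HWDDSPNWL           2856.77        0.03500 none
3    3 GENE078           V18N  H-2Kb       TRHNFITC           3043.70        0.03285 none
```

Row 1 is the planted 9-mer recovered at rank 1 with consensus IC50
≈ 10.8 nM (target 10 nM; affinity score 100/10.84 ≈ 9.2) — a high-affinity
binder, while the next candidates sit in the micromolar non-binder range.
The report also carries each candidate's wild-type peptide and, for the
top candidates, the designed 28-mer SLP.

The expression stage:

```r
study <- simulate_expression(de_params(), seed = 7)
de <- run_de(study$counts, study$effective_lengths, study$samples,
             out_dir = file.path(dir, "de"))
head(de$de[["17"]][order(de$de[["17"]]$q_value), ], 3)
```

```
     gene log2fc t_stat   p_value  q_value
25  G0025 0.8904  19.98 1.670e-05 0.003858
370 G0370 0.9932  20.77 1.022e-05 0.003858
517 G0517 0.8720  19.74 3.249e-06 0.003858
```

Genes planted with a two-fold induction (log2fc ≈ 1) surface at
BH q ≪ 0.05 on the last study day; `de$temporal` flags their monotone
rise across days 11 → 14 → 17.

A thin command-line wrapper with `simulate`, `discover` and `de`
subcommands ships at `inst/cli/neoscreen.R` (exit codes: 0 success,
2 validation error, 3 stage failure).

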