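# RNG kinds are pinned explicitly so identical config + seed gives
# byte-identical outputs on every platform.
RNG_KIND <- "Mersenne-Twister"
RNG_NORMAL <- "Inversion"
RNG_SAMPLE <- "Rejection"

with_fixed_seed <- function(seed, code) {
  withr::with_seed(seed, code, .rng_kind = RNG_KIND,
                   .rng_normal_kind = RNG_NORMAL,
                   .rng_sample_kind = RNG_SAMPLE)
}

#' Configuration of the synthetic tumor cohort
#'
#' The generator emulates the inputs of a neoantigen-discovery study on a
#' toy scale: a proteome with somatic missense variants, one planted
#' high-affinity neoepitope (target consensus IC50 around 10 nM), five
#' matrix predictors sampled around a shared truth matrix, and a transcript
#' expression table in which a fixed fraction of variant transcripts is not
#' expressed. Scales are configurable (the default cohort is small for fast
#' iteration; real tumors carry thousands of nonsynonymous variants).
#'
#' @param seed integer seed; same config + seed reproduces files exactly.
#' @param n_genes number of genes/transcripts in the toy proteome.
#' @param protein_length_range min/max protein length (residues).
#' @param n_variants number of somatic missense variants (including the
#'   planted one).
#' @param target_ic50 planted neoepitope's target consensus IC50 (nM).
#' @param fraction_unexpressed fraction of variant transcripts given zero
#'   expression (the planted transcript is always expressed).
#' @param n_predictors number of matrix predictors (default 5).
#' @param matrix_noise_sd sd of per-predictor deviation from the truth
#'   matrix (log10 nM per cell).
#' @param background_weight_mean,background_weight_sd distribution of
#'   background matrix weights (log10 nM per cell); with intercept 2 a
#'   typical 9-mer scores far above the binding cutoffs.
#' @param intercept matrix intercept (log10 nM).
#' @param de_params list from [de_params()] controlling the expression
#'   simulator.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 200L,
                              protein_length_range = c(60L, 120L),
                              n_variants = 50L,
                              target_ic50 = 10,
                              fraction_unexpressed = 0.2,
                              n_predictors = 5L,
                              matrix_noise_sd = 0.05,
                              background_weight_mean = 0.35,
                              background_weight_sd = 0.15,
                              intercept = 2,
                              de_params = NULL) {
  stopifnot(n_genes >= 1L, n_variants >= 1L, n_variants <= n_genes,
            n_predictors >= 1L,
            fraction_unexpressed >= 0, fraction_unexpressed <= 1,
            target_ic50 > 0,
            length(protein_length_range) == 2L,
            protein_length_range[1] >= 20L,
            protein_length_range[2] >= protein_length_range[1])
  if (is.null(de_params)) de_params <- neoscreen_de_params_default()
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 protein_length_range = as.integer(protein_length_range),
                 n_variants = as.integer(n_variants),
                 target_ic50 = target_ic50,
                 fraction_unexpressed = fraction_unexpressed,
                 n_predictors = as.integer(n_predictors),
                 matrix_noise_sd = matrix_noise_sd,
                 background_weight_mean = background_weight_mean,
                 background_weight_sd = background_weight_sd,
                 intercept = intercept,
                 de_params = de_params),
            class = "simulation_config")
}

#' Parameters of the expression simulator
#'
#' Per-gene baselines are log-normal (`log2` baseline ~
#' Normal(`baseline_log2_mean`, `baseline_log2_sd`)); planted genes carry a
#' multiplicative treatment effect that ramps up linearly across study days
#' to its full size at the last day; replicate noise is Normal on the log2
#' scale. Counts are derived from expression, per-gene effective length and
#' a fixed depth factor.
#'
#' @param n_genes genes in the matrix.
#' @param n_de_genes number of planted induced genes.
#' @param log2_effect full effect size at the last day (1 = two-fold).
#' @param noise_sd replicate noise sd on the log2 scale.
#' @param samples_per_group samples per group per day.
#' @param days study-day labels.
#' @param baseline_log2_mean,baseline_log2_sd baseline distribution.
#' @return list of class `de_params`.
#' @export
de_params <- function(n_genes = 2000L, n_de_genes = 100L, log2_effect = 1,
                      noise_sd = 0.15, samples_per_group = 4L,
                      days = c(11L, 14L, 17L),
                      baseline_log2_mean = 5, baseline_log2_sd = 2) {
  neoscreen_de_params_default(n_genes, n_de_genes, log2_effect, noise_sd,
                              samples_per_group, days, baseline_log2_mean,
                              baseline_log2_sd)
}

neoscreen_de_params_default <- function(n_genes = 2000L, n_de_genes = 100L,
                                        log2_effect = 1,
                      noise_sd = 0.15, samples_per_group = 4L,
                      days = c(11L, 14L, 17L),
                      baseline_log2_mean = 5, baseline_log2_sd = 2) {
  stopifnot(n_genes >= 1L, n_de_genes >= 0L, n_de_genes <= n_genes,
            samples_per_group >= 2L, noise_sd >= 0, length(days) >= 1L)
  structure(list(n_genes = as.integer(n_genes),
                 n_de_genes = as.integer(n_de_genes),
                 log2_effect = log2_effect, noise_sd = noise_sd,
                 samples_per_group = as.integer(samples_per_group),
                 days = as.integer(days),
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd),
            class = "de_params")
}

# Codon for each residue (fixed choice so CDS generation is deterministic).
CODON_OF <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

random_protein <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

#' Simulate a complete synthetic tumor cohort
#'
#' Writes every input the discovery pipeline consumes: a proteome FASTA, a
#' CDS FASTA, a somatic variant TSV (with genomic coordinates for Manhattan
#' layout), a directory of predictor scoring matrices, a transcript
#' expression TSV, and truth files (`truth_planted.tsv`,
#' `truth_unexpressed.tsv`) that record the planted neoepitope and the
#' unexpressed variants. Truth files are never read by the pipeline.
#'
#' Proteins are generated repeat-free at the shortest window length so
#' every enumerated peptide is a unique substring; predictor matrices are
#' i.i.d. perturbations of one truth matrix in which the planted peptide's
#' residue/position cells are set so it scores at `target_ic50`.
#'
#' @param config a `simulation_config`.
#' @param dir output directory (created if needed).
#' @return invisible list of the generated file paths plus the in-memory
#'   truth (planted peptide and unexpressed transcripts).
#' @export
simulate_cohort <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$protein_length_range[1] < 30L) {
    stop("planted gene must comfortably exceed the longest peptide window; ",
         "raise protein_length_range", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "matrices"), showWarnings = FALSE)
  with_fixed_seed(config$seed, simulate_cohort_impl(config, dir))
}

simulate_cohort_impl <- function(config, dir) {
  ng <- config$n_genes
  genes <- sprintf("GENE%03d", seq_len(ng))
  tx <- sprintf("TX%03d", seq_len(ng))
  lens <- sample(config$protein_length_range[1]:config$protein_length_range[2],
                 ng, replace = TRUE)

  # repeat-free at the shortest window length (8): regenerate any protein
  # that introduces a duplicate 8-mer
  seen <- character(0)
  prots <- character(ng)
  for (i in seq_len(ng)) {
    repeat {
      p <- random_protein(lens[i])
      km <- kmers(p, 8L)
      if (!anyDuplicated(km) && !any(km %in% seen)) {
        prots[i] <- p
        seen <- c(seen, km)
        break
      }
    }
  }

  # genomic layout for Manhattan plots
  chrom <- paste0("chr", sample(1:19, ng, replace = TRUE))
  gstart <- sample.int(99000000L, ng) + 1000000L

  # somatic missense variants: distinct genes, interior positions
  vgenes <- sort(sample(seq_len(ng), config$n_variants))
  vpos <- vapply(vgenes, function(i) {
    sample(10:(lens[i] - 10L), 1L) }, integer(1))
  vref <- substring(prots[vgenes], vpos, vpos)
  valt <- vapply(vref, function(r) sample(setdiff(AA_ALPHABET, r), 1L),
                 character(1), USE.NAMES = FALSE)

  # the planted neoepitope: first variant slot, H-2Kb 9-mer with the
  # altered residue at offset 5
  planted_i <- 1L
  gi <- vgenes[planted_i]
  mut_prot <- prots[gi]
  substr(mut_prot, vpos[planted_i], vpos[planted_i]) <- valt[planted_i]
  pl_start <- vpos[planted_i] - 4L
  pl_pep <- substr(mut_prot, pl_start, pl_start + 8L)

  variants <- data.frame(
    gene = genes[vgenes], transcript_id = tx[vgenes],
    protein_change = paste0(vref, vpos, valt),
    chrom = chrom[vgenes],
    pos = gstart[vgenes] + 3L * (vpos - 1L),
    stringsAsFactors = FALSE)

  # expression: log-normal TPM; exactly round(fraction * n) variant
  # transcripts are unexpressed (never the planted one)
  tpm <- round(2^stats::rnorm(ng, 5, 1.5), 2)
  tpm <- pmax(tpm, 1.5)  # background transcripts count as expressed
  n_unexpr <- round(config$fraction_unexpressed * config$n_variants)
  unexpr_slots <- if (n_unexpr > 0) {
    sort(sample(setdiff(seq_len(config$n_variants), planted_i), n_unexpr))
  } else integer(0)
  tpm[vgenes[unexpr_slots]] <- 0
  expression <- data.frame(transcript_id = tx, tpm = tpm,
                           stringsAsFactors = FALSE)

  # predictor matrices: one truth matrix per (allele, length); the planted
  # (H-2Kb, 9) cells are set so the planted peptide scores target_ic50
  alleles <- default_alleles()
  combos <- do.call(rbind, lapply(alleles, function(a) {
    data.frame(allele = a$name, k = a$peptide_lengths,
               stringsAsFactors = FALSE) }))
  pred_ids <- sprintf("pssm%d", seq_len(config$n_predictors))
  matrix_paths <- character(0)
  for (ci in seq_len(nrow(combos))) {
    k <- combos$k[ci]
    truth <- matrix(stats::rnorm(20L * k, config$background_weight_mean,
                                 config$background_weight_sd),
                    20L, k, dimnames = list(AA_ALPHABET, NULL))
    if (combos$allele[ci] == "H-2Kb" && k == 9L) {
      res <- strsplit(pl_pep, "")[[1]]
      per_cell <- (log10(config$target_ic50) - config$intercept) / 9
      truth[cbind(match(res, AA_ALPHABET), 1:9)] <- per_cell
    }
    for (pid in pred_ids) {
      w <- truth + matrix(stats::rnorm(20L * k, 0, config$matrix_noise_sd),
                          20L, k)
      m <- scoring_matrix(combos$allele[ci], w, config$intercept, pid)
      path <- file.path(dir, "matrices",
                        sprintf("%s_k%d_%s.tsv",
                                gsub("-", "", combos$allele[ci]), k, pid))
      write_scoring_matrix(m, path)
      matrix_paths <- c(matrix_paths, path)
    }
  }

  # write FASTA / TSV inputs
  aa <- Biostrings::AAStringSet(prots)
  names(aa) <- paste0(tx, " gene=", genes)
  Biostrings::writeXStringSet(aa, file.path(dir, "proteome.fasta"))
  cds <- vapply(prots, function(p) {
    paste0(paste(CODON_OF[strsplit(p, "")[[1]]], collapse = ""), "TAA")
  }, character(1), USE.NAMES = FALSE)
  dna <- Biostrings::DNAStringSet(cds)
  names(dna) <- paste0(tx, " gene=", genes)
  Biostrings::writeXStringSet(dna, file.path(dir, "cds.fasta"))
  write_tsv(variants, file.path(dir, "variants.tsv"))
  write_tsv(expression, file.path(dir, "expression.tsv"))

  truth_planted <- data.frame(
    gene = genes[gi], transcript_id = tx[gi],
    protein_change = variants$protein_change[planted_i],
    allele = "H-2Kb", length = 9L, window_start = pl_start,
    planted_peptide = pl_pep, target_ic50 = config$target_ic50,
    stringsAsFactors = FALSE)
  write_tsv(truth_planted, file.path(dir, "truth_planted.tsv"))
  truth_unexpr <- data.frame(transcript_id = tx[vgenes],
                             unexpressed = seq_len(config$n_variants) %in%
                               unexpr_slots,
                             stringsAsFactors = FALSE)
  write_tsv(truth_unexpr, file.path(dir, "truth_unexpressed.tsv"))

  invisible(list(
    proteome = file.path(dir, "proteome.fasta"),
    cds = file.path(dir, "cds.fasta"),
    variants = file.path(dir, "variants.tsv"),
    matrix_dir = file.path(dir, "matrices"),
    expression = file.path(dir, "expression.tsv"),
    truth_planted = truth_planted,
    truth_unexpressed = truth_unexpr))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate grouped expression count matrices
#'
#' Produces a genes x samples count matrix with a control and a treated
#' (anti-PD1) group at each study day, per-gene effective lengths, a sample
#' sheet, and the list of planted induced genes. Planted genes carry
#' `log2_effect * d / max(days')` where days' are ranked 1..D, i.e. the
#' effect ramps to full size at the last day ("temporal induction"); all
#' other genes are null. With `log2_effect = 0` the matrix is a global
#' null, suitable for type-I calibration.
#'
#' @param params a `de_params` list.
#' @param seed integer seed.
#' @param dir optional directory; when given, writes `counts.tsv`,
#'   `lengths.tsv`, `samples.tsv`, `truth_de_genes.tsv`.
#' @return list with `counts` (matrix), `effective_lengths`, `samples`
#'   (data.frame: sample, group, day), `de_genes` (character).
#' @export
simulate_expression <- function(params, seed = 1L, dir = NULL) {
  stopifnot(inherits(params, "de_params"))
  out <- with_fixed_seed(seed, simulate_expression_impl(params))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    counts_df <- data.frame(gene = rownames(out$counts), out$counts,
                            check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(counts_df, file.path(dir, "counts.tsv"))
    write_tsv(data.frame(gene = rownames(out$counts),
                         effective_length = out$effective_lengths),
              file.path(dir, "lengths.tsv"))
    write_tsv(out$samples, file.path(dir, "samples.tsv"))
    write_tsv(data.frame(gene = out$de_genes),
              file.path(dir, "truth_de_genes.tsv"))
  }
  out
}

simulate_expression_impl <- function(params) {
  ng <- params$n_genes
  genes <- sprintf("G%04d", seq_len(ng))
  mu <- stats::rnorm(ng, params$baseline_log2_mean, params$baseline_log2_sd)
  el <- round(stats::runif(ng, 500, 3000))
  de_genes <- if (params$n_de_genes > 0) {
    sort(sample(genes, params$n_de_genes))
  } else character(0)
  is_de <- genes %in% de_genes
  days <- sort(params$days)
  ramp <- seq_along(days) / length(days)
  nps <- params$samples_per_group
  depth <- 10
  cols <- list(); meta <- list()
  for (di in seq_along(days)) {
    for (grp in c("control", "anti-PD1")) {
      eff <- if (grp == "anti-PD1") params$log2_effect * ramp[di] else 0
      for (s in seq_len(nps)) {
        lx <- mu + ifelse(is_de, eff, 0) + stats::rnorm(ng, 0, params$noise_sd)
        counts <- round(2^lx * el / 1000 * depth)
        nm <- sprintf("d%d_%s_%d", days[di], gsub("-", "", grp), s)
        cols[[nm]] <- counts
        meta[[nm]] <- data.frame(sample = nm, group = grp,
                                 day = days[di], stringsAsFactors = FALSE)
      }
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- genes
  list(counts = counts, effective_lengths = stats::setNames(el, genes),
       samples = do.call(rbind, c(meta, list(make.row.names = FALSE))),
       de_genes = de_genes)
}

#' Ellipsoid tumor volume from caliper measurements
#'
#' The standard `(L x W^2) / 2` formula (mm^3) used to monitor subcutaneous
#' tumor growth; the formula is asymmetric, with `L` the longer axis.
#'
#' @param length_mm tumor length (mm).
#' @param width_mm tumor width (mm).
#' @return volume in mm^3.
#' @examples
#' tumor_volume(10, 10)  # 500
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm <= 0) || any(width_mm <= 0)) {
    stop("tumor dimensions must be positive", call. = FALSE)
  }
  length_mm * width_mm^2 / 2
}
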