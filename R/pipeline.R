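#' Build and validate a discovery-run configuration
#'
#' Collects input paths and thresholds for [run_discover()]. Tier cutoffs
#' must be positive and strictly decreasing; referenced files must exist.
#'
#' @param proteome proteome FASTA path.
#' @param variants variant TSV path.
#' @param matrix_dir directory of predictor matrix TSVs.
#' @param expression expression TSV path (or `NULL` to skip the expression
#'   screen).
#' @param out_dir output directory.
#' @param tiers named nested IC50 cutoffs (nM), strictly decreasing.
#' @param min_tpm expression threshold.
#' @param alleles list of `mhc_allele`.
#' @param consensus `"geometric"` or `"arithmetic"`.
#' @param missing_expression `"strict"` or `"lenient"` (see
#'   [filter_expressed()]).
#' @param slp_len synthetic-long-peptide length for the designed vaccine
#'   column.
#' @param seed integer recorded in the manifest (discovery itself is
#'   deterministic).
#' @return list of class `run_config`.
#' @export
run_config <- function(proteome, variants, matrix_dir, expression = NULL,
                       out_dir = tempfile("neoscreen_run_"),
                       tiers = DEFAULT_TIERS, min_tpm = 1.0,
                       alleles = default_alleles(),
                       consensus = c("geometric", "arithmetic"),
                       missing_expression = c("strict", "lenient"),
                       slp_len = 28L, seed = 1L) {
  consensus <- match.arg(consensus)
  missing_expression <- match.arg(missing_expression)
  if (any(tiers <= 0) || any(diff(unname(tiers)) >= 0)) {
    validation_error("tier cutoffs must be positive and strictly decreasing")
  }
  for (p in c(proteome, variants, matrix_dir, expression)) {
    if (!is.null(p) && !file.exists(p)) {
      validation_error("input does not exist: ", p)
    }
  }
  structure(list(proteome = proteome, variants = variants,
                 matrix_dir = matrix_dir, expression = expression,
                 out_dir = out_dir, tiers = tiers, min_tpm = min_tpm,
                 alleles = alleles, consensus = consensus,
                 missing_expression = missing_expression,
                 slp_len = as.integer(slp_len), seed = as.integer(seed)),
            class = "run_config")
}

validation_error <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("neoscreen_validation_error", "error")))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "neoscreen_stage_error")) stop(e)
    stop(errorCondition(paste0("stage ", stage, ": ", conditionMessage(e)),
                        class = c("neoscreen_stage_error", "error")))
  })
}

log_stage <- function(...) message("[neoscreen] ", ...)

#' Run the end-to-end neoantigen discovery pipeline
#'
#' Variants -> mutant peptide windows -> per-predictor IC50 -> consensus ->
#' tiers -> expression screen -> ranked report. Writes, under
#' `config$out_dir`: `ranked_report.tsv`, `candidates_all.tsv`, one
#' `tier_<name>.tsv` per cutoff, `manhattan.tsv`, `rejects.tsv` and
#' `manifest.json`. Per-stage record counts (the candidate funnel) are
#' logged to stderr. The run is deterministic: identical inputs give
#' byte-identical outputs.
#'
#' @param config a `run_config`.
#' @return invisible list with the ranked report, manhattan table, rejects
#'   and the funnel counts.
#' @export
run_discover <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  proteome <- with_stage("sequence_model", read_proteome_fasta(config$proteome))
  variants <- with_stage("sequence_model",
                         read_variant_table(config$variants, proteome))
  log_stage("variants: ", nrow(variants))

  candidates <- with_stage("epitope_enumeration",
                           enumerate_candidates(variants, proteome,
                                                config$alleles))
  log_stage("enumerated windows: ", nrow(candidates))

  registry <- with_stage("binding_prediction",
                         load_matrix_registry(config$matrix_dir))
  scored <- with_stage("binding_prediction",
                       predict_candidates(candidates, registry,
                                          method = config$consensus))
  scored <- assign_tiers(scored, config$tiers)
  tier_counts <- vapply(names(config$tiers), function(tn) {
    nrow(tier_filter(scored, config$tiers[[tn]])) }, integer(1))
  log_stage("predicted: ", nrow(scored), "; ",
            paste(names(tier_counts), tier_counts, sep = "=",
                  collapse = ", "))

  if (!is.null(config$expression)) {
    expr <- with_stage("expression_evidence",
                       read_expression_table(config$expression))
    split <- with_stage("expression_evidence",
                        filter_expressed(scored, expr,
                                         min_tpm = config$min_tpm,
                                         missing = config$missing_expression))
    kept <- split$survivors
    rejects <- split$rejects
  } else {
    kept <- scored
    kept$expressed <- NA
    kept$tpm <- NA_real_
    rejects <- kept[0, , drop = FALSE]
  }
  log_stage("expressed: ", nrow(kept), " (rejected ", nrow(rejects), ")")

  ranked <- with_stage("prioritization", rank_candidates(kept))
  ranked$slp <- NA_character_
  if (nrow(ranked) > 0L) {
    idx <- match(ranked$transcript_id, proteome$transcript_id)
    top <- seq_len(min(10L, nrow(ranked)))
    for (i in top) {
      mut <- apply_missense(proteome$sequence[idx[i]],
                            ranked$protein_change[i])
      ranked$slp[i] <- design_long_peptide(mut, ranked_position(ranked, i),
                                           config$slp_len)$sequence
    }
  }
  mtab <- with_stage("prioritization", manhattan_table(ranked))

  report_cols <- c("rank", "candidate_id", "gene", "transcript_id",
                   "protein_change", "allele", "length", "window_start",
                   "mut_offset", "mutant_peptide", "wildtype_peptide",
                   "consensus_ic50_nM", "affinity_score", "tier",
                   "expressed", "tpm", "slp")
  write_tsv(ranked[, intersect(report_cols, names(ranked))],
            file.path(config$out_dir, "ranked_report.tsv"))
  write_tsv(scored, file.path(config$out_dir, "candidates_all.tsv"))
  for (tn in names(config$tiers)) {
    write_tsv(tier_filter(ranked, config$tiers[[tn]]),
              file.path(config$out_dir, paste0("tier_", tn, ".tsv")))
  }
  write_tsv(mtab, file.path(config$out_dir, "manhattan.tsv"))
  write_tsv(rejects, file.path(config$out_dir, "rejects.tsv"))

  funnel <- c(variants = nrow(variants), windows = nrow(candidates),
              predicted = nrow(scored), tier_counts,
              expressed = nrow(kept))
  write_manifest(config, file.path(config$out_dir, "manifest.json"),
                 extra = list(funnel = as.list(funnel)))
  invisible(list(ranked = ranked, manhattan = mtab, rejects = rejects,
                 funnel = funnel))
}

ranked_position <- function(ranked, i) {
  parse_missense_notation(ranked$protein_change[i])$position
}

#' Run the population expression differential-analysis pipeline
#'
#' Computes TPM from counts and effective lengths, tests treated vs control
#' per day on log2(TPM+1), adjusts with Benjamini-Hochberg, and summarizes
#' temporal induction across days. Writes `de_day<d>.tsv`,
#' `volcano_day<d>.tsv`, `temporal.tsv` and `manifest.json` under
#' `out_dir`.
#'
#' @param counts genes x samples count matrix (or path to a TSV whose
#'   first column is `gene`).
#' @param effective_lengths named per-gene lengths (or path to
#'   a `gene`/`effective_length` TSV).
#' @param samples data.frame with `sample`, `group`, `day` (or TSV path).
#' @param out_dir output directory.
#' @param q_cutoff significance cutoff for the volcano flag.
#' @param var_equal pooled-variance t-test if `TRUE` (default Welch).
#' @return invisible list: per-day DE tables, volcano tables, temporal
#'   profile.
#' @export
run_de <- function(counts, effective_lengths, samples,
                   out_dir = tempfile("neoscreen_de_"),
                   q_cutoff = 0.05, var_equal = FALSE) {
  if (is.character(counts)) {
    df <- utils::read.delim(counts, check.names = FALSE)
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- df[[1]]
  }
  if (is.character(effective_lengths)) {
    df <- utils::read.delim(effective_lengths)
    effective_lengths <- stats::setNames(df$effective_length, df$gene)
  }
  if (is.character(samples)) samples <- utils::read.delim(samples)
  if (nrow(counts) == 0L) {
    validation_error("empty gene set: the count matrix has no rows")
  }
  if (!all(c("sample", "group", "day") %in% names(samples))) {
    validation_error("sample sheet needs columns sample, group, day")
  }
  if (!all(samples$sample %in% colnames(counts))) {
    validation_error("sample sheet lists samples absent from the count matrix")
  }
  tab <- table(samples$group, samples$day)
  if (any(tab < 2)) {
    validation_error("de_test requires >= 2 samples per group per day")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  el <- effective_lengths[rownames(counts)]
  tpm <- with_stage("transcriptome_de", compute_tpm(counts, el))

  days <- sort(unique(samples$day))
  de_by_day <- list(); volcano_by_day <- list()
  tpm_by_day <- list(); groups_by_day <- list()
  for (d in days) {
    sel <- samples$day == d
    sub <- tpm[, samples$sample[sel], drop = FALSE]
    grp <- samples$group[sel]
    res <- with_stage("transcriptome_de",
                      run_de_test(sub, grp, control = "control",
                                  var_equal = var_equal))
    vt <- volcano_table(res, q_cutoff)
    de_by_day[[as.character(d)]] <- res
    volcano_by_day[[as.character(d)]] <- vt
    tpm_by_day[[as.character(d)]] <- sub
    groups_by_day[[as.character(d)]] <- grp
    write_tsv(res, file.path(out_dir, paste0("de_day", d, ".tsv")))
    write_tsv(vt, file.path(out_dir, paste0("volcano_day", d, ".tsv")))
    log_stage("day ", d, ": ", sum(res$q_value < q_cutoff), " genes at q < ",
              q_cutoff)
  }
  temporal <- if (length(days) > 1L) {
    with_stage("transcriptome_de",
               temporal_profile(tpm_by_day, groups_by_day,
                                control = "control"))
  } else NULL
  if (!is.null(temporal)) write_tsv(temporal, file.path(out_dir, "temporal.tsv"))
  manifest <- list(tool = "neoscreen", version = pkg_version(),
                   inputs = list(n_genes = nrow(counts),
                                 n_samples = nrow(samples),
                                 days = as.list(days)),
                   q_cutoff = q_cutoff, var_equal = var_equal)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(de = de_by_day, volcano = volcano_by_day,
                 temporal = temporal))
}

#' Generate a full synthetic input bundle
#'
#' Delegates to [simulate_cohort()] and [simulate_expression()] and records
#' the seed in a manifest.
#'
#' @param config a `simulation_config`.
#' @param dir output directory.
#' @return invisible list of generated paths.
#' @export
run_simulate <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  cohort <- simulate_cohort(config, dir)
  simulate_expression(config$de_params, seed = config$seed,
                      dir = file.path(dir, "expression_study"))
  manifest <- list(tool = "neoscreen", version = pkg_version(),
                   seed = config$seed,
                   config = unclass_config(config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cohort)
}

unclass_config <- function(config) {
  x <- unclass(config)
  x$de_params <- unclass(x$de_params)
  x
}

pkg_version <- function() {
  as.character(utils::packageVersion("neoscreen"))
}

write_manifest <- function(config, path, extra = list()) {
  manifest <- c(list(tool = "neoscreen", version = pkg_version(),
                     seed = config$seed,
                     config = lapply(unclass(config), function(x) {
                       if (inherits(x, "mhc_allele")) unclass(x) else x
                     })),
                extra)
  manifest$config$alleles <- lapply(config$alleles, unclass)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
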