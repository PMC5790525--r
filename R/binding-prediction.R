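# IC50 predictions are clamped to this range (nM) so downstream affinity
# scores never divide by zero or overflow.
IC50_MIN <- 0.01
IC50_MAX <- 1e7

#' Construct a position-specific scoring matrix predictor
#'
#' The additive matrix model of the SMM family: predicted
#' `log10(IC50 nM) = intercept + sum_i weights[residue_i, i]` over the k
#' positions of the peptide, then exponentiated and clamped to
#' `[0.01, 1e7]` nM.
#'
#' @param allele allele name the matrix applies to.
#' @param weights 20 x k numeric matrix; rownames must be the 20 residues
#'   in alphabetical order.
#' @param intercept scalar log10 nM.
#' @param predictor_id identifier of the predictor.
#' @return object of class `scoring_matrix`.
#' @export
scoring_matrix <- function(allele, weights, intercept, predictor_id) {
  weights <- as.matrix(weights)
  if (nrow(weights) != 20L || !identical(rownames(weights), AA_ALPHABET)) {
    stop("weights must have 20 rows named by the residues in alphabetical order",
         call. = FALSE)
  }
  if (ncol(weights) < 1L || !all(is.finite(weights))) {
    stop("weights must be a finite 20 x k matrix with k >= 1", call. = FALSE)
  }
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.finite(intercept))
  structure(list(allele = allele, length = ncol(weights),
                 weights = weights, intercept = intercept,
                 predictor_id = predictor_id),
            class = "scoring_matrix")
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat("<scoring_matrix>", x$predictor_id, "for", x$allele,
      "k =", x$length, "intercept =", x$intercept, "\n")
  invisible(x)
}

#' Write a scoring matrix to the TSV interchange format
#'
#' Header lines `#allele=`, `#length=`, `#intercept=`, `#predictor=`,
#' followed by 20 rows (residues in fixed alphabetical order) of k numeric
#' columns.
#'
#' @param matrix a `scoring_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scoring_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#allele=", matrix$allele),
               paste0("#length=", matrix$length),
               paste0("#intercept=", format(matrix$intercept, digits = 17)),
               paste0("#predictor=", matrix$predictor_id)), con)
  body <- cbind(AA_ALPHABET,
                apply(matrix$weights, 2, format, digits = 17))
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load a scoring matrix from its TSV interchange format
#'
#' @param path matrix file written in the format of
#'   [write_scoring_matrix()].
#' @return a `scoring_matrix`.
#' @export
load_scoring_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    hit <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(hit) != 1L) {
      stop("matrix file missing header '#", key, "=': ", path, call. = FALSE)
    }
    sub(paste0("^#", key, "="), "", hit)
  }
  allele <- get("allele")
  k <- as.integer(get("length"))
  intercept <- as.numeric(get("intercept"))
  predictor <- get("predictor")
  if (is.na(k) || is.na(intercept)) {
    stop("non-numeric length or intercept header in ", path, call. = FALSE)
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  res <- vapply(parts, `[`, character(1), 1L)
  missing_res <- setdiff(AA_ALPHABET, res)
  if (length(missing_res) > 0L) {
    stop("matrix body missing residue row(s): ",
         paste(missing_res, collapse = ", "), call. = FALSE)
  }
  if (!identical(res, AA_ALPHABET)) {
    stop("matrix body rows must be the 20 residues in alphabetical order",
         call. = FALSE)
  }
  ncols <- lengths(parts) - 1L
  if (!all(ncols == k)) {
    stop("matrix body has ", max(ncols), " weight column(s); header declares k = ",
         k, call. = FALSE)
  }
  w <- t(vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[-1]))
    if (anyNA(v)) stop("non-numeric cell in matrix row '", p[1], "'",
                       call. = FALSE)
    v
  }, numeric(k)))
  rownames(w) <- res
  scoring_matrix(allele, w, intercept, predictor)
}

#' Predict IC50 for one peptide under a scoring matrix
#'
#' @param matrix a `scoring_matrix`.
#' @param peptide peptide whose length equals the matrix length.
#' @return predicted IC50 in nM, clamped to `[0.01, 1e7]`.
#' @examples
#' w <- matrix(0, 20, 8, dimnames = list(neoscreen:::AA_ALPHABET, NULL))
#' m <- scoring_matrix("H-2Kb", w, intercept = 2, predictor_id = "null")
#' predict_ic50(m, "SIINFEKL")  # 10^2 = 100 nM
#' @export
predict_ic50 <- function(matrix, peptide) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  res <- strsplit(peptide, "")[[1]]
  if (length(res) != matrix$length) {
    stop("peptide length ", length(res), " does not match matrix length ",
         matrix$length, call. = FALSE)
  }
  ridx <- match(res, AA_ALPHABET)
  if (anyNA(ridx)) {
    stop("invalid residue(s) in peptide: ",
         paste(unique(res[is.na(ridx)]), collapse = ", "), call. = FALSE)
  }
  log10_ic50 <- matrix$intercept +
    sum(matrix$weights[cbind(ridx, seq_along(ridx))])
  clamp_ic50(10^log10_ic50)
}

clamp_ic50 <- function(x) pmin(pmax(x, IC50_MIN), IC50_MAX)

# Vectorized scoring of many same-length peptides under one matrix.
predict_ic50_many <- function(matrix, peptides) {
  if (length(peptides) == 0L) return(numeric(0))
  k <- matrix$length
  chars <- strsplit(peptides, "")
  ridx <- matrix(match(unlist(chars), AA_ALPHABET), ncol = k, byrow = TRUE)
  if (anyNA(ridx)) stop("invalid residue in peptide set", call. = FALSE)
  contrib <- matrix$weights[cbind(as.vector(ridx),
                                  rep(seq_len(k), each = length(peptides)))]
  log10_ic50 <- matrix$intercept +
    rowSums(matrix(contrib, ncol = k))
  clamp_ic50(10^log10_ic50)
}

#' Combine per-predictor IC50s into a consensus
#'
#' The default consensus is the geometric mean (arithmetic mean of log10
#' IC50, exponentiated), matching the additive-in-log structure of the
#' matrix model; IC50s span orders of magnitude, so averaging on the nM
#' scale would be dominated by the weakest predictor. An arithmetic mean is
#' available for sensitivity checks.
#'
#' @param ic50s numeric vector of per-predictor IC50s (nM) for one
#'   candidate.
#' @param method `"geometric"` (default) or `"arithmetic"`.
#' @return consensus IC50 (nM), bounded by `min(ic50s)` and `max(ic50s)`.
#' @examples
#' consensus_ic50(c(10, 1000))  # 100
#' @export
consensus_ic50 <- function(ic50s, method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  if (length(ic50s) == 0L) {
    stop("consensus requires at least one prediction", call. = FALSE)
  }
  if (any(!is.finite(ic50s) | ic50s <= 0)) {
    stop("IC50 values must be positive and finite", call. = FALSE)
  }
  if (method == "geometric") 10^mean(log10(ic50s)) else mean(ic50s)
}

#' Load a directory of scoring matrices as a predictor registry
#'
#' @param dir directory containing `*.tsv` matrix files.
#' @return list of `scoring_matrix` objects.
#' @export
load_matrix_registry <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0L) {
    stop("no matrix files (*.tsv) in ", dir, call. = FALSE)
  }
  lapply(files, load_scoring_matrix)
}

#' Score enumerated candidates with a predictor registry
#'
#' Each candidate is scored by every matrix matching its (allele, length);
#' per-predictor IC50s are combined with [consensus_ic50()]. Candidates for
#' which no matrix exists are dropped with a warning.
#'
#' @param candidates data.frame from [enumerate_candidates()].
#' @param registry list of `scoring_matrix` objects.
#' @param method consensus method passed to [consensus_ic50()].
#' @return `candidates` with added columns `consensus_ic50_nM`,
#'   `n_predictors`, plus one `ic50_<predictor>` column per predictor.
#' @export
predict_candidates <- function(candidates, registry,
                               method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  if (nrow(candidates) == 0L) {
    candidates$consensus_ic50_nM <- numeric(0)
    candidates$n_predictors <- integer(0)
    return(candidates)
  }
  keys <- vapply(registry, function(m) paste(m$allele, m$length), character(1))
  ckey <- paste(candidates$allele, candidates$length)
  covered <- ckey %in% keys
  if (!all(covered)) {
    warning(sum(!covered), " candidate(s) without any matching matrix were dropped")
    candidates <- candidates[covered, , drop = FALSE]
    ckey <- ckey[covered]
  }
  preds <- sort(unique(vapply(registry, `[[`, character(1), "predictor_id")))
  per <- matrix(NA_real_, nrow(candidates), length(preds),
                dimnames = list(NULL, preds))
  for (m in registry) {
    sel <- ckey == paste(m$allele, m$length)
    if (!any(sel)) next
    per[sel, m$predictor_id] <- predict_ic50_many(m,
                                                  candidates$mutant_peptide[sel])
  }
  candidates$consensus_ic50_nM <- apply(per, 1, function(v) {
    consensus_ic50(v[!is.na(v)], method = method)
  })
  candidates$n_predictors <- rowSums(!is.na(per))
  colnames(per) <- paste0("ic50_", preds)
  cbind(candidates, as.data.frame(per))
}

#' Merge externally produced IC50 predictions
#'
#' Adapter for predictions computed outside the package (e.g. neural
#' predictors): a TSV with columns `candidate_id`, `predictor_id`,
#' `ic50_nM` is joined onto the candidate table as extra `ic50_<id>`
#' columns, and the consensus is recomputed over all available predictors.
#'
#' @param candidates scored candidate data.frame (from
#'   [predict_candidates()]).
#' @param path external prediction TSV.
#' @param method consensus method.
#' @return candidates with merged predictions and refreshed consensus.
#' @export
merge_external_predictions <- function(candidates, path,
                                       method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  ext <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("candidate_id", "predictor_id", "ic50_nM")
  if (!all(need %in% names(ext))) {
    stop("external prediction table needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  for (pid in unique(ext$predictor_id)) {
    col <- paste0("ic50_", pid)
    sub <- ext[ext$predictor_id == pid, ]
    candidates[[col]] <- clamp_ic50(
      sub$ic50_nM[match(candidates$candidate_id, sub$candidate_id)])
  }
  iccols <- grep("^ic50_", names(candidates), value = TRUE)
  candidates$consensus_ic50_nM <- apply(
    as.matrix(candidates[, iccols, drop = FALSE]), 1,
    function(v) consensus_ic50(v[!is.na(v)], method = method))
  candidates$n_predictors <- rowSums(!is.na(candidates[, iccols, drop = FALSE]))
  candidates
}
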