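#' Read a transcript expression table
#'
#' TSV with columns `transcript_id`, `tpm` and optionally `evidence`
#' (true/false; a binary confirmation such as targeted PCR + Sanger that
#' overrides the TPM threshold when present).
#'
#' @param path TSV file.
#' @return data.frame with `transcript_id`, `tpm`, `evidence` (logical,
#'   NA when absent).
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "tpm")
  if (!all(need %in% names(df))) {
    stop("expression table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$tpm <- as.numeric(df$tpm)
  if (any(is.na(df$tpm) | df$tpm < 0)) {
    stop("tpm must be non-negative and numeric", call. = FALSE)
  }
  df$evidence <- if ("evidence" %in% names(df)) {
    as.logical(toupper(as.character(df$evidence)))
  } else NA
  if (anyDuplicated(df$transcript_id)) {
    stop("duplicate transcript_id rows in expression table", call. = FALSE)
  }
  df[, c("transcript_id", "tpm", "evidence")]
}

#' Annotate and filter candidates by expression evidence
#'
#' Mirrors the screen that removes candidate neoantigens whose gene products
#' are not expressed. A candidate survives when binary evidence is `TRUE`,
#' or when evidence is absent and its transcript's TPM is at least
#' `min_tpm`; evidence `FALSE` always removes it. Rejected candidates are
#' returned alongside survivors rather than silently dropped.
#'
#' @param candidates candidate data.frame with `transcript_id`.
#' @param table expression data.frame from [read_expression_table()].
#' @param min_tpm TPM threshold (default 1.0).
#' @param missing how to treat transcripts absent from the table:
#'   `"strict"` (default) errors; `"lenient"` marks them unexpressed.
#' @return list with elements `survivors` and `rejects`; both carry an
#'   `expressed` logical column and together partition the input.
#' @export
filter_expressed <- function(candidates, table, min_tpm = 1.0,
                             missing = c("strict", "lenient")) {
  missing <- match.arg(missing)
  stopifnot(is.numeric(min_tpm), min_tpm >= 0)
  idx <- match(candidates$transcript_id, table$transcript_id)
  if (anyNA(idx) && missing == "strict") {
    stop("transcript(s) absent from expression table: ",
         paste(unique(candidates$transcript_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  tpm <- table$tpm[idx]
  evidence <- table$evidence[idx]
  expressed <- ifelse(!is.na(evidence), evidence,
                      !is.na(tpm) & tpm >= min_tpm)
  candidates$expressed <- expressed
  candidates$tpm <- tpm
  list(survivors = candidates[expressed, , drop = FALSE],
       rejects = candidates[!expressed, , drop = FALSE])
}
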