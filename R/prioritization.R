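#' Affinity score of an IC50
#'
#' The ranking quantity `(1 / IC50) * 100`: a 50 nM binder scores 2, a
#' 500 nM binder 0.2. Strictly decreasing in IC50, so ranking by descending
#' affinity score equals ranking by ascending IC50.
#'
#' @param ic50_nM positive IC50 in nM (vectorized).
#' @return affinity score(s).
#' @examples
#' affinity_score(c(25, 50, 500))  # 4, 2, 0.2
#' @export
affinity_score <- function(ic50_nM) {
  if (any(!is.finite(ic50_nM) | ic50_nM <= 0)) {
    stop("IC50 must be positive and finite", call. = FALSE)
  }
  (1 / ic50_nM) * 100
}

# Default nested IC50 cutoffs (nM): candidate tiers of increasing stringency.
DEFAULT_TIERS <- c(lt500 = 500, lt50 = 50, lt25 = 25)

#' Filter candidates at a strict IC50 cutoff
#'
#' Comparison is strict (`<`): a candidate at exactly the threshold is
#' excluded. Tiers at decreasing thresholds are nested subsets.
#'
#' @param candidates scored candidate data.frame with
#'   `consensus_ic50_nM`.
#' @param threshold_nM positive cutoff.
#' @return the surviving subset.
#' @export
tier_filter <- function(candidates, threshold_nM) {
  stopifnot(is.numeric(threshold_nM), threshold_nM > 0)
  candidates[candidates$consensus_ic50_nM < threshold_nM, , drop = FALSE]
}

#' Assign the nested binding tier of each candidate
#'
#' @param candidates scored candidate data.frame.
#' @param tiers named numeric vector of cutoffs in decreasing stringency
#'   order is not required; default `c(lt500 = 500, lt50 = 50, lt25 = 25)`.
#' @return `candidates` with a `tier` column (`"lt25"`, `"lt50"`,
#'   `"lt500"` or `"none"`): the most stringent tier passed.
#' @export
assign_tiers <- function(candidates, tiers = DEFAULT_TIERS) {
  stopifnot(all(tiers > 0))
  tiers <- sort(tiers)  # most stringent first
  tier <- rep("none", nrow(candidates))
  for (i in rev(seq_along(tiers))) {
    tier[candidates$consensus_ic50_nM < tiers[i]] <- names(tiers)[i]
  }
  candidates$tier <- tier
  candidates
}

#' Rank scored candidates
#'
#' Ascending consensus IC50; ties broken by gene symbol, then mutant
#' peptide, lexicographically, so reports are deterministic.
#'
#' @param candidates scored candidate data.frame.
#' @return the data.frame reordered, with `affinity_score` and `rank`
#'   columns (1 = strongest predicted binder).
#' @export
rank_candidates <- function(candidates) {
  if (nrow(candidates) == 0L) {
    candidates$affinity_score <- numeric(0)
    candidates$rank <- integer(0)
    return(candidates)
  }
  ord <- order(candidates$consensus_ic50_nM, candidates$gene,
               candidates$mutant_peptide, method = "radix")
  out <- candidates[ord, , drop = FALSE]
  out$affinity_score <- affinity_score(out$consensus_ic50_nM)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Build Manhattan-plot data for ranked candidates
#'
#' When every candidate carries genomic coordinates (`chrom`, `pos`), x is
#' the cumulative genomic coordinate (chromosomes laid end to end in
#' natural order); otherwise x falls back to the candidate index, with a
#' warning if coordinates were present for only some candidates.
#'
#' @param candidates ranked candidate data.frame (with
#'   `affinity_score`).
#' @return data.frame with `x`, `y` (= affinity score), `label`
#'   (`gene_change`), `chrom`, plus the candidate id.
#' @export
manhattan_table <- function(candidates) {
  if (nrow(candidates) == 0L) {
    return(data.frame(candidate_id = character(), x = numeric(),
                      y = numeric(), label = character(),
                      chrom = character(), stringsAsFactors = FALSE))
  }
  has_coord <- !is.na(candidates$chrom) & !is.na(candidates$pos)
  label <- paste(candidates$gene, candidates$protein_change, sep = "_")
  if (all(has_coord)) {
    chroms <- unique(candidates$chrom)
    chroms <- chroms[order_chromosomes(chroms)]
    # lay chromosomes end to end: offset of each = cumulative max pos before it
    span <- vapply(chroms, function(ch) {
      max(candidates$pos[candidates$chrom == ch]) }, numeric(1))
    offset <- stats::setNames(cumsum(c(0, span[-length(span)])), chroms)
    ord <- order(match(candidates$chrom, chroms), candidates$pos)
    cand <- candidates[ord, , drop = FALSE]
    x <- offset[cand$chrom] + cand$pos
    out <- data.frame(candidate_id = cand$candidate_id, x = unname(x),
                      y = cand$affinity_score, label = label[ord],
                      chrom = cand$chrom, stringsAsFactors = FALSE)
  } else {
    if (any(has_coord)) {
      warning("mixed presence of genomic coordinates; ",
              "falling back to index positions")
    }
    out <- data.frame(candidate_id = candidates$candidate_id,
                      x = seq_len(nrow(candidates)),
                      y = candidates$affinity_score,
                      label = label,
                      chrom = NA_character_, stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Natural chromosome order: numeric chromosomes ascending, then X, Y, others.
order_chromosomes <- function(chroms) {
  stripped <- sub("^chr", "", chroms)
  num <- suppressWarnings(as.numeric(stripped))
  special <- match(stripped, c("X", "Y", "M", "MT"))
  key <- ifelse(!is.na(num), num,
                ifelse(!is.na(special), 1000 + special, 2000))
  order(key, stripped)
}

#' Plot a Manhattan table of affinity scores
#'
#' @param mtab data.frame from [manhattan_table()].
#' @param label_top label the top `label_top` candidates by score.
#' @return a ggplot object.
#' @export
plot_manhattan <- function(mtab, label_top = 5L) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires ggplot2", call. = FALSE)
  }
  top <- mtab[order(-mtab$y), , drop = FALSE]
  top <- utils::head(top, label_top)
  ggplot2::ggplot(mtab, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point(ggplot2::aes(colour = chrom),
                        show.legend = FALSE) +
    ggplot2::geom_text(data = top,
                       ggplot2::aes(label = label),
                       vjust = -0.5, size = 3) +
    ggplot2::labs(x = "cumulative genomic position",
                  y = "affinity score (1/IC50 x 100)") +
    ggplot2::theme_minimal()
}
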