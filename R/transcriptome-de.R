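#' Transcripts-per-million from counts and effective lengths
#'
#' The RSEM-style definition: per-gene rate `c_g / l_g`, normalized so the
#' sample sums to one million, `tpm_g = (c_g/l_g) / sum_j(c_j/l_j) * 1e6`.
#'
#' @param counts non-negative count vector or genes x samples matrix.
#' @param effective_lengths positive per-gene effective lengths.
#' @return TPM in the same shape as `counts`; every column sums to 1e6.
#' @examples
#' compute_tpm(c(10, 10), c(1, 2))  # 666666.7, 333333.3
#' @export
compute_tpm <- function(counts, effective_lengths) {
  if (is.matrix(counts) || is.data.frame(counts)) {
    counts <- as.matrix(counts)
    stopifnot(nrow(counts) == length(effective_lengths))
    out <- apply(counts, 2, compute_tpm, effective_lengths = effective_lengths)
    dimnames(out) <- dimnames(counts)
    return(out)
  }
  stopifnot(length(counts) == length(effective_lengths))
  if (any(effective_lengths <= 0)) {
    stop("effective lengths must be positive", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  rate <- counts / effective_lengths
  total <- sum(rate)
  if (total == 0) {
    stop("all-zero sample: cannot compute TPM", call. = FALSE)
  }
  rate / total * 1e6
}

#' Log-transform TPM for differential testing
#'
#' `log2(TPM + 1)`; the pseudocount of 1 keeps zero-TPM genes finite while
#' leaving well-expressed genes essentially on the log2 scale.
#'
#' @param tpm TPM vector or matrix.
#' @return log2(TPM + 1).
#' @export
log_tpm <- function(tpm) log2(tpm + 1)

#' Per-gene two-sample t-tests on log expression
#'
#' Tests each gene's log-transformed expression between two groups with a
#' two-sample t-test (Welch by default; pooled-variance optional). The fold
#' change is `mean(B) - mean(A)` on the log2 scale. Genes constant and
#' equal in both groups get `t = 0, p = 1` by convention (rather than being
#' dropped), so the multiple-testing family size stays equal to the number
#' of genes.
#'
#' @param log_expr_a genes x samples matrix for group A (e.g. control).
#' @param log_expr_b genes x samples matrix for group B (e.g. treated);
#'   same genes, >= 2 samples per group.
#' @param var_equal pooled-variance t-test when `TRUE` (default `FALSE`,
#'   i.e. Welch).
#' @return data.frame with `gene`, `log2fc`, `t_stat`, `p_value`.
#' @export
de_test <- function(log_expr_a, log_expr_b, var_equal = FALSE) {
  log_expr_a <- as.matrix(log_expr_a)
  log_expr_b <- as.matrix(log_expr_b)
  if (nrow(log_expr_a) != nrow(log_expr_b)) {
    stop("group matrices must have the same genes", call. = FALSE)
  }
  if (ncol(log_expr_a) < 2L || ncol(log_expr_b) < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  genes <- rownames(log_expr_a)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(log_expr_a)))
  n <- nrow(log_expr_a)
  t_stat <- numeric(n)
  p_value <- numeric(n)
  log2fc <- rowMeans(log_expr_b) - rowMeans(log_expr_a)
  for (g in seq_len(n)) {
    a <- log_expr_a[g, ]
    b <- log_expr_b[g, ]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) {
        t_stat[g] <- 0; p_value[g] <- 1
      } else {
        t_stat[g] <- sign(mean(b) - mean(a)) * Inf; p_value[g] <- 0
      }
      next
    }
    tt <- stats::t.test(b, a, var.equal = var_equal)
    t_stat[g] <- unname(tt$statistic)
    p_value[g] <- tt$p.value
  }
  data.frame(gene = genes, log2fc = unname(log2fc), t_stat = t_stat,
             p_value = p_value, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: monotone, capped at 1, returned
#' in input order.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return adjusted q-values, same order as input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values) | p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Differential expression between two groups of a TPM matrix
#'
#' Convenience wrapper: log-transforms, tests each gene and adjusts.
#'
#' @param tpm genes x samples TPM matrix.
#' @param groups character/factor of length `ncol(tpm)` with exactly two
#'   levels; the *second* sorted level is treated as the treated group
#'   (fold changes are treated minus control).
#' @param control name of the control level (default the first sorted
#'   level).
#' @param var_equal see [de_test()].
#' @return data.frame with `gene`, `log2fc`, `t_stat`, `p_value`,
#'   `q_value`.
#' @export
run_de_test <- function(tpm, groups, control = NULL, var_equal = FALSE) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2L) {
    stop("exactly two groups required, got: ", paste(lev, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(control)) control <- lev[1]
  treated <- setdiff(lev, control)
  lt <- log_tpm(tpm)
  res <- de_test(lt[, groups == control, drop = FALSE],
                 lt[, groups == treated, drop = FALSE],
                 var_equal = var_equal)
  res$q_value <- bh_adjust(res$p_value)
  res
}

#' Temporal induction profile across study days
#'
#' For each gene and day, the mean log2(TPM+1) per group and the
#' treated-minus-control difference; flags whether the difference increases
#' monotonically across days and which day maximizes it.
#'
#' @param tpm_by_day named list of TPM matrices, one per day (names are the
#'   day labels, e.g. `"11"`, `"14"`, `"17"`).
#' @param groups_by_day named list of group vectors aligned with the
#'   columns of each matrix.
#' @param genes optional subset of genes; default all genes of the first
#'   day.
#' @param control control group label (default sorted-first level).
#' @param expected_days days the study design calls for; a day missing from
#'   the input produces a partial table with a warning.
#' @return data.frame with one row per gene: `diff_day<d>` columns,
#'   `is_monotone_increasing`, `argmax_day`.
#' @export
temporal_profile <- function(tpm_by_day, groups_by_day, genes = NULL,
                             control = NULL,
                             expected_days = names(tpm_by_day)) {
  days <- names(tpm_by_day)
  if (is.null(days) || !identical(sort(days), sort(names(groups_by_day)))) {
    stop("tpm_by_day and groups_by_day must share day names", call. = FALSE)
  }
  absent <- setdiff(as.character(expected_days), days)
  if (length(absent) > 0L) {
    warning("missing day(s) ", paste(absent, collapse = ", "),
            "; returning a partial temporal profile")
  }
  days <- days[order(as.numeric(days))]
  if (is.null(genes)) genes <- rownames(tpm_by_day[[days[1]]])
  diffs <- sapply(days, function(d) {
    tpm <- tpm_by_day[[d]]
    gr <- as.character(groups_by_day[[d]])
    lev <- sort(unique(gr))
    if (length(lev) != 2L) {
      stop("day ", d, " does not have exactly two groups", call. = FALSE)
    }
    ctl <- if (is.null(control)) lev[1] else control
    trt <- setdiff(lev, ctl)
    lt <- log_tpm(tpm[genes, , drop = FALSE])
    rowMeans(lt[, gr == trt, drop = FALSE]) -
      rowMeans(lt[, gr == ctl, drop = FALSE])
  })
  diffs <- matrix(diffs, nrow = length(genes),
                  dimnames = list(genes, paste0("diff_day", days)))
  mono <- apply(diffs, 1, function(v) all(diff(v) > 0))
  argmax <- days[apply(diffs, 1, which.max)]
  out <- data.frame(gene = genes, diffs,
                    is_monotone_increasing = unname(mono),
                    argmax_day = unname(argmax),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Volcano-plot data from adjusted DE results
#'
#' x is the log2 fold change, y is `-log10(q)` with q floored at machine
#' epsilon, and genes at `q < 0.05` (strict) are flagged significant.
#'
#' @param de_results data.frame from [run_de_test()] (needs `gene`,
#'   `log2fc`, `q_value`).
#' @param q_cutoff significance cutoff (default 0.05).
#' @return data.frame with `gene`, `x`, `y`, `significant`.
#' @export
volcano_table <- function(de_results, q_cutoff = 0.05) {
  q <- pmax(de_results$q_value, .Machine$double.eps)
  data.frame(gene = de_results$gene,
             x = de_results$log2fc,
             y = -log10(q),
             significant = de_results$q_value < q_cutoff,
             stringsAsFactors = FALSE)
}

#' Plot a volcano of differential expression results
#'
#' @param vtab data.frame from [volcano_table()].
#' @param label_top number of most significant genes to label.
#' @return a ggplot object.
#' @export
plot_volcano <- function(vtab, label_top = 10L) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires ggplot2", call. = FALSE)
  }
  top <- utils::head(vtab[order(-vtab$y), , drop = FALSE], label_top)
  ggplot2::ggplot(vtab, ggplot2::aes(x = x, y = y, colour = significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_text(data = top, ggplot2::aes(label = gene),
                       vjust = -0.5, size = 3, colour = "black") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 q") +
    ggplot2::theme_minimal()
}
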