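#' Define an MHC class I allele and its peptide lengths
#'
#' MHC class I grooves accommodate short peptides; each allele has
#' characteristic length preferences. Lengths must come from {8, 9, 10, 11}.
#'
#' @param name allele name, e.g. `"H-2Kb"`.
#' @param peptide_lengths integer vector of window lengths.
#' @return object of class `mhc_allele`.
#' @export
mhc_allele <- function(name, peptide_lengths) {
  stopifnot(is.character(name), length(name) == 1L, nchar(name) > 0L)
  peptide_lengths <- sort(unique(as.integer(peptide_lengths)))
  if (length(peptide_lengths) == 0L ||
      !all(peptide_lengths %in% 8:11)) {
    stop("peptide_lengths must be a non-empty subset of {8, 9, 10, 11}",
         call. = FALSE)
  }
  structure(list(name = name, peptide_lengths = peptide_lengths),
            class = "mhc_allele")
}

#' Default murine allele set
#'
#' The two class I alleles of C57BL/6 mice with canonical groove length
#' preferences: H-2Kb binds 8- and 9-mers, H-2Db 9- and 10-mers.
#'
#' @return named list of `mhc_allele` objects.
#' @export
default_alleles <- function() {
  list(`H-2Kb` = mhc_allele("H-2Kb", c(8L, 9L)),
       `H-2Db` = mhc_allele("H-2Db", c(9L, 10L)))
}

#' Enumerate mutant peptide windows overlapping an altered residue
#'
#' For each window length of the allele, every k-mer of the mutant protein
#' whose span contains the mutated position is returned, paired with the
#' corresponding wild-type k-mer. Windows are unique by
#' (allele, mutant peptide, window start).
#'
#' @param mut_protein mutant protein sequence.
#' @param wt_protein wild-type protein sequence (same length).
#' @param position 1-based position of the altered residue.
#' @param allele an `mhc_allele`.
#' @return data.frame with columns `allele`, `length`, `window_start`,
#'   `mut_offset`, `mutant_peptide`, `wildtype_peptide`. Zero rows when the
#'   protein is shorter than every window length.
#' @export
enumerate_mutant_windows <- function(mut_protein, wt_protein, position,
                                     allele) {
  stopifnot(inherits(allele, "mhc_allele"))
  n <- nchar(mut_protein)
  if (nchar(wt_protein) != n) {
    stop("mutant and wild-type proteins differ in length", call. = FALSE)
  }
  if (position < 1L || position > n) {
    stop("position ", position, " out of range for protein of length ", n,
         call. = FALSE)
  }
  if (substr(mut_protein, position, position) ==
      substr(wt_protein, position, position)) {
    stop("mutant and wild-type proteins agree at the stated position",
         call. = FALSE)
  }
  rows <- lapply(allele$peptide_lengths, function(k) {
    if (n < k) return(NULL)
    # spans [s, s+k-1] containing `position`, clipped to the protein
    s_min <- max(1L, position - k + 1L)
    s_max <- min(position, n - k + 1L)
    if (s_min > s_max) return(NULL)
    starts <- s_min:s_max
    data.frame(
      allele = allele$name,
      length = k,
      window_start = starts,
      mut_offset = position - starts + 1L,
      mutant_peptide = substring(mut_protein, starts, starts + k - 1L),
      wildtype_peptide = substring(wt_protein, starts, starts + k - 1L),
      stringsAsFactors = FALSE
    )
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    return(data.frame(allele = character(), length = integer(),
                      window_start = integer(), mut_offset = integer(),
                      mutant_peptide = character(),
                      wildtype_peptide = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Design a synthetic long peptide around a mutant residue
#'
#' Synthetic long peptide (SLP) vaccines embed the minimal epitope in a
#' longer window (28 residues by default) that requires processing in vivo.
#' The mutant residue is placed at offset `ceiling(total_len / 2)`, shifted
#' only when a protein terminus forces truncation.
#'
#' @param mut_protein mutant protein sequence.
#' @param position 1-based position of the altered residue.
#' @param total_len target peptide length (default 28).
#' @return list of class `long_peptide` with `sequence`, `total_len`,
#'   `mut_offset`, `window_start`.
#' @export
design_long_peptide <- function(mut_protein, position, total_len = 28L) {
  n <- nchar(mut_protein)
  total_len <- as.integer(total_len)
  stopifnot(total_len >= 1L)
  if (position < 1L || position > n) {
    stop("position ", position, " out of range for protein of length ", n,
         call. = FALSE)
  }
  centre <- as.integer(ceiling(total_len / 2))
  start <- position - centre + 1L
  start <- min(start, n - total_len + 1L)
  start <- max(start, 1L)
  end <- min(n, start + total_len - 1L)
  seq <- substr(mut_protein, start, end)
  structure(list(sequence = seq,
                 total_len = total_len,
                 mut_offset = position - start + 1L,
                 window_start = start),
            class = "long_peptide")
}

#' @export
print.long_peptide <- function(x, ...) {
  cat("<long_peptide>", x$sequence, "\n  length", nchar(x$sequence),
      "mutant residue at offset", x$mut_offset, "\n")
  invisible(x)
}

#' Wild-type counterpart of a candidate peptide
#'
#' Returns the paired wild-type peptide and asserts the construction
#' invariant that mutant and wild type differ at exactly the mutated offset
#' (Hamming distance 1) — the wild-type pair is what control tetramers use.
#'
#' @param candidate one row of a candidate data.frame (as produced by
#'   [enumerate_mutant_windows()]).
#' @return the wild-type peptide string.
#' @export
wildtype_pair <- function(candidate) {
  mut <- candidate$mutant_peptide
  wt <- candidate$wildtype_peptide
  stopifnot(length(mut) == 1L, length(wt) == 1L)
  d <- hamming1(mut, wt)
  if (length(d) != 1L || d != candidate$mut_offset) {
    stop("invariant violation: mutant and wild-type peptides must differ ",
         "exactly at the mutated offset", call. = FALSE)
  }
  wt
}

hamming1 <- function(a, b) {
  which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Enumerate candidates for a full variant table
#'
#' Applies each missense change to its protein, enumerates windows for every
#' allele, and attaches stable candidate ids
#' (`gene_change_allele_windowstart`).
#'
#' @param variants data.frame from [read_variant_table()].
#' @param proteome data.frame from [read_proteome_fasta()].
#' @param alleles list of `mhc_allele` (default [default_alleles()]).
#' @return data.frame of peptide candidates with provenance columns.
#' @export
enumerate_candidates <- function(variants, proteome,
                                 alleles = default_alleles()) {
  validate_variants(variants, proteome)
  idx <- match(variants$transcript_id, proteome$transcript_id)
  out <- vector("list", nrow(variants) * length(alleles))
  k <- 0L
  for (i in seq_len(nrow(variants))) {
    wt <- proteome$sequence[idx[i]]
    change <- structure(list(ref_aa = variants$ref_aa[i],
                             position = variants$position[i],
                             alt_aa = variants$alt_aa[i]),
                        class = "missense_change")
    mut <- apply_missense(wt, change)
    for (al in alleles) {
      w <- enumerate_mutant_windows(mut, wt, variants$position[i], al)
      if (nrow(w) == 0L) next
      k <- k + 1L
      out[[k]] <- cbind(
        data.frame(gene = variants$gene[i],
                   transcript_id = variants$transcript_id[i],
                   protein_change = variants$protein_change[i],
                   chrom = variants$chrom[i], pos = variants$pos[i],
                   stringsAsFactors = FALSE),
        w
      )
    }
  }
  cand <- if (k > 0L) do.call(rbind, out[seq_len(k)]) else NULL
  if (!is.null(cand)) rownames(cand) <- NULL
  if (is.null(cand)) {
    return(data.frame(gene = character(), transcript_id = character(),
                      protein_change = character(), chrom = character(),
                      pos = integer(), allele = character(),
                      length = integer(), window_start = integer(),
                      mut_offset = integer(), mutant_peptide = character(),
                      wildtype_peptide = character(),
                      candidate_id = character(), stringsAsFactors = FALSE))
  }
  cand$candidate_id <- paste(cand$gene, cand$protein_change, cand$allele,
                             paste0("k", cand$length), cand$window_start,
                             sep = "_")
  cand
}

#' Export candidate peptides as FASTA for external predictors
#'
#' One record per candidate; the record id is the stable candidate id.
#'
#' @param candidates candidate data.frame.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_candidate_fasta <- function(candidates, path) {
  set <- Biostrings::AAStringSet(candidates$mutant_peptide)
  names(set) <- candidates$candidate_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
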