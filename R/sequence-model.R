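#' @keywords internal
"_PACKAGE"

# The 20 proteinogenic residues, alphabetical. This fixed order is also the
# row order of scoring-matrix files.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Check that a string is a valid amino-acid sequence
#'
#' Valid sequences are non-empty and use only the 20-letter alphabet.
#' A single trailing `*` (stop) is tolerated and stripped.
#'
#' @param x character scalar.
#' @return The validated (possibly `*`-stripped) sequence.
#' @export
validate_protein_sequence <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x <- sub("\\*$", "", x)
  if (nchar(x) == 0L) {
    stop("protein sequence is empty", call. = FALSE)
  }
  bad <- setdiff(strsplit(x, "")[[1]], AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("invalid residue(s) in protein sequence: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  x
}

#' Parse protein-level missense notation
#'
#' Parses community notation such as `"P315L"` (reference residue, 1-based
#' protein position, alternate residue) into its components.
#'
#' @param token character scalar like `"P315L"`.
#' @return A list of class `missense_change` with elements `ref_aa`,
#'   `position`, `alt_aa`.
#' @examples
#' parse_missense_notation("P315L")
#' @export
parse_missense_notation <- function(token) {
  stopifnot(is.character(token), length(token) == 1L, !is.na(token))
  m <- regmatches(token, regexec("^([A-Z])([0-9]+)([A-Z])$", token))[[1]]
  if (length(m) != 4L) {
    stop("malformed missense notation: '", token,
         "' (expected <refAA><position><altAA>, e.g. P315L)", call. = FALSE)
  }
  ref <- m[2]
  pos <- as.integer(m[3])
  alt <- m[4]
  if (!(ref %in% AA_ALPHABET) || !(alt %in% AA_ALPHABET)) {
    stop("malformed missense notation: '", token,
         "' contains a non-residue letter", call. = FALSE)
  }
  if (pos < 1L) {
    stop("malformed missense notation: '", token,
         "' has position < 1", call. = FALSE)
  }
  if (ref == alt) {
    stop("not a missense change: '", token,
         "' has identical reference and alternate residues", call. = FALSE)
  }
  structure(list(ref_aa = ref, position = pos, alt_aa = alt),
            class = "missense_change")
}

#' Format a missense change back to notation
#'
#' Inverse of [parse_missense_notation()]: `format_missense(parse_missense_notation(x)) == x`.
#'
#' @param change a `missense_change`.
#' @return character scalar, e.g. `"P315L"`.
#' @export
format_missense <- function(change) {
  stopifnot(inherits(change, "missense_change"))
  paste0(change$ref_aa, change$position, change$alt_aa)
}

#' @export
print.missense_change <- function(x, ...) {
  cat("<missense_change>", format_missense(x), "\n")
  invisible(x)
}

#' Translate a coding sequence with the standard genetic code
#'
#' The CDS must be ACGT only and a whole number of codons. A terminal stop
#' codon is dropped; an internal stop is an error (truncating variants are
#' outside the missense scope of this package).
#'
#' @param cds character scalar DNA sequence.
#' @return Amino-acid string.
#' @examples
#' translate_cds("ATGGCT")  # "MA"
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L, !is.na(cds))
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds)) {
    stop("CDS contains non-ACGT characters", call. = FALSE)
  }
  if (nchar(cds) == 0L || nchar(cds) %% 3L != 0L) {
    stop("CDS length (", nchar(cds), ") is not a positive multiple of 3",
         call. = FALSE)
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
  n <- nchar(aa)
  if (substr(aa, n, n) == "*") {
    aa <- substr(aa, 1L, n - 1L)
  }
  if (grepl("\\*", aa)) {
    stop("internal stop codon in CDS", call. = FALSE)
  }
  if (nchar(aa) == 0L) {
    stop("CDS translates to an empty protein", call. = FALSE)
  }
  aa
}

#' Apply a missense change to a protein sequence
#'
#' Validates that the reference residue matches the protein at the stated
#' 1-based position, then substitutes the alternate residue.
#'
#' @param protein amino-acid string.
#' @param change a `missense_change` (or notation string).
#' @return The mutant protein sequence (same length, differs at exactly one
#'   position).
#' @examples
#' apply_missense("MAPK", "A2V")  # "MVPK"
#' @export
apply_missense <- function(protein, change) {
  if (is.character(change)) change <- parse_missense_notation(change)
  stopifnot(inherits(change, "missense_change"))
  protein <- validate_protein_sequence(protein)
  n <- nchar(protein)
  pos <- change$position
  if (pos > n) {
    stop("position ", pos, " is out of range for a protein of length ", n,
         call. = FALSE)
  }
  obs <- substr(protein, pos, pos)
  if (obs != change$ref_aa) {
    stop("reference residue mismatch at position ", pos, ": expected ",
         change$ref_aa, ", observed ", obs, call. = FALSE)
  }
  substr(protein, pos, pos) <- change$alt_aa
  protein
}

#' Read a proteome FASTA
#'
#' Record ids are transcript ids; the description may carry the gene symbol
#' as `gene=SYMBOL` (otherwise the gene defaults to the transcript id).
#'
#' @param path FASTA file.
#' @return A data.frame with columns `transcript_id`, `gene`, `sequence`.
#' @export
read_proteome_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no records in FASTA: ", path, call. = FALSE)
  full <- names(aa)
  id <- sub("\\s.*$", "", full)
  gene <- ifelse(grepl("gene=", full),
                 sub(".*gene=([^ ]+).*", "\\1", full), id)
  seqs <- vapply(as.character(aa), validate_protein_sequence, character(1),
                 USE.NAMES = FALSE)
  if (anyDuplicated(id)) {
    stop("duplicate transcript ids in FASTA: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  data.frame(transcript_id = id, gene = gene, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Read a CDS FASTA
#'
#' Each record must be a valid coding sequence (ACGT, multiple of 3,
#' no internal stop after translation).
#'
#' @param path FASTA file.
#' @return data.frame with `transcript_id`, `gene`, `cds`, `protein`
#'   (the translation, terminal stop removed).
#' @export
read_cds_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  if (length(dna) == 0L) stop("no records in FASTA: ", path, call. = FALSE)
  full <- names(dna)
  id <- sub("\\s.*$", "", full)
  gene <- ifelse(grepl("gene=", full),
                 sub(".*gene=([^ ]+).*", "\\1", full), id)
  cds <- as.character(dna)
  prot <- vapply(seq_along(cds), function(i) {
    tryCatch(translate_cds(cds[i]),
             error = function(e) stop("record '", id[i], "': ",
                                      conditionMessage(e), call. = FALSE))
  }, character(1))
  data.frame(transcript_id = id, gene = gene, cds = unname(cds),
             protein = prot, stringsAsFactors = FALSE)
}

#' Read a somatic missense variant table
#'
#' Tab-separated with header columns `gene`, `transcript_id`,
#' `protein_change` (e.g. `P315L`); optional `chrom`, `pos` (1-based) and
#' `expressed` (`true`/`false`/`NA`). Rows that fail parsing are reported
#' with their line numbers; duplicate (transcript, change) rows are an error.
#'
#' @param path TSV file.
#' @param proteome optional data.frame from [read_proteome_fasta()]; when
#'   given, every variant's reference residue is validated against it.
#' @return data.frame of variants with parsed `ref_aa`, `position`, `alt_aa`.
#' @export
read_variant_table <- function(path, proteome = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  required <- c("gene", "transcript_id", "protein_change")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    return(empty_variant_frame())
  }
  parsed <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(parse_missense_notation(df$protein_change[i]),
             error = function(e) {
               stop("line ", i + 1L, ": ", conditionMessage(e), call. = FALSE)
             })
  })
  key <- paste(df$transcript_id, df$protein_change)
  if (anyDuplicated(key)) {
    stop("duplicate (transcript_id, protein_change) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  out <- data.frame(
    gene = df$gene,
    transcript_id = df$transcript_id,
    protein_change = df$protein_change,
    ref_aa = vapply(parsed, `[[`, character(1), "ref_aa"),
    position = vapply(parsed, `[[`, integer(1), "position"),
    alt_aa = vapply(parsed, `[[`, character(1), "alt_aa"),
    chrom = if ("chrom" %in% names(df)) df$chrom else NA_character_,
    pos = if ("pos" %in% names(df)) as.integer(df$pos) else NA_integer_,
    expressed = if ("expressed" %in% names(df)) {
      as.logical(toupper(df$expressed))
    } else NA,
    stringsAsFactors = FALSE
  )
  if (!is.null(proteome)) validate_variants(out, proteome)
  out
}

empty_variant_frame <- function() {
  data.frame(gene = character(), transcript_id = character(),
             protein_change = character(), ref_aa = character(),
             position = integer(), alt_aa = character(),
             chrom = character(), pos = integer(), expressed = logical(),
             stringsAsFactors = FALSE)
}

#' Validate variants against a proteome
#'
#' Checks that every variant's transcript exists and that the reference
#' residue matches the protein at the stated position.
#'
#' @param variants data.frame from [read_variant_table()].
#' @param proteome data.frame from [read_proteome_fasta()].
#' @return `variants`, invisibly, on success; otherwise an error.
#' @export
validate_variants <- function(variants, proteome) {
  idx <- match(variants$transcript_id, proteome$transcript_id)
  if (anyNA(idx)) {
    stop("transcript(s) not in proteome: ",
         paste(unique(variants$transcript_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(variants))) {
    prot <- proteome$sequence[idx[i]]
    pos <- variants$position[i]
    if (pos > nchar(prot)) {
      stop("variant ", variants$protein_change[i], " on ",
           variants$transcript_id[i], ": position out of range", call. = FALSE)
    }
    obs <- substr(prot, pos, pos)
    if (obs != variants$ref_aa[i]) {
      stop("variant ", variants$protein_change[i], " on ",
           variants$transcript_id[i], ": expected ", variants$ref_aa[i],
           " at position ", pos, ", observed ", obs, call. = FALSE)
    }
  }
  invisible(variants)
}

#' Read somatic missense variants from a minimal VCF
#'
#' Accepts VCF v4.2 with SNV records only. Each record must carry the custom
#' INFO keys `TRANSCRIPT` and `PCHANGE` (protein-level notation such as
#' `P315L`); all other annotation is ignored. The gene symbol is taken from
#' the optional INFO key `GENE`, defaulting to the transcript id.
#'
#' @param path VCF file.
#' @return data.frame in the same shape as [read_variant_table()].
#' @export
read_variant_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF requires the VariantAnnotation package", call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(vcf)
  if (!all(c("TRANSCRIPT", "PCHANGE") %in% names(info))) {
    stop("VCF must define INFO keys TRANSCRIPT and PCHANGE", call. = FALSE)
  }
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  alt <- vapply(seq_along(altl), function(i) {
    as.character(altl[[i]][1]) }, character(1))
  snv <- nchar(ref) == 1L & nchar(alt) == 1L
  if (!all(snv)) {
    stop("non-SNV record(s) in VCF; only single-nucleotide variants are supported",
         call. = FALSE)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  tx <- unlist_info(info$TRANSCRIPT)
  pch <- unlist_info(info$PCHANGE)
  gene <- if ("GENE" %in% names(info)) unlist_info(info$GENE) else tx
  parsed <- lapply(pch, parse_missense_notation)
  data.frame(
    gene = gene, transcript_id = tx, protein_change = pch,
    ref_aa = vapply(parsed, `[[`, character(1), "ref_aa"),
    position = vapply(parsed, `[[`, integer(1), "position"),
    alt_aa = vapply(parsed, `[[`, character(1), "alt_aa"),
    chrom = chrom, pos = pos, expressed = NA,
    stringsAsFactors = FALSE
  )
}

unlist_info <- function(x) {
  if (is.list(x) || methods::is(x, "List")) {
    vapply(x, function(v) as.character(v)[1], character(1))
  } else {
    as.character(x)
  }
}

#' Classify a CDS-level substitution
#'
#' A single-base change in a coding sequence is translated and classified as
#' `missense`, `synonymous` or `nonsense`. Only missense changes proceed
#' into the pipeline; the other categories are rejected by the caller with
#' the returned label.
#'
#' @param cds reference coding sequence.
#' @param cds_pos 1-based position in the CDS.
#' @param alt_base alternate base (A/C/G/T).
#' @return list with `category` and, for missense, the `change`
#'   (`missense_change`).
#' @export
classify_cds_substitution <- function(cds, cds_pos, alt_base) {
  stopifnot(cds_pos >= 1L, cds_pos <= nchar(cds),
            alt_base %in% c("A", "C", "G", "T"))
  ref_prot <- translate_cds(cds)
  mut <- cds
  substr(mut, cds_pos, cds_pos) <- alt_base
  codon_idx <- (cds_pos - 1L) %/% 3L + 1L
  mut_codon <- substr(mut, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
  mut_aa <- as.character(Biostrings::translate(Biostrings::DNAString(mut_codon),
                                               no.init.codon = TRUE))
  ref_aa <- substr(ref_prot, codon_idx, codon_idx)
  if (mut_aa == "*") {
    return(list(category = "nonsense"))
  }
  if (mut_aa == ref_aa) {
    return(list(category = "synonymous"))
  }
  list(category = "missense",
       change = structure(list(ref_aa = ref_aa, position = codon_idx,
                               alt_aa = mut_aa), class = "missense_change"))
}
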