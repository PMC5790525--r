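test_that("missense notation parses and round-trips", {
  ch <- parse_missense_notation("P315L")
  expect_equal(ch$ref_aa, "P")
  expect_equal(ch$position, 315L)
  expect_equal(ch$alt_aa, "L")
  expect_equal(parse_missense_notation("A1V")$position, 1L)

  expect_error(parse_missense_notation("P315"), "malformed")
  expect_error(parse_missense_notation("P0L"), "position")
  expect_error(parse_missense_notation("X5Z"), "non-residue")
  expect_error(parse_missense_notation("P315P"), "identical")

  # property: parse -> format identity over random valid triplets
  set.seed(11)
  for (i in 1:100) {
    ref <- sample(AA20, 1)
    alt <- sample(setdiff(AA20, ref), 1)
    tok <- paste0(ref, sample(1:5000, 1), alt)
    expect_identical(format_missense(parse_missense_notation(tok)), tok)
  }
})

test_that("CDS translation follows the standard code and stop rules", {
  expect_equal(translate_cds("ATGGCT"), "MA")
  expect_equal(translate_cds("ATGTAA"), "M")
  expect_error(translate_cds("ATGTAAGCT"), "internal stop")
  expect_error(translate_cds("ATGGC"), "multiple of 3")
  expect_error(translate_cds("ATGGCN"), "non-ACGT")

  # independent codon-table oracle on random codon strings
  codon_table <- local({
    bases <- c("T", "C", "A", "G")
    g <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                     stringsAsFactors = FALSE)
    codons <- paste0(g$b1, g$b2, g$b3)
    aas <- strsplit(paste0(
      "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
      "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
    setNames(aas, codons)
  })
  set.seed(12)
  tries <- 0
  while (tries < 100) {
    ncod <- sample(1:30, 1)
    cds <- paste(sample(names(codon_table), ncod, replace = TRUE),
                 collapse = "")
    aa_ref <- codon_table[substring(cds, seq(1, nchar(cds), 3),
                                    seq(3, nchar(cds), 3))]
    internal_stop <- any(aa_ref[-length(aa_ref)] == "*")
    terminal_stop <- aa_ref[length(aa_ref)] == "*"
    if (internal_stop || (terminal_stop && ncod == 1)) next
    expected <- paste(aa_ref[aa_ref != "*"], collapse = "")
    expect_identical(translate_cds(cds), expected)
    tries <- tries + 1
  }
})

test_that("missense application substitutes exactly one residue", {
  expect_equal(apply_missense("MAPK", "A2V"), "MVPK")
  expect_equal(apply_missense("MAPK", "K4R"), "MAPR")
  expect_error(apply_missense("MAPK", "G2V"), "expected G, observed A")
  expect_error(apply_missense("MAPK", "A9V"), "out of range")

  # property: applying the reverse change restores the original
  set.seed(13)
  for (i in 1:50) {
    prot <- random_aa(sample(10:60, 1))
    pos <- sample(nchar(prot), 1)
    ref <- substr(prot, pos, pos)
    alt <- sample(setdiff(AA20, ref), 1)
    mut <- apply_missense(prot, paste0(ref, pos, alt))
    expect_equal(sum(strsplit(mut, "")[[1]] != strsplit(prot, "")[[1]]), 1)
    expect_identical(apply_missense(mut, paste0(alt, pos, ref)), prot)
  }
})

test_that("variant tables are read, validated and rejected with context", {
  good <- write_variant_tsv(data.frame(
    gene = c("Icam1", "H2q4", "Pkd1"),
    transcript_id = c("T1", "T2", "T3"),
    protein_change = c("P315L", "A7V", "K9R")))
  v <- read_variant_table(good)
  expect_equal(nrow(v), 3)
  expect_equal(v$position, c(315L, 7L, 9L))

  empty <- write_variant_tsv(data.frame(gene = character(),
                                        transcript_id = character(),
                                        protein_change = character()))
  expect_equal(nrow(read_variant_table(empty)), 0)

  bad_tok <- write_variant_tsv(data.frame(
    gene = "g", transcript_id = "t", protein_change = "P315"))
  expect_error(read_variant_table(bad_tok), "line 2")

  dup <- write_variant_tsv(data.frame(
    gene = c("g", "g"), transcript_id = c("t", "t"),
    protein_change = c("A1V", "A1V")))
  expect_error(read_variant_table(dup), "duplicate")

  no_col <- write_variant_tsv(data.frame(gene = "g", transcript_id = "t"))
  expect_error(read_variant_table(no_col), "protein_change")
})

test_that("variants are validated against the proteome", {
  prot <- tiny_proteome()
  v <- tiny_variants()
  expect_silent(validate_variants(v, prot))
  v$protein_change[1] <- "W7L"
  v$ref_aa <- c("W", "D"); v$position <- c(7L, 6L); v$alt_aa <- c("L", "E")
  expect_error(validate_variants(v, prot), "expected W")
})

test_that("proteome and CDS FASTA readers recover generated records", {
  dir <- file.path(tempdir(), "fasta_rt")
  simulate_cohort(simulation_config(seed = 21, n_genes = 10, n_variants = 3),
                  dir)
  prot <- read_proteome_fasta(file.path(dir, "proteome.fasta"))
  cds <- read_cds_fasta(file.path(dir, "cds.fasta"))
  expect_equal(nrow(prot), 10)
  expect_identical(prot$transcript_id, cds$transcript_id)
  # CDS translation must reproduce the proteome exactly
  expect_identical(cds$protein, prot$sequence)
  expect_true(all(grepl("^GENE", prot$gene)))
})

test_that("CDS-level substitutions are classified by consequence", {
  cds <- "ATGGCTAAA"  # MAK
  mis <- classify_cds_substitution(cds, 4, "A")  # GCT -> ACT: A2T
  expect_equal(mis$category, "missense")
  expect_equal(format_missense(mis$change), "A2T")
  syn <- classify_cds_substitution(cds, 6, "C")  # GCT -> GCC, still A
  expect_equal(syn$category, "synonymous")
  non <- classify_cds_substitution("ATGTACAAA", 6, "A")  # TAC -> TAA
  expect_equal(non$category, "nonsense")
})

test_that("minimal VCF records map to missense variants", {
  skip_if_not_installed("VariantAnnotation")
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=TRANSCRIPT,Number=1,Type=String,Description="Transcript id">',
    '##INFO=<ID=PCHANGE,Number=1,Type=String,Description="Protein change">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    paste("chr9", "120", ".", "C", "T", ".", "PASS",
          "TRANSCRIPT=TX1;PCHANGE=P315L;GENE=Icam1", sep = "\t"),
    paste("chr2", "55", ".", "G", "A", ".", "PASS",
          "TRANSCRIPT=TX2;PCHANGE=D6E;GENE=H2q4", sep = "\t")), vcf)
  v <- read_variant_vcf(vcf)
  expect_equal(nrow(v), 2)
  expect_equal(v$gene, c("Icam1", "H2q4"))
  expect_equal(v$position, c(315L, 6L))
  expect_equal(v$chrom, c("chr9", "chr2"))
})
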