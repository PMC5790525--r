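test_that("allele definitions constrain peptide lengths", {
  a <- mhc_allele("H-2Kb", c(9, 8))
  expect_equal(a$peptide_lengths, c(8L, 9L))
  expect_error(mhc_allele("X", integer(0)), "non-empty subset")
  expect_error(mhc_allele("X", c(7, 9)), "subset")
  d <- default_alleles()
  expect_equal(d[["H-2Kb"]]$peptide_lengths, c(8L, 9L))
  expect_equal(d[["H-2Db"]]$peptide_lengths, c(9L, 10L))
})

test_that("window enumeration matches the brute-force span oracle", {
  # deterministic example: length 20, position 10, k = 8 -> 8 windows
  set.seed(30)
  wt20 <- random_aa(20)
  mut <- apply_missense(wt20, paste0(substr(wt20, 10, 10), 10,
                                     sample(setdiff(AA20,
                                                    substr(wt20, 10, 10)), 1)))
  w <- enumerate_mutant_windows(mut, wt20, 10, mhc_allele("A", 8))
  expect_equal(nrow(w), length(oracle_windows(mut, 10, 8)))
  expect_equal(nrow(w), 8)
  expect_error(enumerate_mutant_windows(mut, wt20, 25, mhc_allele("A", 8)),
               "out of range")

  # randomized property: counts and offsets equal the oracle
  set.seed(31)
  for (i in 1:60) {
    n <- sample(6:40, 1)
    wtp <- random_aa(n)
    pos <- sample(n, 1)
    ref <- substr(wtp, pos, pos)
    mutp <- apply_missense(wtp, paste0(ref, pos,
                                       sample(setdiff(AA20, ref), 1)))
    k <- sample(8:11, 1)
    w <- enumerate_mutant_windows(mutp, wtp, pos, mhc_allele("A", k))
    starts <- oracle_windows(mutp, pos, k)
    expect_equal(w$window_start, starts)
    if (nrow(w) > 0) {
      expect_true(all(w$mut_offset == pos - w$window_start + 1L))
      expect_true(all(substr(w$mutant_peptide, w$mut_offset,
                             w$mut_offset) == substr(mutp, pos, pos)))
      # every mutant window is a substring of the mutant protein
      expect_true(all(vapply(w$mutant_peptide, grepl, logical(1), x = mutp,
                             fixed = TRUE)))
    }
  }
})

test_that("boundary windows behave at termini and short proteins", {
  set.seed(32)
  wtp <- random_aa(20)
  mutp <- apply_missense(wtp, paste0(substr(wtp, 1, 1), 1,
                                     sample(setdiff(AA20,
                                                    substr(wtp, 1, 1)), 1)))
  w <- enumerate_mutant_windows(mutp, wtp, 1, mhc_allele("A", 8))
  expect_equal(w$window_start, 1L)  # only one span contains residue 1

  short_wt <- random_aa(6)
  short_mut <- apply_missense(short_wt, paste0(substr(short_wt, 3, 3), 3,
                                               setdiff(AA20,
                                                       substr(short_wt, 3, 3))[1]))
  expect_equal(nrow(enumerate_mutant_windows(short_mut, short_wt, 3,
                                             mhc_allele("A", 8))), 0)
})

test_that("mutant windows are absent from repeat-free wild-type proteins", {
  dir <- file.path(tempdir(), "enum_rf")
  simulate_cohort(simulation_config(seed = 33, n_genes = 20, n_variants = 8),
                  dir)
  prot <- read_proteome_fasta(file.path(dir, "proteome.fasta"))
  variants <- read_variant_table(file.path(dir, "variants.tsv"), prot)
  cand <- enumerate_candidates(variants, prot)
  expect_gt(nrow(cand), 0)
  wt_by_tx <- setNames(prot$sequence, prot$transcript_id)
  hits <- mapply(function(pep, tx) grepl(pep, wt_by_tx[[tx]], fixed = TRUE),
                 cand$mutant_peptide, cand$transcript_id)
  expect_false(any(hits))
  # dedup invariant: unique by (allele, peptide, start) within a variant
  key <- paste(cand$candidate_id)
  expect_false(anyDuplicated(key) > 0)
})

test_that("long peptide design centres the mutant residue", {
  set.seed(34)
  prot <- random_aa(200)
  ref <- substr(prot, 100, 100)
  mut <- apply_missense(prot, paste0(ref, 100, sample(setdiff(AA20, ref), 1)))
  lp <- design_long_peptide(mut, 100, 28)
  expect_equal(nchar(lp$sequence), 28)
  expect_equal(lp$mut_offset, 14)
  expect_equal(substr(lp$sequence, 14, 14), substr(mut, 100, 100))

  lp3 <- design_long_peptide(mut, 3, 28)
  expect_equal(lp3$window_start, 1)
  expect_equal(lp3$mut_offset, 3)
  expect_equal(nchar(lp3$sequence), 28)

  lp1 <- design_long_peptide(mut, 50, 1)
  expect_equal(lp1$sequence, substr(mut, 50, 50))

  expect_error(design_long_peptide(mut, 500), "out of range")

  # property: output always contains the mutant residue; interior windows
  # have exactly the requested length
  for (i in 1:40) {
    n <- sample(30:120, 1)
    p <- random_aa(n)
    pos <- sample(n, 1)
    r <- substr(p, pos, pos)
    m <- apply_missense(p, paste0(r, pos, sample(setdiff(AA20, r), 1)))
    lp <- design_long_peptide(m, pos, 28)
    expect_equal(substr(lp$sequence, lp$mut_offset, lp$mut_offset),
                 substr(m, pos, pos))
    expect_equal(nchar(lp$sequence), min(28, n))
  }
})

test_that("wild-type pairs differ from mutants at exactly the altered site", {
  set.seed(35)
  wtp <- random_aa(30)
  mutp <- apply_missense(wtp, paste0(substr(wtp, 15, 15), 15,
                                     sample(setdiff(AA20,
                                                    substr(wtp, 15, 15)), 1)))
  w <- enumerate_mutant_windows(mutp, wtp, 15, mhc_allele("A", 9))
  for (i in seq_len(nrow(w))) {
    wt <- wildtype_pair(w[i, ])
    expect_equal(sum(strsplit(wt, "")[[1]] !=
                       strsplit(w$mutant_peptide[i], "")[[1]]), 1)
  }
  broken <- w[1, ]
  broken$wildtype_peptide <- broken$mutant_peptide
  expect_error(wildtype_pair(broken), "invariant")
})

test_that("candidate FASTA export round-trips ids and sequences", {
  prot <- tiny_proteome()
  cand <- enumerate_candidates(tiny_variants(), prot)
  path <- tempfile(fileext = ".fasta")
  write_candidate_fasta(cand, path)
  back <- Biostrings::readAAStringSet(path)
  expect_equal(length(back), nrow(cand))
  expect_identical(names(back), cand$candidate_id)
  expect_identical(unname(as.character(back)), cand$mutant_peptide)
})
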