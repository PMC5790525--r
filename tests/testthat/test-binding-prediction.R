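test_that("scoring matrices round-trip through the TSV format", {
  set.seed(41)
  m <- make_matrix(k = 8, predictor_id = "rt")
  path <- tempfile(fileext = ".tsv")
  write_scoring_matrix(m, path)
  back <- load_scoring_matrix(path)
  expect_equal(back$allele, m$allele)
  expect_equal(back$length, 8L)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$predictor_id, "rt")
  expect_equal(unname(back$weights), unname(m$weights), tolerance = 1e-12)
})

test_that("malformed matrix files are rejected with the offending detail", {
  set.seed(42)
  m <- make_matrix(k = 8)
  path <- tempfile(fileext = ".tsv")
  write_scoring_matrix(m, path)
  lines <- readLines(path)

  no_w <- lines[!startsWith(lines, "W\t")]
  f1 <- tempfile(); writeLines(no_w, f1)
  expect_error(load_scoring_matrix(f1), "W")

  wrong_k <- sub("^#length=8$", "#length=9", lines)
  f2 <- tempfile(); writeLines(wrong_k, f2)
  expect_error(load_scoring_matrix(f2), "header declares")

  bad_cell <- sub("^(A\t)[^\t]+", "\\1oops", lines)
  f3 <- tempfile(); writeLines(bad_cell, f3)
  expect_error(load_scoring_matrix(f3), "non-numeric")
})

test_that("matrix scoring is the additive log10 model", {
  zero <- matrix(0, 20, 8, dimnames = list(AA20, NULL))
  m0 <- scoring_matrix("H-2Kb", zero, intercept = 2, predictor_id = "z")
  expect_equal(predict_ic50(m0, "SIINFEKL"), 100)

  one <- zero
  one["S", 1] <- 1
  m1 <- scoring_matrix("H-2Kb", one, intercept = 0, predictor_id = "o")
  expect_equal(predict_ic50(m1, "SIINFEKL"), 10)

  expect_error(predict_ic50(m0, "SIINFEK"), "length")
  expect_error(predict_ic50(m0, "SIINFEKB"), "invalid residue")

  # oracle equivalence on random matrices and peptides
  set.seed(43)
  for (i in 1:100) {
    k <- sample(8:11, 1)
    m <- make_matrix(k = k, mean = runif(1, -0.5, 0.5), sd = 0.4)
    pep <- random_aa(k)
    expect_equal(predict_ic50(m, pep),
                 oracle_pssm(m$weights, m$intercept, pep),
                 tolerance = 1e-12)
  }
})

test_that("scoring is monotone in any weight the peptide uses", {
  set.seed(44)
  m <- make_matrix(k = 9)
  pep <- random_aa(9)
  base <- predict_ic50(m, pep)
  for (i in c(1, 5, 9)) {
    m2 <- m
    m2$weights[substr(pep, i, i), i] <- m2$weights[substr(pep, i, i), i] + 0.3
    expect_gt(predict_ic50(m2, pep), base)
  }
})

test_that("predictions are clamped to the documented IC50 range", {
  big <- matrix(5, 20, 8, dimnames = list(AA20, NULL))
  m <- scoring_matrix("A", big, intercept = 0, predictor_id = "hi")
  expect_equal(predict_ic50(m, random_aa(8)), 1e7)
  m$weights[] <- -5
  expect_equal(predict_ic50(m, random_aa(8)), 0.01)
})

test_that("consensus IC50 is the geometric mean with the stated bounds", {
  expect_equal(consensus_ic50(42), 42)
  expect_equal(consensus_ic50(c(10, 1000)), 100)
  expect_error(consensus_ic50(numeric(0)), "at least one")
  expect_error(consensus_ic50(c(10, -1)), "positive")

  set.seed(45)
  for (i in 1:100) {
    ic <- 10^runif(5, -2, 7)
    expect_equal(consensus_ic50(ic), 10^mean(log10(ic)), tolerance = 1e-12)
    # permutation invariance and min/max bounds
    expect_equal(consensus_ic50(sample(ic)), consensus_ic50(ic))
    expect_gte(consensus_ic50(ic), min(ic))
    expect_lte(consensus_ic50(ic), max(ic))
    expect_equal(consensus_ic50(ic, method = "arithmetic"), mean(ic))
  }
})

test_that("candidate scoring uses every matching predictor", {
  set.seed(46)
  prot <- tiny_proteome()
  cand <- enumerate_candidates(tiny_variants(), prot)
  registry <- list()
  for (k in 8:10) {
    for (al in c("H-2Kb", "H-2Db")) {
      for (p in c("p1", "p2")) {
        registry <- c(registry, list(make_matrix(k = k, allele = al,
                                                 predictor_id = p)))
      }
    }
  }
  scored <- predict_candidates(cand, registry)
  expect_equal(nrow(scored), nrow(cand))
  expect_true(all(scored$n_predictors == 2))
  recomputed <- 10^rowMeans(log10(cbind(scored$ic50_p1, scored$ic50_p2)))
  expect_equal(scored$consensus_ic50_nM, recomputed, tolerance = 1e-10)
})

test_that("external predictions merge into the consensus", {
  set.seed(47)
  prot <- tiny_proteome()
  cand <- enumerate_candidates(tiny_variants(), prot)
  registry <- lapply(c("H-2Kb", "H-2Db"), function(al) {
    lapply(8:10, function(k) make_matrix(k = k, allele = al,
                                         predictor_id = "p1"))
  })
  registry <- unlist(registry, recursive = FALSE)
  scored <- predict_candidates(cand, registry)
  ext <- data.frame(candidate_id = scored$candidate_id,
                    predictor_id = "nn",
                    ic50_nM = rep(100, nrow(scored)))
  extf <- tempfile(fileext = ".tsv")
  write.table(ext, extf, sep = "\t", quote = FALSE, row.names = FALSE)
  merged <- merge_external_predictions(scored, extf)
  expect_true(all(merged$n_predictors == 2))
  expect_equal(merged$consensus_ic50_nM,
               10^((log10(merged$ic50_p1) + 2) / 2), tolerance = 1e-10)
})
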