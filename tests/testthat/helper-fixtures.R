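# Shared fixture builders; everything is generated in code at test time.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

random_weight_matrix <- function(k, mean = 0.3, sd = 0.2) {
  matrix(rnorm(20 * k, mean, sd), 20, k, dimnames = list(AA20, NULL))
}

make_matrix <- function(k = 9, allele = "H-2Kb", intercept = 2,
                        predictor_id = "p1", mean = 0.3, sd = 0.2) {
  scoring_matrix(allele, random_weight_matrix(k, mean, sd), intercept,
                 predictor_id)
}

write_variant_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A tiny deterministic proteome + matched variants for fast pipeline tests.
tiny_proteome <- function() {
  data.frame(
    transcript_id = c("TX1", "TX2", "TX3"),
    gene = c("Icam1", "H2q4", "Chst15"),
    sequence = c("MDQILETQRTLTVYNFSALVLTLSQLEVSKPAGHMW",
                 "MAVLKDEQRSTWYNFHIPCGMDEQRSTVVK",
                 "MSTVYKLHEQDANCGWPRFILMSTVYKLHE"),
    stringsAsFactors = FALSE)
}

tiny_variants <- function() {
  read_variant_table(write_variant_tsv(data.frame(
    gene = c("Icam1", "H2q4"),
    transcript_id = c("TX1", "TX2"),
    protein_change = c("T7L", "D6E"),
    stringsAsFactors = FALSE)))
}

# Brute-force window oracle: every substring of the right length whose span
# contains the mutated position.
oracle_windows <- function(protein, position, k) {
  n <- nchar(protein)
  if (n < k) return(integer(0))
  starts <- seq_len(n - k + 1L)
  starts[starts <= position & position <= starts + k - 1L]
}

# Independent BH step-up: q_(i) = min over j >= i of p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Naive per-position scoring loop, independent of the vectorized code path.
oracle_pssm <- function(weights, intercept, peptide) {
  res <- strsplit(peptide, "")[[1]]
  s <- intercept
  for (i in seq_along(res)) s <- s + weights[res[i], i]
  min(max(10^s, 0.01), 1e7)
}
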