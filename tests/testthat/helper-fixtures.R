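# shared fixtures: random tables and a brute-force IVW oracle kept
# deliberately independent of ivw_pool's vectorized arithmetic

random_table <- function(M, seed, n = 10000, label = "fixture") {
  set.seed(seed)
  pairs <- rbind(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
  pick <- sample.int(nrow(pairs), M, replace = TRUE)
  sumstats_table(data.frame(
    marker_id = sprintf("rs%06d", seq_len(M)),
    effect_allele = pairs[pick, 1], other_allele = pairs[pick, 2],
    beta = rnorm(M, 0, 0.05),
    se = runif(M, 0.01, 0.2),
    pvalue = runif(M), n = n,
    stringsAsFactors = FALSE), source_label = label)
}

# two-pass loop summation; never shares code with ivw_pool
oracle_pool <- function(beta, se) {
  W <- 0
  for (s in se) W <- W + 1 / (s * s)
  num <- 0
  for (i in seq_along(beta)) num <- num + beta[i] / (se[i] * se[i])
  list(B = num / W, SE = sqrt(1 / W))
}

write_fixture_file <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
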