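# Small in-code fixtures shared across test files.

# deterministic 10-gene diploid transcriptome with ~200 bp SNP spacing
small_diploid <- function(n_genes = 10, gene_length = 2000,
                          spacing = 200, seed = 42) {
  ref <- random_reference(n_genes, gene_length, gene_length, seed = seed)
  sequences <- stats::setNames(ref$sequence, ref$gene_id)
  dip <- build_diploid_transcriptome(sequences, spacing, seed = seed)
  dip$reference <- ref
  dip
}

# mixed maternal/zygotic expression program over n genes (last n_zyg zygotic)
small_program <- function(gene_ids, n_zyg = 2) {
  n <- length(gene_ids)
  expression_program(
    gene_ids,
    mode = c(rep("maternal_only", n - n_zyg), rep("zygotic_only", n_zyg)),
    maternal_copies = c(rep(100, n - n_zyg), rep(0, n_zyg)),
    zygotic_rate = c(rep(0, n - n_zyg), rep(1, n_zyg)))
}

write_bed12 <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}

write_snp_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# brute-force binomial upper tail: independent oracle for binomial_excess_p,
# multiplying out the pmf term by term (no pbinom/dbinom on purpose)
brute_tail <- function(P, N, p0) {
  if (P <= 0) return(1)
  k <- 0:N
  # pmf via cumulative products of the binomial coefficient recurrence
  logpmf <- lchoose(N, k) + k * log(p0) + (N - k) * log1p(-p0)
  sum(exp(logpmf[k >= P]))
}
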