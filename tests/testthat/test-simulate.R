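test_that("SNP spacing in the diploid transcriptome matches the target mean", {
  ref <- random_reference(1, 100000, 100000, seed = 7)
  dip <- build_diploid_transcriptome(
    stats::setNames(ref$sequence, ref$gene_id), 200, seed = 7)
  expect_gt(nrow(dip$snps), 100)
  observed <- mean(diff(dip$snps$pos))
  expect_lt(abs(observed - 200) / 200, 0.10)
  # paternal differs from maternal exactly at the SNPs
  m <- strsplit(dip$maternal[[1]], "")[[1]]
  p <- strsplit(dip$paternal[[1]], "")[[1]]
  expect_equal(which(m != p) - 1L, dip$snps$pos)
  expect_equal(p[dip$snps$pos + 1L], dip$snps$paternal_allele)
})

test_that("infinite spacing yields identical haplotypes and no SNPs", {
  dip <- build_diploid_transcriptome(c(g = strrep("ACGT", 100)), Inf,
                                     seed = 1)
  expect_identical(dip$maternal, dip$paternal)
  expect_equal(nrow(dip$snps), 0)
  expect_error(build_diploid_transcriptome(c(g = "ACGT"), 0), "> 0")
})

test_that("the diploid transcriptome is deterministic under a fixed seed", {
  ref <- c(a = strrep("ACGTTGCA", 500), b = strrep("GGATCCAT", 400))
  d1 <- build_diploid_transcriptome(ref, 150, seed = 11)
  d2 <- build_diploid_transcriptome(ref, 150, seed = 11)
  expect_identical(d1, d2)
  d3 <- build_diploid_transcriptome(ref, 150, seed = 12)
  expect_false(identical(d1$snps, d3$snps))
})

test_that("nuclei double perfectly: 2^(cycle-1)", {
  expect_equal(expected_nuclei(1), 1L)
  expect_equal(expected_nuclei(3), 4L)   # cycle-3 embryos carry 4 nuclei
  expect_equal(expected_nuclei(6), 32L)  # last cycle at or below 32 nuclei
  expect_equal(expected_nuclei(1:8), as.integer(2^(0:7)))
  expect_error(expected_nuclei(0), ">= 1")
  expect_error(expected_nuclei(2.5), ">= 1")
})

test_that("expression programs respect the maternal/zygotic dichotomy", {
  prog <- expression_program(
    c("mat", "zyg", "mix"),
    mode = c("maternal_only", "zygotic_only", "mixed"),
    maternal_copies = c(80, 0, 25),
    zygotic_rate = c(0, 1, 1),
    onset_cycle = c(1, 1, 7))
  for (st in pipeline_stages()) {
    cp <- simulate_expression(prog, st)
    # maternal-only genes never place copies on the paternal haplotype
    expect_equal(cp$paternal_copies[cp$gene_id == "mat"], 0)
    # zygotic-only genes are exactly symmetric in expectation
    expect_equal(cp$maternal_copies[cp$gene_id == "zyg"],
                 cp$paternal_copies[cp$gene_id == "zyg"])
  }
  # a mixed gene with deposit and late onset: maternal-only early, biallelic
  # later (the zen-like pattern)
  early <- simulate_expression(prog, "c3_6")
  expect_gt(early$maternal_copies[early$gene_id == "mix"], 0)
  expect_equal(early$paternal_copies[early$gene_id == "mix"], 0)
  late <- simulate_expression(prog, "c8")
  expect_gt(late$paternal_copies[late$gene_id == "mix"], 0)

  # zygotic output scales with the pooled nuclei counts
  zyg8 <- simulate_expression(prog, "c8")
  expect_equal(zyg8$maternal_copies[zyg8$gene_id == "zyg"],
               expected_nuclei(8) / 2)

  expect_error(simulate_expression(prog, "c9"), "unknown stage")
  expect_error(expression_program("g", mode = "maternal_only",
                                  zygotic_rate = 1), "zygotic_rate")
})

test_that("error-free reads are exact substrings of their haplotype", {
  dip <- small_diploid()
  cp <- simulate_expression(small_program(names(dip$maternal)), "c8")
  reads <- simulate_reads(dip$maternal, dip$paternal, cp, n_reads = 2000,
                          error_rate = 0, seed = 3)
  hap_seq <- ifelse(reads$haplotype_of_origin == "maternal",
                    dip$maternal[reads$gene_id],
                    dip$paternal[reads$gene_id])
  expect_equal(substring(hap_seq, reads$start + 1,
                         reads$start + reads$length),
               reads$sequence)
})

test_that("a single-SNP base flips to the other parent's allele at rate e/3", {
  # one transcript, one SNP, reads covering it: analytic flip rate e/3
  e <- 0.02
  base <- strrep("A", 36)
  ref <- c(g = paste0(base, "C", base))  # SNP will be planted at pos 36
  dip <- list(maternal = ref,
              paternal = c(g = paste0(base, "G", base)),
              snps = tibble::tibble(chrom = "g", pos = 36L,
                                    maternal_allele = "C",
                                    paternal_allele = "G"))
  cp <- tibble::tibble(gene_id = "g", maternal_copies = 1,
                       paternal_copies = 0)
  n <- 6e4
  reads <- simulate_reads(dip$maternal, dip$paternal, cp, n_reads = n,
                          read_length = 36, error_rate = e, seed = 9)
  covers <- reads$start <= 36 & reads$start + 36 > 36
  snp_base <- substr(reads$sequence[covers], 37 - reads$start[covers],
                     37 - reads$start[covers])
  flip <- mean(snp_base == "G")
  expected <- e / 3
  se <- sqrt(expected * (1 - expected) / sum(covers))
  expect_lt(abs(flip - expected), 3 * se)
})

test_that("zero copies yield zero reads (deficiency null)", {
  dip <- small_diploid(n_genes = 3)
  cp <- tibble::tibble(gene_id = names(dip$maternal),
                       maternal_copies = c(100, 0, 100),
                       paternal_copies = 0)
  reads <- simulate_reads(dip$maternal, dip$paternal, cp, n_reads = 5000,
                          seed = 1)
  deleted <- names(dip$maternal)[2]
  expect_equal(sum(reads$gene_id == deleted), 0)
  # and an all-zero program yields an error-free empty set or errors on
  # impossible read length
  cp0 <- tibble::tibble(gene_id = names(dip$maternal),
                        maternal_copies = 0, paternal_copies = 0)
  expect_equal(nrow(simulate_reads(dip$maternal, dip$paternal, cp0,
                                   n_reads = 10, seed = 1)), 0)
  expect_error(simulate_reads(c(g = "ACGTACGT"), c(g = "ACGTACGT"),
                              tibble::tibble(gene_id = "g",
                                             maternal_copies = 1,
                                             paternal_copies = 0),
                              n_reads = 5, read_length = 50, seed = 1),
               "read_length")
})

test_that("identical seeds give byte-identical FASTQ output", {
  dip <- small_diploid(n_genes = 4)
  cp <- simulate_expression(small_program(names(dip$maternal), n_zyg = 1),
                            "c7")
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  r1 <- simulate_reads(dip$maternal, dip$paternal, cp, 500, seed = 5,
                       stage = "c7")
  r2 <- simulate_reads(dip$maternal, dip$paternal, cp, 500, seed = 5,
                       stage = "c7")
  expect_identical(r1, r2)
  write_reads_fastq(r1, f1)
  write_reads_fastq(r2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("Mendelian crosses segregate as expected", {
  map <- c("en/en" = "mutant", "+/en" = "normal", "+/+" = "normal")
  # heterozygous x heterozygous: a quarter of progeny are mutant
  x <- simulate_cross(c("en", "+"), c("en", "+"), map, 4e4, seed = 2)
  se <- sqrt(0.25 * 0.75 / 4e4)
  expect_lt(abs(x$mutant_fraction - 0.25), 3 * se)
  # wildtype x wildtype: no mutants
  y <- simulate_cross(c("+", "+"), c("+", "+"), c("+/+" = "normal"),
                      1000, seed = 2)
  expect_equal(y$mutant_fraction, 0)
  # deficiency over a point allele: Df/en transheterozygotes are the
  # mutant quarter (oracle: enumerate the four equally likely gametes)
  map2 <- c("Df/en" = "mutant", "+/Df" = "normal", "+/en" = "normal",
            "+/+" = "normal")
  z <- simulate_cross(c("Df", "+"), c("en", "+"), map2, 4e4, seed = 3)
  expect_lt(abs(z$mutant_fraction - 0.25), 3 * se)
  # reachable genotype missing from the map is an error
  expect_error(simulate_cross(c("en", "+"), c("en", "+"),
                              map[-1], 10, seed = 1),
               "en/en")
})
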