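snp_tbl <- function(pos, m = "A", p = "G", gene = "g1") {
  tibble::tibble(chrom = gene, pos = as.integer(pos),
                 maternal_allele = m, paternal_allele = p)
}

test_that("read-SNP overlap respects half-open interval semantics", {
  snps <- snp_tbl(c(135L, 136L))
  # SNP at transcript position 135 sits at offset 35 of a [100, 136) read
  ov <- find_overlapping_snps("g1", 100, 36, snps)
  expect_equal(ov$pos, 135L)
  expect_equal(ov$read_offset, 35L)
  # a SNP at 136 is excluded by the half-open end
  expect_false(136L %in% ov$pos)
  # past-the-end reads are rejected when lengths are known
  expect_error(
    find_overlapping_snps("g1", 100, 36, snps,
                          transcript_lengths = c(g1 = 130)),
    "past the transcript end")
})

test_that("intronic SNPs are excluded by projection onto the transcript", {
  bed <- write_bed12(
    "2R\t1000\t2336\tg1\t0\t+\t1000\t2336\t0\t2\t100,236\t0,1100")
  gm <- read_gene_models(bed)
  snps <- tibble::tibble(chrom = "2R",
                         pos = c(1050L, 1500L, 2150L),  # exon1, intron, exon2
                         maternal_allele = "A", paternal_allele = "G")
  proj <- project_snps(snps, gm)
  expect_equal(nrow(proj), 2)
  expect_equal(proj$pos, c(50L, 150L))  # 1050-1000; 100 + (2150-2100)
  expect_equal(proj$chrom, c("g1", "g1"))
})

test_that("minus-strand projection reflects position and complements alleles", {
  bed <- write_bed12("2R\t100\t200\tgm\t0\t-\t100\t200\t0\t1\t100\t0")
  gm <- read_gene_models(bed)
  snps <- tibble::tibble(chrom = "2R", pos = 110L,
                         maternal_allele = "A", paternal_allele = "G")
  proj <- project_snps(snps, gm)
  expect_equal(proj$pos, 89L)  # 100 - 1 - 10
  expect_equal(proj$maternal_allele, "T")
  expect_equal(proj$paternal_allele, "C")
})

test_that("per-site votes follow the maternal/paternal/conflict rule", {
  mk_read <- function(seq, start = 0L) {
    tibble::tibble(read_id = "r", gene_id = "g1", start = start,
                   length = nchar(seq), stage = "c8", sequence = seq)
  }
  one <- snp_tbl(2L)  # maternal A, paternal G
  # base matches the maternal allele -> maternal call
  a <- assign_reads(mk_read("CCACC"), one)
  expect_equal(a$call, "maternal")
  expect_equal(a$maternal_matches, 1L)
  # base matches the paternal allele -> paternal call
  expect_equal(assign_reads(mk_read("CCGCC"), one)$call, "paternal")
  # base matches neither (sequencing error): no parental information
  u <- assign_reads(mk_read("CCTCC"), one)
  expect_equal(u$call, "uninformative")
  expect_equal(u$neither_matches, 1L)
  expect_equal(u$informative_sites, 1L)
  # two sites voting opposite ways -> conflict
  two <- snp_tbl(c(1L, 3L))
  cf <- assign_reads(mk_read("CACGC"), two)
  expect_equal(cf$call, "conflict")
  expect_equal(cf$maternal_matches, 1L)
  expect_equal(cf$paternal_matches, 1L)
  # no overlapped SNP at all -> uninformative with zero sites
  far <- assign_reads(mk_read("CCCCC"), snp_tbl(50L))
  expect_equal(far$informative_sites, 0L)
  expect_equal(far$call, "uninformative")
  # invariant: votes partition the overlapped sites
  for (x in list(a, u, cf)) {
    expect_equal(x$maternal_matches + x$paternal_matches +
                   x$neither_matches, x$informative_sites)
  }
  expect_error(assign_reads(mk_read("CCNCC"), one), "non-DNA")
})

test_that("tabulation counts calls and conserves totals", {
  asg <- tibble::tibble(
    read_id = sprintf("r%02d", 1:14),
    gene_id = "g1", stage = "c8",
    informative_sites = 1L, maternal_matches = 0L, paternal_matches = 0L,
    neither_matches = 0L,
    call = c(rep("maternal", 10), rep("paternal", 3), "conflict"))
  tc <- tabulate_counts(asg)
  expect_equal(tc$M, 10L)
  expect_equal(tc$P, 3L)
  expect_equal(tc$uninformative, 1L)
  expect_equal(tc$M + tc$P + tc$uninformative, nrow(asg))
  expect_equal(nrow(tabulate_counts(asg[0, ])), 0)
  gm <- tibble::tibble(gene_id = "other")
  expect_error(tabulate_counts(asg, gm), "unknown gene")
})

test_that("assignment recovers the true haplotype on error-free reads", {
  dip <- small_diploid()
  cp <- simulate_expression(small_program(names(dip$maternal)), "c8")
  reads <- simulate_reads(dip$maternal, dip$paternal, cp, n_reads = 20000,
                          error_rate = 0, seed = 21)
  asg <- assign_reads(reads, dip$snps,
                      stats::setNames(nchar(dip$maternal),
                                      names(dip$maternal)))
  informative <- asg$call %in% c("maternal", "paternal")
  expect_gt(sum(informative), 1000)
  expect_equal(mean(asg$call[informative] ==
                      reads$haplotype_of_origin[informative]), 1)
  expect_equal(sum(informative), sum(asg$informative_sites[informative] > 0))
  # conservation: every read receives exactly one call
  expect_equal(nrow(asg), nrow(reads))
  tc <- tabulate_counts(asg)
  expect_equal(sum(tc$M + tc$P + tc$uninformative), nrow(reads))
  # and the tabulated M/P equal the simulator's informative truth counts
  truth_inf <- table(reads$haplotype_of_origin[informative])
  expect_equal(sum(tc$M), unname(truth_inf["maternal"]))
  expect_equal(sum(tc$P), unname(truth_inf["paternal"]))
})

test_that("reciprocal-cross orientation swaps the allele columns", {
  snps <- snp_tbl(c(10L, 20L), m = c("A", "C"), p = c("G", "T"))
  sw <- orient_snps(snps, reciprocal = TRUE)
  expect_equal(sw$maternal_allele, c("G", "T"))
  expect_equal(sw$paternal_allele, c("A", "C"))
  expect_equal(orient_snps(snps, reciprocal = FALSE), snps)
  expect_equal(orient_snps(sw, reciprocal = TRUE)[, ], snps[, ])
})

test_that("FASTQ reads can be placed by exact substring match and assigned", {
  dip <- small_diploid(n_genes = 3, gene_length = 1000, seed = 33)
  cp <- tibble::tibble(gene_id = names(dip$maternal),
                       maternal_copies = 100,
                       paternal_copies = 100)
  reads <- simulate_reads(dip$maternal, dip$paternal, cp, n_reads = 150,
                          error_rate = 0, seed = 33, stage = "c7")
  fq <- tempfile(fileext = ".fastq")
  write_reads_fastq(reads, fq)
  placed <- place_reads(fq, dip$maternal, dip$paternal, stage = "c7")
  expect_gt(nrow(placed), 100)  # a few reads may place ambiguously
  m <- match(placed$read_id, reads$read_id)
  expect_equal(placed$gene_id, reads$gene_id[m])
  expect_equal(placed$start, reads$start[m])
  asg <- assign_reads(placed, dip$snps)
  informative <- asg$call %in% c("maternal", "paternal")
  expect_equal(mean(asg$call[informative] ==
                      reads$haplotype_of_origin[m][informative]), 1)
})
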