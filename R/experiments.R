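#' Measure the sequencing-error misassignment band
#'
#' Simulates a strictly maternal-only transcriptome (every transcript
#' deposited from the mother, none transcribed by the embryo) and keeps
#' drawing error-bearing reads until at least `n_informative` reads overlap
#' a SNP, then reports the fraction of informative reads mis-assigned to
#' the paternal chromosome. With per-base error rate `e`, a read spanning a
#' single SNP is mis-assigned with probability `e/3` (the error must hit
#' the SNP base and turn it into exactly the other parent's allele), so the
#' expected band sits well inside 0.1–1% at default settings.
#'
#' @param n_informative Minimum number of SNP-overlapping reads to
#'   accumulate (default 2e5).
#' @param n_genes,gene_length Transcriptome shape (default 60 genes of
#'   2 kb).
#' @param mean_snp_spacing Mean SNP spacing in nt (default 200).
#' @param read_length Read length in nt (default 36).
#' @param error_rate Per-base substitution error rate (default 0.005).
#' @param seed Master seed.
#' @param batch_size Reads simulated per batch (default 4e5).
#' @return A list: `paternal_fraction` (of informative reads),
#'   `paternal_percent`, counts `maternal`, `paternal`, `conflict`,
#'   `informative`, and `reads_simulated`.
#' @export
simulate_error_band <- function(n_informative = 2e5, n_genes = 60,
                                gene_length = 2000, mean_snp_spacing = 200,
                                read_length = 36, error_rate = 0.005,
                                seed = 1, batch_size = 4e5) {
  ref <- random_reference(n_genes, gene_length, gene_length, seed = seed)
  sequences <- setNames(ref$sequence, ref$gene_id)
  dip <- build_diploid_transcriptome(sequences, mean_snp_spacing, seed)
  copies <- tibble(gene_id = ref$gene_id, maternal_copies = 100,
                   paternal_copies = 0)
  m <- 0; p <- 0; cf <- 0; total <- 0; batch <- 0
  while (m + p < n_informative) {
    batch <- batch + 1
    reads <- simulate_reads(dip$maternal, dip$paternal, copies,
                            n_reads = batch_size,
                            read_length = read_length,
                            error_rate = error_rate,
                            seed = substream_seed(seed, paste0("band", batch)),
                            stage = "c8")
    asg <- assign_reads(reads, dip$snps)
    m <- m + sum(asg$call == "maternal")
    p <- p + sum(asg$call == "paternal")
    cf <- cf + sum(asg$call == "conflict")
    total <- total + nrow(reads)
  }
  frac <- p / (m + p)
  list(paternal_fraction = frac, paternal_percent = 100 * frac,
       maternal = m, paternal = p, conflict = cf, informative = m + p,
       reads_simulated = total)
}

#' Simulate a truth-labelled classifier validation panel
#'
#' Builds a panel of maternal-only and zygotic-only genes with zygotic
#' onsets spread over the early nuclear cycles, runs the full simulate →
#' assign → tabulate path for each stage, and returns the per-gene counts
#' together with the ground truth, ready for [classify_table()] and
#' [evaluate_recovery()].
#'
#' Zygotic genes scale with nuclei number, so read depth roughly doubles
#' each cycle; the default depth gives maternal genes on the order of a
#' hundred informative reads per stage and zygotic genes comfortably more
#' than ten at cycle 8.
#'
#' @param n_maternal,n_zygotic Panel composition (defaults 170 / 30).
#' @param reads_per_stage Reads drawn per stage (default 1.5e5).
#' @param gene_length Transcript length in nt, equal across the panel.
#' @param mean_snp_spacing,read_length,error_rate As in
#'   [simulate_error_band()].
#' @param onset_cycles Cycles over which zygotic onsets are spread
#'   (recycled; default 1:8).
#' @param seed Master seed.
#' @return A list: `counts` (tabulated per gene and stage), `truth`
#'   (`gene_id`, `is_zygotic`, `onset_cycle`), `program`, `snps`.
#' @export
simulate_recovery_panel <- function(n_maternal = 170, n_zygotic = 30,
                                    reads_per_stage = 1.5e5,
                                    gene_length = 2000,
                                    mean_snp_spacing = 200,
                                    read_length = 36, error_rate = 0.005,
                                    onset_cycles = 1:8, seed = 1) {
  n <- n_maternal + n_zygotic
  ref <- random_reference(n, gene_length, gene_length, seed = seed)
  sequences <- setNames(ref$sequence, ref$gene_id)
  dip <- build_diploid_transcriptome(sequences, mean_snp_spacing, seed)
  onsets <- rep(onset_cycles, length.out = n_zygotic)
  program <- expression_program(
    gene_id = ref$gene_id,
    mode = c(rep("maternal_only", n_maternal),
             rep("zygotic_only", n_zygotic)),
    maternal_copies = c(rep(100, n_maternal), rep(0, n_zygotic)),
    zygotic_rate = c(rep(0, n_maternal), rep(1, n_zygotic)),
    onset_cycle = c(rep(1L, n_maternal), onsets),
    scale_with_nuclei = TRUE)
  counts <- dplyr::bind_rows(lapply(pipeline_stages(), function(st) {
    copies <- simulate_expression(program, st)
    reads <- simulate_reads(dip$maternal, dip$paternal, copies,
                            n_reads = reads_per_stage,
                            read_length = read_length,
                            error_rate = error_rate, seed = seed,
                            stage = st)
    tabulate_counts(assign_reads(reads, dip$snps))
  }))
  truth <- tibble(gene_id = ref$gene_id,
                  is_zygotic = c(rep(FALSE, n_maternal),
                                 rep(TRUE, n_zygotic)),
                  onset_cycle = c(rep(NA_integer_, n_maternal),
                                  as.integer(onsets)))
  list(counts = counts, truth = truth, program = program, snps = dip$snps)
}
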