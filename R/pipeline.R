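#' Construct the paternal haplotype from a reference and a SNP table
#'
#' Applies each SNP's paternal allele to a copy of the (maternal) reference
#' sequence. SNP `chrom` names must refer to reference sequence names and
#' positions must carry the maternal allele in the reference.
#'
#' @param reference Named character vector of sequences.
#' @param snps SNP tibble in the same coordinate space.
#' @return Named character vector: the paternal haplotype.
#' @export
apply_snps <- function(reference, snps) {
  stopifnot(all(snps$chrom %in% names(reference)))
  paternal <- reference
  for (nm in unique(snps$chrom)) {
    s <- snps[snps$chrom == nm, , drop = FALSE]
    ch <- strsplit(reference[[nm]], "", fixed = TRUE)[[1]]
    if (any(s$pos >= length(ch))) {
      stop("SNP position beyond end of sequence '", nm, "'", call. = FALSE)
    }
    if (any(ch[s$pos + 1L] != s$maternal_allele)) {
      stop("reference allele mismatch on '", nm,
           "': REF column does not match the reference sequence",
           call. = FALSE)
    }
    ch[s$pos + 1L] <- s$paternal_allele
    paternal[[nm]] <- paste(ch, collapse = "")
  }
  paternal
}

#' Default demo pipeline configuration
#'
#' The configuration shipped at
#' `system.file("extdata", "demo_config.yaml", package = "zygosnp")`,
#' as a list: a small 30-gene transcriptome, SNPs every ~200 bp, 36-nt
#' reads at 0.5% per-base error, five zygotic genes with onsets spread over
#' cycles 1–8, default classifier thresholds.
#'
#' @return A named list usable as `config` in [run_pipeline()].
#' @export
demo_config <- function() {
  read_run_config(system.file("extdata", "demo_config.yaml",
                              package = "zygosnp", mustWork = TRUE))
}

#' Read and validate a pipeline configuration
#'
#' @param config A YAML file path or a named list.
#' @return The validated config list.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  need <- function(field, sub = NULL) {
    node <- if (is.null(sub)) config else config[[sub]]
    ok <- !is.null(node) && (is.null(field) || !is.null(node[[field]]))
    if (!ok) {
      full <- if (is.null(sub)) field else paste(sub, field, sep = ".")
      stop("config is missing required field '", full, "'", call. = FALSE)
    }
  }
  need("seed")
  need(NULL, "reference")
  need(NULL, "reads")
  need("n_per_stage", "reads")
  if (is.null(config$snp) ||
      (is.null(config$snp$mean_spacing) && is.null(config$snp$table))) {
    stop("config is missing required field 'snp' ",
         "(provide snp.mean_spacing to simulate SNPs, or snp.table with ",
         "a SNP table path)", call. = FALSE)
  }
  if (!is.null(config$snp$table) && !file.exists(config$snp$table)) {
    stop("config field 'snp.table' points to a missing file: ",
         config$snp$table, call. = FALSE)
  }
  if (is.null(config$stages)) config$stages <- pipeline_stages()
  check_stage(unlist(config$stages))
  if (config$seed < 0) stop("config field 'seed' must be >= 0",
                            call. = FALSE)
  config
}

log_line <- function(con, ...) writeLines(paste0(...), con)

#' Run the full simulate → assign → quantify → classify pipeline
#'
#' Orchestrates the whole package from one config: simulate (or load) an
#' F1 transcriptome and staged read sets, assign reads by SNP overlap,
#' tabulate per-gene maternal/paternal counts, compute autosomal-anchored
#' RPKM, classify every gene-stage as maternal or zygotic, and write all
#' intermediate and final tables plus a run log to `out_dir`. The run is
#' byte-for-byte reproducible for a fixed seed (the log records versions,
#' seed, thresholds and per-stage read totals, but no timestamps).
#'
#' Files written: `maternal.fa` / `paternal.fa`, `snps.tsv`, per-stage
#' `reads_<stage>.fastq` and `truth_<stage>.tsv`, `assignments.tsv`,
#' `counts.tsv`, `quant.tsv`, `results.tsv`, `onset.tsv`, `summary.json`,
#' `run_log.txt`.
#'
#' @param config YAML path or list (see [demo_config()] and
#'   [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional master seed overriding `config$seed`.
#' @return Invisibly, a list with the classification `results`, `onset`,
#'   `summary`, normalization `factors`, and `paths` of all written files.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(demo_config(), out_dir = tempfile())
#' out$summary
#' }
run_pipeline <- function(config, out_dir, seed = NULL) {
  config <- read_run_config(config)
  if (!is.null(seed)) config$seed <- seed
  seed <- config$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  logp <- file.path(out_dir, "run_log.txt")
  con <- file(logp, "w")
  on.exit(close(con))
  log_line(con, "zygosnp run log")
  log_line(con, "package version: ", as.character(packageVersion("zygosnp")))
  log_line(con, "R version: ", R.version.string)
  log_line(con, "seed: ", seed)

  # --- reference & diploid transcriptome ------------------------------
  rf <- config$reference
  if (!is.null(rf$fasta)) {
    x <- Biostrings::readDNAStringSet(rf$fasta)
    sequences <- setNames(as.character(x), sub(" .*", "", names(x)))
    x_frac_ids <- character(0)
    ref <- tibble(gene_id = names(sequences),
                  length_nt = nchar(sequences),
                  is_autosomal = TRUE, sequence = unname(sequences))
  } else {
    ref <- random_reference(
      n_genes = rf$n_genes %||% 30,
      min_length = rf$min_length %||% 500,
      max_length = rf$max_length %||% 3000,
      x_fraction = rf$x_fraction %||% 0,
      seed = seed)
    sequences <- setNames(ref$sequence, ref$gene_id)
  }
  if (!is.null(config$snp$table)) {
    snps <- read_snp_table(config$snp$table)
    maternal <- sequences
    paternal <- apply_snps(sequences, snps)
    dip <- list(maternal = maternal, paternal = paternal, snps = snps)
  } else {
    dip <- build_diploid_transcriptome(sequences,
                                       config$snp$mean_spacing, seed)
  }
  log_line(con, "genes: ", length(sequences), "; SNPs: ", nrow(dip$snps))
  paths$maternal_fasta <- file.path(out_dir, "maternal.fa")
  paths$paternal_fasta <- file.path(out_dir, "paternal.fa")
  paths$snps <- file.path(out_dir, "snps.tsv")
  write_transcriptome_fasta(dip$maternal, paths$maternal_fasta)
  write_transcriptome_fasta(dip$paternal, paths$paternal_fasta)
  write_snp_table(dip$snps, paths$snps)

  # --- expression program ---------------------------------------------
  ex <- config$expression %||% list()
  n <- length(sequences)
  n_zyg <- min(ex$n_zygotic %||% 5, n)
  onset_range <- ex$onset_cycles %||% c(1, 8)
  onsets <- rep(seq(onset_range[[1]], onset_range[[length(onset_range)]]),
                length.out = n_zyg)
  program <- expression_program(
    gene_id = names(sequences),
    mode = c(rep("maternal_only", n - n_zyg), rep("zygotic_only", n_zyg)),
    maternal_copies = c(rep(ex$maternal_copies %||% 100, n - n_zyg),
                        rep(0, n_zyg)),
    zygotic_rate = c(rep(0, n - n_zyg),
                     rep(ex$zygotic_rate %||% 1, n_zyg)),
    onset_cycle = c(rep(1L, n - n_zyg), onsets),
    scale_with_nuclei = TRUE)

  # --- per-stage reads, assignment, counts ----------------------------
  stages <- unlist(config$stages)
  rd <- config$reads
  tlen <- setNames(nchar(dip$maternal), names(dip$maternal))
  all_counts <- list()
  all_asg <- list()
  quant <- list()
  for (st in stages) {
    copies <- simulate_expression(program, st)
    reads <- simulate_reads(dip$maternal, dip$paternal, copies,
                            n_reads = rd$n_per_stage,
                            read_length = rd$read_length %||% 36,
                            error_rate = rd$error_rate %||% 0.005,
                            seed = seed, stage = st)
    paths[[paste0("fastq_", st)]] <- file.path(out_dir,
                                               paste0("reads_", st, ".fastq"))
    write_reads_fastq(reads, paths[[paste0("fastq_", st)]])
    truth_path <- file.path(out_dir, paste0("truth_", st, ".tsv"))
    write.table(as.data.frame(reads), truth_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths[[paste0("truth_", st)]] <- truth_path
    asg <- assign_reads(reads, dip$snps, transcript_lengths = tlen)
    all_asg[[st]] <- asg
    all_counts[[st]] <- tabulate_counts(asg)
    log_line(con, "stage ", st, ": reads ", nrow(reads),
             "; informative ",
             sum(asg$call %in% c("maternal", "paternal")))
    raw <- table(factor(reads$gene_id, levels = names(sequences)))
    quant[[st]] <- tibble(sample = st, gene_id = names(sequences),
                          count = as.integer(raw),
                          rpkm = rpkm(as.integer(raw), tlen, nrow(reads)),
                          is_autosomal = ref$is_autosomal[
                            match(names(sequences), ref$gene_id)])
  }
  asg_all <- dplyr::bind_rows(all_asg)
  paths$assignments <- file.path(out_dir, "assignments.tsv")
  write.table(as.data.frame(asg_all), paths$assignments, sep = "\t",
              quote = FALSE, row.names = FALSE)
  counts <- dplyr::bind_rows(all_counts)
  paths$counts <- file.path(out_dir, "counts.tsv")
  write_counts(counts, paths$counts)

  # --- RPKM + autosomal normalization ---------------------------------
  quant_all <- dplyr::bind_rows(quant)
  norm <- normalize_autosomal(quant_all)
  for (i in seq_len(nrow(norm$factors))) {
    log_line(con, "scale factor ", norm$factors$sample[i], ": ",
             format(norm$factors$scale_factor[i], digits = 10))
  }
  paths$quant <- file.path(out_dir, "quant.tsv")
  write.table(as.data.frame(norm$normalized), paths$quant, sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- classification --------------------------------------------------
  cc <- config$classifier %||% list()
  cfg <- classifier_config(
    error_ceiling = cc$error_ceiling %||% 0.01,
    min_paternal_fraction = cc$min_paternal_fraction %||% 0.10,
    alpha = cc$alpha %||% 0.05,
    min_informative_reads = cc$min_informative_reads %||% 100,
    low_information_threshold = cc$low_information_threshold %||% 5)
  log_line(con, "classifier: p0 ", cfg$error_ceiling,
           "; f_min ", cfg$min_paternal_fraction,
           "; alpha ", cfg$alpha,
           "; low-information below N ", cfg$low_information_threshold)
  cl <- classify_table(counts, cfg)
  paths$results <- file.path(out_dir, "results.tsv")
  write_results(cl$results, paths$results)
  paths$onset <- file.path(out_dir, "onset.tsv")
  write.table(as.data.frame(cl$onset), paths$onset, sep = "\t",
              quote = FALSE, row.names = FALSE)
  paths$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(calls = cl$summary,
         scale_factors = norm$factors,
         onset = cl$onset[!is.na(cl$onset$onset_stage), ]),
    paths$summary, dataframe = "rows", pretty = TRUE, digits = NA,
    na = "null")
  log_line(con, "results: ", nrow(cl$results), " gene-stage rows")

  invisible(list(results = cl$results, onset = cl$onset,
                 summary = cl$summary, factors = norm$factors,
                 counts = counts, paths = paths, config = config))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
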