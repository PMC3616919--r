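#' Generate a random reference transcriptome
#'
#' Convenience generator for testing and demos: independent uniform-base
#' transcript sequences with optional X-linked genes (relevant only for
#' autosomal normalization downstream).
#'
#' @param n_genes Number of transcripts.
#' @param min_length,max_length Transcript length range in nt (uniform).
#' @param x_fraction Fraction of genes flagged X-linked (the first
#'   `round(x_fraction * n_genes)` genes).
#' @param seed Master seed.
#' @return A tibble with `gene_id`, `length_nt`, `is_autosomal`, `sequence`.
#' @export
random_reference <- function(n_genes = 50, min_length = 500,
                             max_length = 3000, x_fraction = 0, seed = 1) {
  stopifnot(n_genes >= 1, min_length >= 1, max_length >= min_length,
            x_fraction >= 0, x_fraction <= 1)
  with_substream(seed, "reference", {
    lens <- if (min_length == max_length) rep(min_length, n_genes) else
      sample(min_length:max_length, n_genes, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(DNA_BASES, L, replace = TRUE), collapse = ""),
      character(1))
    nx <- round(x_fraction * n_genes)
    tibble(
      gene_id = sprintf("gene_%03d", seq_len(n_genes)),
      length_nt = as.integer(lens),
      is_autosomal = c(rep(FALSE, nx), rep(TRUE, n_genes - nx)),
      sequence = seqs
    )
  })
}

#' Build a diploid F1 transcriptome from reference sequences
#'
#' Plants single-nucleotide substitutions into a copy of each reference
#' sequence to emulate the transcriptome of an F1 hybrid of two inbred
#' lines. The reference is taken as the maternal haplotype; the paternal
#' haplotype differs only at the generated SNPs. Inter-SNP distances are
#' geometric (memoryless) with the given mean — "about every 200 bp"
#' describes an average, not a lattice — and the substituted allele is drawn
#' uniformly from the three alternatives.
#'
#' @param reference Named character vector of transcript sequences
#'   (A/C/G/T), or a [Biostrings::DNAStringSet].
#' @param mean_snp_spacing Mean distance between SNPs in nt (> 0). Use `Inf`
#'   for no SNPs (identical haplotypes).
#' @param seed Master seed; output is deterministic given the seed.
#' @return A list with `maternal` and `paternal` (named character vectors)
#'   and `snps`, a tibble of SNP records in transcript coordinates
#'   (`chrom` = transcript name, `pos` 0-based, `maternal_allele`,
#'   `paternal_allele`).
#' @export
#' @examples
#' ref <- c(t1 = paste(rep("ACGT", 25), collapse = ""))
#' dip <- build_diploid_transcriptome(ref, mean_snp_spacing = 20, seed = 1)
#' dip$snps
build_diploid_transcriptome <- function(reference, mean_snp_spacing = 200,
                                        seed = 1) {
  if (methods::is(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  stopifnot(is.character(reference), length(reference) >= 1,
            !is.null(names(reference)))
  check_dna(reference, "reference sequence")
  if (!is.infinite(mean_snp_spacing) && mean_snp_spacing <= 0) {
    stop("mean_snp_spacing must be > 0 (or Inf for no SNPs)", call. = FALSE)
  }
  with_substream(seed, "diploid", {
    paternal <- reference
    snp_list <- vector("list", length(reference))
    for (i in seq_along(reference)) {
      len <- nchar(reference[[i]])
      if (is.infinite(mean_snp_spacing)) {
        pos <- integer(0)
      } else {
        n_max <- max(16, ceiling(3 * len / mean_snp_spacing) + 10)
        gaps <- rgeom(n_max, prob = 1 / mean_snp_spacing) + 1L
        pos <- cumsum(gaps) - 1L
        while (length(pos) > 0 && pos[length(pos)] < len) {
          gaps <- rgeom(n_max, prob = 1 / mean_snp_spacing) + 1L
          pos <- c(pos, pos[length(pos)] + 1L + cumsum(gaps) - 1L)
        }
        pos <- pos[pos < len]
      }
      if (length(pos) == 0) {
        snp_list[[i]] <- NULL
        next
      }
      ch <- strsplit(reference[[i]], "", fixed = TRUE)[[1]]
      ref_allele <- ch[pos + 1L]
      ref_idx <- match(ref_allele, DNA_BASES)
      alt_idx <- ((ref_idx - 1L + sample.int(3, length(pos),
                                             replace = TRUE)) %% 4L) + 1L
      alt_allele <- DNA_BASES[alt_idx]
      ch[pos + 1L] <- alt_allele
      paternal[[i]] <- paste(ch, collapse = "")
      snp_list[[i]] <- tibble(chrom = names(reference)[i], pos = pos,
                              maternal_allele = ref_allele,
                              paternal_allele = alt_allele)
    }
    snps <- dplyr::bind_rows(snp_list)
    if (nrow(snps) == 0) {
      snps <- tibble(chrom = character(), pos = integer(),
                     maternal_allele = character(),
                     paternal_allele = character())
    }
    list(maternal = reference, paternal = paternal, snps = snps)
  })
}

#' Expected number of nuclei at a given nuclear cycle
#'
#' The early syncytial divisions are perfect doublings: an embryo in nuclear
#' cycle `c` carries `2^(c-1)` nuclei (cycle 1 = the zygotic nucleus, cycle
#' 3 = 4 nuclei, cycle 6 = 32).
#'
#' @param cycle Nuclear cycle index (integer >= 1); vectorized.
#' @return Integer count(s) of nuclei.
#' @export
#' @examples
#' expected_nuclei(3)  # 4
expected_nuclei <- function(cycle) {
  if (any(!is.finite(cycle)) || any(cycle < 1) || any(cycle != round(cycle))) {
    stop("cycle must be an integer >= 1", call. = FALSE)
  }
  as.integer(2^(cycle - 1))
}

#' Define a per-gene expression program
#'
#' Each gene is `maternal_only` (transcripts deposited during oogenesis,
#' maternal haplotype only), `zygotic_only` (transcribed by the embryo from
#' both haplotypes from `onset_cycle` onward), or `mixed` (a maternal
#' deposit plus zygotic synthesis). Zygotic output per cycle is
#' `zygotic_rate` copies per nucleus when `scale_with_nuclei` is set
#' (multiplied by [expected_nuclei()]), otherwise `zygotic_rate` copies per
#' cycle.
#'
#' @param gene_id Character vector of gene ids.
#' @param mode One of `"maternal_only"`, `"zygotic_only"`, `"mixed"`
#'   (recycled).
#' @param maternal_copies Deposited transcript copies (arbitrary abundance
#'   units, >= 0).
#' @param zygotic_rate Zygotic copies per nucleus (or per cycle) >= 0.
#' @param onset_cycle Nuclear cycle of first zygotic transcription (>= 1).
#' @param scale_with_nuclei Logical; scale zygotic output by nuclei count.
#' @return A validated tibble (one row per gene).
#' @export
expression_program <- function(gene_id, mode = "maternal_only",
                               maternal_copies = 0, zygotic_rate = 0,
                               onset_cycle = 1, scale_with_nuclei = TRUE) {
  prog <- tibble(gene_id = gene_id, mode = mode,
                 maternal_copies = maternal_copies,
                 zygotic_rate = zygotic_rate,
                 onset_cycle = as.integer(onset_cycle),
                 scale_with_nuclei = scale_with_nuclei)
  bad_mode <- !prog$mode %in% c("maternal_only", "zygotic_only", "mixed")
  if (any(bad_mode)) stop("unknown expression mode: ",
                          prog$mode[bad_mode][1], call. = FALSE)
  stopifnot(all(prog$maternal_copies >= 0), all(prog$zygotic_rate >= 0),
            all(prog$onset_cycle >= 1))
  if (any(prog$mode == "maternal_only" & prog$zygotic_rate > 0)) {
    stop("maternal_only genes must have zygotic_rate = 0", call. = FALSE)
  }
  if (any(prog$mode == "zygotic_only" & prog$maternal_copies > 0)) {
    stop("zygotic_only genes must have maternal_copies = 0", call. = FALSE)
  }
  prog
}

#' Expected per-haplotype transcript copy numbers at a stage
#'
#' The maternal deposit contributes copies only on the maternal haplotype.
#' Zygotic transcription, active from `onset_cycle` onward, contributes
#' equal expected copies to both haplotypes: the total zygotic output over
#' the stage's nuclear cycles is split evenly between them.
#'
#' @param program Tibble from [expression_program()].
#' @param stage One of [pipeline_stages()] (`c3_6` pools cycles 3–6).
#' @return Tibble with `gene_id`, `stage`, `maternal_copies`,
#'   `paternal_copies` (expected copy numbers, not sampled).
#' @export
#' @examples
#' prog <- expression_program(c("mat", "zyg"),
#'   mode = c("maternal_only", "zygotic_only"),
#'   maternal_copies = c(100, 0), zygotic_rate = c(0, 1))
#' simulate_expression(prog, "c8")
simulate_expression <- function(program, stage) {
  check_stage(stage)
  cycles <- stage_cycles(stage)
  zyg_total <- vapply(seq_len(nrow(program)), function(i) {
    active <- cycles[cycles >= program$onset_cycle[i]]
    if (length(active) == 0) return(0)
    per_cycle <- if (isTRUE(program$scale_with_nuclei[i]))
      expected_nuclei(active) else rep(1, length(active))
    program$zygotic_rate[i] * sum(per_cycle)
  }, numeric(1))
  tibble(gene_id = program$gene_id, stage = stage,
         maternal_copies = program$maternal_copies + zyg_total / 2,
         paternal_copies = zyg_total / 2)
}

#' Simulate error-bearing single-end reads from a diploid transcriptome
#'
#' Reads are drawn from (gene, haplotype) units with probability
#' proportional to copy number times transcript length, start positions
#' uniform over the valid range, substitution errors i.i.d. per base with
#' the erroneous base uniform over the three alternatives. Every read
#' carries its true haplotype of origin, independent of any later
#' assignment. Transcripts shorter than the read length are excluded from
#' sampling (with a warning if they carry weight); if no transcript can
#' yield a read, an error is raised.
#'
#' @param maternal,paternal Named character vectors of haplotype sequences
#'   (as from [build_diploid_transcriptome()]).
#' @param copies Tibble with `gene_id`, `maternal_copies`,
#'   `paternal_copies` (as from [simulate_expression()]). A gene with zero
#'   copies on both haplotypes — e.g. one deleted by a deficiency — yields
#'   no reads.
#' @param n_reads Number of reads to draw (>= 0).
#' @param read_length Read length in nt (default 36, an early short-read
#'   instrument length that maximizes single-SNP reads).
#' @param error_rate Per-base substitution error probability in `[0, 1)`
#'   (default 0.005).
#' @param seed Master seed.
#' @param stage Stage label stamped on the reads.
#' @return A truth-table tibble: `read_id`, `gene_id`,
#'   `haplotype_of_origin`, `start` (0-based transcript offset), `length`,
#'   `stage`, `sequence`.
#' @export
simulate_reads <- function(maternal, paternal, copies, n_reads,
                           read_length = 36, error_rate = 0.005, seed = 1,
                           stage = "c8") {
  stopifnot(error_rate >= 0, error_rate < 1, read_length >= 1)
  if (n_reads < 0) stop("n_reads must be >= 0", call. = FALSE)
  check_stage(stage)
  stopifnot(all(copies$gene_id %in% names(maternal)),
            all(copies$gene_id %in% names(paternal)))

  units <- dplyr::bind_rows(
    tibble(gene_id = copies$gene_id, haplotype = "maternal",
           copies = copies$maternal_copies),
    tibble(gene_id = copies$gene_id, haplotype = "paternal",
           copies = copies$paternal_copies))
  units$sequence <- ifelse(units$haplotype == "maternal",
                           maternal[units$gene_id], paternal[units$gene_id])
  units$len <- nchar(units$sequence)
  too_short <- units$len < read_length
  units$weight <- units$copies * units$len
  units$weight[too_short] <- 0
  if (any(units$weight > 0) && any(too_short & units$copies > 0)) {
    warning("excluding ", sum(too_short & units$copies > 0),
            " transcript unit(s) shorter than the read length")
  }
  units <- units[units$weight > 0, , drop = FALSE]
  empty <- tibble(read_id = character(), gene_id = character(),
                  haplotype_of_origin = character(), start = integer(),
                  length = integer(), stage = character(),
                  sequence = character())
  if (n_reads == 0) return(empty)
  if (nrow(units) == 0) {
    if (any(nchar(c(maternal, paternal)) < read_length)) {
      stop("read_length exceeds every transcript with positive copy number",
           call. = FALSE)
    }
    return(empty)
  }

  with_substream(seed, paste0("reads_", stage), {
    u <- sample.int(nrow(units), n_reads, replace = TRUE,
                    prob = units$weight)
    start <- floor(runif(n_reads) * (units$len[u] - read_length + 1))
    seqs <- substring(units$sequence[u], start + 1, start + read_length)

    # i.i.d. substitution errors: per-read error count is binomial, error
    # positions are distinct within a read, erroneous base uniform over the
    # other three
    n_err <- rbinom(n_reads, read_length, error_rate)
    which_err <- which(n_err > 0)
    if (length(which_err) > 0) {
      err_read <- rep(which_err, n_err[which_err])
      err_pos <- unlist(lapply(which_err, function(i)
        if (n_err[i] == 1) sample.int(read_length, 1)
        else sample.int(read_length, n_err[i])), use.names = FALSE)
      cur <- substr(seqs[err_read], err_pos, err_pos)
      cur_idx <- match(cur, DNA_BASES)
      new_idx <- ((cur_idx - 1L + sample.int(3, length(cur),
                                             replace = TRUE)) %% 4L) + 1L
      new_base <- DNA_BASES[new_idx]
      # apply one error per read at a time so multiple hits in one read all
      # land (vectorized substr<- writes one position per element)
      rank_in_read <- stats::ave(seq_along(err_read), err_read,
                                 FUN = seq_along)
      for (k in seq_len(max(rank_in_read))) {
        sel <- rank_in_read == k
        i <- err_read[sel]
        substr(seqs[i], err_pos[sel], err_pos[sel]) <- new_base[sel]
      }
    }
    tibble(read_id = sprintf("%s_read_%07d", stage, seq_len(n_reads)),
           gene_id = units$gene_id[u],
           haplotype_of_origin = units$haplotype[u],
           start = as.integer(start), length = as.integer(read_length),
           stage = stage, sequence = seqs)
  })
}

#' Write simulated reads as FASTQ
#'
#' Sanger-encoded FASTQ with a constant quality character (the simulator
#' has a flat error profile, so per-base qualities carry no information).
#' Output is byte-identical for identical inputs.
#'
#' @param reads Truth-table tibble from [simulate_reads()].
#' @param path Output FASTQ path.
#' @param quality_char Single quality character (default `"I"`, Phred 40).
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path, quality_char = "I") {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  quals <- Biostrings::BStringSet(strrep(quality_char, nchar(reads$sequence)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Write a transcriptome as FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcriptome_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Simulate a Mendelian cross
#'
#' Offspring genotypes are drawn by independent uniform gamete choice from
#' each parent; phenotypes follow a user-supplied genotype-to-phenotype
#' map. Genotype keys are the two alleles sorted and joined with `/`, so
#' `en/+` is keyed `"+/en"`.
#'
#' @param parent1,parent2 Character vectors of length 2: the two alleles of
#'   each parent (e.g. `c("en", "+")`).
#' @param phenotype_map Named character vector mapping genotype keys to
#'   phenotypes (e.g. `c("en/en" = "mutant", "+/en" = "normal",
#'   "+/+" = "normal")`). Every genotype reachable from the parents must be
#'   present.
#' @param n_offspring Number of offspring to draw (>= 0).
#' @param seed Master seed.
#' @return A list: `genotypes` (tibble of genotype counts), `phenotypes`
#'   (tibble of phenotype counts), `mutant_fraction` (fraction with
#'   phenotype `"mutant"`; `NA` if no offspring).
#' @export
#' @examples
#' simulate_cross(c("en", "+"), c("en", "+"),
#'   c("en/en" = "mutant", "+/en" = "normal", "+/+" = "normal"),
#'   n_offspring = 1000, seed = 1)$mutant_fraction
simulate_cross <- function(parent1, parent2, phenotype_map, n_offspring,
                           seed = 1) {
  stopifnot(length(parent1) == 2, length(parent2) == 2,
            is.character(phenotype_map), !is.null(names(phenotype_map)))
  if (n_offspring < 0) stop("n_offspring must be >= 0", call. = FALSE)
  geno_key <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "/")
  }
  reachable <- unique(as.vector(outer(parent1, parent2, geno_key)))
  missing <- setdiff(reachable, names(phenotype_map))
  if (length(missing) > 0) {
    stop("phenotype_map is missing reachable genotype(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  with_substream(seed, "cross", {
    g1 <- parent1[sample.int(2, n_offspring, replace = TRUE)]
    g2 <- parent2[sample.int(2, n_offspring, replace = TRUE)]
    geno <- geno_key(g1, g2)
    pheno <- unname(phenotype_map[geno])
    gt <- as_tibble(as.data.frame(table(genotype = geno),
                                  stringsAsFactors = FALSE))
    pt <- as_tibble(as.data.frame(table(phenotype = pheno),
                                  stringsAsFactors = FALSE))
    names(gt)[2] <- "n"
    names(pt)[2] <- "n"
    mf <- if (n_offspring == 0) NA_real_ else
      sum(pheno == "mutant") / n_offspring
    list(genotypes = gt, phenotypes = pt, mutant_fraction = mf)
  })
}
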