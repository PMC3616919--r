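#' Read a SNP table distinguishing two parental lines
#'
#' The expected dialect is a minimal, VCF-like TSV with four columns:
#' `CHROM`, `POS` (1-based, as in VCF), `REF` and `ALT`, where `REF` is the
#' allele carried by the line used as the mother and `ALT` the allele of the
#' paternal line (see [orient_snps()] for reciprocal crosses). Lines starting
#' with `#` are comments; gzip-compressed files are read transparently. Only
#' biallelic single-nucleotide substitutions are accepted — the whole
#' parent-of-origin method rests on single-base differences.
#'
#' @param path Path to the SNP table.
#' @return A tibble with columns `chrom`, `pos` (0-based, the package's
#'   internal convention), `maternal_allele`, `paternal_allele`, sorted by
#'   `(chrom, pos)`.
#' @export
#' @seealso [write_snp_table()], [project_snps()]
read_snp_table <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble(chrom = character(), pos = integer(),
                  maternal_allele = character(),
                  paternal_allele = character()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 4)) {
    stop("malformed SNP line ", idx[which(nfield < 4)[1]],
         ": expected 4 tab-separated fields (CHROM POS REF ALT)",
         call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:4))
  pos1 <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos1) || any(pos1 < 1)) {
    bad <- which(is.na(pos1) | pos1 < 1)[1]
    stop("malformed SNP line ", idx[bad], ": POS must be a positive integer",
         call. = FALSE)
  }
  ref <- m[, 3]; alt <- m[, 4]
  mono <- ref %in% DNA_BASES & alt %in% DNA_BASES
  if (any(!mono)) {
    stop("malformed SNP line ", idx[which(!mono)[1]],
         ": REF and ALT must be single bases A/C/G/T ",
         "(indels and multi-nucleotide variants are not substitutions)",
         call. = FALSE)
  }
  if (any(ref == alt)) {
    stop("invalid SNP line ", idx[which(ref == alt)[1]],
         ": REF and ALT are identical", call. = FALSE)
  }
  out <- tibble(chrom = m[, 1], pos = pos1 - 1L,
                maternal_allele = ref, paternal_allele = alt)
  dplyr::arrange(out, .data$chrom, .data$pos)
}

#' Write a SNP table
#'
#' Inverse of [read_snp_table()]: positions are converted back to 1-based
#' VCF-style coordinates on disk. Reading the written file recovers the
#' input exactly.
#'
#' @param snps Tibble as returned by [read_snp_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(snps, path) {
  stopifnot(all(c("chrom", "pos", "maternal_allele", "paternal_allele")
                %in% names(snps)))
  if (nrow(snps) > 0 && any(snps$pos < 0)) {
    stop("negative SNP position", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#CHROM\tPOS\tREF\tALT", con)
  if (nrow(snps) > 0) {
    writeLines(paste(snps$chrom, snps$pos + 1L, snps$maternal_allele,
                     snps$paternal_allele, sep = "\t"), con)
  }
  invisible(path)
}

#' Read gene models from a BED12 file
#'
#' Exon structure comes from the BED block fields; transcript length and
#' intron count are derived from the blocks (length = sum of block sizes,
#' introns = blocks - 1). Genes on chromosome X (`X` or `chrX`) are flagged
#' as non-autosomal, which matters for [normalize_autosomal()].
#'
#' @param path Path to a BED12 file.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   list-columns `exon_starts` (0-based genomic) and `exon_widths`,
#'   `transcript_length_nt`, `intron_count`, `is_autosomal`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks)) {
    # BED6 or less: the whole span is a single exon
    blocks <- IRanges::IRangesList(lapply(seq_along(gr), function(i)
      IRanges::IRanges(start = 1L, width = BiocGenerics::width(gr)[i])))
  } else {
    blocks <- gr$blocks
  }
  n_exon <- lengths(blocks)
  starts0 <- vector("list", length(gr))
  widths <- vector("list", length(gr))
  chrom_start <- BiocGenerics::start(gr) - 1L  # 0-based gene start
  for (i in seq_along(gr)) {
    b <- blocks[[i]]
    w <- BiocGenerics::width(b)
    s <- chrom_start[i] + BiocGenerics::start(b) - 1L  # 0-based genomic
    o <- order(s)
    s <- s[o]; w <- w[o]
    if (any(w <= 0)) {
      stop("gene '", gr$name[i], "': zero-length exon block", call. = FALSE)
    }
    if (length(s) > 1 && any(s[-1] < (s + w)[-length(s)])) {
      stop("gene '", gr$name[i], "': overlapping exon blocks", call. = FALSE)
    }
    starts0[[i]] <- as.integer(s)
    widths[[i]] <- as.integer(w)
  }
  chrom <- as.character(GenomicRanges::seqnames(gr))
  tibble(
    gene_id = gr$name,
    chrom = chrom,
    strand = as.character(BiocGenerics::strand(gr)),
    exon_starts = starts0,
    exon_widths = widths,
    transcript_length_nt = vapply(widths, sum, integer(1)),
    intron_count = as.integer(n_exon - 1L),
    is_autosomal = !chrom %in% c("X", "chrX", "Y", "chrY")
  )
}

#' Published allele counts for the pre-blastoderm zygotic gene cohort
#'
#' Loads the packaged table of per-gene maternal (M) and paternal (P)
#' SNP-read counts observed in staged embryo pools (nuclear cycles 3–6
#' pooled, cycle 7, cycle 8) from an F1 hybrid of two inbred lines, together
#' with transcript size and intron number for each gene. Blank cells in the
#' published table are treated as "no informative reads detected at that
#' stage" and yield no count row. One gene (*scw*) appears twice with
#' different counts; both rows are kept, keyed by `row_id`, and flagged
#' `exclude_from_onset` so they never enter gene-level aggregation.
#'
#' @return A list with two tibbles:
#'   \describe{
#'     \item{counts}{`row_id`, `gene_id`, `stage`, `M`, `P`,
#'       `uninformative` (0: the published table reports only informative
#'       reads), `exclude_from_onset`.}
#'     \item{genes}{`row_id`, `gene_id`, `size_nt` (transcript length as
#'       printed; one entry, *Egfr*, is printed in ambiguous units and kept
#'       verbatim), `introns`, `is_autosomal` (X-linked genes *sisA*, *sc*,
#'       *l(1)sc*, *run*, *roX1* are flagged), `note` (footnote flags:
#'       `not_annotated`, `overlaps_Nmd3`, `single_500bp_region`).}
#'   }
#' @export
#' @examples
#' fx <- load_zygotic_gene_counts()
#' subset(fx$counts, gene_id == "zen")
load_zygotic_gene_counts <- function() {
  path <- system.file("extdata", "zygotic_cohort_counts.tsv",
                      package = "zygosnp", mustWork = TRUE)
  raw <- read.delim(path, sep = "\t", header = TRUE, fill = TRUE,
                    na.strings = c("", "NA"), check.names = FALSE,
                    colClasses = c(
                      gene = "character", m_c3_6 = "integer",
                      p_c3_6 = "integer", m_c7 = "integer", p_c7 = "integer",
                      m_c8 = "integer", p_c8 = "integer",
                      size_nt = "numeric", introns = "integer",
                      note = "character"))
  raw$row_id <- seq_len(nrow(raw))
  dup <- raw$gene %in% raw$gene[duplicated(raw$gene)]
  x_linked <- c("sisA", "sc", "l(1)sc", "run", "roX1")

  stage_cols <- list(c3_6 = c("m_c3_6", "p_c3_6"),
                     c7 = c("m_c7", "p_c7"),
                     c8 = c("m_c8", "p_c8"))
  counts <- dplyr::bind_rows(lapply(names(stage_cols), function(st) {
    cc <- stage_cols[[st]]
    ok <- !is.na(raw[[cc[1]]]) | !is.na(raw[[cc[2]]])
    tibble(row_id = raw$row_id[ok], gene_id = raw$gene[ok], stage = st,
           M = ifelse(is.na(raw[[cc[1]]][ok]), 0L, raw[[cc[1]]][ok]),
           P = ifelse(is.na(raw[[cc[2]]][ok]), 0L, raw[[cc[2]]][ok]),
           uninformative = 0L,
           exclude_from_onset = dup[ok])
  }))
  counts <- dplyr::arrange(counts, .data$row_id,
                           match(.data$stage, pipeline_stages()))
  genes <- tibble(row_id = raw$row_id, gene_id = raw$gene,
                  size_nt = raw$size_nt, introns = raw$introns,
                  is_autosomal = !raw$gene %in% x_linked,
                  note = raw$note)
  list(counts = counts, genes = genes)
}

count_cols <- c("gene_id", "stage", "M", "P", "uninformative")

validate_counts <- function(rows) {
  missing <- setdiff(count_cols, names(rows))
  if (length(missing) > 0) {
    stop("count table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(rows) > 0) {
    check_stage(rows$stage)
    if (any(rows$M < 0 | rows$P < 0 | rows$uninformative < 0)) {
      stop("negative read count", call. = FALSE)
    }
  }
  invisible(rows)
}

#' Write / read per-gene allele count tables
#'
#' Plain TSV with fixed column order `gene_id, stage, M, P, uninformative`;
#' a written table read back is identical to the input. Extra columns (e.g.
#' `row_id`, `exclude_from_onset`) are preserved after the fixed block.
#'
#' @param rows A count tibble (see [tabulate_counts()]).
#' @param path File path.
#' @return `write_counts()` returns `path` invisibly; `read_counts()`
#'   returns the tibble.
#' @export
write_counts <- function(rows, path) {
  validate_counts(rows)
  extra <- setdiff(names(rows), count_cols)
  out <- as.data.frame(rows[, c(count_cols, extra)])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  out <- as_tibble(read.delim(path, sep = "\t", header = TRUE,
                              check.names = FALSE,
                              stringsAsFactors = FALSE))
  validate_counts(out)
  out
}

result_cols <- c("gene_id", "stage", "N", "paternal_fraction", "p_value",
                 "p_adjusted", "call", "zygotic_fraction_estimate",
                 "confident")

#' Write / read classification result tables
#'
#' Plain TSV with fixed column order (`gene_id, stage, N, paternal_fraction,
#' p_value, p_adjusted, call, zygotic_fraction_estimate, confident`);
#' numeric columns are written at full precision so a written table read
#' back equals the input.
#'
#' @param results Result tibble from [classify_table()].
#' @param path File path.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns the tibble.
#' @export
write_results <- function(results, path) {
  missing <- setdiff(result_cols, names(results))
  if (length(missing) > 0) {
    stop("result table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- as.data.frame(results[, result_cols])
  for (cc in c("paternal_fraction", "p_value", "p_adjusted",
               "zygotic_fraction_estimate")) {
    out[[cc]] <- sprintf("%.17g", out[[cc]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  out <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (cc in c("paternal_fraction", "p_value", "p_adjusted",
               "zygotic_fraction_estimate")) {
    out[[cc]] <- as.numeric(out[[cc]])
  }
  out$confident <- as.logical(out$confident)
  as_tibble(out)
}
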