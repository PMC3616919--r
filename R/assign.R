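#' Project genomic SNPs onto transcript coordinates
#'
#' Maps SNPs given in genomic coordinates onto each gene's transcript using
#' the exon structure. SNPs falling in introns (or outside the gene) are
#' excluded by the projection — an intronic polymorphism can never be seen
#' in a spliced read. For minus-strand genes the transcript runs 3'→5' along
#' the genome, so positions are reflected and alleles complemented.
#'
#' @param snps SNP tibble in genomic coordinates (from [read_snp_table()]).
#' @param gene_models Gene model tibble (from [read_gene_models()]).
#' @return SNP tibble in transcript coordinates: `chrom` is the `gene_id`,
#'   `pos` the 0-based transcript offset.
#' @export
project_snps <- function(snps, gene_models) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- vector("list", nrow(gene_models))
  for (i in seq_len(nrow(gene_models))) {
    g <- gene_models[i, ]
    s <- snps[snps$chrom == g$chrom, , drop = FALSE]
    if (nrow(s) == 0) next
    ex_start <- g$exon_starts[[1]]
    ex_width <- g$exon_widths[[1]]
    cum <- cumsum(c(0L, ex_width))  # transcript offset of each exon start
    hit <- rep(NA_integer_, nrow(s))
    for (e in seq_along(ex_start)) {
      inside <- s$pos >= ex_start[e] & s$pos < ex_start[e] + ex_width[e]
      hit[inside] <- cum[e] + (s$pos[inside] - ex_start[e])
    }
    keep <- !is.na(hit)
    if (!any(keep)) next
    tpos <- hit[keep]
    ma <- s$maternal_allele[keep]
    pa <- s$paternal_allele[keep]
    if (g$strand == "-") {
      tpos <- g$transcript_length_nt - 1L - tpos
      ma <- unname(comp[ma])
      pa <- unname(comp[pa])
    }
    out[[i]] <- tibble(chrom = g$gene_id, pos = as.integer(tpos),
                       maternal_allele = ma, paternal_allele = pa)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(chrom = character(), pos = integer(),
                  maternal_allele = character(),
                  paternal_allele = character()))
  }
  dplyr::arrange(res, .data$chrom, .data$pos)
}

#' SNPs overlapped by one read placement
#'
#' Returns the SNPs whose transcript coordinate lies in the half-open read
#' interval `[start, start + length)`, with their offsets within the read.
#'
#' @param gene_id Gene/transcript the read is placed on.
#' @param start 0-based transcript offset of the read.
#' @param length Read length in nt.
#' @param snps SNP tibble in transcript coordinates (`chrom` = gene id).
#' @param transcript_lengths Optional named vector of transcript lengths;
#'   when given, a read extending past the transcript end is an error.
#' @return Tibble of overlapped SNPs with an extra `read_offset` column.
#' @export
find_overlapping_snps <- function(gene_id, start, length, snps,
                                  transcript_lengths = NULL) {
  stopifnot(length(gene_id) == 1, start >= 0, length >= 1)
  if (!is.null(transcript_lengths)) {
    tl <- transcript_lengths[[gene_id]]
    if (!is.null(tl) && start + length > tl) {
      stop("read on '", gene_id, "' extends past the transcript end (",
           start + length, " > ", tl, ")", call. = FALSE)
    }
  }
  s <- snps[snps$chrom == gene_id, , drop = FALSE]
  s <- s[s$pos >= start & s$pos < start + length, , drop = FALSE]
  s$read_offset <- as.integer(s$pos - start)
  s
}

#' Assign reads to the maternal or paternal chromosome by SNP overlap
#'
#' For every read, each overlapped SNP site is compared against the two
#' parental alleles and votes maternal, paternal, or neither (a base
#' matching neither allele is a sequencing error and carries no parental
#' information). The read is called `maternal` if at least one site votes
#' maternal and none votes paternal, `paternal` symmetrically, `conflict`
#' if both sides receive votes, and `uninformative` if no site votes.
#' Conflict reads are excluded from the maternal/paternal tallies rather
#' than majority-voted: with short reads and ~200 bp SNP spacing multi-SNP
#' reads are rare, and exclusion cannot inflate the zygotic signal.
#'
#' @param reads Read tibble with `read_id`, `gene_id`, `start` (0-based
#'   transcript offset), `length`, `sequence`, and optionally `stage`
#'   (as produced by [simulate_reads()] or [place_reads()]).
#' @param snps SNP tibble in transcript coordinates (`chrom` = gene id),
#'   e.g. from [build_diploid_transcriptome()] or [project_snps()].
#' @param transcript_lengths Optional named vector; reads extending past
#'   their transcript end raise an error.
#' @return An assignment tibble: `read_id`, `gene_id`, `stage`,
#'   `informative_sites`, `maternal_matches`, `paternal_matches`,
#'   `neither_matches`, `call`.
#' @export
assign_reads <- function(reads, snps, transcript_lengths = NULL) {
  stopifnot(all(c("read_id", "gene_id", "start", "length", "sequence")
                %in% names(reads)))
  n <- nrow(reads)
  if (n == 0) {
    return(tibble(read_id = character(), gene_id = character(),
                  stage = character(), informative_sites = integer(),
                  maternal_matches = integer(), paternal_matches = integer(),
                  neither_matches = integer(), call = character()))
  }
  check_dna(reads$sequence, "read sequence")
  if (!is.null(transcript_lengths)) {
    tl <- transcript_lengths[reads$gene_id]
    over <- !is.na(tl) & (reads$start + reads$length > tl)
    if (any(over)) {
      stop("read '", reads$read_id[which(over)[1]],
           "' extends past the transcript end", call. = FALSE)
    }
  }
  snps <- dplyr::arrange(snps, .data$chrom, .data$pos)
  snp_by_gene <- split(seq_len(nrow(snps)), snps$chrom)

  n_sites <- integer(n)
  mm <- integer(n)
  pm <- integer(n)
  nm <- integer(n)
  read_idx_by_gene <- split(seq_len(n), reads$gene_id)
  for (g in names(read_idx_by_gene)) {
    ri <- read_idx_by_gene[[g]]
    si <- snp_by_gene[[g]]
    if (is.null(si)) next
    pos <- snps$pos[si]
    start <- reads$start[ri]
    lo <- findInterval(start - 0.5, pos) + 1L
    hi <- findInterval(start + reads$length[ri] - 0.5, pos)
    k <- pmax(hi - lo + 1L, 0L)
    n_sites[ri] <- k
    if (sum(k) == 0) next
    has <- k > 0
    ridx <- rep(ri[has], k[has])               # global read row
    sidx <- si[sequence(k[has], from = lo[has])]  # global SNP row
    off <- snps$pos[sidx] - reads$start[ridx]
    base <- substr(reads$sequence[ridx], off + 1, off + 1)
    is_m <- base == snps$maternal_allele[sidx]
    is_p <- base == snps$paternal_allele[sidx]
    add <- function(counts, flag) {
      t <- rowsum(as.integer(flag), group = ridx)
      counts[as.integer(rownames(t))] <- t[, 1]
      counts
    }
    mm <- add(mm, is_m)
    pm <- add(pm, is_p)
    nm <- add(nm, !is_m & !is_p)
  }
  call <- ifelse(mm + pm == 0, "uninformative",
          ifelse(mm > 0 & pm == 0, "maternal",
          ifelse(pm > 0 & mm == 0, "paternal", "conflict")))
  tibble(read_id = reads$read_id, gene_id = reads$gene_id,
         stage = if ("stage" %in% names(reads)) reads$stage
                 else NA_character_,
         informative_sites = n_sites, maternal_matches = mm,
         paternal_matches = pm, neither_matches = nm, call = call)
}

#' Place FASTQ reads on a transcriptome by exact substring match
#'
#' For input that arrives as plain FASTQ (no truth table), reads are placed
#' on the maternal or paternal transcript sequence at their unique exact
#' match. This is deliberately not an aligner: heuristic, mismatch-tolerant
#' alignment is off-the-shelf territory, and the contribution here is the
#' assignment step. Reads without an exact match on either haplotype (e.g.
#' reads carrying a sequencing error) are dropped; reads matching at more
#' than one location are dropped as ambiguous.
#'
#' @param fastq_path Path to a FASTQ file.
#' @param maternal,paternal Named character vectors of haplotype sequences.
#' @param stage Stage label stamped on the placed reads.
#' @return A read tibble suitable for [assign_reads()].
#' @export
place_reads <- function(fastq_path, maternal, paternal, stage = "c8") {
  fq <- Biostrings::readDNAStringSet(fastq_path, format = "fastq")
  seqs <- as.character(fq)
  ids <- sub(" .*", "", names(fq))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    hits <- list()
    for (g in names(maternal)) {
      for (hap in c("maternal", "paternal")) {
        subj <- if (hap == "maternal") maternal[[g]] else paternal[[g]]
        at <- gregexpr(seqs[i], subj, fixed = TRUE)[[1]]
        if (at[1] != -1) {
          for (a in at) hits[[length(hits) + 1]] <- c(g, a - 1L)
        }
      }
    }
    starts <- unique(vapply(hits, function(h) paste(h[1], h[2]),
                            character(1)))
    if (length(starts) != 1) next  # unmatched or ambiguous placement
    h <- strsplit(starts, " ")[[1]]
    out[[i]] <- tibble(read_id = ids[i], gene_id = h[1],
                       start = as.integer(h[2]),
                       length = nchar(seqs[i]), stage = stage,
                       sequence = seqs[i])
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(read_id = character(), gene_id = character(),
                  start = integer(), length = integer(),
                  stage = character(), sequence = character())
  }
  res
}

#' Swap SNP allele orientation for the reciprocal cross
#'
#' The SNP table's REF column is the allele of the line used as mother. In
#' the reciprocal cross the same line is the father, so maternal and
#' paternal alleles swap; samples from reciprocal crosses must be
#' re-oriented with this helper before their counts are merged.
#'
#' @param snps SNP tibble.
#' @param reciprocal Logical; if `TRUE`, swap the allele columns.
#' @return The (possibly re-oriented) SNP tibble.
#' @export
orient_snps <- function(snps, reciprocal = FALSE) {
  if (!reciprocal) return(snps)
  tibble(chrom = snps$chrom, pos = snps$pos,
         maternal_allele = snps$paternal_allele,
         paternal_allele = snps$maternal_allele)
}

#' Tabulate per-gene maternal/paternal read counts
#'
#' Counts assigned reads per gene and stage: `M` = reads called maternal,
#' `P` = paternal; conflict and uninformative reads land in
#' `uninformative`. Totals are conserved: `M + P + uninformative` equals
#' the number of input assignments for each (gene, stage).
#'
#' @param assignments Assignment tibble from [assign_reads()].
#' @param gene_models Optional gene model tibble; assignments referencing a
#'   gene absent from it raise an error.
#' @return Count tibble with `gene_id`, `stage`, `M`, `P`, `uninformative`.
#' @export
tabulate_counts <- function(assignments, gene_models = NULL) {
  if (nrow(assignments) == 0) {
    return(tibble(gene_id = character(), stage = character(),
                  M = integer(), P = integer(), uninformative = integer()))
  }
  if (!is.null(gene_models)) {
    unknown <- setdiff(unique(assignments$gene_id), gene_models$gene_id)
    if (length(unknown) > 0) {
      stop("assignment references unknown gene(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  assignments |>
    dplyr::group_by(.data$gene_id, .data$stage) |>
    dplyr::summarise(
      M = sum(.data$call == "maternal"),
      P = sum(.data$call == "paternal"),
      uninformative = sum(.data$call %in% c("conflict", "uninformative")),
      .groups = "drop")
}
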