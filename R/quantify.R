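#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM = count / ((length/1000) * (total/1e6))`. Vectorized over genes.
#'
#' @param count Per-gene read count (>= 0).
#' @param transcript_length_nt Transcript length in nt (> 0).
#' @param total_mapped_reads Total mapped reads in the sample (> 0).
#' @return RPKM value(s).
#' @export
#' @examples
#' rpkm(1000, 1000, 1e6)   # 1000
#' rpkm(40, 2000, 8e6)     # 2.5
rpkm <- function(count, transcript_length_nt, total_mapped_reads) {
  if (any(transcript_length_nt <= 0)) {
    stop("transcript_length_nt must be > 0", call. = FALSE)
  }
  if (any(total_mapped_reads <= 0)) {
    stop("total_mapped_reads must be > 0", call. = FALSE)
  }
  count / ((transcript_length_nt / 1000) * (total_mapped_reads / 1e6))
}

#' Normalize samples so total autosomal RPKM is constant
#'
#' Each sample is rescaled so that its summed autosomal-gene RPKM equals
#' that of the first sample (any constant would do; anchoring to sample 1
#' makes outputs reproducible). X-linked genes are scaled by their sample's
#' factor but never enter the constraint.
#'
#' @param quant Tibble with columns `sample`, `gene_id`, `rpkm`,
#'   `is_autosomal` (one row per gene per sample).
#' @return A list: `factors` (tibble `sample`, `scale_factor`) and
#'   `normalized` (the input with `rpkm` replaced by scaled values).
#' @export
normalize_autosomal <- function(quant) {
  stopifnot(all(c("sample", "gene_id", "rpkm", "is_autosomal")
                %in% names(quant)), nrow(quant) >= 1)
  samples <- unique(quant$sample)
  sums <- vapply(samples, function(s)
    sum(quant$rpkm[quant$sample == s & quant$is_autosomal]), numeric(1))
  if (any(sums <= 0)) {
    stop("sample '", samples[which(sums <= 0)[1]],
         "' has no autosomal signal (autosomal RPKM sum is 0)",
         call. = FALSE)
  }
  factors <- sums[1] / sums
  out <- quant
  out$rpkm <- out$rpkm * unname(factors)[match(out$sample, samples)]
  list(factors = tibble(sample = samples,
                        scale_factor = unname(factors)),
       normalized = out)
}
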