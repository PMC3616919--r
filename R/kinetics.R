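#' Kinetics configuration for expression feasibility
#'
#' Rates and the interphase window used to ask whether a transcript and its
#' protein can be produced within one short syncytial interphase. Defaults:
#' RNA polymerase II elongation 1500 nt/min (a measured fly rate; 4300
#' nt/min, a mammalian tissue-culture rate, is the common alternative),
#' translation 540 amino acids/min, and a 10-minute interphase window (the
#' early cycles are under ten minutes).
#'
#' @param elongation_rate Transcription elongation rate in nt/min (> 0).
#' @param translation_rate Translation rate in aa/min (> 0).
#' @param interphase_window Available window in minutes (> 0).
#' @return An object of class `kinetics_config`.
#' @export
kinetics_config <- function(elongation_rate = 1500, translation_rate = 540,
                            interphase_window = 10) {
  stopifnot(elongation_rate > 0, translation_rate > 0,
            interphase_window > 0)
  structure(list(elongation_rate = elongation_rate,
                 translation_rate = translation_rate,
                 interphase_window = interphase_window),
            class = "kinetics_config")
}

#' Minimum time to elongate a transcript
#'
#' @param length_nt Transcript length in nt (>= 0; vectorized).
#' @param elongation_rate Elongation rate in nt/min (> 0).
#' @return Time in minutes (`length / rate`).
#' @export
#' @examples
#' transcript_time(4207, 1500)  # ~2.8 min
#' transcript_time(4207, 4300)  # < 1 min
transcript_time <- function(length_nt, elongation_rate = 1500) {
  if (any(length_nt < 0)) stop("length_nt must be >= 0", call. = FALSE)
  if (any(elongation_rate <= 0)) {
    stop("elongation_rate must be > 0", call. = FALSE)
  }
  length_nt / elongation_rate
}

#' Minimum time to translate a protein
#'
#' @param length_aa Protein length in amino acids (>= 0; vectorized).
#' @param translation_rate Translation rate in aa/min (> 0).
#' @return Time in minutes (`length / rate`).
#' @export
#' @examples
#' protein_time(540, 540)  # 1 min
protein_time <- function(length_aa, translation_rate = 540) {
  if (any(length_aa < 0)) stop("length_aa must be >= 0", call. = FALSE)
  if (any(translation_rate <= 0)) {
    stop("translation_rate must be > 0", call. = FALSE)
  }
  length_aa / translation_rate
}

#' Is expression feasible within an interphase window?
#'
#' `TRUE` when the summed transcript and protein synthesis times fit within
#' the window, boundary inclusive (the question is feasibility, not a sharp
#' cutoff).
#'
#' @param transcript_minutes,protein_minutes Times in minutes (>= 0;
#'   vectorized).
#' @param window Window in minutes (default 10).
#' @return Logical.
#' @export
#' @examples
#' expression_feasible(2.8, 1.0)       # TRUE
#' expression_feasible(25, 0)          # FALSE
expression_feasible <- function(transcript_minutes, protein_minutes = 0,
                                window = 10) {
  if (any(transcript_minutes < 0) || any(protein_minutes < 0)) {
    stop("times must be >= 0", call. = FALSE)
  }
  transcript_minutes + protein_minutes <= window
}

#' Feasibility table for a set of gene models
#'
#' Computes, for each gene, the minimum transcript synthesis time (and
#' protein synthesis time when protein lengths are supplied) and whether
#' expression fits within the configured interphase window.
#'
#' @param gene_models Tibble with `gene_id` and `transcript_length_nt`
#'   (e.g. from [read_gene_models()]).
#' @param protein_lengths_aa Optional named numeric vector of protein
#'   lengths (aa); genes absent from it get protein time 0.
#' @param config A [kinetics_config()].
#' @return Tibble with `gene_id`, `transcript_length_nt`,
#'   `transcript_minutes`, `protein_minutes`, `total_minutes`, `feasible`.
#' @export
feasibility_table <- function(gene_models, protein_lengths_aa = NULL,
                              config = kinetics_config()) {
  tt <- transcript_time(gene_models$transcript_length_nt,
                        config$elongation_rate)
  pl <- if (is.null(protein_lengths_aa)) rep(0, nrow(gene_models)) else {
    x <- unname(protein_lengths_aa[gene_models$gene_id])
    ifelse(is.na(x), 0, x)
  }
  pt <- protein_time(pl, config$translation_rate)
  tibble(gene_id = gene_models$gene_id,
         transcript_length_nt = gene_models$transcript_length_nt,
         transcript_minutes = tt, protein_minutes = pt,
         total_minutes = tt + pt,
         feasible = expression_feasible(tt, pt, config$interphase_window))
}
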