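#' Classifier configuration
#'
#' Thresholds for the maternal/zygotic decision rule. A gene-stage with
#' fewer than `low_information_threshold` informative reads is
#' `low_information`. Otherwise it is called `zygotic` when its paternal
#' fraction is at least `min_paternal_fraction` *and* the (BH-adjusted)
#' one-sided binomial p-value for exceeding the sequencing-error ceiling is
#' at most `alpha`; else `maternal`. "Roughly equal" maternal/paternal
#' counts are deliberately *not* tested against 0.5: strongly unbalanced
#' but genuinely zygotic genes (a large maternal deposit plus zygotic
#' synthesis) would be wrongly rejected by a symmetric test.
#'
#' @param error_ceiling Top of the paternal fraction band attributable to
#'   sequencing error in a purely maternal transcript pool (default 0.01,
#'   i.e. 1%).
#' @param min_paternal_fraction Minimum paternal fraction for a zygotic
#'   call (default 0.10, the complement of a ">90% maternal" criterion).
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param min_informative_reads Informative reads required for a maternal
#'   call to be flagged confident (default 100); does not change the call.
#' @param low_information_threshold Below this many informative reads no
#'   call is attempted (default 5).
#' @param adjust_method Multiple-testing adjustment applied within each
#'   stage by [classify_table()] (default `"BH"`).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(error_ceiling = 0.01,
                              min_paternal_fraction = 0.10,
                              alpha = 0.05,
                              min_informative_reads = 100,
                              low_information_threshold = 5,
                              adjust_method = "BH") {
  stopifnot(error_ceiling > 0, min_paternal_fraction < 1,
            error_ceiling < min_paternal_fraction,
            alpha > 0, alpha < 1,
            min_informative_reads >= 0, low_information_threshold >= 1)
  structure(list(error_ceiling = error_ceiling,
                 min_paternal_fraction = min_paternal_fraction,
                 alpha = alpha,
                 min_informative_reads = min_informative_reads,
                 low_information_threshold = low_information_threshold,
                 adjust_method = adjust_method),
            class = "classifier_config")
}

#' @export
print.classifier_config <- function(x, ...) {
  cat("maternal/zygotic classifier config\n")
  cat(sprintf("  error ceiling p0:        %g\n", x$error_ceiling))
  cat(sprintf("  min paternal fraction:   %g\n", x$min_paternal_fraction))
  cat(sprintf("  alpha (adjusted):        %g\n", x$alpha))
  cat(sprintf("  min informative (conf.): %d\n",
              as.integer(x$min_informative_reads)))
  cat(sprintf("  low-information below N: %d\n",
              as.integer(x$low_information_threshold)))
  cat(sprintf("  adjustment:              %s (within stage)\n",
              x$adjust_method))
  invisible(x)
}

#' Paternal fraction of informative reads
#'
#' `P / (M + P)`; near 0 for maternal-only genes, around 0.5 for purely
#' zygotic genes with no maternal deposit.
#'
#' @param M,P Maternal- and paternal-assigned read counts.
#' @return The paternal fraction; errors when `M + P == 0` (callers must
#'   branch to `low_information` first).
#' @export
#' @examples
#' paternal_fraction(88, 83)
paternal_fraction <- function(M, P) {
  if (any(M < 0 | P < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(M + P == 0)) {
    stop("paternal fraction undefined for M + P == 0", call. = FALSE)
  }
  P / (M + P)
}

#' Exact one-sided binomial test for excess over the error ceiling
#'
#' Upper-tail probability `Pr[X >= P]` for `X ~ Binomial(M + P, p0)`: how
#' surprising the observed paternal count is if paternal-assigned reads
#' arose only from sequencing errors at rate `p0`.
#'
#' @param M,P Maternal- and paternal-assigned read counts (vectorized).
#' @param p0 Error ceiling, `0 < p0 < 1`.
#' @return Exact p-value(s).
#' @export
#' @examples
#' binomial_excess_p(10, 1, 0.01)  # 1 - 0.99^11
binomial_excess_p <- function(M, P, p0) {
  if (any(M < 0 | P < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(p0 <= 0 | p0 >= 1)) stop("p0 must be in (0, 1)", call. = FALSE)
  pbinom(P - 1, M + P, p0, lower.tail = FALSE)
}

# decision rule shared by classify_gene_stage and classify_table
decide_call <- function(N, frac, p_adj, config) {
  ifelse(N < config$low_information_threshold, "low_information",
  ifelse(!is.na(frac) & frac >= config$min_paternal_fraction &
         !is.na(p_adj) & p_adj <= config$alpha, "zygotic", "maternal"))
}

#' Classify one gene-stage as maternal or zygotic
#'
#' Applies the decision rule of [classifier_config()] to a single count
#' row. Because a single test needs no multiple-testing adjustment, the raw
#' binomial p-value is used here; [classify_table()] applies the configured
#' within-stage adjustment across genes.
#'
#' @param M,P Maternal- and paternal-assigned informative read counts.
#' @param gene_id,stage Identifiers carried through to the result.
#' @param config A [classifier_config()].
#' @return A one-row tibble: `gene_id`, `stage`, `N`, `paternal_fraction`,
#'   `p_value`, `p_adjusted`, `call`, `zygotic_fraction_estimate`
#'   (`min(1, 2P/N)`, the fraction of the gene's transcripts attributable
#'   to zygotic synthesis under balanced biallelic transcription atop a
#'   maternal-only deposit), `confident`.
#' @export
#' @examples
#' classify_gene_stage(88, 83, gene_id = "zen", stage = "c8")$call
classify_gene_stage <- function(M, P, gene_id = NA_character_,
                                stage = NA_character_,
                                config = classifier_config()) {
  stopifnot(length(M) == 1, length(P) == 1, M >= 0, P >= 0)
  N <- M + P
  frac <- if (N > 0) P / N else NA_real_
  p <- if (N > 0) binomial_excess_p(M, P, config$error_ceiling) else NA_real_
  call <- decide_call(N, frac, p, config)
  tibble(gene_id = gene_id, stage = stage, N = as.integer(N),
         paternal_fraction = frac, p_value = p, p_adjusted = p,
         call = call,
         zygotic_fraction_estimate = if (N > 0) min(1, 2 * P / N)
                                     else NA_real_,
         confident = call != "maternal" | N >= config$min_informative_reads)
}

#' Earliest stage at which a gene is called zygotic
#'
#' @param results Result tibble (one gene's rows, or many genes') with
#'   `gene_id`, `stage`, `call`. Rows flagged `exclude_from_onset` (if the
#'   column is present) are skipped.
#' @return Tibble `gene_id`, `onset_stage` (`NA` when no stage qualifies).
#' @export
call_onset <- function(results) {
  r <- results
  if ("exclude_from_onset" %in% names(r)) {
    r <- r[!r$exclude_from_onset, , drop = FALSE]
  }
  r |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(onset_stage = {
      z <- .data$stage[.data$call == "zygotic"]
      if (length(z) == 0) NA_character_
      else pipeline_stages()[min(match(z, pipeline_stages()))]
    }, .groups = "drop")
}

#' Classify a full count table
#'
#' Applies the maternal/zygotic decision to every row, with the configured
#' multiple-testing adjustment applied within each stage across the rows
#' that reach the testing threshold (low-information rows carry no
#' p-value). Gene-level onset stages are then called on rows not flagged
#' `exclude_from_onset`.
#'
#' @param rows Count tibble with `gene_id`, `stage`, `M`, `P` (extra
#'   columns such as `row_id`, `uninformative`, `exclude_from_onset` are
#'   carried through / honored).
#' @param config A [classifier_config()].
#' @return A list: `results` (per-row classification), `onset` (per-gene
#'   earliest zygotic stage) and `summary` (calls per stage).
#' @export
#' @examples
#' fx <- load_zygotic_gene_counts()
#' cl <- classify_table(fx$counts)
#' cl$summary
classify_table <- function(rows, config = classifier_config()) {
  empty <- tibble(gene_id = character(), stage = character(),
                  N = integer(), paternal_fraction = numeric(),
                  p_value = numeric(), p_adjusted = numeric(),
                  call = character(), zygotic_fraction_estimate = numeric(),
                  confident = logical())
  if (nrow(rows) == 0) {
    return(list(results = empty,
                onset = tibble(gene_id = character(),
                               onset_stage = character()),
                summary = tibble(stage = character(), call = character(),
                                 n = integer())))
  }
  validate_counts(dplyr::mutate(rows, uninformative =
    if ("uninformative" %in% names(rows)) rows$uninformative else 0L))
  N <- rows$M + rows$P
  frac <- ifelse(N > 0, rows$P / N, NA_real_)
  p <- rep(NA_real_, nrow(rows))
  tested <- N >= config$low_information_threshold
  p[N > 0] <- binomial_excess_p(rows$M[N > 0], rows$P[N > 0],
                                config$error_ceiling)
  p_adj <- rep(NA_real_, nrow(rows))
  for (st in unique(rows$stage)) {
    sel <- rows$stage == st & tested
    p_adj[sel] <- p.adjust(p[sel], method = config$adjust_method)
  }
  call <- decide_call(N, frac, p_adj, config)
  results <- tibble(
    gene_id = rows$gene_id, stage = rows$stage, N = as.integer(N),
    paternal_fraction = frac, p_value = p, p_adjusted = p_adj, call = call,
    zygotic_fraction_estimate = ifelse(N > 0, pmin(1, 2 * rows$P / N),
                                       NA_real_),
    confident = call != "maternal" | N >= config$min_informative_reads)
  if ("exclude_from_onset" %in% names(rows)) {
    results$exclude_from_onset <- rows$exclude_from_onset
  }
  if ("row_id" %in% names(rows)) results$row_id <- rows$row_id
  onset <- call_onset(results)
  results$exclude_from_onset <- NULL
  summary <- results |>
    dplyr::count(.data$stage, .data$call, name = "n") |>
    dplyr::arrange(match(.data$stage, pipeline_stages()), .data$call)
  list(results = results, onset = onset, summary = summary)
}

#' Sensitivity and specificity of zygotic calls against simulated truth
#'
#' Evaluates classifier calls against a truth table from a simulated panel:
#' sensitivity is the fraction of (zygotic gene, post-onset stage) pairs
#' called zygotic; specificity is the fraction of maternal-gene rows with
#' at least `min_n` informative reads not called zygotic. A stage is
#' post-onset when the gene's onset cycle is at or before the stage's last
#' pooled nuclear cycle.
#'
#' @param results Result tibble from [classify_table()].
#' @param truth Tibble with `gene_id`, `is_zygotic` (logical) and
#'   `onset_cycle` (for zygotic genes).
#' @param min_n Informative-read floor for the specificity denominator
#'   (default 100).
#' @return List with `sensitivity`, `specificity`, and the joined
#'   per-row table `detail`.
#' @export
evaluate_recovery <- function(results, truth, min_n = 100) {
  last_cycle <- vapply(results$stage, function(s) max(stage_cycles(s)),
                       numeric(1))
  d <- dplyr::left_join(results, truth, by = "gene_id")
  d$post_onset <- d$is_zygotic & d$onset_cycle <= last_cycle
  sens_rows <- d[d$post_onset %in% TRUE, , drop = FALSE]
  spec_rows <- d[!d$is_zygotic & d$N >= min_n, , drop = FALSE]
  list(
    sensitivity = if (nrow(sens_rows) == 0) NA_real_
                  else mean(sens_rows$call == "zygotic"),
    specificity = if (nrow(spec_rows) == 0) NA_real_
                  else mean(spec_rows$call != "zygotic"),
    detail = d
  )
}
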