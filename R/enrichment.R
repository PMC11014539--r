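#' Per-sample TCW enrichment and minimum APOBEC load
#'
#' Computes the APOBEC enrichment statistic for one sample:
#' \deqn{E_{TCW} = \frac{mut_{TCW}/ctx_{TCW}}{mut_C/ctx_C}}
#' where `mut_c` counts pyrimidine-frame C>T and C>G substitutions at any
#' cytosine (the SBS2+SBS13 chemistry; C>A is excluded), `mut_tcw` the subset
#' at TCW (W = A/T), and `ctx_*` are the motif-space denominators from
#' [count_motifs()]. The one-sided (greater) Fisher exact P tests enrichment
#' of TCW among the mutated cytosines against the context background. The
#' minimum APOBEC load is `mut_tcw * (E - 1)/E` for E > 1 and 0 otherwise —
#' the excess of TCW mutations over the background expectation, a lower bound
#' on the APOBEC-attributable burden.
#'
#' `q_bh` is filled by [cohort_adjust()]; for a lone sample it is `NA`.
#'
#' @param catalog a context-annotated [mutation_catalog()].
#' @param motifs a `motif_counts` object computed from the same reference.
#' @param alpha significance level used by [cohort_adjust()] (default 0.05).
#' @param motif the target trinucleotide class, `"TCW"` (default) or `"TCA"`
#'   (used by the tetranucleotide phenotype gate).
#' @return A one-row data frame of class `enrichment_result` with columns
#'   `sample_id`, `mut_tcw`, `mut_c`, `ctx_tcw`, `ctx_c`, `e_tcw`, `p_fisher`,
#'   `q_bh`, `apobec_load_min`, `apobec_load_min_rounded`, `enriched_flag`.
#' @export
tcw_enrichment <- function(catalog, motifs, alpha = 0.05, motif = c("TCW", "TCA")) {
  motif <- match.arg(motif)
  m <- catalog$mutations
  if (is.null(m$pyr_ref)) {
    stop_apobec("catalog must be context-annotated", class = "configuration_error")
  }
  ctx_tcw <- if (motif == "TCW") motifs$n_TCW else motifs$n_TCA
  ctx_c <- motifs$n_C
  if (is.na(ctx_tcw) || is.na(ctx_c) || ctx_tcw == 0 || ctx_c == 0) {
    stop_apobec("undefined enrichment statistic: zero motif denominator",
                class = "undefined_statistic")
  }
  ok <- (m$ok_context %||% TRUE) & m$pyr_ref == "C" & m$pyr_alt %in% c("T", "G")
  tri <- substr(m$context5, 2, 4)
  at_motif <- if (motif == "TCW") {
    substr(tri, 1, 1) == "T" & substr(tri, 3, 3) %in% c("A", "T")
  } else {
    tri == "TCA"
  }
  mut_c <- sum(ok, na.rm = TRUE)
  mut_tcw <- sum(ok & at_motif, na.rm = TRUE)
  e_tcw <- if (mut_c == 0) 0 else (mut_tcw / ctx_tcw) / (mut_c / ctx_c)
  p_fisher <- if (mut_c == 0) 1 else {
    tab <- matrix(c(mut_tcw, ctx_tcw, mut_c - mut_tcw, ctx_c - ctx_tcw), nrow = 2)
    stats::fisher.test(tab, alternative = "greater")$p.value
  }
  res <- data.frame(sample_id = catalog$sample_id,
                    mut_tcw = mut_tcw, mut_c = mut_c,
                    ctx_tcw = ctx_tcw, ctx_c = ctx_c,
                    e_tcw = e_tcw, p_fisher = p_fisher,
                    q_bh = NA_real_,
                    apobec_load_min = NA_real_,
                    apobec_load_min_rounded = NA_real_,
                    enriched_flag = NA,
                    stringsAsFactors = FALSE)
  class(res) <- c("enrichment_result", "data.frame")
  min_apobec_load(res)
}

#' Minimum APOBEC mutation-load estimate
#'
#' `apobec_load_min = mut_tcw * (e_tcw - 1)/e_tcw` when `e_tcw > 1`, else 0:
#' the TCW mutations in excess of what the background cytosine mutation rate
#' would place at TCW. Reported both raw and rounded (half-even) to an
#' integer.
#'
#' @param result an `enrichment_result` row from [tcw_enrichment()].
#' @return The result with `apobec_load_min` and `apobec_load_min_rounded`
#'   filled.
#' @export
min_apobec_load <- function(result) {
  load <- ifelse(result$e_tcw > 1,
                 result$mut_tcw * (result$e_tcw - 1) / result$e_tcw,
                 0)
  result$apobec_load_min <- load
  result$apobec_load_min_rounded <- round(load)
  result
}

#' Benjamini-Hochberg adjustment across a cohort
#'
#' Applies the BH step-up correction to the per-sample Fisher P-values and
#' sets `enriched_flag = q_bh < alpha` (default alpha 0.05), preserving input
#' order.
#'
#' @param results a list of `enrichment_result` rows, or one stacked data
#'   frame with a `p_fisher` column.
#' @param alpha significance level (default 0.05).
#' @return A stacked `enrichment_result` data frame with `q_bh` and
#'   `enriched_flag` filled.
#' @export
cohort_adjust <- function(results, alpha = 0.05) {
  if (is.data.frame(results)) {
    tab <- results
  } else {
    tab <- do.call(rbind, results)
  }
  if (nrow(tab) < 1) {
    stop_apobec("cohort_adjust needs at least one result", class = "configuration_error")
  }
  tab$q_bh <- stats::p.adjust(tab$p_fisher, method = "BH")
  tab$enriched_flag <- tab$q_bh < alpha
  class(tab) <- c("enrichment_result", "data.frame")
  tab
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result>", nrow(x), "sample(s)\n")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more row(s)\n")
  invisible(x)
}

#' Run enrichment across a cohort of catalogs
#'
#' Convenience wrapper: per-sample [count_motifs()] + [tcw_enrichment()]
#' followed by [cohort_adjust()].
#'
#' @param catalogs list of context-annotated catalogs.
#' @param reference FASTA path or `DNAStringSet`.
#' @param scope,window passed to [count_motifs()]. With `scope = "genome"` the
#'   motif denominators are computed once and shared.
#' @param alpha significance level.
#' @return A stacked `enrichment_result` data frame, one row per sample.
#' @export
enrich_cohort <- function(catalogs, reference, scope = "windows", window = 20,
                          alpha = 0.05) {
  reference <- load_reference(reference)
  shared <- if (scope == "genome") count_motifs(reference, scope = "genome") else NULL
  rows <- lapply(catalogs, function(cat) {
    motifs <- shared %||% count_motifs(reference, cat, window = window, scope = scope)
    tcw_enrichment(cat, motifs, alpha = alpha)
  })
  cohort_adjust(rows, alpha = alpha)
}
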