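#' Signature-attribution evidence of APOBEC activity
#'
#' A sample carries signature-level evidence of APOBEC mutagenesis when the
#' mutations attributed to SBS2 + SBS13 make up at least `frac_threshold` of
#' all its mutations (the commonly used 5% per-sample attribution threshold)
#' AND number at least `min_count` (50, the floor used when classifying
#' external cohorts).
#'
#' @param attr a list or one-row data frame with `sample_id`, `counts` (named
#'   numeric including `SBS2` and `SBS13`) and `total` (> 0).
#' @param frac_threshold fraction of total mutations (default 0.05).
#' @param min_count minimum SBS2+SBS13 count (default 50).
#' @return logical.
#' @export
signature_presence <- function(attr, frac_threshold = 0.05, min_count = 50) {
  counts <- attr$counts
  if (!all(c("SBS2", "SBS13") %in% names(counts))) {
    stop_apobec("attribution must include SBS2 and SBS13 (0 allowed)",
                class = "configuration_error")
  }
  if (is.null(attr$total) || attr$total <= 0) {
    stop_apobec("attribution total must be > 0", class = "domain_error")
  }
  apo <- counts[["SBS2"]] + counts[["SBS13"]]
  (apo / attr$total >= frac_threshold) && (apo >= min_count)
}

#' Two-evidence APOBEC subtype rule
#'
#' Decision table over the two detection routes — signature attribution
#' (`sig_present`) and motif enrichment (`enriched`):
#' both TRUE gives `"HAS"` (high APOBEC subtype), enrichment only gives
#' `"LAS"` (low APOBEC subtype), neither gives `"no_APOBEC"`. The remaining
#' cell (signature without enrichment) is unobserved in practice — the motif
#' test confirms essentially every signature-positive sample — and maps
#' conservatively to `"LAS"` with a discordance warning.
#'
#' @param sig_present logical, from [signature_presence()].
#' @param enriched logical, from the cohort-adjusted enrichment flag.
#' @return `"HAS"`, `"LAS"` or `"no_APOBEC"`. Vectorized.
#' @export
assign_subtype <- function(sig_present, enriched) {
  stopifnot(length(sig_present) == length(enriched))
  out <- ifelse(sig_present & enriched, "HAS",
         ifelse(!sig_present & !enriched, "no_APOBEC", "LAS"))
  if (any(sig_present & !enriched)) {
    warning(sum(sig_present & !enriched),
            " sample(s) signature-positive but motif-negative; called LAS")
  }
  out
}

#' YTCA/RTCA tetranucleotide phenotype statistics for one sample
#'
#' Counts APOBEC-type (pyrimidine-frame C>T/C>G) mutations in the TCA
#' trinucleotide context and splits them by the base 5' of the T: Y (C or T,
#' the APOBEC3A-favoured contexts) versus R (A or G, APOBEC3B-favoured).
#' Under random mutagenesis the expected YTCA count is the observed TCA
#' mutation total times the genomic fraction of TCA motifs that are YTCA; the
#' goodness-of-fit chi-square (1 df, no continuity correction) measures the
#' departure. Cohort-level BH correction and the final phenotype call are
#' made by [classify_phenotypes()].
#'
#' @param catalog a context-annotated [mutation_catalog()].
#' @param motifs a `motif_counts` with `n_YTCA`, `n_RTCA` (and `n_TCA`, `n_C`
#'   for the TCA-enrichment gate).
#' @return A one-row data frame: `sample_id`, `n_ytca`, `n_rtca`, `exp_ytca`,
#'   `exp_rtca`, `chi2`, `p_chi2`, `p_tca_fisher` (one-sided TCA-enrichment
#'   Fisher P, the gate statistic).
#' @export
ytca_rtca_classify <- function(catalog, motifs) {
  if (motifs$n_YTCA + motifs$n_RTCA == 0) {
    stop_apobec("no YTCA/RTCA motifs in context space", class = "domain_error")
  }
  m <- catalog$mutations
  if (is.null(m$context5)) {
    stop_apobec("catalog must be context-annotated", class = "configuration_error")
  }
  ok <- (m$ok_context %||% TRUE) & m$pyr_ref == "C" & m$pyr_alt %in% c("T", "G")
  tca <- ok & substr(m$context5, 2, 4) == "TCA"
  five <- substr(m$context5, 1, 1)
  n_ytca <- sum(tca & five %in% c("C", "T"), na.rm = TRUE)
  n_rtca <- sum(tca & five %in% c("A", "G"), na.rm = TRUE)
  n_obs <- n_ytca + n_rtca
  f_y <- motifs$n_YTCA / (motifs$n_YTCA + motifs$n_RTCA)
  exp_y <- n_obs * f_y
  exp_r <- n_obs * (1 - f_y)
  chi2 <- if (n_obs == 0 || exp_y == 0 || exp_r == 0) NA_real_ else {
    (n_ytca - exp_y)^2 / exp_y + (n_rtca - exp_r)^2 / exp_r
  }
  p_chi2 <- if (is.na(chi2)) NA_real_ else stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  gate <- tcw_enrichment(catalog, motifs, motif = "TCA")
  data.frame(sample_id = catalog$sample_id,
             n_ytca = n_ytca, n_rtca = n_rtca,
             exp_ytca = exp_y, exp_rtca = exp_r,
             chi2 = chi2, p_chi2 = p_chi2,
             p_tca_fisher = gate$p_fisher,
             stringsAsFactors = FALSE)
}

#' Cohort A3A-like / A3B-like phenotype calls
#'
#' Applies the two cohort-level BH corrections and the decision rule: a
#' sample is evaluable only if it is enriched for TCA mutations (one-sided
#' Fisher gate, BH Q < alpha, same machinery as the TCW test); among
#' evaluable samples the tetranucleotide chi-square P-values are BH-adjusted
#' and a significant sample is called `A3A_like` when YTCA is observed above
#' expectation, `A3B_like` when RTCA is. Everything else is `NA_pheno`.
#'
#' @param stats_tab stacked rows from [ytca_rtca_classify()].
#' @param alpha significance level (default 0.05).
#' @return `stats_tab` plus `tca_enriched`, `q_pheno` and `phenotype`
#'   (`"A3A_like"`, `"A3B_like"`, `"NA_pheno"`).
#' @export
classify_phenotypes <- function(stats_tab, alpha = 0.05) {
  stats_tab$tca_enriched <-
    stats::p.adjust(stats_tab$p_tca_fisher, method = "BH") < alpha
  stats_tab$q_pheno <- NA_real_
  eligible <- stats_tab$tca_enriched & !is.na(stats_tab$p_chi2)
  if (any(eligible)) {
    stats_tab$q_pheno[eligible] <-
      stats::p.adjust(stats_tab$p_chi2[eligible], method = "BH")
  }
  sig <- !is.na(stats_tab$q_pheno) & stats_tab$q_pheno < alpha
  stats_tab$phenotype <- ifelse(
    sig & stats_tab$n_ytca > stats_tab$exp_ytca, "A3A_like",
    ifelse(sig & stats_tab$n_rtca > stats_tab$exp_rtca, "A3B_like", "NA_pheno"))
  stats_tab
}

#' Full subtype + phenotype calls for a cohort
#'
#' Combines enrichment results, signature attributions and the
#' tetranucleotide statistics into one call table.
#'
#' @param enrichment cohort-adjusted `enrichment_result` data frame.
#' @param attributions data frame with columns `sample_id`, `signature`,
#'   `count` (long form) covering at least SBS2 and SBS13, plus a `total`
#'   column or the convention that rows sum to the total.
#' @param pheno_stats stacked rows from [ytca_rtca_classify()], matching
#'   sample ids (optional; phenotype columns are NA when absent).
#' @param frac_threshold,min_count passed to [signature_presence()].
#' @param alpha significance level.
#' @return A data frame of class `subtype_call`, one row per sample:
#'   `sample_id`, `sig_present`, `enriched`, `subtype`, plus the phenotype
#'   columns when `pheno_stats` is given.
#' @export
call_subtypes <- function(enrichment, attributions, pheno_stats = NULL,
                          frac_threshold = 0.05, min_count = 50, alpha = 0.05) {
  ids <- enrichment$sample_id
  sig_present <- vapply(ids, function(id) {
    rows <- attributions[attributions$sample_id == id, , drop = FALSE]
    if (nrow(rows) == 0) {
      stop_apobec("no signature attribution for sample %s", id,
                  class = "configuration_error")
    }
    counts <- stats::setNames(rows$count, rows$signature)
    for (s in c("SBS2", "SBS13")) if (!s %in% names(counts)) counts[s] <- 0
    total <- if ("total" %in% names(rows)) rows$total[1] else sum(rows$count)
    signature_presence(list(counts = counts, total = total),
                       frac_threshold = frac_threshold, min_count = min_count)
  }, logical(1))
  out <- data.frame(sample_id = ids,
                    sig_present = unname(sig_present),
                    enriched = enrichment$enriched_flag,
                    stringsAsFactors = FALSE)
  out$subtype <- assign_subtype(out$sig_present, out$enriched)
  if (!is.null(pheno_stats)) {
    ph <- classify_phenotypes(pheno_stats, alpha = alpha)
    out <- merge(out, ph, by = "sample_id", sort = FALSE)
  }
  class(out) <- c("subtype_call", "data.frame")
  out
}

#' @export
print.subtype_call <- function(x, ...) {
  cat("<subtype_call>", nrow(x), "sample(s):",
      paste(names(table(x$subtype)), table(x$subtype), sep = "=", collapse = " "),
      "\n")
  if ("phenotype" %in% names(x)) {
    cat("  phenotype:",
        paste(names(table(x$phenotype)), table(x$phenotype), sep = "=", collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Subtype-association regression for a binary genomic feature
#'
#' Logistic regression of a binary outcome (e.g. nonsynonymous driver-gene
#' mutation status) on subtype, adjusted for covariates; alongside, the
#' unadjusted two-sided Fisher exact test on the 2x2 subtype-by-outcome
#' table. Complete separation is flagged (`converged = FALSE`) rather than
#' silently dropped.
#'
#' @param feature_table data frame with `outcome` (0/1), `subtype` (factor or
#'   character; the second level is the exposure of interest) and any
#'   covariate columns named in `covariates`.
#' @param covariates character vector of covariate column names (default
#'   none).
#' @return A one-row data frame: `log_or`, `ci_lo`, `ci_hi`, `p_wald`,
#'   `or_fisher`, `p_fisher`, `converged`.
#' @export
subtype_association <- function(feature_table, covariates = character(0)) {
  stopifnot(all(c("outcome", "subtype") %in% names(feature_table)))
  ft <- feature_table
  ft$subtype <- factor(ft$subtype)
  if ("LAS" %in% levels(ft$subtype)) {
    ft$subtype <- stats::relevel(ft$subtype, ref = "LAS")  # HAS vs LAS odds
  }
  if (nlevels(ft$subtype) != 2 || min(table(ft$subtype)) < 2) {
    stop_apobec("need two subtype levels with >= 2 samples each",
                class = "configuration_error")
  }
  tab <- table(ft$subtype, factor(ft$outcome, levels = c(0, 1)))
  if (any(colSums(tab) == 0)) {
    # degenerate outcome (identical in both subtypes): no association
    fish <- list(estimate = c(odds_ratio = 1), p.value = 1)
  } else {
    fish <- stats::fisher.test(tab, alternative = "two.sided")
  }
  form <- stats::as.formula(paste("outcome ~ subtype",
                                  if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""))
  fit <- suppressWarnings(stats::glm(form, data = ft, family = stats::binomial()))
  co <- summary(fit)$coefficients
  row <- grep("^subtype", rownames(co))[1]
  est <- co[row, "Estimate"]; se <- co[row, "Std. Error"]
  separated <- !fit$converged || abs(est) > 10 || se > 10
  data.frame(log_or = est,
             ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
             p_wald = co[row, "Pr(>|z|)"],
             or_fisher = unname(fish$estimate), p_fisher = fish$p.value,
             converged = !separated,
             stringsAsFactors = FALSE)
}
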