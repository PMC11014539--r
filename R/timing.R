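#' Count clock-like CpG>TpG mutations
#'
#' Clock-like (SBS1-type) mutations are pyrimidine-frame C>T substitutions in
#' an NpCpG context — the central trinucleotide of the annotated 5-base
#' context is N-C-G. Counts are split by clonality (`ccf >= clonal_threshold`
#' is clonal); mutations with unknown clonality are excluded with a message,
#' and a catalog with no resolved clonality at all is refused since the
#' timing model cannot run on it.
#'
#' @param catalog a context-annotated [mutation_catalog()] with CCF.
#' @param clonal_threshold CCF at or above which a mutation is clonal
#'   (default 0.8).
#' @return A one-row data frame: `sample_id`, `n_clock_clonal`,
#'   `n_clock_subclonal`, `n_clock_unknown`, plus `age_dx`, `purity`,
#'   `ploidy`, `nrpcc` pulled from the catalog metadata when present.
#' @export
count_clock_mutations <- function(catalog, clonal_threshold = 0.8) {
  m <- catalog$mutations
  if (is.null(m$context5)) {
    stop_apobec("catalog must be context-annotated", class = "configuration_error")
  }
  flag <- ifelse(is.na(m$ccf), "unknown",
                 ifelse(m$ccf >= clonal_threshold, "clonal", "subclonal"))
  if (nrow(m) > 0 && all(flag == "unknown")) {
    stop_apobec(paste("all mutations have unknown clonality; supply CCF",
                      "(clonality-dependent stages refuse to guess)"),
                class = "configuration_error")
  }
  is_clock <- (m$ok_context %||% TRUE) & m$pyr_ref == "C" & m$pyr_alt == "T" &
    substr(m$context5, 4, 4) == "G"
  n_unknown <- sum(is_clock & flag == "unknown", na.rm = TRUE)
  if (n_unknown > 0) {
    message(n_unknown, " clock mutation(s) with unknown clonality excluded")
  }
  md <- catalog$metadata
  data.frame(sample_id = catalog$sample_id,
             n_clock_clonal = sum(is_clock & flag == "clonal", na.rm = TRUE),
             n_clock_subclonal = sum(is_clock & flag == "subclonal", na.rm = TRUE),
             n_clock_unknown = n_unknown,
             age_dx = md$age %||% NA_real_,
             purity = md$purity %||% NA_real_,
             ploidy = md$ploidy %||% NA_real_,
             nrpcc = md$nrpcc %||% NA_real_,
             stringsAsFactors = FALSE)
}

#' Partially pooled clock-mutation rate model
#'
#' Relates the clonal clock burden to age at diagnosis. The diploid-
#' equivalent burden `n_clock_clonal / (ploidy/2)` is modelled as Poisson
#' with mean `r_i * age_i`, where the per-sample rates `r_i` are partially
#' pooled around a cohort-level rate with log-normal spread — fit as a
#' Poisson generalized linear mixed model with a per-sample random intercept
#' and `log(age * ploidy/2)` offset. Purity enters upstream through the
#' CCF-based clonality threshold, not as a divisor (avoiding double
#' correction); low-quality samples are excluded before fitting (defaults:
#' purity > 0.3, and NRPCC > 10 when NRPCC is available).
#'
#' @param cohort stacked rows from [count_clock_mutations()] (needs `age_dx`,
#'   `ploidy`; `purity`/`nrpcc` used for filtering).
#' @param purity_min exclude samples with purity <= this (default 0.3).
#' @param nrpcc_min exclude samples with NRPCC <= this when NRPCC is present
#'   (default 10).
#' @param level width of the per-sample rate intervals (default 0.90).
#' @return An object of class `clock_model`: `cohort_rate` (mutations per
#'   year per diploid genome, at the cohort log-scale centre), `sigma_log`
#'   (log-normal spread), `rates` (per-sample data frame with `rate`, `lo`,
#'   `hi`), `n_used`, `n_excluded`, `converged`, and the underlying `fit`.
#' @export
fit_clock_model <- function(cohort, purity_min = 0.3, nrpcc_min = 10,
                            level = 0.90) {
  keep <- !is.na(cohort$age_dx) & cohort$age_dx > 0 &
    !is.na(cohort$ploidy) & cohort$ploidy > 0 &
    (is.na(cohort$purity) | cohort$purity > purity_min) &
    (is.na(cohort$nrpcc) | cohort$nrpcc > nrpcc_min)
  d <- cohort[keep, , drop = FALSE]
  if (nrow(d) < 10) {
    stop_apobec("fewer than 10 usable samples after quality filtering (%d)",
                nrow(d), class = "configuration_error")
  }
  d$offset_log <- log(d$age_dx * d$ploidy / 2)
  fit_once <- function(nAGQ) {
    lme4::glmer(n_clock_clonal ~ 1 + (1 | sample_id),
                offset = offset_log, data = d,
                family = stats::poisson(), nAGQ = nAGQ,
                control = lme4::glmerControl(check.conv.singular = "ignore"))
  }
  # Laplace first, then the more robust PIRLS-only fit; a cohort with no
  # between-sample rate variance defeats the mixed model's inner loop, in
  # which case the pooled Poisson GLM is the exact limiting model
  fit <- tryCatch(fit_once(1L),
                  error = function(e) tryCatch(fit_once(0L),
                                               error = function(e2) NULL))
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (is.null(fit)) {
    fit <- stats::glm(n_clock_clonal ~ 1 + offset(offset_log), data = d,
                      family = stats::poisson())
    beta0 <- unname(stats::coef(fit)[1])
    se0 <- summary(fit)$coefficients[1, "Std. Error"]
    sigma_log <- 0
    converged <- fit$converged
    rates <- data.frame(sample_id = d$sample_id,
                        rate = exp(beta0),
                        lo = exp(beta0 - z * se0),
                        hi = exp(beta0 + z * se0),
                        stringsAsFactors = FALSE)
  } else {
    msgs <- fit@optinfo$conv$lme4$messages
    converged <- is.null(msgs) || length(msgs) == 0
    beta0 <- unname(lme4::fixef(fit)[1])
    sigma_log <- sqrt(unname(lme4::VarCorr(fit)$sample_id[1]))
    re <- lme4::ranef(fit, condVar = TRUE)$sample_id
    condsd <- sqrt(as.numeric(attr(re, "postVar")))
    log_r <- beta0 + re[["(Intercept)"]]
    rates <- data.frame(sample_id = rownames(re),
                        rate = exp(log_r),
                        lo = exp(log_r - z * condsd),
                        hi = exp(log_r + z * condsd),
                        stringsAsFactors = FALSE)
  }
  structure(list(cohort_rate = exp(beta0), sigma_log = sigma_log,
                 rates = rates, n_used = nrow(d),
                 n_excluded = sum(!keep), level = level,
                 converged = converged, fit = fit),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat("<clock_model> cohort clock rate:",
      format(x$cohort_rate, digits = 4), "mutations/year (diploid-equivalent)\n")
  cat("  log-normal spread sigma:", format(x$sigma_log, digits = 3),
      " samples used:", x$n_used,
      if (x$n_excluded) paste0(" (", x$n_excluded, " excluded)"), "\n")
  if (!x$converged) cat("  WARNING: fit did not cleanly converge\n")
  invisible(x)
}

#' @export
coef.clock_model <- function(object, ...) {
  c(cohort_rate = object$cohort_rate, sigma_log = object$sigma_log)
}

#' MRCA age and tumor latency from subclonal clock burden
#'
#' Subclonal clock-like mutations accumulate between the emergence of the
#' most recent common ancestor (MRCA) and diagnosis, at the per-sample clock
#' rate accelerated by a factor `acceleration` (default 5, reflecting the
#' elevated mutational burden of the expanding tumor). The latency is the
#' diploid-equivalent subclonal clock burden divided by `rate *
#' acceleration`, and the MRCA age is the age at diagnosis minus the
#' latency, floored at zero with a flag. Doubling the acceleration exactly
#' halves the latency. Uncertainty is propagated from the per-sample rate
#' interval.
#'
#' @param clock one row from [count_clock_mutations()].
#' @param rate per-sample rate estimate; either a scalar or the matching row
#'   of `clock_model$rates` (then intervals propagate).
#' @param acceleration multiplier A >= 1 (default 5).
#' @return A one-row data frame: `sample_id`, `latency_years`,
#'   `latency_lo`, `latency_hi`, `mrca_age`, `floored`.
#' @export
estimate_mrca <- function(clock, rate, acceleration = 5) {
  if (acceleration < 1) stop_apobec("acceleration must be >= 1", class = "domain_error")
  if (is.data.frame(rate)) {
    r <- rate$rate; r_lo <- rate$lo; r_hi <- rate$hi
  } else {
    r <- rate; r_lo <- NA_real_; r_hi <- NA_real_
  }
  if (any(r <= 0)) stop_apobec("rate must be > 0", class = "domain_error")
  burden <- clock$n_clock_subclonal / (clock$ploidy / 2)
  latency <- burden / (r * acceleration)
  mrca <- clock$age_dx - latency
  floored <- !is.na(mrca) & mrca < 0
  mrca[floored] <- 0
  data.frame(sample_id = clock$sample_id,
             latency_years = latency,
             latency_lo = burden / (r_hi * acceleration),
             latency_hi = burden / (r_lo * acceleration),
             mrca_age = mrca,
             floored = floored,
             stringsAsFactors = FALSE)
}

#' Cohort MRCA/latency table
#'
#' Convenience wrapper joining [fit_clock_model()] per-sample rates with
#' [estimate_mrca()] across a cohort.
#'
#' @param cohort stacked rows from [count_clock_mutations()].
#' @param model a fitted `clock_model`.
#' @param acceleration passed to [estimate_mrca()].
#' @return Data frame, one row per sample that entered the model.
#' @export
estimate_mrca_cohort <- function(cohort, model, acceleration = 5) {
  rows <- lapply(seq_len(nrow(model$rates)), function(i) {
    id <- model$rates$sample_id[i]
    estimate_mrca(cohort[cohort$sample_id == id, , drop = FALSE],
                  model$rates[i, , drop = FALSE], acceleration = acceleration)
  })
  do.call(rbind, rows)
}
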