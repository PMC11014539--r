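#' Build a binned mutation-density matrix
#'
#' Counts a sample's mutations into non-overlapping genomic bins and attaches
#' the per-bin covariates and cell-type expression centroids used by the
#' cell-of-origin regression. Internally bins are 1-based inclusive
#' `[start, end]`; a BED-style 0-based half-open `[start0, end0)` bin file
#' maps to `start = start0 + 1, end = end0`.
#'
#' @param catalog a [mutation_catalog()].
#' @param bins data frame with `chrom`, `start`, `end` (1-based inclusive).
#' @param covariate_table data frame, one row per bin, with
#'   `replication_timing`, `gc_fraction`, `mean_expression`,
#'   `log_intronic_fraction`, `log_exonic_fraction` (rows align with `bins`).
#' @param centroid_table data frame or matrix, one row per bin, one column
#'   per cell type, holding log-scale expression centroid values.
#' @return An object of class `bin_matrix`: `bins`, `counts`, `covariates`,
#'   `centroids`, `sample_id`, `n_dropped` (bins lost to missing
#'   covariates).
#' @export
build_bin_matrix <- function(catalog, bins, covariate_table, centroid_table) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bins)))
  centroid_table <- as.data.frame(centroid_table)
  stopifnot(nrow(covariate_table) == nrow(bins),
            nrow(centroid_table) == nrow(bins))
  # overlap validation within chromosome
  for (chrom in unique(bins$chrom)) {
    b <- bins[bins$chrom == chrom, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) > 1 && any(b$start[-1] <= b$end[-nrow(b)])) {
      stop_apobec("overlapping bins on %s", chrom, class = "validation_error")
    }
  }
  counts <- integer(nrow(bins))
  m <- catalog$mutations
  for (i in seq_len(nrow(bins))) {
    counts[i] <- sum(m$chrom == bins$chrom[i] &
                     m$pos >= bins$start[i] & m$pos <= bins$end[i])
  }
  complete <- stats::complete.cases(covariate_table) & stats::complete.cases(centroid_table)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(n_dropped, " bin(s) dropped for missing covariates")
  }
  structure(list(bins = bins[complete, , drop = FALSE],
                 counts = counts[complete],
                 covariates = covariate_table[complete, , drop = FALSE],
                 centroids = centroid_table[complete, , drop = FALSE],
                 sample_id = catalog$sample_id,
                 n_dropped = n_dropped),
            class = "bin_matrix")
}

#' Assemble a bin matrix from precomputed counts
#'
#' Direct constructor for when per-bin counts already exist (e.g. the
#' simulator's Gamma-Poisson bin counts) rather than being tallied from a
#' catalog.
#'
#' @param counts integer vector, one count per bin.
#' @param bins,covariates,centroids as in [build_bin_matrix()].
#' @param sample_id sample identifier.
#' @return A `bin_matrix`.
#' @export
bin_matrix <- function(counts, bins, covariates, centroids, sample_id = "sample") {
  stopifnot(length(counts) == nrow(bins),
            nrow(covariates) == nrow(bins),
            nrow(as.data.frame(centroids)) == nrow(bins))
  structure(list(bins = bins, counts = as.integer(counts),
                 covariates = covariates,
                 centroids = as.data.frame(centroids),
                 sample_id = sample_id, n_dropped = 0L),
            class = "bin_matrix")
}

#' Gamma-Poisson regression of mutation density on one expression centroid
#'
#' Fits, by maximum likelihood, `count ~ GammaPoisson(mu, phi)` with
#' `log mu = b0 + b1 * centroid + gamma * covariates` and variance
#' `mu + phi * mu^2` (negative binomial; `phi = 1/theta`). The relative risk
#' `rr = exp(b1)` measures how mutation density scales with the cell type's
#' expression; Wald 95% intervals are computed on the log scale. A separate
#' regression is fitted for each cell type.
#'
#' @param matrix_obj a `bin_matrix` from [build_bin_matrix()].
#' @param cell_type column name of `matrix_obj$centroids`.
#' @return A one-row data frame: `cell_type`, `rr`, `ci_lo`, `ci_hi`,
#'   `beta1`, `se`, `phi`, `converged`.
#' @export
fit_coo_regression <- function(matrix_obj, cell_type) {
  stopifnot(inherits(matrix_obj, "bin_matrix"))
  if (!cell_type %in% names(matrix_obj$centroids)) {
    stop_apobec("unknown cell type '%s'", cell_type, class = "configuration_error")
  }
  if (length(matrix_obj$counts) < 50) {
    stop_apobec("need >= 50 bins, have %d", length(matrix_obj$counts),
                class = "configuration_error")
  }
  if (sum(matrix_obj$counts) == 0) {
    stop_apobec("all bin counts are zero", class = "configuration_error")
  }
  centroid <- matrix_obj$centroids[[cell_type]]
  if (stats::sd(centroid) == 0) {
    return(data.frame(cell_type = cell_type, rr = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_, beta1 = NA_real_, se = NA_real_,
                      phi = NA_real_, converged = FALSE,
                      stringsAsFactors = FALSE))
  }
  d <- data.frame(count = matrix_obj$counts, centroid = centroid,
                  matrix_obj$covariates)
  form <- stats::as.formula(paste("count ~ centroid +",
                                  paste(names(matrix_obj$covariates), collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(form, data = d, control = stats::glm.control(maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(data.frame(cell_type = cell_type, rr = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_, beta1 = NA_real_, se = NA_real_,
                      phi = NA_real_, converged = FALSE,
                      stringsAsFactors = FALSE))
  }
  co <- summary(fit)$coefficients
  b1 <- co["centroid", "Estimate"]; se <- co["centroid", "Std. Error"]
  data.frame(cell_type = cell_type,
             rr = exp(b1),
             ci_lo = exp(b1 - 1.96 * se), ci_hi = exp(b1 + 1.96 * se),
             beta1 = b1, se = se,
             phi = 1 / fit$theta,
             converged = isTRUE(fit$converged),
             stringsAsFactors = FALSE)
}

# proximal airway vs distal alveolar lung lineages
.COO_CLASS <- c(Club = "proximal", Basal = "proximal", Ciliated = "proximal",
                Goblet = "proximal", Neuroendocrine = "proximal",
                AT1 = "distal", AT2 = "distal")

#' Cell-of-origin call from per-cell-type relative risks
#'
#' Fits one Gamma-Poisson regression per cell type and calls the cell of
#' origin as the type with the smallest relative risk — the strongest
#' depletion of mutations in that type's highly expressed regions, the
#' expressed-region hypomutation convention (invertible via `convention =
#' "enrichment"`). Ties are broken by the narrower confidence interval. Cell
#' types in the default seven-type lung schema map onto a proximal/distal
#' class.
#'
#' @param matrix_obj a `bin_matrix`.
#' @param cell_types which centroid columns to fit (default all).
#' @param convention `"depletion"` (argmin rr, default) or `"enrichment"`
#'   (argmax rr).
#' @return An object of class `coo_result`: `sample_id`, `rr_table` (one row
#'   per converged cell type), `coo_call`, `class_call` (`"proximal"`,
#'   `"distal"` or `NA` for unknown schemas).
#' @export
assign_coo <- function(matrix_obj, cell_types = names(matrix_obj$centroids),
                       convention = c("depletion", "enrichment")) {
  convention <- match.arg(convention)
  rr_table <- do.call(rbind, lapply(cell_types, function(ct) {
    fit_coo_regression(matrix_obj, ct)
  }))
  ok <- rr_table[rr_table$converged & !is.na(rr_table$rr), , drop = FALSE]
  if (nrow(ok) < 2) {
    stop_apobec("fewer than 2 converged cell-type fits", class = "configuration_error")
  }
  target <- if (convention == "depletion") ok$rr else -ok$rr
  best <- which(target == min(target))
  if (length(best) > 1) {
    width <- ok$ci_hi[best] - ok$ci_lo[best]
    best <- best[which.min(width)]
    message("tie in rr broken by narrower confidence interval")
  }
  call <- ok$cell_type[best]
  structure(list(sample_id = matrix_obj$sample_id,
                 rr_table = rr_table,
                 coo_call = call,
                 class_call = unname(.COO_CLASS[call])),
            class = "coo_result")
}

#' @export
print.coo_result <- function(x, ...) {
  cat("<coo_result> sample", x$sample_id, "->", x$coo_call,
      if (!is.na(x$class_call %||% NA)) paste0("(", x$class_call, ")"), "\n")
  print.data.frame(x$rr_table, digits = 3)
  invisible(x)
}

#' Compare cell-of-origin calls between subtypes
#'
#' Builds the proximal/distal by subtype 2x2 table with a two-sided Fisher
#' exact test, and the per-cell-type median relative risk by subtype.
#'
#' @param coo_results list of `coo_result` objects.
#' @param subtype_calls data frame with `sample_id`, `subtype`.
#' @return A list: `table` (2x2), `or`, `p_fisher`, `median_rr` (cell type x
#'   subtype matrix).
#' @export
compare_coo_subtypes <- function(coo_results, subtype_calls) {
  ids <- vapply(coo_results, `[[`, character(1), "sample_id")
  cls <- vapply(coo_results, function(x) x$class_call %||% NA_character_, character(1))
  sub <- subtype_calls$subtype[match(ids, subtype_calls$sample_id)]
  keep <- !is.na(cls) & !is.na(sub)
  tab <- table(class = factor(cls[keep], levels = c("proximal", "distal")),
               subtype = factor(sub[keep]))
  fish <- if (all(dim(tab) == c(2, 2)) && all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    stats::fisher.test(tab)
  } else {
    list(estimate = NA_real_, p.value = NA_real_)
  }
  rr_long <- do.call(rbind, lapply(seq_along(coo_results), function(i) {
    rt <- coo_results[[i]]$rr_table
    rt$subtype <- sub[i]
    rt
  }))
  rr_long <- rr_long[!is.na(rr_long$subtype) & !is.na(rr_long$rr), , drop = FALSE]
  med <- tapply(rr_long$rr, list(rr_long$cell_type, rr_long$subtype),
                stats::median)
  list(table = tab, or = unname(fish$estimate), p_fisher = fish$p.value,
       median_rr = med)
}
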