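# small synthetic design shared by the COO tests
coo_design <- function(nb = 200, seed = 1, cell_types = c("AT2", "Basal")) {
  set.seed(seed)
  bins <- data.frame(chrom = "chr1",
                     start = (seq_len(nb) - 1L) * 100L + 1L,
                     end = seq_len(nb) * 100L)
  centroids <- as.data.frame(matrix(rnorm(nb * length(cell_types)), nrow = nb,
                                    dimnames = list(NULL, cell_types)))
  covariates <- data.frame(replication_timing = rnorm(nb),
                           gc_fraction = runif(nb, 0.3, 0.6),
                           mean_expression = rowMeans(centroids),
                           log_intronic_fraction = log(runif(nb, 0.2, 0.8)),
                           log_exonic_fraction = log(runif(nb, 0.01, 0.2)))
  list(bins = bins, centroids = centroids, covariates = covariates)
}

gp_counts <- function(design, target, beta1, phi, b0 = 3) {
  mu <- exp(b0 + beta1 * design$centroids[[target]])
  rnbinom(nrow(design$bins), mu = mu, size = 1 / phi)
}

test_that("bin counting follows the interval convention", {
  bins <- data.frame(chrom = "chr1", start = c(1L, 11L, 21L), end = c(10L, 20L, 30L))
  cov <- data.frame(replication_timing = 0, gc_fraction = 0.5,
                    mean_expression = 0, log_intronic_fraction = -1,
                    log_exonic_fraction = -2)[rep(1, 3), ]
  cen <- data.frame(AT2 = c(0, 1, 2), Basal = c(2, 1, 0))
  cat1 <- tiny_catalog(c(5, 15, 25), rep("C", 3), rep("T", 3))
  bm <- build_bin_matrix(cat1, bins, cov, cen)
  expect_equal(bm$counts, c(1L, 1L, 1L))

  # BED-style boundary: half-open [0,10) holds 1-based position 10
  cat2 <- tiny_catalog(10, "C", "T")
  bm2 <- build_bin_matrix(cat2, bins, cov, cen)
  expect_equal(bm2$counts, c(1L, 0L, 0L))

  bad <- bins; bad$start[2] <- 5L
  expect_error(build_bin_matrix(cat1, bad, cov, cen), class = "validation_error")

  cov_na <- cov; cov_na$gc_fraction[2] <- NA
  expect_message(bm3 <- build_bin_matrix(cat1, bins, cov_na, cen), "dropped")
  expect_equal(length(bm3$counts), 2)
})

test_that("counts built against a depleting centroid correlate negatively", {
  d <- coo_design(nb = 400, seed = 2)
  y <- gp_counts(d, "AT2", beta1 = -0.8, phi = 0.2)
  expect_lt(cor(y, d$centroids$AT2, method = "spearman"), -0.3)
})

test_that("Gamma-Poisson fit recovers the centroid coefficient", {
  d <- coo_design(nb = 500, seed = 3)
  set.seed(3)
  y <- gp_counts(d, "AT2", beta1 = -0.5, phi = 0.3)
  bm <- bin_matrix(y, d$bins, d$covariates, d$centroids)
  fit <- fit_coo_regression(bm, "AT2")
  expect_true(fit$converged)
  expect_lt(abs(fit$beta1 - (-0.5)), 0.15)
  expect_true(fit$ci_lo < exp(-0.5) && exp(-0.5) < fit$ci_hi)
  expect_lt(abs(fit$phi - 0.3), 0.15)

  # degenerate constant centroid is flagged
  d2 <- d; d2$centroids$AT2 <- 1
  bm2 <- bin_matrix(y, d2$bins, d2$covariates, d2$centroids)
  expect_false(fit_coo_regression(bm2, "AT2")$converged)
})

test_that("rr is invariant to centroid translation (absorbed by intercept)", {
  d <- coo_design(nb = 300, seed = 4)
  set.seed(4)
  y <- gp_counts(d, "AT2", beta1 = -0.5, phi = 0.3)
  bm <- bin_matrix(y, d$bins, d$covariates, d$centroids)
  f1 <- fit_coo_regression(bm, "AT2")
  d$centroids$AT2 <- d$centroids$AT2 + 7
  d$covariates$mean_expression <- rowMeans(d$centroids)
  bm_shift <- bin_matrix(y, d$bins, d$covariates, d$centroids)
  f2 <- fit_coo_regression(bm_shift, "AT2")
  expect_equal(f1$rr, f2$rr, tolerance = 1e-4)
})

test_that("negative-binomial likelihood approaches Poisson as phi -> 0", {
  y <- 0:20
  mu <- 4.2
  for (phi in c(1e-4, 1e-6)) {
    nb <- dnbinom(y, mu = mu, size = 1 / phi, log = TRUE)
    po <- dpois(y, mu, log = TRUE)
    expect_equal(nb, po, tolerance = 50 * phi)
  }
})

test_that("assign_coo takes the depletion argmin and maps lineage class", {
  d <- coo_design(nb = 400, seed = 5)
  set.seed(5)
  y <- gp_counts(d, "AT2", beta1 = -0.6, phi = 0.3)
  bm <- bin_matrix(y, d$bins, d$covariates, d$centroids)
  res <- assign_coo(bm)
  expect_equal(res$coo_call, "AT2")
  expect_equal(res$class_call, "distal")

  # enrichment convention inverts the call when signs flip
  y_en <- gp_counts(d, "Basal", beta1 = +0.6, phi = 0.3)
  bm_en <- bin_matrix(y_en, d$bins, d$covariates, d$centroids)
  res_en <- assign_coo(bm_en, convention = "enrichment")
  expect_equal(res_en$coo_call, "Basal")
  expect_equal(res_en$class_call, "proximal")
})

test_that("subtype comparison builds the 2x2 table with a Fisher test", {
  mk_res <- function(id, call) {
    structure(list(sample_id = id,
                   rr_table = data.frame(cell_type = call, rr = 0.7,
                                         ci_lo = 0.6, ci_hi = 0.8,
                                         beta1 = log(0.7), se = 0.05,
                                         phi = 0.3, converged = TRUE),
                   coo_call = call,
                   class_call = c(AT2 = "distal", Basal = "proximal")[[call]]),
              class = "coo_result")
  }
  res <- c(lapply(sprintf("H%02d", 1:10), mk_res, call = "Basal"),
           lapply(sprintf("H%02d", 11:12), mk_res, call = "AT2"),
           lapply(sprintf("L%02d", 1:3), mk_res, call = "Basal"),
           lapply(sprintf("L%02d", 4:12), mk_res, call = "AT2"))
  calls <- data.frame(sample_id = c(sprintf("H%02d", 1:12), sprintf("L%02d", 1:12)),
                      subtype = rep(c("HAS", "LAS"), each = 12))
  cmp <- compare_coo_subtypes(res, calls)
  expect_equal(as.vector(cmp$table), c(10, 2, 3, 9))
  oracle <- fisher.test(matrix(c(10, 2, 3, 9), 2))$p.value
  expect_equal(cmp$p_fisher, oracle)
  expect_gt(cmp$or, 1)
})
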