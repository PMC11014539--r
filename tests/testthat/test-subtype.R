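test_that("signature presence needs both the 5% fraction and the 50-count floor", {
  attr_of <- function(apo, total) {
    list(counts = c(SBS2 = apo / 2, SBS13 = apo / 2, SBS4 = 100), total = total)
  }
  expect_false(signature_presence(attr_of(400, 10000)))  # 4% < 5%
  expect_false(signature_presence(attr_of(49, 500)))     # 9.8% but < 50
  expect_true(signature_presence(attr_of(600, 10000)))   # both criteria
  expect_error(signature_presence(list(counts = c(SBS2 = 1, SBS13 = 1), total = 0)),
               class = "domain_error")
  expect_error(signature_presence(list(counts = c(SBS2 = 1), total = 10)),
               class = "configuration_error")
})

test_that("subtype decision table is total over all four flag combinations", {
  expect_equal(assign_subtype(TRUE, TRUE), "HAS")
  expect_equal(assign_subtype(FALSE, TRUE), "LAS")
  expect_equal(assign_subtype(FALSE, FALSE), "no_APOBEC")
  expect_warning(got <- assign_subtype(TRUE, FALSE), "discordance|signature-positive")
  expect_equal(got, "LAS")
})

test_that("tetranucleotide chi-square matches the textbook statistic", {
  # perfect null: observed split equals motif split
  mk_stats <- function(n_y, n_r, f_y) {
    n <- n_y + n_r
    e_y <- n * f_y; e_r <- n * (1 - f_y)
    (n_y - e_y)^2 / e_y + (n_r - e_r)^2 / e_r
  }
  expect_equal(mk_stats(50, 50, 0.5), 0)
  expect_equal(mk_stats(75, 25, 0.5), 25)   # (25^2/50) * 2

  # exhaustive small-table sweep against chisq.test with given probabilities
  for (n in c(4, 9, 17)) {
    for (y in 0:n) {
      for (f in c(0.3, 0.5, 0.62)) {
        ours <- mk_stats(y, n - y, f)
        ref <- suppressWarnings(
          stats::chisq.test(c(y, n - y), p = c(f, 1 - f))$statistic)
        expect_equal(ours, unname(ref))
      }
    }
  }
})

test_that("ytca_rtca_classify counts tetranucleotide contexts from the catalog", {
  # CTCAG: YTCA context (5' C); GTCAG: RTCA (5' G); both C>T at TCA
  ref <- ref_from_string(paste0("AACTCAG", strrep("A", 20), "GGTCAGT",
                                strrep("A", 20), "TTTCATT"))
  pos <- c(5, 31, 58)
  cat1 <- annotate_context(tiny_catalog(pos, rep("C", 3), rep("T", 3)), ref)
  mo <- count_motifs(ref, scope = "genome")
  st <- ytca_rtca_classify(cat1, mo)
  expect_equal(st$n_ytca, 2)  # CTCA and TTCA
  expect_equal(st$n_rtca, 1)
  expect_equal(st$n_ytca + st$n_rtca, 3)
  f_y <- mo$n_YTCA / (mo$n_YTCA + mo$n_RTCA)
  expect_equal(st$exp_ytca, 3 * f_y)
})

test_that("phenotype calls are invariant to reverse-complement representation", {
  ref <- ref_from_string(paste0("AACTCAG", strrep("A", 20), "GGTCAGT"))
  rc <- ref_from_string(as.character(
    Biostrings::reverseComplement(ref[[1]])))
  len <- nchar(as.character(ref[[1]]))
  pos <- c(5, 31)
  cat_fwd <- annotate_context(tiny_catalog(pos, c("C", "C"), c("T", "T")), ref)
  cat_rev <- annotate_context(
    tiny_catalog(len - pos + 1, c("G", "G"), c("A", "A")), rc)
  mo_f <- count_motifs(ref, scope = "genome")
  mo_r <- count_motifs(rc, scope = "genome")
  st_f <- ytca_rtca_classify(cat_fwd, mo_f)
  st_r <- ytca_rtca_classify(cat_rev, mo_r)
  expect_equal(st_f$n_ytca, st_r$n_ytca)
  expect_equal(st_f$n_rtca, st_r$n_rtca)
  expect_equal(st_f$chi2, st_r$chi2)
})

test_that("cohort phenotype classification gates on TCA enrichment", {
  ref <- simulate_reference(2e5, 0.41, seed = 13)
  cats <- list()
  for (i in 1:4) {
    cfg <- sim_config(seed = 13, genome_length = 2e5, total_mutations = 600,
                      w_apobec = if (i <= 2) 0.6 else 0, w_smoking = 0.3,
                      w_flat = if (i <= 2) 0.1 else 0.7,
                      ytca_bias = 0.9)
    cats[[i]] <- annotate_context(simulate_sample(cfg, ref, seed = 50 + i)$catalog, ref)
  }
  mo <- count_motifs(ref, scope = "genome")
  stats_tab <- do.call(rbind, lapply(cats, ytca_rtca_classify, motifs = mo))
  stats_tab$sample_id <- paste0("S", 1:4)
  ph <- classify_phenotypes(stats_tab)
  expect_true(all(ph$phenotype[1:2] == "A3A_like"))
  expect_true(all(ph$phenotype[3:4] == "NA_pheno"))   # not TCA-enriched
  expect_true(all(ph$tca_enriched[1:2]))
})

test_that("call_subtypes joins enrichment and attribution evidence", {
  enr <- data.frame(sample_id = c("A", "B", "C"),
                    enriched_flag = c(TRUE, TRUE, FALSE))
  attr_tab <- data.frame(
    sample_id = rep(c("A", "B", "C"), each = 2),
    signature = rep(c("SBS2", "SBS13"), 3),
    count = c(300, 300, 5, 5, 0, 0),
    total = rep(c(2000, 2000, 2000), each = 2))
  calls <- call_subtypes(enr, attr_tab)
  expect_equal(calls$subtype, c("HAS", "LAS", "no_APOBEC"))
})

test_that("association stage reports Fisher and logistic estimates", {
  # outcome identical in both subtypes: no association
  ft0 <- data.frame(outcome = rep(1, 40), subtype = rep(c("LAS", "HAS"), 20))
  a0 <- subtype_association(ft0)
  expect_equal(a0$or_fisher, 1)
  expect_equal(a0$p_fisher, 1)

  # [[30,10],[10,30]] two-sided Fisher equals enumeration oracle
  ft <- data.frame(outcome = c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30)),
                   subtype = rep(c("HAS", "LAS"), c(40, 40)))
  a <- subtype_association(ft)
  # oracle: sum of all tables at fixed margins with prob <= observed
  probs <- vapply(0:40, function(x) {
    exp(lchoose(40, x) + lchoose(40, 40 - x) - lchoose(80, 40))
  }, numeric(1))
  obs_p <- probs[31]  # a = 30
  expect_equal(a$p_fisher, sum(probs[probs <= obs_p * (1 + 1e-7)]),
               tolerance = 1e-9)
  expect_true(a$converged)
  expect_gt(a$log_or, 0)

  # complete separation flagged, not dropped
  sep <- data.frame(outcome = rep(c(1, 0), c(20, 20)),
                    subtype = rep(c("HAS", "LAS"), c(20, 20)))
  expect_false(subtype_association(sep)$converged)
})
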