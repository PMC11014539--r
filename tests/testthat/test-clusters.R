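test_that("cluster P-value is the negative-binomial gap tail", {
  expect_equal(cluster_pvalue(2, 0, 0.01), 0.01)           # single zero gap
  expect_equal(cluster_pvalue(2, 1e9, 1e-6), 1, tolerance = 1e-12)  # genome-scale
  expect_error(cluster_pvalue(2, 10, 0), class = "domain_error")
  expect_error(cluster_pvalue(2, 10, 1), class = "domain_error")
  expect_error(cluster_pvalue(1, 10, 0.1), class = "domain_error")

  # valid CDF in the gap argument: nondecreasing from ~0 to 1
  p <- cluster_pvalue(rep(6, 5), c(0, 10, 100, 1e4, 1e7), 1e-4)
  expect_true(all(diff(p) > 0))
  expect_lt(p[1], 1e-15)
  expect_equal(p[5], 1, tolerance = 1e-6)
  # monotone decreasing in k at fixed gap
  pk <- vapply(2:6, cluster_pvalue, numeric(1), gap_bp = 100, pi = 1e-3)
  expect_true(all(diff(pk) < 0))
})

test_that("cluster P-value matches a powered Monte-Carlo placement oracle", {
  # at pi where a 1e5-replicate MC resolves the tail: uniform per-base
  # placement makes consecutive gaps geometric, simulated independently here
  set.seed(99)
  pi <- 2e-3; k <- 6; B <- 1e5
  gaps <- matrix(stats::rgeom(B * (k - 1), pi), ncol = k - 1)
  span_fail <- rowSums(gaps)
  p_mc <- mean(span_fail <= 250)
  se <- sqrt(p_mc * (1 - p_mc) / B)
  p_impl <- cluster_pvalue(k, 250, pi)
  expect_lt(abs(p_impl - p_mc), 3 * se)
})

test_that("complex events collapse before k is counted", {
  # 100,105 are <10 bp apart -> one event -> k=1, discarded; 2000 is isolated
  cat1 <- tiny_catalog(c(100, 105, 2000), rep("C", 3), rep("T", 3),
                       genome_length = 1e6)
  cs <- detect_clusters(cat1)
  expect_equal(nrow(cs$clusters), 0)

  # 6 mutations 50 bp apart in a sparse genome -> one kataegis cluster
  cat2 <- tiny_catalog(seq(1000, by = 50, length.out = 6), rep("C", 6),
                       rep("T", 6), genome_length = 1e6)
  cat2$mutations <- rbind(cat2$mutations,
                          transform(cat2$mutations[1:4, ],
                                    pos = c(5e5, 6e5, 7e5, 8e5)))
  cat2 <- mutation_catalog(cat2$mutations, "T1", genome_length = 1e6)
  cs2 <- detect_clusters(cat2)
  expect_equal(nrow(cs2$clusters), 1)
  expect_equal(cs2$clusters$k, 6)
  expect_equal(cs2$clusters$span_bp, 250)
  expect_equal(cs2$clusters$klass, "kataegis")
})

test_that("coordination and scssDNA proxy rules follow the strand definition", {
  base <- tiny_catalog(seq(1000, by = 50, length.out = 5), rep("C", 5),
                       rep("T", 5), genome_length = 1e7)
  cs <- detect_clusters(base)
  expect_equal(cs$clusters$coordination, "C")
  expect_true(cs$clusters$is_scssdna_proxy)
  expect_equal(cs$kataegis_count, 1L)

  # 3 mutations: omikli, never an scssDNA proxy
  om <- tiny_catalog(seq(1000, by = 50, length.out = 3), rep("C", 3),
                     rep("T", 3), genome_length = 1e7)
  cs_om <- detect_clusters(om)
  expect_equal(cs_om$clusters$klass, "omikli")
  expect_false(cs_om$clusters$is_scssdna_proxy)

  # mixed C/G membership is not a proxy
  mx <- tiny_catalog(seq(1000, by = 50, length.out = 5),
                     c("C", "C", "G", "C", "C"),
                     c("T", "T", "A", "T", "T"), genome_length = 1e7)
  cs_mx <- detect_clusters(mx)
  expect_equal(cs_mx$clusters$coordination, "mixed")
  expect_false(cs_mx$clusters$is_scssdna_proxy)
})

test_that("scssDNA percentage is summed proxy span over genome length", {
  pos <- c(seq(1000, by = 1000, length.out = 5),        # span 4000
           seq(101000, by = 1500, length.out = 5))      # span 6000
  cat1 <- tiny_catalog(pos, rep("C", 10), rep("T", 10), genome_length = 1e6)
  cs <- detect_clusters(cat1, d_max = 2000)
  expect_equal(nrow(cs$clusters), 2)
  expect_true(all(cs$clusters$is_scssdna_proxy))
  expect_equal(cs$scssdna_percent, 100 * (4000 + 6000) / 1e6)
})

test_that("cluster detection is invariant to input row order", {
  set.seed(8)
  ref <- simulate_reference(1e6, 0.41, seed = 8)
  sim <- simulate_sample(sim_config(genome_length = 1e6, total_mutations = 300,
                                    kataegis_lambda = 5), ref, seed = 8)
  cat1 <- sim$catalog
  shuf <- cat1$mutations[sample(nrow(cat1$mutations)), ]
  cat2 <- mutation_catalog(shuf, cat1$sample_id,
                           genome_length = cat1$genome_length)
  cs1 <- detect_clusters(cat1)
  cs2 <- detect_clusters(cat2)
  expect_equal(cs1$clusters, cs2$clusters)
})

test_that("kataegis spectrum normalizes and isolates APOBEC fraction", {
  # build a catalog whose only cluster members are known channels
  ref <- ref_from_string(paste0(strrep("G", 50), "ATCAG", strrep("G", 40),
                                "ACCAG", strrep("G", 50)))
  # place a tight run of TCA C>T and CCA C>A mutations by hand
  pos <- c(53, 98)
  cat1 <- annotate_context(tiny_catalog(pos, c("C", "C"), c("T", "A")), ref)
  cs <- structure(list(sample_id = "T1",
                       clusters = data.frame(chrom = "chr1", start = 53, end = 98,
                                             k = 4, n_members = 2, span_bp = 45,
                                             gap_bp = 44, p_cluster = 1e-9,
                                             klass = "kataegis", coordination = "C",
                                             is_scssdna_proxy = TRUE),
                       members = c(1L, 1L), pi = 1e-5, genome_length = 195),
                  class = "cluster_set")
  sp <- kataegis_spectrum(cs, cat1)
  expect_equal(sum(sp$spectrum), 1)
  expect_equal(sp$apobec_fraction, 0.5)   # one C>T at TCA, one C>A at CCA
  expect_equal(unname(sp$spectrum[["T[C>T]A"]]), 0.5)
  expect_equal(unname(sp$spectrum[["C[C>A]A"]]), 0.5)

  empty <- structure(list(sample_id = "T1", clusters = cs$clusters[0, ],
                          members = rep(NA_integer_, 2), pi = 1e-5,
                          genome_length = 195), class = "cluster_set")
  sp0 <- kataegis_spectrum(empty, cat1)
  expect_true(sp0$empty)
  expect_true(is.na(sp0$apobec_fraction))
})

test_that("null uniform catalogs yield clusters at about the analytic expectation", {
  # expected retained clusters: for each consecutive k-tuple the P-threshold
  # bounds the false rate; with n mutations the count of k>=2 clusters at
  # P<=1e-4 is at most ~ n * 1e-4 in expectation -- check no explosion
  set.seed(31)
  total <- 0
  for (b in 1:20) {
    pos <- sort(sample.int(1e6, 500))
    cat1 <- tiny_catalog(pos, rep("C", 500), rep("T", 500), genome_length = 1e6)
    total <- total + nrow(detect_clusters(cat1)$clusters)
  }
  expect_lte(total, 5)  # 20 null genomes, ~0.05 expected false clusters each
})
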