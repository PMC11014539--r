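#' Simulation configuration
#'
#' Bundles every knob of the synthetic tumor-cohort generator with documented
#' defaults. The generator emulates the processes the pipeline analyses: a
#' smoking-like C>A process at cytosines, an APOBEC process at TCW with a
#' tunable YTCA/RTCA bias, a clock-like C>T process at NpCpG proportional to
#' age, kataegis events with C/G strand coordination, a clonal/subclonal CCF
#' structure, and bin-level mutation densities log-linearly coupled to one
#' cell-type expression centroid.
#'
#' @param seed master seed; all randomness derives from it.
#' @param genome_length reference length in bases (default 1e6).
#' @param gc_fraction reference GC content (default 0.41, human-like).
#' @param n_samples cohort size.
#' @param total_mutations dispersed-process SNVs per sample (smoking + APOBEC
#'   + flat); clock mutations are drawn on top from age.
#' @param w_smoking,w_apobec,w_flat non-negative process weights (normalized
#'   internally).
#' @param ytca_bias probability an APOBEC TCA-context mutation lands at YTCA
#'   (0.5 = no A3A/A3B skew).
#' @param clock_rate clock-like mutations per year per diploid genome (the
#'   cohort log-scale centre).
#' @param clock_rate_sd_log log-normal spread of per-sample clock rates
#'   around `clock_rate` (default 0.2, realistic inter-tumor variation).
#' @param acceleration true rate acceleration during tumor latency (default 5).
#' @param subclonal_fraction probability a non-clock mutation is subclonal.
#' @param age_range,purity_range,latency_range per-sample draws, uniform.
#' @param ploidy tumor ploidy (scalar or per-sample vector).
#' @param kataegis_lambda mean kataegis events per sample (Poisson; default 0).
#' @param kataegis_k_min,kataegis_k_extra_mean event size k = k_min +
#'   Poisson(k_extra_mean).
#' @param kataegis_gap_mean mean geometric gap between cluster members (bp).
#' @param attr_noise_sd multiplicative log-normal noise on the emitted
#'   signature attributions (0 = truth counts exactly).
#' @param coo_n_bins,coo_beta1,coo_phi,coo_b0 Gamma-Poisson parameters of the
#'   cell-of-origin bin counts.
#' @param coo_cell_types centroid schema (default the seven-type lung schema).
#' @param coo_target target cell type whose centroid couples to mutation
#'   density (scalar or per-sample vector).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 1e6, gc_fraction = 0.41,
                       n_samples = 10,
                       total_mutations = 2000,
                       w_smoking = 0.5, w_apobec = 0.25, w_flat = 0.25,
                       ytca_bias = 0.5,
                       clock_rate = 1.5, clock_rate_sd_log = 0.2,
                       acceleration = 5,
                       subclonal_fraction = 0.15,
                       age_range = c(45, 75), purity_range = c(0.5, 0.9),
                       latency_range = c(2, 10), ploidy = 2,
                       kataegis_lambda = 0, kataegis_k_min = 6,
                       kataegis_k_extra_mean = 2, kataegis_gap_mean = 100,
                       attr_noise_sd = 0,
                       coo_n_bins = 500, coo_beta1 = -0.5, coo_phi = 0.3,
                       coo_b0 = 3,
                       coo_cell_types = c("Basal", "Neuroendocrine", "Goblet",
                                          "Ciliated", "Club", "AT1", "AT2"),
                       coo_target = "AT2") {
  w <- c(w_smoking, w_apobec, w_flat)
  if (any(w < 0) || sum(w) <= 0) {
    stop_apobec("process weights must be non-negative with positive sum",
                class = "domain_error")
  }
  if (ytca_bias < 0 || ytca_bias > 1 || gc_fraction < 0 || gc_fraction > 1 ||
      subclonal_fraction < 0 || subclonal_fraction > 1) {
    stop_apobec("probabilities must lie in [0, 1]", class = "domain_error")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a reference sequence
#'
#' I.i.d. bases with `P(G) + P(C) = gc`; deterministic under `seed`.
#'
#' @param length bases (>= 10 kb recommended so motif statistics stabilize).
#' @param gc GC fraction in \[0, 1\].
#' @param seed integer seed.
#' @param path optional FASTA output path.
#' @return A `DNAStringSet` with a single contig `chr1` (written to `path`
#'   when given).
#' @export
simulate_reference <- function(length, gc, seed, path = NULL) {
  if (gc < 0 || gc > 1) stop_apobec("gc must lie in [0, 1]", class = "domain_error")
  set.seed(as.integer(seed))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- sample(BASES, length, replace = TRUE, prob = p[BASES])
  ref <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(ref) <- "chr1"
  if (!is.null(path)) Biostrings::writeXStringSet(ref, path)
  ref
}

# Signed-position inventory of mutable motif sites on one reference.
# Positive positions are reference-strand C sites, negative are reference G
# sites (the motif lies on the minus strand). Positions within 2 bp of a
# contig end are excluded so every placed mutation has a full 5-base context.
motif_site_inventory <- function(reference) {
  reference <- load_reference(reference)
  starts_of <- function(subject, patterns, offset) {
    unlist(lapply(patterns, function(p) {
      Biostrings::start(Biostrings::matchPattern(p, subject)) + offset
    }))
  }
  inv <- list(CG_sites = integer(), TCW = integer(), TCT = integer(),
              YTCA = integer(), RTCA = integer(), NCG = integer(),
              contig = character(), contig_length = integer())
  chrom <- names(reference)[1]
  subject <- reference[[chrom]]
  len <- length(subject)
  clip <- function(pos) pos[abs(pos) >= 3 & abs(pos) <= len - 2]
  c_pos <- starts_of(subject, "C", 0L)
  g_pos <- starts_of(subject, "G", 0L)
  tca_p <- starts_of(subject, "TCA", 1L);  tca_m <- starts_of(subject, "TGA", 1L)
  tct_p <- starts_of(subject, "TCT", 1L);  tct_m <- starts_of(subject, "AGA", 1L)
  ytca_p <- starts_of(subject, c("CTCA", "TTCA"), 2L)
  ytca_m <- starts_of(subject, c("TGAG", "TGAA"), 1L)
  rtca_p <- starts_of(subject, c("ATCA", "GTCA"), 2L)
  rtca_m <- starts_of(subject, c("TGAT", "TGAC"), 1L)
  cg <- starts_of(subject, "CG", 0L)
  inv$CG_sites <- clip(c(c_pos, -g_pos))
  inv$TCW <- clip(c(tca_p, tct_p, -tca_m, -tct_m))
  inv$TCT <- clip(c(tct_p, -tct_m))
  inv$YTCA <- clip(c(ytca_p, -ytca_m))
  inv$RTCA <- clip(c(rtca_p, -rtca_m))
  inv$TCA <- clip(c(tca_p, -tca_m))
  inv$NCG <- clip(c(cg, -(cg + 1L)))
  inv$contig <- chrom
  inv$contig_length <- len
  inv
}

# draw n unused signed sites from a pool, marking them used
take_sites <- function(pool, n, used, what) {
  if (n == 0) return(integer(0))
  avail <- pool[!used[abs(pool)]]
  if (length(avail) < n) {
    stop_apobec("requested %d %s mutations but only %d unused sites remain",
                n, what, length(avail), class = "site_exhausted")
  }
  picked <- if (length(avail) == 1) avail else sample(avail, n)
  picked
}

mutation_rows <- function(sites, process) {
  n <- length(sites)
  if (n == 0) {
    return(data.frame(pos = integer(), ref = character(), alt = character(),
                      process = character(), kataegis_event = integer(),
                      stringsAsFactors = FALSE))
  }
  plus <- sites > 0
  ref <- ifelse(plus, "C", "G")
  alt <- switch(process,
    smoking = ifelse(plus, "A", "T"),
    clock = ifelse(plus, "T", "A"),
    apobec = ,
    kataegis = {
      tg <- sample(c("T", "G"), n, replace = TRUE)   # pyrimidine-frame alt
      ifelse(plus, tg, chartr("TG", "AC", tg))
    },
    stop("unknown process"))
  data.frame(pos = abs(sites), ref = ref, alt = alt,
             process = if (process == "kataegis") "apobec" else process,
             kataegis_event = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Simulate one tumor sample
#'
#' Draws a mutation catalog from the configured process mixture on a shared
#' reference, with full ground truth. Smoking-like mutations are C>A at
#' cytosines; APOBEC mutations are C>T or C>G (1:1, pyrimidine frame) at TCW
#' sites, with TCA-context sites split between YTCA and RTCA targets at
#' probability `ytca_bias`; clock-like mutations are C>T at NpCpG with count
#' Poisson in `age * clock_rate * ploidy/2` (clonal) and
#' `latency * clock_rate * acceleration * ploidy/2` (subclonal); the flat
#' process mutates uniform positions to a uniform alternative base. Kataegis
#' events place `k` strand-coordinated APOBEC-type mutations (all reference
#' C or all reference G) at TCW sites with geometric gaps. Placement is
#' collision-free; exhausting a motif inventory raises an error with count
#' diagnostics.
#'
#' @param config a [sim_config()]; per-sample fields (`age`, `purity`,
#'   `ploidy`, `latency`) may be overridden via `params`.
#' @param reference `DNAStringSet` (use [simulate_reference()]).
#' @param seed integer seed for this sample.
#' @param params optional named list overriding per-sample draws: `age`,
#'   `purity`, `ploidy`, `latency`, `clock_rate`, `sample_id`.
#' @param inventory optional precomputed [motif_site_inventory()] (computed
#'   from `reference` when missing; precompute it when simulating cohorts).
#' @return A list with `catalog` (a [mutation_catalog()], context columns
#'   unfilled — run [annotate_context()]) and `truth` (per-mutation process
#'   labels aligned with the catalog rows, kataegis intervals, clock counts,
#'   latency, MRCA age, realized YTCA/RTCA counts).
#' @export
simulate_sample <- function(config, reference, seed, params = list(),
                            inventory = NULL) {
  set.seed(as.integer(seed))
  inv <- inventory %||% motif_site_inventory(reference)
  chrom <- inv$contig
  len <- inv$contig_length
  age <- params$age %||% stats::runif(1, config$age_range[1], config$age_range[2])
  purity <- params$purity %||% stats::runif(1, config$purity_range[1], config$purity_range[2])
  ploidy <- params$ploidy %||% config$ploidy[1]
  latency <- params$latency %||% stats::runif(1, config$latency_range[1], config$latency_range[2])
  sample_id <- params$sample_id %||% sprintf("sim_%05d", seed %% 100000L)
  used <- logical(len)
  mark <- function(sites) used[abs(sites)] <<- TRUE

  # kataegis events (drawn first so they claim contiguous site runs)
  n_events <- stats::rpois(1, config$kataegis_lambda)
  kat_rows <- list(); kat_intervals <- list()
  tcw_plus <- sort(inv$TCW[inv$TCW > 0])
  tcw_minus <- sort(-inv$TCW[inv$TCW < 0])
  for (ev in seq_len(n_events)) {
    strand <- sample(c("C", "G"), 1)
    sites_strand <- if (strand == "C") tcw_plus else tcw_minus
    k <- config$kataegis_k_min + stats::rpois(1, config$kataegis_k_extra_mean)
    origin_i <- sample(length(sites_strand) - 1L, 1)
    picked <- sites_strand[origin_i]
    cur <- origin_i
    while (length(picked) < k) {
      gap <- stats::rgeom(1, 1 / config$kataegis_gap_mean)
      nxt <- findInterval(sites_strand[cur] + gap + 1L, sites_strand) + 1L
      if (nxt > length(sites_strand)) break
      picked <- c(picked, sites_strand[nxt])
      cur <- nxt
    }
    picked <- picked[!used[picked]]
    if (length(picked) < 2) next
    signed <- if (strand == "C") picked else -picked
    mark(signed)
    rows <- mutation_rows(signed, "kataegis")
    rows$kataegis_event <- ev
    kat_rows[[length(kat_rows) + 1]] <- rows
    kat_intervals[[length(kat_intervals) + 1]] <-
      data.frame(event = ev, strand = strand,
                 start = min(picked), end = max(picked), k = length(picked))
  }
  kat <- if (length(kat_rows)) do.call(rbind, kat_rows) else
    data.frame(pos = integer(), ref = character(), alt = character(),
               process = character(), kataegis_event = integer(),
               stringsAsFactors = FALSE)
  n_kat <- nrow(kat)

  # dispersed processes
  w <- c(config$w_smoking, config$w_apobec, config$w_flat)
  w <- w / sum(w)
  n_disp <- max(config$total_mutations - n_kat, 0)
  n_proc <- as.vector(stats::rmultinom(1, n_disp, w))
  names(n_proc) <- c("smoking", "apobec", "flat")

  smoking_sites <- take_sites(inv$CG_sites, n_proc[["smoking"]], used, "smoking")
  mark(smoking_sites)

  # APOBEC: TCA vs TCT by site availability, then YTCA vs RTCA by bias
  n_apo <- n_proc[["apobec"]]
  p_tca <- length(inv$TCA) / length(inv$TCW)
  n_tca <- stats::rbinom(1, n_apo, p_tca)
  n_y <- stats::rbinom(1, n_tca, config$ytca_bias)
  y_sites <- take_sites(inv$YTCA, n_y, used, "YTCA"); mark(y_sites)
  r_sites <- take_sites(inv$RTCA, n_tca - n_y, used, "RTCA"); mark(r_sites)
  t_sites <- take_sites(inv$TCT, n_apo - n_tca, used, "TCT"); mark(t_sites)
  apo_sites <- c(y_sites, r_sites, t_sites)

  # flat: uniform positions, uniform alternative base
  n_flat <- n_proc[["flat"]]
  flat_pos <- integer(0)
  if (n_flat > 0) {
    cand <- sample.int(len - 4L, min(4L * n_flat + 50L, len - 4L)) + 2L
    cand <- cand[!used[cand]]
    cand <- cand[!duplicated(cand)]
    if (length(cand) < n_flat) {
      stop_apobec("requested %d flat mutations but only %d unused positions sampled",
                  n_flat, length(cand), class = "site_exhausted")
    }
    flat_pos <- cand[seq_len(n_flat)]
    used[flat_pos] <- TRUE
  }

  # clock process (per-sample rate with log-normal spread around the centre)
  clock_rate_i <- params$clock_rate %||%
    (config$clock_rate * exp(stats::rnorm(1, 0, config$clock_rate_sd_log)))
  n_clock_clonal <- stats::rpois(1, clock_rate_i * age * ploidy / 2)
  n_clock_sub <- stats::rpois(1, clock_rate_i * config$acceleration *
                                   latency * ploidy / 2)
  clock_sites <- take_sites(inv$NCG, n_clock_clonal + n_clock_sub, used, "clock")
  mark(clock_sites)

  ref_str <- as.character(reference[[chrom]])
  flat_ref <- substring(ref_str, flat_pos, flat_pos)
  flat_alt <- vapply(flat_ref, function(b) sample(setdiff(BASES, b), 1), character(1))
  flat_df <- data.frame(pos = flat_pos, ref = unname(flat_ref),
                        alt = unname(flat_alt), process = rep("flat", n_flat),
                        stringsAsFactors = FALSE)
  flat_df <- flat_df[flat_df$ref %in% BASES, , drop = FALSE]

  flat_df$kataegis_event <- rep(NA_integer_, nrow(flat_df))
  parts <- rbind(
    mutation_rows(smoking_sites, "smoking"),
    mutation_rows(apo_sites, "apobec"),
    flat_df,
    mutation_rows(clock_sites, "clock"),
    kat[, c("pos", "ref", "alt", "process", "kataegis_event")]
  )
  n_all <- nrow(parts)
  is_clock <- parts$process == "clock"
  clock_clonal_idx <- which(is_clock)[seq_len(n_clock_clonal)]
  is_kat <- !is.na(parts$kataegis_event)
  subclonal <- stats::runif(n_all) < config$subclonal_fraction
  subclonal[is_kat] <- FALSE
  subclonal[is_clock] <- TRUE
  subclonal[clock_clonal_idx] <- FALSE
  ccf <- ifelse(subclonal, stats::runif(n_all, 0.2, 0.5), 1.0)
  parts$ccf <- ccf
  parts$chrom <- chrom
  o <- order(parts$pos)
  parts <- parts[o, , drop = FALSE]
  rownames(parts) <- NULL

  catalog <- mutation_catalog(
    parts[, c("chrom", "pos", "ref", "alt", "ccf")], sample_id,
    genome_length = nonN_length(reference),
    metadata = list(age = age, purity = purity, ploidy = ploidy,
                    sex = sample(c("M", "F"), 1),
                    histology = sample(c("LUAD", "LUSC"), 1),
                    nrpcc = stats::runif(1, 12, 30)))
  # catalog construction preserves position order (single contig, unique pos)
  truth <- list(
    sample_id = sample_id,
    labels = parts[, c("chrom", "pos", "process", "kataegis_event")],
    apobec_count = sum(parts$process == "apobec"),
    apobec_tcw_count = sum(parts$process == "apobec"),
    smoking_count = sum(parts$process == "smoking"),
    flat_count = sum(parts$process == "flat"),
    clock_clonal = n_clock_clonal, clock_subclonal = n_clock_sub,
    clock_rate = clock_rate_i,
    n_ytca = n_y, n_rtca = n_tca - n_y,
    kataegis = if (length(kat_intervals)) do.call(rbind, kat_intervals) else NULL,
    age = age, latency = latency, mrca_age = age - latency,
    purity = purity, ploidy = ploidy,
    ytca_bias = config$ytca_bias)
  list(catalog = catalog, truth = truth)
}

#' Simulate a full cohort with every pipeline input
#'
#' Generates the reference, per-sample catalogs and ground truth, the
#' metadata table, truth-derived signature attributions (SBS2+SBS13 from the
#' APOBEC labels, SBS4 from smoking, SBS1 from clock, SBS5 from the flat
#' process; optional multiplicative noise), and the cell-of-origin tables
#' (bins, covariates, centroids and Gamma-Poisson bin counts coupled to each
#' sample's target centroid). When `out_dir` is given, every file the
#' pipeline consumes is written there (FASTA, VCFs, TSVs, truth and manifest
#' JSON) deterministically.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return A list: `reference`, `catalogs`, `truths`, `metadata`,
#'   `attributions`, `coo` (list with `bins`, `covariates`, `centroids`,
#'   `counts` matrix, `targets`), `config`.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  seeds <- derive_seeds(config$seed, config$n_samples + 2L)
  reference <- simulate_reference(config$genome_length, config$gc_fraction,
                                  seeds[1])
  inv <- motif_site_inventory(reference)
  set.seed(seeds[2])
  n <- config$n_samples
  ages <- stats::runif(n, config$age_range[1], config$age_range[2])
  purities <- stats::runif(n, config$purity_range[1], config$purity_range[2])
  latencies <- stats::runif(n, config$latency_range[1], config$latency_range[2])
  ploidies <- rep_len(config$ploidy, n)
  targets <- rep_len(config$coo_target, n)
  ids <- sprintf("S%03d", seq_len(n))

  catalogs <- vector("list", n); truths <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- simulate_sample(config, reference, seeds[2 + i],
                           params = list(age = ages[i], purity = purities[i],
                                         ploidy = ploidies[i],
                                         latency = latencies[i],
                                         sample_id = ids[i]),
                           inventory = inv)
    catalogs[[i]] <- sim$catalog
    truths[[i]] <- sim$truth
  }
  names(catalogs) <- ids; names(truths) <- ids

  metadata <- data.frame(
    sample_id = ids, age = ages,
    sex = vapply(catalogs, function(x) x$metadata$sex, character(1)),
    histology = vapply(catalogs, function(x) x$metadata$histology, character(1)),
    purity = purities, ploidy = ploidies,
    nrpcc = vapply(catalogs, function(x) x$metadata$nrpcc, numeric(1)),
    stringsAsFactors = FALSE)

  set.seed(seeds[2] + 1L)
  attributions <- do.call(rbind, lapply(seq_len(n), function(i) {
    tr <- truths[[i]]
    apo <- tr$apobec_count
    counts <- c(SBS2 = floor(apo / 2), SBS13 = apo - floor(apo / 2),
                SBS4 = tr$smoking_count, SBS1 = tr$clock_clonal + tr$clock_subclonal,
                SBS5 = tr$flat_count)
    if (config$attr_noise_sd > 0) {
      counts <- round(counts * exp(stats::rnorm(length(counts), 0, config$attr_noise_sd)))
    }
    data.frame(sample_id = ids[i], signature = names(counts),
               count = as.numeric(counts),
               total = nrow(catalogs[[i]]$mutations),
               stringsAsFactors = FALSE)
  }))

  # cell-of-origin tables: GP counts coupled to each sample's target centroid
  nb <- config$coo_n_bins
  width <- config$genome_length %/% nb
  bins <- data.frame(chrom = "chr1",
                     start = (seq_len(nb) - 1L) * width + 1L,
                     end = seq_len(nb) * width)
  covariates <- data.frame(
    replication_timing = stats::rnorm(nb),
    gc_fraction = stats::runif(nb, 0.3, 0.6),
    mean_expression = NA_real_,
    log_intronic_fraction = log(stats::runif(nb, 0.2, 0.8)),
    log_exonic_fraction = log(stats::runif(nb, 0.01, 0.2)))
  centroids <- as.data.frame(matrix(stats::rnorm(nb * length(config$coo_cell_types)),
                                    nrow = nb,
                                    dimnames = list(NULL, config$coo_cell_types)))
  covariates$mean_expression <- rowMeans(centroids)
  gamma <- c(replication_timing = 0.1, gc_fraction = 0.2,
             mean_expression = 0.05, log_intronic_fraction = 0.05,
             log_exonic_fraction = 0.05)
  counts <- matrix(0L, nrow = nb, ncol = n, dimnames = list(NULL, ids))
  for (i in seq_len(n)) {
    eta <- config$coo_b0 + config$coo_beta1 * centroids[[targets[i]]] +
      as.matrix(covariates[, names(gamma)]) %*% gamma
    counts[, i] <- stats::rnbinom(nb, mu = exp(eta), size = 1 / config$coo_phi)
  }

  out <- list(reference = reference, catalogs = catalogs, truths = truths,
              metadata = metadata, attributions = attributions,
              coo = list(bins = bins, covariates = covariates,
                         centroids = centroids, counts = counts,
                         targets = stats::setNames(targets, ids)),
              config = config)
  if (!is.null(out_dir)) write_cohort(out, out_dir)
  out
}

# serialize a simulated cohort to disk (deterministic bytes given the cohort)
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) utils::write.table(x, file.path(out_dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(cohort$reference, file.path(out_dir, "reference.fa"))
  clens <- stats::setNames(Biostrings::width(cohort$reference), names(cohort$reference))
  for (id in names(cohort$catalogs)) {
    write_vcf(cohort$catalogs[[id]], file.path(out_dir, paste0(id, ".vcf")),
              contig_lengths = clens)
  }
  tsv(cohort$metadata, "metadata.tsv")
  tsv(cohort$attributions, "signatures.tsv")
  bed <- data.frame(chrom = cohort$coo$bins$chrom,
                    start0 = cohort$coo$bins$start - 1L,
                    end0 = cohort$coo$bins$end)
  utils::write.table(bed, file.path(out_dir, "bins.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  tsv(cohort$coo$covariates, "covariates.tsv")
  tsv(cohort$coo$centroids, "centroids.tsv")
  tsv(as.data.frame(cohort$coo$counts), "coo_counts.tsv")
  truth_slim <- lapply(cohort$truths, function(tr) {
    tr$labels <- NULL  # per-mutation labels stay in memory; files carry summaries
    tr
  })
  jsonlite::write_json(truth_slim, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
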