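#' Negative-binomial cluster P-value
#'
#' Under a constant-rate null where every base mutates independently with
#' per-base probability `pi`, the number of non-mutated bases separating `k`
#' consecutive mutations is the sum of `k - 1` geometric gap lengths, i.e.
#' negative binomial with `k - 1` successes and success probability `pi`. The
#' cluster P-value is the lower tail `Pr(NB(k - 1, pi) <= gap_bp)` where
#' `gap_bp` counts the intervening non-mutated bases (for mutations at
#' adjacent bases, `gap_bp = 0` and the P-value is `pi` at `k = 2`). It is a
#' valid CDF in `gap_bp` and monotone decreasing in `k` at fixed span.
#'
#' @param k member count (>= 2), after complex-event collapse.
#' @param gap_bp total intervening non-mutated bases across the cluster
#'   (sum over consecutive member pairs of distance minus one; >= 0).
#' @param pi per-base mutation probability, in (0, 1).
#' @return P-value in \[0, 1\]. Vectorized over `k` and `gap_bp`.
#' @export
cluster_pvalue <- function(k, gap_bp, pi) {
  if (any(pi <= 0) || any(pi >= 1)) {
    stop_apobec("pi must lie strictly in (0, 1)", class = "domain_error")
  }
  if (any(k < 2)) stop_apobec("k must be >= 2", class = "domain_error")
  if (any(gap_bp < 0)) stop_apobec("gap_bp must be >= 0", class = "domain_error")
  stats::pnbinom(gap_bp, size = k - 1, prob = pi)
}

#' Detect clustered mutations
#'
#' Candidate clusters are maximal same-chromosome runs with consecutive
#' inter-mutation distances at most `d_max` (default 1000 bp; the P-value
#' filter, not `d_max`, is the binding criterion). Within a candidate,
#' consecutive members closer than 10 bp are collapsed to one event — they
#' originate from a single mutagenic lesion rather than independent hits —
#' keeping the first member's coordinate as the representative, and the
#' post-collapse event count `k` is used for the P-value. Clusters are
#' retained iff `p_cluster <= p_max` (default 1e-4) and post-collapse
#' `k >= 2`, then classified by [classify_clusters()].
#'
#' The per-base mutation probability `pi` is estimated per sample as total
#' SNVs over the non-N genome length (constant-rate null; regional rate
#' variation is deliberately ignored, a conservative simplification).
#'
#' @param catalog a [mutation_catalog()] with `genome_length` set.
#' @param d_max candidate gap threshold in bp (default 1000).
#' @param p_max retention threshold on the cluster P-value (default 1e-4).
#' @param complex_bp distances below this collapse to one event (default 10).
#' @return A list of class `cluster_set`: `sample_id`, `clusters` (data frame:
#'   chrom, start, end, k, n_members, span_bp, gap_bp, p_cluster, klass,
#'   coordination, is_scssdna_proxy), `members` (per-mutation cluster id),
#'   `pi`, `genome_length`, and the per-sample summaries added by
#'   [classify_clusters()].
#' @export
detect_clusters <- function(catalog, d_max = 1000, p_max = 1e-4, complex_bp = 10) {
  if (is.na(catalog$genome_length) || catalog$genome_length <= 0) {
    stop_apobec("catalog genome_length missing; annotate against a reference first",
                class = "configuration_error")
  }
  m <- catalog$mutations
  n <- nrow(m)
  pi_hat <- n / catalog$genome_length
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      k = integer(), n_members = integer(), span_bp = integer(),
                      gap_bp = integer(), p_cluster = numeric(),
                      klass = character(), coordination = character(),
                      is_scssdna_proxy = logical(), stringsAsFactors = FALSE)
  cs <- structure(list(sample_id = catalog$sample_id, clusters = empty,
                       members = rep(NA_integer_, n), pi = pi_hat,
                       genome_length = catalog$genome_length,
                       d_max = d_max, p_max = p_max),
                  class = "cluster_set")
  if (n < 2 || pi_hat <= 0 || pi_hat >= 1) return(classify_clusters(cs, catalog))
  # catalogs are kept sorted by construction
  gap_next <- c(diff(m$pos), NA)
  same_chr <- c(m$chrom[-1] == m$chrom[-n], FALSE)
  new_run <- c(TRUE, !(same_chr[-n] & gap_next[-n] <= d_max))
  run_id <- cumsum(new_run)
  rows <- list()
  member_id <- rep(NA_integer_, n)
  cl_id <- 0L
  for (r in which(tabulate(run_id) >= 2)) {
    idx <- which(run_id == r)
    pos <- m$pos[idx]
    d <- diff(pos)
    # collapse complex events: a new event starts where distance >= complex_bp
    event <- cumsum(c(TRUE, d >= complex_bp))
    k_eff <- max(event)
    if (k_eff < 2) next
    rep_pos <- pos[!duplicated(event)]           # first member of each event
    gap_bp <- sum(pmax(diff(rep_pos) - 1L, 0L))
    p <- cluster_pvalue(k_eff, gap_bp, pi_hat)
    if (p > p_max) next
    cl_id <- cl_id + 1L
    member_id[idx] <- cl_id
    rows[[cl_id]] <- data.frame(chrom = m$chrom[idx[1]],
                                start = pos[1], end = pos[length(pos)],
                                k = k_eff, n_members = length(idx),
                                span_bp = pos[length(pos)] - pos[1],
                                gap_bp = gap_bp, p_cluster = p,
                                klass = NA_character_,
                                coordination = NA_character_,
                                is_scssdna_proxy = NA,
                                stringsAsFactors = FALSE)
  }
  if (length(rows)) cs$clusters <- do.call(rbind, rows)
  cs$members <- member_id
  classify_clusters(cs, catalog)
}

#' Classify clusters and summarize strand-coordinated ssDNA
#'
#' `coordination` is judged on the reference-strand mutated base: `"C"` if
#' every member mutates a reference C, `"G"` if every member mutates a
#' reference G, else `"mixed"`. `klass` is `"omikli"` for k in 2..3 and
#' `"kataegis"` for k >= 4. Clusters with more than 3 events all at C or all
#' at G proxy long persistent strand-coordinated ssDNA tracts; the tract
#' length is the distance between the bordering mutations of the cluster, and
#' `scssdna_percent` is 100 times the summed proxy spans over the genome
#' length.
#'
#' @param cluster_set a `cluster_set` from [detect_clusters()].
#' @param catalog the catalog the clusters came from.
#' @return The `cluster_set` with `klass`, `coordination`,
#'   `is_scssdna_proxy`, `scssdna_percent`, `kataegis_count` and
#'   `kataegis_mutation_count` filled.
#' @export
classify_clusters <- function(cluster_set, catalog) {
  cl <- cluster_set$clusters
  m <- catalog$mutations
  if (nrow(cl)) {
    for (i in seq_len(nrow(cl))) {
      refs <- m$ref[which(cluster_set$members == i)]
      cl$coordination[i] <- if (all(refs == "C")) "C"
                            else if (all(refs == "G")) "G"
                            else "mixed"
    }
    cl$klass <- ifelse(cl$k >= 4, "kataegis", "omikli")
    cl$is_scssdna_proxy <- cl$k >= 4 & cl$coordination != "mixed"
  }
  cluster_set$clusters <- cl
  proxy_span <- if (nrow(cl)) sum(cl$span_bp[cl$is_scssdna_proxy]) else 0
  cluster_set$scssdna_percent <- 100 * proxy_span / cluster_set$genome_length
  cluster_set$kataegis_count <- if (nrow(cl)) sum(cl$klass == "kataegis") else 0L
  cluster_set$kataegis_mutation_count <-
    if (nrow(cl)) sum(cl$n_members[cl$klass == "kataegis"]) else 0L
  cluster_set
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("<cluster_set> sample", x$sample_id, "\n")
  cat(sprintf("  clusters: %d (kataegis %d, mutations in kataegis %d)\n",
              nrow(x$clusters), x$kataegis_count, x$kataegis_mutation_count))
  cat(sprintf("  pi: %.3g  scssDNA: %.4f%%\n", x$pi, x$scssdna_percent))
  invisible(x)
}

# canonical 96-channel ordering: 6 pyrimidine substitution types x 16 flanks
channel_names_96 <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) for (l in BASES) for (r in BASES) {
    out <- c(out, paste0(l, "[", s, "]", r))
  }
  out
}

#' Trinucleotide spectrum of kataegis mutations
#'
#' Returns the 96-channel spectrum (pyrimidine substitution type by flanking
#' bases) of all mutations belonging to kataegis clusters, normalized to sum
#' 1, plus the fraction of kataegis mutations that are APOBEC-type (C>T or
#' C>G at TCW).
#'
#' @param cluster_set a classified `cluster_set`.
#' @param catalog the context-annotated catalog it came from.
#' @return A list with `spectrum` (named numeric, sums to 1 when nonempty),
#'   `apobec_fraction` (`NA` with `empty = TRUE` when there are no kataegis
#'   mutations) and `n_mutations`.
#' @export
kataegis_spectrum <- function(cluster_set, catalog) {
  m <- catalog$mutations
  if (is.null(m$context5)) {
    stop_apobec("catalog must be context-annotated", class = "configuration_error")
  }
  cl <- cluster_set$clusters
  kat_ids <- which(cl$klass == "kataegis")
  idx <- which(cluster_set$members %in% kat_ids & (m$ok_context %||% TRUE))
  chans <- channel_names_96()
  if (length(idx) == 0) {
    return(list(spectrum = stats::setNames(numeric(96), chans),
                apobec_fraction = NA_real_, n_mutations = 0L, empty = TRUE))
  }
  sub <- m[idx, , drop = FALSE]
  lab <- paste0(substr(sub$context5, 2, 2), "[", sub$pyr_ref, ">", sub$pyr_alt,
                "]", substr(sub$context5, 4, 4))
  spec <- table(factor(lab, levels = chans))
  spec <- as.numeric(spec) / length(idx)
  names(spec) <- chans
  tri <- substr(sub$context5, 2, 4)
  apo <- sub$pyr_ref == "C" & sub$pyr_alt %in% c("T", "G") &
    substr(tri, 1, 1) == "T" & substr(tri, 3, 3) %in% c("A", "T")
  list(spectrum = spec, apobec_fraction = mean(apo),
       n_mutations = length(idx), empty = FALSE)
}

#' Write cluster intervals as BED
#'
#' 0-based half-open intervals, one line per retained cluster.
#'
#' @param cluster_set a classified `cluster_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_bed <- function(cluster_set, path) {
  cl <- cluster_set$clusters
  lines <- sprintf("%s\t%d\t%d\t%s_k%d\t%g\t.",
                   cl$chrom, cl$start - 1L, cl$end, cl$klass, cl$k, cl$p_cluster)
  writeLines(lines, path)
  invisible(path)
}
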