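# in-code fixtures shared across test files

# a tiny reference from an explicit sequence string
ref_from_string <- function(seq, name = "chr1") {
  ref <- Biostrings::DNAStringSet(seq)
  names(ref) <- name
  ref
}

# a catalog from parallel vectors, on contig chr1 unless stated
tiny_catalog <- function(pos, ref, alt, ccf = NA_real_, chrom = "chr1",
                         sample_id = "T1", genome_length = NA_real_,
                         metadata = list()) {
  mutation_catalog(
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, ccf = ccf,
               stringsAsFactors = FALSE),
    sample_id, genome_length = genome_length, metadata = metadata)
}

# brute-force motif counts by scanning every offset of seq and its revcomp
brute_motif_counts <- function(seq) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  count_in <- function(s, words) {
    n <- 0L
    for (w in words) {
      wl <- nchar(w)
      if (nchar(s) < wl) next
      for (i in seq_len(nchar(s) - wl + 1L)) {
        if (substr(s, i, i + wl - 1L) == w) n <- n + 1L
      }
    }
    n
  }
  both <- function(words) count_in(seq, words) + count_in(rc, words)
  list(n_C = both("C"),
       n_TCW = both(c("TCA", "TCT")),
       n_TCA = both("TCA"),
       n_YTCA = both(c("CTCA", "TTCA")),
       n_RTCA = both(c("ATCA", "GTCA")))
}

# exhaustive hypergeometric tail: P(X >= a) for the one-sided Fisher test on
# [[a, b], [c, d]] with margins fixed (a+b draws from an urn of a+c successes
# out of a+b+c+d)
fisher_tail_oracle <- function(a, b, c, d) {
  n1 <- a + b          # observed mutations
  K <- a + c           # motif column total
  N <- a + b + c + d
  xs <- max(0, n1 - (N - K)):min(n1, K)
  probs <- exp(lchoose(K, xs) + lchoose(N - K, n1 - xs) - lchoose(N, n1))
  sum(probs[xs >= a])
}

# write lines to a temp file and return the path
tmp_file_with <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

sim_cfg_fast <- function(...) {
  sim_config(genome_length = 2e5, n_samples = 2, total_mutations = 500, ...)
}
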