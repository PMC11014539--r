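#' Annotate pyrimidine-normalized sequence context
#'
#' Fills `pyr_ref`, `pyr_alt` and `context5` for every mutation. Mutations at
#' reference purines (G or A) are reverse-complemented into the pyrimidine
#' frame, the universal strand convention of single-base-substitution
#' signature analysis, so `pyr_ref` is always C or T and `context5[3]` equals
#' `pyr_ref`. Mutations whose 5-base window contains an N or runs off the
#' contig get `ok_context = FALSE` and are excluded from motif statistics.
#'
#' The operation is idempotent: re-annotating an annotated catalog yields the
#' same result.
#'
#' @param catalog a [mutation_catalog()].
#' @param reference FASTA path or `DNAStringSet` (see [load_reference()]).
#' @return The catalog with context columns filled and `genome_length` set to
#'   the non-N reference length.
#' @export
annotate_context <- function(catalog, reference) {
  reference <- load_reference(reference)
  m <- catalog$mutations
  m$pyr_ref <- NA_character_
  m$pyr_alt <- NA_character_
  m$context5 <- NA_character_
  m$ok_context <- FALSE
  for (chrom in unique(m$chrom)) {
    if (!chrom %in% names(reference)) {
      stop_apobec("contig '%s' absent from reference", chrom, class = "coordinate_error")
    }
    idx <- which(m$chrom == chrom)
    seq_chr <- as.character(reference[[chrom]])
    len <- nchar(seq_chr)
    pos <- m$pos[idx]
    if (any(pos > len)) {
      bad <- idx[which(pos > len)[1]]
      stop_apobec("position %d on %s beyond contig end (%d)",
                  m$pos[bad], chrom, len, class = "coordinate_error")
    }
    ref_base <- substring(seq_chr, pos, pos)
    mismatch <- ref_base != m$ref[idx] & ref_base != "N"
    if (any(mismatch)) {
      bad <- idx[which(mismatch)[1]]
      stop_apobec("ref allele %s at %s:%d disagrees with reference base %s",
                  m$ref[bad], chrom, m$pos[bad], ref_base[which(mismatch)[1]],
                  class = "reference_mismatch")
    }
    in_range <- pos >= 3 & pos <= len - 2
    ctx <- rep(NA_character_, length(idx))
    ctx[in_range] <- substring(seq_chr, pos[in_range] - 2, pos[in_range] + 2)
    is_pur <- m$ref[idx] %in% c("G", "A")
    pyr_ref <- ifelse(is_pur, complement_base(m$ref[idx]), m$ref[idx])
    pyr_alt <- ifelse(is_pur, complement_base(m$alt[idx]), m$alt[idx])
    flip <- is_pur & !is.na(ctx)
    if (any(flip)) ctx[flip] <- revcomp(ctx[flip])
    ok <- !is.na(ctx) & !grepl("N", ctx, fixed = TRUE)
    m$pyr_ref[idx] <- pyr_ref
    m$pyr_alt[idx] <- pyr_alt
    m$context5[idx] <- ctx
    m$ok_context[idx] <- ok
  }
  n_bad <- sum(!m$ok_context)
  if (n_bad > 0) {
    message(n_bad, " mutation(s) with N-containing or truncated context excluded from motif statistics")
  }
  catalog$mutations <- m
  catalog$genome_length <- nonN_length(reference)
  catalog
}

# Literal motif inventories (plus-strand spellings; a motif "counts" if it
# matches on the plus strand or if its reverse complement does, i.e. the
# motif occurs on the minus strand).
.MOTIFS <- list(
  TCW  = list(plus = c("TCA", "TCT"),           minus = c("TGA", "AGA")),
  TCA  = list(plus = "TCA",                     minus = "TGA"),
  YTCA = list(plus = c("CTCA", "TTCA"),         minus = c("TGAG", "TGAA")),
  RTCA = list(plus = c("ATCA", "GTCA"),         minus = c("TGAT", "TGAC"))
)

count_patterns <- function(subject_set, patterns) {
  total <- 0L
  for (p in patterns) {
    total <- total + sum(Biostrings::vcountPattern(p, subject_set))
  }
  total
}

#' Count APOBEC-relevant context motifs
#'
#' Counts cytosine positions and TCW / TCA / YTCA / RTCA motifs on both
#' strands of the reference, either over the whole genome or over the union of
#' windows around each mutated cytosine. `n_C` counts evaluable cytosines on
#' either strand (C plus G on the plus strand); a motif is counted once per
#' occurrence per strand. N-containing motifs are never counted. Overlapping
#' windows are merged before counting so no base is counted twice.
#'
#' @param reference FASTA path or `DNAStringSet`.
#' @param catalog a context-annotated [mutation_catalog()]; required when
#'   `scope = "windows"`.
#' @param window half-width in bases of the window around each mutated
#'   cytosine (default 20, i.e. 41-base windows, the established
#'   motif-enrichment convention).
#' @param scope `"windows"` or `"genome"`.
#' @return A list of class `motif_counts` with `n_C`, `n_TCW`, `n_TCA`,
#'   `n_YTCA`, `n_RTCA`, `scope`, `window`.
#' @export
count_motifs <- function(reference, catalog = NULL, window = 20,
                         scope = c("windows", "genome")) {
  scope <- match.arg(scope)
  reference <- load_reference(reference)
  if (scope == "genome") {
    subject <- reference
  } else {
    if (is.null(catalog)) {
      stop_apobec("scope='windows' needs a catalog", class = "configuration_error")
    }
    if (window < 2) {
      stop_apobec("window half-width must be >= 2", class = "configuration_error")
    }
    m <- catalog$mutations
    if (is.null(m$pyr_ref)) {
      stop_apobec("catalog must be context-annotated before windowed motif counting",
                  class = "configuration_error")
    }
    keep <- m$pyr_ref == "C" & (m$ok_context %||% TRUE)
    m <- m[keep, , drop = FALSE]
    if (nrow(m) == 0) {
      warning("no mutated cytosines: windowed motif counts are zero")
      return(structure(list(n_C = 0L, n_TCW = 0L, n_TCA = 0L, n_YTCA = 0L,
                            n_RTCA = 0L, scope = scope, window = window),
                       class = "motif_counts"))
    }
    pieces <- list()
    for (chrom in unique(m$chrom)) {
      len <- length(reference[[chrom]])
      pos <- m$pos[m$chrom == chrom]
      ir <- IRanges::reduce(IRanges::IRanges(pmax(pos - window, 1L),
                                             pmin(pos + window, len)))
      pieces[[chrom]] <- Biostrings::DNAStringSet(
        Biostrings::Views(reference[[chrom]], ir))
    }
    subject <- do.call(c, unname(pieces))
  }
  n_C <- sum(Biostrings::letterFrequency(subject, c("C", "G")))
  counts <- lapply(.MOTIFS, function(mm) {
    count_patterns(subject, mm$plus) + count_patterns(subject, mm$minus)
  })
  structure(list(n_C = n_C,
                 n_TCW = counts$TCW,
                 n_TCA = counts$TCA,
                 n_YTCA = counts$YTCA,
                 n_RTCA = counts$RTCA,
                 scope = scope,
                 window = if (scope == "windows") window else NA_integer_),
            class = "motif_counts")
}

#' @export
print.motif_counts <- function(x, ...) {
  cat("<motif_counts> scope:", x$scope,
      if (!is.na(x$window %||% NA)) paste0("(half-width ", x$window, ")"), "\n")
  cat(sprintf("  C: %d  TCW: %d  TCA: %d  YTCA: %d  RTCA: %d\n",
              x$n_C, x$n_TCW, x$n_TCA, x$n_YTCA, x$n_RTCA))
  invisible(x)
}
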