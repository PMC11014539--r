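#' Somatic SNV catalog for one sample
#'
#' A `mutation_catalog` holds one sample's somatic single-nucleotide variants
#' together with the bookkeeping every downstream stage needs: the non-N
#' reference length used as the denominator of per-base mutation rates, and
#' per-sample metadata (age, sex, histology, purity, ploidy).
#'
#' The `mutations` data frame has one row per SNV with columns `chrom`, `pos`
#' (1-based), `ref`, `alt`, `ccf` (cancer-cell fraction, `NA` when unknown) and
#' `clonal_flag` (`"clonal"`, `"subclonal"` or `"unknown"`). After
#' [annotate_context()] it additionally carries `pyr_ref`, `pyr_alt`,
#' `context5` (5-base pyrimidine-normalized reference context centred on the
#' mutated base) and `ok_context` (FALSE when the context window contains N or
#' falls off the contig; such records are excluded from motif statistics).
#'
#' @param mutations data frame with at least `chrom`, `pos`, `ref`, `alt`.
#' @param sample_id sample identifier.
#' @param genome_length count of non-N reference bases (may be `NA` until a
#'   reference is attached).
#' @param metadata named list (age, sex, histology, purity, ploidy, ...).
#' @return An object of class `mutation_catalog`.
#' @export
mutation_catalog <- function(mutations, sample_id,
                             genome_length = NA_real_, metadata = list()) {
  stopifnot(is.data.frame(mutations))
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(mutations))
  if (length(miss)) {
    stop_apobec("catalog is missing column(s): %s", paste(miss, collapse = ", "),
                class = "catalog_error")
  }
  mutations$chrom <- as.character(mutations$chrom)
  mutations$pos <- as.integer(mutations$pos)
  mutations$ref <- toupper(as.character(mutations$ref))
  mutations$alt <- toupper(as.character(mutations$alt))
  if (is.null(mutations$ccf)) mutations$ccf <- NA_real_
  if (is.null(mutations$clonal_flag)) {
    mutations$clonal_flag <- ifelse(is.na(mutations$ccf), "unknown",
                                    ifelse(mutations$ccf >= 0.8, "clonal", "subclonal"))
  }
  bad <- !(mutations$ref %in% BASES) | !(mutations$alt %in% BASES) |
    mutations$ref == mutations$alt | is.na(mutations$pos) | mutations$pos < 1
  if (any(bad)) {
    stop_apobec("invalid SNV record(s) at row(s): %s",
                paste(utils::head(which(bad), 5), collapse = ", "),
                class = "catalog_error")
  }
  # sort and deduplicate on (chrom, pos, alt)
  o <- order(mutations$chrom, mutations$pos, mutations$alt)
  mutations <- mutations[o, , drop = FALSE]
  dup <- duplicated(mutations[, c("chrom", "pos", "alt")])
  if (any(dup)) mutations <- mutations[!dup, , drop = FALSE]
  rownames(mutations) <- NULL
  structure(
    list(sample_id = as.character(sample_id),
         mutations = mutations,
         genome_length = as.numeric(genome_length),
         metadata = metadata),
    class = "mutation_catalog"
  )
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat("<mutation_catalog> sample", x$sample_id, "\n")
  cat("  SNVs:", nrow(x$mutations),
      " contigs:", length(unique(x$mutations$chrom)),
      " genome_length:", format(x$genome_length, big.mark = ","), "\n")
  if (!is.null(x$mutations$context5) && any(!is.na(x$mutations$context5))) {
    cat("  context annotated (", sum(x$mutations$ok_context %||% FALSE),
        " usable )\n", sep = "")
  }
  invisible(x)
}

#' @export
length.mutation_catalog <- function(x) nrow(x$mutations)

#' Read a somatic SNV catalog from VCF or MAF
#'
#' Only biallelic SNVs are retained: records whose REF or ALT is not a single
#' A/C/G/T base (indels, MNVs, multi-allelic rows) are dropped with a message.
#' Duplicate (chrom, pos, alt) records are deduplicated. An optional CCF
#' annotation is read from the `CCF` INFO key (VCF) or a `CCF` column (MAF);
#' when absent, clonality is `"unknown"` and clonality-dependent stages refuse
#' to run rather than guess.
#'
#' @param path file path (VCF may be plain or bgzipped).
#' @param format `"vcf"` or `"maf"`. MAF here means a tab-separated table with
#'   at least Chromosome, Start_Position, Reference_Allele, Tumor_Seq_Allele2
#'   and Tumor_Sample_Barcode; extra columns are ignored.
#' @param sample_id sample identifier; for MAF defaults to the (single)
#'   Tumor_Sample_Barcode present.
#' @return A [mutation_catalog()].
#' @export
read_mutations <- function(path, format = c("vcf", "maf"), sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_apobec("file not found: %s", path, class = "io_error")
  }
  if (format == "vcf") {
    v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    if (nrow(fix) == 0) {
      warning("empty variant catalog: ", path)
      df <- data.frame(chrom = character(), pos = integer(),
                       ref = character(), alt = character())
      return(mutation_catalog(df, sample_id %||% basename(path)))
    }
    pos <- suppressWarnings(as.integer(fix$POS))
    if (anyNA(pos)) {
      stop_apobec("malformed coordinate at VCF data line(s): %s",
                  paste(utils::head(which(is.na(pos)), 5), collapse = ", "),
                  class = "parse_error")
    }
    info <- vcfR::getINFO(v) %||% rep(NA_character_, nrow(fix))
    ccf <- suppressWarnings(as.numeric(sub(".*(?:^|;)CCF=([0-9.eE+-]+).*", "\\1",
                                           info, perl = TRUE)))
    ccf[!grepl("(^|;)CCF=", info)] <- NA_real_
    df <- data.frame(chrom = fix$CHROM, pos = pos,
                     ref = toupper(fix$REF), alt = toupper(fix$ALT),
                     ccf = ccf, stringsAsFactors = FALSE)
    sample_id <- sample_id %||% sub("\\.vcf(\\.gz)?$", "", basename(path))
  } else {
    df0 <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("Chromosome", "Start_Position", "Reference_Allele",
              "Tumor_Seq_Allele2", "Tumor_Sample_Barcode")
    miss <- setdiff(need, names(df0))
    if (length(miss)) {
      stop_apobec("MAF is missing column(s): %s", paste(miss, collapse = ", "),
                  class = "parse_error")
    }
    if (is.null(sample_id)) {
      ids <- unique(df0$Tumor_Sample_Barcode)
      if (length(ids) != 1) {
        stop_apobec("MAF holds %d samples; pass sample_id", length(ids),
                    class = "parse_error")
      }
      sample_id <- ids
    } else {
      df0 <- df0[df0$Tumor_Sample_Barcode == sample_id, , drop = FALSE]
    }
    pos <- suppressWarnings(as.integer(df0$Start_Position))
    if (anyNA(pos) && nrow(df0) > 0) {
      stop_apobec("malformed coordinate at MAF line(s): %s",
                  paste(utils::head(which(is.na(pos)), 5), collapse = ", "),
                  class = "parse_error")
    }
    df <- data.frame(chrom = as.character(df0$Chromosome), pos = pos,
                     ref = toupper(df0$Reference_Allele),
                     alt = toupper(df0$Tumor_Seq_Allele2),
                     ccf = if ("CCF" %in% names(df0)) as.numeric(df0$CCF) else NA_real_,
                     stringsAsFactors = FALSE)
  }
  snv <- df$ref %in% BASES & df$alt %in% BASES & df$ref != df$alt
  n_drop <- sum(!snv)
  if (n_drop > 0) {
    message(n_drop, " non-SNV record(s) dropped from ", basename(path))
  }
  df <- df[snv, , drop = FALSE]
  if (nrow(df) == 0) warning("empty SNV catalog: ", path)
  mutation_catalog(df, sample_id)
}

#' Load a reference genome as a DNAStringSet
#'
#' @param x path to a FASTA file, or a `DNAStringSet` (returned unchanged).
#' @return A named `Biostrings::DNAStringSet`.
#' @export
load_reference <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  ref <- Biostrings::readDNAStringSet(x)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

# non-N length of a reference
nonN_length <- function(reference) {
  sum(Biostrings::letterFrequency(reference, BASES))
}

#' Write a catalog as VCF
#'
#' Minimal VCFv4.2 writer for simulator output and round-trip tests; CCF is
#' stored in INFO.
#'
#' @param catalog a [mutation_catalog()].
#' @param path output path.
#' @param contig_lengths optional named vector for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(catalog, path, contig_lengths = NULL) {
  m <- catalog$mutations
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=apobecsmoke simulate sample=%s", catalog$sample_id),
           "##INFO=<ID=CCF,Number=1,Type=Float,Description=\"Cancer cell fraction\">")
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- ifelse(is.na(m$ccf), ".", sprintf("CCF=%.4f", m$ccf))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  m$chrom, m$pos, m$ref, m$alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write an annotated catalog as TSV
#'
#' Stable column order: chrom, pos, ref, alt, ccf, clonal_flag, pyr_ref,
#' pyr_alt, context5, ok_context.
#'
#' @param catalog a [mutation_catalog()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(catalog, path) {
  cols <- intersect(c("chrom", "pos", "ref", "alt", "ccf", "clonal_flag",
                      "pyr_ref", "pyr_alt", "context5", "ok_context"),
                    names(catalog$mutations))
  utils::write.table(catalog$mutations[, cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
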