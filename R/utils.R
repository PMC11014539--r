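# internal helpers shared across modules

BASES <- c("A", "C", "G", "T")

#' @importFrom Biostrings DNAStringSet reverseComplement
revcomp <- function(x) {
  out <- character(length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    out[ok] <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x[ok])))
  }
  out[!ok] <- NA_character_
  out
}

complement_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_apobec <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "apobecsmoke_error")))
}

# Derive a stream of per-use seeds from one master seed, staying inside the
# 32-bit integer range R requires of set.seed().
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}
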