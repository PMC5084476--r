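#' @useDynLib c4kit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor hclust as.dist rnorm runif rlnorm median quantile setNames
#' @importFrom utils read.delim write.table head tail
NULL

# Classed conditions so callers/tests can distinguish failure modes.
c4_abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "c4kit_error", "error", "condition")))
}

c4_warn <- function(msg, class = "c4kit_warning") {
  warning(warningCondition(msg, class = c(class, "warning", "condition")))
}

DNA <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (alphabet A/C/G/T/N).
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA string of length n at the given GC fraction.
rand_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA, n, replace = TRUE, prob = p), collapse = "")
}

# All k-mers of a single sequence as a character vector.
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
}

# Substring of a circular sequence: start is 1-based, len may wrap the origin.
circ_substr <- function(s, start, len) {
  n <- nchar(s)
  start <- ((start - 1) %% n) + 1
  if (start + len - 1 <= n) {
    substr(s, start, start + len - 1)
  } else {
    paste0(substr(s, start, n), substr(s, 1, start + len - 1 - n))
  }
}

# Rotate a circular sequence so that (1-based) position `start` comes first.
rotate_seq <- function(s, start) circ_substr(s, start, nchar(s))

#' Write sequences to FASTA / FASTQ
#'
#' @param x Named character vector of sequences.
#' @param path Output file.
#' @param qual Constant quality character for FASTQ records.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), filepath = path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(x, path, qual = "I") {
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("read", seq_along(x))
  rec <- paste0("@", ids, "\n", x, "\n+\n",
                vapply(nchar(x), function(n) strrep(qual, n), ""))
  writeLines(rec, path)
  invisible(path)
}

#' Read sequences from FASTA / FASTQ as plain character vectors
#'
#' @param path Input file.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}
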