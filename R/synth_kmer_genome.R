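#' Specification for a genome with unique and duplicated fractions
#'
#' The simulated nuclear genome consists of a unique fraction present once
#' and a duplicated block present exactly twice, so its k-mer multiplicity
#' histogram shows a single-copy peak at the sequencing depth and a second
#' peak at twice the depth.
#'
#' @param unique_bp Bases of single-copy sequence (> 0).
#' @param duplicated_bp Bases of sequence present exactly twice (> 0).
#' @param gc_fraction GC content.
#' @param seed Integer seed.
#' @return Object of class `kmer_genome_spec`.
#' @export
kmer_genome_spec <- function(unique_bp = 1e6, duplicated_bp = 2e5,
                             gc_fraction = 0.5, seed = 1L) {
  if (unique_bp <= 0 || duplicated_bp <= 0) {
    c4_abort("unique_bp and duplicated_bp must be positive", "invalid_spec")
  }
  structure(list(unique_bp = as.integer(unique_bp),
                 duplicated_bp = as.integer(duplicated_bp),
                 gc_fraction = gc_fraction, seed = as.integer(seed)),
            class = "kmer_genome_spec")
}

#' Generate a genome with a known unique/duplicated partition
#'
#' Layout is `U1 + D + U2 + D`: the unique fraction is split around the first
#' copy of the duplicated block so the two copies are not adjacent. Total
#' length is `unique_bp + 2 * duplicated_bp`.
#'
#' @param spec A [kmer_genome_spec()].
#' @return List with `sequence` and `truth` (data.frame of 0-based
#'   half-open intervals labelled unique/duplicated).
#' @export
generate_kmer_genome <- function(spec = kmer_genome_spec()) {
  stopifnot(inherits(spec, "kmer_genome_spec"))
  set.seed(spec$seed)
  u1_len <- spec$unique_bp %/% 2L
  u2_len <- spec$unique_bp - u1_len
  u1 <- rand_dna(u1_len, spec$gc_fraction)
  u2 <- rand_dna(u2_len, spec$gc_fraction)
  d <- rand_dna(spec$duplicated_bp, spec$gc_fraction)
  seq <- paste0(u1, d, u2, d)
  b <- cumsum(c(0L, u1_len, spec$duplicated_bp, u2_len, spec$duplicated_bp))
  truth <- data.frame(
    role = c("unique", "duplicated", "unique", "duplicated"),
    start = b[1:4], end = b[2:5])
  list(sequence = seq, truth = truth)
}
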