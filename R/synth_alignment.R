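#' Plant diagnostic residues into a protein alignment
#'
#' Substitutes the stated residues at the alignment columns corresponding to
#' reference ungapped positions (1-based, matching mutation nomenclature such
#' as A780S). All other columns are untouched and the alignment width is
#' preserved.
#'
#' @param template Named character vector of aligned protein sequences
#'   (equal widths; `-` for gaps).
#' @param plants data.frame with columns `seq_id`, `position` (reference
#'   ungapped position), `residue` (one-letter code). May have zero rows.
#' @param reference_id Name of the sequence defining the numbering.
#' @return The modified alignment (named character vector).
#' @export
generate_alignment <- function(template, plants, reference_id) {
  if (!reference_id %in% names(template)) {
    c4_abort(sprintf("reference '%s' absent from alignment", reference_id),
             "invalid_input")
  }
  widths <- nchar(template)
  if (length(unique(widths)) != 1) {
    c4_abort("aligned sequences must have equal widths", "invalid_input")
  }
  out <- template
  if (nrow(plants) == 0) return(out)
  pos_map <- map_reference_positions(template, reference_id)
  for (i in seq_len(nrow(plants))) {
    p <- plants$position[i]
    if (p < 1 || p > length(pos_map)) {
      c4_abort(sprintf("position %d beyond reference length %d",
                       p, length(pos_map)), "out_of_range")
    }
    id <- plants$seq_id[i]
    if (!id %in% names(out)) {
      c4_abort(sprintf("sequence '%s' absent from alignment", id), "invalid_input")
    }
    col <- pos_map[p]
    substr(out[[id]], col, col) <- as.character(plants$residue[i])
  }
  out
}

#' Simulate a synthetic protein alignment scaffold
#'
#' Convenience generator for residue-scan tests: a random reference protein
#' and `n_seqs - 1` queries identical to it, with optional random gap columns
#' inserted to exercise reference-anchored numbering.
#'
#' @param n_seqs Number of sequences (reference first).
#' @param length Reference protein length (ungapped).
#' @param n_gap_cols Number of all-but-one-gap columns to insert.
#' @param seed Integer seed.
#' @return Named character vector of aligned sequences; the reference is
#'   named `ref`.
#' @export
simulate_protein_alignment <- function(n_seqs = 5, length = 900,
                                       n_gap_cols = 0, seed = 1L) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ref <- paste(sample(aa, length, replace = TRUE), collapse = "")
  seqs <- setNames(rep(ref, n_seqs),
                   c("ref", sprintf("query%d", seq_len(n_seqs - 1))))
  if (n_gap_cols > 0) {
    for (i in seq_len(n_gap_cols)) {
      # insert a column that is a residue in one random non-reference
      # sequence and a gap elsewhere
      w <- nchar(seqs[[1]])
      at <- sample.int(w + 1, 1)
      carrier <- sample(2:n_seqs, 1)
      for (j in seq_along(seqs)) {
        ins <- if (j == carrier) sample(aa, 1) else "-"
        seqs[[j]] <- paste0(substr(seqs[[j]], 1, at - 1), ins,
                            substr(seqs[[j]], at, w))
      }
    }
  }
  seqs
}
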