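#' Diagnostic residue table
#'
#' Sites of known C4-adaptive amino-acid substitutions, numbered on the
#' ungapped reference sequence (1-based, matching mutation nomenclature such
#' as A780S in PEPC). Tables for enzymes whose coordinates come from the
#' positive-selection literature (e.g. the nine PEPCK sites) are supplied as
#' data files, never invented; a bundled example table carries PEPC position
#' 780 only (`system.file("extdata", "pepc_sites.tsv", package = "c4kit")`).
#'
#' @param enzyme Enzyme label.
#' @param reference_id Sequence id defining the numbering.
#' @param sites data.frame with columns `position` (strictly increasing),
#'   `c3_residue` (single code), `c4_residues` (one or more codes, e.g.
#'   `"S"` or `"ST"`).
#' @return Object of class `diagnostic_table`.
#' @export
diagnostic_table <- function(enzyme, reference_id, sites) {
  stopifnot(all(c("position", "c3_residue", "c4_residues") %in% names(sites)))
  if (is.unsorted(sites$position, strictly = TRUE)) {
    c4_abort("site positions must be strictly increasing", "invalid_input")
  }
  aa <- "ACDEFGHIKLMNPQRSTVWY"
  res_ok <- function(x) all(strsplit(paste(x, collapse = ""), "")[[1]] %in%
                              strsplit(aa, "")[[1]])
  if (!res_ok(sites$c3_residue) || !res_ok(sites$c4_residues)) {
    c4_abort("residues must be valid one-letter amino-acid codes", "invalid_input")
  }
  structure(list(enzyme = enzyme, reference_id = reference_id, sites = sites),
            class = "diagnostic_table")
}

#' Read a diagnostic table from TSV
#'
#' Expected columns: `enzyme`, `reference_id`, `position`, `c3_residue`,
#' `c4_residues`.
#'
#' @param path TSV file.
#' @return A [diagnostic_table()].
#' @export
read_diagnostic_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  diagnostic_table(df$enzyme[1], df$reference_id[1],
                   df[, c("position", "c3_residue", "c4_residues")])
}

#' Map reference ungapped positions to alignment columns
#'
#' @param alignment Named character vector of aligned sequences (`-` gaps).
#' @param reference_id Sequence defining the numbering.
#' @return Integer vector: element `i` is the alignment column of reference
#'   ungapped position `i` (1-based).
#' @export
map_reference_positions <- function(alignment, reference_id) {
  if (!reference_id %in% names(alignment)) {
    c4_abort(sprintf("reference '%s' absent from alignment", reference_id),
             "invalid_input")
  }
  ch <- strsplit(alignment[[reference_id]], "", fixed = TRUE)[[1]]
  which(ch != "-")
}

#' Scan an alignment for diagnostic residue states
#'
#' Classifies, per sequence and site, the residue at the alignment column
#' anchored to the reference numbering: a member of the derived set is
#' `C4-like`, the ancestral residue is `C3-like`, a gap is `gap`, anything
#' else `other`. Because numbering is reference-anchored, inserting gap
#' columns never changes a classification.
#'
#' @param alignment Named character vector of aligned sequences.
#' @param table A [diagnostic_table()].
#' @return data.frame of class `residue_report`: one row per
#'   (sequence, site) with `residue` and `state`.
#' @export
scan_residues <- function(alignment, table) {
  stopifnot(inherits(table, "diagnostic_table"))
  pos_map <- map_reference_positions(alignment, table$reference_id)
  if (any(table$sites$position > length(pos_map))) {
    c4_abort("site position beyond reference length", "out_of_range")
  }
  cols <- pos_map[table$sites$position]
  rows <- lapply(names(alignment), function(id) {
    res <- substring(alignment[[id]], cols, cols)
    derived <- strsplit(table$sites$c4_residues, "", fixed = TRUE)
    state <- mapply(function(r, anc, der) {
      if (r == "-") "gap"
      else if (r %in% der) "C4-like"
      else if (r == anc) "C3-like"
      else "other"
    }, res, table$sites$c3_residue, derived)
    data.frame(seq_id = id, enzyme = table$enzyme,
               position = table$sites$position, column = cols,
               residue = res, state = unname(state))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("residue_report", "data.frame")
  out
}

#' Summarize C4-like site counts per sequence
#'
#' Counts `C4-like` sites per sequence (gap sites excluded) and issues a
#' `C4-signature` verdict when the count reaches `min_sites`.
#'
#' @param report A [scan_residues()] result.
#' @param min_sites Minimum derived-site count for the verdict (default 1).
#' @return data.frame with per-sequence state counts and `verdict`.
#' @export
summarize_residues <- function(report, min_sites = 1) {
  stopifnot(inherits(report, "residue_report"))
  ids <- unique(report$seq_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    r <- report[report$seq_id == id, ]
    n4 <- sum(r$state == "C4-like")
    if (all(r$state == "gap")) {
      c4_warn(sprintf("sequence '%s' is all-gap at every site", id), "all_gap")
    }
    data.frame(seq_id = id,
               n_c4_like = n4,
               n_c3_like = sum(r$state == "C3-like"),
               n_other = sum(r$state == "other"),
               n_gap = sum(r$state == "gap"),
               verdict = ifelse(n4 >= min_sites, "C4-signature", "no-signature"))
  }))
  rownames(out) <- NULL
  out
}

#' Read / write aligned protein FASTA as plain character vectors
#'
#' @param path File path.
#' @return Named character vector.
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_alignment
#' @param x Named character vector of aligned sequences.
#' @export
write_alignment <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(x), filepath = path)
  invisible(path)
}
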