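#' Trim contig ends
#'
#' Removes `n` bases from each end of a contig to discard potentially
#' misassembled tips; always applied before read extension.
#'
#' @param contig Character scalar.
#' @param n Bases to trim from each end (default 100).
#' @return Trimmed contig with the cumulative `trimmed_by` attribute updated.
#' @export
trim_ends <- function(contig, n = 100) {
  len <- nchar(contig)
  if (len <= 2 * n) {
    c4_abort(sprintf("contig of %d bp too short to trim %d bp from each end",
                     len, n), "too_short")
  }
  prev <- attr(contig, "trimmed_by")
  out <- substr(contig, n + 1, len - n)
  attr(out, "trimmed_by") <- (if (is.null(prev)) 0L else prev) + as.integer(n)
  out
}

#' Find reads containing a contig-end k-mer exactly
#'
#' Searches all reads for the exact k-mer and, separately, for its reverse
#' complement, mirroring a grep of raw reads on both strands.
#'
#' @param end_kmer k-mer from a trimmed contig end (default length 20).
#' @param reads Character vector of reads.
#' @return data.frame with `read` (index), `offset` (0-based position of the
#'   match within the read as given), `strand` (`"+"` if the read contains
#'   the k-mer, `"-"` if it contains the reverse complement).
#' @export
find_matching_reads <- function(end_kmer, reads) {
  hits_f <- grep(end_kmer, reads, fixed = TRUE)
  hits_r <- grep(revcomp(end_kmer), reads, fixed = TRUE)
  off <- function(idx, pat) {
    if (length(idx) == 0) return(integer(0))
    vapply(regexpr(pat, reads[idx], fixed = TRUE), identity, 0L) - 1L
  }
  data.frame(
    read = c(hits_f, hits_r),
    offset = c(off(hits_f, end_kmer), off(hits_r, revcomp(end_kmer))),
    strand = rep(c("+", "-"), c(length(hits_f), length(hits_r))))
}

# One round of rightward consensus extension. Returns list(added, reason):
# reason is NA while extension can continue, otherwise one of
# "no-matching-reads", "no-extension", "insufficient-support", "ambiguous".
extend_right_once <- function(seq, reads, k, min_support) {
  kmer <- substr(seq, nchar(seq) - k + 1, nchar(seq))
  m <- find_matching_reads(kmer, reads)
  if (nrow(m) == 0) return(list(added = "", reason = "no-matching-reads"))
  oriented <- ifelse(m$strand == "+", reads[m$read], revcomp(reads[m$read]))
  # after orientation the k-mer is on the forward strand of every read
  off <- as.integer(regexpr(kmer, oriented, fixed = TRUE)) - 1L
  tails <- substring(oriented, off + k + 1)
  tails <- tails[nchar(tails) > 0]
  if (length(tails) == 0) return(list(added = "", reason = "no-extension"))
  max_len <- max(nchar(tails))
  added <- character(0)
  reason <- NA_character_
  for (j in seq_len(max_len)) {
    bases <- substr(tails, j, j)
    bases <- bases[bases != ""]
    tab <- table(factor(bases, levels = DNA))
    top <- max(tab)
    if (top < min_support) { reason <- "insufficient-support"; break }
    if (sum(tab == top) > 1) { reason <- "ambiguous"; break }
    added <- c(added, names(tab)[which.max(tab)])
  }
  list(added = paste(added, collapse = ""), reason = reason)
}

#' Extend a contig by iterative exact k-mer read matching
#'
#' Repeatedly takes the terminal k-mer of each end, collects all reads
#' containing it (either strand), aligns them by the exact match and appends
#' the consensus of the bases the reads contribute beyond the end. Extension
#' of an end stops when no read extends it, when consensus support drops
#' below `min_support`, when the consensus is ambiguous (tie), or after
#' `max_rounds` rounds.
#'
#' @param contig Character scalar (length >= k).
#' @param reads Character vector of reads.
#' @param k Matching k-mer length (default 20).
#' @param min_support Minimum reads supporting a consensus base (default 2).
#' @param max_rounds Maximum extension rounds per end.
#' @param ends Which ends to extend.
#' @return List with `sequence`, `left` / `right` (per-end lists with bases
#'   `added` and the termination `reason`).
#' @export
extend_contig <- function(contig, reads, k = 20, min_support = 2,
                          max_rounds = 1000, ends = c("both", "left", "right")) {
  ends <- match.arg(ends)
  if (nchar(contig) < k) c4_abort("contig shorter than k", "too_short")
  extend_dir <- function(seq) {
    total <- 0L
    reason <- "max-rounds"
    for (r in seq_len(max_rounds)) {
      step <- extend_right_once(seq, reads, k, min_support)
      seq <- paste0(seq, step$added)
      total <- total + nchar(step$added)
      if (!is.na(step$reason) && nchar(step$added) == 0) { reason <- step$reason; break }
      if (!is.na(step$reason) && step$reason %in% c("no-matching-reads")) {
        reason <- step$reason; break
      }
    }
    list(seq = seq, added = total, reason = reason)
  }
  out <- as.character(contig)
  right <- list(added = 0L, reason = "not-extended")
  left <- list(added = 0L, reason = "not-extended")
  if (ends %in% c("both", "right")) {
    r <- extend_dir(out)
    out <- r$seq
    right <- r[c("added", "reason")]
  }
  if (ends %in% c("both", "left")) {
    r <- extend_dir(revcomp(out))
    out <- revcomp(r$seq)
    left <- r[c("added", "reason")]
  }
  list(sequence = out, left = left, right = right)
}

# Largest exact overlap s >= k with suffix(a, s) == prefix(b, s); 0 if none.
best_overlap <- function(a, b, k) {
  na <- nchar(a)
  tail_k <- substr(a, na - k + 1, na)
  hits <- gregexpr(tail_k, b, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(0L)
  best <- 0L
  for (p in hits) {
    s <- p + k - 1L
    if (s > na || s > nchar(b)) next
    if (substr(a, na - s + 1, na) == substr(b, 1, s)) best <- max(best, s)
  }
  best
}

# Count reads spanning a junction window (either strand).
junction_support <- function(window, reads) {
  length(grep(window, reads, fixed = TRUE)) +
    length(grep(revcomp(window), reads, fixed = TRUE))
}

#' Close all gaps between contigs and circularize
#'
#' Contigs are extended by consensus k-mer matching until their ends overlap
#' exactly by at least `k`, then merged; the process repeats until a single
#' sequence remains whose own ends overlap, which is then circularized.
#' Every junction (merge point and the final origin joint) is re-verified by
#' requiring at least `min_support` reads spanning it.
#'
#' @param contigs Named character vector of contigs (>= 1).
#' @param reads Character vector of reads.
#' @param k Matching/overlap k-mer length (default 20).
#' @param min_support Minimum consensus / junction-spanning read support.
#' @param max_rounds Overall cap on extend-merge iterations.
#' @param rounds_per_step Extension rounds granted per contig end between
#'   merge attempts.
#' @return List with `sequence` (circular, arbitrary rotation/strand),
#'   `junctions` (data.frame of junction positions and read support) and
#'   `iterations`. On failure, signals an `unresolved_gap` error listing the
#'   surviving contig ends (with the partial contigs attached to the
#'   condition).
#' @export
close_gaps <- function(contigs, reads, k = 20, min_support = 2,
                       max_rounds = 200, rounds_per_step = 3) {
  if (length(contigs) < 1) c4_abort("need at least one contig", "invalid_input")
  seqs <- as.character(contigs)
  junctions <- list()
  for (iter in seq_len(max_rounds)) {
    # 1) try to merge a pair (either orientation of the second contig)
    if (length(seqs) > 1) {
      merged <- FALSE
      for (i in seq_along(seqs)) {
        for (j in seq_along(seqs)) {
          if (i == j) next
          for (flip in c(FALSE, TRUE)) {
            b <- if (flip) revcomp(seqs[j]) else seqs[j]
            s <- best_overlap(seqs[i], b, k)
            if (s >= k) {
              joint_pos <- nchar(seqs[i])
              new_seq <- paste0(seqs[i], substring(b, s + 1))
              win <- substr(new_seq, max(1, joint_pos - k + 1), joint_pos + k)
              junctions[[length(junctions) + 1]] <- data.frame(
                type = "merge", position = joint_pos,
                support = junction_support(win, reads))
              seqs <- c(new_seq, seqs[-c(i, j)])
              merged <- TRUE
              break
            }
          }
          if (merged) break
        }
        if (merged) break
      }
      if (merged) next
    }
    # 2) single contig: attempt circularization via self-overlap
    if (length(seqs) == 1) {
      a <- seqs[1]
      na <- nchar(a)
      tail_k <- substr(a, na - k + 1, na)
      hits <- gregexpr(tail_k, a, fixed = TRUE)[[1]]
      hits <- hits[hits + k - 1 < na & hits + k - 1 <= na / 2]
      closed <- FALSE
      for (p in hits) {
        s <- p + k - 1L
        if (substr(a, na - s + 1, na) == substr(a, 1, s)) {
          circ <- substr(a, 1, na - s)
          win <- paste0(substr(circ, nchar(circ) - k + 1, nchar(circ)),
                        substr(circ, 1, k))
          junctions[[length(junctions) + 1]] <- data.frame(
            type = "origin", position = 0L,
            support = junction_support(win, reads))
          jt <- do.call(rbind, junctions)
          weak <- jt$support < min_support
          if (any(weak)) {
            c4_warn(sprintf("%d junction(s) below min_support", sum(weak)),
                    "weak_junction")
          }
          return(list(sequence = circ, junctions = jt, iterations = iter))
        }
      }
      if (!closed) {
        ext <- extend_contig(a, reads, k, min_support,
                             max_rounds = rounds_per_step)
        if (ext$left$added + ext$right$added == 0) {
          c4_abort(paste0("cannot circularize: both ends stopped (",
                          ext$left$reason, " / ", ext$right$reason, ")"),
                   "unresolved_gap", contigs = seqs)
        }
        seqs[1] <- ext$sequence
        next
      }
    }
    # 3) several contigs, none mergeable: extend every contig a little
    progress <- FALSE
    stop_reasons <- character(0)
    for (i in seq_along(seqs)) {
      ext <- extend_contig(seqs[i], reads, k, min_support,
                           max_rounds = rounds_per_step)
      if (ext$left$added + ext$right$added > 0) progress <- TRUE
      stop_reasons <- c(stop_reasons,
                        paste0(names(seqs)[i] %||% i, ":",
                               ext$left$reason, "/", ext$right$reason))
      seqs[i] <- ext$sequence
    }
    if (!progress) {
      c4_abort(paste0("unresolved gap(s); surviving contig ends: ",
                      paste(stop_reasons, collapse = "; ")),
               "unresolved_gap", contigs = seqs)
    }
  }
  c4_abort("max_rounds reached before closure", "unresolved_gap", contigs = seqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
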