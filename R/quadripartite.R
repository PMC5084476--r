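# Longest pair of disjoint reverse-complement-identical repeats on a circular
# sequence, found by anchoring k-mers of the doubled sequence against the
# k-mers of its reverse complement and chaining diagonal runs of hits.
find_ir_pair <- function(s, min_ir, anchor_k = 31) {
  n <- nchar(s)
  s2 <- paste0(s, s)
  r2 <- revcomp(s2)
  ks <- seq_kmers(s2, anchor_k)
  kr <- seq_kmers(r2, anchor_k)
  m <- match(kr, ks)
  ok <- !is.na(m)
  if (!any(ok)) return(NULL)
  # maximal runs with consecutive j and the matched position advancing by one
  # (modulo n: match() reports first occurrences in the doubled string, so a
  # repeat spanning the origin shows a jump of exactly n that must chain)
  idx <- which(ok)
  mm <- (m[idx] - 1L) %% n
  brk <- c(TRUE, diff(idx) != 1 | (diff(mm) %% n) != 1)
  run_id <- cumsum(brk)
  runs <- data.frame(j1 = tapply(idx, run_id, min),
                     j2 = tapply(idx, run_id, max))
  runs$len <- runs$j2 - runs$j1 + anchor_k        # matched bases
  runs <- runs[runs$len >= min_ir & runs$len <= n, , drop = FALSE]
  if (nrow(runs) == 0) return(NULL)
  runs <- runs[order(-runs$len), , drop = FALSE]
  for (q in seq_len(nrow(runs))) {
    j1 <- runs$j1[q]; j2 <- runs$j2[q]
    i1 <- m[j1]                                    # 1-based start in s2
    L <- runs$len[q]
    # partner: r2[j..j+k) == revcomp(s2[2n-j-k+2 .. 2n-j+1])
    p_start <- 2 * n - j2 - anchor_k + 2           # 1-based start in s2
    a0 <- ((i1 - 1) %% n)                          # 0-based circular starts
    b0 <- ((p_start - 1) %% n)
    ia <- c(a0, L); ib <- c(b0, L)
    if (arcs_disjoint(ia, ib, n)) {
      return(list(ir1 = ia, ir2 = ib, length = L))
    }
  }
  NULL
}

# Are two circular arcs (0-based start, length) disjoint? Two arcs overlap
# on the circle iff either arc's start falls inside the other.
arcs_disjoint <- function(a, b, n) {
  inside <- function(p, s, l) ((p - s) %% n) < l
  !(inside(b[1], a[1], a[2]) || inside(a[1], b[1], b[2]))
}

#' Detect the quadripartite plastome structure and canonicalize
#'
#' Finds the longest pair of disjoint reverse-complement-identical repeats of
#' at least `min_ir` bases on the circular assembly, labels the longer
#' intervening single-copy region LSC and the shorter SSC, and
#' rotates/flips the sequence to the conventional `LSC + IRb + SSC + IRa`
#' linearization. Orientation is resolved deterministically (the
#' lexicographically smaller of the two valid canonical strings), so a
#' flipped or rotated input yields an identical canonical output.
#'
#' @param assembly Circular nucleotide sequence (character scalar, any
#'   rotation/strand).
#' @param min_ir Minimum inverted-repeat length to accept (>= 100).
#' @param anchor_k Anchor k-mer size for repeat finding.
#' @return List with `partition` (a `plastome_partition`) and `sequence`
#'   (canonical linearization).
#' @export
detect_quadripartite <- function(assembly, min_ir = 1000, anchor_k = 31) {
  if (min_ir < 100) c4_abort("min_ir must be >= 100", "invalid_parameter")
  n <- nchar(assembly)
  if (n < 4 * min_ir) {
    c4_abort("assembly too short to host a quadripartite structure",
             "no_quadripartite")
  }
  canonical_of <- function(s) {
    pair <- find_ir_pair(s, min_ir, anchor_k)
    if (is.null(pair)) return(NULL)
    ir_len <- pair$length
    # single-copy arcs between the repeats
    end1 <- (pair$ir1[1] + ir_len) %% n
    end2 <- (pair$ir2[1] + ir_len) %% n
    sc_a <- c(end1, (pair$ir2[1] - end1) %% n)   # after ir1
    sc_b <- c(end2, (pair$ir1[1] - end2) %% n)   # after ir2
    if (sc_a[2] == 0 || sc_b[2] == 0) return(NULL)
    if (sc_a[2] >= sc_b[2]) {
      lsc <- sc_a; ssc <- sc_b
      irb <- pair$ir2; ira <- pair$ir1
    } else {
      lsc <- sc_b; ssc <- sc_a
      irb <- pair$ir1; ira <- pair$ir2
    }
    # canonical: start at the LSC start; order is LSC, IRb, SSC, IRa
    list(seq = rotate_seq(s, lsc[1] + 1),
         lsc = lsc[2], ir = ir_len, ssc = ssc[2])
  }
  fwd <- canonical_of(assembly)
  rev <- canonical_of(revcomp(assembly))
  if (is.null(fwd) && is.null(rev)) {
    c4_abort(sprintf("no disjoint inverted-repeat pair >= %d bp found", min_ir),
             "no_quadripartite")
  }
  pick <- if (is.null(rev) || (!is.null(fwd) && fwd$seq <= rev$seq)) fwd else rev
  list(partition = new_partition(pick$lsc, pick$ir, pick$ssc),
       sequence = pick$seq)
}

#' k-mer coverage track over an assembly with anomaly flagging
#'
#' Per-position abundance (in the reads, strand-canonical) of the k-mer
#' starting at each assembly position, summarised in tiling windows. Windows
#' whose mean abundance deviates from the modal single-copy level by more
#' than `fold_tol` are flagged as anomalies -- except inside inverted
#' repeats, where the expected level is twofold (windows straddling an IR
#' boundary are exempt because their expectation is mixed).
#'
#' @param assembly Character scalar (assumed circular).
#' @param reads Character vector of reads.
#' @param k k-mer size (default 20; must not exceed the read length).
#' @param window Window size in bases for the summary track.
#' @param ir Optional data.frame of 0-based half-open IR intervals
#'   (columns `start`, `end`) on the assembly, e.g. from
#'   [detect_quadripartite()].
#' @param fold_tol Flag a window when its mean differs from its expected
#'   level by more than this factor.
#' @return List of class `coverage_track`: `abundance` (per-position
#'   integer), `windows` (data.frame with mean abundance, expected level and
#'   flag), `anomalies` (flagged subset), `modal_level`.
#' @export
coverage_track <- function(assembly, reads, k = 20, window = 500,
                           ir = NULL, fold_tol = 1.5) {
  if (k < 1 || k > 31) c4_abort("k must be in [1, 31]", "invalid_parameter")
  if (length(reads) > 0 && k > min(nchar(reads))) {
    c4_abort("k exceeds the read length", "invalid_parameter")
  }
  n <- nchar(assembly)
  if (n < k) c4_abort("assembly shorter than k", "invalid_parameter")
  if (length(reads) == 0) {
    c4_warn("empty read set: coverage track is all zero", "empty_reads")
    ab <- integer(n)
  } else {
    ab <- cpp_position_abundance(assembly, as.character(reads), as.integer(k),
                                 TRUE, TRUE)
  }
  starts <- seq(0L, n - 1L, by = window)
  ends <- pmin(starts + window, n)
  wmean <- vapply(seq_along(starts),
                  function(i) mean(ab[(starts[i] + 1):ends[i]]), 0)
  in_ir <- rep(FALSE, length(starts))
  straddles <- rep(FALSE, length(starts))
  if (!is.null(ir) && nrow(ir) > 0) {
    for (i in seq_along(starts)) {
      ov <- pmin(ends[i], ir$end) - pmax(starts[i], ir$start)
      cov <- sum(pmax(0, ov))
      in_ir[i] <- cov == (ends[i] - starts[i])
      straddles[i] <- cov > 0 && !in_ir[i]
    }
  }
  modal <- median(wmean[!in_ir & !straddles])
  expected <- ifelse(in_ir, 2 * modal, modal)
  flagged <- !straddles &
    (wmean > expected * fold_tol | wmean < expected / fold_tol)
  windows <- data.frame(start = starts, end = ends, mean = wmean,
                        expected = expected, in_ir = in_ir,
                        boundary = straddles, flagged = flagged)
  structure(list(k = k, abundance = ab, windows = windows,
                 anomalies = windows[windows$flagged, , drop = FALSE],
                 modal_level = modal),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: k=%d, %d positions, modal level %.1fx, %d anomalous window(s)\n",
              x$k, length(x$abundance), x$modal_level, nrow(x$anomalies)))
  invisible(x)
}
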