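#' Plastome simulation specification
#'
#' Describes a circular quadripartite chloroplast genome: a large single-copy
#' region (LSC), a small single-copy region (SSC) and two inverted-repeat
#' copies (IRb, IRa) with IRa the reverse complement of IRb. Defaults follow
#' typical panicoid grass plastome geometry.
#'
#' @param lsc_len,ssc_len,ir_len Segment lengths in bases.
#' @param gc_fraction GC content of the simulated sequence, in `[0, 1]`.
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @return An object of class `plastome_spec`.
#' @export
plastome_spec <- function(lsc_len = 82090, ssc_len = 12572, ir_len = 22719,
                          gc_fraction = 0.38, seed = 1L) {
  lens <- c(lsc_len = lsc_len, ssc_len = ssc_len, ir_len = ir_len)
  if (any(!is.finite(lens)) || any(lens < 100)) {
    c4_abort("plastome segment lengths must all be >= 100 bases", "invalid_spec")
  }
  if (gc_fraction < 0 || gc_fraction > 1) {
    c4_abort("gc_fraction must lie in [0, 1]", "invalid_spec")
  }
  structure(list(lsc_len = as.integer(lsc_len), ssc_len = as.integer(ssc_len),
                 ir_len = as.integer(ir_len), gc_fraction = gc_fraction,
                 seed = as.integer(seed)),
            class = "plastome_spec")
}

# Quadripartite partition record: lengths plus 0-based half-open intervals on
# the canonical linearization LSC | IRb | SSC | IRa.
new_partition <- function(lsc, ir, ssc) {
  total <- lsc + ssc + 2L * ir
  b <- cumsum(c(0L, lsc, ir, ssc, ir))
  structure(list(
    lsc_len = as.integer(lsc), irb_len = as.integer(ir),
    ssc_len = as.integer(ssc), ira_len = as.integer(ir),
    total = as.integer(total),
    boundaries = data.frame(
      region = c("LSC", "IRb", "SSC", "IRa"),
      start = b[1:4], end = b[2:5])),
    class = "plastome_partition")
}

#' @export
print.plastome_partition <- function(x, ...) {
  cat(sprintf("Quadripartite plastome partition (total %s bp)\n",
              format(x$total, big.mark = ",")))
  print(x$boundaries, row.names = FALSE)
  invisible(x)
}

#' Generate a circular quadripartite plastome with known partition
#'
#' Emits `LSC + IRb + SSC + IRa` where IRa is the exact reverse complement of
#' IRb, together with the true partition (the ground truth consumed by the
#' finishing-pipeline oracles).
#'
#' @param spec A [plastome_spec()].
#' @return A list of class `plastome` with elements `sequence` (character
#'   scalar, canonical linearization) and `partition`
#'   (`plastome_partition`).
#' @export
generate_plastome <- function(spec = plastome_spec()) {
  stopifnot(inherits(spec, "plastome_spec"))
  set.seed(spec$seed)
  lsc <- rand_dna(spec$lsc_len, spec$gc_fraction)
  ssc <- rand_dna(spec$ssc_len, spec$gc_fraction)
  irb <- rand_dna(spec$ir_len, spec$gc_fraction)
  # pin the repeat boundaries: a chance complementary base just outside the
  # designed repeat would extend the true maximal inverted repeat by one,
  # making the recorded partition ambiguous. Resample the flanking bases so
  # the designed IR is exactly the maximal repeat.
  comp1 <- function(b) chartr("ACGT", "TGCA", b)
  while (substr(lsc, 1, 1) == comp1(substr(lsc, spec$lsc_len, spec$lsc_len))) {
    substr(lsc, 1, 1) <- sample(DNA, 1)
  }
  while (substr(ssc, spec$ssc_len, spec$ssc_len) == comp1(substr(ssc, 1, 1))) {
    substr(ssc, spec$ssc_len, spec$ssc_len) <- sample(DNA, 1)
  }
  seq <- paste0(lsc, irb, ssc, revcomp(irb))
  structure(list(sequence = seq,
                 partition = new_partition(spec$lsc_len, spec$ir_len, spec$ssc_len)),
            class = "plastome")
}

#' Shred a genome into error-prone short reads
#'
#' Uniform random read sampling with strand-random orientation and i.i.d.
#' substitution errors; on circular genomes reads may span the origin.
#' Emulates 2x100 bp Illumina shotgun data (substitutions only; the
#' downstream extension algorithm uses exact matching, so substitutions
#' suffice to exercise robustness).
#'
#' @param genome Character scalar (A/C/G/T).
#' @param read_len Read length in bases.
#' @param coverage Fold sequencing depth (>= 1); the read count is
#'   `ceiling(coverage * nchar(genome) / read_len)`.
#' @param error_rate Per-base substitution probability, in `[0, 0.05]`.
#' @param circular Should reads wrap the origin?
#' @param seed Integer seed.
#' @return Named character vector of reads.
#' @export
shred_reads <- function(genome, read_len = 100, coverage = 50,
                        error_rate = 0, circular = TRUE, seed = 1L) {
  n <- nchar(genome)
  if (n == 0) c4_abort("genome is empty", "invalid_spec")
  if (read_len > n) c4_abort("read_len exceeds genome length", "invalid_spec")
  if (coverage < 1) c4_abort("coverage must be >= 1", "invalid_spec")
  if (error_rate < 0 || error_rate > 0.05) {
    c4_abort("error_rate must lie in [0, 0.05]", "invalid_spec")
  }
  set.seed(seed)
  n_reads <- ceiling(coverage * n / read_len)
  if (circular) {
    starts <- sample.int(n, n_reads, replace = TRUE)
    g2 <- paste0(genome, substr(genome, 1, read_len - 1))
    reads <- substring(g2, starts, starts + read_len - 1)
  } else {
    starts <- sample.int(n - read_len + 1, n_reads, replace = TRUE)
    reads <- substring(genome, starts, starts + read_len - 1)
  }
  flip <- runif(n_reads) < 0.5
  reads[flip] <- revcomp(reads[flip])
  if (error_rate > 0) {
    n_err <- stats::rbinom(n_reads, read_len, error_rate)
    for (i in which(n_err > 0)) {
      pos <- sample.int(read_len, n_err[i])
      ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
      ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(DNA, b), 1), "")
      reads[i] <- paste(ch, collapse = "")
    }
  }
  setNames(reads, paste0("read", seq_len(n_reads)))
}

#' Break a genome into contigs with known gaps
#'
#' Places `n_gaps` disjoint gaps on the circular genome and returns the
#' intervening arcs as contigs, optionally with random bases appended to
#' contig ends to emulate misassembled tips (to be removed by the trim-100
#' rule). The gap truth table is returned for oracle tests.
#'
#' @param genome Character scalar.
#' @param n_gaps Number of gaps (>= 1).
#' @param min_gap Minimum gap length in bases; actual gaps are drawn in
#'   `[min_gap, 2 * min_gap]`.
#' @param end_slop Maximum number of random bases appended at each contig end.
#' @param seed Integer seed.
#' @param avoid Optional data.frame of 0-based half-open intervals (columns
#'   `start`, `end`) that gaps must stay clear of (with a trim-plus-k
#'   margin). Assemblers break plastome contigs at repeat junctions rather
#'   than across them, and a gap straddling an IR boundary has no unique
#'   local closure (the two flip-flop isomers are equally supported), so
#'   junction coordinates are typically passed here.
#' @return List with `contigs` (named character vector) and `gaps`
#'   (data.frame of 0-based half-open gap intervals on the input genome).
#' @export
seed_contigs <- function(genome, n_gaps = 3, min_gap = 150, end_slop = 0,
                         seed = 1L, avoid = NULL) {
  n <- nchar(genome)
  if (n_gaps < 1) c4_abort("n_gaps must be >= 1", "invalid_spec")
  min_contig <- 2L * as.integer(min_gap)  # keep contigs workable
  if (n_gaps * (2 * min_gap + min_contig) > n) {
    c4_abort("gaps cannot fit on this genome", "invalid_spec")
  }
  set.seed(seed)
  gap_len <- min_gap + sample.int(min_gap + 1, n_gaps, replace = TRUE) - 1L
  margin <- 150L  # trim-100 plus extension k plus slack
  clear_of_avoid <- function(cuts) {
    if (is.null(avoid) || nrow(avoid) == 0) return(TRUE)
    gs <- cuts - 1L - margin
    ge <- cuts - 1L + gap_len + margin
    for (i in seq_along(cuts)) {
      if (any(pmax(gs[i], avoid$start) < pmin(ge[i], avoid$end))) return(FALSE)
      # circular wrap of the expanded gap
      if (ge[i] > n && any(avoid$start < ge[i] - n)) return(FALSE)
      if (gs[i] < 0 && any(avoid$end > n + gs[i])) return(FALSE)
    }
    TRUE
  }
  # choose gap start offsets: split the circle into n_gaps arcs of random
  # length, each arc hosting one gap at its start
  repeat {
    cuts <- sort(sample.int(n, n_gaps))
    arc <- diff(c(cuts, cuts[1] + n))
    if (all(arc >= gap_len + min_contig) && clear_of_avoid(cuts)) break
  }
  gap_start <- cuts                       # 1-based on genome
  gap_end <- gap_start + gap_len          # exclusive
  contigs <- character(n_gaps)
  for (i in seq_len(n_gaps)) {
    s <- gap_end[i]                       # contig starts after gap i
    e <- gap_start[if (i == n_gaps) 1 else i + 1] + (if (i == n_gaps) n else 0)
    contigs[i] <- circ_substr(genome, s, e - s)
    if (end_slop > 0) {
      contigs[i] <- paste0(rand_dna(sample.int(end_slop + 1, 1) - 1),
                           contigs[i],
                           rand_dna(sample.int(end_slop + 1, 1) - 1))
    }
  }
  list(contigs = setNames(contigs, paste0("contig", seq_len(n_gaps))),
       gaps = data.frame(gap = seq_len(n_gaps),
                         start = gap_start - 1L, end = gap_end - 1L,
                         length = gap_len))
}
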