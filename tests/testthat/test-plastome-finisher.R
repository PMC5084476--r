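test_that("trim_ends removes exactly n bases per end and tracks provenance", {
  ctg <- paste(rep("ACGT", 250), collapse = "")  # 1000 bp
  out <- trim_ends(ctg, 100)
  expect_equal(nchar(out), 800)
  expect_identical(as.character(out), substr(ctg, 101, 900))
  expect_equal(attr(out, "trimmed_by"), 100L)
  expect_identical(as.character(trim_ends(ctg, 0)), ctg)
  expect_error(trim_ends(strrep("A", 150), 100), class = "too_short")
})

test_that("find_matching_reads reports exact hits on both strands", {
  kmer <- "AAACCCGGGTTTAACCGGAT"  # not its own reverse complement
  reads <- c(r1 = paste0("TTTTT", kmer, "GGGGG"),
             r2 = revcomp(paste0("AA", kmer, "CC")),
             r3 = strrep("C", 30))
  m <- find_matching_reads(kmer, reads)
  expect_equal(nrow(m), 2)
  fwd <- m[m$strand == "+", ]
  expect_equal(fwd$read, 1)
  expect_equal(fwd$offset, 5)  # 0-based: len("TTTTT")
  expect_equal(m$read[m$strand == "-"], 2)
  expect_equal(nrow(find_matching_reads(strrep("A", 20), reads["r3"])), 0)
})

test_that("consensus extension recovers source bases and stops on ambiguity", {
  pl <- small_plastome()
  reads <- shred_reads(pl$sequence, coverage = 50, error_rate = 0, seed = 11)
  start <- 2001
  ctg <- substr(pl$sequence, start, start + 499)
  ext <- extend_contig(ctg, reads, k = 20, max_rounds = 3)
  expect_gt(ext$right$added, 0)
  expect_gt(ext$left$added, 0)
  # every extended base matches the source genome
  g2 <- paste0(pl$sequence, pl$sequence)
  expect_true(grepl(ext$sequence, g2, fixed = TRUE))

  # no matching reads -> unchanged
  none <- extend_contig(ctg, reads = c("TTTTTTTTTTTTTTTTTTTTTTTTT"), k = 20)
  expect_identical(none$sequence, ctg)
  expect_equal(none$right$reason, "no-matching-reads")

  # explicit tie: two read groups support different next bases equally
  base <- strrep("ACGTG", 8)  # 40 bp contig
  tie_reads <- c(paste0(substr(base, 21, 40), "A"),
                 paste0(substr(base, 21, 40), "A"),
                 paste0(substr(base, 21, 40), "C"),
                 paste0(substr(base, 21, 40), "C"))
  tie <- extend_contig(base, tie_reads, k = 20, ends = "right")
  expect_identical(tie$sequence, base)
  expect_equal(tie$right$reason, "ambiguous")

  # insufficient support: a single read is below min_support = 2
  single <- extend_contig(base, tie_reads[1], k = 20, ends = "right")
  expect_identical(single$sequence, base)
  expect_equal(single$right$reason, "insufficient-support")
})

test_that("close_gaps reassembles the circle from gapped contigs", {
  pl <- small_plastome(seed = 5)
  reads <- shred_reads(pl$sequence, coverage = 50, error_rate = 0, seed = 12)
  sc <- seed_contigs(pl$sequence, n_gaps = 2, min_gap = 150, end_slop = 20,
                     seed = 13)
  ctg <- vapply(sc$contigs, function(x) trim_ends(x, 100), "")
  res <- close_gaps(ctg, reads, k = 20)
  expect_equal(nchar(res$sequence), nchar(pl$sequence))
  # equality up to rotation and strand
  g2 <- paste0(pl$sequence, pl$sequence)
  expect_true(grepl(res$sequence, g2, fixed = TRUE) ||
                grepl(revcomp(res$sequence), g2, fixed = TRUE))
  expect_true(all(res$junctions$support >= 2))

  # a single contig covering the circle with >= k self-overlap circularizes
  full <- paste0(pl$sequence, substr(pl$sequence, 1, 30))
  res1 <- close_gaps(c(one = full), reads, k = 20)
  expect_equal(nchar(res1$sequence), nchar(pl$sequence))

  # removing all reads over one gap leaves it unresolved
  gap <- sc$gaps[1, ]
  gap_mid <- (gap$start + gap$end) / 2
  pos <- unlist(lapply(seq_along(reads), function(i) {
    hit <- regexpr(reads[i], g2, fixed = TRUE)
    if (hit > 0) hit else regexpr(revcomp(reads[i]), g2, fixed = TRUE)
  }))
  covers <- (pos <= gap_mid + 1) & (pos + 99 >= gap_mid - 1)
  covers <- covers | ((pos - nchar(pl$sequence) <= gap_mid + 1) &
                        (pos - nchar(pl$sequence) + 99 >= gap_mid - 1))
  expect_error(close_gaps(ctg, reads[!covers], k = 20),
               class = "unresolved_gap")
})

test_that("detect_quadripartite finds true partitions, invariantly to orientation", {
  pl <- small_plastome(seed = 6)
  q <- detect_quadripartite(pl$sequence, min_ir = 500)
  expect_equal(q$partition$lsc_len, 8000)
  expect_equal(q$partition$ssc_len, 1500)
  expect_equal(q$partition$irb_len, 2000)
  expect_equal(q$partition$total, 13500)
  expect_equal(q$partition$lsc_len + q$partition$ssc_len +
                 2 * q$partition$irb_len, q$partition$total)
  # rotation + strand flip yields the identical canonical output
  flipped <- revcomp(paste0(substr(pl$sequence, 4001, 13500),
                            substr(pl$sequence, 1, 4000)))
  q2 <- detect_quadripartite(flipped, min_ir = 500)
  expect_identical(q2$sequence, q$sequence)
  expect_equal(q2$partition$boundaries, q$partition$boundaries)
  # rotation that splits an IR across the origin still resolves
  rot <- paste0(substr(pl$sequence, 9001, 13500),
                substr(pl$sequence, 1, 9000))  # cut inside IRb
  q3 <- detect_quadripartite(rot, min_ir = 500)
  expect_identical(q3$sequence, q$sequence)

  set.seed(1)
  random <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                  collapse = "")
  expect_error(detect_quadripartite(random, min_ir = 500),
               class = "no_quadripartite")
  expect_error(detect_quadripartite(pl$sequence, min_ir = 10),
               class = "invalid_parameter")
})

test_that("coverage_track matches shredding arithmetic and flags dropouts", {
  pl <- small_plastome(seed = 7)
  reads <- shred_reads(pl$sequence, coverage = 50, error_rate = 0, seed = 14)
  q <- detect_quadripartite(pl$sequence, min_ir = 500)
  ir <- q$partition$boundaries[q$partition$boundaries$region %in%
                                 c("IRb", "IRa"), c("start", "end")]
  tr <- coverage_track(q$sequence, reads, k = 20, window = 500, ir = ir)
  expected <- 50 * (100 - 20 + 1) / 100  # 40.5
  expect_lt(abs(tr$modal_level - expected) / expected, 0.1)
  ir_ratio <- mean(tr$windows$mean[tr$windows$in_ir]) / tr$modal_level
  expect_lt(abs(ir_ratio - 2), 0.15)
  expect_equal(nrow(tr$anomalies), 0)
  expect_length(tr$abundance, nchar(q$sequence))  # circular track

  # deleting reads over a 1 kb interval flags that window
  g2 <- paste0(pl$sequence, pl$sequence)
  pos <- vapply(reads, function(r) {
    h <- regexpr(r, g2, fixed = TRUE)
    if (h > 0) as.integer(h) else as.integer(regexpr(revcomp(r), g2, fixed = TRUE))
  }, 0L)
  drop <- (pos >= 3000 & pos <= 4000) |
    (pos - nchar(pl$sequence) >= 3000 & pos - nchar(pl$sequence) <= 4000)
  tr2 <- coverage_track(pl$sequence, reads[!drop], k = 20, window = 500)
  expect_gt(nrow(tr2$anomalies), 0)
  expect_true(any(tr2$anomalies$start >= 2500 & tr2$anomalies$end <= 4700))

  expect_error(coverage_track(pl$sequence, reads, k = 150),
               class = "invalid_parameter")
  expect_warning(coverage_track(substr(pl$sequence, 1, 2000), character(0), k = 20),
                 class = "empty_reads")
})
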