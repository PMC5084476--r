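test_that("generated plastome has exact quadripartite construction", {
  pl <- generate_plastome(plastome_spec(lsc_len = 1000, ssc_len = 300,
                                        ir_len = 200, seed = 1))
  s <- pl$sequence
  expect_equal(nchar(s), 1700)
  # IRa (bases 1501-1700) is the reverse complement of IRb (bases 1001-1200)
  expect_identical(substr(s, 1501, 1700), revcomp(substr(s, 1001, 1200)))
  p <- pl$partition
  expect_equal(p$lsc_len + p$ssc_len + 2 * p$irb_len, p$total)
  expect_equal(p$boundaries$end - p$boundaries$start,
               c(p$lsc_len, p$irb_len, p$ssc_len, p$ira_len))
  # determinism
  pl2 <- generate_plastome(plastome_spec(lsc_len = 1000, ssc_len = 300,
                                         ir_len = 200, seed = 1))
  expect_identical(pl2$sequence, s)
  # Table-2-scale defaults give the full published geometry
  expect_equal(generate_plastome(plastome_spec(seed = 2))$partition$total, 140100)
  expect_error(plastome_spec(lsc_len = 50), class = "invalid_spec")
})

test_that("shred_reads honours count, exactness, orientation and errors", {
  pl <- generate_plastome(plastome_spec(lsc_len = 1000, ssc_len = 300,
                                        ir_len = 200, seed = 1))
  reads <- shred_reads(pl$sequence, read_len = 100, coverage = 50,
                       error_rate = 0, seed = 2)
  expect_length(reads, 850)  # ceiling(50 * 1700 / 100)
  # every error-free read is a substring of the doubled genome or its revcomp
  g2 <- paste0(pl$sequence, pl$sequence)
  in_genome <- vapply(reads, function(r) {
    grepl(r, g2, fixed = TRUE) || grepl(revcomp(r), g2, fixed = TRUE)
  }, TRUE)
  expect_true(all(in_genome))
  # both orientations occur
  fwd <- vapply(reads, function(r) grepl(r, g2, fixed = TRUE), TRUE)
  expect_true(any(fwd) && any(!fwd))
  expect_error(shred_reads(pl$sequence, read_len = 5000), class = "invalid_spec")

  # substitution rate within 3 binomial SDs of the target
  err_reads <- shred_reads(pl$sequence, read_len = 100, coverage = 60,
                           error_rate = 0.01, seed = 3)
  n_bases <- sum(nchar(err_reads))
  mism <- sum(vapply(err_reads, function(r) {
    !(grepl(r, g2, fixed = TRUE) || grepl(revcomp(r), g2, fixed = TRUE))
  }, TRUE))
  # read-level: P(read error-free) = (1-0.01)^100; compare observed fraction
  p_read <- 1 - 0.99^100
  sd3 <- 3 * sqrt(p_read * (1 - p_read) / length(err_reads))
  expect_lt(abs(mism / length(err_reads) - p_read), sd3)
  expect_gt(n_bases, 1e5)
})

test_that("seed_contigs produces covering contigs with recorded gap truth", {
  pl <- small_plastome()
  sc <- seed_contigs(pl$sequence, n_gaps = 2, min_gap = 150, end_slop = 0,
                     seed = 4)
  expect_length(sc$contigs, 2)
  expect_equal(nrow(sc$gaps), 2)
  expect_lte(sum(nchar(sc$contigs)), nchar(pl$sequence) - 300)
  g2 <- paste0(pl$sequence, pl$sequence)
  expect_true(all(vapply(sc$contigs, grepl, TRUE, x = g2, fixed = TRUE)))
  # gap truth intervals are disjoint from contig bases: gap k-mers absent
  for (i in seq_len(nrow(sc$gaps))) {
    gap_seq <- substr(pl$sequence, sc$gaps$start[i] + 1, sc$gaps$end[i])
    expect_false(any(grepl(gap_seq, sc$contigs, fixed = TRUE)))
  }
  expect_error(seed_contigs(pl$sequence, n_gaps = 50, min_gap = 5000),
               class = "invalid_spec")
})

test_that("kmer genome generator partitions unique and duplicated sequence", {
  g <- generate_kmer_genome(kmer_genome_spec(unique_bp = 1e4,
                                             duplicated_bp = 2e3, seed = 1))
  expect_equal(nchar(g$sequence), 1e4 + 2 * 2e3)
  dup <- substr(g$sequence, g$truth$start[2] + 1, g$truth$end[2])
  expect_equal(length(gregexpr(dup, g$sequence, fixed = TRUE)[[1]]), 2)
  # k-mers inside the duplicated block occur >= 2 times
  cnt <- count_kmers(g$sequence, 21)
  dup_kmers <- count_kmers(dup, 21)
  m <- match(dup_kmers$kmer, cnt$kmer)
  expect_true(all(cnt$count[m] >= 2))
  # GC of a 50% GC genome within 3 SD of 0.5
  gc <- sum(strsplit(g$sequence, "")[[1]] %in% c("G", "C")) / nchar(g$sequence)
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / nchar(g$sequence)))
})

test_that("gradient generator is deterministic with planted fold effects", {
  d <- gradient_design(n_genes = 50, n_tf = 20,
                       planted = data.frame(tf = 1:2,
                                            pattern = c("Zmays", "Zmays,Sbicolor"),
                                            fold = 4),
                       noise_cv = 0.2, seed = 5)
  g1 <- generate_gradient(d)
  g2 <- generate_gradient(d)
  expect_identical(g1$datasets$Zmays$fpkm, g2$datasets$Zmays$fpkm)
  expect_error(gradient_design(n_replicates = 1), class = "invalid_design")
  expect_error(gradient_design(planted = data.frame(tf = 999, pattern = "Zmays",
                                                    fold = 4)),
               class = "invalid_design")
  expect_error(gradient_design(planted = data.frame(tf = 1, pattern = "Osativa",
                                                    fold = 4)),
               class = "invalid_design")

  # with noise_cv -> 0 the perturbed/unperturbed segment-mean ratio is the fold
  d0 <- gradient_design(n_genes = 10, n_tf = 4,
                        planted = data.frame(tf = 1, pattern = "Zmays", fold = 4),
                        noise_cv = 1e-4, seed = 6)
  g <- generate_gradient(d0)
  segs <- as.integer(strsplit(g$truth$segments[1], ",")[[1]])
  p_zm <- mean_profiles(g$datasets$Zmays)["tf0001", ]
  p_os <- mean_profiles(g$datasets$Osativa)["tf0001", ]
  expect_equal(unname(p_zm[segs] / p_os[segs]), c(4, 4), tolerance = 1e-2)
  other <- setdiff(1:4, segs)
  expect_equal(unname(p_zm[other] / p_os[other]), c(1, 1), tolerance = 1e-2)
})

test_that("alignment generator plants residues without touching other columns", {
  aln <- simulate_protein_alignment(n_seqs = 3, length = 100, n_gap_cols = 2,
                                    seed = 1)
  out <- generate_alignment(aln, data.frame(seq_id = "query1", position = 50,
                                            residue = "W"), "ref")
  col <- map_reference_positions(aln, "ref")[50]
  expect_identical(substr(out[["query1"]], col, col), "W")
  # only that column changed
  chars_in <- strsplit(aln[["query1"]], "")[[1]]
  chars_out <- strsplit(out[["query1"]], "")[[1]]
  expect_equal(which(chars_in != chars_out), col)
  expect_identical(out[["ref"]], aln[["ref"]])
  expect_equal(nchar(out), nchar(aln))
  # empty plant list is the identity
  expect_identical(generate_alignment(aln, data.frame()[0, ], "ref"), aln)
  expect_error(generate_alignment(aln, data.frame(seq_id = "query1",
                                                  position = 101, residue = "W"),
                                  "ref"),
               class = "out_of_range")
})

test_that("simulate_aci reduces to the model curve at zero noise", {
  p <- aci_params("C3")
  obs <- simulate_aci("C3", p, noise_sd = 0, seed = 1)
  expect_equal(obs$a, model_curve(default_ci_grid(), p)$a)
  obs1 <- simulate_aci("C4", noise_sd = 0.5, seed = 9)
  obs2 <- simulate_aci("C4", noise_sd = 0.5, seed = 9)
  expect_identical(obs1, obs2)
  expect_error(simulate_aci("C3", ci_grid = c(-5, 100)), class = "invalid_spec")
})
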