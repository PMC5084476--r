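# Shared small fixtures, built in code at test time.

# A small quadripartite plastome that keeps the finishing loop fast.
small_plastome <- function(seed = 3) {
  generate_plastome(plastome_spec(lsc_len = 8000, ssc_len = 1500,
                                  ir_len = 2000, seed = seed))
}

# Brute-force canonical k-mer counting, independent of the C++ counter.
brute_kmer_counts <- function(reads, k) {
  kmers <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) return(character(0))
    substring(r, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
  }))
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  canon <- pmin(kmers, revcomp(kmers))
  tab <- table(canon)
  data.frame(kmer = names(tab), count = as.integer(tab))
}

# Brute-force Spearman correlation: Pearson on mid-ranks, written from the
# definition (ties averaged), independent of stats::cor's spearman path.
brute_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Default screen config over the synthetic TF universe.
synthetic_screen_config <- function(n_tf = 200, ...) {
  screen_config(cluster_tf_ids = sprintf("tf%04d", seq_len(n_tf)), ...)
}

# Synthetic stand-in for a nine-site PEPCK-style diagnostic table (the real
# coordinates come from the positive-selection literature and are not
# bundled); positions are arbitrary but strictly increasing.
synthetic_pepck_table <- function() {
  diagnostic_table(
    enzyme = "PEPCK-synthetic",
    reference_id = "ref",
    sites = data.frame(
      position = c(55, 120, 190, 270, 333, 410, 478, 512, 590),
      c3_residue = c("A", "G", "S", "T", "K", "E", "D", "N", "Q"),
      c4_residues = c("V", "A", "N", "S", "R", "Q", "E", "H", "L")))
}

run_screen <- function(seed, planted = default_planted(), ...) {
  g <- generate_gradient(gradient_design(seed = seed, planted = planted, ...))
  profs <- lapply(g$datasets, mean_profiles)
  cand <- suppressWarnings(tf_filter(profs, g$ortholog_map,
                                     synthetic_screen_config()))
  list(candidates = cand, truth = g$truth)
}
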