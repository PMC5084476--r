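#' Count k-mers in a read set
#'
#' Strand-canonical counting (each k-mer and its reverse complement are
#' pooled under the lexicographically smaller encoding), as appropriate for
#' strand-random sequencing reads. k-mers containing non-ACGT characters are
#' skipped.
#'
#' @param reads Character vector of reads (or any sequences).
#' @param k k-mer size, `1 <= k <= 31`. Odd k avoids palindromic
#'   self-canonicalization; 20 is used for plastome QC and 21 for genome
#'   sizing.
#' @param canonical Pool a k-mer with its reverse complement?
#' @return data.frame with columns `kmer` and `count`.
#' @export
count_kmers <- function(reads, k, canonical = TRUE) {
  if (!is.numeric(k) || k < 1 || k > 31) {
    c4_abort("k must be an integer in [1, 31]", "invalid_parameter")
  }
  res <- cpp_count_kmers(as.character(reads), as.integer(k), canonical, TRUE)
  data.frame(kmer = res$kmer, count = res$count)
}

#' Build a k-mer multiplicity histogram
#'
#' `entries[m]` is the number of distinct (canonical) k-mers observed exactly
#' `m` times. Single-copy genome sequence produces a peak centered at the
#' average sequencing depth; two-copy sequence a second peak at twice that
#' depth.
#'
#' @param counts Integer vector of k-mer multiplicities, or the data.frame
#'   returned by [count_kmers()].
#' @return data.frame of class `kmer_histogram` with columns `multiplicity`
#'   and `count` (zero-count multiplicities included up to the maximum).
#' @export
build_histogram <- function(counts) {
  if (is.data.frame(counts)) counts <- counts$count
  if (length(counts) == 0) c4_abort("no k-mer counts supplied", "invalid_input")
  tab <- tabulate(counts)
  structure(data.frame(multiplicity = seq_along(tab), count = tab),
            class = c("kmer_histogram", "data.frame"))
}

# Centered moving average used to stabilise desk-scale histograms before
# peak/valley finding.
smooth_entries <- function(x, window = 5) {
  w <- max(1L, as.integer(window))
  if (w %% 2 == 0) w <- w + 1L
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2) |>
               (\(z) { z[is.na(z)] <- x[is.na(z)]; z })())
}

#' Estimate genome size from a k-mer histogram
#'
#' Standard total-mass-over-depth estimator: the error cutoff is the first
#' local minimum of the (smoothed) histogram, the coverage peak `c` is the
#' weighted mode above the cutoff, total genome size is
#' `sum(m * entries[m]) / c` over `m > cutoff`, and the single-copy fraction
#' is the number of distinct k-mers in the first peak's support
#' `(cutoff, 1.5c)` -- the midpoint between the 1x and 2x peaks.
#'
#' @param hist A [build_histogram()] result.
#' @param smooth_window Moving-average width for peak finding.
#' @return List of class `genome_size_estimate` with `coverage_peak`,
#'   `total_bp`, `single_copy_bp`, `error_cutoff`.
#' @export
estimate_genome_size <- function(hist, smooth_window = 5) {
  stopifnot(inherits(hist, "kmer_histogram"))
  e <- hist$count
  m <- hist$multiplicity
  s <- smooth_entries(e, smooth_window)
  # first local minimum: first multiplicity from which the histogram rises
  rise <- which(diff(s) > 0)
  if (length(rise) == 0) {
    c4_abort("histogram is monotone decreasing: no peak separable from the error slope",
             "estimation_failed",
             diagnostics = list(max_multiplicity = max(m), mass = sum(as.numeric(m) * e)))
  }
  cutoff <- rise[1]
  above <- which(m > cutoff)
  peak_m <- m[above][which.max(s[above])]
  if (s[peak_m] <= 0) {
    c4_abort("no k-mer mass above the error cutoff", "estimation_failed")
  }
  # weighted mode: mass-weighted mean multiplicity over the first peak's
  # support (half to one-and-a-half times the modal multiplicity, so the
  # window scales with coverage and excludes the two-copy peak)
  win <- which(m > cutoff & m >= 0.5 * peak_m & m < 1.5 * peak_m)
  cov_peak <- sum(m[win] * e[win]) / sum(e[win])
  sel <- m > cutoff
  total_bp <- sum(as.numeric(m[sel]) * e[sel]) / cov_peak
  sc <- m > cutoff & m < 1.5 * cov_peak
  single_copy_bp <- sum(as.numeric(e[sc]))
  structure(list(coverage_peak = cov_peak, total_bp = total_bp,
                 single_copy_bp = single_copy_bp, error_cutoff = cutoff),
            class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf(paste0("k-mer genome size estimate\n",
                     "  coverage peak : %.1f x\n",
                     "  total size    : %.3f Mb\n",
                     "  single copy   : %.3f Mb\n",
                     "  error cutoff  : multiplicity <= %d\n"),
              x$coverage_peak, x$total_bp / 1e6, x$single_copy_bp / 1e6,
              x$error_cutoff))
  invisible(x)
}

#' Locate histogram peaks above the error cutoff
#'
#' Utility for QC: local maxima of the smoothed histogram above the error
#' cutoff, e.g. to verify that two-copy sequence peaks near twice the
#' single-copy depth.
#'
#' @inheritParams estimate_genome_size
#' @return Integer vector of peak multiplicities, ascending.
#' @export
find_histogram_peaks <- function(hist, smooth_window = 5) {
  stopifnot(inherits(hist, "kmer_histogram"))
  s <- smooth_entries(hist$count, smooth_window)
  rise <- which(diff(s) > 0)
  if (length(rise) == 0) return(integer(0))
  cutoff <- rise[1]
  n <- length(s)
  is_peak <- c(FALSE, s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n], FALSE)
  peaks <- hist$multiplicity[is_peak & hist$multiplicity > cutoff & s > 0]
  peaks
}
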