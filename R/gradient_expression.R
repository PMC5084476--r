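#' Compute FPKM from fragment counts
#'
#' `FPKM(g, s) = counts(g, s) * 1e9 / (gene_length(g) * library_size(s))` --
#' fragments per kilobase of transcript per million mapped fragments.
#'
#' @param counts Integer matrix, genes x samples.
#' @param gene_lengths Gene lengths in bases (named or in row order).
#' @param library_sizes Mapped-fragment totals per sample (in column order).
#' @return Numeric FPKM matrix of the same shape.
#' @export
compute_fpkm <- function(counts, gene_lengths, library_sizes) {
  counts <- as.matrix(counts)
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts))) {
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  if (any(gene_lengths <= 0) || any(is.na(gene_lengths))) {
    c4_abort("gene lengths must be positive", "invalid_input")
  }
  if (any(library_sizes <= 0)) {
    c4_abort("library sizes must be positive", "invalid_input")
  }
  sweep(counts / gene_lengths, 2, library_sizes, "/") * 1e9
}

# Pull the FPKM matrix out of a gradient_dataset or pass a matrix through.
as_fpkm_matrix <- function(x) {
  if (inherits(x, "gradient_dataset")) x$fpkm else as.matrix(x)
}

#' Filter to expressed genes
#'
#' A gene is retained iff its FPKM is at or above `threshold` in at least one
#' segment of any replicate (i.e. the maximum over all samples reaches the
#' threshold).
#'
#' @param x A `gradient_dataset` or FPKM matrix (genes x samples).
#' @param threshold Minimum FPKM (default 1).
#' @return Character vector of retained gene identifiers.
#' @export
filter_expressed <- function(x, threshold = 1) {
  m <- as_fpkm_matrix(x)
  keep <- apply(m, 1, max) >= threshold
  rownames(m)[keep]
}

#' Sample-by-sample correlation matrix
#'
#' Spearman (mid-rank, ties averaged -- required for FPKM data with many
#' zeros) or Pearson correlation across genes, typically after
#' [filter_expressed()].
#'
#' @param x A `gradient_dataset` or FPKM matrix.
#' @param method `"spearman"` or `"pearson"`.
#' @param genes Optional gene subset (e.g. the [filter_expressed()] result).
#' @return Symmetric correlation matrix with unit diagonal; constant sample
#'   vectors yield `NA` entries with a warning.
#' @export
segment_correlation <- function(x, method = c("spearman", "pearson"),
                                genes = NULL) {
  method <- match.arg(method)
  m <- as_fpkm_matrix(x)
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (ncol(m) < 2) c4_abort("need at least two samples", "invalid_input")
  const <- apply(m, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    c4_warn(sprintf("constant sample vector(s): %s -- correlations undefined",
                    paste(colnames(m)[const], collapse = ", ")),
            "constant_sample")
  }
  suppressWarnings(cor(m, method = method))
}

# Member leaves of every internal node of an hclust tree.
hclust_node_members <- function(h) {
  n <- length(h$order) + 1  # not used; kept for clarity
  members <- vector("list", nrow(h$merge))
  for (i in seq_len(nrow(h$merge))) {
    get <- function(j) if (j < 0) -j else members[[j]]
    members[[i]] <- c(get(h$merge[i, 1]), get(h$merge[i, 2]))
  }
  members
}

#' Cluster samples and check replicate coherence
#'
#' Average-linkage hierarchical clustering on the distance `1 - correlation`.
#' The coherence report states, per segment, whether its replicates form a
#' clade before joining any other segment's samples.
#'
#' @param corr Correlation matrix from [segment_correlation()] with sample
#'   names of the form `species:segment:replicate`.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List with `tree` (an `hclust`) and `coherence` (data.frame with
#'   columns `segment`, `coherent`).
#' @export
cluster_samples <- function(corr, linkage = "average") {
  if (any(is.na(corr))) {
    c4_warn("missing correlations: using pairwise-complete maxima", "missing_corr")
    corr[is.na(corr)] <- min(corr, na.rm = TRUE)
  }
  d <- as.dist(1 - corr)
  h <- hclust(d, method = linkage)
  ids <- do.call(rbind, strsplit(colnames(corr), ":", fixed = TRUE))
  seg <- paste(ids[, 1], ids[, 2], sep = ":")
  members <- hclust_node_members(h)
  coherence <- do.call(rbind, lapply(unique(seg), function(sg) {
    leaves <- which(seg == sg)
    if (length(leaves) == 1) {
      return(data.frame(segment = sg, coherent = TRUE))
    }
    # smallest node containing all replicates of this segment
    for (mem in members) {
      if (all(leaves %in% mem)) {
        return(data.frame(segment = sg, coherent = setequal(mem, leaves)))
      }
    }
    data.frame(segment = sg, coherent = FALSE)
  }))
  list(tree = h, coherence = coherence)
}

#' Per-gene mean profiles on matched comparison stages
#'
#' Averages replicates per native segment, then maps native segments to the
#' four comparison stages via the match table (a stage mapped to several
#' native segments -- e.g. a basal segment capturing both base and transition
#' zones of a finer gradient -- takes the mean of those segments' means).
#' Base-to-tip order is preserved. Only within-species profiles are produced;
#' absolute FPKM is never compared across species.
#'
#' @param x A `gradient_dataset`.
#' @param match List of 4 integer vectors: native segment labels per
#'   comparison stage. Default identity (stages 1:4 = segments 1:4).
#' @return Numeric matrix (genes x 4 stages) of class `segment_profiles`
#'   with the species kept as an attribute.
#' @export
mean_profiles <- function(x, match = as.list(1:4)) {
  stopifnot(inherits(x, "gradient_dataset"))
  if (length(match) != 4) c4_abort("match table must define 4 stages", "config_error")
  segs <- sort(unique(x$segment))
  if (!all(unlist(match) %in% segs)) {
    c4_abort("match table names a segment absent from the dataset", "config_error")
  }
  n_genes <- nrow(x$fpkm)
  seg_means <- matrix(vapply(segs, function(sg) {
    rowMeans(x$fpkm[, x$segment == sg, drop = FALSE])
  }, numeric(n_genes)), nrow = n_genes, dimnames = list(rownames(x$fpkm), segs))
  prof <- matrix(vapply(match, function(native) {
    rowMeans(seg_means[, as.character(native), drop = FALSE])
  }, numeric(n_genes)), nrow = n_genes,
  dimnames = list(rownames(x$fpkm), paste0("stage", 1:4)))
  structure(prof, species = x$species, class = c("segment_profiles", "matrix", "array"))
}
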