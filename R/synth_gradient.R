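#' Default five-species comparison panel
#'
#' Three C4 panicoids (maize and sorghum in the Andropogoneae, *Setaria
#' viridis* in the Paniceae) against two C3 comparators (*Dichanthelium
#' oligosanthes* in the Paniceae and rice in the BEP clade). Maize is the
#' reference species carrying the co-expression-cluster TF list.
#'
#' @return data.frame with columns `species`, `type`, `clade`, `reference`.
#' @export
default_species_panel <- function() {
  data.frame(
    species = c("Zmays", "Sbicolor", "Sviridis", "Doligosanthes", "Osativa"),
    type = c("C4", "C4", "C4", "C3", "C3"),
    clade = c("Andropogoneae", "Andropogoneae", "Paniceae", "Paniceae", "BEP"),
    reference = c(TRUE, FALSE, FALSE, FALSE, FALSE))
}

#' Default planted-divergence table
#'
#' Mirrors the 4/3/1 split of regulator divergence patterns across the three
#' C4 species: four TFs divergent in the reference only, three shared with
#' the second Andropogoneae species, one shared by all three C4 species.
#'
#' @param fold Effect-size fold applied on the perturbed segments.
#' @return data.frame with columns `tf` (index), `pattern`
#'   (comma-separated species), `fold`.
#' @export
default_planted <- function(fold = 4) {
  data.frame(
    tf = 1:8,
    pattern = c(rep("Zmays", 4),
                rep("Zmays,Sbicolor", 3),
                "Zmays,Sbicolor,Sviridis"),
    fold = fold)
}

#' Leaf developmental-gradient experiment design
#'
#' @param species Species panel as from [default_species_panel()].
#' @param n_genes Number of background (non-TF) genes.
#' @param n_tf Number of transcription factors.
#' @param n_segments Number of leaf segments sampled base to tip (fixed 4).
#' @param n_replicates Replicates per segment (>= 2; the source studies do
#'   not print replicate counts, so 3 is the default and a parameter).
#' @param planted Planted-divergence table as from [default_planted()];
#'   `NULL` for a no-signal dataset.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   (log-normal) replicate noise.
#' @param ortholog_dropout Fraction of TFs whose ortholog is deleted in each
#'   non-reference species.
#' @param seed Integer seed.
#' @return Object of class `gradient_design`.
#' @export
gradient_design <- function(species = default_species_panel(),
                            n_genes = 500, n_tf = 200, n_segments = 4,
                            n_replicates = 3, planted = default_planted(),
                            noise_cv = 0.2, ortholog_dropout = 0,
                            seed = 1L) {
  if (n_replicates < 2) c4_abort("need >= 2 replicates per segment", "invalid_design")
  if (n_segments != 4) c4_abort("the gradient design uses 4 segments", "invalid_design")
  if (!is.null(planted)) {
    if (any(planted$tf < 1 | planted$tf > n_tf)) {
      c4_abort("planted tf indices must lie in [1, n_tf]", "invalid_design")
    }
    pat <- strsplit(planted$pattern, ",", fixed = TRUE)
    c4_sp <- species$species[species$type == "C4"]
    ok <- vapply(pat, function(p) length(p) > 0 && all(p %in% c4_sp), TRUE)
    if (!all(ok)) {
      c4_abort("divergence patterns must be non-empty subsets of the C4 species",
               "invalid_design")
    }
  }
  structure(list(species = species, n_genes = as.integer(n_genes),
                 n_tf = as.integer(n_tf), n_segments = 4L,
                 n_replicates = as.integer(n_replicates), planted = planted,
                 noise_cv = noise_cv, ortholog_dropout = ortholog_dropout,
                 seed = as.integer(seed)),
            class = "gradient_design")
}

# Smooth 4-point base shapes (base -> tip), spanning the roughly
# order-of-magnitude dynamic range developmental-gradient transcripts show.
# The increasing class mimics the photosynthesis-like "rising tipward"
# profiles the screen must distinguish.
shape_library <- function() {
  list(flat = c(1, 1, 1, 1),
       increasing = c(0.25, 0.45, 0.67, 1),
       decreasing = c(1, 0.67, 0.45, 0.25),
       peaked = c(0.3, 1, 0.6, 0.25))
}

# Constructor for a per-species FPKM container.
new_gradient_dataset <- function(species, fpkm, segment, replicate) {
  structure(list(species = species, fpkm = fpkm,
                 segment = segment, replicate = replicate),
            class = "gradient_dataset")
}

#' @export
print.gradient_dataset <- function(x, ...) {
  cat(sprintf("gradient_dataset: %s, %d genes x %d samples (%d segments x %d replicates)\n",
              x$species, nrow(x$fpkm), ncol(x$fpkm),
              length(unique(x$segment)), length(unique(x$replicate))))
  invisible(x)
}

#' Generate multi-species leaf-gradient expression data with planted truth
#'
#' Background genes share a per-gene base profile across all species: a
#' log-normal expression level times one of a small library of smooth
#' 4-point shapes (flat, increasing, decreasing, peaked) with random
#' amplitude. Replicate noise is multiplicative log-normal with coefficient
#' of variation `noise_cv`. Planted TFs have their profile multiplied by the
#' stated fold on the two segments where their base shape is lowest -- i.e.
#' the perturbation changes the *shape* of the profile -- but only in the
#' species named by their divergence pattern.
#'
#' @param design A [gradient_design()].
#' @return List with `datasets` (named list of `gradient_dataset`, one per
#'   species), `truth` (planted table with perturbed segments), and
#'   `ortholog_map` (data.frame gene x species; `NA` marks a deleted
#'   ortholog).
#' @export
generate_gradient <- function(design = gradient_design()) {
  stopifnot(inherits(design, "gradient_design"))
  set.seed(design$seed)
  sp <- design$species
  n_seg <- design$n_segments
  n_rep <- design$n_replicates
  genes <- c(sprintf("tf%04d", seq_len(design$n_tf)),
             sprintf("bg%04d", seq_len(design$n_genes)))
  n_total <- length(genes)

  shapes <- shape_library()
  shape_id <- sample(names(shapes), n_total, replace = TRUE)
  level <- rlnorm(n_total, meanlog = log(20), sdlog = 1.2)
  # planted regulators emulate the expressed-TF candidate list (which is
  # conditioned on leaf expression), so their level draw is truncated below
  # at 10 FPKM; decoys keep the unconditional distribution
  if (!is.null(design$planted)) {
    idx <- unique(design$planted$tf)
    lo <- stats::plnorm(10, log(20), 1.2)
    level[idx] <- stats::qlnorm(runif(length(idx), lo, 1), log(20), 1.2)
  }
  # random amplitude = contrast exponent on the shape (flat stays flat,
  # graded shapes keep a clearly non-flat normalized form)
  amplitude <- runif(n_total, 0.8, 1.2)
  base_profile <- t(vapply(seq_len(n_total), function(i) {
    s <- shapes[[shape_id[i]]]^amplitude[i]
    level[i] * s / mean(s)
  }, numeric(n_seg)))
  rownames(base_profile) <- genes

  # planted perturbations: per TF, the two lowest-shape segments x fold
  truth <- NULL
  perturb <- list()
  if (!is.null(design$planted)) {
    truth <- design$planted
    truth$gene <- sprintf("tf%04d", truth$tf)
    truth$segments <- vapply(truth$gene, function(g) {
      s <- shapes[[shape_id[match(g, genes)]]]
      paste(order(s, decreasing = FALSE)[1:2], collapse = ",")
    }, "")
    for (i in seq_len(nrow(truth))) {
      perturb[[truth$gene[i]]] <- list(
        species = strsplit(truth$pattern[i], ",", fixed = TRUE)[[1]],
        segments = as.integer(strsplit(truth$segments[i], ",", fixed = TRUE)[[1]]),
        fold = truth$fold[i])
    }
  }

  sdlog <- sqrt(log(1 + design$noise_cv^2))
  datasets <- list()
  for (s in sp$species) {
    prof <- base_profile
    for (g in names(perturb)) {
      pl <- perturb[[g]]
      if (s %in% pl$species) prof[g, pl$segments] <- prof[g, pl$segments] * pl$fold
    }
    seg <- rep(seq_len(n_seg), each = n_rep)
    repl <- rep(seq_len(n_rep), times = n_seg)
    mean_mat <- prof[, seg, drop = FALSE]
    noise <- matrix(rlnorm(length(mean_mat), meanlog = -sdlog^2 / 2, sdlog = sdlog),
                    nrow = n_total)
    fpkm <- mean_mat * noise
    colnames(fpkm) <- sprintf("%s:%d:%d", s, seg, repl)
    datasets[[s]] <- new_gradient_dataset(s, fpkm, seg, repl)
  }

  # ortholog map: identity except TF dropout in non-reference species
  ref <- sp$species[sp$reference][1]
  omap <- data.frame(gene = genes)
  for (s in sp$species) {
    ids <- paste0(s, "_", genes)
    if (s != ref && design$ortholog_dropout > 0) {
      tf_idx <- seq_len(design$n_tf)
      drop <- tf_idx[runif(design$n_tf) < design$ortholog_dropout]
      ids[drop] <- NA
    }
    omap[[s]] <- ids
  }

  list(datasets = datasets, truth = truth, ortholog_map = omap)
}
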