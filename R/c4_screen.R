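#' Configuration for the comparative C4 regulator screen
#'
#' @param cluster_tf_ids Reference-species TF identifiers (the stand-in for
#'   the photosynthesis co-expression clusters; stage-1 input).
#' @param mean_fpkm_min Minimum mean FPKM across the four stages in the
#'   reference species (stage 2; default 4).
#' @param divergence_metric Profile divergence statistic.
#' @param divergence_tau Divergence threshold for flagging a C4 species
#'   against the C3 consensus (stage 3).
#' @param c3_consistency_tau Maximum divergence allowed between the two C3
#'   species for the consensus to be trusted.
#' @param tip_fold_min,tip_fpkm_min Tip/base fold and absolute tip FPKM
#'   required for a C4-style induction call.
#' @return Object of class `screen_config`.
#' @export
screen_config <- function(cluster_tf_ids,
                          mean_fpkm_min = 4,
                          divergence_metric = c("one-minus-pearson",
                                                "euclidean-on-normalized"),
                          divergence_tau = 0.3,
                          c3_consistency_tau = 0.3,
                          tip_fold_min = 4,
                          tip_fpkm_min = 50) {
  divergence_metric <- match.arg(divergence_metric)
  thr <- c(mean_fpkm_min, divergence_tau, c3_consistency_tau,
           tip_fold_min, tip_fpkm_min)
  if (any(thr <= 0)) c4_abort("screen thresholds must be positive", "invalid_spec")
  structure(list(cluster_tf_ids = cluster_tf_ids,
                 mean_fpkm_min = mean_fpkm_min,
                 divergence_metric = divergence_metric,
                 divergence_tau = divergence_tau,
                 c3_consistency_tau = c3_consistency_tau,
                 tip_fold_min = tip_fold_min,
                 tip_fpkm_min = tip_fpkm_min),
            class = "screen_config")
}

#' Call C4-style transcriptional induction from a 4-stage profile
#'
#' TRUE iff the tip value reaches `tip_fpkm_min`, the tip/base fold reaches
#' `tip_fold_min`, and the profile is non-decreasing from stage 2 onward
#' (10 % tolerance). A gene expressed high but flat -- the carbonic-anhydrase
#' pattern typical of C3 leaves -- fails the fold criterion and is not
#' called induced.
#'
#' @param profile Numeric 4-vector of stage means, base to tip.
#' @param config A [screen_config()] (only the induction thresholds are
#'   used); defaults allow standalone calls.
#' @return List with `induced` (logical) and `diagnostics`.
#' @export
assess_induction <- function(profile,
                             config = screen_config(cluster_tf_ids = character(0))) {
  stopifnot(length(profile) == 4)
  tip <- profile[4]
  base <- profile[1]
  fold <- if (base > 0) tip / base else Inf
  monotone <- profile[3] >= 0.9 * profile[2] && profile[4] >= 0.9 * profile[3]
  induced <- tip >= config$tip_fpkm_min && fold >= config$tip_fold_min && monotone
  list(induced = induced,
       diagnostics = list(tip = tip, fold = fold, monotone = monotone))
}

#' Max-normalize a 4-stage profile
#'
#' Divides by the profile maximum so cross-species comparisons are on shape,
#' never on absolute FPKM. An all-zero profile is flagged non-expressed
#' (`NA` values with attribute `non_expressed`).
#'
#' @param profile Numeric 4-vector.
#' @return Normalized 4-vector (max = 1), or `NA`s flagged non-expressed.
#' @export
normalize_profile <- function(profile) {
  stopifnot(length(profile) == 4)
  mx <- max(profile)
  if (!is.finite(mx) || mx <= 0) {
    return(structure(rep(NA_real_, 4), non_expressed = TRUE))
  }
  profile / mx
}

# A normalized profile is "effectively flat" when its minimum exceeds 0.55 of
# its maximum: replicate noise keeps a truly flat profile's range well under
# 2-fold while genuinely graded profiles span several-fold, and a 4-point
# Pearson correlation on near-constant vectors is noise, so flat-ish profiles
# are compared on the euclidean metric instead.
is_near_constant <- function(p, tol = 0.55) {
  min(p) > tol * max(p)
}

#' Divergence between two normalized profiles
#'
#' `one-minus-pearson` gives `1 - r` in `[0, 2]`;
#' `euclidean-on-normalized` gives `||p - q|| / 2` in `[0, 1]`. Under the
#' correlation metric, (near-)constant profiles fall back to the euclidean
#' metric with a warning, since correlation is undefined or meaningless
#' there.
#'
#' @param p,q Normalized 4-vectors (see [normalize_profile()]).
#' @param metric Divergence statistic.
#' @param warn Emit the fallback warning?
#' @return Non-negative divergence score, or `NA` if either profile is
#'   non-expressed.
#' @export
profile_divergence <- function(p, q,
                               metric = c("one-minus-pearson",
                                          "euclidean-on-normalized"),
                               warn = TRUE) {
  metric <- match.arg(metric)
  if (anyNA(p) || anyNA(q)) return(NA_real_)
  if (metric == "one-minus-pearson" &&
      (is_near_constant(p) || is_near_constant(q))) {
    if (warn) c4_warn("near-constant profile: falling back to euclidean metric",
                      "constant_profile")
    metric <- "euclidean-on-normalized"
  }
  if (metric == "one-minus-pearson") {
    1 - cor(p, q)
  } else {
    sqrt(sum((p - q)^2)) / 2
  }
}

#' Three-stage comparative screen for C4-divergent regulators
#'
#' Stage 1 keeps TFs on the co-expression cluster list; stage 2 keeps TFs
#' whose reference-species mean FPKM across the four stages is at least
#' `mean_fpkm_min`; stage 3 forms the C3 consensus profile (mean of the
#' normalized C3 profiles), requires the two C3 species to be mutually
#' consistent, and flags each C4 species whose normalized profile diverges
#' from the consensus by more than `divergence_tau`. TFs with at least one
#' flag survive. A missing ortholog makes a species non-comparable (recorded,
#' not flagged); a TF with no orthologs outside the reference is reported as
#' reference-specific.
#'
#' @param profiles Named list of `segment_profiles` matrices (one per
#'   species, from [mean_profiles()]).
#' @param ortholog_map data.frame: column `gene` (reference ids) plus one
#'   column per species (`NA` = ortholog absent).
#' @param config A [screen_config()].
#' @param species_info Species panel (see [default_species_panel()]).
#' @return data.frame of class `tf_candidates`: one row per surviving TF
#'   with per-species divergence scores, flags and the lineage `category`;
#'   stage attrition counts in attribute `attrition`.
#' @export
tf_filter <- function(profiles, ortholog_map, config,
                      species_info = default_species_panel()) {
  ref <- species_info$species[species_info$reference][1]
  c3_sp <- species_info$species[species_info$type == "C3"]
  c4_sp <- species_info$species[species_info$type == "C4"]
  if (!ref %in% names(profiles)) {
    c4_abort("reference species missing from profiles", "invalid_input")
  }
  if (length(c3_sp) < 1 || length(c4_sp) < 1) {
    c4_abort("need at least one C3 and one C4 comparator", "invalid_input")
  }

  stage1 <- intersect(config$cluster_tf_ids, rownames(profiles[[ref]]))
  skipped <- setdiff(config$cluster_tf_ids, stage1)
  if (length(skipped) > 0) {
    c4_warn(sprintf("%d cluster TF(s) absent from the reference dataset; skipped",
                    length(skipped)), "missing_tf")
  }
  ref_means <- rowMeans(profiles[[ref]][stage1, , drop = FALSE])
  stage2 <- stage1[ref_means >= config$mean_fpkm_min]

  rows <- list()
  for (g in stage2) {
    orth <- ortholog_map[match(g, ortholog_map$gene), , drop = FALSE]
    has_orth <- vapply(species_info$species, function(s) {
      s == ref || (nrow(orth) == 1 && !is.na(orth[[s]]))
    }, TRUE)
    norm_prof <- lapply(species_info$species, function(s) {
      if (!has_orth[[s]] || !g %in% rownames(profiles[[s]])) return(NULL)
      normalize_profile(profiles[[s]][g, ])
    })
    names(norm_prof) <- species_info$species
    comparable <- !vapply(norm_prof, is.null, TRUE) &
      !vapply(norm_prof, function(p) !is.null(p) && anyNA(p), TRUE)

    c3_avail <- c3_sp[comparable[c3_sp]]
    scores <- setNames(rep(NA_real_, length(c4_sp)), c4_sp)
    flags <- setNames(rep(NA, length(c4_sp)), c4_sp)
    if (length(c3_avail) == 0) {
      # no C3 comparison possible; ortholog absent everywhere means the
      # regulator is trivially reference-specific
      if (sum(comparable) <= 1) {
        rows[[g]] <- list(gene = g, scores = scores, flags = flags,
                          category = "reference-specific",
                          note = "no-orthologs")
      }
      next
    }
    if (length(c3_avail) == 2) {
      d_c3 <- profile_divergence(norm_prof[[c3_avail[1]]],
                                 norm_prof[[c3_avail[2]]],
                                 config$divergence_metric, warn = FALSE)
      if (!is.na(d_c3) && d_c3 > config$c3_consistency_tau) next
    }
    consensus <- Reduce(`+`, norm_prof[c3_avail]) / length(c3_avail)
    for (s in c4_sp) {
      if (!comparable[[s]]) next
      scores[s] <- profile_divergence(norm_prof[[s]], consensus,
                                      config$divergence_metric, warn = FALSE)
      flags[s] <- scores[s] > config$divergence_tau
    }
    if (any(flags, na.rm = TRUE)) {
      rows[[g]] <- list(gene = g, scores = scores, flags = flags,
                        category = classify_lineage(flags, species_info),
                        note = "")
    }
  }

  out <- do.call(rbind, lapply(rows, function(r) {
    df <- data.frame(gene = r$gene, category = r$category, note = r$note)
    for (s in names(r$scores)) df[[paste0("score_", s)]] <- r$scores[[s]]
    for (s in names(r$flags)) df[[paste0("flag_", s)]] <- r$flags[[s]]
    df
  }))
  if (is.null(out)) {
    out <- data.frame(gene = character(0), category = character(0),
                      note = character(0))
  }
  rownames(out) <- NULL
  attr(out, "attrition") <- c(input = length(config$cluster_tf_ids),
                              stage1 = length(stage1),
                              stage2 = length(stage2),
                              candidates = nrow(out))
  class(out) <- c("tf_candidates", "data.frame")
  out
}

#' Lineage classification of a divergence-flag pattern
#'
#' Reference species only -> `reference-specific`; reference plus all C4
#' species of the same clade (and no others) -> `Andropogoneae-shared`
#' (clade-shared); all C4 species -> `pan-C4`; anything else -> `none`.
#' Non-comparable species (`NA` flags) are ignored.
#'
#' @param flags Named logical vector over the C4 species (`NA` =
#'   non-comparable).
#' @param species_info Species panel with `species`, `clade`, `reference`.
#' @return One of `"reference-specific"`, `"Andropogoneae-shared"`,
#'   `"pan-C4"`, `"none"`.
#' @export
classify_lineage <- function(flags, species_info = default_species_panel()) {
  ref <- species_info$species[species_info$reference][1]
  ref_clade <- species_info$clade[species_info$species == ref]
  comp <- names(flags)[!is.na(flags)]
  on <- names(flags)[!is.na(flags) & flags]
  if (length(on) == 0) return("none")
  if (!ref %in% on) return("none")
  if (setequal(on, comp)) return("pan-C4")
  if (length(on) == 1 && on == ref) return("reference-specific")
  same_clade <- comp[species_info$clade[match(comp, species_info$species)] == ref_clade]
  if (setequal(on, same_clade)) return("Andropogoneae-shared")
  "none"
}
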