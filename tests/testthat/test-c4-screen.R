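test_that("assess_induction separates induced, flat, and declining profiles", {
  cfg <- screen_config(cluster_tf_ids = character(0))
  expect_true(assess_induction(c(10, 100, 400, 800), cfg)$induced)
  # high but flat (the C3 carbonic-anhydrase pattern) is not induced
  expect_false(assess_induction(c(500, 500, 500, 500), cfg)$induced)
  expect_false(assess_induction(c(10, 8, 6, 5), cfg)$induced)
  # tip below the absolute floor fails even with a large fold
  expect_false(assess_induction(c(1, 10, 20, 40), cfg)$induced)
  # non-monotone tip-ward decline fails despite fold and floor
  expect_false(assess_induction(c(10, 400, 100, 60), cfg)$induced)
})

test_that("normalize_profile is scale-invariant and flags silence", {
  expect_equal(normalize_profile(c(2, 4, 8, 8)), c(0.25, 0.5, 1, 1))
  p <- c(3, 1, 7, 2)
  expect_equal(normalize_profile(17 * p), normalize_profile(p))
  z <- normalize_profile(c(0, 0, 0, 0))
  expect_true(all(is.na(z)))
  expect_true(attr(z, "non_expressed"))
})

test_that("profile_divergence matches hand-computed Pearson and euclidean", {
  expect_equal(profile_divergence(c(0.2, 0.4, 0.8, 1), c(0.2, 0.4, 0.8, 1)), 0)
  # perfect anticorrelation
  expect_equal(profile_divergence(c(0, 1/3, 2/3, 1), c(1, 2/3, 1/3, 0)), 2,
               tolerance = 1e-12)
  set.seed(12)
  for (i in 1:20) {
    p <- normalize_profile(runif(4, 0.01, 1))
    q <- normalize_profile(runif(4, 0.01, 1))
    hand <- 1 - sum((p - mean(p)) * (q - mean(q))) /
      sqrt(sum((p - mean(p))^2) * sum((q - mean(q))^2))
    if (!c4kit:::is_near_constant(p) && !c4kit:::is_near_constant(q)) {
      expect_equal(profile_divergence(p, q, warn = FALSE), hand,
                   tolerance = 1e-12)
    }
    expect_equal(profile_divergence(p, q, metric = "euclidean-on-normalized"),
                 sqrt(sum((p - q)^2)) / 2, tolerance = 1e-12)
  }
  # flat profiles fall back to euclidean with a warning
  expect_warning(
    d <- profile_divergence(c(1, 0.97, 0.99, 0.98), c(0.5, 1, 0.2, 0.4)),
    class = "constant_profile")
  expect_equal(d, sqrt(sum((c(1, 0.97, 0.99, 0.98) - c(0.5, 1, 0.2, 0.4))^2)) / 2)
})

test_that("tf_filter recovers planted regulators and respects stage rules", {
  res <- run_screen(seed = 101)
  expect_setequal(res$candidates$gene, res$truth$gene)
  # planted categories follow the 4/3/1 divergence patterns
  expect_equal(sum(res$candidates$category == "reference-specific"), 4)
  expect_equal(sum(res$candidates$category == "Andropogoneae-shared"), 3)
  expect_equal(sum(res$candidates$category == "pan-C4"), 1)

  # no planted signal -> no candidates
  none <- run_screen(seed = 102, planted = NULL)
  expect_equal(nrow(none$candidates), 0)

  # divergence_tau = Inf removes everything; tau ~ 0 keeps every stage-2
  # survivor with comparable orthologs
  g <- generate_gradient(gradient_design(seed = 103))
  profs <- lapply(g$datasets, mean_profiles)
  cfg_inf <- synthetic_screen_config(divergence_tau = 1e9)
  expect_equal(nrow(suppressWarnings(tf_filter(profs, g$ortholog_map, cfg_inf))), 0)
  cfg_zero <- synthetic_screen_config(divergence_tau = 1e-9,
                                      c3_consistency_tau = 1e9)
  all_in <- suppressWarnings(tf_filter(profs, g$ortholog_map, cfg_zero))
  expect_equal(nrow(all_in),
               unname(attr(all_in, "attrition")["stage2"]))

  # mean reference FPKM below 4 is excluded at stage 2
  profs2 <- profs
  profs2$Zmays["tf0001", ] <- c(3, 3, 3, 3)
  out <- suppressWarnings(tf_filter(profs2, g$ortholog_map,
                                    synthetic_screen_config()))
  expect_false("tf0001" %in% out$gene)

  # ortholog absent everywhere outside the reference -> reference-specific
  omap <- g$ortholog_map
  omap[omap$gene == "tf0002", c("Sbicolor", "Sviridis", "Doligosanthes",
                                "Osativa")] <- NA
  out2 <- suppressWarnings(tf_filter(profs, omap, synthetic_screen_config()))
  row <- out2[out2$gene == "tf0002", ]
  expect_equal(row$category, "reference-specific")
  expect_equal(row$note, "no-orthologs")
})

test_that("planted-recovery recall is non-decreasing in effect fold", {
  recall_at <- function(fold) {
    hits <- vapply(1:5, function(s) {
      res <- run_screen(seed = 200 + s, planted = default_planted(fold = fold))
      mean(res$truth$gene %in% res$candidates$gene)
    }, 0)
    mean(hits)
  }
  r <- vapply(c(2, 4, 8), recall_at, 0)
  expect_true(all(diff(r) >= 0))
  expect_equal(r[3], 1)
})

test_that("classify_lineage is total and deterministic over flag patterns", {
  combos <- expand.grid(Zmays = c(TRUE, FALSE), Sbicolor = c(TRUE, FALSE),
                        Sviridis = c(TRUE, FALSE))
  got <- apply(combos, 1, function(fl) classify_lineage(unlist(fl)))
  expect_true(all(got %in% c("reference-specific", "Andropogoneae-shared",
                             "pan-C4", "none")))
  expect_equal(classify_lineage(c(Zmays = TRUE, Sbicolor = FALSE,
                                  Sviridis = FALSE)), "reference-specific")
  expect_equal(classify_lineage(c(Zmays = TRUE, Sbicolor = TRUE,
                                  Sviridis = FALSE)), "Andropogoneae-shared")
  expect_equal(classify_lineage(c(Zmays = TRUE, Sbicolor = TRUE,
                                  Sviridis = TRUE)), "pan-C4")
  expect_equal(classify_lineage(c(Zmays = TRUE, Sbicolor = FALSE,
                                  Sviridis = TRUE)), "none")
  expect_equal(classify_lineage(c(Zmays = FALSE, Sbicolor = TRUE,
                                  Sviridis = TRUE)), "none")
})
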