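# Inter-regional dissimilarity, CB distances, stage correlations, PCA.

test_that("inter-regional difference: hand-worked toy and identical samples", {
  # log2 profiles (1,3) and (2,5): mean(|1-2|, |3-5|) = 1.5
  a <- make_atlas(2^c(1, 2, 3, 5), regions = c("A", "B"), replicates = 1,
                  proteins = c("P1", "P2"))
  res <- inter_regional_difference(a, "F50", c("A", "B"))
  expect_equal(res$value, 1.5)
  expect_equal(res$n_pairs, 1)
  # two identical samples -> 0
  b <- make_atlas(2^c(1, 1, 3, 3), regions = c("A", "B"), replicates = 1,
                  proteins = c("P1", "P2"))
  expect_equal(inter_regional_difference(b, "F50", c("A", "B"))$value, 0)
})

test_that("inter-regional difference is invariant to sample order and excludes within-region pairs", {
  sim <- simulate_atlas(small_sim_config(n_proteins = 60, seed = 3))
  a <- sim$atlas
  res1 <- inter_regional_difference(a, "F90", "CTX")
  shuffled <- atlas_subset(a, rev(a$meta$sample_id))
  res2 <- inter_regional_difference(shuffled, "F90", "CTX")
  expect_equal(res1$value, res2$value)
  meta <- a$meta
  n_ctx <- sum(meta$stage == "F90" & meta$macro_region == "CTX")
  n_regions <- dplyr::n_distinct(
    meta$region[meta$stage == "F90" & meta$macro_region == "CTX"]
  )
  # within-region replicate pairs are excluded
  expect_equal(res1$n_pairs,
               choose(n_ctx, 2) - n_regions * choose(3, 2))
  with_within <- inter_regional_difference(a, "F90", "CTX",
                                           include_within = TRUE)
  expect_equal(with_within$n_pairs, choose(n_ctx, 2))
})

test_that("single-region groups fall back to all pairs with a warning (CB case)", {
  sim <- simulate_atlas(small_sim_config(n_proteins = 40, seed = 3))
  expect_warning(res <- inter_regional_difference(sim$atlas, "F90", "CB"),
                 "single region")
  expect_equal(res$n_pairs, 3)
})

test_that("technical CB replicates at F90 depress the CB curve at that stage", {
  sim <- sim_fixture()
  curve <- suppressWarnings(interregional_curve(sim$atlas))
  cb <- curve[curve$group == "CB", ]
  expect_equal(as.character(cb$stage[which.min(cb$value)]), "F90")
})

test_that("a planted V-shaped region-effect schedule recovers its minimum stage", {
  cfg <- sim_config(n_proteins = 500, region_effect_sd = 0.8,
                    region_effect_scale = c(F50 = 1, F90 = 0.7,
                                            F120 = 0.35, P3 = 0.8),
                    seed = 29)
  sim <- simulate_atlas(cfg)
  curve <- suppressWarnings(interregional_curve(sim$atlas))
  for (g in c("CTX", "sCTX")) {
    sub <- curve[curve$group == g, ]
    expect_equal(as.character(sub$stage[which.min(sub$value)]), "F120",
                 info = g)
  }
})

test_that("CB distance: identical region gives 0 and a 3-4-5 toy gives 5", {
  # CB log2 profile (1, 2, 0, 0) vs X (4, 6, 0, 0): distance sqrt(9+16)=5
  lfq <- matrix(2^c(1, 2, 0, 0,
                    1 + 3, 2 + 4, 0, 0), nrow = 4,
                dimnames = list(paste0("P", 1:4), c("cb", "x")))
  lfq[3:4, ] <- 1 # detected, equal
  meta <- tibble::tibble(sample_id = c("cb", "x"), stage = "F50",
                         region = c("CB", "X"))
  b <- lfq_atlas(lfq, meta)
  d <- cb_distance(b, "F50")
  expect_equal(d$distance, 5)
  # identical region
  lfq2 <- cbind(lfq, y = lfq[, "cb"])
  meta2 <- dplyr::bind_rows(meta,
                            tibble::tibble(sample_id = "y", stage = "F50",
                                           region = "Y"))
  d2 <- cb_distance(lfq_atlas(lfq2, meta2), "F50")
  expect_equal(d2$distance[d2$region == "Y"], 0)
})

test_that("CB distances satisfy the triangle inequality on common proteins", {
  sim <- simulate_atlas(small_sim_config(n_proteins = 100, dropout = 0,
                                         n_emergent = 0, seed = 5))
  x <- log2_matrix(sim$atlas)
  meta <- sim$atlas$meta
  prof <- function(r) rowMeans(x[, meta$stage == "F50" & meta$region == r,
                                 drop = FALSE])
  d <- function(a, b) sqrt(sum((prof(a) - prof(b))^2))
  regions <- c("PFC", "V1", "CB")
  expect_lte(d("PFC", "CB"), d("PFC", "V1") + d("V1", "CB") + 1e-9)
  # and cb_distance matches the direct computation with full detection
  cbd <- cb_distance(sim$atlas, "F50")
  expect_equal(cbd$distance[cbd$region == "PFC"], d("PFC", "CB"))
})

test_that("planted growing CB divergence yields increasing CB distances over stages", {
  cfg <- sim_config(n_proteins = 300, n_cb_markers = 40, marker_shift = 0,
                    seed = 31)
  sim <- simulate_atlas(cfg)
  # impose a CB shift growing with stage on the planted CB block
  a <- sim$atlas
  cb_ids <- sim$truth$protein_id[sim$truth$class == "CB" &
                                   !is.na(sim$truth$class)]
  lfq <- a$lfq
  for (s in stage_levels()) {
    cols <- a$meta$stage == s & a$meta$region == "CB"
    shift <- 2^(match(s, stage_levels()) - 1)
    lfq[cb_ids, cols] <- lfq[cb_ids, cols] * shift
  }
  b <- lfq_atlas(lfq, a$meta)
  mean_d <- vapply(stage_levels(), \(s) mean(cb_distance(b, s)$distance),
                   numeric(1))
  expect_true(all(diff(mean_d) > 0))
})

test_that("stage correlations: self-correlation 1, anti-correlation -1, adjacency structure", {
  sim <- sim_fixture()
  sc <- stage_correlation(sim$atlas)
  self <- sc[sc$stage_a == sc$stage_b, ]
  expect_equal(self$r, rep(1, nrow(self)), tolerance = 1e-12)
  expect_true(all(sc$r[sc$stage_a != sc$stage_b] < 1))
  # symmetric
  ab <- sc$r[sc$stage_a == "F50" & sc$stage_b == "P3"]
  ba <- sc$r[sc$stage_a == "P3" & sc$stage_b == "F50"]
  expect_equal(ab, ba)
  # anti-correlated constructed profiles
  lfq <- matrix(2^c(1, 2, 3, 4, 5, 5, 4, 3, 2, 1), nrow = 5,
                dimnames = list(paste0("P", 1:5), c("a", "b")))
  meta <- tibble::tibble(sample_id = c("a", "b"),
                         stage = c("F50", "P3"), region = "PFC")
  sc2 <- stage_correlation(lfq_atlas(lfq, meta))
  expect_equal(sc2$r[sc2$stage_a == "F50" & sc2$stage_b == "P3"], -1)
})

test_that("PCA: duplicate samples coincide, variance fractions are proper, planted axis found", {
  sim <- simulate_atlas(small_sim_config(n_proteins = 200, dropout = 0, seed = 8))
  a <- sim$atlas
  dup_meta <- dplyr::bind_rows(
    a$meta,
    dplyr::mutate(a$meta[1, ], sample_id = "dup")
  )
  dup_lfq <- cbind(a$lfq, dup = a$lfq[, 1])
  p <- atlas_pca(lfq_atlas(dup_lfq, dup_meta), n_components = 3)
  sc <- tidy(p)
  expect_equal(unlist(sc[sc$sample_id == "dup", c("PC1", "PC2", "PC3")]),
               unlist(sc[sc$sample_id == a$meta$sample_id[1],
                         c("PC1", "PC2", "PC3")]),
               ignore_attr = TRUE)
  expect_lte(sum(p$var_explained), 1)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  # constructed 2-feature data with one dominant axis
  set.seed(1)
  t_axis <- rnorm(30, 0, 3)
  lfq <- rbind(2^(20 + t_axis + rnorm(30, 0, 0.01)),
               2^(20 + 2 * t_axis + rnorm(30, 0, 0.01)))
  dimnames(lfq) <- list(c("P1", "P2"), paste0("s", 1:30))
  meta <- tibble::tibble(sample_id = paste0("s", 1:30), stage = "F50",
                         region = "A")
  p2 <- atlas_pca(lfq_atlas(lfq, meta), n_components = 2)
  dir <- p2$rotation[, 1]
  planted <- c(1, 2) / sqrt(5)
  expect_gt(abs(sum(dir * planted)), 0.99)
})

test_that("PCA scores are invariant up to sign under sample permutation", {
  sim <- simulate_atlas(small_sim_config(n_proteins = 150, seed = 10))
  a <- sim$atlas
  p1 <- atlas_pca(a)
  perm <- atlas_subset(a, sample(a$meta$sample_id))
  p2 <- atlas_pca(perm)
  s1 <- tidy(p1) |> dplyr::arrange(sample_id)
  s2 <- tidy(p2) |> dplyr::arrange(sample_id)
  for (pc in c("PC1", "PC2")) {
    agree <- max(abs(s1[[pc]] - s2[[pc]]), abs(s1[[pc]] + s2[[pc]]))
    expect_equal(min(max(abs(s1[[pc]] - s2[[pc]])),
                     max(abs(s1[[pc]] + s2[[pc]]))), 0, tolerance = 1e-8)
  }
})
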