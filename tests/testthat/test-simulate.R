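# Synthetic-data generator: determinism, design emulation, truth ledgers,
# marginal correctness.

test_that("identical seed and config give byte-identical output", {
  s1 <- simulate_atlas(small_sim_config(n_proteins = 60, seed = 9))
  s2 <- simulate_atlas(small_sim_config(n_proteins = 60, seed = 9))
  expect_identical(s1$atlas$lfq, s2$atlas$lfq)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$gene_sets, s2$gene_sets)
  s3 <- simulate_atlas(small_sim_config(n_proteins = 60, seed = 10))
  expect_false(identical(s1$atlas$lfq, s3$atlas$lfq))
})

test_that("sampling design mirrors the widening region panel and CB technical replicates", {
  sim <- simulate_atlas(small_sim_config(n_proteins = 20, seed = 1))
  meta <- sim$atlas$meta
  expect_equal(unname(table(meta$stage)[stage_levels()]) / 3,
               c(5, 11, 18, 18), ignore_attr = TRUE)
  expect_equal(nrow(meta), 156)
  cb_f90 <- meta[meta$stage == "F90" & meta$region == "CB", ]
  expect_true(all(cb_f90$replicate_kind == "technical"))
  expect_equal(dplyr::n_distinct(cb_f90$animal_id), 2)
  # day table increases with stage order
  days <- meta |>
    dplyr::distinct(stage, day) |>
    dplyr::arrange(match(stage, stage_levels()))
  expect_true(all(diff(days$day) > 0))
})

test_that("truth ledger partitions planted proteins with no conflicting roles", {
  sim <- sim_fixture()
  expect_equal(anyDuplicated(sim$truth$protein_id), 0)
  expect_true(all(sim$truth$role %in% c("marker", "emergent", "trajectory")))
})

test_that("planted emergent proteins are absent before onset and detected after", {
  sim <- sim_fixture()
  a <- sim$atlas
  em <- dplyr::filter(sim$truth, role == "emergent",
                      transition == "F90->F120")
  pre <- a$meta$sample_id[a$meta$stage %in% c("F50", "F90")]
  post <- a$meta$sample_id[a$meta$stage %in% c("F120", "P3")]
  expect_true(all(a$lfq[em$protein_id, pre] == 0))
  expect_true(all(a$lfq[em$protein_id, post] > 0))
})

test_that("over-planting is rejected and invalid dropout is rejected", {
  expect_error(sim_config(n_proteins = 50, n_stage_markers = 20),
               "planted")
  expect_error(sim_config(dropout = 1), "dropout")
})

test_that("with dropout 0 the per-protein stage means converge to baseline plus effects", {
  one_region <- list(F50 = "PFC", F90 = "PFC", F120 = "PFC", P3 = "PFC")
  cfg <- sim_config(
    n_proteins = 50, regions = one_region, replicates = 200,
    dropout = 0, n_stage_markers = 0, n_cb_markers = 0, n_emergent = 0,
    n_trajectory = 0, seed = 31
  )
  sim <- simulate_atlas(cfg)
  x <- log2_matrix(sim$atlas)
  eff <- sim$effects
  for (s in stage_levels()) {
    obs <- rowMeans(x[, sim$atlas$meta$stage == s, drop = FALSE])
    pred <- eff$baseline + eff$stage_effect[, s] +
      eff$region_effect[, "PFC"] * cfg$region_effect_scale[[s]]
    # noise sd 0.5 over 200 replicates: mean error sd ~ 0.035
    expect_lt(max(abs(obs - pred)), 0.2)
  }
})

test_that("null configuration produces no planted structure and near-baseline marker rates", {
  cfg <- sim_config(n_proteins = 300, stage_effect_sd = 0,
                    region_effect_sd = 0, dropout = 0,
                    n_stage_markers = 0, n_cb_markers = 0,
                    n_emergent = 0, n_trajectory = 0, seed = 12)
  sim <- simulate_atlas(cfg)
  expect_equal(nrow(sim$truth), 0)
  mk <- find_markers(sim$atlas,
                     class_partition(sim$atlas, "stage",
                                     exclude_regions = "CB"))
  expect_lt(mean(mk$marker), 0.02)
  dep <- dep_stage_vs_rest(sim$atlas, grouping = "all_excl_cb")
  expect_lt(sum(dep$dep), 5)
})

test_that("ortholog panel generator hits its correlation targets exactly in noiseless mode", {
  pan <- simulate_ortholog_panel(n_orthologs = 120, seed = 4)
  cors <- ortholog_correlations(pan$panel)
  joined <- dplyr::inner_join(cors, pan$truth, by = "ortholog_id")
  expect_equal(joined$r_monkey_human, joined$target_r_monkey_human,
               tolerance = 1e-6)
  expect_equal(joined$r_mouse_human, joined$target_r_mouse_human,
               tolerance = 1e-6)
  expect_equal(joined$r_monkey_mouse, joined$target_r_monkey_mouse,
               tolerance = 1e-6)
})

test_that("ortholog generator validates fractions and supports forced extremes", {
  expect_error(simulate_ortholog_panel(10, c(human_specific = 0.9,
                                             conserved = 0.3)),
               "sum")
  # identical vectors give r = 1; negated give r = -1
  v <- c(1, 3, 2, 5, 4)
  panel <- tibble::tibble(
    ortholog_id = "O1",
    species = rep(panel_species(), each = 5),
    region = rep(panel_regions(), 3),
    abundance = c(v, v, -v)
  )
  cors <- ortholog_correlations(panel)
  expect_equal(cors$r_monkey_human, 1)
  expect_equal(cors$r_mouse_human, -1)
})

test_that("RNA/protein pair generator reproduces its ledger exactly and validates input", {
  pr <- simulate_rna_protein_pairs(n_genes = 600, seed = 8)
  typed <- classify_six_types(pr$pairs)
  expect_identical(typed$type, as.integer(pr$truth$type))
  # type-specific constructions: Type1 small both, Type5 opposite signs
  t1 <- typed[pr$truth$type == 1, ]
  expect_true(all(abs(log2(t1$fc_rna)) < 1 & abs(log2(t1$fc_protein)) < 1))
  t5 <- typed[pr$truth$type == 5, ]
  expect_true(all(sign(log2(t5$fc_rna)) != sign(log2(t5$fc_protein))))
  expect_error(simulate_rna_protein_pairs(10, rep(1 / 5, 5)), "six")
  expect_error(simulate_rna_protein_pairs(10, c(-0.1, 0.3, 0.2, 0.2, 0.2, 0.2)),
               "non-negative")
})
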