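# Emergence calls, rates of change, set trajectories, fuzzy trend
# clustering.

test_that("emergence definition: zero-before plus significant detection-after is new", {
  # P1: absent at F50, strongly detected at F90; P2: present throughout
  # P2 sets the detection floor (2^15) well below P1's later values
  lfq <- matrix(2^15, nrow = 2, ncol = 6,
                dimnames = list(c("P1", "P2"), paste0("s", 1:6)))
  lfq[1, 1:3] <- 0
  lfq[1, 4:6] <- 2^c(20, 20.1, 19.9)
  meta <- tibble::tibble(sample_id = paste0("s", 1:6),
                         stage = rep(c("F50", "F90"), each = 3),
                         region = "PFC")
  calls <- call_new_proteins(lfq_atlas(lfq, meta), "PFC", "F50->F90")
  expect_equal(calls$status[calls$protein_id == "P1"], "new")
  expect_equal(calls$status[calls$protein_id == "P2"], "continuing")
  expect_lt(calls$p[calls$protein_id == "P1"], 0.05)
  expect_gt(calls$fold_change[calls$protein_id == "P1"], 1)
})

test_that("non-adjacent transitions are rejected", {
  sim <- simulate_atlas(small_sim_config(n_proteins = 20, seed = 1))
  expect_error(call_new_proteins(sim$atlas, "PFC", "F50->F120"),
               "not adjacent")
  expect_error(rate_of_change(sim$atlas, region_class = "PFC",
                              transition = "F50->F120"), "not adjacent")
})

test_that("planted emergent proteins are recalled and always-detected proteins never called new", {
  cfg <- sim_config(n_proteins = 400, dropout = 0, seed = 37)
  sim <- simulate_atlas(cfg)
  always_detected <- rownames(sim$atlas$lfq)[
    rowSums(sim$atlas$lfq == 0) == 0
  ]
  for (tr in c("F50->F90", "F90->F120", "F120->P3")) {
    calls <- call_new_proteins(sim$atlas, c("PFC", "TL", "PL", "V1"), tr)
    planted <- sim$truth$protein_id[sim$truth$transition == tr &
                                      !is.na(sim$truth$transition)]
    recall <- mean(calls$status[match(planted, calls$protein_id)] == "new")
    expect_gte(recall, 0.95)
    false_new <- intersect(calls$protein_id[calls$status == "new"],
                           always_detected)
    expect_length(false_new, 0)
  }
})

test_that("new calls are anti-monotone in the p threshold", {
  sim <- simulate_atlas(sim_config(n_proteins = 300, seed = 41))
  loose <- call_new_proteins(sim$atlas, "PFC", "F90->F120", alpha = 0.05)
  strict <- call_new_proteins(sim$atlas, "PFC", "F90->F120", alpha = 1e-6)
  expect_true(all(strict$protein_id[strict$status == "new"] %in%
                    loose$protein_id[loose$status == "new"]))
})

test_that("rate of change: flat zero, hand arithmetic, telescoping additivity", {
  lfq <- matrix(2^20, 1, 6, dimnames = list("P1", paste0("s", 1:6)))
  lfq[1, 4:6] <- 2^24
  meta <- tibble::tibble(sample_id = paste0("s", 1:6),
                         stage = rep(c("F50", "F90"), each = 3),
                         region = "PFC")
  r <- rate_of_change(lfq_atlas(lfq, meta), region_class = "PFC",
                      transition = "F50->F90")
  expect_equal(r$rate_per_day, 4 / 40) # +4 log2 over 40 days
  flat <- lfq_atlas(matrix(2^20, 1, 6,
                           dimnames = dimnames(lfq)), meta)
  expect_equal(rate_of_change(flat, region_class = "PFC",
                              transition = "F50->F90")$rate_per_day, 0)

  sim <- simulate_atlas(small_sim_config(n_proteins = 100, dropout = 0, seed = 2))
  ids <- rownames(sim$atlas$lfq)[1:50]
  days <- stage_days()
  rates <- purrr::map(
    c("F50->F90", "F90->F120", "F120->P3"),
    \(tr) rate_of_change(sim$atlas, ids, "PFC", tr)$rate_per_day
  )
  total_gap <- unname(days["P3"] - days["F50"])
  gaps <- c(40, 30, 33)
  telescoped <- (rates[[1]] * gaps[1] + rates[[2]] * gaps[2] +
                   rates[[3]] * gaps[3]) / total_gap
  x <- log2_matrix(sim$atlas)
  meta2 <- sim$atlas$meta
  direct <- (rowMeans(x[ids, meta2$lineage == "PFC" & meta2$stage == "P3",
                        drop = FALSE]) -
               rowMeans(x[ids, meta2$lineage == "PFC" &
                            meta2$stage == "F50", drop = FALSE])) /
    total_gap
  expect_equal(telescoped, unname(direct), tolerance = 1e-9)
})

test_that("planted faster trajectory-set change in PFC exceeds the other lineages", {
  sim <- sim_fixture()
  traj_ids <- sim$truth$protein_id[sim$truth$role == "trajectory"]
  rates <- purrr::map_dbl(c("PFC", "TL", "PL", "V1"), \(lin) {
    rate_of_change(sim$atlas, traj_ids, lin, "F50->F90")$set_mean_rate[1]
  })
  expect_equal(which.max(rates), 1)
})

test_that("set trajectory of a singleton set equals that protein's per-sample sums", {
  sim <- simulate_atlas(small_sim_config(n_proteins = 50, seed = 44))
  ann <- sim$annotation
  one <- list(SOLO = ann$gene_symbol[7])
  st <- set_trajectory(sim$atlas, one, ann)
  direct <- tapply(sim$atlas$lfq[7, ], sim$atlas$meta$stage, mean)
  expect_equal(st$trajectory$mean_abundance,
               as.vector(direct[as.character(st$trajectory$stage)]))
})

test_that("planted increasing set is significant in PFC but not elsewhere; flat sets are not flagged", {
  sim <- sim_fixture()
  sets <- sim$gene_sets["SYNAPTIC_ASSEMBLY"]
  st_pfc <- set_trajectory(sim$atlas, sets, sim$annotation,
                           regions = "PFC")
  expect_true(all(st_pfc$segments$significant))
  st_v1 <- set_trajectory(sim$atlas, sets, sim$annotation, regions = "V1")
  expect_false(any(st_v1$segments$significant))
  # empty mapped set warns and is skipped
  expect_warning(
    expect_error(
      set_trajectory(sim$atlas, list(EMPTY = "NOSUCHGENE"),
                     sim$annotation),
      "No gene set"
    ),
    "maps to no protein"
  )
})

test_that("fuzzy memberships sum to 1 and the objective never increases", {
  sim <- simulate_atlas(small_sim_config(n_proteins = 200, seed = 3))
  fit <- fuzzy_cmeans_trends(sim$atlas, seed = 5)
  expect_equal(unname(rowSums(fit$membership)),
               rep(1, nrow(fit$membership)), tolerance = 1e-9)
  expect_true(all(diff(fit$objective) <= 1e-8))
  fit2 <- fuzzy_cmeans_trends(sim$atlas, seed = 5)
  expect_identical(fit$membership, fit2$membership)
})

test_that("four planted trend archetypes are recovered at 90%+ hard-label accuracy", {
  set.seed(13)
  arch <- rbind(
    up = scale(c(1, 2, 3, 4))[, 1],
    down = scale(c(4, 3, 2, 1))[, 1],
    updown = scale(c(1, 4, 4, 1))[, 1],
    downup = scale(c(4, 1, 1, 4))[, 1]
  )
  n_per <- 40
  x <- arch[rep(1:4, each = n_per), ] +
    matrix(rnorm(4 * n_per * 4, 0, 0.15), 4 * n_per, 4)
  rownames(x) <- sprintf("P%03d", seq_len(nrow(x)))
  fit <- fuzzy_cmeans(x, centers = 4, seed = 2)
  truth <- rep(1:4, each = n_per)
  tab <- table(truth, fit$cluster)
  accuracy <- sum(apply(tab, 1, max)) / length(truth)
  expect_gte(accuracy, 0.9)
})

test_that("fuzzifier near 1 approaches k-means assignment on a separable toy", {
  set.seed(21)
  centers <- rbind(c(0, 0, 0, 0), c(5, 5, 0, 0), c(0, 5, 5, 0))
  x <- centers[rep(1:3, each = 25), ] + matrix(rnorm(300, 0, 0.2), 75, 4)
  rownames(x) <- sprintf("P%02d", 1:75)
  fit <- fuzzy_cmeans(x, centers = 3, fuzzifier = 1.05, seed = 4)
  km <- stats::kmeans(x, centers = centers)
  tab <- table(fit$cluster, km$cluster)
  expect_equal(sum(apply(tab, 1, max)), 75)
})

test_that("fuzzy c-means agrees with the e1071 reference on a toy problem", {
  skip_if_not_installed("e1071")
  set.seed(9)
  x <- rbind(matrix(rnorm(60, 0, 0.3), 15, 4),
             matrix(rnorm(60, 4, 0.3), 15, 4))
  rownames(x) <- sprintf("P%02d", 1:30)
  fit <- fuzzy_cmeans(x, centers = 2, fuzzifier = 2, seed = 1,
                      tol = 1e-10, max_iter = 1000)
  ref <- e1071::cmeans(x, centers = fit$centroids, m = 2,
                       iter.max = 1000)
  # same converged centroids (order fixed by warm start) and memberships
  expect_equal(unname(ref$centers), unname(fit$centroids),
               tolerance = 1e-3)
  expect_equal(unname(ref$membership), unname(fit$membership),
               tolerance = 1e-2)
})

test_that("degenerate clustering inputs are rejected", {
  x <- matrix(rep(c(1, 2, 3, 4), 5), 5, 4, byrow = TRUE)
  expect_error(fuzzy_cmeans(x, centers = 3), "distinct")
})
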