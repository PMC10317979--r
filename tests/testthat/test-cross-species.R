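# Ortholog correlations, conservation classes, distributions, KS, family
# tables.

toy_panel <- function(h, m, mo, id = "O1") {
  tibble::tibble(
    ortholog_id = id,
    species = rep(panel_species(), each = 5),
    region = rep(panel_regions(), 3),
    abundance = c(h, m, mo)
  )
}

test_that("pairwise Pearson correlations match the closed-form hand computation", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(1, 2, 3, 4, 6)
  # hand-evaluated Pearson for (1..5) vs (1,2,3,4,6)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  cors <- ortholog_correlations(toy_panel(a, b, a))
  expect_equal(cors$r_monkey_human, r_hand, tolerance = 1e-12)
  expect_equal(cors$r_monkey_mouse, r_hand, tolerance = 1e-12)
  expect_equal(cors$r_mouse_human, 1)
  # constant vector -> undefined
  cors2 <- ortholog_correlations(toy_panel(rep(2, 5), a, b))
  expect_true(is.na(cors2$r_monkey_human))
})

test_that("panels missing a species or region are rejected", {
  bad <- toy_panel(1:5, 1:5, 1:5)[-1, ]
  expect_error(ortholog_correlations(bad), "five regions|three species")
})

test_that("classification worked examples are forced by the interval rules", {
  calls <- classify_conservation(tibble::tibble(
    ortholog_id = c("a", "b", "c", "d"),
    r_monkey_human = c(-0.8, 0.9, 0.9, 0.3),
    r_mouse_human = c(-0.6, 0.2, 0.8, 0.2),
    r_monkey_mouse = c(0.5, 0.3, 0.9, 0.1)
  ))
  expect_equal(calls$class, c("human_specific", "primate_specific",
                              "conserved", "unclassified"))
})

test_that("noiseless constructed panels are recovered 100% and classes partition the panel", {
  pan <- simulate_ortholog_panel(n_orthologs = 400, seed = 6)
  calls <- classify_conservation(ortholog_correlations(pan$panel))
  expect_equal(calls$class, pan$truth$class)
  counts <- table(calls$class)
  expect_equal(sum(counts), 400)
})

test_that("the three interval rules are pairwise disjoint over random correlation triples", {
  set.seed(8)
  n <- 10000
  mh <- runif(n, -1, 1)
  mouse_h <- runif(n, -1, 1)
  mm <- runif(n, -1, 1)
  P <- oracle_conservation(mh, mouse_h, mm)
  expect_true(all(rowSums(P) <= 1))
  calls <- classify_conservation(tibble::tibble(
    ortholog_id = as.character(seq_len(n)),
    r_monkey_human = mh, r_mouse_human = mouse_h, r_monkey_mouse = mm
  ))
  oracle_label <- apply(P, 1, \(row) {
    if (any(row)) colnames(P)[which(row)] else "unclassified"
  })
  expect_equal(calls$class, unname(oracle_label))
})

test_that("noisy panels are still recovered at 95%+", {
  pan <- simulate_ortholog_panel(
    n_orthologs = 300,
    class_fractions = c(human_specific = 0.2, primate_specific = 0.2,
                        conserved = 0.2),
    seed = 11, noise_sd = 0.05
  )
  calls <- classify_conservation(ortholog_correlations(pan$panel))
  expect_gte(mean(calls$class == pan$truth$class), 0.95)
})

test_that("correlation histogram percentages sum to 100 and the cumulative curve is proper", {
  pan <- simulate_ortholog_panel(n_orthologs = 250, seed = 13)
  calls <- ortholog_correlations(pan$panel)
  dist <- correlation_distribution(calls)
  sums <- dist$histogram |>
    dplyr::group_by(comparison) |>
    dplyr::summarise(total = sum(percent),
                     last_cum = dplyr::last(cumulative_percent),
                     monotone = all(diff(cumulative_percent) >= -1e-9))
  expect_equal(sums$total, rep(100, 3), tolerance = 1e-9)
  expect_equal(sums$last_cum, rep(100, 3), tolerance = 1e-9)
  expect_true(all(sums$monotone))
  # all r = 1 concentrates in the top bin
  ones <- tibble::tibble(ortholog_id = c("a", "b"),
                         r_monkey_human = 1, r_mouse_human = 1,
                         r_monkey_mouse = 1)
  d1 <- correlation_distribution(ones)
  top <- d1$histogram |>
    dplyr::filter(comparison == "monkey_human")
  expect_equal(top$percent[8], 100)
})

test_that("the KS statistic equals the brute-force maximum ECDF gap", {
  set.seed(17)
  for (i in 1:10) {
    a <- rnorm(sample(5:50, 1))
    b <- rnorm(sample(5:50, 1), mean = runif(1, -1, 1))
    D <- suppressWarnings(ks.test(a, b)$statistic)
    expect_equal(unname(D), brute_ks_D(a, b), tolerance = 1e-12)
  }
  # KS of a sample against itself is 0
  a <- rnorm(20)
  expect_equal(brute_ks_D(a, a), 0)
})

test_that("family correlation tables rank families by abundance and keep all members", {
  pan <- simulate_ortholog_panel(n_orthologs = 150, seed = 19,
                                 n_families = 6)
  fam <- family_correlations(pan$panel, pan$annotation, top_k = 3)
  expect_equal(dplyr::n_distinct(fam$family), 3)
  expect_true(all(fam$family_rank <= 3))
  # top_k larger than family count returns all families
  fam_all <- family_correlations(pan$panel, pan$annotation, top_k = 99)
  expect_equal(dplyr::n_distinct(fam_all$family), 6)
  # a single-member family yields exactly three comparison rows
  ann1 <- pan$annotation
  solo_fam <- ann1$family[1]
  solo <- fam_all |>
    dplyr::filter(ortholog_id == ann1$ortholog_id[1])
  expect_equal(nrow(solo), 3)
  # planted mixture: half conserved, half human-specific members show both signs
  pan2 <- simulate_ortholog_panel(
    n_orthologs = 40,
    class_fractions = c(human_specific = 0.5, conserved = 0.5),
    seed = 23, n_families = 1
  )
  fam2 <- family_correlations(pan2$panel, pan2$annotation, top_k = 1)
  mh <- fam2$r[fam2$comparison == "monkey_human"]
  expect_true(any(mh > 0.75) && any(mh < -0.5))
})
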