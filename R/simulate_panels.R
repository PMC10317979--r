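# Generators for the cross-species ortholog panel and the paired
# RNA/protein fold-change table. Both plant exact, ledgered structure.

#' Regions shared across species in the ortholog panel
#' @return Character vector of the five shared regions.
#' @export
panel_regions <- function() c("PFC", "STr", "MD", "Hipp", "CB")

#' Species in the ortholog panel
#' @return Character vector `c("human", "monkey", "mouse")`.
#' @export
panel_species <- function() c("human", "monkey", "mouse")

# Build three length-n vectors whose sample Pearson correlation matrix is
# exactly R (correlation targeting by construction, not rejection):
# columns of a centered orthonormal basis are mixed by chol(R).
correlated_triplet <- function(r_hm, r_hmouse, r_mmouse, n = 5) {
  R <- matrix(c(1, r_hm, r_hmouse,
                r_hm, 1, r_mmouse,
                r_hmouse, r_mmouse, 1), 3, 3)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort("Infeasible correlation targets: matrix not positive semidefinite.")
  }
  # centered orthonormal basis of dimension 3 in R^n (needs n >= 4)
  B <- matrix(rnorm(n * 3), n, 3)
  B <- scale(B, center = TRUE, scale = FALSE)
  B <- qr.Q(qr(B))[, 1:3, drop = FALSE]
  B <- scale(B, center = TRUE, scale = FALSE) # numerically re-center
  B <- apply(B, 2, \(v) v / sqrt(sum(v^2) / (n - 1)))
  U <- chol(R + diag(1e-12, 3)) # upper-triangular, U'U = R
  B %*% U # columns: human, monkey, mouse; cor(V) = U' (B'B/(n-1)) U = R
}

# Class-conditional correlation targets. The third (unconstrained)
# correlation is set to the product of the two drawn ones, which keeps the
# 3x3 matrix positive semidefinite for any draws in [-1, 1].
draw_class_targets <- function(class) {
  switch(class,
    conserved = {
      a <- runif(1, 0.8, 0.98)  # monkey-human
      b <- runif(1, 0.8, 0.98)  # monkey-mouse
      c(r_hm = a, r_hmouse = a * b, r_mmouse = b)
    },
    human_specific = {
      a <- runif(1, -0.95, -0.55) # monkey-human
      b <- runif(1, -0.95, -0.55) # mouse-human
      c(r_hm = a, r_hmouse = b, r_mmouse = a * b)
    },
    primate_specific = {
      a <- runif(1, 0.8, 0.98)    # monkey-human
      b <- runif(1, -0.3, 0.4)    # mouse-human
      c(r_hm = a, r_hmouse = b, r_mmouse = a * b)
    },
    unclassified = {
      a <- runif(1, -0.45, 0.6)
      b <- runif(1, -0.45, 0.6)
      c(r_hm = a, r_hmouse = b, r_mmouse = a * b)
    },
    abort(paste0("Unknown conservation class: ", class))
  )
}

#' Simulate a cross-species ortholog abundance panel
#'
#' For each 1:1 ortholog, builds 5-region abundance vectors for human,
#' monkey and mouse whose pairwise Pearson correlations land exactly in the
#' intervals defining the intended conservation class (constructed vectors,
#' not rejection sampling). Orthologs are also assigned to protein families
#' with family-specific abundance levels, supporting family-level summaries.
#'
#' @param n_orthologs Number of orthologs. The default mirrors the size of
#'   a three-species comparison panel (3025).
#' @param class_fractions Named fractions for `human_specific`,
#'   `primate_specific` and `conserved`; the remainder is unclassified.
#'   Defaults are 531/3025, 591/3025 and 457/3025.
#' @param seed Integer seed.
#' @param noise_sd SD of Gaussian perturbation added to the constructed
#'   vectors; 0 (default) keeps class membership exact.
#' @param n_families Number of protein families to assign.
#' @return List with `panel` (long tibble: `ortholog_id`, `species`,
#'   `region`, `abundance`), `truth` (`ortholog_id`, `class`, target
#'   correlations, `family`), and `annotation` (ortholog to family map).
#' @export
simulate_ortholog_panel <- function(n_orthologs = 3025,
                                    class_fractions = c(
                                      human_specific = 531 / 3025,
                                      primate_specific = 591 / 3025,
                                      conserved = 457 / 3025
                                    ),
                                    seed = 1L,
                                    noise_sd = 0,
                                    n_families = 12) {
  if (any(class_fractions < 0)) {
    abort("Class fractions must be non-negative.")
  }
  if (sum(class_fractions) > 1 + 1e-12) {
    abort("Class fractions must sum to <= 1.")
  }
  wanted <- c("human_specific", "primate_specific", "conserved")
  missing <- setdiff(names(class_fractions), wanted)
  if (length(missing) > 0) {
    abort(paste0("Unknown class fraction name(s): ",
                 paste(missing, collapse = ", ")))
  }
  with_seed(seed, {
    counts <- floor(n_orthologs * class_fractions[wanted])
    counts[is.na(counts)] <- 0
    classes <- c(rep(wanted, times = counts))
    classes <- c(classes,
                 rep("unclassified", n_orthologs - length(classes)))
    ids <- sprintf("ORTH%04d", seq_len(n_orthologs))
    families <- sprintf("FAM%02d", seq_len(n_families))
    fam_level <- stats::setNames(rnorm(n_families, 25, 2), families)
    fam_assign <- sample(families, n_orthologs, replace = TRUE)
    reg_vec <- panel_regions()
    sp_vec <- panel_species()

    rows <- vector("list", n_orthologs)
    truth <- vector("list", n_orthologs)
    for (i in seq_len(n_orthologs)) {
      tg <- draw_class_targets(classes[i])
      V <- correlated_triplet(tg["r_hm"], tg["r_hmouse"], tg["r_mmouse"])
      if (noise_sd > 0) {
        V <- V + matrix(rnorm(length(V), 0, noise_sd), nrow(V))
      }
      V <- V + fam_level[[fam_assign[i]]]
      rows[[i]] <- tibble::tibble(
        ortholog_id = ids[i],
        species = rep(sp_vec, each = length(reg_vec)),
        region = rep(reg_vec, times = length(sp_vec)),
        abundance = as.vector(V)
      )
      truth[[i]] <- tibble::tibble(
        ortholog_id = ids[i], class = classes[i],
        target_r_monkey_human = unname(tg["r_hm"]),
        target_r_mouse_human = unname(tg["r_hmouse"]),
        target_r_monkey_mouse = unname(tg["r_mmouse"]),
        family = fam_assign[i]
      )
    }
    list(
      panel = purrr::list_rbind(rows),
      truth = purrr::list_rbind(truth),
      annotation = tibble::tibble(ortholog_id = ids, family = fam_assign)
    )
  })
}

#' Simulate paired RNA/protein fold changes
#'
#' Draws (RNA FC, protein FC) pairs from the region of fold-change space
#' that defines each of the six concordance types, so the ledgered type is
#' reproduced exactly by [classify_six_types()] on noiseless draws. Type 4
#' occupies the consistent-direction boundary at |FC| = 2 on one axis (see
#' the methods vignette for why its interior is empty).
#'
#' @param n_genes Number of genes.
#' @param type_fractions Fractions over types 1..6 summing to 1. Defaults
#'   mirror a frontal-lobe type composition (78.7/15.6/1.4% for types 1-3,
#'   the remainder split over types 4-6).
#' @param seed Integer seed.
#' @return List with `pairs` (tibble: `gene`, `fc_rna`, `fc_protein`) and
#'   `truth` (`gene`, `type`).
#' @export
simulate_rna_protein_pairs <- function(n_genes = 2000,
                                       type_fractions = c(
                                         0.787, 0.156, 0.014,
                                         0.010, 0.020, 0.013
                                       ),
                                       seed = 1L) {
  if (length(type_fractions) != 6) {
    abort("`type_fractions` must have six entries.")
  }
  if (any(type_fractions < 0)) {
    abort("Type fractions must be non-negative.")
  }
  if (abs(sum(type_fractions) - 1) > 1e-8) {
    abort("Type fractions must sum to 1.")
  }
  with_seed(seed, {
    counts <- floor(n_genes * type_fractions)
    while (sum(counts) < n_genes) { # assign remainder to the largest type
      k <- which.max(type_fractions)
      counts[k] <- counts[k] + (n_genes - sum(counts))
    }
    types <- rep(1:6, times = counts)
    n <- length(types)
    sgn <- function(n) sample(c(-1, 1), n, replace = TRUE)
    small <- function(n) runif(n, -0.9, 0.9)      # |log2 FC| < 1
    big <- function(n) runif(n, 1.1, 3)           # |log2 FC| > 1
    lr <- numeric(n)
    lp <- numeric(n)
    for (ty in 1:6) {
      i <- which(types == ty)
      m <- length(i)
      if (m == 0) next
      switch(as.character(ty),
        "1" = { lr[i] <- small(m); lp[i] <- small(m) },
        "2" = { lr[i] <- small(m); lp[i] <- sgn(m) * big(m) },
        "3" = { lr[i] <- sgn(m) * big(m); lp[i] <- small(m) },
        "4" = { s <- sgn(m); lr[i] <- s * 1; lp[i] <- s * big(m) },
        "5" = { s <- sgn(m); lr[i] <- s * big(m); lp[i] <- -s * big(m) },
        "6" = { s <- sgn(m); lr[i] <- s * big(m); lp[i] <- s * big(m) }
      )
    }
    ord <- sample.int(n)
    genes <- sprintf("GENE%04d", seq_len(n))
    list(
      pairs = tibble::tibble(
        gene = genes, fc_rna = 2^lr[ord], fc_protein = 2^lp[ord]
      ),
      truth = tibble::tibble(gene = genes, type = types[ord])
    )
  })
}
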