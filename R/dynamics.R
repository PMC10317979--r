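# Inter-regional dissimilarity, CB-to-region distances, stage-stage
# correlations, and PCA.

macro_group_samples <- function(meta, stage, group) {
  if (!stage %in% meta$stage) {
    abort(paste0("Stage ", stage, " absent from atlas."))
  }
  in_group <- if (all(group %in% c("CB", "CTX", "sCTX"))) {
    meta$macro_region %in% group
  } else {
    meta$region %in% group
  }
  which(meta$stage == stage & in_group)
}

#' Inter-regional difference at one stage
#'
#' Over all unordered pairs of samples from *different* regions within a
#' macro-region group, computes the mean absolute difference of log2 LFQ
#' over proteins detected in both samples, then averages over pairs. For a
#' group with a single region (the CB case) there are no cross-region
#' pairs; the statistic falls back to all sample pairs with a warning, so
#' technical replicates depress the value exactly as replicate-level
#' pairing would.
#'
#' @param atlas An [lfq_atlas].
#' @param stage Stage label.
#' @param group Macro-region name (`"CB"`, `"CTX"`, `"sCTX"`) or a vector
#'   of region codes.
#' @param include_within Also include same-region pairs when cross-region
#'   pairs exist (default FALSE: the statistic is inter-regional).
#' @param return_pairs Return the per-pair values instead of the summary.
#' @return Tibble with `stage`, `group`, `value`, `n_pairs` (or per-pair
#'   rows when `return_pairs = TRUE`).
#' @export
inter_regional_difference <- function(atlas, stage, group,
                                      include_within = FALSE,
                                      return_pairs = FALSE) {
  meta <- atlas$meta
  idx <- macro_group_samples(meta, stage, group)
  if (length(idx) < 2) {
    abort("Need at least 2 samples in the group at the stage.")
  }
  x <- log2_matrix(atlas)[, idx, drop = FALSE]
  regions <- meta$region[idx]
  pairs <- combn(seq_along(idx), 2)
  cross <- regions[pairs[1, ]] != regions[pairs[2, ]]
  if (!any(cross)) {
    warn(paste0("Group has a single region at ", stage,
                "; falling back to all sample pairs."))
  } else if (!include_within) {
    pairs <- pairs[, cross, drop = FALSE]
  }
  vals <- vapply(seq_len(ncol(pairs)), function(k) {
    a <- x[, pairs[1, k]]
    b <- x[, pairs[2, k]]
    mean(abs(a - b), na.rm = TRUE)
  }, numeric(1))
  label <- if (is.character(group) && length(group) == 1) group else
    paste(group, collapse = "+")
  if (return_pairs) {
    return(tibble::tibble(
      stage = stage, group = label,
      sample_a = colnames(x)[pairs[1, ]],
      sample_b = colnames(x)[pairs[2, ]],
      value = vals
    ))
  }
  tibble::tibble(stage = stage, group = label, value = mean(vals),
                 n_pairs = ncol(pairs))
}

#' Inter-regional difference curve over stages
#'
#' Convenience wrapper evaluating [inter_regional_difference()] for each
#' (stage, group) combination available in the atlas.
#'
#' @param atlas An [lfq_atlas].
#' @param groups Macro-region groups (default CB, CTX, sCTX).
#' @return Tibble with `stage`, `group`, `value`, `n_pairs`.
#' @export
interregional_curve <- function(atlas, groups = c("CB", "CTX", "sCTX")) {
  meta <- atlas$meta
  stages <- intersect(stage_levels(), unique(meta$stage))
  tidyr::crossing(stage = stages, group = groups) |>
    purrr::pmap(\(stage, group) {
      idx <- macro_group_samples(meta, stage, group)
      if (length(idx) < 2) {
        return(NULL)
      }
      suppressWarnings(inter_regional_difference(atlas, stage, group))
    }) |>
    purrr::list_rbind() |>
    mutate(stage = stage_factor(.data$stage)) |>
    arrange(.data$group, .data$stage)
}

#' Euclidean distance of a reference region to the others
#'
#' Distance between the mean log2 profile of the reference region
#' (cerebellum by default) and each other region at a stage, over proteins
#' with a defined mean in both regions.
#'
#' @param atlas An [lfq_atlas].
#' @param stage Stage label.
#' @param ref_region Reference region (default `"CB"`).
#' @return Tibble with `stage`, `region`, `distance`, `n_proteins`.
#' @export
cb_distance <- function(atlas, stage, ref_region = "CB") {
  meta <- atlas$meta
  if (!any(meta$stage == stage & meta$region == ref_region)) {
    abort(paste0(ref_region, " not sampled at ", stage, "."))
  }
  x <- log2_matrix(atlas)
  cols <- which(meta$stage == stage)
  mean_profile <- function(region) {
    idx <- cols[meta$region[cols] == region]
    rowMeans(x[, idx, drop = FALSE], na.rm = TRUE)
  }
  ref <- mean_profile(ref_region)
  others <- setdiff(unique(meta$region[cols]), ref_region)
  purrr::map(others, \(r) {
    v <- mean_profile(r)
    shared <- !is.na(ref) & !is.na(v)
    if (!any(shared)) {
      abort(paste0("No shared detected proteins between ", ref_region,
                   " and ", r, " at ", stage, "."))
    }
    tibble::tibble(
      stage = stage, region = r,
      distance = sqrt(sum((ref[shared] - v[shared])^2)),
      n_proteins = sum(shared)
    )
  }) |>
    purrr::list_rbind()
}

#' Stage-by-stage Pearson correlation of mean profiles
#'
#' Averages replicates into per-stage mean log2 profiles first, then
#' correlates each pair of stages over proteins detected in both, with the
#' two-sided p-value of the correlation test. Degenerate (constant)
#' profiles give NA.
#'
#' @param atlas An [lfq_atlas].
#' @param min_shared Minimum shared proteins per stage pair.
#' @return Tibble with `stage_a`, `stage_b`, `r`, `p`, `n_proteins`.
#' @export
stage_correlation <- function(atlas, min_shared = 3) {
  meta <- atlas$meta
  x <- log2_matrix(atlas)
  stages <- intersect(stage_levels(), unique(meta$stage))
  profiles <- purrr::map(stages, \(s) {
    rowMeans(x[, meta$stage == s, drop = FALSE], na.rm = TRUE)
  }) |>
    setNames(stages)
  tidyr::crossing(stage_a = stages, stage_b = stages) |>
    purrr::pmap(\(stage_a, stage_b) {
      a <- profiles[[stage_a]]
      b <- profiles[[stage_b]]
      shared <- !is.na(a) & !is.na(b)
      if (sum(shared) < min_shared) {
        abort(paste0("Fewer than ", min_shared, " shared proteins for ",
                     stage_a, " vs ", stage_b, "."))
      }
      a <- a[shared]
      b <- b[shared]
      if (sd(a) == 0 || sd(b) == 0) {
        return(tibble::tibble(stage_a = stage_a, stage_b = stage_b,
                              r = NA_real_, p = NA_real_,
                              n_proteins = sum(shared)))
      }
      ht <- suppressWarnings(cor.test(a, b))
      tibble::tibble(stage_a = stage_a, stage_b = stage_b,
                     r = unname(ht$estimate), p = ht$p.value,
                     n_proteins = length(a))
    }) |>
    purrr::list_rbind()
}

#' PCA of atlas samples
#'
#' Centered (unscaled by default) principal component analysis of the
#' complete-case log2 matrix (proteins detected in every sample), via
#' singular value decomposition.
#'
#' @param atlas An [lfq_atlas].
#' @param n_components Number of components to keep.
#' @param scale. Scale proteins to unit variance before the SVD.
#' @return An `atlas_pca` object; see [tidy.atlas_pca()] and
#'   [glance.atlas_pca()].
#' @export
atlas_pca <- function(atlas, n_components = 2, scale. = FALSE) {
  x <- log2_matrix(atlas)
  complete <- rowSums(is.na(x)) == 0
  if (sum(complete) < max(2, n_components)) {
    abort("Fewer complete-case proteins than requested components.")
  }
  fit <- prcomp(t(x[complete, , drop = FALSE]), center = TRUE,
                scale. = scale.)
  n_components <- min(n_components, ncol(fit$x))
  var_frac <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- tibble::as_tibble(fit$x[, seq_len(n_components), drop = FALSE]) |>
    mutate(sample_id = rownames(fit$x), .before = 1) |>
    left_join(atlas$meta, by = "sample_id")
  structure(
    list(scores = scores, var_explained = var_frac[seq_len(n_components)],
         rotation = fit$rotation[, seq_len(n_components), drop = FALSE],
         n_proteins = sum(complete)),
    class = "atlas_pca"
  )
}

#' @export
print.atlas_pca <- function(x, ...) {
  cat("<atlas_pca> ", nrow(x$scores), " samples, ", x$n_proteins,
      " complete-case proteins\n", sep = "")
  cat("  variance explained: ",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Tidy PCA scores
#' @param x An `atlas_pca`.
#' @param ... Unused.
#' @return Tibble of per-sample scores with metadata.
#' @export
tidy.atlas_pca <- function(x, ...) x$scores

#' One-row PCA summary
#' @param x An `atlas_pca`.
#' @param ... Unused.
#' @return Tibble with `n_samples`, `n_proteins` and per-component
#'   variance fractions.
#' @export
glance.atlas_pca <- function(x, ...) {
  out <- tibble::tibble(n_samples = nrow(x$scores),
                        n_proteins = x$n_proteins)
  for (i in seq_along(x$var_explained)) {
    out[[paste0("var_pc", i)]] <- x$var_explained[i]
  }
  out
}

#' @describeIn atlas_pca Score plot coloured by stage, shaped by
#'   macro-region.
#' @param object An `atlas_pca`.
#' @param ... Unused.
#' @export
autoplot.atlas_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2,
                               colour = stage_factor(.data$stage),
                               shape = .data$macro_region)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]),
      colour = "stage", shape = "macro-region"
    ) +
    ggplot2::theme_minimal()
}
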