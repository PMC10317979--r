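# Differentially expressed protein (DEP) identification: two-sided
# pooled-variance Student's t-tests on log2 LFQ, Bonferroni-corrected
# within each contrast (family = proteins tested in that contrast).

dep_contrast <- function(atlas, idx_in, idx_out, label, alpha = 0.05,
                         min_n = 2L) {
  x <- log2_matrix(atlas)
  res <- row_t_test(x, idx_in, idx_out, min_n = min_n)
  fc <- row_fold_change(lfq_matrix(atlas), idx_in, idx_out)
  family_size <- sum(res$tested)
  tibble::tibble(
    protein_id = rownames(x),
    contrast = label,
    t = res$t,
    df = res$df,
    p = res$p,
    p_adj = pmin(1, res$p * family_size),
    fold_change = fc,
    direction = dplyr::case_when(
      !res$tested ~ NA_character_,
      res$t > 0 ~ "up",
      res$t < 0 ~ "down",
      TRUE ~ "none"
    ),
    tested = res$tested,
    dep = res$tested & !is.na(res$p) & pmin(1, res$p * family_size) < alpha
  )
}

#' Region-vs-rest DEPs at one stage
#'
#' For each region sampled at the stage, tests every protein between the
#' region's samples and all other same-stage samples (two-sided
#' pooled-variance t on log2 LFQ). A protein is tested only when each side
#' has at least `min_n` detected values; untested proteins are reported
#' with `tested = FALSE`. Bonferroni correction is applied over the
#' proteins tested within each region contrast, and `dep` flags adjusted
#' p < `alpha`.
#'
#' @param atlas An [lfq_atlas].
#' @param stage Stage label present in the atlas.
#' @param alpha Significance level on the adjusted p-value.
#' @param min_n Minimum detected values per side.
#' @return Tibble with one row per (region, protein): `protein_id`,
#'   `contrast`, `region`, `stage`, `t`, `df`, `p`, `p_adj`,
#'   `fold_change`, `direction`, `tested`, `dep`.
#' @export
dep_region_vs_rest <- function(atlas, stage, alpha = 0.05, min_n = 2L) {
  meta <- atlas$meta
  if (!stage %in% meta$stage) {
    abort(paste0("Stage ", stage, " absent from atlas."))
  }
  cols <- which(meta$stage == stage)
  regions <- unique(meta$region[cols])
  purrr::map(regions, \(r) {
    idx_in <- cols[meta$region[cols] == r]
    idx_out <- cols[meta$region[cols] != r]
    dep_contrast(atlas, idx_in, idx_out,
                 label = paste0(r, "_vs_rest@", stage),
                 alpha = alpha, min_n = min_n) |>
      mutate(region = r, stage = stage, .after = "contrast")
  }) |>
    purrr::list_rbind()
}

resolve_grouping <- function(meta, grouping) {
  keep <- switch(grouping,
    all = rep(TRUE, nrow(meta)),
    all_excl_cb = meta$macro_region != "CB",
    ctx = meta$macro_region == "CTX",
    sctx = meta$macro_region == "sCTX",
    abort(paste0("Unknown grouping: ", grouping))
  )
  if (!any(keep)) abort("Grouping removes every sample.")
  lost <- setdiff(unique(meta$stage), unique(meta$stage[keep]))
  if (length(lost) > 0) {
    abort(paste0("Grouping removes whole stage(s): ",
                 paste(lost, collapse = ", ")))
  }
  keep
}

#' Stage-vs-rest DEPs
#'
#' One-vs-rest contrasts across the four stages, with the same test and
#' per-contrast Bonferroni correction as [dep_region_vs_rest()]. The
#' `grouping` restricts the sample set first (`"all_excl_cb"` drops CB,
#' `"ctx"`/`"sctx"` keep one macro-region); removing a whole stage is an
#' error.
#'
#' @param atlas An [lfq_atlas].
#' @param grouping One of `"all_excl_cb"` (default), `"all"`, `"ctx"`,
#'   `"sctx"`.
#' @inheritParams dep_region_vs_rest
#' @return Tibble as in [dep_region_vs_rest()] with a `stage` column for
#'   the one-vs-rest stage.
#' @export
dep_stage_vs_rest <- function(atlas, grouping = "all_excl_cb",
                              alpha = 0.05, min_n = 2L) {
  meta <- atlas$meta
  keep <- resolve_grouping(meta, grouping)
  cols_all <- which(keep)
  stages <- intersect(stage_levels(), unique(meta$stage[keep]))
  purrr::map(stages, \(s) {
    idx_in <- cols_all[meta$stage[cols_all] == s]
    idx_out <- cols_all[meta$stage[cols_all] != s]
    dep_contrast(atlas, idx_in, idx_out,
                 label = paste0(s, "_vs_rest[", grouping, "]"),
                 alpha = alpha, min_n = min_n) |>
      mutate(stage = s, .after = "contrast")
  }) |>
    purrr::list_rbind()
}

#' Stage-axis vs region-axis DEP summary
#'
#' Venn-style summary: the union of stage-vs-rest DEPs, the union of
#' region-vs-rest DEPs over all stages, and their intersection, computed on
#' the same grouped sample set.
#'
#' @inheritParams dep_stage_vs_rest
#' @return Tibble with columns `axis` (`"stage"`, `"region"`, `"both"`) and
#'   `n_deps`, plus a `proteins` list-column of the protein IDs.
#' @export
dep_summary <- function(atlas, grouping = "all_excl_cb", alpha = 0.05,
                        min_n = 2L) {
  meta <- atlas$meta
  keep <- resolve_grouping(meta, grouping)
  sub <- atlas_subset(atlas, meta$sample_id[keep])
  stage_dep <- dep_stage_vs_rest(sub, grouping = "all", alpha = alpha,
                                 min_n = min_n) |>
    filter(.data$dep) |>
    pull("protein_id") |>
    unique()
  region_dep <- unique(unlist(purrr::map(
    intersect(stage_levels(), unique(sub$meta$stage)),
    \(s) {
      res <- dep_region_vs_rest(sub, s, alpha = alpha, min_n = min_n)
      res$protein_id[res$dep]
    }
  )))
  tibble::tibble(
    axis = c("stage", "region", "both"),
    n_deps = c(length(stage_dep), length(region_dep),
               length(intersect(stage_dep, region_dep))),
    proteins = list(stage_dep, region_dep, intersect(stage_dep, region_dep))
  )
}
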