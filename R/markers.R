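# One-vs-rest ROC-AUC marker detection. A marker is a protein with
# AUC > 0.7 and linear fold change > 1 in its class.

#' One-vs-rest ROC AUC (Mann-Whitney construction)
#'
#' AUC over all cross pairs: a pair scores 1 when the in-class value is
#' larger, 0.5 on a tie. Missing values are excluded; an empty group after
#' exclusion gives NA (undefined).
#'
#' @param values_in,values_out Numeric vectors for the class and the rest.
#' @return AUC in \[0, 1\], or NA.
#' @export
auc_one_vs_rest <- function(values_in, values_out) {
  auc_pair(values_in, values_out)
}

#' Build a sample partition from a metadata variable
#'
#' Convenience for [find_markers()]: one class per level of a metadata
#' column, optionally after excluding regions or restricting to some
#' stages.
#'
#' @param atlas An [lfq_atlas].
#' @param var Metadata column to partition by (e.g. `"stage"`,
#'   `"macro_region"`).
#' @param exclude_regions Regions to drop before partitioning.
#' @param stages Optional stages to keep.
#' @return Tibble with `sample_id`, `class`.
#' @export
class_partition <- function(atlas, var, exclude_regions = NULL,
                            stages = NULL) {
  meta <- atlas$meta
  if (!var %in% names(meta)) {
    abort(paste0("No metadata column `", var, "`."))
  }
  keep <- !(meta$region %in% (exclude_regions %||% character(0)))
  if (!is.null(stages)) keep <- keep & meta$stage %in% stages
  tibble::tibble(sample_id = meta$sample_id[keep],
                 class = as.character(meta[[var]][keep]))
}

#' One-vs-rest marker detection
#'
#' Scores every protein in every class of a sample partition by
#' Mann-Whitney AUC (class vs rest) and linear fold change of detected
#' intensities. Markers are proteins with `auc > auc_cutoff` and
#' `fold_change > fc_cutoff`; they are ranked by AUC descending, ties
#' broken by fold change then protein ID. A protein must be detected in at
#' least `min_detected` class samples to be a candidate; classes with
#' fewer than two samples are skipped with a warning.
#'
#' @param atlas An [lfq_atlas].
#' @param classes Tibble with `sample_id` and `class` covering the samples
#'   to include (see [class_partition()]).
#' @param auc_cutoff AUC threshold (default 0.7).
#' @param fc_cutoff Fold-change threshold (default 1, linear ratio).
#' @param min_detected Minimum detected class samples for a candidate.
#' @return Tibble with `protein_id`, `class`, `auc`, `fold_change`,
#'   `n_detected_in`, `marker`, `rank` (NA for non-markers).
#' @export
find_markers <- function(atlas, classes, auc_cutoff = 0.7, fc_cutoff = 1,
                         min_detected = 2L) {
  stopifnot(all(c("sample_id", "class") %in% names(classes)))
  unknown <- setdiff(classes$sample_id, atlas$meta$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("Unknown sample(s) in partition: ",
                 paste(unknown, collapse = ", ")))
  }
  x <- log2_matrix(atlas)
  lfq <- lfq_matrix(atlas)
  cls <- split(classes$sample_id, classes$class)
  small <- names(cls)[lengths(cls) < 2]
  if (length(small) > 0) {
    warn(paste0("Skipping class(es) with < 2 samples: ",
                paste(small, collapse = ", ")))
    cls <- cls[lengths(cls) >= 2]
  }
  all_samples <- unlist(cls, use.names = FALSE)
  purrr::imap(cls, \(ids, cl) {
    idx_in <- match(ids, colnames(x))
    idx_out <- match(setdiff(all_samples, ids), colnames(x))
    auc <- row_auc(x, idx_in, idx_out)
    fc <- row_fold_change(lfq, idx_in, idx_out)
    n_in <- rowSums(!is.na(x[, idx_in, drop = FALSE]))
    candidate <- n_in >= min_detected
    marker <- candidate & !is.na(auc) & !is.na(fc) &
      auc > auc_cutoff & fc > fc_cutoff
    out <- tibble::tibble(
      protein_id = rownames(x), class = cl, auc = auc, fold_change = fc,
      n_detected_in = n_in, marker = marker
    )
    ranked <- out |>
      filter(.data$marker) |>
      arrange(desc(.data$auc), desc(.data$fold_change), .data$protein_id) |>
      mutate(rank = dplyr::row_number()) |>
      select("protein_id", "rank")
    left_join(out, ranked, by = "protein_id")
  }) |>
    purrr::list_rbind()
}

#' Top-marker expression matrix for heatmap-style output
#'
#' Takes the `top_n` markers per class (by rank) and returns, for each
#' (class, protein), mean z-scored log2 intensity per class, the usual
#' normalised heatmap input.
#'
#' @param markers Output of [find_markers()].
#' @param atlas The [lfq_atlas] the markers were computed on.
#' @param classes The sample partition used.
#' @param top_n Markers kept per class.
#' @return Tibble with `protein_id`, `marker_class`, `class`,
#'   `mean_scaled_log2`.
#' @export
top_marker_matrix <- function(markers, atlas, classes, top_n = 20) {
  top <- markers |>
    filter(.data$marker, .data$rank <= top_n) |>
    select(marker_class = "class", "protein_id")
  x <- log2_matrix(atlas)[unique(top$protein_id), , drop = FALSE]
  z <- t(scale(t(x)))
  cls <- classes |> filter(.data$sample_id %in% colnames(x))
  tibble::as_tibble(z, rownames = "protein_id") |>
    pivot_longer(-"protein_id", names_to = "sample_id",
                 values_to = "scaled_log2") |>
    inner_join(cls, by = "sample_id") |>
    group_by(.data$protein_id, .data$class) |>
    summarise(mean_scaled_log2 = mean(.data$scaled_log2, na.rm = TRUE),
              .groups = "drop") |>
    inner_join(top, by = "protein_id", relationship = "many-to-many")
}
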