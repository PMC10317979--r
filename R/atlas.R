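# The lfq_atlas container: a proteins x samples LFQ intensity matrix plus
# per-sample metadata. An intensity of exactly 0 means the protein was not
# detected in that sample; detected entries are strictly positive.

#' Construct an LFQ atlas
#'
#' Bundles a proteins-by-samples matrix of label-free quantification (LFQ)
#' intensities with its sample metadata. `lfq == 0` encodes non-detection;
#' all analyses treat undetected entries as missing (never as true zeros),
#' and presence/emergence logic treats them as absent.
#'
#' @param lfq Numeric matrix of non-negative intensities; rownames are
#'   protein IDs, colnames are sample IDs.
#' @param meta Data frame of sample metadata with at least `sample_id`,
#'   `stage` and `region`. Missing `macro_region`, `lineage` or `day`
#'   columns are derived from `region`/`stage` defaults; `replicate_kind`
#'   defaults to "biological".
#' @return An object of class `lfq_atlas`.
#' @export
lfq_atlas <- function(lfq, meta) {
  if (!is.matrix(lfq) || !is.numeric(lfq)) {
    abort("`lfq` must be a numeric matrix.")
  }
  if (any(is.na(lfq))) {
    abort("`lfq` must not contain NA; use 0 for undetected entries.")
  }
  if (any(lfq < 0)) {
    abort("Negative LFQ intensity found; intensities must be >= 0.")
  }
  if (is.null(rownames(lfq))) {
    abort("`lfq` must have protein IDs as rownames.")
  }
  meta <- tibble::as_tibble(meta)
  required <- c("sample_id", "stage", "region")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("`meta` lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  assert_stages_known(meta$stage)
  if (is.null(colnames(lfq))) {
    abort("`lfq` must have sample IDs as colnames.")
  }
  unmatched <- setdiff(colnames(lfq), meta$sample_id)
  if (length(unmatched) > 0) {
    abort(paste0("Sample(s) in matrix but not metadata: ",
                 paste(unmatched, collapse = ", ")))
  }
  unmatched <- setdiff(meta$sample_id, colnames(lfq))
  if (length(unmatched) > 0) {
    abort(paste0("Sample(s) in metadata but not matrix: ",
                 paste(unmatched, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id) > 0) {
    abort("Duplicated sample_id in metadata.")
  }
  lfq <- lfq[, meta$sample_id, drop = FALSE]
  if (!"macro_region" %in% names(meta)) {
    meta$macro_region <- macro_region_of(meta$region)
  }
  if (!"lineage" %in% names(meta)) {
    meta$lineage <- lineage_of(meta$region)
  }
  if (!"day" %in% names(meta)) {
    meta$day <- unname(stage_days()[meta$stage])
  }
  if (!"animal_id" %in% names(meta)) {
    meta$animal_id <- NA_character_
  }
  if (!"replicate_kind" %in% names(meta)) {
    meta$replicate_kind <- "biological"
  }
  structure(list(lfq = lfq, meta = meta), class = "lfq_atlas")
}

#' @export
print.lfq_atlas <- function(x, ...) {
  cat("<lfq_atlas> ", nrow(x$lfq), " proteins x ", ncol(x$lfq), " samples\n",
      sep = "")
  det <- mean(x$lfq > 0)
  cat("  detected entries: ", sprintf("%.1f%%", 100 * det), "\n", sep = "")
  tab <- table(x$meta$stage)[intersect(stage_levels(), unique(x$meta$stage))]
  cat("  samples per stage: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.lfq_atlas <- function(x) dim(x$lfq)

#' Long-format view of an atlas
#'
#' @param x An `lfq_atlas`.
#' @param ... Unused.
#' @return Tibble with one row per (protein, sample): `protein_id`,
#'   `sample_id`, `lfq`, `detected`, `log2_lfq` (NA where undetected), and
#'   the sample metadata columns.
#' @export
as_tibble.lfq_atlas <- function(x, ...) {
  long <- tibble::tibble(
    protein_id = rep(rownames(x$lfq), times = ncol(x$lfq)),
    sample_id = rep(colnames(x$lfq), each = nrow(x$lfq)),
    lfq = as.vector(x$lfq)
  ) |>
    mutate(
      detected = .data$lfq > 0,
      log2_lfq = ifelse(.data$detected, log2(.data$lfq), NA_real_)
    )
  left_join(long, x$meta, by = "sample_id")
}

#' Protein IDs of an atlas
#' @param atlas An `lfq_atlas`.
#' @return Character vector.
#' @export
atlas_proteins <- function(atlas) rownames(atlas$lfq)

#' Sample metadata of an atlas
#' @param atlas An `lfq_atlas`.
#' @return Tibble of per-sample metadata.
#' @export
atlas_meta <- function(atlas) atlas$meta

#' Detection mask
#'
#' @param atlas An `lfq_atlas`.
#' @return Logical matrix, TRUE where the protein was detected (LFQ > 0).
#' @export
detection_mask <- function(atlas) atlas$lfq > 0

#' Log2 intensity matrix
#'
#' @param atlas An `lfq_atlas`.
#' @return Numeric matrix of log2(LFQ) with NA at undetected entries.
#' @export
log2_matrix <- function(atlas) {
  x <- atlas$lfq
  out <- ifelse(x > 0, log2(x), NA_real_)
  dimnames(out) <- dimnames(x)
  out
}

#' Raw intensity matrix with undetected entries as NA
#'
#' @param atlas An `lfq_atlas`.
#' @return Numeric matrix; 0 entries replaced by NA.
#' @export
lfq_matrix <- function(atlas) {
  x <- atlas$lfq
  x[x == 0] <- NA_real_
  x
}

#' Subset an atlas by samples
#'
#' @param atlas An `lfq_atlas`.
#' @param sample_ids Character vector of samples to keep, in this order.
#' @return An `lfq_atlas` restricted to those samples.
#' @export
atlas_subset <- function(atlas, sample_ids) {
  missing <- setdiff(sample_ids, atlas$meta$sample_id)
  if (length(missing) > 0) {
    abort(paste0("Unknown sample(s): ", paste(missing, collapse = ", ")))
  }
  meta <- atlas$meta[match(sample_ids, atlas$meta$sample_id), ]
  lfq_atlas(atlas$lfq[, sample_ids, drop = FALSE], meta)
}

#' Group-mean fold change of LFQ intensity
#'
#' Linear-scale ratio of group means over detected entries only: undetected
#' (zero) intensities are excluded from each mean, never averaged in as
#' zeros. The ratio is undefined (NA) for a protein with no detected value
#' in either group.
#'
#' @param atlas An `lfq_atlas`.
#' @param group_a,group_b Character vectors of sample IDs (numerator /
#'   denominator groups).
#' @param proteins Optional character vector restricting the result.
#' @return Tibble with `protein_id`, `mean_a`, `mean_b`, `n_detected_a`,
#'   `n_detected_b`, `fold_change` (NA when undefined).
#' @export
fold_change <- function(atlas, group_a, group_b, proteins = NULL) {
  x <- lfq_matrix(atlas)
  if (!is.null(proteins)) {
    x <- x[proteins, , drop = FALSE]
  }
  ia <- match(group_a, colnames(x))
  ib <- match(group_b, colnames(x))
  if (anyNA(ia) || anyNA(ib)) {
    abort("fold_change: unknown sample ID in group_a/group_b.")
  }
  ma <- unname(rowMeans(x[, ia, drop = FALSE], na.rm = TRUE))
  mb <- unname(rowMeans(x[, ib, drop = FALSE], na.rm = TRUE))
  na <- unname(rowSums(!is.na(x[, ia, drop = FALSE])))
  nb <- unname(rowSums(!is.na(x[, ib, drop = FALSE])))
  fc <- ifelse(na > 0 & nb > 0, ma / mb, NA_real_)
  tibble::tibble(
    protein_id = rownames(x),
    mean_a = ifelse(na > 0, ma, NA_real_),
    mean_b = ifelse(nb > 0, mb, NA_real_),
    n_detected_a = na,
    n_detected_b = nb,
    fold_change = fc
  )
}
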