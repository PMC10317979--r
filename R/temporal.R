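# Protein emergence between adjacent stages, per-day rates of change, and
# gene-set abundance trajectories.

adjacent_transition <- function(transition) {
  stages <- stage_levels()
  parts <- strsplit(transition, "->", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    abort("Transition must look like \"F50->F90\".")
  }
  i <- match(parts, stages)
  if (anyNA(i) || i[2] != i[1] + 1) {
    abort(paste0("Transition ", transition,
                 " is not adjacent in stage order."))
  }
  parts
}

#' Call newly emerging proteins between adjacent stages
#'
#' Within a region class, a protein is "new" at the later stage when (i)
#' its LFQ intensity is zero in every sample of the class at all earlier
#' stages, (ii) it is detected at the later stage, and (iii) the
#' later-vs-earlier comparison is significantly up (p < `alpha`, fold
#' change > `fc_cutoff`). Because the earlier group is all zeros, its
#' log2 values are undefined; the test places the earlier group at the
#' detection floor (the smallest positive intensity in the dataset), the
#' package's resolution of an otherwise undefined comparison. Proteins
#' detected at the earlier stage are "continuing"; all others (never
#' detected, or appearing without passing the significance gate) are
#' "absent".
#'
#' @param atlas An [lfq_atlas].
#' @param region_class Regions (or a lineage label) defining the sample
#'   class; matched against `lineage` when it names one, else `region`.
#' @param transition Adjacent transition, e.g. `"F120->P3"`.
#' @param alpha Significance level on the raw p.
#' @param fc_cutoff Linear fold-change threshold.
#' @param min_n Minimum detected later-stage values for the test.
#' @return Tibble with `protein_id`, `region_class`, `transition`,
#'   `status`, `p`, `fold_change`, `detection_floor`.
#' @export
call_new_proteins <- function(atlas, region_class, transition,
                              alpha = 0.05, fc_cutoff = 1, min_n = 2L) {
  stages <- adjacent_transition(transition)
  meta <- atlas$meta
  in_class <- if (all(region_class %in% meta$lineage)) {
    meta$lineage %in% region_class
  } else {
    meta$region %in% region_class
  }
  earlier_all <- in_class &
    match(meta$stage, stage_levels()) < match(stages[2], stage_levels())
  earlier_adj <- in_class & meta$stage == stages[1]
  later <- in_class & meta$stage == stages[2]
  if (!any(earlier_adj) || !any(later)) {
    abort("Both stages of the transition must be sampled for the class.")
  }
  lfq <- atlas$lfq
  floor_val <- min(lfq[lfq > 0])
  zero_before <- rowSums(lfq[, earlier_all, drop = FALSE] > 0) == 0
  detected_earlier <- rowSums(lfq[, earlier_adj, drop = FALSE] > 0) > 0
  n_later <- rowSums(lfq[, later, drop = FALSE] > 0)
  detected_later <- n_later > 0

  x_later <- ifelse(lfq[, later, drop = FALSE] > 0,
                    log2(lfq[, later, drop = FALSE]), NA_real_)
  n_e <- sum(earlier_adj)
  st <- row_stats(x_later)
  # pooled t against a constant earlier group at the detection floor
  df <- st$n + n_e - 2
  sp2 <- (st$n - 1) * st$var / df
  se <- sqrt(sp2 * (1 / st$n + 1 / n_e))
  tt <- (st$mean - log2(floor_val)) / se
  p <- 2 * pt(-abs(tt), df)
  zero_var <- !is.na(sp2) & sp2 == 0
  p[zero_var & st$mean != log2(floor_val)] <- 0
  p[zero_var & st$mean == log2(floor_val)] <- 1
  p[st$n < min_n] <- NA_real_
  fc <- 2^st$mean / floor_val
  fc[st$n == 0] <- NA_real_

  status <- dplyr::case_when(
    detected_earlier ~ "continuing",
    zero_before & detected_later & !is.na(p) & p < alpha &
      !is.na(fc) & fc > fc_cutoff ~ "new",
    TRUE ~ "absent"
  )
  tibble::tibble(
    protein_id = rownames(lfq),
    region_class = paste(region_class, collapse = "+"),
    transition = transition,
    status = status,
    p = ifelse(detected_earlier, NA_real_, p),
    fold_change = ifelse(detected_earlier, NA_real_, fc),
    detection_floor = floor_val
  )
}

#' Per-day rate of abundance change
#'
#' For each protein of a set, (mean log2 at the later stage minus mean
#' log2 at the earlier stage) divided by the number of days between the
#' stages, over the samples of a region class.
#'
#' @inheritParams call_new_proteins
#' @param proteins Protein IDs of the set (default: all).
#' @param days Named day table (default [stage_days()]).
#' @return Tibble with `protein_id`, `region_class`, `transition`,
#'   `rate_per_day`, and the set mean as attribute-free summary column
#'   `set_mean_rate`.
#' @export
rate_of_change <- function(atlas, proteins = NULL, region_class,
                           transition, days = stage_days()) {
  stages <- adjacent_transition(transition)
  gap <- unname(days[stages[2]] - days[stages[1]])
  if (is.na(gap) || gap == 0) {
    abort("Zero or undefined day gap for the transition.")
  }
  meta <- atlas$meta
  in_class <- if (all(region_class %in% meta$lineage)) {
    meta$lineage %in% region_class
  } else {
    meta$region %in% region_class
  }
  x <- log2_matrix(atlas)
  if (!is.null(proteins)) x <- x[proteins, , drop = FALSE]
  m1 <- rowMeans(x[, in_class & meta$stage == stages[1], drop = FALSE],
                 na.rm = TRUE)
  m2 <- rowMeans(x[, in_class & meta$stage == stages[2], drop = FALSE],
                 na.rm = TRUE)
  rate <- unname((m2 - m1) / gap)
  tibble::tibble(
    protein_id = rownames(x),
    region_class = paste(region_class, collapse = "+"),
    transition = transition,
    rate_per_day = rate,
    set_mean_rate = mean(rate, na.rm = TRUE)
  )
}

#' Gene-set abundance trajectories over stages
#'
#' For each gene set, sums the member-protein LFQ intensities per sample,
#' averages the per-sample sums within each stage (mean, sd), and flags
#' adjacent-stage segments whose per-sample sums differ significantly
#' (two-sided pooled-variance t-test): the solid/dashed trend distinction.
#' Sets with no mapped protein are skipped with a warning.
#'
#' @param atlas An [lfq_atlas].
#' @param sets Named list of gene symbol vectors.
#' @param ann Annotation tibble mapping `protein_id` to `gene_symbol`.
#' @param regions Optional region/lineage restriction (as in
#'   [call_new_proteins()]).
#' @param alpha Significance level for segment tests.
#' @return List with `trajectory` (tibble: `set_name`, `stage`,
#'   `mean_abundance`, `sd_abundance`, `n_samples`) and `segments`
#'   (adjacent-stage test results with `significant`).
#' @export
set_trajectory <- function(atlas, sets, ann, regions = NULL,
                           alpha = 0.05) {
  ann <- as_annotation(ann)
  meta <- atlas$meta
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(regions)) {
    keep <- if (all(regions %in% meta$lineage)) {
      meta$lineage %in% regions
    } else {
      meta$region %in% regions
    }
  }
  lfq <- atlas$lfq[, keep, drop = FALSE]
  meta <- meta[keep, ]
  gene_to_protein <- ann |>
    filter(!is.na(.data$gene_symbol)) |>
    select("protein_id", "gene_symbol")
  per_set <- purrr::imap(sets, \(genes, nm) {
    ids <- gene_to_protein$protein_id[gene_to_protein$gene_symbol %in% genes]
    ids <- intersect(ids, rownames(lfq))
    if (length(ids) == 0) {
      warn(paste0("Gene set ", nm, " maps to no protein; skipped."))
      return(NULL)
    }
    tibble::tibble(
      set_name = nm,
      sample_id = colnames(lfq),
      stage = meta$stage,
      summed = unname(colSums(lfq[ids, , drop = FALSE]))
    )
  }) |>
    purrr::list_rbind()
  if (is.null(per_set) || nrow(per_set) == 0) {
    abort("No gene set mapped to any protein.")
  }
  trajectory <- per_set |>
    group_by(.data$set_name, .data$stage) |>
    summarise(mean_abundance = mean(.data$summed),
              sd_abundance = sd(.data$summed),
              n_samples = dplyr::n(), .groups = "drop") |>
    mutate(stage = stage_factor(.data$stage)) |>
    arrange(.data$set_name, .data$stage)
  segments <- per_set |>
    mutate(category = .data$set_name, group = "all",
           percent = .data$summed) |>
    adjacent_stage_trend_test(value = "percent", category = "category",
                              group = "group", alpha = alpha) |>
    select(set_name = "category", "stage_from", "stage_to", "t", "p",
           "significant", "any_significant")
  list(trajectory = trajectory, segments = segments)
}
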