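# Intensity-weighted composition: the percentage of a sample's total LFQ
# intensity carried by proteins of a subcellular localization or protein
# family. Multi-label proteins count fully toward each of their labels;
# unannotated proteins stay in the denominator.

#' Composition percentages per sample and category
#'
#' For each sample and category label, sums the LFQ intensities of member
#' proteins and divides by the sample's total intensity (x100). Categories
#' without member proteins yield exactly 0%.
#'
#' @param atlas An [lfq_atlas].
#' @param ann Annotation tibble (see [as_annotation()]).
#' @param scheme `"localization"` or `"family"`.
#' @return Tibble with `sample_id`, `category`, `percent`, joined with the
#'   sample metadata.
#' @export
composition_percent <- function(atlas, ann,
                                scheme = c("localization", "family")) {
  scheme <- match.arg(scheme)
  ann <- as_annotation(ann)
  total <- colSums(atlas$lfq)
  if (any(total == 0)) {
    abort(paste0("Sample(s) with zero total intensity: ",
                 paste(colnames(atlas$lfq)[total == 0], collapse = ", ")))
  }
  membership <- ann |>
    select("protein_id", category = dplyr::all_of(scheme)) |>
    tidyr::unnest("category") |>
    filter(.data$protein_id %in% rownames(atlas$lfq))
  categories <- sort(unique(membership$category))
  per_cat <- purrr::map(categories, \(cat) {
    ids <- membership$protein_id[membership$category == cat]
    tibble::tibble(
      sample_id = colnames(atlas$lfq),
      category = cat,
      percent = unname(100 * colSums(atlas$lfq[ids, , drop = FALSE]) /
                         total)
    )
  }) |>
    purrr::list_rbind()
  left_join(per_cat, atlas$meta, by = "sample_id")
}

#' Adjacent-stage significance of composition (or other per-sample) trends
#'
#' Two-sided pooled-variance t-test of a per-sample quantity between each
#' pair of adjacent stages, within each group (e.g. region): the
#' solid-vs-dashed line distinction of a trend chart. Segments missing a
#' stage are skipped with a message. Tests are uncorrected per segment by
#' default; set `p_adjust` to apply a correction across segments within
#' each group and category.
#'
#' @param profiles Tibble with `stage`, a value column, a category column
#'   and a grouping column (e.g. output of [composition_percent()]).
#' @param value Name of the value column (default `"percent"`).
#' @param category Name of the category column (default `"category"`).
#' @param group Name of the grouping column (default `"region"`).
#' @param alpha Significance level.
#' @param p_adjust Method passed to [stats::p.adjust()] (default
#'   `"none"`).
#' @return Tibble with one row per (group, category, adjacent segment):
#'   `stage_from`, `stage_to`, `t`, `p`, `significant`, plus
#'   `any_significant` per (group, category).
#' @export
adjacent_stage_trend_test <- function(profiles, value = "percent",
                                      category = "category",
                                      group = "region", alpha = 0.05,
                                      p_adjust = "none") {
  stopifnot(all(c("stage", value, category, group) %in% names(profiles)))
  df <- profiles |>
    select(stage = "stage",
           value = dplyr::all_of(value),
           category = dplyr::all_of(category),
           group = dplyr::all_of(group))
  stages <- intersect(stage_levels(), unique(df$stage))
  segments <- tibble::tibble(stage_from = stages[-length(stages)],
                             stage_to = stages[-1])
  res <- df |>
    tidyr::nest(data = c("stage", "value")) |>
    dplyr::cross_join(segments) |>
    mutate(fit = purrr::pmap(
      list(.data$data, .data$stage_from, .data$stage_to),
      \(d, s1, s2) {
        a <- d$value[d$stage == s1]
        b <- d$value[d$stage == s2]
        if (length(a) < 2 || length(b) < 2) {
          inform(paste0("Skipping segment ", s1, "->", s2,
                        ": fewer than 2 samples on one side."))
          return(tibble::tibble(t = NA_real_, p = NA_real_))
        }
        ht <- pooled_t2(a, b)
        tibble::tibble(t = ht$t, p = ht$p)
      }
    )) |>
    select(-"data") |>
    tidyr::unnest("fit") |>
    group_by(.data$group, .data$category) |>
    mutate(
      p_adj = p.adjust(.data$p, method = p_adjust),
      significant = !is.na(.data$p_adj) & .data$p_adj < alpha,
      any_significant = any(.data$significant)
    ) |>
    ungroup()
  res
}
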