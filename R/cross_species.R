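# Cross-species ortholog correlation analysis and conservation classes.
# Per 1:1 ortholog, Pearson correlations of 5-region abundance profiles
# under the three pairwise species comparisons; interval rules assign
# human-specific / primate-specific / conserved labels.

panel_wide <- function(panel) {
  needed <- c("ortholog_id", "species", "region", "abundance")
  missing <- setdiff(needed, names(panel))
  if (length(missing) > 0) {
    abort(paste0("Panel lacks column(s): ", paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(panel$species), panel_species())
  if (length(bad) > 0) {
    abort(paste0("Unknown species: ", paste(bad, collapse = ", ")))
  }
  counts <- panel |>
    dplyr::count(.data$ortholog_id, .data$species)
  if (any(counts$n != length(panel_regions())) ||
      !all(table(counts$ortholog_id) == length(panel_species()))) {
    abort("Each ortholog needs all three species over the five regions.")
  }
  panel
}

pearson_or_na <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) {
    return(NA_real_)
  }
  cor(a, b)
}

#' Pairwise cross-species correlations per ortholog
#'
#' Pearson correlation of the 5-region abundance vectors for each ortholog
#' under monkey-human, mouse-human, and monkey-mouse comparisons. Constant
#' vectors give NA (undefined) correlations.
#'
#' @param panel Long tibble with `ortholog_id`, `species`
#'   (human/monkey/mouse), `region`, `abundance`; every ortholog must have
#'   all three species over the five shared regions.
#' @return Tibble with `ortholog_id`, `r_monkey_human`, `r_mouse_human`,
#'   `r_monkey_mouse`.
#' @export
ortholog_correlations <- function(panel) {
  panel <- panel_wide(panel)
  region_order <- panel_regions()
  wide <- panel |>
    arrange(.data$ortholog_id,
            match(.data$region, region_order)) |>
    tidyr::nest(data = c("species", "region", "abundance"))
  res <- purrr::map(wide$data, \(d) {
    v <- split(d$abundance, d$species)
    tibble::tibble(
      r_monkey_human = pearson_or_na(v$monkey, v$human),
      r_mouse_human = pearson_or_na(v$mouse, v$human),
      r_monkey_mouse = pearson_or_na(v$monkey, v$mouse)
    )
  }) |>
    purrr::list_rbind()
  tibble::tibble(ortholog_id = wide$ortholog_id) |>
    dplyr::bind_cols(res)
}

in_interval <- function(x, lo, hi) !is.na(x) & x >= lo & x <= hi

#' Conservation class from pairwise correlations
#'
#' Interval rules (closed endpoints), applied in precedence order:
#' human-specific when both monkey-human and mouse-human correlations lie
#' in \[-1, -0.5\]; else conserved when monkey-human and monkey-mouse both
#' lie in \[0.75, 1\]; else primate-specific when monkey-human lies in
#' \[0.75, 1\] but neither mouse-human nor monkey-mouse does; anything
#' else (including undefined correlations) is unclassified. The rules are
#' exhaustive and mutually exclusive, so every ortholog gets exactly one
#' label.
#'
#' @param correlations Output of [ortholog_correlations()].
#' @return The input with a `class` column added.
#' @export
classify_conservation <- function(correlations) {
  mh <- correlations$r_monkey_human
  mouse_h <- correlations$r_mouse_human
  mm <- correlations$r_monkey_mouse
  correlations |>
    mutate(class = dplyr::case_when(
      in_interval(mh, -1, -0.5) & in_interval(mouse_h, -1, -0.5) ~
        "human_specific",
      in_interval(mh, 0.75, 1) & in_interval(mm, 0.75, 1) ~ "conserved",
      in_interval(mh, 0.75, 1) & !in_interval(mouse_h, 0.75, 1) &
        !in_interval(mm, 0.75, 1) ~ "primate_specific",
      TRUE ~ "unclassified"
    ))
}

#' Distribution of ortholog correlations
#'
#' Fixed-width histogram over \[-1, 1\] (default 8 bins of width 0.25),
#' cumulative percentages, per-comparison medians, and two-sample
#' Kolmogorov-Smirnov tests between the comparisons' correlation
#' distributions.
#'
#' @param correlations Output of [ortholog_correlations()].
#' @param n_bins Number of equal-width bins over \[-1, 1\].
#' @return List with `histogram` (`comparison`, `bin`, `bin_mid`,
#'   `n`, `percent`, `cumulative_percent`), `medians`, and `ks`
#'   (pairwise D and p).
#' @export
correlation_distribution <- function(correlations, n_bins = 8) {
  long <- correlations |>
    pivot_longer(dplyr::starts_with("r_"), names_to = "comparison",
                 values_to = "r") |>
    mutate(comparison = sub("^r_", "", .data$comparison)) |>
    filter(!is.na(.data$r))
  if (any(table(long$comparison) < 2)) {
    abort("Need at least 2 defined correlations per comparison.")
  }
  breaks <- seq(-1, 1, length.out = n_bins + 1)
  histogram <- long |>
    mutate(bin = cut(.data$r, breaks = breaks, include.lowest = TRUE)) |>
    group_by(.data$comparison, .data$bin, .drop = FALSE) |>
    summarise(n = dplyr::n(), .groups = "drop_last") |>
    mutate(
      percent = 100 * .data$n / sum(.data$n),
      cumulative_percent = cumsum(.data$percent)
    ) |>
    ungroup() |>
    mutate(bin_mid = (breaks[as.integer(.data$bin)] +
                        breaks[as.integer(.data$bin) + 1]) / 2,
           .after = "bin")
  medians <- long |>
    group_by(.data$comparison) |>
    summarise(median_r = median(.data$r), n = dplyr::n(), .groups = "drop")
  comps <- unique(long$comparison)
  ks <- combn(comps, 2, simplify = FALSE) |>
    purrr::map(\(pr) {
      a <- long$r[long$comparison == pr[1]]
      b <- long$r[long$comparison == pr[2]]
      ht <- suppressWarnings(ks.test(a, b))
      tibble::tibble(comparison_a = pr[1], comparison_b = pr[2],
                     D = unname(ht$statistic), p = ht$p.value)
    }) |>
    purrr::list_rbind()
  list(histogram = histogram, medians = medians, ks = ks)
}

#' Per-protein correlations within the most abundant families
#'
#' Ranks protein families by total panel abundance, keeps the `top_k`
#' most abundant, and reports each member ortholog's three pairwise
#' correlations in long, heatmap-ready form.
#'
#' @param panel Long ortholog panel (see [ortholog_correlations()]).
#' @param ann Tibble mapping `ortholog_id` to `family`.
#' @param top_k Number of families to keep (all when fewer exist).
#' @return Tibble with `family`, `family_rank`, `ortholog_id`,
#'   `comparison`, `r`.
#' @export
family_correlations <- function(panel, ann, top_k = 5) {
  stopifnot(all(c("ortholog_id", "family") %in% names(ann)))
  cors <- ortholog_correlations(panel) |>
    inner_join(ann, by = "ortholog_id")
  fam_rank <- panel |>
    inner_join(ann, by = "ortholog_id") |>
    group_by(.data$family) |>
    summarise(total_abundance = sum(.data$abundance), .groups = "drop") |>
    arrange(desc(.data$total_abundance)) |>
    mutate(family_rank = dplyr::row_number()) |>
    filter(.data$family_rank <= top_k)
  cors |>
    inner_join(fam_rank, by = "family") |>
    pivot_longer(dplyr::starts_with("r_"), names_to = "comparison",
                 values_to = "r") |>
    mutate(comparison = sub("^r_", "", .data$comparison)) |>
    select("family", "family_rank", "ortholog_id", "comparison", "r") |>
    arrange(.data$family_rank, .data$ortholog_id, .data$comparison)
}
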