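# Six-type RNA/protein fold-change concordance. Fold changes are linear
# postnatal/prenatal ratios; magnitude is |log2 FC| against log2(2) = 1,
# direction is the sign of log2 FC.

#' Paired RNA/protein fold changes per gene
#'
#' Computes the linear protein fold change (postnatal over prenatal stage
#' mean of detected intensities) per gene within a region, and joins the
#' matching RNA fold change. Genes with an undefined prenatal or postnatal
#' protein mean, or an RNA fold change that is missing or non-positive,
#' are excluded with a message.
#'
#' @param atlas An [lfq_atlas].
#' @param rna Tibble with `gene`, `region`, and either `fc_rna` or
#'   `prenatal_mean`/`postnatal_mean` columns.
#' @param ann Annotation tibble mapping `protein_id` to `gene_symbol`.
#' @param region Region code(s) or lineage label defining the samples.
#' @param stages Length-2 vector, prenatal then postnatal (default
#'   `c("F120", "P3")`).
#' @return Tibble with `gene`, `region`, `fc_rna`, `fc_protein`.
#' @export
compute_fc_pair <- function(atlas, rna, ann, region,
                            stages = c("F120", "P3")) {
  stopifnot(length(stages) == 2)
  ann <- as_annotation(ann)
  meta <- atlas$meta
  in_class <- if (all(region %in% meta$lineage)) {
    meta$lineage %in% region
  } else {
    meta$region %in% region
  }
  pre <- in_class & meta$stage == stages[1]
  post <- in_class & meta$stage == stages[2]
  if (!any(pre) || !any(post)) {
    abort("Both stages must be sampled in the chosen region.")
  }
  x <- lfq_matrix(atlas)
  m_pre <- rowMeans(x[, pre, drop = FALSE], na.rm = TRUE)
  m_post <- rowMeans(x[, post, drop = FALSE], na.rm = TRUE)
  prot <- tibble::tibble(
    protein_id = rownames(x),
    fc_protein = unname(m_post / m_pre)
  ) |>
    inner_join(select(ann, "protein_id", gene = "gene_symbol"),
               by = "protein_id") |>
    filter(!is.na(.data$gene))
  if ("fc_rna" %in% names(rna)) {
    rna_fc <- select(rna, "gene", dplyr::any_of("region"), "fc_rna")
  } else {
    stopifnot(all(c("prenatal_mean", "postnatal_mean") %in% names(rna)))
    rna_fc <- rna |>
      mutate(fc_rna = .data$postnatal_mean / .data$prenatal_mean) |>
      select("gene", dplyr::any_of("region"), "fc_rna")
  }
  if ("region" %in% names(rna_fc)) {
    rna_fc <- filter(rna_fc, .data$region %in% !!region) |>
      select(-"region")
  }
  out <- inner_join(prot, rna_fc, by = "gene") |>
    mutate(region = paste(!!region, collapse = "+")) |>
    select("gene", "region", "fc_rna", "fc_protein")
  bad <- !is.finite(out$fc_rna) | !is.finite(out$fc_protein) |
    out$fc_rna <= 0 | out$fc_protein <= 0
  if (any(bad)) {
    inform(paste0("Excluding ", sum(bad),
                  " gene(s) with undefined fold change."))
  }
  out[!bad, ]
}

#' Classify genes into the six RNA/protein concordance types
#'
#' With `lr = log2(fc_rna)`, `lp = log2(fc_protein)`, "large" meaning
#' `|log2 FC| > 1` (|FC| > 2) and "small" `|log2 FC| < 1`:
#' * Type 6 - same direction, both large (concordant large change);
#' * Type 5 - opposite directions, both large (discordant large change);
#' * Type 2 - protein large, RNA small;
#' * Type 3 - RNA large, protein small;
#' * Type 4 - same direction, at least one |FC| exactly on the threshold
#'   with the other large (the residual boundary of the rule system; see
#'   the vignette for why its interior is empty);
#' * Type 1 - everything else (small change on both axes).
#' Every finite positive FC pair receives exactly one type. A gene with
#' either FC exactly 1 has no direction and can never be Type 5 or 6.
#'
#' @param pairs Tibble with `fc_rna` and `fc_protein` (linear ratios).
#' @return The input with an integer `type` column.
#' @export
classify_six_types <- function(pairs) {
  stopifnot(all(c("fc_rna", "fc_protein") %in% names(pairs)))
  if (any(!is.finite(pairs$fc_rna) | !is.finite(pairs$fc_protein) |
            pairs$fc_rna <= 0 | pairs$fc_protein <= 0)) {
    abort("Fold changes must be finite and positive.")
  }
  lr <- log2(pairs$fc_rna)
  lp <- log2(pairs$fc_protein)
  big_r <- abs(lr) > 1
  big_p <- abs(lp) > 1
  small_r <- abs(lr) < 1
  small_p <- abs(lp) < 1
  consistent <- sign(lr) == sign(lp) & sign(lr) != 0
  opposite <- sign(lr) * sign(lp) < 0
  pairs |>
    mutate(type = dplyr::case_when(
      consistent & big_r & big_p ~ 6L,
      opposite & big_r & big_p ~ 5L,
      big_p & small_r ~ 2L,
      big_r & small_p ~ 3L,
      consistent & (big_r | big_p) ~ 4L,
      TRUE ~ 1L
    ))
}

#' Percentage of genes per concordance type
#'
#' @param typed Output of [classify_six_types()] (optionally grouped by a
#'   `region` column).
#' @return Tibble with `region` (if present), `type` (1..6) and `percent`;
#'   percentages sum to 100 within each region.
#' @export
type_percentages <- function(typed) {
  by_region <- "region" %in% names(typed)
  grouped <- if (by_region) group_by(typed, .data$region) else typed
  counts <- grouped |>
    dplyr::count(type = factor(.data$type, levels = 1:6), .drop = FALSE) |>
    mutate(percent = 100 * .data$n / sum(.data$n),
           type = as.integer(as.character(.data$type)))
  ungroup(counts)
}

#' Per-type over-representation analysis
#'
#' Runs [ora()] for the genes of each concordance type against the shared
#' gene universe (all classified genes). Empty types are skipped.
#'
#' @param typed Output of [classify_six_types()] with a `gene` column.
#' @param sets Named list of gene sets.
#' @param ... Passed to [ora()].
#' @return Tibble of ORA results with a `type` column.
#' @export
type_enrichment <- function(typed, sets, ...) {
  stopifnot("gene" %in% names(typed))
  universe <- unique(typed$gene)
  purrr::map(sort(unique(typed$type)), \(ty) {
    genes <- unique(typed$gene[typed$type == ty])
    if (length(genes) == 0) {
      return(NULL)
    }
    ora(genes, sets, universe, ...) |>
      mutate(type = ty, .before = 1)
  }) |>
    purrr::list_rbind()
}
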