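# End-to-end orchestration: simulate -> DEP -> markers -> composition ->
# dynamics -> events -> clustering -> enrichment -> cross-species ->
# concordance, written as a deterministic TSV bundle with a run manifest.

#' Run configuration
#'
#' Central configuration for [full_run()]: thresholds (defaulting to the
#' standard cutoffs: alpha 0.05, AUC 0.7, fold-change 1 for markers and 2
#' for concordance magnitude), the stage-day table, generator settings and
#' the root seed from which every source of randomness flows. Unknown keys
#' are rejected.
#'
#' @param seed Root integer seed.
#' @param alpha Significance level for t-tests.
#' @param auc_cutoff Marker AUC threshold.
#' @param fc_cutoff Marker fold-change threshold (linear).
#' @param q_cutoff ORA BH-adjusted cutoff.
#' @param dep_grouping Grouping for the stage/region DEP summary.
#' @param n_clusters Trend clusters.
#' @param fuzzifier Fuzzy c-means fuzziness exponent.
#' @param stage_day Named day table.
#' @param sim Overrides passed to [sim_config()] (list).
#' @param ortholog Overrides passed to [simulate_ortholog_panel()] (list).
#' @param concordance Overrides passed to
#'   [simulate_rna_protein_pairs()] (list).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, alpha = 0.05, auc_cutoff = 0.7,
                       fc_cutoff = 1, q_cutoff = 0.05,
                       dep_grouping = "all_excl_cb", n_clusters = 4,
                       fuzzifier = 2, stage_day = stage_days(),
                       sim = list(), ortholog = list(),
                       concordance = list()) {
  cfg <- as.list(environment())
  for (nm in c("sim", "ortholog", "concordance")) {
    if (!is.list(cfg[[nm]])) abort(paste0("`", nm, "` must be a list."))
  }
  allowed_sim <- names(formals(sim_config))
  bad <- setdiff(names(cfg$sim), allowed_sim)
  if (length(bad) > 0) {
    abort(paste0("Unknown sim key(s): ", paste(bad, collapse = ", ")))
  }
  structure(cfg, class = "run_config")
}

write_output_tsv <- function(x, path, produced_by, units) {
  writeLines(paste0("# produced_by: ", produced_by, " | units: ", units),
             path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Run the full pipeline on simulated data
#'
#' Generates an atlas, ortholog panel and RNA/protein pairs from the
#' configured seed, runs every analysis stage, and writes one TSV per
#' result (each with a header comment naming the producing operation and
#' units) plus a manifest. Identical config and seed produce a
#' byte-identical bundle. Any stage failure aborts with the stage named.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list of the in-memory results.
#' @export
full_run <- function(config = run_config(), outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(outdir, ...)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("full_run failed at stage `", name, "`: ",
                   conditionMessage(e)))
    })
  }

  sim_args <- utils::modifyList(list(seed = config$seed), config$sim)
  sim <- step("simulate", do.call(sim_config, sim_args) |> simulate_atlas())
  atlas <- sim$atlas
  write_abundance(atlas, out("abundance_matrix.tsv"), out("sample_meta.tsv"))
  write_output_tsv(sim$truth, out("truth_ledger.tsv"),
                   "simulate_atlas", "log2 shift")
  write_annotation(sim$annotation, out("annotation.tsv"))
  write_gmt(sim$gene_sets, out("gene_sets.gmt"))

  dep <- step("dep", {
    per_stage <- purrr::map(
      intersect(stage_levels(), unique(atlas$meta$stage)),
      \(s) dep_region_vs_rest(atlas, s, alpha = config$alpha)
    ) |>
      purrr::list_rbind()
    summary <- dep_summary(atlas, grouping = config$dep_grouping,
                           alpha = config$alpha)
    counts <- per_stage |>
      filter(.data$dep) |>
      dplyr::count(.data$stage, .data$region, name = "n_deps")
    list(per_stage = per_stage, summary = summary, counts = counts)
  })
  write_output_tsv(dep$counts, out("dep_counts.tsv"),
                   "dep_region_vs_rest", "DEP count (adj p < alpha)")
  write_output_tsv(select(dep$summary, -"proteins"), out("dep_summary.tsv"),
                   "dep_summary", "protein count")

  markers <- step("markers", {
    cls <- class_partition(atlas, "stage", exclude_regions = "CB")
    stage_markers <- find_markers(atlas, cls,
                                  auc_cutoff = config$auc_cutoff,
                                  fc_cutoff = config$fc_cutoff)
    cb_cls <- atlas$meta |>
      mutate(class = ifelse(.data$region == "CB", "CB", "other")) |>
      select("sample_id", "class")
    cb_markers <- find_markers(atlas, cb_cls,
                               auc_cutoff = config$auc_cutoff,
                               fc_cutoff = config$fc_cutoff) |>
      filter(.data$class == "CB")
    list(stage = stage_markers, cb = cb_markers)
  })
  write_output_tsv(filter(markers$stage, .data$marker),
                   out("stage_markers.tsv"), "find_markers",
                   "AUC, linear fold change")
  write_output_tsv(filter(markers$cb, .data$marker), out("cb_markers.tsv"),
                   "find_markers", "AUC, linear fold change")

  composition <- step("composition", {
    prof <- composition_percent(atlas, sim$annotation, "localization")
    segs <- adjacent_stage_trend_test(prof, group = "macro_region",
                                      alpha = config$alpha)
    list(profiles = prof, segments = segs)
  })
  write_output_tsv(
    select(composition$profiles, "sample_id", "category", "percent"),
    out("composition_localization.tsv"), "composition_percent",
    "% of total LFQ intensity"
  )
  write_output_tsv(composition$segments, out("composition_segments.tsv"),
                   "adjacent_stage_trend_test", "t, p")

  dynamics <- step("dynamics", {
    curve <- interregional_curve(atlas)
    dist_cb <- purrr::map(
      intersect(stage_levels(), unique(atlas$meta$stage)),
      \(s) cb_distance(atlas, s)
    ) |>
      purrr::list_rbind()
    corr <- stage_correlation(atlas)
    pca <- atlas_pca(atlas)
    list(curve = curve, dist_cb = dist_cb, corr = corr, pca = pca)
  })
  write_output_tsv(dynamics$curve, out("interregional_curve.tsv"),
                   "inter_regional_difference", "mean |log2 difference|")
  write_output_tsv(dynamics$dist_cb, out("cb_distances.tsv"),
                   "cb_distance", "Euclidean distance of mean log2 profiles")
  write_output_tsv(dynamics$corr, out("stage_correlations.tsv"),
                   "stage_correlation", "Pearson r")
  write_output_tsv(tidy(dynamics$pca), out("pca_scores.tsv"),
                   "atlas_pca", "PC scores (log2 scale)")

  events <- step("events", {
    transitions <- paste(stage_levels()[-4], stage_levels()[-1],
                         sep = "->")
    lineages <- c("PFC", "TL", "PL", "V1")
    calls <- tidyr::crossing(lineage = lineages,
                             transition = transitions) |>
      purrr::pmap(\(lineage, transition) {
        call_new_proteins(atlas, lineage, transition,
                          alpha = config$alpha,
                          fc_cutoff = config$fc_cutoff)
      }) |>
      purrr::list_rbind()
    new_counts <- calls |>
      filter(.data$status == "new") |>
      dplyr::count(.data$region_class, .data$transition, name = "n_new")
    rates <- tidyr::crossing(lineage = lineages,
                             transition = transitions) |>
      purrr::pmap(\(lineage, transition) {
        rate_of_change(atlas, region_class = lineage,
                       transition = transition,
                       days = config$stage_day) |>
          distinct(.data$region_class, .data$transition,
                   .data$set_mean_rate)
      }) |>
      purrr::list_rbind()
    traj <- set_trajectory(atlas, sim$gene_sets, sim$annotation,
                           alpha = config$alpha)
    list(calls = calls, new_counts = new_counts, rates = rates,
         trajectory = traj)
  })
  write_output_tsv(events$new_counts, out("new_protein_counts.tsv"),
                   "call_new_proteins", "protein count")
  write_output_tsv(events$rates, out("rates_of_change.tsv"),
                   "rate_of_change", "log2 units per day")
  write_output_tsv(events$trajectory$trajectory, out("set_trajectories.tsv"),
                   "set_trajectory", "summed LFQ intensity")
  write_output_tsv(events$trajectory$segments,
                   out("set_trajectory_segments.tsv"),
                   "set_trajectory", "t, p")

  clusters <- step("cluster", fuzzy_cmeans_trends(
    atlas, centers = config$n_clusters, fuzzifier = config$fuzzifier,
    seed = config$seed
  ))
  write_output_tsv(tidy(clusters), out("trend_memberships.tsv"),
                   "fuzzy_cmeans_trends", "membership in [0, 1]")

  enrich <- step("enrich", enrichment_dynamics(
    atlas, sim$annotation, sim$gene_sets, grouping = "ctx",
    auc_cutoff = config$auc_cutoff, fc_cutoff = config$fc_cutoff
  ))
  write_output_tsv(enrich$enrichment, out("enrichment.tsv"),
                   "ora", "hypergeometric p, BH q")
  write_output_tsv(enrich$overlap, out("enrichment_overlap.tsv"),
                   "overlap_rate", "%")
  write_output_tsv(enrich$new_sets, out("newly_enriched.tsv"),
                   "newly_enriched", "set names")

  xspecies <- step("xspecies", {
    orth_args <- utils::modifyList(list(seed = config$seed + 1L),
                                   config$ortholog)
    panel <- do.call(simulate_ortholog_panel, orth_args)
    calls <- classify_conservation(ortholog_correlations(panel$panel))
    dist <- correlation_distribution(calls)
    fam <- family_correlations(panel$panel, panel$annotation)
    list(panel = panel, calls = calls, dist = dist, fam = fam)
  })
  write_output_tsv(xspecies$calls, out("conservation_calls.tsv"),
                   "classify_conservation", "Pearson r")
  write_output_tsv(xspecies$dist$histogram, out("correlation_histogram.tsv"),
                   "correlation_distribution", "% of orthologs")
  write_output_tsv(xspecies$fam, out("family_correlations.tsv"),
                   "family_correlations", "Pearson r")

  concordance <- step("concordance", {
    pair_args <- utils::modifyList(list(seed = config$seed + 2L),
                                   config$concordance)
    pairs <- do.call(simulate_rna_protein_pairs, pair_args)
    typed <- classify_six_types(pairs$pairs)
    pct <- type_percentages(typed)
    list(pairs = pairs, typed = typed, percent = pct)
  })
  write_output_tsv(concordance$typed, out("concordance_types.tsv"),
                   "classify_six_types", "linear fold change")
  write_output_tsv(concordance$percent, out("concordance_percent.tsv"),
                   "type_percentages", "% of genes")

  manifest <- list(
    package = "lfqatlas",
    version = as.character(utils::packageVersion("lfqatlas")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    outputs = sort(list.files(outdir))
  )
  manifest_lines <- c(
    paste0("package: ", manifest$package),
    paste0("version: ", manifest$version),
    paste0("seed: ", manifest$seed),
    paste0("config_hash: ", manifest$config_hash),
    "outputs:",
    paste0("  - ", manifest$outputs)
  )
  writeLines(manifest_lines, out("manifest.yml"))

  invisible(list(sim = sim, dep = dep, markers = markers,
                 composition = composition, dynamics = dynamics,
                 events = events, clusters = clusters, enrich = enrich,
                 xspecies = xspecies, concordance = concordance,
                 manifest = manifest))
}
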