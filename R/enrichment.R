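# Hypergeometric over-representation analysis (ORA) and the adjacent-stage
# overlap / novelty of enriched set names.

#' Over-representation analysis of a query set
#'
#' Exact hypergeometric upper-tail test of the overlap between a query and
#' each gene set, within a background universe, with Benjamini-Hochberg
#' correction across the tested sets. Enrichment is called at
#' `q < q_cutoff`.
#'
#' @param query Character vector of gene symbols (intersected with the
#'   universe first).
#' @param sets Named list of gene symbol vectors.
#' @param universe Character vector: the background of all testable genes.
#' @param q_cutoff BH-adjusted significance cutoff (default 0.05).
#' @return Tibble with `set_name`, `k` (overlap), `n` (query size), `K`
#'   (set size in universe), `N` (universe size), `p`, `q`, `enriched`.
#' @export
ora <- function(query, sets, universe, q_cutoff = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) {
    abort("Empty universe.")
  }
  query <- intersect(unique(query), universe)
  n <- length(query)
  N <- length(universe)
  res <- purrr::imap(sets, \(genes, nm) {
    set_u <- intersect(unique(genes), universe)
    K <- length(set_u)
    k <- length(intersect(query, set_u))
    # upper tail P(X >= k) for X ~ Hypergeometric(N, K, n)
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(set_name = nm, k = k, n = n, K = K, N = N, p = p)
  }) |>
    purrr::list_rbind()
  res |>
    mutate(
      q = p.adjust(.data$p, method = "BH"),
      enriched = .data$q < q_cutoff
    ) |>
    arrange(.data$p)
}

#' Overlap rate of two enriched-set name lists
#'
#' Percentage overlap between the sets enriched at two adjacent stages.
#' The denominator is not uniquely defined by the figure it mirrors, so
#' both conventions are returned: `"union"` (symmetric Jaccard-style,
#' 100·|A∩B|/|A∪B|) and `"later"` (100·|A∩B|/|B|, consistent with the
#' newly-enriched framing). Both lists empty gives NA.
#'
#' @param sets_a Names enriched at the earlier stage.
#' @param sets_b Names enriched at the later stage.
#' @return Tibble with `rule` and `percent`.
#' @export
overlap_rate <- function(sets_a, sets_b) {
  a <- unique(sets_a)
  b <- unique(sets_b)
  inter <- length(intersect(a, b))
  uni <- length(union(a, b))
  tibble::tibble(
    rule = c("union", "later"),
    percent = c(
      if (uni == 0) NA_real_ else 100 * inter / uni,
      if (length(b) == 0) NA_real_ else 100 * inter / length(b)
    )
  )
}

#' Newly enriched set names
#'
#' Set names enriched at the later stage but not at the earlier one.
#'
#' @param sets_a,sets_b Enriched names at the earlier / later stage.
#' @return Character vector `sets_b \ sets_a`.
#' @export
newly_enriched <- function(sets_a, sets_b) {
  setdiff(unique(sets_b), unique(sets_a))
}

#' Enrichment-overlap dynamics of stage markers
#'
#' End-to-end convenience: detects markers per stage within a macro-region
#' grouping, runs ORA per stage, and summarises the adjacent-stage overlap
#' rate and newly enriched sets.
#'
#' @param atlas An [lfq_atlas].
#' @param ann Annotation tibble (for gene mapping).
#' @param sets Named list of gene sets (symbols).
#' @param grouping Macro-region grouping (`"ctx"`, `"sctx"`,
#'   `"all_excl_cb"`, `"all"`).
#' @param stages Stages to include (default all present).
#' @param ... Passed to [find_markers()].
#' @return List with `enrichment` (per-stage ORA results), `overlap`
#'   (per-transition overlap rates under both rules) and `new_sets`
#'   (per-transition newly enriched names).
#' @export
enrichment_dynamics <- function(atlas, ann, sets, grouping = "ctx",
                                stages = NULL, ...) {
  ann <- as_annotation(ann)
  meta <- atlas$meta
  keep <- resolve_grouping(meta, grouping)
  sub <- atlas_subset(atlas, meta$sample_id[keep])
  stages <- stages %||% intersect(stage_levels(), unique(sub$meta$stage))
  gene_of <- setNames(ann$gene_symbol, ann$protein_id)
  universe <- unique(stats::na.omit(gene_of[rownames(atlas$lfq)]))
  cls <- class_partition(sub, "stage", stages = stages)
  markers <- find_markers(sub, cls, ...)
  enr <- purrr::map(stages, \(s) {
    ids <- markers$protein_id[markers$marker & markers$class == s]
    genes <- unique(stats::na.omit(gene_of[ids]))
    ora(genes, sets, universe) |>
      mutate(stage = s, .before = 1)
  }) |>
    purrr::list_rbind()
  enriched_names <- purrr::map(stages, \(s) {
    enr$set_name[enr$stage == s & enr$enriched]
  }) |>
    setNames(stages)
  transitions <- tibble::tibble(from = stages[-length(stages)],
                                to = stages[-1])
  overlap <- purrr::pmap(transitions, \(from, to) {
    overlap_rate(enriched_names[[from]], enriched_names[[to]]) |>
      mutate(transition = paste0(from, "->", to), .before = 1)
  }) |>
    purrr::list_rbind()
  new_sets <- purrr::pmap(transitions, \(from, to) {
    tibble::tibble(
      transition = paste0(from, "->", to),
      set_name = newly_enriched(enriched_names[[from]],
                                enriched_names[[to]])
    )
  }) |>
    purrr::list_rbind()
  list(enrichment = enr, overlap = overlap, new_sets = new_sets)
}
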