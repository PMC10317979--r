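# TSV / GMT input and output.

#' Read an LFQ abundance matrix and sample metadata
#'
#' The matrix TSV has protein IDs in the first column and one column per
#' sample; the metadata TSV is keyed by `sample_id`. Samples are reordered
#' to follow the metadata. Every matrix column must match exactly one
#' metadata row; negative intensities are an error.
#'
#' @param matrix_path Path to the intensity TSV.
#' @param meta_path Path to the metadata TSV.
#' @return An [lfq_atlas].
#' @export
read_abundance <- function(matrix_path, meta_path) {
  mat_df <- readr::read_tsv(matrix_path, show_col_types = FALSE,
                            progress = FALSE, comment = "#")
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE,
                          progress = FALSE, comment = "#")
  lfq <- as.matrix(mat_df[, -1, drop = FALSE])
  rownames(lfq) <- as.character(mat_df[[1]])
  storage.mode(lfq) <- "double"
  lfq_atlas(lfq, meta)
}

#' Write an LFQ atlas to TSV files
#'
#' Inverse of [read_abundance()]: writes the intensity matrix (protein IDs
#' in the first column) and the sample metadata.
#'
#' @param atlas An `lfq_atlas`.
#' @param matrix_path,meta_path Output paths.
#' @return `atlas`, invisibly.
#' @export
write_abundance <- function(atlas, matrix_path, meta_path) {
  mat_df <- tibble::as_tibble(atlas$lfq, rownames = "protein_id")
  readr::write_tsv(mat_df, matrix_path, progress = FALSE)
  readr::write_tsv(atlas$meta, meta_path, progress = FALSE)
  invisible(atlas)
}

#' Read a protein annotation table
#'
#' Expects columns `protein_id`, optional `gene_symbol`, and optional
#' multi-label columns `localization` and `family` with `;`-separated
#' labels. Lookups for unknown proteins yield empty label sets rather than
#' errors.
#'
#' @param path Path to the annotation TSV.
#' @return Tibble with list-columns `localization` and `family`.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "#")
  as_annotation(ann)
}

#' Normalise an annotation data frame
#'
#' @param ann Data frame with `protein_id` and optionally `gene_symbol`,
#'   `localization`, `family` (`;`-separated strings or list-columns).
#' @return Tibble with character `gene_symbol` and list-columns
#'   `localization`, `family`.
#' @export
as_annotation <- function(ann) {
  ann <- tibble::as_tibble(ann)
  if (!"protein_id" %in% names(ann)) {
    abort("Annotation needs a `protein_id` column.")
  }
  if (!"gene_symbol" %in% names(ann)) {
    ann$gene_symbol <- NA_character_
  }
  split_labels <- function(x) {
    if (is.list(x)) {
      return(purrr::map(x, \(v) as.character(v[!is.na(v) & nzchar(v)])))
    }
    strsplit(ifelse(is.na(x), "", as.character(x)), ";", fixed = TRUE) |>
      purrr::map(\(v) v[nzchar(v)])
  }
  ann$localization <- if ("localization" %in% names(ann)) {
    split_labels(ann$localization)
  } else {
    rep(list(character(0)), nrow(ann))
  }
  ann$family <- if ("family" %in% names(ann)) {
    split_labels(ann$family)
  } else {
    rep(list(character(0)), nrow(ann))
  }
  ann
}

#' Write an annotation table
#'
#' @param ann Annotation tibble as returned by [as_annotation()].
#' @param path Output TSV path.
#' @return `ann`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  out <- ann |>
    mutate(
      localization = purrr::map_chr(.data$localization, paste, collapse = ";"),
      family = purrr::map_chr(.data$family, paste, collapse = ";")
    )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(ann)
}

#' Read a gene-set collection from a GMT file
#'
#' One set per line: name, description, then member gene symbols. Empty
#' sets are dropped with a warning.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    abort("read_gmt requires the fgsea package.")
  }
  sets <- fgsea::gmtPathways(path)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warn(paste0("Dropping ", sum(empty), " empty gene set(s)."))
    sets <- sets[!empty]
  }
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `sets`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("All gene sets must be named.")
  }
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- purrr::imap_chr(sets, \(genes, name) {
    paste(c(name, descriptions[[match(name, names(sets))]], genes),
          collapse = "\t")
  })
  writeLines(lines, path)
  invisible(sets)
}
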