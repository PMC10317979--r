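# Synthetic LFQ atlas generator. Intensities are log-normal on the log2
# scale: log2(LFQ) = baseline + stage effect + scaled region effect +
# planted shifts + replicate noise, with zero-inflated detection (dropout
# sets LFQ to 0). Planted structure (markers, emergent proteins, a
# region-specific trajectory set) is recorded in a truth ledger.

#' Simulation configuration
#'
#' Defaults emulate the study design of a fetal-to-neonatal brain atlas:
#' 5/11/18/18 regions across the stages F50/F90/F120/P3, three replicates
#' per region and stage, stage variability exceeding region variability,
#' a per-stage damping of region effects that bottoms at F120 (producing a
#' V-shaped inter-regional difference curve), and technical (rather than
#' biological) CB replicates at F90.
#'
#' @param n_proteins Number of proteins.
#' @param regions Named list of region codes per stage.
#' @param replicates Samples per (region, stage).
#' @param baseline_mean,baseline_sd Per-protein baseline log2 intensity.
#' @param stage_effect_sd SD of per-(protein, stage) effects (log2 units).
#' @param region_effect_sd SD of per-(protein, region) effects (log2 units).
#' @param region_effect_scale Per-stage multiplier on region effects.
#' @param noise_sd Replicate noise SD (log2 units).
#' @param technical_noise_sd Noise SD between technical replicates.
#' @param dropout Marginal probability that an entry is zeroed.
#' @param dropout_mode `"intensity"` (default: logistic in the log2 mean,
#'   low-abundance entries drop out more, as in real LFQ data — this keeps
#'   a complete-case stratum of abundant proteins) or `"uniform"`
#'   (intensity-independent).
#' @param n_stage_markers Planted markers per stage class.
#' @param n_cb_markers Planted CB markers.
#' @param marker_shift Additive log2 shift of a marker in its class.
#' @param n_emergent Planted emergent proteins per adjacent-stage
#'   transition.
#' @param n_trajectory Planted proteins with a monotone increasing stage
#'   trend confined to `trajectory_lineage`.
#' @param trajectory_step Per-stage log2 increment of the trajectory set.
#' @param trajectory_lineage Lineage receiving the trajectory trend.
#' @param cb_f90_technical Replace the third CB sample at F90 with a
#'   technical re-measurement of another CB sample, as in the emulated
#'   design.
#' @param seed Integer seed; fixes the output bit-for-bit.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 2000,
                       regions = stage_regions(),
                       replicates = 3,
                       baseline_mean = 25,
                       baseline_sd = 1.5,
                       stage_effect_sd = 1.0,
                       region_effect_sd = 0.35,
                       region_effect_scale = c(F50 = 1, F90 = 0.75,
                                               F120 = 0.5, P3 = 0.85),
                       noise_sd = 0.5,
                       technical_noise_sd = 0.05,
                       dropout = 0.1,
                       dropout_mode = c("intensity", "uniform"),
                       n_stage_markers = 20,
                       n_cb_markers = 20,
                       marker_shift = 2,
                       n_emergent = 20,
                       n_trajectory = 30,
                       trajectory_step = 1,
                       trajectory_lineage = "PFC",
                       cb_f90_technical = TRUE,
                       seed = 1L) {
  dropout_mode <- match.arg(dropout_mode)
  cfg <- list(
    n_proteins = n_proteins, regions = regions, replicates = replicates,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    stage_effect_sd = stage_effect_sd, region_effect_sd = region_effect_sd,
    region_effect_scale = region_effect_scale, noise_sd = noise_sd,
    technical_noise_sd = technical_noise_sd,
    dropout = dropout, dropout_mode = dropout_mode,
    n_stage_markers = n_stage_markers, n_cb_markers = n_cb_markers,
    marker_shift = marker_shift, n_emergent = n_emergent,
    n_trajectory = n_trajectory, trajectory_step = trajectory_step,
    trajectory_lineage = trajectory_lineage,
    cb_f90_technical = cb_f90_technical, seed = seed
  )
  counts <- c(n_proteins, replicates, lengths(regions))
  if (any(counts <= 0)) {
    abort("All counts in sim_config must be positive.")
  }
  if (dropout < 0 || dropout >= 1) {
    abort("`dropout` must be in [0, 1).")
  }
  n_planted <- n_stage_markers * length(stage_levels()) + n_cb_markers +
    n_emergent * (length(stage_levels()) - 1) + n_trajectory
  if (n_planted > n_proteins) {
    abort("More planted proteins requested than `n_proteins`.")
  }
  structure(cfg, class = "sim_config")
}

sim_sample_sheet <- function(cfg) {
  stages <- stage_levels()
  meta <- purrr::map(stages, \(s) {
    tidyr::crossing(
      stage = s,
      region = cfg$regions[[s]],
      replicate = seq_len(cfg$replicates)
    )
  }) |>
    purrr::list_rbind() |>
    mutate(
      sample_id = paste(.data$stage, .data$region, .data$replicate, sep = "_"),
      macro_region = macro_region_of(.data$region),
      lineage = lineage_of(.data$region),
      day = unname(stage_days()[.data$stage]),
      animal_id = paste0(.data$stage, "_A", .data$replicate),
      replicate_kind = "biological"
    )
  if (isTRUE(cfg$cb_f90_technical) && "CB" %in% cfg$regions$F90 &&
      cfg$replicates >= 3) {
    idx <- which(meta$stage == "F90" & meta$region == "CB")
    meta$replicate_kind[idx] <- "technical"
    # one biological sample lost: the third run re-measures animal 1
    meta$animal_id[idx[length(idx)]] <- meta$animal_id[idx[1]]
  }
  meta |>
    select("sample_id", "stage", "day", "region", "macro_region",
           "lineage", "animal_id", "replicate_kind", "replicate")
}

#' Simulate an LFQ atlas with planted structure
#'
#' Draws log-normal intensities under the configured stage/region effect
#' model, plants stage and CB markers (additive log2 shifts), emergent
#' proteins (forced to zero before an onset stage), and a region-specific
#' increasing trajectory set, then applies dropout. Alongside the atlas it
#' returns a truth ledger of every planted membership, a protein annotation
#' table (gene symbols, subcellular localizations, protein families), and a
#' gene-set collection containing the planted marker-process sets, the
#' planted trajectory set, and random disease-like sets.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `atlas` ([lfq_atlas]), `truth` (tibble:
#'   `protein_id`, `role`, `class`, `transition`, `shift`), `annotation`,
#'   `gene_sets` (named list), and `effects` (the drawn baseline and
#'   stage/region effect matrices, for calibration checks).
#' @export
simulate_atlas <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    meta <- sim_sample_sheet(cfg)
    n_s <- nrow(meta)
    n_p <- cfg$n_proteins
    proteins <- sprintf("PROT%04d", seq_len(n_p))
    stages <- stage_levels()
    all_regions <- sort(unique(unlist(cfg$regions)))

    baseline <- rnorm(n_p, cfg$baseline_mean, cfg$baseline_sd)
    stage_eff <- matrix(rnorm(n_p * length(stages), 0, cfg$stage_effect_sd),
                        n_p, length(stages), dimnames = list(proteins, stages))
    region_eff <- matrix(
      rnorm(n_p * length(all_regions), 0, cfg$region_effect_sd),
      n_p, length(all_regions), dimnames = list(proteins, all_regions)
    )

    # planted roles occupy disjoint protein blocks
    idx <- 0
    take <- function(n) {
      out <- seq(idx + 1, length.out = n)
      idx <<- idx + n
      out
    }
    truth <- list()
    marker_rows <- list()
    for (s in stages) {
      rows <- take(cfg$n_stage_markers)
      marker_rows[[s]] <- rows
      truth[[length(truth) + 1]] <- tibble::tibble(
        protein_id = proteins[rows], role = "marker", class = s,
        transition = NA_character_, shift = cfg$marker_shift
      )
    }
    cb_rows <- take(cfg$n_cb_markers)
    truth[[length(truth) + 1]] <- tibble::tibble(
      protein_id = proteins[cb_rows], role = "marker", class = "CB",
      transition = NA_character_, shift = cfg$marker_shift
    )
    emergent_rows <- list()
    transitions <- paste(stages[-length(stages)], stages[-1], sep = "->")
    for (k in seq_along(transitions)) {
      rows <- take(cfg$n_emergent)
      emergent_rows[[transitions[k]]] <- rows
      truth[[length(truth) + 1]] <- tibble::tibble(
        protein_id = proteins[rows], role = "emergent",
        class = NA_character_, transition = transitions[k],
        shift = NA_real_
      )
    }
    traj_rows <- take(cfg$n_trajectory)
    if (cfg$n_trajectory > 0) {
      truth[[length(truth) + 1]] <- tibble::tibble(
        protein_id = proteins[traj_rows], role = "trajectory",
        class = cfg$trajectory_lineage, transition = NA_character_,
        shift = cfg$trajectory_step
      )
    }
    truth <- purrr::list_rbind(truth)

    # Marker and trajectory proteins carry no random background stage
    # effects: the ledgered shift/step contrast is their true effect, so
    # planted structure is exact by construction (as for the emergent and
    # ortholog plants).
    planted_rows <- c(unlist(marker_rows), cb_rows, traj_rows)
    stage_eff[planted_rows, ] <- 0

    stage_idx <- match(meta$stage, stages)
    # mean log2 matrix, proteins x samples
    mu <- matrix(baseline, n_p, n_s) +
      stage_eff[, stage_idx, drop = FALSE] +
      region_eff[, match(meta$region, all_regions), drop = FALSE] *
        rep(unname(cfg$region_effect_scale[meta$stage]), each = n_p)

    # planted marker shifts in their target class
    for (s in stages) {
      cols <- which(meta$stage == s)
      mu[marker_rows[[s]], cols] <- mu[marker_rows[[s]], cols] + cfg$marker_shift
    }
    cb_cols <- which(meta$region == "CB")
    mu[cb_rows, cb_cols] <- mu[cb_rows, cb_cols] + cfg$marker_shift

    # planted monotone trajectory confined to one lineage
    if (cfg$n_trajectory > 0) {
      traj_cols <- which(meta$lineage == cfg$trajectory_lineage)
      step <- (stage_idx[traj_cols] - 1) * cfg$trajectory_step
      mu[traj_rows, traj_cols] <- mu[traj_rows, traj_cols] +
        rep(step, each = length(traj_rows))
    }

    log2_x <- mu + matrix(rnorm(n_p * n_s, 0, cfg$noise_sd), n_p, n_s)

    # technical replicates: re-measurement of the same extract
    tech <- which(meta$replicate_kind == "technical")
    if (length(tech) > 1) {
      base_col <- log2_x[, tech[1]]
      for (j in tech[-1]) {
        log2_x[, j] <- base_col + rnorm(n_p, 0, cfg$technical_noise_sd)
      }
    }

    lfq <- 2^log2_x
    dimnames(lfq) <- list(proteins, meta$sample_id)

    # dropout (zero-inflation)
    if (cfg$dropout > 0) {
      if (cfg$dropout_mode == "uniform") {
        drop <- matrix(runif(n_p * n_s) < cfg$dropout, n_p, n_s)
      } else {
        # logistic in the log2 mean: low-abundance entries drop out more,
        # calibrated so the marginal rate is approximately `dropout`
        z <- scale(as.vector(mu))
        pr <- stats::plogis(stats::qlogis(cfg$dropout) - 1.5 * z)
        drop <- matrix(runif(n_p * n_s) < pr, n_p, n_s)
      }
      lfq[drop] <- 0
    }

    # emergent proteins: absent before onset, detected from onset on
    for (k in seq_along(transitions)) {
      rows <- emergent_rows[[transitions[k]]]
      onset <- k + 1 # index of the later stage
      pre_cols <- which(stage_idx < onset)
      post_cols <- which(stage_idx >= onset)
      lfq[rows, pre_cols] <- 0
      zeroed <- lfq[rows, post_cols, drop = FALSE] == 0
      if (any(zeroed)) { # dropout must not erase planted detections
        repl <- 2^(mu[rows, post_cols, drop = FALSE][zeroed])
        lfq[rows, post_cols][zeroed] <- repl
      }
    }

    atlas <- lfq_atlas(lfq, select(meta, -"replicate"))

    annotation <- sim_annotation(proteins)
    gene_sets <- sim_gene_sets(truth, annotation)

    list(atlas = atlas, truth = truth, annotation = annotation,
         gene_sets = gene_sets,
         effects = list(baseline = setNames(baseline, proteins),
                        stage_effect = stage_eff,
                        region_effect = region_eff))
  })
}

# Gene symbols are one-to-one with proteins; localizations and families are
# drawn from small label pools, with a few proteins dual-localized.
sim_annotation <- function(proteins) {
  locs <- c("Nucleoplasm", "Cytosol", "Plasma membrane", "Mitochondria",
            "Golgi apparatus", "Endoplasmic reticulum", "Vesicles")
  fams <- c("Protein kinase superfamily", "Tubulin family",
            "Spectrin family", "Intermediate filament family",
            "ALB/AFP/VDB family", "Metallo-dependent hydrolases superfamily",
            "Ras superfamily", "Solute carrier family")
  n <- length(proteins)
  loc1 <- sample(locs, n, replace = TRUE)
  dual <- runif(n) < 0.1
  loc2 <- sample(locs, n, replace = TRUE)
  localization <- purrr::map(seq_len(n), \(i) {
    unique(c(loc1[i], if (dual[i]) loc2[i]))
  })
  tibble::tibble(
    protein_id = proteins,
    gene_symbol = sub("PROT", "GENE", proteins),
    localization = localization,
    family = as.list(sample(fams, n, replace = TRUE))
  )
}

# Planted marker-process sets (one per class), the trajectory set, and
# random disease-like gene lists.
sim_gene_sets <- function(truth, annotation) {
  gene_of <- setNames(annotation$gene_symbol, annotation$protein_id)
  sets <- list()
  markers <- truth |> filter(.data$role == "marker")
  for (cl in unique(markers$class)) {
    ids <- markers$protein_id[markers$class == cl]
    sets[[paste0("PROCESS_", cl)]] <- unname(gene_of[ids])
  }
  # processes shared by adjacent stages, so enriched-set overlap between
  # consecutive stages is non-trivial
  stages <- intersect(stage_levels(), unique(markers$class))
  for (k in seq_len(max(0L, length(stages) - 1L))) {
    ids <- markers$protein_id[markers$class %in% stages[k:(k + 1)]]
    sets[[paste0("PROCESS_", stages[k], "_", stages[k + 1])]] <-
      unname(gene_of[ids])
  }
  traj <- truth$protein_id[truth$role == "trajectory"]
  if (length(traj) > 0) {
    sets[["SYNAPTIC_ASSEMBLY"]] <- unname(gene_of[traj])
  }
  background <- setdiff(annotation$gene_symbol, unlist(sets))
  for (d in c("AD", "ASD", "MDD", "PD", "SCZ")) {
    sets[[d]] <- sample(background, min(40, length(background)))
  }
  sets
}
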