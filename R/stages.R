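# Stage order, day table, and the default anatomical sampling design.

#' Developmental stage order
#'
#' The four developmental stages in chronological order: three fetal time
#' points (days post-fertilization) and one neonatal time point.
#'
#' @return Character vector `c("F50", "F90", "F120", "P3")`.
#' @export
stage_levels <- function() c("F50", "F90", "F120", "P3")

#' Default days post-fertilization per stage
#'
#' F50/F90/F120 are days post-fertilization; P3 is 3 days after birth, taken
#' as gestation (about 150 days in the cynomolgus monkey) plus 3.
#'
#' @return Named numeric vector of days, one per stage.
#' @export
stage_days <- function() {
  c(F50 = 50, F90 = 90, F120 = 120, P3 = 153)
}

#' Default brain regions sampled at each stage
#'
#' The sampling design widens as the brain differentiates: 5 regions at F50,
#' 11 at F90, and 18 at F120 and P3.
#'
#' @return Named list of character vectors, one per stage.
#' @export
stage_regions <- function() {
  list(
    F50  = c("PFC", "TL", "PL", "V1", "CB"),
    F90  = c("aPFC", "pPFC", "IC", "M1", "TL", "PL", "V1", "CB",
             "STr", "Hipp", "Amy"),
    F120 = c("sPFG", "mPFG", "iPFG", "OFC", "IC", "M1", "aCG", "sTG",
             "mTG", "iTG", "S1", "sPL", "V1", "CB", "STr", "Hipp",
             "MD", "Amy"),
    P3   = c("sPFG", "mPFG", "iPFG", "OFC", "IC", "M1", "aCG", "sTG",
             "mTG", "iTG", "S1", "sPL", "V1", "CB", "STr", "Hipp",
             "MD", "Amy")
  )
}

#' Macro-region of a brain region
#'
#' Maps region codes onto the three macro-regions: cerebellum (CB),
#' subcortical tissue (sCTX: striatum, hippocampus, thalamus, amygdala) and
#' cortex (CTX: everything else).
#'
#' @param region Character vector of region codes.
#' @return Character vector with entries in `c("CTX", "sCTX", "CB")`.
#' @export
macro_region_of <- function(region) {
  sctx <- c("STr", "Hipp", "MD", "Amy")
  dplyr::case_when(
    region == "CB" ~ "CB",
    region %in% sctx ~ "sCTX",
    TRUE ~ "CTX"
  )
}

#' Cortical lineage of a brain region
#'
#' Region codes change across stages as finer subdivisions become
#' dissectable; the lineage groups subdivisions of the same cortical
#' territory (PFC, TL, PL, V1) so that a territory can be followed over
#' stages. Subcortical regions and CB map to themselves; remaining cortical
#' areas map to "CTXo".
#'
#' @param region Character vector of region codes.
#' @return Character vector of lineage labels.
#' @export
lineage_of <- function(region) {
  pfc <- c("PFC", "aPFC", "pPFC", "sPFG", "mPFG", "iPFG", "OFC")
  tl  <- c("TL", "sTG", "mTG", "iTG")
  pl  <- c("PL", "sPL")
  self <- c("V1", "CB", "STr", "Hipp", "MD", "Amy")
  dplyr::case_when(
    region %in% pfc ~ "PFC",
    region %in% tl ~ "TL",
    region %in% pl ~ "PL",
    region %in% self ~ region,
    TRUE ~ "CTXo"
  )
}
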