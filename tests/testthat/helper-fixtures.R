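# Shared fixtures and independent oracles. Fixtures are built in code; the
# memoised default simulation is reused across test files.

.fixture_env <- new.env(parent = emptyenv())

# Default-condition simulation (study-design emulation), computed once.
sim_fixture <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_atlas(sim_config(seed = 20260924L))
  }
  .fixture_env$sim
}

# Downscaled simulation config: planted blocks shrunk to fit small
# protein counts; any field may still be overridden.
small_sim_config <- function(...) {
  args <- utils::modifyList(
    list(n_proteins = 100, n_stage_markers = 2, n_cb_markers = 2,
         n_emergent = 2, n_trajectory = 3),
    list(...)
  )
  do.call(sim_config, args)
}

# Small hand-built atlas: one stage unless given, regions x replicates.
# `values` is given protein by protein (row-major).
make_atlas <- function(values, regions, replicates = 2, stage = "F50",
                       proteins = NULL) {
  n_s <- length(regions) * replicates
  lfq <- matrix(values, ncol = n_s, byrow = TRUE)
  rownames(lfq) <- proteins %||%
    sprintf("P%02d", seq_len(nrow(lfq)))
  meta <- tibble::tibble(
    sample_id = paste0("s", seq_len(n_s)),
    stage = stage,
    region = rep(regions, each = replicates)
  )
  colnames(lfq) <- meta$sample_id
  lfq_atlas(lfq, meta)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force pair-count AUC oracle (independent of the rank-based path).
brute_auc <- function(v_in, v_out) {
  v_in <- v_in[!is.na(v_in)]
  v_out <- v_out[!is.na(v_out)]
  if (length(v_in) == 0 || length(v_out) == 0) return(NA_real_)
  s <- 0
  for (a in v_in) {
    for (b in v_out) {
      s <- s + (a > b) + 0.5 * (a == b)
    }
  }
  s / (length(v_in) * length(v_out))
}

# Brute-force hypergeometric upper tail by enumerating all C(N, n) draws.
brute_hyper_p <- function(k, K, N, n) {
  marked <- seq_len(K)
  draws <- combn(N, n)
  mean(apply(draws, 2, function(d) sum(d %in% marked) >= k))
}

# Brute-force two-sample KS statistic: max ECDF gap over pooled points.
brute_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# Order-free six-type predicate oracle: six explicitly disjoint predicates
# written straight from the disambiguated rule system (see vignette).
oracle_six_types <- function(fc_rna, fc_protein) {
  lr <- log2(fc_rna)
  lp <- log2(fc_protein)
  big_r <- abs(lr) > 1; big_p <- abs(lp) > 1
  small_r <- abs(lr) < 1; small_p <- abs(lp) < 1
  bnd_r <- abs(lr) == 1; bnd_p <- abs(lp) == 1
  cons <- sign(lr) == sign(lp) & sign(lr) != 0
  opp <- sign(lr) * sign(lp) < 0
  P <- cbind(
    t1 = (small_r & small_p) | (bnd_r & !big_p) | (bnd_p & !big_r) |
      (!cons & ((big_r & bnd_p) | (bnd_r & big_p))),
    t2 = big_p & small_r,
    t3 = big_r & small_p,
    t4 = cons & ((big_r & bnd_p) | (bnd_r & big_p)),
    t5 = opp & big_r & big_p,
    t6 = cons & big_r & big_p
  )
  # drop the double-counted non-consistent boundary cells from t1
  P[, "t1"] <- P[, "t1"] & !P[, "t4"]
  P
}

# Conservation interval predicates, written independently of the classifier.
oracle_conservation <- function(mh, mouse_h, mm) {
  inside <- function(x, lo, hi) !is.na(x) & x >= lo & x <= hi
  h <- inside(mh, -1, -0.5) & inside(mouse_h, -1, -0.5)
  co <- inside(mh, 0.75, 1) & inside(mm, 0.75, 1)
  pr <- inside(mh, 0.75, 1) & !inside(mouse_h, 0.75, 1) &
    !inside(mm, 0.75, 1)
  cbind(human_specific = h, conserved = co, primate_specific = pr)
}
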