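# Internal numerical helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Row-wise count / mean / variance ignoring NA, for a numeric matrix.
row_stats <- function(x) {
  n <- unname(rowSums(!is.na(x)))
  m <- unname(rowMeans(x, na.rm = TRUE))
  m[n == 0] <- NA_real_
  centered <- x - m
  v <- unname(rowSums(centered^2, na.rm = TRUE)) / pmax(n - 1, 1)
  v[n < 2] <- NA_real_
  list(n = n, mean = m, var = v)
}

# Vectorised two-sided pooled-variance (Student) t-test across matrix rows.
# `x` holds log2 intensities with NA for undetected entries; `idx_a`/`idx_b`
# are column indices for the two groups. Rows need `min_n` detected values on
# each side to be tested. Zero pooled variance with equal means gives t = 0,
# p = 1; with unequal means it gives p = 0 (infinite separation).
row_t_test <- function(x, idx_a, idx_b, min_n = 2L) {
  a <- row_stats(x[, idx_a, drop = FALSE])
  b <- row_stats(x[, idx_b, drop = FALSE])
  tested <- a$n >= min_n & b$n >= min_n
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / df
  se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  tt <- (a$mean - b$mean) / se
  p <- 2 * pt(-abs(tt), df)
  degenerate <- tested & !is.na(sp2) & sp2 == 0
  tt[degenerate & a$mean == b$mean] <- 0
  p[degenerate & a$mean == b$mean] <- 1
  p[degenerate & a$mean != b$mean] <- 0
  tt[degenerate & a$mean != b$mean] <-
    sign(a$mean - b$mean)[degenerate & a$mean != b$mean] * Inf
  tt[!tested] <- NA_real_
  p[!tested] <- NA_real_
  tibble::tibble(
    mean_a = a$mean, mean_b = b$mean,
    n_a = a$n, n_b = b$n,
    t = tt, df = ifelse(tested, df, NA_real_), p = p,
    tested = tested
  )
}

# Row-wise linear fold change of group means over detected entries.
# `lfq` is the raw intensity matrix with NA for undetected.
row_fold_change <- function(lfq, idx_a, idx_b) {
  ma <- rowMeans(lfq[, idx_a, drop = FALSE], na.rm = TRUE)
  mb <- rowMeans(lfq[, idx_b, drop = FALSE], na.rm = TRUE)
  na <- rowSums(!is.na(lfq[, idx_a, drop = FALSE]))
  nb <- rowSums(!is.na(lfq[, idx_b, drop = FALSE]))
  fc <- ma / mb
  fc[na == 0 | nb == 0] <- NA_real_
  unname(fc)
}

# Mann-Whitney AUC for one row of values; NA excluded, ties get 0.5 credit.
auc_pair <- function(v_in, v_out) {
  v_in <- v_in[!is.na(v_in)]
  v_out <- v_out[!is.na(v_out)]
  n_in <- length(v_in)
  n_out <- length(v_out)
  if (n_in == 0 || n_out == 0) {
    return(NA_real_)
  }
  r <- rank(c(v_in, v_out))
  (sum(r[seq_len(n_in)]) - n_in * (n_in + 1) / 2) / (n_in * n_out)
}

# Row-wise AUC over a matrix with NA for undetected entries.
row_auc <- function(x, idx_in, idx_out) {
  vapply(
    seq_len(nrow(x)),
    function(i) auc_pair(x[i, idx_in], x[i, idx_out]),
    numeric(1)
  )
}

# Scalar two-sided pooled-variance Student t for two samples, defined on
# degenerate input: equal constant groups give t = 0, p = 1; unequal
# constant groups give p = 0.
pooled_t2 <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / df
  if (sp2 == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, p = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, p = 2 * pt(-abs(tt), df))
}

stage_factor <- function(stage) {
  factor(stage, levels = stage_levels())
}

assert_stages_known <- function(stage) {
  bad <- setdiff(unique(stage), stage_levels())
  if (length(bad) > 0) {
    abort(paste0("Unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  invisible(stage)
}
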