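# Fuzzy c-means clustering of standardized stage-mean trajectories (the
# soft time-course clustering popularised for expression data). Implemented
# here so the per-iteration objective is available; e1071::cmeans serves as
# an independent cross-check in the tests.

#' Fuzzy c-means on a numeric matrix
#'
#' Minimises the weighted within-cluster sum of squares
#' \eqn{J = \sum_{i,j} u_{ij}^m \|x_i - c_j\|^2} with memberships
#' \eqn{u_{ij}} summing to 1 per row, by alternating membership and
#' centroid updates. A point coinciding with a centroid gets full
#' membership there. Initial centroids are `centers` distinct rows drawn
#' under `seed`.
#'
#' @param x Numeric matrix (observations x features), no NA.
#' @param centers Number of clusters.
#' @param fuzzifier Fuzziness exponent m > 1 (default 2).
#' @param tol Convergence tolerance on the objective decrease.
#' @param max_iter Iteration cap.
#' @param seed Seed for centroid initialisation.
#' @return List with `membership` (rows sum to 1), `centroids`,
#'   `cluster` (hard labels by argmax), `objective` (per-iteration trace),
#'   `iterations`, `converged`.
#' @export
fuzzy_cmeans <- function(x, centers, fuzzifier = 2, tol = 1e-6,
                         max_iter = 500, seed = 1L) {
  stopifnot(is.matrix(x), !anyNA(x), centers >= 1, fuzzifier > 1)
  if (nrow(unique(as.data.frame(x))) < centers) {
    abort("Fewer distinct profiles than requested clusters.")
  }
  n <- nrow(x)
  cent <- with_seed(seed, {
    # sample until the initial centroids are distinct
    repeat {
      idx <- sample.int(n, centers)
      cand <- x[idx, , drop = FALSE]
      if (nrow(unique(as.data.frame(cand))) == centers) break
    }
    cand
  })
  m <- fuzzifier
  obj_trace <- numeric(0)
  memb <- NULL
  for (iter in seq_len(max_iter)) {
    d2 <- outer(rowSums(x^2), rep(1, centers)) +
      outer(rep(1, n), rowSums(cent^2)) - 2 * x %*% t(cent)
    d2[d2 < 0] <- 0
    memb <- matrix(0, n, centers)
    zero <- d2 <= .Machine$double.eps
    has_zero <- rowSums(zero) > 0
    if (any(has_zero)) {
      memb[has_zero, ] <- zero[has_zero, , drop = FALSE] /
        rowSums(zero[has_zero, , drop = FALSE])
    }
    if (any(!has_zero)) {
      w <- d2[!has_zero, , drop = FALSE]^(-1 / (m - 1))
      memb[!has_zero, ] <- w / rowSums(w)
    }
    obj <- sum(memb^m * d2)
    obj_trace <- c(obj_trace, obj)
    um <- memb^m
    cent <- t(um) %*% x / colSums(um)
    converged <- iter > 1 &&
      abs(obj_trace[iter - 1] - obj) <= tol * max(1, abs(obj))
    if (converged) break
  }
  colnames(memb) <- rownames(cent) <- paste0("cluster", seq_len(centers))
  rownames(memb) <- rownames(x)
  list(
    membership = memb, centroids = cent,
    cluster = max.col(memb, ties.method = "first"),
    objective = obj_trace, iterations = length(obj_trace),
    converged = converged
  )
}

#' Fuzzy c-means trend clustering of stage-mean trajectories
#'
#' Averages each protein's detected log2 intensities per stage,
#' standardises the trajectory to zero mean and unit variance (the usual
#' preprocessing for soft time-course clustering), drops proteins with a
#' missing stage mean or a flat trajectory, and clusters with
#' [fuzzy_cmeans()].
#'
#' @param atlas An [lfq_atlas].
#' @param centers Number of trend clusters (default 4).
#' @param fuzzifier Fuzziness exponent (default 2).
#' @param tol,max_iter,seed Passed to [fuzzy_cmeans()].
#' @return A `fuzzy_trends` object; see [tidy.fuzzy_trends()],
#'   [glance.fuzzy_trends()], [autoplot.fuzzy_trends()].
#' @export
fuzzy_cmeans_trends <- function(atlas, centers = 4, fuzzifier = 2,
                                tol = 1e-6, max_iter = 500, seed = 1L) {
  meta <- atlas$meta
  stages <- intersect(stage_levels(), unique(meta$stage))
  if (length(stages) < 2) {
    abort("Need at least two stages for trend clustering.")
  }
  x <- log2_matrix(atlas)
  stage_means <- vapply(stages, \(s) {
    rowMeans(x[, meta$stage == s, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(x)))
  ok <- rowSums(is.na(stage_means)) == 0 &
    apply(stage_means, 1, sd) > 0
  z <- t(scale(t(stage_means[ok, , drop = FALSE])))
  fit <- fuzzy_cmeans(z, centers = centers, fuzzifier = fuzzifier,
                      tol = tol, max_iter = max_iter, seed = seed)
  structure(
    c(fit, list(stages = stages, n_dropped = sum(!ok))),
    class = "fuzzy_trends"
  )
}

#' @export
print.fuzzy_trends <- function(x, ...) {
  cat("<fuzzy_trends> ", nrow(x$membership), " proteins, ",
      nrow(x$centroids), " clusters over ",
      paste(x$stages, collapse = " "), "\n", sep = "")
  cat("  iterations: ", x$iterations, "; objective: ",
      format(x$objective[length(x$objective)], digits = 6), "\n", sep = "")
  invisible(x)
}

#' Tidy fuzzy trend memberships
#' @param x A `fuzzy_trends` object.
#' @param ... Unused.
#' @return Long tibble: `protein_id`, `cluster`, `membership`,
#'   `hard_label` (TRUE on the argmax cluster).
#' @export
tidy.fuzzy_trends <- function(x, ...) {
  tibble::as_tibble(x$membership, rownames = "protein_id") |>
    pivot_longer(-"protein_id", names_to = "cluster",
                 values_to = "membership") |>
    group_by(.data$protein_id) |>
    mutate(hard_label = .data$membership == max(.data$membership)) |>
    ungroup()
}

#' One-row fuzzy clustering summary
#' @param x A `fuzzy_trends` object.
#' @param ... Unused.
#' @return Tibble with `n_proteins`, `n_clusters`, `iterations`,
#'   `objective`, `converged`, `n_dropped`.
#' @export
glance.fuzzy_trends <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x$membership),
    n_clusters = nrow(x$centroids),
    iterations = x$iterations,
    objective = x$objective[length(x$objective)],
    converged = x$converged,
    n_dropped = x$n_dropped
  )
}

#' @describeIn fuzzy_cmeans_trends Centroid trajectories per cluster.
#' @param object A `fuzzy_trends` object.
#' @param ... Unused.
#' @export
autoplot.fuzzy_trends <- function(object, ...) {
  cent <- tibble::as_tibble(object$centroids, rownames = "cluster") |>
    pivot_longer(-"cluster", names_to = "stage", values_to = "z") |>
    mutate(stage = stage_factor(.data$stage))
  ggplot2::ggplot(cent, ggplot2::aes(.data$stage, .data$z,
                                     group = .data$cluster,
                                     colour = .data$cluster)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "stage", y = "standardised log2 abundance") +
    ggplot2::theme_minimal()
}
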