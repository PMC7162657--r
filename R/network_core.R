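#' Construct a connectome object
#'
#' A connectome couples a symmetric, nonnegative, zero-diagonal weighted
#' adjacency matrix (e.g. a tractography connection-probability matrix) with
#' node labels and an a-priori node-to-system partition (e.g. seven functional
#' systems plus a subcortical block).
#'
#' @param weights N x N numeric matrix; symmetric, nonnegative, zero diagonal.
#' @param partition character vector of length N assigning each node to a
#'   system.
#' @param node_labels optional character vector of node names; defaults to
#'   `node_001 ...`.
#' @return An object of class `connectome` with elements `weights`,
#'   `node_labels`, `partition`.
#' @export
connectome <- function(weights, partition, node_labels = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("adjacency matrix must be square")
  if (max(abs(weights - t(weights))) > 0) stop("adjacency matrix must be symmetric")
  if (any(diag(weights) != 0)) stop("adjacency matrix must have a zero diagonal")
  if (any(weights < 0)) stop("adjacency weights must be nonnegative")
  if (any(!is.finite(weights))) stop("adjacency weights must be finite")
  partition <- as.character(partition)
  if (length(partition) != n) stop("partition must cover all nodes")
  if (is.null(node_labels)) node_labels <- sprintf("node_%03d", seq_len(n))
  if (length(node_labels) != n) stop("node_labels must have one entry per node")
  dimnames(weights) <- list(node_labels, node_labels)
  structure(list(weights = weights, node_labels = node_labels,
                 partition = partition),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome: %d nodes, %d systems, total strength %.4g\n",
              nrow(x$weights), length(unique(x$partition)),
              sum(x$weights[upper.tri(x$weights)])))
  invisible(x)
}

#' Normalize an adjacency matrix for control, controllability or modularity
#'
#' Three conventions used at different stages of the analysis:
#' \describe{
#'   \item{control}{`A / (1 + xi0) - I`, a continuous-time stable system
#'     matrix (all eigenvalues have negative real part). With
#'     `scaling = "literal"` the variant `A / xi0 - I` is returned instead,
#'     which leaves a marginally stable zero eigenvalue.}
#'   \item{modal}{`A / (1 + xi0)`, spectral radius below one, used for modal
#'     controllability.}
#'   \item{modularity}{`A / xi0`, nonnegative with spectral radius one, used
#'     before computing modularity so that scales are comparable across
#'     subjects without introducing negative weights.}
#' }
#' Here `xi0` is the largest eigenvalue (spectral radius) of the raw matrix.
#'
#' @param x a [connectome] or a symmetric numeric matrix.
#' @param mode one of `"control"`, `"modal"`, `"modularity"`.
#' @param scaling denominator convention for `mode = "control"`:
#'   `"one_plus"` (default, `1 + xi0`) or `"literal"` (`xi0`).
#' @return list of class `normalized_matrix` with `matrix`, `mode`,
#'   `spectral_radius`.
#' @export
normalize_adjacency <- function(x, mode = c("control", "modal", "modularity"),
                                scaling = c("one_plus", "literal")) {
  mode <- match.arg(mode)
  scaling <- match.arg(scaling)
  A <- if (inherits(x, "connectome")) x$weights else as.matrix(x)
  if (max(abs(A - t(A))) > 1e-10 * max(1, max(abs(A))))
    stop("adjacency must be symmetric")
  xi0 <- max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  if (xi0 <= 0) stop("degenerate input: spectral radius is not positive (all-zero matrix?)")
  m <- switch(mode,
    control = {
      denom <- if (scaling == "one_plus") 1 + xi0 else xi0
      A / denom - diag(nrow(A))
    },
    modal = A / (1 + xi0),
    modularity = A / xi0
  )
  structure(list(matrix = m, mode = mode, spectral_radius = xi0),
            class = "normalized_matrix")
}

#' Modal controllability of each node
#'
#' Summarizes each node's ability to push the system into difficult-to-reach
#' dynamic modes. For the eigenpairs `(lambda_j, v_j)` of the scaled symmetric
#' adjacency, the score of node `i` is
#' `phi_i = sum_j (1 - lambda_j^2) * v_{ij}^2`, so nodes aligned with fast
#' decaying (hard to reach) modes score high.
#'
#' @param normalized a `normalized_matrix` with `mode = "modal"`, or a
#'   symmetric matrix with spectral radius below one.
#' @return numeric vector of per-node scores in (0, 1].
#' @export
modal_controllability <- function(normalized) {
  m <- if (inherits(normalized, "normalized_matrix")) {
    if (normalized$mode != "modal")
      stop("modal controllability requires mode = \"modal\" normalization")
    normalized$matrix
  } else as.matrix(normalized)
  if (max(abs(m - t(m))) > 1e-10 * max(1, max(abs(m))))
    stop("modal controllability requires a symmetric matrix")
  e <- eigen(m, symmetric = TRUE)
  drop((e$vectors^2) %*% (1 - e$values^2))
}

#' Graph metrics against a fixed a-priori partition
#'
#' Computes the sensitivity-analysis covariates: per-node modal
#' controllability, Newman weighted modularity `Q` of the fixed partition (no
#' community detection; computed on the spectral-radius-scaled matrix, which
#' leaves `Q` unchanged because `Q` is scale invariant), per-node participation
#' coefficients `P_i = 1 - sum_s (k_is / k_i)^2`, and strength summaries
#' (within-target-system sum, target-system-to-other sum, total strength; each
#' undirected edge counted once).
#'
#' @param x a [connectome].
#' @param target_system system label used for the strength summaries
#'   (default `"fronto_parietal"`).
#' @return list of class `graph_metrics` with `modal_controllability`,
#'   `modularity_q`, `participation`, `system_strengths`, `total_strength`.
#' @export
graph_metrics <- function(x, target_system = "fronto_parietal") {
  stopifnot(inherits(x, "connectome"))
  A <- x$weights
  part <- x$partition
  if (!target_system %in% part)
    stop(sprintf("unknown system label '%s'", target_system))

  phi <- modal_controllability(normalize_adjacency(x, mode = "modal"))

  Am <- normalize_adjacency(x, mode = "modularity")$matrix
  two_m <- sum(Am)
  k <- rowSums(Am)
  q <- 0
  for (s in unique(part)) {
    idx <- part == s
    q <- q + sum(Am[idx, idx]) / two_m - (sum(k[idx]) / two_m)^2
  }

  strength <- rowSums(A)
  p <- rep(0, length(strength))
  pos <- strength > 0
  for (s in unique(part)) {
    idx <- part == s
    ks <- rowSums(A[, idx, drop = FALSE])
    p[pos] <- p[pos] + (ks[pos] / strength[pos])^2
  }
  p <- 1 - p
  p[!pos] <- 0  # isolated nodes: participation defined as 0
  if (any(!pos)) message(sprintf("%d isolated node(s); participation set to 0", sum(!pos)))

  ut <- upper.tri(A)
  in_t <- part == target_system
  within <- sum(A[in_t, in_t][upper.tri(A[in_t, in_t, drop = FALSE])])
  between <- sum(A[in_t, !in_t])
  structure(list(
    modal_controllability = phi,
    modularity_q = q,
    participation = p,
    system_strengths = c(within = within, between = between),
    total_strength = sum(A[ut])
  ), class = "graph_metrics")
}
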