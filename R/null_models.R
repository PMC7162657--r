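#' Degree- and strength-preserving surrogate network
#'
#' Produces a null connectome with randomized topology but identical degree
#' sequence and weight multiset, and an approximately preserved strength
#' sequence. The binary topology is randomized by Maslov-Sneppen
#' degree-preserving double-edge swaps; the original weights are then
#' re-assigned to the new edges by iterative rank matching against the
#' residual strength product of their endpoints. On graphs too small or too
#' dense for any swap (e.g. near-complete tractography matrices) the topology
#' is left unchanged and strength preservation comes from the weight
#' re-ranking alone, with a message.
#'
#' @param x a [connectome] with at least 4 edges.
#' @param seed optional integer seed.
#' @param n_swap_per_edge swap-attempt budget per edge (default 10).
#' @param refine_passes maximum swap-refinement sweeps polishing the
#'   strength sequence after the greedy assignment (default 20).
#' @return a surrogate [connectome].
#' @export
rewire_preserving_degree_strength <- function(x, seed = NULL,
                                              n_swap_per_edge = 10,
                                              refine_passes = 20) {
  stopifnot(inherits(x, "connectome"))
  if (!is.null(seed)) set.seed(seed)
  A <- x$weights
  n <- nrow(A)
  ut <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  m <- nrow(ut)
  if (m < 4) stop("graph must have at least 4 edges")
  w <- A[cbind(ut[, 1], ut[, 2])]

  g <- igraph::graph_from_edgelist(ut, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  g2 <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                 niter = n_swap_per_edge * m))
  el <- igraph::as_edgelist(g2, names = FALSE)
  el <- unname(cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  el0 <- unname(cbind(pmin(ut[, 1], ut[, 2]), pmax(ut[, 1], ut[, 2])))
  storage.mode(el) <- storage.mode(el0) <- "integer"
  same <- identical(el0[order(el0[, 1], el0[, 2]), , drop = FALSE],
                    el[order(el[, 1], el[, 2]), , drop = FALSE])
  if (same)
    message("graph admits no degree-preserving swap; ",
            "returning weight-permuted variant (strength re-ranking only)")

  w_new <- .assign_weights_rank(el[, 1], el[, 2], w, rowSums(A), refine_passes)
  B <- matrix(0, n, n)
  B[el] <- w_new
  B <- B + t(B)
  connectome(B, x$partition, x$node_labels)
}

#' Ensemble of surrogate networks
#'
#' @param x a [connectome].
#' @param n_null number of surrogates.
#' @param seed base seed; surrogate `k` uses `seed + k`.
#' @param n_swap_per_edge,refine_passes see
#'   [rewire_preserving_degree_strength].
#' @return list of class `null_ensemble` with `surrogates`, `seeds` and
#'   `preservation` (per-surrogate degree-match flag and strength
#'   correlation).
#' @export
null_ensemble <- function(x, n_null = 100, seed = 1L, n_swap_per_edge = 10,
                          refine_passes = 20) {
  seeds <- seed + seq_len(n_null)
  surrogates <- vector("list", n_null)
  degree_ok <- logical(n_null)
  strength_r <- numeric(n_null)
  deg0 <- rowSums(x$weights > 0)
  s0 <- rowSums(x$weights)
  n_vacuous <- 0L
  for (k in seq_len(n_null)) {
    s <- withCallingHandlers(
      rewire_preserving_degree_strength(x, seed = seeds[k],
                                        n_swap_per_edge = n_swap_per_edge,
                                        refine_passes = refine_passes),
      message = function(m) {
        n_vacuous <<- n_vacuous + 1L
        invokeRestart("muffleMessage")
      })
    surrogates[[k]] <- s
    degree_ok[k] <- identical(rowSums(s$weights > 0), deg0)
    strength_r[k] <- cor(s0, rowSums(s$weights))
  }
  if (n_vacuous > 0)
    message(sprintf(paste("%d/%d surrogate(s) admitted no degree-preserving",
                          "swap; weight re-ranking only"), n_vacuous, n_null))
  structure(list(surrogates = surrogates, seeds = seeds,
                 preservation = data.frame(degree_ok = degree_ok,
                                           strength_r = strength_r)),
            class = "null_ensemble")
}

#' Paired test of real versus null-network energy
#'
#' Paired t-test of per-subject mean null energy against real energy; the
#' mean difference is reported as null minus real, so a positive difference
#' means the empirical networks need less energy than their surrogates.
#'
#' @param real_energies,null_mean_energies paired per-subject vectors
#'   (length >= 3).
#' @return list with `t`, `df`, `p_value`, `mean_diff`.
#' @export
real_vs_null_energy_test <- function(real_energies, null_mean_energies) {
  if (length(real_energies) != length(null_mean_energies))
    stop("paired vectors must have equal length")
  if (length(real_energies) < 3) stop("need at least 3 pairs")
  d <- null_mean_energies - real_energies
  if (sd(d) == 0) stop("degenerate test: paired differences have zero variance")
  tt <- t.test(null_mean_energies, real_energies, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(d))
}

#' One-tailed permutation p-value for a null-network age effect
#'
#' The observed (signed) effect size is compared with the effects measured on
#' null networks; the p-value is the portion of null networks with an equal
#' or more negative effect, computed as `(k + 1) / (n + 1)` so that it can
#' never be zero.
#'
#' @param real_effect signed effect size (e.g. GAM Z or partial r) of the
#'   real network.
#' @param null_effects vector of effects from the null networks (length >= 1).
#' @return the one-tailed p-value.
#' @export
null_age_effect_test <- function(real_effect, null_effects) {
  if (length(null_effects) < 1) stop("need at least one null effect")
  k <- sum(null_effects <= real_effect)
  (k + 1) / (length(null_effects) + 1)
}
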