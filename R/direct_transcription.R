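#' Direct-transcription solution of the control problem
#'
#' An independent cross-check for [solve_optimal_control]: instead of the
#' costate shooting solution, the control input is discretized as piecewise
#' constant over `n_intervals` equal intervals, states are propagated with
#' the exact interval propagator, and the resulting finite-dimensional
#' quadratic program (running state cost + energy cost, terminal-state
#' equality constraint) is solved through its KKT system. As the number of
#' intervals grows this converges to the continuous optimum from above; it
#' shares no code path with the shooting solver and is intended for
#' validation on small systems (the dense KKT matrix has
#' `(n_intervals + constraints) * N` rows).
#'
#' @param task a [control_task].
#' @param n_intervals number of piecewise-constant control intervals
#'   (default 250).
#' @return list with `total_energy`, `inputs` (`n_intervals x N`), `states`
#'   (`(n_intervals + 1) x N`), `objective`.
#' @export
direct_transcription_energy <- function(task, n_intervals = 250) {
  stopifnot(inherits(task, "control_task"))
  A <- task$A
  n <- nrow(A)
  K <- as.integer(n_intervals)
  h <- task$horizon_T / K
  Bmat <- diag(as.numeric(task$b_mask), n)
  aug <- rbind(cbind(A, Bmat), matrix(0, n, 2 * n)) * h
  E <- as.matrix(Matrix::expm(Matrix::Matrix(aug)))
  Ad <- E[seq_len(n), seq_len(n), drop = FALSE]
  Bd <- E[seq_len(n), n + seq_len(n), drop = FALSE]   # int_0^h e^{As} ds B

  # G maps stacked inputs to stacked states x_1..x_K; row blocks built by
  # the recursion row_k = [Ad %*% row_{k-1}, Bd]
  G <- matrix(0, K * n, K * n)
  xfree <- matrix(0, K + 1, n)
  xfree[1, ] <- task$x0
  row_prev <- NULL
  for (k in seq_len(K)) {
    cols <- seq_len(k * n)
    if (k == 1) {
      G[seq_len(n), seq_len(n)] <- Bd
    } else {
      G[(k - 1) * n + seq_len(n), cols] <-
        cbind(Ad %*% row_prev, Bd)
    }
    row_prev <- G[(k - 1) * n + seq_len(n), cols, drop = FALSE]
    xfree[k + 1, ] <- Ad %*% xfree[k, ]
  }

  # trapezoid state-cost weights on knots 1..K (knot 0 is fixed at x0)
  tw <- rep(1, K); tw[K] <- 0.5
  w <- h * as.numeric(outer(as.numeric(task$s_mask), tw))  # node index fastest
  dev_free <- as.numeric(t(xfree[-1, , drop = FALSE])) -
    rep(task$xT, times = K)
  Gw <- G * sqrt(w)
  Hmat <- 2 * (crossprod(Gw) + task$rho * h * diag(K * n))
  g <- 2 * as.numeric(crossprod(G, w * dev_free))
  Cmat <- G[(K - 1) * n + seq_len(n), , drop = FALSE]
  rvec <- task$xT - xfree[K + 1, ]
  kkt <- rbind(cbind(Hmat, t(Cmat)),
               cbind(Cmat, matrix(0, n, n)))
  sol <- solve(kkt, c(-g, rvec))
  u <- matrix(sol[seq_len(K * n)], K, n, byrow = TRUE)
  u[, !task$b_mask] <- 0
  states <- xfree
  for (k in seq_len(K))
    states[k + 1, ] <- Ad %*% states[k, ] + Bd %*% u[k, ]
  dev <- sweep(states[-1, , drop = FALSE], 2, task$xT)
  obj <- sum(h * tw * rowSums(sweep(dev^2, 2, as.numeric(task$s_mask), "*"))) +
    task$rho * h * sum(u^2)
  list(total_energy = h * sum(u^2), inputs = u, states = states,
       objective = obj)
}
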