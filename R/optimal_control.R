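#' Build brain-state vectors
#'
#' A brain state is a length-N vector of per-region activity magnitudes. The
#' baseline state is all zeros; a system-indicator state puts `magnitude` on
#' the nodes of one system and zero elsewhere; a noisy state adds Gaussian
#' perturbation (sd `noise_sd`) around `magnitude` on the system nodes only,
#' leaving off-target nodes exactly zero; `continuous_from_file` loads an
#' arbitrary finite activation vector (e.g. a task-contrast map).
#'
#' @param partition character vector of node system labels.
#' @param kind one of `"baseline"`, `"system_indicator"`, `"noisy"`,
#'   `"continuous_from_file"`.
#' @param system system label for indicator/noisy kinds.
#' @param magnitude activation magnitude on the target system (default 1).
#' @param noise_sd Gaussian sd for the noisy kind (default 0.1).
#' @param count number of noisy states to draw (default 1).
#' @param seed optional integer seed for the noisy draws.
#' @param file path to a one-column text file for `continuous_from_file`.
#' @return a numeric vector, or a list of vectors when `kind = "noisy"` and
#'   `count > 1`.
#' @export
build_state <- function(partition,
                        kind = c("baseline", "system_indicator", "noisy",
                                 "continuous_from_file"),
                        system = "fronto_parietal", magnitude = 1,
                        noise_sd = 0.1, count = 1, seed = NULL, file = NULL) {
  kind <- match.arg(kind)
  n <- length(partition)
  if (kind == "baseline") return(numeric(n))
  if (kind == "continuous_from_file") {
    v <- as.numeric(utils::read.table(file)[[1]])
    if (length(v) != n) stop("vector length mismatch on file load")
    if (any(!is.finite(v))) stop("state vector must be finite")
    return(v)
  }
  if (!system %in% partition)
    stop(sprintf("unknown system label '%s'", system))
  idx <- partition == system
  base <- numeric(n)
  base[idx] <- magnitude
  if (kind == "system_indicator") return(base)
  if (!is.null(seed)) set.seed(seed)
  states <- lapply(seq_len(count), function(i) {
    v <- base
    v[idx] <- v[idx] + rnorm(sum(idx), 0, noise_sd)
    v
  })
  if (count == 1) states[[1]] else states
}

#' Define a multi-point optimal control task
#'
#' Specifies the transition problem: drive the linear system
#' `dx/dt = A x + B u` from `x0` to `xT` in time `horizon_T`, minimizing
#' `int_0^T (xT - x)' S (xT - x) + rho u'u dt` subject to the terminal
#' equality `x(T) = xT`. `B` is a 0-1 diagonal input matrix over the control
#' set (default all nodes) and `S` a 0-1 diagonal matrix over the constrained
#' set whose trajectory is penalized for straying from the target (default:
#' the target-system nodes).
#'
#' @param normalized_A a `normalized_matrix` with `mode = "control"` (see
#'   [normalize_adjacency]) or an equivalent stable matrix.
#' @param x0,xT initial and target states (length N).
#' @param constrained_set integer or logical index of the nodes entering the
#'   running state cost (`S`); must be nonempty.
#' @param control_set integer or logical index of control nodes (`B`);
#'   default all.
#' @param horizon_T time horizon (default 1).
#' @param rho energy penalty weight, must be positive (default 1).
#' @param dt integration step; `horizon_T / dt` must be an integer
#'   (default 0.001, i.e. 1,000 steps at the default horizon).
#' @return list of class `control_task`.
#' @export
control_task <- function(normalized_A, x0, xT, constrained_set,
                         control_set = NULL, horizon_T = 1, rho = 1,
                         dt = 0.001) {
  A <- if (inherits(normalized_A, "normalized_matrix")) {
    if (normalized_A$mode != "control")
      stop("control tasks require mode = \"control\" normalization")
    normalized_A$matrix
  } else as.matrix(normalized_A)
  n <- nrow(A)
  x0 <- as.numeric(x0); xT <- as.numeric(xT)
  if (length(x0) != n || length(xT) != n)
    stop("state vectors must match the network dimension")
  if (any(!is.finite(x0)) || any(!is.finite(xT))) stop("states must be finite")
  if (rho <= 0) stop("rho must be positive")
  if (dt <= 0) stop("dt must be positive")
  steps <- horizon_T / dt
  if (abs(steps - round(steps)) > 1e-8)
    stop("horizon_T / dt must be an integer number of steps")
  to_logical <- function(set) {
    out <- rep(FALSE, n)
    out[set] <- TRUE
    out
  }
  s_mask <- to_logical(constrained_set)
  if (!any(s_mask)) stop("constrained_set must be nonempty")
  b_mask <- if (is.null(control_set)) rep(TRUE, n) else to_logical(control_set)
  if (!any(b_mask)) stop("control_set must be nonempty")
  structure(list(A = A, x0 = x0, xT = xT, s_mask = s_mask, b_mask = b_mask,
                 horizon_T = horizon_T, rho = rho, dt = dt,
                 steps = as.integer(round(steps))),
            class = "control_task")
}

#' Assemble the augmented state-costate system
#'
#' The Pontryagin stationarity conditions couple the state `x` and costate
#' `p` into one affine linear system `d/dt [x; p] = A_tilde [x; p] + b_tilde`
#' with
#' `A_tilde = [[A, -BB'/(2 rho)], [-2S, -A']]` and `b_tilde = [0; 2 S xT]`.
#' Its matrix exponential at the horizon provides the shooting solution for
#' `p(0)`. The particular solution `c = A_tilde^{-1} (e^{A_tilde T} - I)
#' b_tilde` is obtained by a linear solve, never an explicit inverse.
#'
#' @param task a [control_task].
#' @return list of class `augmented_system` with `a_tilde`, `b_tilde`,
#'   `expm_blocks` (E11, E12, E21, E22), `c_split` (c1, c2) and
#'   `e12_condition`.
#' @export
build_augmented_system <- function(task) {
  stopifnot(inherits(task, "control_task"))
  A <- task$A
  n <- nrow(A)
  bb <- diag(as.numeric(task$b_mask), n)      # B B' for 0-1 diagonal B
  S <- diag(as.numeric(task$s_mask), n)
  at <- rbind(cbind(A, -bb / (2 * task$rho)),
              cbind(-2 * S, -t(A)))
  bt <- c(numeric(n), 2 * (as.numeric(task$s_mask) * task$xT))
  eAT <- as.matrix(Matrix::expm(Matrix::Matrix(at * task$horizon_T)))
  rhs <- (eAT - diag(2 * n)) %*% bt
  cvec <- tryCatch(solve(at, rhs),
                   error = function(e) stop("augmented system is numerically singular: ",
                                            conditionMessage(e)))
  resid <- max(abs(at %*% cvec - rhs))
  if (resid > 1e-8 * max(1, sqrt(sum(bt^2))))
    stop("particular-solution residual too large; system ill conditioned")
  E12 <- eAT[seq_len(n), n + seq_len(n), drop = FALSE]
  cond <- kappa(E12, exact = FALSE)
  if (!is.finite(cond) || cond > 1e12)
    stop("shooting matrix E12 is ill conditioned (kappa > 1e12); ",
         "consider a larger rho or shorter horizon")
  structure(list(
    a_tilde = at, b_tilde = bt,
    expm_blocks = list(E11 = eAT[seq_len(n), seq_len(n), drop = FALSE],
                       E12 = E12,
                       E21 = eAT[n + seq_len(n), seq_len(n), drop = FALSE],
                       E22 = eAT[n + seq_len(n), n + seq_len(n), drop = FALSE]),
    c_split = list(c1 = cvec[seq_len(n)], c2 = cvec[n + seq_len(n)]),
    e12_condition = cond
  ), class = "augmented_system")
}

#' Solve the optimal control problem
#'
#' Shooting solution of the two-point boundary value problem: the initial
#' costate is `p(0) = E12^{-1} (xT - E11 x0 - c1)`, after which the augmented
#' state is propagated forward with the exact one-step propagator
#' `z_{k+1} = e^{A_tilde dt} z_k + c_dt` (exact discretization of the affine
#' system; no Euler error). The optimal input is `u* = -(1/(2 rho)) B' p*`,
#' and per-node energies `E_i = int_0^T u_i^2 dt` are computed by trapezoidal
#' quadrature on the stored grid.
#'
#' @param task a [control_task].
#' @return list of class `control_solution` with trajectories `states`,
#'   `costates`, `inputs` (each `(steps+1) x N`), `nodal_energy`,
#'   `total_energy`, `distance_series` (Euclidean distance to target over the
#'   constrained set at every grid point), `terminal_error`
#'   (max-norm of `x(T) - xT`) and `times`.
#' @export
solve_optimal_control <- function(task) {
  stopifnot(inherits(task, "control_task"))
  aug <- build_augmented_system(task)
  n <- nrow(task$A)
  eb <- aug$expm_blocks
  p0 <- solve(eb$E12, task$xT - eb$E11 %*% task$x0 - aug$c_split$c1)

  Ed <- as.matrix(Matrix::expm(Matrix::Matrix(aug$a_tilde * task$dt)))
  cd <- solve(aug$a_tilde, (Ed - diag(2 * n)) %*% aug$b_tilde)

  steps <- task$steps
  z <- matrix(0, steps + 1L, 2 * n)
  z[1L, ] <- c(task$x0, p0)
  for (k in seq_len(steps)) {
    z[k + 1L, ] <- Ed %*% z[k, ] + cd
    if (any(!is.finite(z[k + 1L, ])))
      stop("numerical failure: non-finite values during propagation")
  }
  states <- z[, seq_len(n), drop = FALSE]
  costates <- z[, n + seq_len(n), drop = FALSE]
  inputs <- -costates / (2 * task$rho)
  inputs[, !task$b_mask] <- 0

  tgrid <- seq(0, task$horizon_T, by = task$dt)
  u2 <- inputs^2
  # trapezoid weights over the stored grid
  w <- rep(task$dt, steps + 1L); w[c(1L, steps + 1L)] <- task$dt / 2
  nodal_energy <- as.numeric(crossprod(u2, w))
  d <- states[, task$s_mask, drop = FALSE] -
    matrix(task$xT[task$s_mask], steps + 1L, sum(task$s_mask), byrow = TRUE)
  distance_series <- sqrt(rowSums(d^2))
  structure(list(
    states = states, costates = costates, inputs = inputs,
    nodal_energy = nodal_energy, total_energy = sum(nodal_energy),
    distance_series = distance_series,
    terminal_error = max(abs(states[steps + 1L, ] - task$xT)),
    times = tgrid, task = task, e12_condition = aug$e12_condition
  ), class = "control_solution")
}

#' Summaries of a solved control trajectory
#'
#' Aggregates the per-node energies to system level (mean over the nodes of
#' each system), reports the whole-brain mean energy, and the total trajectory
#' distance (sum of the distance series over all stored time points).
#'
#' @param solution a `control_solution`.
#' @param partition character vector of node system labels.
#' @return list with `nodal_energy`, `system_energy` (named means),
#'   `whole_brain_energy`, `total_distance`, `terminal_error`.
#' @export
summarize_trajectory <- function(solution, partition) {
  stopifnot(inherits(solution, "control_solution"))
  e <- solution$nodal_energy
  if (length(partition) != length(e))
    stop("partition must match the network dimension")
  sys <- tapply(e, partition, mean)
  list(nodal_energy = e,
       system_energy = sys[unique(partition)],
       whole_brain_energy = mean(e),
       total_distance = sum(solution$distance_series),
       terminal_error = solution$terminal_error)
}

#' Control energy for every subject of a cohort
#'
#' Convenience wrapper running the full per-subject analysis: normalize each
#' connectome (`control` mode), build the baseline and target-system indicator
#' states, solve the optimal control problem and aggregate energies.
#'
#' @param connectomes list of [connectome] objects sharing one partition.
#' @param target_system system label activated in the target state.
#' @param constrain `"target_system"` (penalize only target-system nodes; the
#'   default) or `"all"` (whole-brain state cost).
#' @param xT optional explicit target state overriding the indicator state.
#' @param x0 optional explicit initial state (default baseline zeros).
#' @param rho,horizon_T,dt solver parameters, see [control_task].
#' @return list with `nodal` (subjects x nodes energy matrix), `system`
#'   (subjects x systems), `whole_brain`, `total_distance`, `terminal_error`
#'   vectors.
#' @export
cohort_control_energy <- function(connectomes, target_system = "fronto_parietal",
                                  constrain = c("target_system", "all"),
                                  xT = NULL, x0 = NULL,
                                  rho = 1, horizon_T = 1, dt = 0.001) {
  constrain <- match.arg(constrain)
  part <- connectomes[[1]]$partition
  n <- length(part)
  if (is.null(x0)) x0 <- build_state(part, "baseline")
  if (is.null(xT)) xT <- build_state(part, "system_indicator", system = target_system)
  s_set <- if (constrain == "all") seq_len(n) else which(part == target_system)
  nodal <- matrix(NA_real_, length(connectomes), n)
  tdist <- terr <- numeric(length(connectomes))
  systems <- unique(part)
  sysmat <- matrix(NA_real_, length(connectomes), length(systems),
                   dimnames = list(NULL, systems))
  for (i in seq_along(connectomes)) {
    An <- normalize_adjacency(connectomes[[i]], mode = "control")
    sol <- solve_optimal_control(control_task(An, x0, xT, constrained_set = s_set,
                                              horizon_T = horizon_T, rho = rho, dt = dt))
    sm <- summarize_trajectory(sol, part)
    nodal[i, ] <- sm$nodal_energy
    sysmat[i, ] <- sm$system_energy[systems]
    tdist[i] <- sm$total_distance
    terr[i] <- sm$terminal_error
  }
  colnames(nodal) <- connectomes[[1]]$node_labels
  list(nodal = nodal, system = sysmat, whole_brain = rowMeans(nodal),
       total_distance = tdist, terminal_error = terr)
}
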