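# Finite-horizon controllability Gramians, minimum control energy,
# persistence energy, per-node control input and node-removal control impact
# for the linear system dx/dt = A x + B u.

.as_A <- function(A) {
  if (inherits(A, "dynamics_matrix")) A$A
  else if (is.matrix(A) && is.numeric(A)) A
  else stop("`A` must be a dynamics_matrix or a numeric matrix")
}

.expm <- function(M) as.matrix(Matrix::expm(Matrix::Matrix(M)))

.is_symmetric <- function(M) isSymmetric(M, tol = 1e-12)

# Default actuator matrix: identity (every node receives its own input).
.as_B <- function(B, n) {
  if (is.null(B)) return(diag(n))
  B <- as.matrix(B)
  if (nrow(B) != n) stop("B has ", nrow(B), " rows for an ", n, "-node system")
  if (any(colSums(abs(B)) == 0)) stop("B has an all-zero column")
  B
}

#' Finite-horizon controllability Gramian
#'
#' Computes `Wc(T) = integral_0^T exp(A t) B B' exp(A' t) dt`, the matrix
#' whose inverse quadratic form gives the minimum control energy of a state
#' transition over horizon `T`.
#'
#' Methods: `"block_expm"` (default) evaluates the integral exactly through
#' one matrix exponential of the `2n x 2n` block matrix
#' `[[-A, BB'], [0, A']]` (Van Loan construction); `"quadrature"` integrates
#' `exp(At) BB' exp(A't)` on a uniform grid by composite Simpson's rule;
#' `"spectral"` uses the eigendecomposition of `A` and is exact, but only
#' valid for symmetric `A` with `B` the identity (the package default
#' dynamics), where `Wc = V diag((exp(2 lambda T) - 1) / (2 lambda)) V'`.
#'
#' @param A A `dynamics_matrix` (see [normalize_dynamics()]) or a stable
#'   numeric matrix.
#' @param T Time horizon, `>= 0` (model time units).
#' @param B Actuator matrix (`n x m`); `NULL` means the identity.
#' @param method `"block_expm"`, `"quadrature"` or `"spectral"`.
#' @param n_quad Grid size for `"quadrature"` (forced odd; default 501).
#' @return Object of class `gramian`: list with `Wc` (symmetric positive
#'   semidefinite `n x n`), `T` and `method`.
#' @export
controllability_gramian <- function(A, T, B = NULL,
                                    method = c("block_expm", "quadrature",
                                               "spectral"),
                                    n_quad = 501) {
  method <- match.arg(method)
  A <- .as_A(A)
  n <- nrow(A)
  if (!is.numeric(T) || length(T) != 1 || T < 0)
    stop("horizon T must be a single number >= 0")
  B <- .as_B(B, n)
  if (T == 0) {
    Wc <- matrix(0, n, n)
  } else if (method == "block_expm") {
    BBt <- B %*% t(B)
    C <- rbind(cbind(-A, BBt),
               cbind(matrix(0, n, n), t(A)))
    Fm <- .expm(C * T)
    F12 <- Fm[seq_len(n), n + seq_len(n), drop = FALSE]
    F22 <- Fm[n + seq_len(n), n + seq_len(n), drop = FALSE]
    Wc <- t(F22) %*% F12
  } else if (method == "quadrature") {
    if (n_quad %% 2 == 0) n_quad <- n_quad + 1
    dt <- T / (n_quad - 1)
    Edt <- .expm(A * dt)
    BBt <- B %*% t(B)
    Ek <- diag(n)
    acc <- matrix(0, n, n)
    # Simpson weights 1,4,2,...,4,1
    for (k in seq_len(n_quad)) {
      wk <- if (k == 1 || k == n_quad) 1 else if (k %% 2 == 0) 4 else 2
      acc <- acc + wk * (Ek %*% BBt %*% t(Ek))
      if (k < n_quad) Ek <- Ek %*% Edt
    }
    Wc <- acc * dt / 3
  } else {
    if (!.is_symmetric(A))
      stop("spectral method requires a symmetric A")
    if (!isTRUE(all.equal(B, diag(n), tolerance = 1e-12)))
      stop("spectral method requires B = identity")
    eg <- eigen(A, symmetric = TRUE)
    lam <- eg$values
    g <- ifelse(abs(lam) < 1e-14, T, (exp(2 * lam * T) - 1) / (2 * lam))
    Wc <- eg$vectors %*% (g * t(eg$vectors))
  }
  Wc <- (Wc + t(Wc)) / 2
  dimnames(Wc) <- dimnames(A)
  structure(list(Wc = Wc, T = T, method = method), class = "gramian")
}

# Symmetric inverse with condition-number guard. Returns list(solve =
# function(v), condition).
.gramian_inverse <- function(Wc, cond_limit = 1e12) {
  eg <- eigen(Wc, symmetric = TRUE)
  d <- eg$values
  if (min(d) < -1e-10 * max(abs(d)))
    stop("Gramian is not positive semidefinite (min eigenvalue ", min(d), ")")
  cond <- max(d) / max(min(d), .Machine$double.xmin)
  if (min(d) <= 0 || cond > cond_limit)
    stop(sprintf("Gramian is numerically singular (condition number %.3g > %.3g)",
                 cond, cond_limit))
  V <- eg$vectors
  list(solve = function(v) V %*% ((t(V) %*% v) / d), condition = cond)
}

#' Minimum control energy of a state transition
#'
#' For the linear system `dx/dt = A x + B u`, computes the control input of
#' least integrated squared magnitude that drives the state from `x0` at
#' time 0 to `xf` at time `T`:
#' `E = v' Wc(T)^{-1} v` with boundary mismatch `v = xf - exp(A T) x0`, and
#' optimal input `u*(t) = B' exp(A'(T - t)) Wc(T)^{-1} v`.
#'
#' @param A `dynamics_matrix` or stable numeric matrix.
#' @param x0,xf Initial and target state vectors (or `brain_state` objects).
#' @param T Horizon, `> 0`.
#' @param B Actuator matrix; `NULL` = identity.
#' @param n_steps Trajectory grid size (default 1001).
#' @param method Gramian method, passed to [controllability_gramian()];
#'   `"auto"` picks `"spectral"` for symmetric `A` with identity `B`, else
#'   `"block_expm"`.
#' @param trajectories If `FALSE`, skip the input/state trajectories and
#'   per-node input quadrature and return only the energy (fast path for
#'   large batch computations).
#' @param cond_limit Condition-number guard for Gramian inversion.
#' @return Object of class `energy_result`: `energy` (scalar `E >= 0`),
#'   `node_input` (per-actuator integral of `u_i(t)^2`, sums to `E` when `B`
#'   is the identity), `u_traj` (`m x n_steps`), `x_traj` (`n x n_steps`),
#'   `times`, `v`, `gramian_condition`.
#' @export
min_control_energy <- function(A, x0, xf, T, B = NULL, n_steps = 1001,
                               method = c("auto", "block_expm", "quadrature",
                                          "spectral"),
                               trajectories = TRUE, cond_limit = 1e12) {
  method <- match.arg(method)
  Am <- .as_A(A)
  n <- nrow(Am)
  if (inherits(x0, "brain_state")) x0 <- x0$values
  if (inherits(xf, "brain_state")) xf <- xf$values
  if (length(x0) != n || length(xf) != n)
    stop(sprintf("state length (%d, %d) does not match system size %d",
                 length(x0), length(xf), n))
  if (T <= 0) stop("horizon T must be > 0")
  B <- .as_B(B, n)
  m <- ncol(B)
  identB <- m == n && isTRUE(all.equal(B, diag(n), tolerance = 1e-12))
  if (method == "auto")
    method <- if (.is_symmetric(Am) && identB) "spectral" else "block_expm"
  gr <- controllability_gramian(Am, T, B, method)
  inv <- .gramian_inverse(gr$Wc, cond_limit)
  eAT <- .expm(Am * T)
  v <- as.numeric(xf - eAT %*% x0)
  z <- as.numeric(inv$solve(v))
  energy <- sum(v * z)
  res <- list(energy = energy, v = v, T = T,
              gramian_condition = inv$condition, method = method)
  if (trajectories) {
    times <- seq(0, T, length.out = n_steps)
    dt <- times[2] - times[1]
    # w_k = exp(A'(T - t_k)) z, filled backwards from w(T) = z
    EdtT <- .expm(t(Am) * dt)
    Wmat <- matrix(0, n, n_steps)
    Wmat[, n_steps] <- z
    for (k in seq(n_steps - 1, 1))
      Wmat[, k] <- EdtT %*% Wmat[, k + 1]
    U <- t(B) %*% Wmat
    X <- simulate_trajectory(Am, B, U, x0, T)
    node_input <- .trapz_rows(U^2, dt)
    names(node_input) <- colnames(B) %||% rownames(Am)[seq_len(m)]
    res$u_traj <- U
    res$x_traj <- X
    res$times <- times
    res$node_input <- node_input
  }
  structure(res, class = "energy_result")
}

#' @export
print.energy_result <- function(x, ...) {
  cat(sprintf("energy_result: E = %.6g (T = %g, Gramian condition %.3g)\n",
              x$energy, x$T, x$gramian_condition))
  invisible(x)
}

.trapz_rows <- function(M, dt) {
  K <- ncol(M)
  dt * (rowSums(M) - (M[, 1] + M[, K]) / 2)
}

#' Persistence energy of a brain state
#'
#' The persistence energy `Pe` is the minimum control energy required to
#' maintain a state over the horizon: the self-transition `x0 = xf = x` of
#' [min_control_energy()]. Because the free dynamics decay, holding a
#' nonzero activation pattern requires continuous input; `Pe` quantifies the
#' magnitude of that theoretical input and scales with the square of the
#' state amplitude.
#'
#' @inheritParams min_control_energy
#' @param x State vector or `brain_state`.
#' @return An `energy_result`; its `energy` field is `Pe`.
#' @export
persistence_energy <- function(A, x, T = 1.0, B = NULL, n_steps = 1001,
                               method = "auto", trajectories = TRUE,
                               cond_limit = 1e12) {
  min_control_energy(A, x0 = x, xf = x, T = T, B = B, n_steps = n_steps,
                     method = method, trajectories = trajectories,
                     cond_limit = cond_limit)
}

#' Persistence energy for a batch of states on a fixed system
#'
#' Factorizes the Gramian and state-transition matrix once and evaluates
#' `Pe = v' Wc^{-1} v` per state, so cohort-scale energy tables stay cheap.
#' Requires `B = identity` (the package default actuation).
#'
#' @param A `dynamics_matrix` or stable numeric matrix.
#' @param states List of `brain_state` objects (with complete meta).
#' @param T Horizon.
#' @param method Gramian method (default `"auto"`).
#' @return Data frame with one row per state: meta columns plus `energy`.
#' @export
persistence_energy_set <- function(A, states, T = 1.0, method = "auto") {
  Am <- .as_A(A)
  n <- nrow(Am)
  if (method == "auto")
    method <- if (.is_symmetric(Am)) "spectral" else "block_expm"
  gr <- controllability_gramian(Am, T, NULL, method)
  inv <- .gramian_inverse(gr$Wc)
  eAT <- .expm(Am * T)
  rows <- lapply(states, function(s) {
    x <- if (inherits(s, "brain_state")) s$values else as.numeric(s)
    if (length(x) != n) stop("state length does not match system size")
    v <- x - as.numeric(eAT %*% x)
    e <- sum(v * inv$solve(v))
    m <- if (inherits(s, "brain_state")) s$meta else list()
    data.frame(subject = m$subject %||% NA_character_,
               group = m$group %||% NA_character_,
               drug = m$drug %||% NA_character_,
               task = m$task %||% NA_character_,
               condition = m$condition %||% NA_character_,
               energy = e, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Node-removal control impact
#'
#' Measures each node's importance for maintaining a state by iteratively
#' removing it from the network and recomputing the persistence energy. In
#' the default `"remove_node"` mode node `i` is deleted from the raw weight
#' matrix, the dynamics are re-normalized on the reduced weights (reduced
#' largest eigenvalue), and the state and actuators are truncated to the
#' remaining nodes. In `"remove_actuator"` mode only column `i` of the
#' identity actuator matrix is dropped, leaving network and state intact.
#'
#' Impact is relative: `impact_i = (Pe_without_i - Pe_full) / Pe_full`.
#'
#' @param network A [structural_network()] (raw weights; re-normalized per
#'   removal).
#' @param x State vector or `brain_state` on the same labels.
#' @param T Horizon (default 1).
#' @param c Stabilization constant for [normalize_dynamics()] (default 1).
#' @param mode `"remove_node"` (default) or `"remove_actuator"`.
#' @param cond_limit Gramian condition guard; a node whose removal makes the
#'   reduced Gramian numerically singular gets an `NA` impact and a warning.
#' @return Object of class `control_impact_map`: `impact` (named vector),
#'   `baseline_energy`, `definition_tag`.
#' @export
control_impact <- function(network, x, T = 1.0, c = 1.0,
                           mode = c("remove_node", "remove_actuator"),
                           cond_limit = 1e12) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "structural_network"))
  if (inherits(x, "brain_state")) {
    if (!identical(x$labels, network$labels))
      stop("state labels do not match network labels")
    x <- x$values
  }
  n <- network$n_nodes
  if (n < 2) stop("need at least 2 nodes")
  if (length(x) != n) stop("state length does not match network size")
  dyn <- normalize_dynamics(network, c)
  pe_full <- persistence_energy(dyn, x, T, trajectories = FALSE,
                                cond_limit = cond_limit)$energy
  if (pe_full == 0)
    stop("baseline persistence energy is 0; relative impact undefined ",
         "(consider an absolute measure)")
  impact <- rep(NA_real_, n)
  names(impact) <- network$labels
  for (i in seq_len(n)) {
    pe_i <- tryCatch({
      if (mode == "remove_node") {
        wr <- network$weights[-i, -i, drop = FALSE]
        netr <- structural_network(wr, network$labels[-i])
        dynr <- normalize_dynamics(netr, c)
        persistence_energy(dynr, x[-i], T, trajectories = FALSE,
                           cond_limit = cond_limit)$energy
      } else {
        Bi <- diag(n)[, -i, drop = FALSE]
        persistence_energy(dyn, x, T, B = Bi, method = "block_expm",
                           trajectories = FALSE,
                           cond_limit = cond_limit)$energy
      }
    }, error = function(e) {
      warning(sprintf("impact for node %s unavailable: %s",
                      network$labels[i], conditionMessage(e)), call. = FALSE)
      NA_real_
    })
    impact[i] <- (pe_i - pe_full) / pe_full
  }
  structure(list(impact = impact, baseline_energy = pe_full,
                 definition_tag = paste0("relative_", mode)),
            class = "control_impact_map")
}

#' @export
print.control_impact_map <- function(x, ...) {
  cat(sprintf("control_impact_map (%s): %d nodes, baseline Pe = %.6g\n",
              x$definition_tag, length(x$impact), x$baseline_energy))
  top <- sort(x$impact, decreasing = TRUE)
  top <- top[seq_len(min(3, length(top)))]
  cat("  top impact:", paste(sprintf("%s=%.3g", names(top), top),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Forward-simulate the controlled linear system
#'
#' Integrates `dx/dt = A x + B u` for a sampled input on a uniform grid,
#' using the exact state-transition matrix per step and trapezoidal
#' treatment of the input (second-order accurate). Used to verify that the
#' optimal input actually reaches the target state.
#'
#' @param A `dynamics_matrix` or numeric matrix.
#' @param B Actuator matrix; `NULL` = identity.
#' @param u_samples `m x n_steps` input samples on the uniform grid over
#'   `[0, T]` (a vector is treated as one row).
#' @param x0 Initial state.
#' @param T Horizon.
#' @return `n x n_steps` state trajectory; column `k` is `x(t_k)`.
#' @export
simulate_trajectory <- function(A, B = NULL, u_samples, x0, T) {
  Am <- .as_A(A)
  n <- nrow(Am)
  B <- .as_B(B, n)
  if (is.null(dim(u_samples))) u_samples <- matrix(u_samples, nrow = 1)
  if (nrow(u_samples) != ncol(B))
    stop("u_samples rows (", nrow(u_samples), ") must match B columns (",
         ncol(B), ")")
  K <- ncol(u_samples)
  if (K < 2) stop("need at least 2 input samples")
  dt <- T / (K - 1)
  Ed <- .expm(Am * dt)
  Bu <- B %*% u_samples
  X <- matrix(0, n, K)
  X[, 1] <- x0
  for (k in seq_len(K - 1))
    X[, k + 1] <- Ed %*% (X[, k] + (dt / 2) * Bu[, k]) + (dt / 2) * Bu[, k + 1]
  X
}

#' Integrated squared input from trajectory samples
#'
#' Composite-trapezoid estimate of `integral u(t)' u(t) dt` from samples on
#' a uniform grid.
#'
#' @param u_samples `m x K` input samples (vector = one row).
#' @param dt Grid spacing, `> 0`.
#' @return Scalar energy estimate.
#' @export
energy_from_trajectory <- function(u_samples, dt) {
  if (dt <= 0) stop("dt must be > 0")
  if (is.null(dim(u_samples))) u_samples <- matrix(u_samples, nrow = 1)
  s <- colSums(u_samples^2)
  K <- length(s)
  dt * (sum(s) - (s[1] + s[K]) / 2)
}
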