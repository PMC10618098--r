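# Test fixtures and independent oracles. Everything here is deliberately
# naive and separate from the package's computation paths.

expm_dense <- function(M) as.matrix(Matrix::expm(Matrix::Matrix(M)))

# Random valid structural network (symmetric, non-negative, zero diagonal).
random_network <- function(n, seed, density = 0.5) {
  set.seed(seed)
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  vals <- ifelse(runif(sum(up)) < density, rexp(sum(up)), 0)
  w[up] <- vals
  w <- w + t(w)
  structural_network(w)
}

# Random stable system matrix: normalized network dynamics (symmetric) or a
# diagonally shifted random matrix (nonsymmetric).
random_stable_A <- function(n, seed, symmetric = TRUE) {
  if (symmetric) {
    normalize_dynamics(random_network(n, seed))$A
  } else {
    set.seed(seed)
    M <- matrix(rnorm(n * n, sd = 0.3), n)
    M - diag(n) * (max(abs(eigen(M, only.values = TRUE)$values)) + 0.5)
  }
}

# Brute-force minimum-energy oracle: exact zero-order-hold discretization of
# dx/dt = Ax + Bu over K steps, minimum-norm piecewise-constant input via the
# discrete reachability Gramian. Returns the integrated squared input
# dt * v' (sum_j Ad^j Bd Bd' Ad'^j)^{-1} v with v = xf - Ad^K x0.
discretized_min_energy <- function(A, B, x0, xf, T, K = 2000) {
  n <- nrow(A)
  dt <- T / K
  blk <- rbind(cbind(A, B), matrix(0, ncol(B), n + ncol(B)))
  E <- expm_dense(blk * dt)
  Ad <- E[seq_len(n), seq_len(n), drop = FALSE]
  Bd <- E[seq_len(n), n + seq_len(ncol(B)), drop = FALSE]
  S <- Bd %*% t(Bd)
  G <- matrix(0, n, n)
  xK <- x0
  for (j in seq_len(K)) {
    G <- G + S
    S <- Ad %*% S %*% t(Ad)
    xK <- Ad %*% xK
  }
  v <- xf - as.numeric(xK)
  dt * sum(v * solve(G, v))
}

# Brute-force control impact: rebuild every reduced problem from scratch
# using only the Gramian definition (quadrature) and a plain solve().
bruteforce_impact <- function(network, x, T = 1, c = 1) {
  pe_naive <- function(w, xv) {
    lam <- max(eigen(w, symmetric = TRUE, only.values = TRUE)$values)
    A <- w / (lam + c) - diag(nrow(w))
    Wc <- controllability_gramian(A, T, method = "quadrature", n_quad = 2001)$Wc
    v <- xv - as.numeric(expm_dense(A * T) %*% xv)
    sum(v * solve(Wc, v))
  }
  base <- pe_naive(network$weights, x)
  vapply(seq_len(network$n_nodes), function(i) {
    (pe_naive(network$weights[-i, -i], x[-i]) - base) / base
  }, 0)
}

# One-cell crossover data frame with a known outcome structure.
make_crossover_df <- function(n_per_group, subject_effect, noise_sd,
                              g01 = 0, b1 = 0, g11 = 0, seed = 1) {
  set.seed(seed)
  subs <- c(sprintf("c%02d", seq_len(n_per_group)),
            sprintf("r%02d", seq_len(n_per_group)))
  grp <- rep(c("control", "relative"), each = n_per_group)
  off <- rnorm(2 * n_per_group, 0, subject_effect)
  do.call(rbind, lapply(seq_along(subs), function(i) {
    do.call(rbind, lapply(c("placebo", "alprazolam"), function(d) {
      mu <- 1 + g01 * (grp[i] == "relative") + b1 * (d == "alprazolam") +
        g11 * (grp[i] == "relative") * (d == "alprazolam")
      data.frame(subject = subs[i], group = grp[i], drug = d,
                 energy = mu + off[i] + rnorm(1, 0, noise_sd),
                 stringsAsFactors = FALSE)
    }))
  }))
}

# Small calibrated cohort (the acceptance-scale synthetic world): 20+20
# subjects, 100 nodes. Returns the threat-memory energy table plus pieces.
calibrated_cohort_energy <- function(seed, delta = 0.06, n_nodes = 100,
                                     n_per_group = 20) {
  cfg <- cohort_config(n_controls = n_per_group, n_relatives = n_per_group,
                       n_nodes = n_nodes, delta_interaction = delta,
                       seed = seed)
  net <- generate_connectome(n_nodes, density = 0.3, seed = seed + 500000L)
  st <- generate_states(cfg, net)
  dyn <- normalize_dynamics(net)
  tm <- Filter(function(s) s$meta$task == "memory" &&
                 s$meta$condition == "threat", st$states)
  list(config = cfg, network = net, dyn = dyn, states = st$states,
       threat_memory = tm,
       energy = persistence_energy_set(dyn, tm, T = 1))
}

gamma11_of <- function(fit) {
  co <- fit$coefficients
  co[co$symbol == "gamma11", c("estimate", "p")]
}
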