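test_that("Gramian methods agree with each other and with the scalar law", {
  # 1-node system a = -1, b = 1: Wc(T) = (1 - e^{-2T})/2
  A1 <- matrix(-1, 1, 1)
  for (T in c(0.5, 1, 2)) {
    expect_equal(controllability_gramian(A1, T)$Wc[1, 1],
                 (1 - exp(-2 * T)) / 2, tolerance = 1e-12)
  }
  expect_equal(controllability_gramian(A1, 0)$Wc, matrix(0, 1, 1))

  for (seed in 1:6) {
    n <- sample(3:20, 1)
    sym <- seed %% 2 == 0
    A <- random_stable_A(n, seed, symmetric = sym)
    T <- c(0.5, 1, 3)[1 + seed %% 3]
    g1 <- controllability_gramian(A, T, method = "block_expm")$Wc
    g2 <- controllability_gramian(A, T, method = "quadrature")$Wc
    expect_lt(norm(g1 - g2, "F") / norm(g1, "F"), 1e-8)
    if (sym) {
      g3 <- controllability_gramian(A, T, method = "spectral")$Wc
      expect_lt(norm(g1 - g3, "F") / norm(g1, "F"), 1e-10)
    }
    # symmetric PSD always
    expect_true(isSymmetric(g1, tol = 1e-10))
    ev <- eigen(g1, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10 * max(ev))
  }
  expect_error(controllability_gramian(matrix(-1, 1, 1), -1), ">= 0")
})

test_that("minimum control energy matches the discretized least-norm oracle", {
  for (seed in 1:6) {
    n <- sample(3:8, 1)
    A <- random_stable_A(n, seed, symmetric = seed %% 2 == 0)
    set.seed(seed + 50)
    x0 <- rnorm(n); xf <- rnorm(n)
    res <- min_control_energy(A, x0, xf, T = 1, trajectories = FALSE)
    oracle <- discretized_min_energy(A, diag(n), x0, xf, T = 1, K = 2000)
    expect_equal(res$energy, oracle, tolerance = 1e-5)
  }
})

test_that("optimal control reaches the target and its energy is consistent", {
  A <- random_stable_A(6, 17)
  set.seed(99)
  x0 <- rnorm(6); xf <- rnorm(6)
  res <- min_control_energy(A, x0, xf, T = 1, n_steps = 1001)
  xT <- res$x_traj[, ncol(res$x_traj)]
  expect_lt(max(abs(xT - xf)) / max(abs(xf)), 1e-4)
  dt <- res$times[2] - res$times[1]
  expect_equal(energy_from_trajectory(res$u_traj, dt), res$energy,
               tolerance = 1e-5)
  expect_equal(sum(res$node_input), res$energy, tolerance = 1e-6)

  # free drift: zero energy, zero input
  xf_free <- as.numeric(expm_dense(A * 1) %*% x0)
  free <- min_control_energy(A, x0, xf_free, T = 1)
  expect_lt(free$energy, 1e-10)
  expect_lt(max(abs(free$u_traj)), 1e-8)

  # relabeling equivariance: permuting the nodes permutes node_input
  p <- sample(6)
  resp <- min_control_energy(A[p, p], x0[p], xf[p], T = 1)
  expect_equal(resp$energy, res$energy, tolerance = 1e-10)
  expect_equal(unname(resp$node_input), unname(res$node_input[p]),
               tolerance = 1e-8)
})

test_that("persistence energy satisfies the scalar law and quadratic scaling", {
  A1 <- matrix(-1, 1, 1)
  for (T in c(0.1, 1, 5)) {
    expect_equal(persistence_energy(A1, 1, T)$energy,
                 2 * (1 - exp(-T)) / (1 + exp(-T)), tolerance = 1e-10)
  }
  expect_equal(persistence_energy(A1, 0, T = 1)$energy, 0)

  A <- random_stable_A(8, 23)
  set.seed(23)
  x <- rnorm(8)
  pe1 <- persistence_energy(A, x, T = 1, trajectories = FALSE)$energy
  pe3 <- persistence_energy(A, 3 * x, T = 1, trajectories = FALSE)$energy
  expect_equal(pe3, 9 * pe1, tolerance = 1e-10)

  # the batch evaluator agrees with the per-state path
  states <- lapply(1:5, function(k) {
    set.seed(100 + k)
    make_state(rnorm(8), meta = list(subject = paste0("s", k),
                                     group = "control", drug = "placebo",
                                     task = "memory", condition = "threat"))
  })
  tab <- persistence_energy_set(A, states, T = 1)
  direct <- vapply(states, function(s)
    persistence_energy(A, s, T = 1, trajectories = FALSE)$energy, 0)
  expect_equal(tab$energy, direct, tolerance = 1e-10)
})

test_that("simulate_trajectory reproduces free drift and equilibria", {
  A <- random_stable_A(5, 31)
  u0 <- matrix(0, 5, 101)
  expect_equal(simulate_trajectory(A, NULL, u0, rep(0, 5), T = 1),
               matrix(0, 5, 101))
  set.seed(31)
  x0 <- rnorm(5)
  X <- simulate_trajectory(A, NULL, u0, x0, T = 1)
  expect_equal(X[, 101], as.numeric(expm_dense(A) %*% x0), tolerance = 1e-8)
})

test_that("trajectory energy quadrature handles basic shapes", {
  expect_equal(energy_from_trajectory(rep(0, 11), dt = 0.1), 0)
  # constant scalar input u = 1 over T = 2
  expect_equal(energy_from_trajectory(rep(1, 21), dt = 0.1), 2)
  expect_error(energy_from_trajectory(rep(1, 5), dt = -1), "dt")
})

test_that("actuator-column removal never decreases minimum energy", {
  for (seed in 1:4) {
    n <- 5
    A <- random_stable_A(n, 40 + seed)
    set.seed(40 + seed)
    x0 <- rnorm(n); xf <- rnorm(n)
    e_full <- min_control_energy(A, x0, xf, T = 1,
                                 trajectories = FALSE)$energy
    for (i in seq_len(n)) {
      Bi <- diag(n)[, -i, drop = FALSE]
      e_red <- tryCatch(
        min_control_energy(A, x0, xf, T = 1, B = Bi, method = "block_expm",
                           trajectories = FALSE)$energy,
        error = function(e) NA_real_)
      if (!is.na(e_red)) expect_gte(e_red, e_full - 1e-8 * abs(e_full))
    }
  }
})

test_that("control impact matches a from-scratch recomputation oracle", {
  net <- random_network(4, seed = 55, density = 1)
  set.seed(55)
  x <- rnorm(4)
  im <- control_impact(net, x, T = 1, c = 1)
  expect_equal(unname(im$impact), bruteforce_impact(net, x), tolerance = 1e-6)
  expect_identical(im$definition_tag, "relative_remove_node")

  # two disconnected identical dyads with equal state values: equal impact
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 1
  twin <- structural_network(w)
  im2 <- suppressWarnings(control_impact(twin, c(1, 2, 1, 2), T = 1))
  expect_equal(im2$impact[[1]], im2$impact[[3]], tolerance = 1e-10)
  expect_equal(im2$impact[[2]], im2$impact[[4]], tolerance = 1e-10)

  # node relabeling permutes the impact vector
  p <- c(3, 1, 4, 2)
  netp <- structural_network(net$weights[p, p], net$labels[p])
  imp <- control_impact(netp, x[p], T = 1)
  expect_equal(unname(imp$impact), unname(im$impact[p]), tolerance = 1e-8)

  # zero state: relative impact undefined
  expect_error(control_impact(net, rep(0, 4)), "undefined|absolute")

  # actuator-only variant: impacts are non-negative (input set shrinks)
  ia <- control_impact(net, x, T = 1, mode = "remove_actuator")
  expect_true(all(ia$impact > -1e-10, na.rm = TRUE))
  expect_identical(ia$definition_tag, "relative_remove_actuator")
})
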