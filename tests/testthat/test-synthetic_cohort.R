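test_that("connectome generator is deterministic, dense when asked, modular", {
  a <- generate_connectome(30, density = 0.4, seed = 9)
  b <- generate_connectome(30, density = 0.4, seed = 9)
  expect_identical(a$weights, b$weights)

  full <- generate_connectome(15, density = 1.0, seed = 2)
  expect_true(all(full$weights[upper.tri(full$weights)] > 0))

  # planted modules: in-block weights exceed out-of-block weights on average
  ratio <- vapply(1:20, function(s) {
    net <- generate_connectome(40, density = 0.3, seed = 300 + s,
                               k_blocks = 4)
    blk <- rep(1:4, length.out = 40)
    up <- which(upper.tri(net$weights), arr.ind = TRUE)
    w <- net$weights[upper.tri(net$weights)]
    inb <- blk[up[, 1]] == blk[up[, 2]]
    mean(w[inb]) - mean(w[!inb])
  }, 0)
  expect_gt(mean(ratio), 0)

  g <- generate_connectome(30, density = 0.3, model = "geometric_like",
                           seed = 4)
  expect_s3_class(g, "structural_network")
  expect_error(generate_connectome(10, density = 0), "density")
})

test_that("state generator injects the interaction through state amplitude", {
  # noise-free degenerate world: identical states across subjects/sessions
  cfg0 <- cohort_config(n_controls = 2, n_relatives = 2, n_nodes = 12,
                        delta_interaction = 0, drug_amplitude_effect = 1,
                        subject_sd = 0, session_noise_sd = 0, seed = 8)
  net <- generate_connectome(12, density = 0.6, seed = 12)
  st0 <- generate_states(cfg0, net)
  cell <- Filter(function(s) s$meta$task == "identification" &&
                   s$meta$condition == "neutral", st0$states)
  ref <- cell[[1]]$values
  for (s in cell) expect_identical(s$values, ref)

  # quadratic scaling law: noise-free Pe ratio drug/placebo is (1+delta)^2
  cfg <- cohort_config(n_controls = 2, n_relatives = 2, n_nodes = 12,
                       delta_interaction = 0.3, subject_sd = 0,
                       session_noise_sd = 0, seed = 8)
  st <- generate_states(cfg, net)
  dyn <- normalize_dynamics(net)
  tm <- Filter(function(s) s$meta$task == "memory" &&
                 s$meta$condition == "threat" &&
                 s$meta$group == "relative", st$states)
  pe <- vapply(tm, function(s)
    persistence_energy(dyn, s, trajectories = FALSE)$energy, 0)
  drug <- vapply(tm, function(s) s$meta$drug, "")
  expect_equal(mean(pe[drug == "alprazolam"]) / mean(pe[drug == "placebo"]),
               1.3^2, tolerance = 1e-6)

  # same seed gives an identical cohort; out-of-slab parcels are zero
  st2 <- generate_states(cfg, net)
  expect_identical(st$states[[5]]$values, st2$states[[5]]$values)
  anyout <- st$states[[1]]
  expect_true(all(anyout$values[!anyout$slab_mask] == 0))
})

test_that("behavior couples efficiency to persistence energy as configured", {
  base_tbl <- expand.grid(subject = sprintf("s%02d", 1:20),
                          drug = c("placebo", "alprazolam"),
                          task = "identification", condition = "threat",
                          stringsAsFactors = FALSE)
  base_tbl$group <- rep(c("control", "relative"), 20)
  set.seed(77)
  base_tbl$energy <- rlnorm(nrow(base_tbl))

  # zero slope, drop and noise: constant efficiency
  cfg0 <- cohort_config(efficiency_slope = 0, drug_efficiency_drop = 0,
                        behavior_noise_sd = 0, seed = 1)
  b0 <- generate_behavior(base_tbl, cfg0, seed = 5)
  eff0 <- efficiency(b0$accuracy, b0$median_rt)
  expect_equal(max(eff0) - min(eff0), 0, tolerance = 1e-12)

  # positive slope, no noise: efficiency is a monotone function of Pe
  cfgs <- cohort_config(efficiency_slope = 0.1, drug_efficiency_drop = 0,
                        behavior_noise_sd = 0, seed = 1)
  bs <- generate_behavior(base_tbl, cfgs, seed = 5)
  effs <- efficiency(bs$accuracy, bs$median_rt)
  expect_equal(cor(base_tbl$energy, effs, method = "spearman"), 1)

  # drug drop 0.1 shows up as a mean efficiency deficit of about 0.1
  cfgd <- cohort_config(efficiency_slope = 0, drug_efficiency_drop = 0.1,
                        behavior_noise_sd = 0.05, seed = 1)
  drops <- vapply(1:50, function(s) {
    b <- generate_behavior(base_tbl, cfgd, seed = 1000 + s)
    e <- efficiency(b$accuracy, b$median_rt)
    mean(e[b$drug == "placebo"]) - mean(e[b$drug == "alprazolam"])
  }, 0)
  expect_lt(abs(mean(drops) - 0.1), 0.01)
  expect_true(all(generate_behavior(base_tbl, cfgd, seed = 2)$median_rt > 0))
})

test_that("receptor-like maps hit the 0-100 range and the target rank blend", {
  set.seed(4)
  target <- rnorm(233)
  maps <- generate_pet_maps(233, 4, target, target_rho = 0.5, seed = 6)
  for (m in maps) {
    expect_equal(min(m), 0)
    expect_equal(max(m), 100)
  }
  exact <- generate_pet_maps(233, 1, target, target_rho = 1, seed = 6)
  expect_equal(cor(exact[[1]], target, method = "spearman"), 1)

  achieved <- vapply(1:50, function(s)
    cor(generate_pet_maps(233, 1, target, 0.5, seed = s)[[1]], target,
        method = "spearman"), 0)
  expect_lt(abs(mean(achieved) - 0.5), 0.1)

  expect_error(generate_pet_maps(10, 1, rep(1, 10), 0.5, 1), "constant")
})

test_that("demographics generator matches configured proportions and bounds", {
  cfg <- cohort_config(n_controls = 500, n_relatives = 500, seed = 10)
  d1 <- generate_demographics(cfg, seed = 3,
                              p_female = c(control = 0.5, relative = 0.5))
  d2 <- generate_demographics(cfg, seed = 3,
                              p_female = c(control = 0.5, relative = 0.5))
  expect_identical(d1, d2)
  expect_lt(abs(mean(d1$sex == "F") - 0.5), 0.04)
  ctrl <- d1[d1$group == "control", ]
  rel <- d1[d1$group == "relative", ]
  expect_true(all(ctrl$age >= 21.1 & ctrl$age <= 56.5))
  expect_true(all(rel$age >= 20.9 & rel$age <= 59.4))
})

test_that("a noise-free cohort recovers the injected interaction sign", {
  for (seed in 1:3) {
    cfg <- cohort_config(n_controls = 4, n_relatives = 4, n_nodes = 20,
                         delta_interaction = 0.2, subject_sd = 0,
                         session_noise_sd = 1e-3, seed = seed)
    net <- generate_connectome(20, density = 0.4, seed = seed + 20)
    st <- generate_states(cfg, net)
    dyn <- normalize_dynamics(net)
    tm <- Filter(function(s) s$meta$task == "memory" &&
                   s$meta$condition == "threat", st$states)
    fit <- fit_energy_model(persistence_energy_set(dyn, tm, T = 1))
    expect_gt(gamma11_of(fit)$estimate, 0)
  }
})
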