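test_that("energy mixed model maps coefficients and handles degeneracy", {
  # constant outcome: intercept = constant, slopes 0
  df <- make_crossover_df(5, 0, 0, seed = 1)
  df$energy <- 2.5
  fit <- fit_energy_model(df)
  co <- fit$coefficients
  expect_equal(co$estimate[co$symbol == "gamma00"], 2.5)
  expect_true(all(co$estimate[co$symbol != "gamma00"] == 0))

  # zero subject variance, balanced: fixed effects equal OLS coefficients
  df2 <- make_crossover_df(10, 0, 0.5, g01 = 0.3, b1 = -0.2, g11 = 0.4,
                           seed = 2)
  fit2 <- fit_energy_model(df2, standardize = FALSE)
  ols <- lm(energy ~ drug * group,
            data = transform(df2,
                             drug = factor(drug, c("placebo", "alprazolam")),
                             group = factor(group, c("control", "relative"))))
  expect_equal(unname(fit2$coefficients$estimate), unname(coef(ols)),
               tolerance = 1e-6)
  # symbol map is stable
  expect_identical(fit2$coefficients$symbol,
                   c("gamma00", "beta1i", "gamma01", "gamma11"))
  # standardization is linear: identical slope p-values (intercept shifts)
  fit2z <- fit_energy_model(df2, standardize = TRUE)
  expect_equal(fit2z$coefficients$p[-1], fit2$coefficients$p[-1],
               tolerance = 1e-8)

  expect_error(fit_energy_model(df2[df2$group == "control", ]),
               "2 subjects per group")
})

test_that("energy model recovers injected interactions with subject effects", {
  df <- make_crossover_df(20, 0.5, 0.2, g01 = 0.1, b1 = 0.1, g11 = 0.6,
                          seed = 3)
  fit <- fit_energy_model(df, standardize = FALSE)
  g <- gamma11_of(fit)
  expect_gt(g$estimate, 0)
  expect_lt(g$p, 0.01)
  expect_true(fit$converged)
})

test_that("efficiency model finds constructed couplings and nothing else", {
  set.seed(11)
  n <- 30
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(subject = sprintf("s%02d", i),
               group = c("control", "relative")[1 + i %% 2],
               drug = c("placebo", "alprazolam"),
               age = runif(1, 20, 60), sex = sample(c("F", "M"), 1),
               energy = rlnorm(2), stringsAsFactors = FALSE)
  }))
  df$efficiency <- 0.5 + 0.2 * scale(df$energy)[, 1] + rnorm(nrow(df), 0, 0.02)
  fit <- fit_efficiency_model(df)
  co <- fit$coefficients
  beta <- co[co$symbol == "beta", ]
  expect_gt(beta$estimate, 0)
  expect_lt(beta$p, 0.001)

  # permuting efficiency destroys the association
  perm_beta <- vapply(1:50, function(k) {
    set.seed(k)
    dfp <- df
    dfp$efficiency <- sample(df$efficiency)
    cop <- fit_efficiency_model(dfp)$coefficients
    cop[cop$symbol == "beta", "estimate"]
  }, 0)
  expect_lt(mean(abs(perm_beta)), abs(beta$estimate) / 2)
})

test_that("efficiency-model slope test has calibrated type-I error", {
  rej <- 0
  for (r in 1:100) {
    set.seed(6000 + r)
    df <- do.call(rbind, lapply(1:20, function(i) {
      data.frame(subject = sprintf("s%02d", i),
                 group = c("control", "relative")[1 + i %% 2],
                 drug = c("placebo", "alprazolam"),
                 age = runif(1, 20, 60), sex = sample(c("F", "M"), 1),
                 energy = rlnorm(2),
                 efficiency = 0.5 + 0.3 * rnorm(1) + rnorm(2, 0, 0.1),
                 stringsAsFactors = FALSE)
    }))
    fit <- fit_efficiency_model(df)
    if (isTRUE(fit$converged)) {
      co <- fit$coefficients
      if (co[co$symbol == "beta", "p"] < 0.05) rej <- rej + 1
    }
  }
  expect_gte(rej / 100, 0.00)
  expect_lte(rej / 100, 0.10)
})

test_that("efficiency and BH-FDR primitives follow their definitions", {
  expect_equal(efficiency(1.0, 2.0), 0.5)
  expect_equal(efficiency(0.0, 1.7), 0.0)
  expect_equal(efficiency(0.9, 1.5), 0.6)
  expect_error(efficiency(0.9, 0), "> 0")
  expect_error(efficiency(1.2, 1), "\\[0, 1\\]")

  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.4, 0.01, 0.2, 0.03)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_identical(order(q), order(p))   # order of distinct p preserved
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("control-input difference maps subtract sessions per parcel", {
  expect_equal(unname(control_input_diff(c(a = 1, b = 3), c(a = 2, b = 1))),
               c(1, 2))
  expect_equal(control_input_diff(c(a = 1, b = 3), c(a = 2, b = 1),
                                  mode = "signed"),
               c(a = -1, b = 2))
  x <- c(a = 0.3, b = 0.8)
  expect_equal(unname(control_input_diff(x, x)), c(0, 0))
  expect_true(all(control_input_diff(c(a = 1), c(a = 5)) >= 0))
  expect_error(control_input_diff(c(a = 1), c(b = 1)), "labels")
})

test_that("receptor alignment permutation test is exact at the floor and reproducible", {
  set.seed(21)
  base <- rnorm(40)
  # every subject's map rank-identical to the receptor map
  dm <- t(vapply(1:5, function(s) base + 0, numeric(40)))
  res <- receptor_alignment_test(dm, base, n_perm = 500, seed = 77)
  expect_equal(res$observed, 1)
  expect_equal(res$p, 1 / 501)
  res2 <- receptor_alignment_test(dm, base, n_perm = 500, seed = 77)
  expect_identical(res2$p, res$p)
  expect_identical(res2$null, res$null)

  # observed statistic equals the mean of per-subject Spearman correlations
  set.seed(22)
  dm2 <- matrix(rnorm(5 * 40), 5)
  rmap <- runif(40)
  r3 <- receptor_alignment_test(dm2, rmap, n_perm = 99, seed = 1)
  direct <- mean(apply(dm2, 1, cor, y = rmap, method = "spearman"))
  expect_equal(r3$observed, direct, tolerance = 1e-12)

  # mask restricts the computation and constant maps fail
  mask <- c(rep(TRUE, 25), rep(FALSE, 15))
  r4 <- receptor_alignment_test(dm2, rmap, n_perm = 99, seed = 1,
                                slab_mask = mask)
  direct4 <- mean(apply(dm2[, 1:25], 1, cor, y = rmap[1:25],
                        method = "spearman"))
  expect_equal(r4$observed, direct4, tolerance = 1e-12)
  flat <- rmap; flat[mask] <- 1
  expect_error(receptor_alignment_test(dm2, flat, 99, 1, mask), "constant")

  tests <- receptor_alignment_tests(dm2, list(m1 = rmap, m2 = rev(rmap)),
                                    n_perm = 99, seed = 5)
  expect_identical(tests$q, bh_fdr(tests$p))
})

test_that("demographic statistics reproduce the cohort table's worked examples", {
  demo <- data.frame(
    group = rep(c("control", "relative"), c(27, 20)),
    sex = c(rep(c("F", "M"), c(14, 13)), rep(c("F", "M"), c(11, 9))),
    handedness = c(rep(c("R", "L"), c(25, 2)), rep(c("R", "L"), c(16, 4))),
    smoke = c(rep(c("N", "Y"), c(21, 6)), rep(c("N", "Y"), c(16, 4))),
    stringsAsFactors = FALSE)
  tab <- demographics_table(demo,
                            categorical = c("sex", "handedness", "smoke"),
                            events = c(sex = "F", handedness = "L",
                                       smoke = "N"))
  expect_equal(tab$statistic[tab$variable == "sex"], (14 * 9) / (13 * 11),
               tolerance = 1e-12)            # prints as 0.88
  expect_equal(tab$statistic[tab$variable == "handedness"], 0.32,
               tolerance = 1e-12)
  expect_equal(tab$statistic[tab$variable == "smoke"], 0.875,
               tolerance = 1e-12)            # prints as 0.88
  expect_equal(tab$p[tab$variable == "sex"], 1.0, tolerance = 1e-6)
  expect_equal(tab$p[tab$variable == "handedness"], 0.38, tolerance = 0.005)

  # balanced 2x2: OR 1, Fisher p 1
  bal <- data.frame(group = rep(c("control", "relative"), each = 2),
                    v = rep(c("a", "b"), 2), stringsAsFactors = FALSE)
  tb <- demographics_table(bal, categorical = "v", events = c(v = "a"))
  expect_equal(tb$statistic, 1)
  expect_equal(tb$p, 1)

  # continuous: t-test df and Wilcoxon z machinery
  set.seed(9)
  demo$age <- rnorm(47, 40, 10)
  ct <- demographics_table(demo, continuous = "age")
  expect_equal(ct$df, 45)
  cw <- demographics_table(demo, continuous = "age", nonnormal = "age")
  expect_identical(cw$type, "continuous_wilcoxon")
  expect_true(is.finite(cw$statistic))
})

test_that("Cohen's d uses the pooled-SD convention", {
  expect_equal(cohens_d(11.5, 7.2, 27, 15.0, 7.2, 20), 3.5 / 7.2,
               tolerance = 1e-12)           # the schizotypy-scale example, ~0.49
  expect_equal(cohens_d(5, 1, 10, 5, 1, 10), 0)
  expect_equal(cohens_d(0, 1, 10, 1, 1, 10), 1.0)
  expect_error(cohens_d(0, 0, 10, 1, 0, 10), "undefined")
})
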