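# Mixed-effects inference on persistence energy and task efficiency,
# Benjamini-Hochberg FDR, receptor-map permutation alignment, and cohort
# demographic statistics.

.factorize_design <- function(df) {
  if ("group" %in% names(df))
    df$group <- factor(df$group, levels = GROUPS)
  if ("drug" %in% names(df))
    df$drug <- factor(df$drug, levels = DRUGS)
  if ("sex" %in% names(df))
    df$sex <- factor(df$sex, levels = c("F", "M"))
  df
}

.zscore <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) x - mean(x) else (x - mean(x)) / s
}

.lme_ttable <- function(fit) {
  tt <- summary(fit)$tTable
  data.frame(term = rownames(tt), estimate = tt[, "Value"],
             se = tt[, "Std.Error"], df = tt[, "DF"],
             p = tt[, "p-value"], row.names = NULL,
             stringsAsFactors = FALSE)
}

.degenerate_result <- function(df, outcome, terms, symbols) {
  co <- data.frame(term = terms, symbol = symbols,
                   estimate = c(mean(outcome), rep(0, length(terms) - 1)),
                   se = NA_real_, df = NA_real_, p = NA_real_,
                   stringsAsFactors = FALSE)
  structure(list(coefficients = co, n_obs = nrow(df),
                 n_subjects = length(unique(df$subject)),
                 converged = TRUE, degenerate = TRUE, fit = NULL),
            class = "mixed_model_result")
}

#' Mixed-effects model of persistence energy (one task x condition cell)
#'
#' Fits `energy ~ drug * group` with a random intercept per subject by
#' restricted maximum likelihood, the crossover-design model for a
#' drug-by-group effect on persistence energy. Coefficients are mapped to
#' the conventional symbols: `gamma00` (intercept), `gamma01` (group main
#' effect, relative vs control), `beta1i` (drug main effect, alprazolam vs
#' placebo) and `gamma11` (group-by-drug interaction). With the default
#' `standardize = TRUE` the outcome is z-scored within the cell, so
#' coefficients are in outcome-SD units; standardization is linear and does
#' not change t-statistics or p-values.
#'
#' @param df Data frame with columns `subject`, `group`, `drug`, `energy`
#'   (one task x condition cell) plus any `covariates`.
#' @param covariates Optional character vector of additional fixed-effect
#'   columns (e.g. `c("age", "sex")`).
#' @param standardize Z-score the outcome within the cell (default `TRUE`).
#' @return Object of class `mixed_model_result`: `coefficients` (term,
#'   symbol, estimate, se, df, p), `n_obs`, `n_subjects`, `converged`,
#'   `fit` (the `nlme::lme` object, or `NULL`).
#' @export
fit_energy_model <- function(df, covariates = NULL, standardize = TRUE) {
  need <- c("subject", "group", "drug", "energy")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  if (length(unique(df$subject[df$group == "control"])) < 2 ||
      length(unique(df$subject[df$group == "relative"])) < 2)
    stop("need at least 2 subjects per group")
  df <- .factorize_design(df)
  terms_rhs <- paste(c("drug * group", covariates), collapse = " + ")
  y <- df$energy
  if (stats::sd(y) == 0) {
    terms <- c("(Intercept)", "drugalprazolam", "grouprelative",
               if (!is.null(covariates)) covariates,
               "drugalprazolam:grouprelative")
    symbols <- c("gamma00", "beta1i", "gamma01",
                 if (!is.null(covariates)) covariates, "gamma11")
    return(.degenerate_result(df, y, terms, symbols))
  }
  df$.y <- if (standardize) .zscore(y) else y
  fml <- stats::as.formula(paste(".y ~", terms_rhs))
  fit <- tryCatch(
    nlme::lme(fml, random = ~ 1 | subject, data = df, method = "REML",
              na.action = stats::na.omit),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(coefficients = NULL, n_obs = nrow(df),
                          n_subjects = length(unique(df$subject)),
                          converged = FALSE,
                          message = conditionMessage(fit), fit = NULL),
                     class = "mixed_model_result"))
  }
  co <- .lme_ttable(fit)
  sym <- c("(Intercept)" = "gamma00", "drugalprazolam" = "beta1i",
           "grouprelative" = "gamma01",
           "drugalprazolam:grouprelative" = "gamma11")
  co$symbol <- ifelse(co$term %in% names(sym), sym[co$term], co$term)
  co <- co[, c("term", "symbol", "estimate", "se", "df", "p")]
  structure(list(coefficients = co, n_obs = nrow(df),
                 n_subjects = length(unique(df$subject)),
                 converged = TRUE, fit = fit),
            class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("mixed_model_result: NOT CONVERGED (", x$message, ")\n")
    return(invisible(x))
  }
  cat(sprintf("mixed_model_result: %d obs, %d subjects\n", x$n_obs,
              x$n_subjects))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Fit persistence-energy models for every task x condition cell
#'
#' One [fit_energy_model()] per cell, with Benjamini-Hochberg adjustment of
#' each term's p-values across the emotion conditions within task.
#'
#' @param energy_tbl Long energy table (`subject`, `group`, `drug`, `task`,
#'   `condition`, `energy`).
#' @param covariates,standardize Passed to [fit_energy_model()].
#' @return Data frame with columns `task`, `condition`, `term`, `symbol`,
#'   `estimate`, `se`, `df`, `p`, `q`, `converged`.
#' @export
fit_energy_models <- function(energy_tbl, covariates = NULL,
                              standardize = TRUE) {
  cells <- unique(energy_tbl[, c("task", "condition")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    d <- energy_tbl[energy_tbl$task == cells$task[i] &
                      energy_tbl$condition == cells$condition[i], ]
    r <- fit_energy_model(d, covariates, standardize)
    if (!isTRUE(r$converged) || is.null(r$coefficients))
      return(data.frame(task = cells$task[i], condition = cells$condition[i],
                        term = NA_character_, symbol = NA_character_,
                        estimate = NA_real_, se = NA_real_, df = NA_real_,
                        p = NA_real_, converged = FALSE,
                        stringsAsFactors = FALSE))
    cbind(task = cells$task[i], condition = cells$condition[i],
          r$coefficients, converged = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (tk in unique(out$task)) for (sy in unique(out$symbol)) {
    sel <- which(out$task == tk & out$symbol == sy & !is.na(out$p))
    if (length(sel)) out$q[sel] <- bh_fdr(out$p[sel])
  }
  rownames(out) <- NULL
  out
}

#' Mixed-effects model of task efficiency (one task x condition cell)
#'
#' Fits `efficiency ~ energy + drug + group + age + sex` with a random
#' intercept per subject. The persistence-energy slope is reported under the
#' symbol `beta`. Efficiency and energy are z-scored within the cell by
#' default (standardized slope).
#'
#' @param df Data frame with columns `subject`, `group`, `drug`,
#'   `efficiency`, `energy`, `age`, `sex`.
#' @param standardize Z-score efficiency and energy within the cell.
#' @return A `mixed_model_result` (see [fit_energy_model()]).
#' @export
fit_efficiency_model <- function(df, standardize = TRUE) {
  need <- c("subject", "group", "drug", "efficiency", "energy", "age", "sex")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  df <- .factorize_design(df)
  if (stats::sd(df$efficiency) == 0) {
    terms <- c("(Intercept)", ".pe", "drugalprazolam", "grouprelative",
               "age", "sexM")
    return(.degenerate_result(df, df$efficiency, terms,
                              c("intercept", "beta", "drug", "group",
                                "age", "sex")))
  }
  df$.y <- if (standardize) .zscore(df$efficiency) else df$efficiency
  df$.pe <- if (standardize) .zscore(df$energy) else df$energy
  fit <- tryCatch(
    nlme::lme(.y ~ .pe + drug + group + age + sex, random = ~ 1 | subject,
              data = df, method = "REML", na.action = stats::na.omit),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(coefficients = NULL, n_obs = nrow(df),
                          n_subjects = length(unique(df$subject)),
                          converged = FALSE,
                          message = conditionMessage(fit), fit = NULL),
                     class = "mixed_model_result"))
  }
  co <- .lme_ttable(fit)
  sym <- c("(Intercept)" = "intercept", ".pe" = "beta",
           "drugalprazolam" = "drug", "grouprelative" = "group",
           "age" = "age", "sexM" = "sex")
  co$symbol <- ifelse(co$term %in% names(sym), sym[co$term], co$term)
  co <- co[, c("term", "symbol", "estimate", "se", "df", "p")]
  structure(list(coefficients = co, n_obs = nrow(df),
                 n_subjects = length(unique(df$subject)),
                 converged = TRUE, fit = fit),
            class = "mixed_model_result")
}

#' Fit efficiency models for every task x condition cell
#'
#' One [fit_efficiency_model()] per cell, with Benjamini-Hochberg
#' adjustment of the persistence-energy slope's p-value across all six
#' task x condition models.
#'
#' @param records Data frame with `subject`, `group`, `drug`, `task`,
#'   `condition`, `efficiency`, `energy`, `age`, `sex`.
#' @param standardize Passed through.
#' @return Data frame like [fit_energy_models()]'s.
#' @export
fit_efficiency_models <- function(records, standardize = TRUE) {
  cells <- unique(records[, c("task", "condition")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    d <- records[records$task == cells$task[i] &
                   records$condition == cells$condition[i], ]
    r <- fit_efficiency_model(d, standardize)
    if (!isTRUE(r$converged) || is.null(r$coefficients))
      return(data.frame(task = cells$task[i], condition = cells$condition[i],
                        term = NA_character_, symbol = NA_character_,
                        estimate = NA_real_, se = NA_real_, df = NA_real_,
                        p = NA_real_, converged = FALSE,
                        stringsAsFactors = FALSE))
    cbind(task = cells$task[i], condition = cells$condition[i],
          r$coefficients, converged = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  sel <- which(out$symbol == "beta" & !is.na(out$p))
  if (length(sel)) out$q[sel] <- bh_fdr(out$p[sel])
  rownames(out) <- NULL
  out
}

#' Task performance efficiency
#'
#' Proportion of correct responses divided by the median reaction time for
#' correct responses (units: accuracy per second).
#'
#' @param accuracy Proportion correct in `[0, 1]`.
#' @param median_rt Median correct-response reaction time in seconds, `> 0`.
#' @return `accuracy / median_rt` (vectorized).
#' @export
efficiency <- function(accuracy, median_rt) {
  if (any(accuracy < 0 | accuracy > 1, na.rm = TRUE))
    stop("accuracy must lie in [0, 1]")
  if (any(median_rt <= 0, na.rm = TRUE))
    stop("median_rt must be > 0")
  accuracy / median_rt
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: never decreases a p-value,
#' preserves the order of distinct p-values, and caps at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-parcel control-input difference map
#'
#' Difference in total (integrated squared) control input per parcel between
#' drug and placebo sessions; absolute values by default.
#'
#' @param node_input_drug,node_input_placebo Named numeric vectors of
#'   per-parcel integrated control input for the two sessions of one
#'   subject.
#' @param mode `"absolute"` (default) or `"signed"` (drug minus placebo).
#' @return Named numeric vector on the shared parcels.
#' @export
control_input_diff <- function(node_input_drug, node_input_placebo,
                               mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  if (!is.null(names(node_input_drug)) || !is.null(names(node_input_placebo))) {
    if (!identical(names(node_input_drug), names(node_input_placebo)))
      stop("parcel labels of the two sessions do not match")
  } else if (length(node_input_drug) != length(node_input_placebo)) {
    stop("parcel count mismatch between sessions")
  }
  d <- node_input_drug - node_input_placebo
  if (mode == "absolute") abs(d) else d
}

#' Permutation test of spatial alignment with a receptor map
#'
#' The observed statistic is the mean over subjects of the Spearman
#' correlation between each subject's control-input difference map and the
#' receptor density map, computed on in-slab parcels. The null distribution
#' permutes the receptor map's parcel labels within the slab — one shared
#' permutation per iteration across subjects, preserving the
#' between-subject correlation structure of the statistic. Two-sided p-value
#' `(1 + #{|null| >= |observed|}) / (n_perm + 1)`, so the smallest
#' attainable p is `1/(n_perm + 1)`.
#'
#' @param diff_maps Subjects-by-parcels numeric matrix (or list of equal
#'   length vectors) of per-subject difference maps.
#' @param receptor_map Numeric parcel vector, non-constant on the mask.
#' @param n_perm Number of permutations (default 500).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param slab_mask Optional logical parcel mask (default: all parcels).
#' @return Object of class `permutation_result`: `observed` (mean Spearman
#'   rho), `subject_rho`, `p`, `n_perm`, `null_mean`, `null_sd`, `null`,
#'   `seed`.
#' @export
receptor_alignment_test <- function(diff_maps, receptor_map, n_perm = 500,
                                    seed = 1L, slab_mask = NULL) {
  if (is.list(diff_maps)) diff_maps <- do.call(rbind, diff_maps)
  if (is.null(dim(diff_maps))) diff_maps <- matrix(diff_maps, nrow = 1)
  if (nrow(diff_maps) < 2) stop("need at least 2 subjects")
  P <- ncol(diff_maps)
  if (length(receptor_map) != P)
    stop("receptor map length does not match parcel count")
  if (is.null(slab_mask)) slab_mask <- rep(TRUE, P)
  idx <- which(slab_mask)
  if (length(idx) < 3) stop("need at least 3 in-slab parcels")
  D <- diff_maps[, idx, drop = FALSE]
  r <- receptor_map[idx]
  if (stats::sd(r) == 0) stop("receptor map is constant on the mask")
  np <- length(idx)
  std_ranks <- function(x) as.numeric(.zscore(rank(x)))
  Rstd <- t(apply(D, 1, std_ranks))
  rstd <- std_ranks(r)
  rho_of <- function(rv) as.numeric(Rstd %*% rv) / (np - 1)
  subject_rho <- rho_of(rstd)
  obs <- mean(subject_rho)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(k)
    mean(rho_of(rstd[sample.int(np)])), 0))
  p <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
  structure(list(observed = obs, subject_rho = subject_rho, p = p,
                 n_perm = n_perm, null_mean = mean(null),
                 null_sd = stats::sd(null), null = null, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result: mean rho = %.4f, p = %.4g (%d permutations, null sd %.3g)\n",
    x$observed, x$p, x$n_perm, x$null_sd))
  invisible(x)
}

#' Alignment tests across a set of receptor maps, with FDR
#'
#' Runs [receptor_alignment_test()] for each map and adjusts p-values across
#' maps by Benjamini-Hochberg.
#'
#' @param diff_maps As in [receptor_alignment_test()].
#' @param receptor_maps Named list of receptor maps.
#' @param n_perm,seed,slab_mask Passed through; each map gets its own seed
#'   stream derived from `seed`.
#' @return Data frame: `receptor`, `observed_rho`, `p`, `q`, `n_perm`,
#'   `seed`.
#' @export
receptor_alignment_tests <- function(diff_maps, receptor_maps, n_perm = 500,
                                     seed = 1L, slab_mask = NULL) {
  seeds <- derive_seeds(seed, length(receptor_maps))
  rows <- lapply(seq_along(receptor_maps), function(k) {
    r <- receptor_alignment_test(diff_maps, receptor_maps[[k]], n_perm,
                                 seeds[k], slab_mask)
    data.frame(receptor = names(receptor_maps)[k], observed_rho = r$observed,
               p = r$p, n_perm = n_perm, seed = seeds[k],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[, c("receptor", "observed_rho", "p", "q", "n_perm", "seed")]
}

#' Cohen's d from summary statistics
#'
#' Standardized mean difference `(mean2 - mean1) / s_pooled` with pooled SD
#' `sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2))`. Sign convention:
#' group 2 minus group 1.
#'
#' @param mean1,sd1,n1 Group 1 summary statistics.
#' @param mean2,sd2,n2 Group 2 summary statistics.
#' @return Scalar effect size.
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) {
    if (mean1 == mean2) return(0)
    stop("pooled SD is 0 with unequal means; effect size undefined")
  }
  (mean2 - mean1) / sp
}

# Wilcoxon rank-sum z-statistic (normal approximation with tie correction).
.wilcox_z <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  r <- rank(c(x1, x2))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((n1 + n2 + 1) -
                            sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  (W - mu) / sqrt(sig2)
}

#' Group-comparison statistics for a demographics table
#'
#' For each categorical variable: Fisher's exact p-value and the
#' cross-product odds ratio, oriented as the odds of the stated event
#' category in group 1 divided by group 2 (group order = factor order of
#' `group_col`). A zero cell makes the odds ratio undefined (`NA`; no
#' continuity correction is applied unless `haldane = TRUE`). For each
#' continuous variable: pooled-variance two-sample t-test (df
#' `n1 + n2 - 2`), or a Wilcoxon rank-sum z-test for variables listed in
#' `nonnormal`; Cohen's d (group 2 minus group 1) is reported for every
#' continuous variable.
#'
#' @param df Data frame, one row per subject.
#' @param group_col Name of the two-level grouping column.
#' @param categorical Character vector of categorical variable names.
#' @param continuous Character vector of continuous variable names.
#' @param nonnormal Subset of `continuous` to test by Wilcoxon rank-sum.
#' @param events Named character vector giving the event category per
#'   categorical variable (default: first level alphabetically).
#' @param haldane Add 0.5 to every cell of a 2x2 table containing a zero
#'   before forming the odds ratio (default `FALSE`).
#' @return Data frame: `variable`, `type`, `event`, `statistic` (odds ratio,
#'   t, or z), `df`, `p`, `cohens_d`.
#' @export
demographics_table <- function(df, group_col = "group",
                               categorical = character(),
                               continuous = character(),
                               nonnormal = character(),
                               events = NULL, haldane = FALSE) {
  g <- df[[group_col]]
  if (is.null(g)) stop("grouping column not found: ", group_col)
  g <- as.factor(g)
  lv <- levels(droplevels(g))
  if (length(lv) != 2) stop("need exactly two groups")
  i1 <- which(g == lv[1]); i2 <- which(g == lv[2])
  if (length(i1) < 2 || length(i2) < 2) stop("need >= 2 members per group")
  rows <- list()
  for (v in categorical) {
    x <- as.factor(df[[v]])
    ev <- if (!is.null(events) && v %in% names(events)) events[[v]]
          else sort(levels(x))[1]
    a <- sum(x[i1] == ev); b <- sum(x[i1] != ev)
    cc <- sum(x[i2] == ev); d <- sum(x[i2] != ev)
    tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
    p <- stats::fisher.test(tab)$p.value
    or <- if (any(tab == 0)) {
      if (haldane) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
      else NA_real_
    } else (a * d) / (b * cc)
    rows[[length(rows) + 1]] <-
      data.frame(variable = v, type = "categorical", event = ev,
                 statistic = or, df = NA_real_, p = p, cohens_d = NA_real_,
                 stringsAsFactors = FALSE)
  }
  for (v in continuous) {
    x1 <- df[[v]][i1]; x2 <- df[[v]][i2]
    x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]
    d_es <- cohens_d(mean(x1), stats::sd(x1), length(x1),
                     mean(x2), stats::sd(x2), length(x2))
    if (v %in% nonnormal) {
      z <- .wilcox_z(x1, x2)
      p <- stats::wilcox.test(x1, x2, exact = FALSE, correct = FALSE)$p.value
      rows[[length(rows) + 1]] <-
        data.frame(variable = v, type = "continuous_wilcoxon", event = NA,
                   statistic = z, df = NA_real_, p = p, cohens_d = d_es,
                   stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(x1, x2, var.equal = TRUE)
      rows[[length(rows) + 1]] <-
        data.frame(variable = v, type = "continuous_t", event = NA,
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value,
                   cohens_d = d_es, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
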