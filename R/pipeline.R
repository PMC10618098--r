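# End-to-end analysis orchestration: simulate -> energies -> impact ->
# nulls -> models -> alignment, with a JSON run config, per-stage TSV
# outputs and a run manifest. The numbered scripts under analysis/ are thin
# drivers over these stage functions.

#' Default run configuration
#'
#' Nested configuration for [run_pipeline()]. Round-trips losslessly through
#' JSON ([write_run_config()] / [read_run_config()]). Every stochastic stage
#' derives an explicit seed from `seed`.
#'
#' @param seed Master seed.
#' @param outdir Output directory.
#' @param ... Overrides for nested blocks, e.g.
#'   `cohort = list(n_nodes = 50)`, `control = list(T = 2)`.
#' @return Object of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, outdir = "results", ...) {
  cfg <- list(
    paths = list(network = "synthetic"),
    cohort = list(n_controls = 27, n_relatives = 20, n_nodes = 233,
                  slab_fraction = 0.6, delta_interaction = 0.06,
                  drug_amplitude_effect = 1.0, subject_sd = 0.2,
                  session_noise_sd = 0.3, template_amplitude = 1.0,
                  efficiency_base = 0.6, efficiency_slope = 0.05,
                  drug_efficiency_drop = 0.05, behavior_noise_sd = 0.05),
    connectome = list(density = 0.3, model = "modular"),
    control = list(T = 1.0, c = 1.0, n_steps = 1001,
                   out_of_slab_policy = "zero", normalization = "none"),
    stats = list(n_perm = 500, alpha = 0.05, n_structural_nulls = 5,
                 n_spatial_nulls = 5, k_receptor_maps = 10,
                 receptor_target_rho = 0.5),
    seed = as.integer(seed),
    outdir = outdir)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- "run_config"
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' Checks that every required key is present, failing with the missing key's
#' dotted name.
#'
#' @param config A `run_config` or plain nested list.
#' @return The validated config (class `run_config`), invisibly usable.
#' @export
validate_run_config <- function(config) {
  need <- list(
    c("cohort", "n_controls"), c("cohort", "n_relatives"),
    c("cohort", "n_nodes"), c("cohort", "slab_fraction"),
    c("cohort", "delta_interaction"),
    c("control", "T"), c("control", "c"), c("control", "n_steps"),
    c("stats", "n_perm"), c("stats", "alpha"),
    "seed", "outdir")
  for (key in need) {
    val <- config
    for (k in key) val <- val[[k]]
    if (is.null(val))
      stop(paste(key, collapse = "."), " required")
  }
  if (config$control$T <= 0) stop("control.T must be > 0")
  class(config) <- "run_config"
  config
}

#' Write / read a run configuration as JSON
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `read_run_config` returns the validated `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

.cohort_from_config <- function(config, seed) {
  do.call(cohort_config, c(config$cohort, list(seed = seed)))
}

.stage_paths <- function(outdir) {
  list(network = file.path(outdir, "connectome.tsv"),
       states = file.path(outdir, "states.tsv"),
       demographics = file.path(outdir, "demographics.tsv"),
       behavior = file.path(outdir, "behavior.tsv"),
       receptors = file.path(outdir, "receptor_maps.tsv"),
       energy = file.path(outdir, "energy.tsv"),
       node_input = file.path(outdir, "node_input.tsv"),
       impact = file.path(outdir, "impact.tsv"),
       structural_null = file.path(outdir, "structural_null_coefs.tsv"),
       structural_null_cor = file.path(outdir, "structural_null_energy_cor.tsv"),
       spatial_null = file.path(outdir, "spatial_null_coefs.tsv"),
       energy_models = file.path(outdir, "energy_models.tsv"),
       efficiency_models = file.path(outdir, "efficiency_models.tsv"),
       demographics_stats = file.path(outdir, "demographics_stats.tsv"),
       alignment = file.path(outdir, "alignment.tsv"),
       manifest = file.path(outdir, "manifest.json"))
}

#' Pipeline stage: simulate the synthetic cohort
#'
#' Generates (or loads) the connectome and generates states, demographics,
#' behavior and receptor-like maps, writing the TSVs consumed by later
#' stages. The receptor-map reference is the cohort-mean absolute
#' threat-identification activation, so one synthetic "receptor" genuinely
#' co-varies with task-relevant parcels at the configured Spearman level.
#'
#' @param config A `run_config`.
#' @return Invisibly, the list of written paths.
#' @export
stage_simulate <- function(config) {
  config <- validate_run_config(config)
  paths <- .stage_paths(config$outdir)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 3)
  ccfg <- .cohort_from_config(config, seeds[1])
  network <- if (identical(config$paths$network, "synthetic") ||
                 is.null(config$paths$network))
    generate_connectome(ccfg$n_nodes, density = config$connectome$density,
                        model = config$connectome$model, seed = seeds[2])
  else load_network(config$paths$network)
  cohort <- generate_cohort(ccfg, network, T = config$control$T,
                            c = config$control$c)
  write_network(network, paths$network)
  write_tsv(states_to_table(cohort$states), paths$states)
  write_tsv(cohort$demographics, paths$demographics)
  write_tsv(cohort$behavior, paths$behavior)
  ti <- Filter(function(s) s$meta$task == "identification" &&
                 s$meta$condition == "threat", cohort$states)
  ref <- Reduce(`+`, lapply(ti, function(s) abs(s$values))) / length(ti)
  maps <- generate_pet_maps(ccfg$n_nodes, config$stats$k_receptor_maps,
                            target_map = ref,
                            target_rho = config$stats$receptor_target_rho,
                            seed = seeds[3])
  rec <- data.frame(parcel_label = network$labels,
                    do.call(cbind, maps), check.names = FALSE)
  write_tsv(rec, paths$receptors)
  invisible(paths)
}

.load_stage_inputs <- function(config) {
  paths <- .stage_paths(config$outdir)
  network <- load_network(paths$network)
  states <- table_to_states(read_tsv(paths$states), network$labels)
  list(paths = paths, network = network, states = states)
}

#' Pipeline stage: persistence energies and node inputs
#'
#' Computes the persistence energy of every record's state and, for threat
#' records, the per-parcel integrated control input, writing `energy.tsv`
#' and `node_input.tsv`.
#'
#' @param config A `run_config`.
#' @export
stage_energy <- function(config) {
  config <- validate_run_config(config)
  inp <- .load_stage_inputs(config)
  dyn <- normalize_dynamics(inp$network, config$control$c)
  etab <- persistence_energy_set(dyn, inp$states, config$control$T)
  write_tsv(etab, inp$paths$energy)
  threat <- Filter(function(s) s$meta$condition == "threat", inp$states)
  ni <- do.call(rbind, lapply(threat, function(s) {
    r <- persistence_energy(dyn, s, config$control$T,
                            n_steps = config$control$n_steps)
    data.frame(subject = s$meta$subject, group = s$meta$group,
               drug = s$meta$drug, task = s$meta$task,
               condition = s$meta$condition,
               parcel_label = inp$network$labels,
               value = unname(r$node_input), stringsAsFactors = FALSE)
  }))
  write_tsv(ni, inp$paths$node_input)
  invisible(inp$paths)
}

#' Pipeline stage: node-removal control impact
#'
#' Control impact of every node for the cohort-mean threat state of each
#' task, written long-format to `impact.tsv`.
#'
#' @param config A `run_config`.
#' @export
stage_impact <- function(config) {
  config <- validate_run_config(config)
  inp <- .load_stage_inputs(config)
  rows <- lapply(TASKS, function(tk) {
    sel <- Filter(function(s) s$meta$task == tk &&
                    s$meta$condition == "threat", inp$states)
    xbar <- Reduce(`+`, lapply(sel, `[[`, "values")) / length(sel)
    im <- control_impact(inp$network, xbar, T = config$control$T,
                         c = config$control$c)
    data.frame(task = tk, condition = "threat",
               parcel_label = names(im$impact), value = unname(im$impact),
               baseline_energy = im$baseline_energy,
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), inp$paths$impact)
  invisible(inp$paths)
}

#' Pipeline stage: structural and spatial null analyses
#'
#' Recomputes energies under (a) degree-preserving rewired connectomes and
#' (b) spatially permuted states, refits the energy mixed models on each,
#' and writes the null coefficient tables plus the Spearman correlation
#' between original and structural-null energies.
#'
#' @param config A `run_config`.
#' @export
stage_nulls <- function(config) {
  config <- validate_run_config(config)
  inp <- .load_stage_inputs(config)
  paths <- inp$paths
  etab <- read_tsv(paths$energy)
  seeds <- derive_seeds(config$seed + 101L, 2)
  ns <- config$stats$n_structural_nulls
  sseeds <- derive_seeds(seeds[1], ns)
  key <- function(d) paste(d$subject, d$drug, d$task, d$condition)
  struct_rows <- list(); cor_rows <- list()
  for (k in seq_len(ns)) {
    nullnet <- suppressWarnings(
      rewire_null(inp$network, n_swaps_per_edge = 10, seed = sseeds[k]))
    dyn <- normalize_dynamics(nullnet, config$control$c)
    en <- persistence_energy_set(dyn, inp$states, config$control$T)
    co <- fit_energy_models(en)
    co$null_id <- k
    struct_rows[[k]] <- co
    m <- match(key(en), key(etab))
    cor_rows[[k]] <- data.frame(
      null_id = k, seed = sseeds[k],
      spearman = stats::cor(en$energy, etab$energy[m], method = "spearman"))
  }
  write_tsv(do.call(rbind, struct_rows), paths$structural_null)
  write_tsv(do.call(rbind, cor_rows), paths$structural_null_cor)
  np <- config$stats$n_spatial_nulls
  pseeds <- derive_seeds(seeds[2], np)
  dyn0 <- normalize_dynamics(inp$network, config$control$c)
  spat_rows <- lapply(seq_len(np), function(k) {
    stseeds <- derive_seeds(pseeds[k], length(inp$states))
    nulls <- Map(spatial_null, inp$states, as.list(stseeds))
    en <- persistence_energy_set(dyn0, nulls, config$control$T)
    co <- fit_energy_models(en)
    co$null_id <- k
    co
  })
  write_tsv(do.call(rbind, spat_rows), paths$spatial_null)
  invisible(paths)
}

#' Pipeline stage: mixed-model and demographic statistics
#'
#' Fits the persistence-energy models (drug x group per task x condition,
#' FDR within task), the efficiency models (efficiency ~ energy + drug +
#' group + age + sex, FDR across all cells), and the demographics
#' comparison table.
#'
#' @param config A `run_config`.
#' @export
stage_stats <- function(config) {
  config <- validate_run_config(config)
  paths <- .stage_paths(config$outdir)
  etab <- read_tsv(paths$energy)
  write_tsv(fit_energy_models(etab), paths$energy_models)
  beh <- read_tsv(paths$behavior)
  demo <- read_tsv(paths$demographics)
  rec <- merge(merge(etab, beh,
                     by = c("subject", "group", "drug", "task", "condition")),
               demo, by = c("subject", "group"))
  rec$efficiency <- efficiency(rec$accuracy, rec$median_rt)
  write_tsv(fit_efficiency_models(rec), paths$efficiency_models)
  write_tsv(demographics_table(demo, categorical = "sex",
                               continuous = "age", nonnormal = "age",
                               events = c(sex = "F")),
            paths$demographics_stats)
  invisible(paths)
}

#' Pipeline stage: receptor-map alignment
#'
#' Builds per-subject absolute control-input difference maps
#' (alprazolam minus placebo) for each threat task, tests their spatial
#' alignment with every receptor map by label permutation, and adjusts
#' across maps by FDR.
#'
#' @param config A `run_config`.
#' @export
stage_align <- function(config) {
  config <- validate_run_config(config)
  paths <- .stage_paths(config$outdir)
  ni <- read_tsv(paths$node_input)
  rec <- read_tsv(paths$receptors)
  stab <- read_tsv(paths$states)
  slab <- stab$in_slab[match(rec$parcel_label, stab$parcel_label)]
  maps <- as.list(rec[, setdiff(names(rec), "parcel_label"), drop = FALSE])
  seeds <- derive_seeds(config$seed + 211L, length(TASKS))
  rows <- lapply(seq_along(TASKS), function(ti) {
    tk <- TASKS[ti]
    d <- ni[ni$task == tk, ]
    subj <- unique(d$subject)
    dm <- t(vapply(subj, function(s) {
      dd <- d[d$subject == s & d$drug == "alprazolam", ]
      dp <- d[d$subject == s & d$drug == "placebo", ]
      stopifnot(identical(dd$parcel_label, dp$parcel_label))
      control_input_diff(
        stats::setNames(dd$value, dd$parcel_label),
        stats::setNames(dp$value, dp$parcel_label))[rec$parcel_label]
    }, numeric(nrow(rec))))
    out <- receptor_alignment_tests(dm, maps, n_perm = config$stats$n_perm,
                                    seed = seeds[ti], slab_mask = slab)
    cbind(task = tk, out, stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), paths$alignment)
  invisible(paths)
}

#' Run the full analysis pipeline
#'
#' Chains the stages `simulate`, `energy`, `impact`, `nulls`, `stats`,
#' `align` (or the subset given in `stages`, assuming earlier stages'
#' outputs exist) and writes a JSON manifest recording the config, seeds,
#' package version and completed stages. Identical config and seed give
#' byte-identical numeric tables.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param stages Character vector of stages to run, in order.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "energy", "impact", "nulls",
                                    "stats", "align")) {
  config <- validate_run_config(config)
  known <- c("simulate", "energy", "impact", "nulls", "stats", "align")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage: ", bad[1])
  paths <- .stage_paths(config$outdir)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  completed <- character()
  for (st in known[known %in% stages]) {
    message("stage ", st, " (seed ", config$seed, ")")
    switch(st,
           simulate = stage_simulate(config),
           energy = stage_energy(config),
           impact = stage_impact(config),
           nulls = stage_nulls(config),
           stats = stage_stats(config),
           align = stage_align(config))
    completed <- c(completed, st)
    manifest <- list(config = unclass(config), seed = config$seed,
                     package_version =
                       as.character(utils::packageVersion("persistenergy")),
                     stages_completed = completed)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(config$outdir)
}
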