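# Parcel-level activation states (GLM beta weights), slab masking and
# spatial permutation nulls.

#' Construct a brain activation state
#'
#' A brain state is a vector of parcel-averaged GLM beta weights describing
#' task-evoked activation, together with a mask marking which parcels fall
#' inside the functional imaging slab. Parcels outside the slab carry no
#' activation estimate; under the default `"zero"` policy they are set to
#' exactly 0 while the full parcel set (and hence all indirect structural
#' pathways) is retained, and under `"drop"` the state is restricted to the
#' in-slab parcels (the dynamics must then be restricted to the same mask).
#'
#' @param values Numeric vector of beta weights, one per parcel.
#' @param slab_mask Logical vector, `TRUE` for in-slab parcels. Default all
#'   `TRUE`.
#' @param labels Character parcel identifiers matching `values`.
#' @param meta Named list of record keys: `subject`, `group` (`control` /
#'   `relative`), `drug` (`placebo` / `alprazolam`), `task` (`identification`
#'   / `memory`), `condition` (`threat` / `nonthreat` / `neutral`).
#' @param out_of_slab_policy `"zero"` (default) or `"drop"`.
#' @return An object of class `brain_state`: list with `values`, `slab_mask`,
#'   `labels`, `meta`.
#' @export
make_state <- function(values, slab_mask = NULL, labels = NULL,
                       meta = list(), out_of_slab_policy = c("zero", "drop")) {
  out_of_slab_policy <- match.arg(out_of_slab_policy)
  values <- as.numeric(values)
  n <- length(values)
  if (is.null(slab_mask)) slab_mask <- rep(TRUE, n)
  if (is.null(labels)) labels <- sprintf("p%03d", seq_len(n))
  labels <- as.character(labels)
  if (length(slab_mask) != n || length(labels) != n)
    stop(sprintf("length mismatch: %d values, %d mask entries, %d labels",
                 n, length(slab_mask), length(labels)))
  if (any(!is.finite(values))) stop("non-finite state values")
  if (!any(slab_mask)) stop("slab mask excludes every parcel")
  if (out_of_slab_policy == "drop") {
    values <- values[slab_mask]
    labels <- labels[slab_mask]
    slab_mask <- rep(TRUE, length(values))
  } else {
    values[!slab_mask] <- 0
  }
  structure(list(values = values, slab_mask = slab_mask,
                 labels = labels, meta = meta),
            class = "brain_state")
}

#' @export
print.brain_state <- function(x, ...) {
  m <- x$meta
  key <- paste(unlist(m[c("subject", "group", "drug", "task", "condition")]),
               collapse = "/")
  cat(sprintf("brain_state: %d parcels (%d in slab)%s\n",
              length(x$values), sum(x$slab_mask),
              if (nzchar(key)) paste0(" [", key, "]") else ""))
  invisible(x)
}

#' Spatially permuted null state
#'
#' Destroys the correspondence between activation values and parcel identity
#' by uniformly permuting the in-slab values; out-of-slab entries are left
#' untouched. Used to test whether a result depends on the task-specific
#' spatial activation pattern rather than on its value distribution.
#'
#' @param state A [make_state()] object.
#' @param seed Integer seed; deterministic given the seed.
#' @return A `brain_state` with permuted in-slab values and `meta$null =
#'   "spatial"`.
#' @export
spatial_null <- function(state, seed) {
  stopifnot(inherits(state, "brain_state"))
  idx <- which(state$slab_mask)
  if (length(idx) < 2) stop("need at least 2 in-slab parcels to permute")
  v <- state$values
  v[idx] <- with_seed(seed, v[sample(idx)])
  meta <- state$meta
  meta$null <- "spatial"
  make_state(v, state$slab_mask, state$labels, meta, "zero")
}

#' Normalize state amplitude
#'
#' @param state A `brain_state`.
#' @param mode `"none"` (identity, the default: persistence energy scales
#'   with the square of state amplitude, and amplitude effects are part of
#'   the signal of interest) or `"unit_norm"` (divide by the Euclidean norm,
#'   for amplitude-free sensitivity analyses).
#' @return A `brain_state`.
#' @export
normalize_state <- function(state, mode = c("none", "unit_norm")) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "brain_state"))
  if (mode == "none") return(state)
  nrm <- sqrt(sum(state$values^2))
  if (nrm == 0) stop("cannot unit-normalize a zero state")
  state$values <- state$values / nrm
  state
}

#' Convert a list of brain states to a long-format table
#'
#' One row per (subject, group, drug, task, condition, parcel), matching the
#' on-disk state TSV dialect.
#'
#' @param states List of `brain_state` objects with complete meta.
#' @return A data frame with columns `subject`, `group`, `drug`, `task`,
#'   `condition`, `parcel_label`, `beta`, `in_slab`.
#' @export
states_to_table <- function(states) {
  stopifnot(length(states) > 0)
  do.call(rbind, lapply(states, function(s) {
    m <- s$meta
    data.frame(subject = m$subject, group = m$group, drug = m$drug,
               task = m$task, condition = m$condition,
               parcel_label = s$labels, beta = s$values,
               in_slab = s$slab_mask, stringsAsFactors = FALSE)
  }))
}

#' Rebuild brain states from a long-format table
#'
#' Inverse of [states_to_table()]. Parcel order within each record follows
#' `parcel_order` when given, otherwise the order of first appearance.
#'
#' @param tab Long-format data frame (see [states_to_table()]).
#' @param parcel_order Optional character vector fixing the canonical parcel
#'   order (normally the loaded network's labels).
#' @return A list of `brain_state` objects.
#' @export
table_to_states <- function(tab, parcel_order = NULL) {
  need <- c("subject", "group", "drug", "task", "condition",
            "parcel_label", "beta", "in_slab")
  if (!all(need %in% names(tab)))
    stop("state table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  key <- interaction(tab$subject, tab$drug, tab$task, tab$condition,
                     drop = TRUE, lex.order = TRUE)
  lapply(split(tab, key), function(d) {
    if (is.null(parcel_order)) ord <- seq_len(nrow(d))
    else {
      ord <- match(parcel_order, d$parcel_label)
      if (any(is.na(ord)))
        stop("state record missing parcel ", parcel_order[is.na(ord)][1])
    }
    make_state(d$beta[ord], as.logical(d$in_slab[ord]), d$parcel_label[ord],
               meta = list(subject = d$subject[1], group = d$group[1],
                           drug = d$drug[1], task = d$task[1],
                           condition = d$condition[1]))
  })
}
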