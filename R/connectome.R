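# Structural connectome ingestion, validation, averaging, dynamics
# normalization and degree-preserving rewiring nulls.

#' Construct a structural brain network
#'
#' A structural network is a weighted, undirected graph over labeled parcels.
#' Edge weights are non-negative connection strengths (e.g. quantitative
#' anisotropy from diffusion imaging); the diagonal is zero.
#'
#' @param weights Square numeric matrix of connection strengths. Must be
#'   symmetric (absolute tolerance `1e-10`), non-negative, finite, with a
#'   zero diagonal.
#' @param labels Character vector of unique parcel identifiers, one per row
#'   of `weights`. Defaults to the matrix dimnames, or `"p001"...` when absent.
#' @return An object of class `structural_network` with elements `weights`
#'   (with dimnames set to `labels`), `labels` and `n_nodes`.
#' @export
structural_network <- function(weights, labels = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("`weights` must be a numeric matrix")
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop(sprintf("`weights` must be square, got %d x %d", n, ncol(weights)))
  if (is.null(labels)) {
    labels <- rownames(weights)
    if (is.null(labels)) labels <- sprintf("p%03d", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n)
    stop(sprintf("%d labels for %d nodes", length(labels), n))
  if (anyDuplicated(labels))
    stop("duplicate parcel labels: ", labels[duplicated(labels)][1])
  if (any(!is.finite(weights)))
    stop("non-finite weight at row ", which(!is.finite(weights), arr.ind = TRUE)[1, 1])
  asym <- abs(weights - t(weights))
  if (max(asym) > 1e-10) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("asymmetric weights at [%d,%d]: %g vs %g",
                 ij[1], ij[2], weights[ij[1], ij[2]], weights[ij[2], ij[1]]))
  }
  if (any(diag(weights) != 0))
    stop("nonzero diagonal at node ", which(diag(weights) != 0)[1])
  if (any(weights < 0)) {
    ij <- which(weights < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative weight at [%d,%d]", ij[1], ij[2]))
  }
  weights <- (weights + t(weights)) / 2   # remove sub-tolerance asymmetry
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = labels, n_nodes = n),
            class = "structural_network")
}

#' @export
print.structural_network <- function(x, ...) {
  m <- x$weights[upper.tri(x$weights)]
  cat(sprintf("structural_network: %d nodes, %d edges, mean weight %.4g\n",
              x$n_nodes, sum(m > 0), mean(m[m > 0])))
  invisible(x)
}

#' Load a structural network from a TSV file
#'
#' Two dialects are supported. `matrix_tsv`: first row holds tab-separated
#' parcel labels, each subsequent row a label followed by `n` numeric weights.
#' `edge_list`: a header `source<TAB>target<TAB>weight` followed by one row
#' per undirected edge; unlisted pairs get weight zero and duplicate pairs
#' must agree on the weight.
#'
#' @param path Path to the file.
#' @param format One of `"matrix_tsv"` or `"edge_list"`.
#' @param labels For `edge_list` only: optional full label set (to include
#'   isolated parcels and fix node order); defaults to the sorted union of
#'   source/target labels.
#' @return A [structural_network()].
#' @export
load_network <- function(path, format = c("matrix_tsv", "edge_list"),
                         labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read network file: ", path)
  if (format == "matrix_tsv") {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             row.names = 1, check.names = FALSE)
    w <- as.matrix(tab)
    if (nrow(w) != ncol(w))
      stop(sprintf("non-square matrix in %s: %d rows, %d columns",
                   path, nrow(w), ncol(w)))
    if (!identical(rownames(w), colnames(w)))
      stop("row labels do not match column labels in ", path)
    structural_network(w, rownames(w))
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    need <- c("source", "target", "weight")
    if (!all(need %in% names(tab)))
      stop("edge list must have columns source, target, weight")
    if (is.null(labels))
      labels <- sort(unique(c(tab$source, tab$target)))
    n <- length(labels)
    w <- matrix(0, n, n, dimnames = list(labels, labels))
    seen <- new.env(parent = emptyenv())
    for (k in seq_len(nrow(tab))) {
      a <- tab$source[k]; b <- tab$target[k]; val <- tab$weight[k]
      if (!(a %in% labels) || !(b %in% labels))
        stop("edge row ", k, " names unknown parcel")
      if (a == b) stop("self-loop at row ", k, " (", a, ")")
      key <- paste(sort(c(a, b)), collapse = "\r")
      prev <- get0(key, envir = seen)
      if (!is.null(prev) && prev != val)
        stop(sprintf("conflicting duplicate edge %s-%s: %g vs %g", a, b, prev, val))
      assign(key, val, envir = seen)
      w[a, b] <- val
      w[b, a] <- val
    }
    structural_network(w, labels)
  }
}

#' Write a structural network as matrix TSV
#'
#' Emits the `matrix_tsv` dialect read by [load_network()], with 12
#' significant digits so identical inputs yield byte-identical files.
#'
#' @param network A [structural_network()].
#' @param path Output path.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "structural_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("parcel", network$labels), collapse = "\t"), con)
  body <- apply(network$weights, 1, function(r)
    paste(formatC(r, digits = 12, format = "g"), collapse = "\t"))
  writeLines(paste(network$labels, body, sep = "\t"), con)
  invisible(path)
}

#' Element-wise group average of structural networks
#'
#' Study-level connectomes are commonly the arithmetic mean of per-subject
#' matrices over a reference sample.
#'
#' @param networks List of [structural_network()] objects with identical
#'   labels in identical order.
#' @return A [structural_network()] holding the element-wise mean.
#' @export
group_average <- function(networks) {
  if (length(networks) < 1) stop("need at least one network")
  stopifnot(all(vapply(networks, inherits, TRUE, "structural_network")))
  ref <- networks[[1]]$labels
  for (i in seq_along(networks)) {
    li <- networks[[i]]$labels
    if (!identical(li, ref)) {
      j <- which(li != ref)[1]
      if (is.na(j)) j <- min(length(li), length(ref)) + 1
      stop(sprintf("label mismatch in network %d at position %d", i, j))
    }
  }
  w <- Reduce(`+`, lapply(networks, `[[`, "weights")) / length(networks)
  structural_network(w, ref)
}

#' Normalize a connectome into a stable linear dynamics matrix
#'
#' Builds the state matrix of the linear model `dx/dt = A x + B u` as
#' `A = W / (lambda_max(W) + c) - I`, where `lambda_max(W)` is the largest
#' eigenvalue of the weight matrix. For non-negative symmetric `W` and
#' `c > 0` every eigenvalue of `A` is negative, so the free dynamics decay
#' toward the origin; the largest eigenvalue of `A` is `-c/(lambda_max + c)`.
#'
#' @param network A [structural_network()].
#' @param c Stabilization constant, strictly positive. Default 1.
#' @return An object of class `dynamics_matrix`: list with `A` (dimnames
#'   from the network), `c`, `source_lambda_max` and `labels`.
#' @export
normalize_dynamics <- function(network, c = 1.0) {
  stopifnot(inherits(network, "structural_network"))
  if (!is.numeric(c) || length(c) != 1 || c <= 0)
    stop("stabilization constant `c` must be a positive scalar")
  W <- network$weights
  lam <- max(eigen(W, symmetric = TRUE, only.values = TRUE)$values)
  A <- W / (lam + c) - diag(nrow(W))
  dimnames(A) <- dimnames(W)
  structure(list(A = A, c = c, source_lambda_max = lam,
                 labels = network$labels),
            class = "dynamics_matrix")
}

#' @export
print.dynamics_matrix <- function(x, ...) {
  cat(sprintf("dynamics_matrix: %d nodes, c = %g, lambda_max(W) = %.4g, max eig(A) = %.4g\n",
              nrow(x$A), x$c, x$source_lambda_max,
              -x$c / (x$source_lambda_max + x$c)))
  invisible(x)
}

# Undirected edge list (i < j) of the nonzero upper triangle.
.edge_list <- function(w) {
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Degree-preserving rewired null network
#'
#' Topology null model for weighted connectomes: repeated double-edge swaps
#' on the binarized graph preserve every node's degree while randomizing
#' which nodes are connected; the original weight multiset is then assigned
#' to the surviving edges. With `weight_assignment = "shuffle"` weights are
#' placed uniformly at random (degree preserved, strength randomized); with
#' `"strength_rank"` the largest weights are greedily placed on the edges
#' whose endpoints have the largest original strengths, approximately
#' preserving the strength sequence.
#'
#' @param network A [structural_network()].
#' @param n_swaps_per_edge Attempted swaps per edge (default 10); `0` returns
#'   the input unchanged.
#' @param seed Integer seed; the result is reproducible given the seed.
#' @param weight_assignment `"shuffle"` (default) or `"strength_rank"`.
#' @return A [structural_network()] with the same degree sequence and weight
#'   multiset. A warning is emitted if the null network is disconnected.
#' @export
rewire_null <- function(network, n_swaps_per_edge = 10, seed,
                        weight_assignment = c("shuffle", "strength_rank")) {
  stopifnot(inherits(network, "structural_network"))
  weight_assignment <- match.arg(weight_assignment)
  w <- network$weights
  n <- nrow(w)
  edges <- .edge_list(w)
  m <- nrow(edges)
  if (n_swaps_per_edge == 0) return(network)
  if (m < 2) stop("too few edges to swap (need >= 2 disjoint edges)")
  wts <- w[edges]

  out <- with_seed(seed, {
    adj <- w > 0
    n_target <- round(n_swaps_per_edge * m)
    done <- 0L
    attempts <- 0L
    max_attempts <- 100L * n_target
    while (done < n_target && attempts < max_attempts) {
      attempts <- attempts + 1L
      k <- sample.int(m, 2)
      a <- edges[k[1], 1]; b <- edges[k[1], 2]
      c2 <- edges[k[2], 1]; d <- edges[k[2], 2]
      # randomly orient the second edge
      if (stats::runif(1) < 0.5) { tmp <- c2; c2 <- d; d <- tmp }
      # propose (a,b),(c,d) -> (a,c),(b,d)
      if (length(unique(c(a, b, c2, d))) < 4) next
      e1 <- sort(c(a, c2)); e2 <- sort(c(b, d))
      if (adj[e1[1], e1[2]] || adj[e2[1], e2[2]]) next
      adj[a, b] <- adj[b, a] <- FALSE
      adj[c2, d] <- adj[d, c2] <- FALSE
      adj[e1[1], e1[2]] <- adj[e1[2], e1[1]] <- TRUE
      adj[e2[1], e2[2]] <- adj[e2[2], e2[1]] <- TRUE
      edges[k[1], ] <- e1
      edges[k[2], ] <- e2
      done <- done + 1L
    }
    new_edges <- .edge_list(1 * adj)
    wnew <- matrix(0, n, n)
    if (weight_assignment == "shuffle") {
      assigned <- sample(wts)
    } else {
      s <- rowSums(w)
      score <- s[new_edges[, 1]] + s[new_edges[, 2]]
      assigned <- numeric(m)
      # heaviest weights on edges between high-strength endpoints
      assigned[order(score, decreasing = TRUE)] <- sort(wts, decreasing = TRUE)
    }
    wnew[new_edges] <- assigned
    wnew <- wnew + t(wnew)
    wnew
  })
  dimnames(out) <- dimnames(w)
  res <- structural_network(out, network$labels)
  comp <- .n_components(out > 0)
  if (comp > 1)
    warning(sprintf("rewired null network has %d connected components", comp))
  res
}

.n_components <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      nb <- which(adj[v, ] & !seen)
      stack <- c(stack, nb)
    }
  }
  comp
}
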