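#' Row-stochastic transition matrix of a network
#'
#' Normalizes a symmetric non-negative adjacency matrix by its degree
#' matrix, `P = D^-1 A`, so every row sums to 1. The walk itself propagates
#' probability mass with the transpose of `P` (mass flows from a node to
#' its neighbours in proportion to edge weight), which makes the walk's
#' stationary distribution degree-proportional.
#'
#' @param A Symmetric non-negative matrix (see [adjacency_matrix()]).
#' @return Row-stochastic matrix of the same dimension.
#' @export
transition_matrix <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    abort("`A` must be a square matrix.")
  }
  deg <- rowSums(A)
  zero <- deg <= 0
  if (any(zero)) {
    who <- rownames(A)[zero] %||% as.character(which(zero))
    abort(sprintf(
      "Isolated node(s) with zero degree: %s. The walk is undefined there.",
      paste(head(who, 5), collapse = ", ")
    ))
  }
  A / deg
}

#' Run a restart random walk to convergence
#'
#' Iterates `p_{t+1} = (1 - gamma) * t(P) %*% p_t + gamma * p0` until the
#' chosen norm of successive differences falls to `tol` or `max_iter` is
#' reached. `gamma` is the restart probability: at every step the walker
#' returns to the seed distribution `p0` with probability `gamma` and
#' otherwise steps along an edge. The iteration conserves probability mass
#' exactly, so each iterate is itself a distribution over genes.
#'
#' @param P Row-stochastic transition matrix from [transition_matrix()].
#' @param p0 Restart distribution (non-negative, sums to 1, length
#'   `nrow(P)`).
#' @param gamma Restart probability in \[0, 1\]. Default 0.2.
#' @param tol Convergence tolerance on the difference norm. Default 1e-6.
#' @param max_iter Iteration cap. Default 1000. If the cap is hit before
#'   the tolerance (possible e.g. for `gamma = 0` on a bipartite graph,
#'   where the power iteration oscillates), the last iterate is returned
#'   flagged `converged = FALSE` rather than looping forever.
#' @param norm Norm for the convergence test: `"l1"` (default), `"l2"`, or
#'   `"max"`.
#'
#' @return An object of class `walk_profile`: list with `p` (named
#'   probability vector), `p0`, `gamma`, `iterations`, `converged`, and
#'   `residual` (final difference norm).
#' @export
restart_walk <- function(P, p0, gamma = 0.2, tol = 1e-6, max_iter = 1000,
                         norm = c("l1", "l2", "max")) {
  norm <- match.arg(norm)
  stopifnot_scalar_number(gamma, "gamma")
  if (gamma < 0 || gamma > 1) abort("`gamma` must lie in [0, 1].")
  stopifnot_scalar_number(tol, "tol", positive = TRUE)
  if (max_iter < 1) abort("`max_iter` must be at least 1.")
  if (length(p0) != nrow(P)) {
    abort(sprintf(
      "Dimension mismatch: p0 has length %d but P is %d x %d.",
      length(p0), nrow(P), ncol(P)
    ))
  }
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-9) {
    abort("`p0` must be a probability vector (non-negative, summing to 1).")
  }
  diff_norm <- switch(norm,
    l1 = function(v) sum(abs(v)),
    l2 = function(v) sqrt(sum(v^2)),
    max = function(v) max(abs(v))
  )
  Pt <- t(P)
  p <- as.numeric(p0)
  converged <- FALSE
  residual <- Inf
  iters <- 0L
  for (i in seq_len(max_iter)) {
    p_new <- (1 - gamma) * as.numeric(Pt %*% p) + gamma * p0
    residual <- diff_norm(p_new - p)
    p <- p_new
    iters <- i
    if (residual <= tol) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(
      p = setNames(p, rownames(P)),
      p0 = setNames(as.numeric(p0), rownames(P)),
      gamma = gamma,
      iterations = iters,
      converged = converged,
      residual = residual
    ),
    class = "walk_profile"
  )
}

#' @export
print.walk_profile <- function(x, ...) {
  cat(sprintf(
    "<walk_profile> gamma=%.3g, %d iterations, %s (residual %.3g), %d genes\n",
    x$gamma, x$iterations,
    if (x$converged) "converged" else "NOT converged", x$residual, length(x$p)
  ))
  invisible(x)
}

#' Tidy a walk profile into a `(gene, probability)` tibble
#'
#' @param x A `walk_profile` from [restart_walk()] or [encode_network()].
#' @param ... Unused.
#' @return Tibble sorted by descending probability, ties by gene id.
#' @export
tidy.walk_profile <- function(x, ...) {
  tibble::tibble(gene = names(x$p), probability = as.numeric(x$p)) |>
    dplyr::arrange(dplyr::desc(.data$probability), .data$gene)
}

#' Degree-proportional stationary distribution
#'
#' For an undirected walk on a connected weighted graph, the stationary
#' distribution is proportional to node strength: `pi_i = deg_i / sum of
#' all degrees`. The returned vector is checked against the fixed-point
#' identity `pi %*% P = pi` to 1e-10.
#'
#' @param A Symmetric non-negative adjacency matrix with positive total
#'   weight.
#' @return Named probability vector `pi` over nodes.
#' @export
stationary_distribution <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) abort("`A` must be square.")
  if (sum(A) <= 0) abort("`A` must have positive total weight.")
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
  if (igraph::components(g)$no > 1) {
    warn(paste(
      "Graph is disconnected: the stationary formula still holds per",
      "component, but the walk's limit depends on where it starts."
    ))
  }
  deg <- rowSums(A)
  pi <- deg / sum(deg)
  P <- transition_matrix(A)
  gap <- max(abs(as.numeric(pi %*% P) - pi))
  if (gap > 1e-10) {
    abort(sprintf("Internal check failed: |pi P - pi| = %.3g > 1e-10.", gap))
  }
  setNames(pi, rownames(A))
}

#' Encode a network as restart-walk profiles around the seed genes
#'
#' Runs one restart walk per configuration, each starting from the uniform
#' distribution over the seed genes. By default three walks with restart
#' probabilities 0.1, 0.3 and 0.5 are run, giving three views of the
#' topology at increasing localization around the seeds; these feed the
#' three members of the downstream model ensemble. Alternatively
#' `snapshot_iters` takes intermediate iterates of a single walk.
#'
#' @param network A [gene_network()].
#' @param seeds Character vector of seed genes (see [seed_genes()]).
#' @param gammas Restart probabilities, one walk per value. Default
#'   `c(0.1, 0.3, 0.5)`.
#' @param snapshot_iters Optional integer vector: instead of varying
#'   `gammas`, run one walk at `gammas[1]` and return the iterates after
#'   these many iterations.
#' @inheritParams restart_walk
#' @return List of `walk_profile` objects, one per configuration.
#' @export
encode_network <- function(network, seeds, gammas = c(0.1, 0.3, 0.5),
                           tol = 1e-6, max_iter = 1000,
                           norm = c("l1", "l2", "max"),
                           snapshot_iters = NULL) {
  norm <- match.arg(norm)
  stopifnot(inherits(network, "gene_network"))
  if (length(seeds) == 0) abort("`seeds` must be non-empty.")
  if (length(gammas) == 0) abort("`gammas` must be non-empty.")
  missing <- setdiff(seeds, network$nodes)
  if (length(missing)) {
    abort(sprintf(
      "Seed gene(s) not in network: %s.",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  P <- transition_matrix(adjacency_matrix(network))
  p0 <- setNames(numeric(length(network$nodes)), network$nodes)
  p0[seeds] <- 1 / length(seeds)
  if (!is.null(snapshot_iters)) {
    snapshot_iters <- sort(as.integer(snapshot_iters))
    if (any(snapshot_iters < 1)) abort("`snapshot_iters` must be >= 1.")
    return(lapply(snapshot_iters, function(k) {
      restart_walk(P, p0, gamma = gammas[1], tol = 0 + .Machine$double.xmin,
                   max_iter = k, norm = norm)
    }))
  }
  lapply(gammas, function(g) {
    restart_walk(P, p0, gamma = g, tol = tol, max_iter = max_iter, norm = norm)
  })
}

#' Restart-walk diffusion kernel
#'
#' Closed form of the converged restart walk started from every single-node
#' indicator: column j of the result is the limiting distribution of a walk
#' restarting at node j, i.e. `gamma * solve(I - (1 - gamma) * t(P))`.
#' Row i therefore mixes information over the network neighbourhood of
#' gene i, and multiplying it into a per-gene feature matrix diffuses those
#' features along the topology.
#'
#' @param network A [gene_network()], or a row-stochastic matrix.
#' @param gamma Restart probability in (0, 1\].
#' @return Dense matrix `K` with `K[, j]` the walk profile seeded at node
#'   j; every column sums to 1.
#' @export
diffusion_kernel <- function(network, gamma) {
  stopifnot_scalar_number(gamma, "gamma")
  if (gamma <= 0 || gamma > 1) abort("`gamma` must lie in (0, 1].")
  P <- if (inherits(network, "gene_network")) {
    transition_matrix(adjacency_matrix(network))
  } else {
    network
  }
  n <- nrow(P)
  K <- gamma * solve(diag(n) - (1 - gamma) * t(P))
  dimnames(K) <- dimnames(P)
  K
}
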