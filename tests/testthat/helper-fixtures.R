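# Shared fixtures and independent oracles, all built in code.

# Tiny deterministic networks ------------------------------------------------

triangle_network <- function(w = c(1, 1, 1)) {
  gene_network(
    tibble::tibble(
      gene_a = c("g1", "g1", "g2"),
      gene_b = c("g2", "g3", "g3"),
      score = w
    ),
    score_scale = 1
  )
}

path_network <- function(w = c(0.5, 0.2)) {
  gene_network(
    tibble::tibble(
      gene_a = c("g1", "g2"), gene_b = c("g2", "g3"), score = w
    ),
    score_scale = 1
  )
}

# Random connected weighted graph as an adjacency matrix. Draws G(n, p)
# until connected, then puts uniform weights on the edges.
random_connected_adjacency <- function(n, p = max(0.1, 2 * log(n) / n)) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  A <- matrix(0, n, n)
  el <- igraph::as_edgelist(g)
  w <- runif(nrow(el), 0.1, 1)
  A[el] <- w
  A[el[, c(2, 1), drop = FALSE]] <- w
  rownames(A) <- colnames(A) <- sprintf("n%03d", seq_len(n))
  A
}

# Independent oracles --------------------------------------------------------

# Closed-form restart walk: p = gamma * (I - (1-gamma) t(P))^-1 p0.
walk_linear_solve <- function(P, p0, gamma) {
  n <- nrow(P)
  as.numeric(gamma * solve(diag(n) - (1 - gamma) * t(P), p0))
}

# Brute-force pairwise concordance AUC (ties count one half).
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Exhaustive threshold-enumeration AUPR: walk every distinct score level
# from the top, recompute precision/recall from scratch at each level.
aupr_enumeration <- function(scores, labels) {
  npos <- sum(labels == 1)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  rec_prev <- 0
  for (thr in thresholds) {
    sel <- scores >= thr
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / npos
    area <- area + prec * (rec - rec_prev)
    rec_prev <- rec
  }
  area
}

# Scalar triple-loop matrix product.
matmul_bruteforce <- function(A, B) {
  out <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(B))) {
      acc <- 0
      for (k in seq_len(ncol(A))) acc <- acc + A[i, k] * B[k, j]
      out[i, j] <- acc
    }
  }
  out
}
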