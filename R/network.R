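#' Build a weighted undirected gene network from an edge table
#'
#' Constructs the in-memory gene interaction network used by the walk and
#' downstream scoring. Edges are undirected: a pair is stored once
#' regardless of orientation, duplicate pairs are resolved by keeping the
#' maximum weight, and self-loops are dropped with a warning. Node order is
#' lexicographic, so the adjacency matrix is reproducible for any row order
#' of the input.
#'
#' @param edges A data frame with columns `gene_a`, `gene_b`, `score`
#'   (additional columns are ignored). Scores must be non-negative.
#' @param score_scale Positive divisor applied to raw scores. STRING-style
#'   combined scores ship on a 0--1000 scale, so the default 1000 maps
#'   weights into \[0, 1\]. Use `score_scale = 1` for already-normalized
#'   weights.
#'
#' @return An object of class `gene_network`: a list with `nodes`
#'   (lexicographically ordered gene identifiers), `edges` (a tibble with
#'   `gene_a < gene_b` and `weight`), and `node_index` (named integer
#'   positions).
#'
#' @examples
#' edges <- tibble::tibble(
#'   gene_a = c("TSHR", "TG", "TSHR"),
#'   gene_b = c("TG", "TPO", "TPO"),
#'   score  = c(900, 700, 400)
#' )
#' net <- gene_network(edges)
#' adjacency_matrix(net)
#' @export
gene_network <- function(edges, score_scale = 1000) {
  stopifnot_scalar_number(score_scale, "score_scale", positive = TRUE)
  if (!is.data.frame(edges) || nrow(edges) == 0) {
    abort("`edges` must be a non-empty data frame.")
  }
  need <- c("gene_a", "gene_b", "score")
  if (!all(need %in% names(edges))) {
    abort(sprintf(
      "`edges` must have columns %s.",
      paste0("`", need, "`", collapse = ", ")
    ))
  }
  ed <- tibble::tibble(
    gene_a = trimws(as.character(edges$gene_a)),
    gene_b = trimws(as.character(edges$gene_b)),
    score  = as.numeric(edges$score)
  )
  if (anyNA(ed$score) || any(!is.finite(ed$score))) {
    abort("Edge scores must all be finite numbers.")
  }
  if (any(ed$score < 0)) {
    abort("Edge scores must be non-negative.")
  }
  loops <- ed$gene_a == ed$gene_b
  if (any(loops)) {
    warn(sprintf("Dropped %d self-loop edge(s).", sum(loops)))
    ed <- ed[!loops, , drop = FALSE]
  }
  if (nrow(ed) == 0) {
    abort("No usable edges remain after dropping self-loops.")
  }
  # canonical orientation, then max-merge duplicates
  swap <- ed$gene_a > ed$gene_b
  tmp <- ed$gene_a[swap]
  ed$gene_a[swap] <- ed$gene_b[swap]
  ed$gene_b[swap] <- tmp
  ed <- ed |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(weight = max(.data$score) / score_scale, .groups = "drop") |>
    dplyr::arrange(.data$gene_a, .data$gene_b)

  nodes <- sort(unique(c(ed$gene_a, ed$gene_b)))
  structure(
    list(
      nodes = nodes,
      edges = ed,
      node_index = setNames(seq_along(nodes), nodes)
    ),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf(
    "<gene_network> %d genes, %d edges, weights in [%.3g, %.3g]\n",
    length(x$nodes), nrow(x$edges), min(x$edges$weight), max(x$edges$weight)
  ))
  invisible(x)
}

#' Read a weighted edge list file
#'
#' Parses a STRING-style export: three whitespace- or tab-delimited columns
#' `gene_a`, `gene_b`, `score`. A header line is auto-detected when the
#' third field of the first row is not numeric. Plain or gzip-compressed
#' text is accepted.
#'
#' @param path Path to the edge list file.
#' @return A tibble with columns `gene_a`, `gene_b`, `score`, suitable for
#'   [gene_network()].
#' @export
read_edge_list <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(sprintf("Edge list file '%s' is empty.", path))
  }
  fields <- strsplit(trimws(lines), "[\t ]+")
  first <- fields[[1]]
  start <- 1L
  if (length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))) {
    start <- 2L # header row
  }
  if (start > length(fields)) {
    abort(sprintf("Edge list file '%s' has a header but no data rows.", path))
  }
  rows <- fields[start:length(fields)]
  bad_len <- which(vapply(rows, length, 1L) < 3L)
  if (length(bad_len)) {
    abort(sprintf(
      "Malformed edge row at line %d of '%s': expected 3 fields.",
      bad_len[1] + start - 1L, path
    ))
  }
  score <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 3L)))
  if (anyNA(score)) {
    abort(sprintf(
      "Malformed edge row at line %d of '%s': score is not numeric.",
      which(is.na(score))[1] + start - 1L, path
    ))
  }
  tibble::tibble(
    gene_a = vapply(rows, `[[`, "", 1L),
    gene_b = vapply(rows, `[[`, "", 2L),
    score = score
  )
}

#' Read an edge list file and build the network in one step
#'
#' @inheritParams read_edge_list
#' @inheritParams gene_network
#' @return A `gene_network`.
#' @export
read_gene_network <- function(path, score_scale = 1000) {
  gene_network(read_edge_list(path), score_scale = score_scale)
}

#' Load known disease (seed) genes and intersect with the network
#'
#' Seed genes anchor the restart vector of the random walk and form the
#' positive class for training. Identifiers absent from the network are
#' dropped with a message; an empty intersection is an error because the
#' restart vector would be all-zero.
#'
#' @param genes Character vector of gene identifiers, or a one-column data
#'   frame of them.
#' @param network A [gene_network()].
#' @return Character vector of seed genes present in the network, sorted.
#' @export
seed_genes <- function(genes, network) {
  stopifnot(inherits(network, "gene_network"))
  if (is.data.frame(genes)) genes <- genes[[1]]
  genes <- unique(trimws(as.character(genes)))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0) {
    abort("Seed gene list is empty.")
  }
  keep <- genes[genes %in% network$nodes]
  dropped <- length(genes) - length(keep)
  if (length(keep) == 0) {
    abort("None of the seed genes are present in the network.")
  }
  inform(sprintf(
    "Seed genes: %d kept, %d not in network (dropped).",
    length(keep), dropped
  ))
  sort(keep)
}

#' Read a seed-gene list file
#'
#' One identifier per line; `#` starts a comment; blank lines are ignored.
#' Plain or gzip text.
#'
#' @param path Path to the seed list file.
#' @param network Optional [gene_network()]; when supplied the list is
#'   intersected with the network via [seed_genes()].
#' @return Character vector of gene identifiers.
#' @export
read_seed_genes <- function(path, network = NULL) {
  lines <- readr::read_lines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    abort(sprintf("Seed gene file '%s' contains no identifiers.", path))
  }
  if (is.null(network)) unique(lines) else seed_genes(lines, network)
}

#' Adjacency matrix of a gene network
#'
#' @param network A [gene_network()].
#' @return A dense symmetric numeric matrix with zero diagonal, rows and
#'   columns in the network's lexicographic node order.
#' @export
adjacency_matrix <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  n <- length(network$nodes)
  A <- matrix(0, n, n, dimnames = list(network$nodes, network$nodes))
  ia <- network$node_index[network$edges$gene_a]
  ib <- network$node_index[network$edges$gene_b]
  A[cbind(ia, ib)] <- network$edges$weight
  A[cbind(ib, ia)] <- network$edges$weight
  A
}
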