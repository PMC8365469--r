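#' Build the binary gene-by-ncRNA regulation matrix
#'
#' Each gene's raw feature vector records which non-coding RNAs regulate
#' it: entry 1 if the RNA interacts with the gene, 0 otherwise. Columns are
#' ordered deterministically with the lncRNA block first (lexicographic),
#' then the miRNA block (lexicographic). Genes with no annotation keep
#' all-zero rows; they still receive signal from neighbours once the matrix
#' is diffused along the network.
#'
#' @param pairs Data frame with columns `gene`, `rna_id`, `rna_class`
#'   (values `"lncRNA"` or `"miRNA"`). Duplicate pairs collapse to a
#'   single 1; rows whose gene is absent from the network are dropped with
#'   a warning.
#' @param network A [gene_network()]; rows of the result follow its node
#'   order.
#' @return Binary numeric matrix, genes x RNAs, with attribute
#'   `"rna_class"` giving each column's class.
#' @export
regulation_matrix <- function(pairs, network) {
  stopifnot(inherits(network, "gene_network"))
  if (!is.data.frame(pairs) || nrow(pairs) == 0) {
    abort("`pairs` must be a non-empty data frame.")
  }
  need <- c("gene", "rna_id", "rna_class")
  if (!all(need %in% names(pairs))) {
    abort("`pairs` must have columns `gene`, `rna_id`, `rna_class`.")
  }
  pr <- tibble::tibble(
    gene = trimws(as.character(pairs$gene)),
    rna_id = trimws(as.character(pairs$rna_id)),
    rna_class = trimws(as.character(pairs$rna_class))
  )
  bad <- which(!pr$rna_class %in% c("lncRNA", "miRNA"))
  if (length(bad)) {
    abort(sprintf(
      "Unknown rna_class '%s' at row %d (expected 'lncRNA' or 'miRNA').",
      pr$rna_class[bad[1]], bad[1]
    ))
  }
  unknown <- !pr$gene %in% network$nodes
  if (any(unknown)) {
    warn(sprintf(
      "Dropped %d regulation pair(s) whose gene is not in the network.",
      sum(unknown)
    ))
    pr <- pr[!unknown, , drop = FALSE]
  }
  if (nrow(pr) == 0) {
    abort("No usable regulation pairs after matching genes to the network.")
  }
  pr <- dplyr::distinct(pr)
  cls <- pr |>
    dplyr::distinct(.data$rna_id, .data$rna_class) |>
    dplyr::arrange(.data$rna_class, .data$rna_id)
  if (anyDuplicated(cls$rna_id)) {
    dup <- cls$rna_id[duplicated(cls$rna_id)][1]
    abort(sprintf("RNA id '%s' is listed under both classes.", dup))
  }
  # lncRNA block sorts before miRNA block ("lncRNA" < "miRNA")
  G <- matrix(
    0, nrow = length(network$nodes), ncol = nrow(cls),
    dimnames = list(network$nodes, cls$rna_id)
  )
  G[cbind(network$node_index[pr$gene], match(pr$rna_id, cls$rna_id))] <- 1
  attr(G, "rna_class") <- setNames(cls$rna_class, cls$rna_id)
  G
}

#' Read a gene--ncRNA regulation pair file
#'
#' TSV (or whitespace-delimited) with header `gene`, `rna_id`,
#' `rna_class`; plain or gzip text.
#'
#' @param path Path to the pair file.
#' @return Tibble with columns `gene`, `rna_id`, `rna_class`, ready for
#'   [regulation_matrix()].
#' @export
read_regulation_pairs <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(sprintf("Regulation file '%s' is empty.", path))
  }
  fields <- strsplit(trimws(lines), "[\t ]+")
  start <- if (identical(tolower(fields[[1]][1]), "gene")) 2L else 1L
  if (start > length(fields)) {
    abort(sprintf("Regulation file '%s' has a header but no data rows.", path))
  }
  rows <- fields[start:length(fields)]
  bad <- which(vapply(rows, length, 1L) < 3L)
  if (length(bad)) {
    abort(sprintf(
      "Malformed regulation row at line %d of '%s': expected 3 fields.",
      bad[1] + start - 1L, path
    ))
  }
  tibble::tibble(
    gene = vapply(rows, `[[`, "", 1L),
    rna_id = vapply(rows, `[[`, "", 2L),
    rna_class = vapply(rows, `[[`, "", 3L)
  )
}

#' Fuse a network weighting with the regulation matrix
#'
#' Matrix product of a per-gene weighting (typically the restart-walk
#' diffusion kernel, see [diffusion_kernel()]) with the binary regulation
#' matrix: each output row is a convex-like mixture of the regulation rows
#' of network-proximal genes, so the fused features carry both the
#' regulatory annotation and the network topology.
#'
#' @param weights Square numeric matrix, genes x genes (rows index output
#'   genes). The identity recovers the regulation matrix unchanged.
#' @param regulation Matrix from [regulation_matrix()] (genes x RNAs).
#' @return Numeric feature matrix, genes x RNAs.
#' @export
fuse_features <- function(weights, regulation) {
  if (!is.matrix(weights) || !is.matrix(regulation)) {
    abort("`weights` and `regulation` must be matrices.")
  }
  if (ncol(weights) != nrow(regulation)) {
    abort(sprintf(
      "Dimension mismatch: weights is %d x %d but regulation has %d rows.",
      nrow(weights), ncol(weights), nrow(regulation)
    ))
  }
  out <- weights %*% regulation
  dimnames(out) <- list(rownames(weights), colnames(regulation))
  out
}

#' Build the walk-fused feature sets for the model ensemble
#'
#' For each restart probability, diffuses the regulation matrix through the
#' restart-walk kernel and appends the disease-level walk profile (seeded
#' at the known genes) as one extra column, `".disease_walk"`. The default
#' three restart probabilities produce the three feature sets consumed by
#' [train_ensemble()].
#'
#' @param network A [gene_network()].
#' @param seeds Seed genes (see [seed_genes()]).
#' @param regulation Matrix from [regulation_matrix()].
#' @param gammas Restart probabilities, one feature set per value.
#' @inheritParams restart_walk
#' @return Named list of feature matrices (one per gamma), each with a
#'   `"gamma"` attribute recording its provenance.
#' @export
build_feature_sets <- function(network, seeds, regulation,
                               gammas = c(0.1, 0.3, 0.5),
                               tol = 1e-6, max_iter = 1000) {
  stopifnot(inherits(network, "gene_network"))
  if (!identical(rownames(regulation), network$nodes)) {
    abort("`regulation` rows must match the network node order.")
  }
  profiles <- encode_network(network, seeds, gammas = gammas,
                             tol = tol, max_iter = max_iter)
  sets <- purrr::map2(gammas, profiles, function(g, prof) {
    K <- diffusion_kernel(network, g)
    F <- fuse_features(K, regulation)
    F <- cbind(F, .disease_walk = as.numeric(prof$p))
    attr(F, "gamma") <- g
    F
  })
  names(sets) <- sprintf("gamma_%g", gammas)
  sets
}
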