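#' Specification for a synthetic prioritization benchmark
#'
#' Describes a planted-module benchmark: a weighted network in which a
#' designated disease module is much more densely wired internally than
#' the background (the topological signature of known disease genes
#' clustering together), plus a binary regulation matrix in which module
#' genes preferentially carry a set of module-specific ncRNA regulators.
#' A subset of the module is revealed as seeds; the remaining module genes
#' are the unlabeled positives a method should recover.
#'
#' Defaults are sized for fast, repeated benchmarking: 300 genes with a
#' 60-gene module and 30 seeds, within-module edge probability 0.20
#' against a 0.02 background, edge weights uniform on \[0.4, 1\], and 40
#' lncRNAs plus 40 miRNAs of which 10 + 10 are module regulators carried
#' by module genes with probability 0.6 versus 0.05 elsewhere.
#'
#' @param n_genes Total genes.
#' @param n_disease Planted module size.
#' @param n_seeds Labeled (seed) subset of the module.
#' @param p_in Within-module edge probability.
#' @param p_out Background edge probability (must be `< p_in`).
#' @param weight_range Length-2 interval for uniform edge weights.
#' @param n_lnc,n_mi Number of lncRNAs / miRNAs.
#' @param n_module_lnc,n_module_mi How many of each are module-specific
#'   regulators.
#' @param enrich_module Probability a module gene carries each module
#'   regulator.
#' @param enrich_background Probability any gene carries a non-module
#'   regulator, and a background gene a module regulator (must be
#'   `< enrich_module`).
#' @param rng_seed Integer seed; the whole bundle is deterministic in it.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_genes = 300, n_disease = 60, n_seeds = 30,
                       p_in = 0.20, p_out = 0.02,
                       weight_range = c(0.4, 1),
                       n_lnc = 40, n_mi = 40,
                       n_module_lnc = 10, n_module_mi = 10,
                       enrich_module = 0.6, enrich_background = 0.05,
                       rng_seed = 1) {
  spec <- list(
    n_genes = n_genes, n_disease = n_disease, n_seeds = n_seeds,
    p_in = p_in, p_out = p_out, weight_range = weight_range,
    n_lnc = n_lnc, n_mi = n_mi,
    n_module_lnc = n_module_lnc, n_module_mi = n_module_mi,
    enrich_module = enrich_module, enrich_background = enrich_background,
    rng_seed = rng_seed
  )
  if (!(n_seeds <= n_disease && n_disease <= n_genes)) {
    abort("Need n_seeds <= n_disease <= n_genes.")
  }
  if (n_seeds < 1) abort("Need at least one seed gene.")
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    abort("Need 0 <= p_out < p_in <= 1.")
  }
  if (length(weight_range) != 2 || weight_range[1] <= 0 ||
      weight_range[1] > weight_range[2]) {
    abort("`weight_range` must be a positive, ordered interval.")
  }
  if (!(enrich_background < enrich_module)) {
    abort("Need enrich_background < enrich_module.")
  }
  if (n_module_lnc > n_lnc || n_module_mi > n_mi) {
    abort("Module regulators cannot exceed the RNA counts.")
  }
  structure(spec, class = "synth_spec")
}

#' Generate a synthetic prioritization benchmark
#'
#' Draws the planted-partition network (module edges with probability
#' `p_in`, all other pairs `p_out`, weights uniform in `weight_range`),
#' keeps the largest connected component so the walk is well defined,
#' samples the seed set from the surviving module genes, and draws the
#' regulation pairs with module-enriched probabilities. Pure in-memory;
#' use [export_bundle()] to write files.
#'
#' @param spec A [synth_spec()].
#' @return An object of class `synth_bundle`: `network`
#'   ([gene_network()]), `seeds`, `regulation` (binary matrix),
#'   `regulation_pairs` (tibble), `truth` (tibble `gene`, `label` with 1
#'   for every module gene, labeled or not), and the `spec`.
#' @export
generate_bundle <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$rng_seed, {
    ndig <- max(3, nchar(as.character(spec$n_genes)))
    genes <- sprintf(paste0("G%0", ndig, "d"), seq_len(spec$n_genes))
    module <- genes[seq_len(spec$n_disease)]
    g <- igraph::sample_sbm(
      spec$n_genes,
      pref.matrix = matrix(c(spec$p_in, spec$p_out,
                             spec$p_out, spec$p_out), 2),
      block.sizes = c(spec$n_disease, spec$n_genes - spec$n_disease)
    )
    igraph::V(g)$name <- genes
    comp <- igraph::components(g)
    keep <- names(comp$membership)[comp$membership == which.max(comp$csize)]
    module_kept <- intersect(module, keep)
    if (length(module_kept) < spec$n_seeds) {
      abort(paste(
        "Largest connected component retains too few module genes;",
        "increase p_out or p_in."
      ))
    }
    g <- igraph::induced_subgraph(g, keep)
    el <- igraph::as_edgelist(g)
    edges <- tibble::tibble(
      gene_a = el[, 1], gene_b = el[, 2],
      score = runif(nrow(el), spec$weight_range[1], spec$weight_range[2])
    )
    network <- gene_network(edges, score_scale = 1)
    dropped <- spec$n_genes - length(network$nodes)
    if (dropped > 0) {
      inform(sprintf(
        "Largest component retained: %d of %d genes (%d module genes).",
        length(network$nodes), spec$n_genes, length(module_kept)
      ))
    }
    seeds <- sort(sample(module_kept, spec$n_seeds))

    lnc <- sprintf("L%03d", seq_len(spec$n_lnc))
    mi <- sprintf("M%03d", seq_len(spec$n_mi))
    module_rnas <- c(lnc[seq_len(spec$n_module_lnc)],
                     mi[seq_len(spec$n_module_mi)])
    rnas <- c(lnc, mi)
    rna_class <- rep(c("lncRNA", "miRNA"), c(spec$n_lnc, spec$n_mi))
    is_module_gene <- network$nodes %in% module_kept
    prob <- matrix(spec$enrich_background,
                   nrow = length(network$nodes), ncol = length(rnas))
    prob[is_module_gene, rnas %in% module_rnas] <- spec$enrich_module
    hit <- matrix(runif(length(prob)) < prob, nrow = nrow(prob))
    idx <- which(hit, arr.ind = TRUE)
    if (nrow(idx) == 0) abort("Regulation draw produced no pairs.")
    pairs <- tibble::tibble(
      gene = network$nodes[idx[, 1]],
      rna_id = rnas[idx[, 2]],
      rna_class = rna_class[idx[, 2]]
    ) |>
      dplyr::arrange(.data$gene, .data$rna_id)
    regulation <- regulation_matrix(pairs, network)
    truth <- tibble::tibble(
      gene = network$nodes,
      label = as.integer(is_module_gene)
    )
    structure(
      list(
        network = network, seeds = seeds, regulation = regulation,
        regulation_pairs = pairs, truth = truth, spec = spec
      ),
      class = "synth_bundle"
    )
  })
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat(sprintf(
    "<synth_bundle> %d genes (%d module, %d seeds), %d edges, %d RNAs, %d regulation pairs\n",
    length(x$network$nodes), sum(x$truth$label), length(x$seeds),
    nrow(x$network$edges), ncol(x$regulation), nrow(x$regulation_pairs)
  ))
  invisible(x)
}

#' Write a synthetic bundle to plain-text files
#'
#' Writes `edges.tsv` (gene_a, gene_b, score — weights on their native
#' scale, so reload with `score_scale = 1`), `seeds.txt`,
#' `regulation.tsv` and `truth.tsv` into `dir`. The files round-trip
#' through [read_gene_network()], [read_seed_genes()] and
#' [read_regulation_pairs()] to the identical in-memory objects.
#'
#' @param bundle A [generate_bundle()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synth_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  edges <- bundle$network$edges
  writeLines(
    c(
      "gene_a\tgene_b\tscore",
      sprintf("%s\t%s\t%.17g", edges$gene_a, edges$gene_b, edges$weight)
    ),
    file.path(dir, "edges.tsv")
  )
  writeLines(bundle$seeds, file.path(dir, "seeds.txt"))
  readr::write_tsv(bundle$regulation_pairs, file.path(dir, "regulation.tsv"))
  readr::write_tsv(bundle$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
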