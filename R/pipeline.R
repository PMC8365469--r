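#' Train the three-member RVM ensemble
#'
#' Fits one relevance vector machine per walk-derived feature set on the
#' designated training genes. The three members carry equal weight; their
#' averaged prediction is the final gene score. All members are trained on
#' the identical gene subset.
#'
#' @param training Data frame with columns `gene` and `label` (binary 0/1,
#'   both classes present); rows designate the training genes.
#' @param feature_sets List of exactly three feature matrices with
#'   identical gene rownames (see [build_feature_sets()]).
#' @param width Kernel bandwidth shared by the members; `NULL` uses the
#'   median heuristic per member.
#' @param ... Further arguments passed to [rvm_fit()] (`max_iter`,
#'   `prune_threshold`, ...).
#' @return An object of class `rvm_ensemble`: the three fitted members with
#'   their feature provenance and equal weights 1/3.
#' @export
train_ensemble <- function(training, feature_sets, width = NULL, ...) {
  if (!is.list(feature_sets) || length(feature_sets) != 3) {
    abort("`feature_sets` must be a list of exactly three feature matrices.")
  }
  rn <- rownames(feature_sets[[1]])
  if (is.null(rn)) abort("Feature matrices must have gene rownames.")
  for (k in 2:3) {
    if (!identical(rownames(feature_sets[[k]]), rn)) {
      abort("All three feature sets must share identical gene rows.")
    }
  }
  if (!is.data.frame(training) ||
      !all(c("gene", "label") %in% names(training))) {
    abort("`training` must be a data frame with columns `gene` and `label`.")
  }
  genes <- as.character(training$gene)
  labels <- as.numeric(training$label)
  if (!all(labels %in% c(0, 1))) abort("`label` must be binary 0/1.")
  if (length(unique(labels)) < 2) {
    abort("Training labels must contain both classes.")
  }
  missing <- setdiff(genes, rn)
  if (length(missing)) {
    abort(sprintf(
      "Training gene(s) absent from feature matrices: %s.",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  members <- purrr::map(feature_sets, function(F) {
    rvm_fit(F[genes, , drop = FALSE], labels, width = width, ...)
  })
  structure(
    list(
      members = members,
      provenance = purrr::map(feature_sets, ~ attr(.x, "gamma")),
      member_weights = rep(1 / 3, 3),
      training_genes = genes
    ),
    class = "rvm_ensemble"
  )
}

#' @export
print.rvm_ensemble <- function(x, ...) {
  rv <- vapply(x$members, function(m) length(m$relevance_index), 1L)
  cat(sprintf(
    "<rvm_ensemble> 3 equal-weight members (relevance vectors: %s), trained on %d genes\n",
    paste(rv, collapse = "/"), length(x$training_genes)
  ))
  invisible(x)
}

#' Tidy an RVM ensemble
#'
#' @param x An [train_ensemble()] fit.
#' @param ... Unused.
#' @return Per-member summary tibble (member id, provenance gamma,
#'   relevance-vector count, noise variance, convergence).
#' @export
tidy.rvm_ensemble <- function(x, ...) {
  purrr::imap_dfr(x$members, function(m, i) {
    g <- glance(m)
    tibble::tibble(
      member = if (is.character(i)) i else paste0("m", i),
      gamma = x$provenance[[i]] %||% NA_real_,
      n_relevance = g$n_relevance,
      sigma2 = g$sigma2,
      iterations = g$iterations,
      converged = g$converged
    )
  })
}

#' Score candidate genes with a fitted ensemble
#'
#' Each member predicts from its own feature set; the final score is the
#' equal-weight arithmetic mean of the three member scores. The table is
#' sorted by descending final score with lexicographic gene-id
#' tie-breaking, so ranking is deterministic.
#'
#' @param model An [train_ensemble()] fit.
#' @param feature_sets The same three feature matrices used in training
#'   (full gene rows).
#' @param genes Genes to score; default all rows of the feature matrices.
#'   Unknown genes raise an error naming them.
#' @param seeds Character vector of known disease genes, flagged (never
#'   treated as novel).
#' @return A tibble with columns `gene`, `score_m1`, `score_m2`,
#'   `score_m3`, `score_final`, `rank`, `is_seed`.
#' @export
score_genes <- function(model, feature_sets, genes = NULL,
                        seeds = character()) {
  stopifnot(inherits(model, "rvm_ensemble"))
  if (length(feature_sets) != 3) {
    abort("`feature_sets` must hold the ensemble's three feature matrices.")
  }
  rn <- rownames(feature_sets[[1]])
  if (is.null(genes)) genes <- rn
  genes <- as.character(genes)
  missing <- setdiff(genes, rn)
  if (length(missing)) {
    abort(sprintf(
      "Unknown gene(s): %s.", paste(head(missing, 10), collapse = ", ")
    ))
  }
  preds <- purrr::map2(model$members, feature_sets, function(m, F) {
    predict(m, F[genes, , drop = FALSE])$.pred
  })
  out <- tibble::tibble(
    gene = genes,
    score_m1 = preds[[1]],
    score_m2 = preds[[2]],
    score_m3 = preds[[3]]
  ) |>
    dplyr::mutate(
      # compensated form of the equal-weight mean: exact (not merely within
      # rounding) when the three members agree
      score_final = .data$score_m1 +
        ((.data$score_m2 - .data$score_m1) +
           (.data$score_m3 - .data$score_m1)) / 3,
      is_seed = .data$gene %in% seeds
    ) |>
    dplyr::arrange(dplyr::desc(.data$score_final), .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select(
      "gene", "score_m1", "score_m2", "score_m3",
      "score_final", "rank", "is_seed"
    )
  out
}

#' Report putative novel disease genes
#'
#' Filters the score table to genes that are not already known (seed)
#' genes and whose final score reaches the threshold. The full ranked
#' table remains available from [score_genes()], so the threshold is a
#' reporting convenience, not a hard model decision.
#'
#' @param scores Score table from [score_genes()].
#' @param seeds Known disease genes.
#' @param threshold Minimum final score to report. Default 0.5.
#' @return Filtered tibble sorted by descending score.
#' @export
novel_genes <- function(scores, seeds, threshold = 0.5) {
  if (!is.finite(threshold)) {
    if (!identical(threshold, -Inf)) abort("`threshold` must be finite or -Inf.")
  }
  out <- scores |>
    dplyr::filter(!.data$gene %in% seeds, .data$score_final >= threshold) |>
    dplyr::arrange(dplyr::desc(.data$score_final), .data$gene)
  inform(sprintf("%d candidate novel gene(s) at threshold %.3g.",
                 nrow(out), threshold))
  out
}

#' Run the full prioritization pipeline on one dataset
#'
#' Convenience wrapper: encodes the network with three restart walks,
#' fuses the walk kernels with the regulation matrix, trains the ensemble
#' on the seed genes (positives) versus a reproducible random sample of
#' non-seed genes (negatives, same count as the seeds), and scores every
#' gene in the network.
#'
#' @param network A [gene_network()].
#' @param seeds Seed genes (see [seed_genes()]).
#' @param regulation Matrix from [regulation_matrix()].
#' @param gammas Restart probabilities for the three walks.
#' @param n_negative Number of negative training genes sampled from the
#'   non-seed pool. Default `length(seeds)`.
#' @param rng_seed Integer seed controlling the negative sample.
#' @param width,... Passed to [train_ensemble()] / [rvm_fit()].
#' @return List with `scores` (tibble from [score_genes()]), `model`, the
#'   `feature_sets`, and the sampled `negatives`.
#' @export
rwrvm_run <- function(network, seeds, regulation,
                      gammas = c(0.1, 0.3, 0.5),
                      n_negative = length(seeds), rng_seed = 42,
                      width = NULL, ...) {
  feature_sets <- build_feature_sets(network, seeds, regulation,
                                     gammas = gammas)
  pool <- setdiff(network$nodes, seeds)
  negatives <- sample_negatives(pool, n_negative, rng_seed)
  training <- tibble::tibble(
    gene = c(seeds, negatives),
    label = rep(c(1, 0), c(length(seeds), length(negatives)))
  )
  model <- train_ensemble(training, feature_sets, width = width, ...)
  scores <- score_genes(model, feature_sets, seeds = seeds)
  list(
    scores = scores, model = model,
    feature_sets = feature_sets, negatives = negatives
  )
}
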