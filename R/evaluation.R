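#' Sample negative genes from the unlabeled pool
#'
#' In the positive-unlabeled setting only disease genes are annotated, so
#' "negatives" are drawn uniformly without replacement from the genes that
#' are not seeds. Reproducible for a given seed; the caller's RNG state is
#' left untouched.
#'
#' @param pool Character vector of candidate genes (must exclude seeds).
#' @param n Number of negatives to draw.
#' @param rng_seed Integer seed.
#' @return Character vector of `n` genes.
#' @export
sample_negatives <- function(pool, n, rng_seed) {
  pool <- as.character(pool)
  if (n > length(pool)) {
    abort(sprintf(
      "Cannot draw %d negatives from a pool of %d genes.", n, length(pool)
    ))
  }
  with_seed(rng_seed, sample(pool, n))
}

#' Assign genes to stratified k folds
#'
#' Positives and negatives are shuffled and dealt into folds separately,
#' so each fold keeps the class balance by construction and fold sizes
#' within a class differ by at most one. Every gene lands in exactly one
#' fold.
#'
#' @param positives,negatives Character vectors of gene ids (disjoint).
#' @param k Number of folds (at least 2).
#' @param rng_seed Integer seed.
#' @return Tibble with columns `gene`, `label` (1/0), `fold` (1..k).
#' @export
kfold_assign <- function(positives, negatives, k, rng_seed) {
  if (k < 2) abort("`k` must be at least 2.")
  if (length(positives) < k || length(negatives) < k) {
    abort("Each class must have at least `k` members.")
  }
  with_seed(rng_seed, {
    pos <- sample(as.character(positives))
    neg <- sample(as.character(negatives))
    tibble::tibble(
      gene = c(pos, neg),
      label = rep(c(1, 0), c(length(pos), length(neg))),
      fold = c(
        rep_len(seq_len(k), length(pos)),
        rep_len(seq_len(k), length(neg))
      )
    )
  })
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann--Whitney) formula with midranks, so it
#' equals the probability that a uniformly chosen positive outranks a
#' uniformly chosen negative, with ties counted one half. Invariant under
#' strictly monotone transforms of the scores.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length.")
  }
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    abort("Both classes must be present to compute AUC.")
  }
  r <- rank(scores) # midranks for ties
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision--recall curve
#'
#' Step-curve area from a descending-score sweep in which tied scores are
#' processed as a single block: precision is evaluated only after all
#' items at a threshold are admitted, and the area accumulates
#' `precision * delta(recall)` over blocks. With all scores tied the
#' curve collapses to a single point at the class prevalence.
#'
#' @inheritParams roc_auc
#' @return AUPR in (0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length.")
  }
  npos <- sum(labels == 1)
  if (npos == 0) abort("At least one positive is required for AUPR.")
  sweep <- pr_points(scores, labels)
  sum(sweep$precision * diff(c(0, sweep$recall)))
}

#' ROC curve points
#'
#' One `(fpr, tpr)` point per distinct score threshold (descending), tied
#' scores as a block, with the (0, 0) origin prepended. Useful for
#' plotting or exporting curves, including for externally supplied
#' baseline score vectors.
#'
#' @inheritParams roc_auc
#' @return Tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.numeric(labels)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) abort("Both classes must be present.")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  block_end <- which(diff(s) != 0)
  block_end <- c(block_end, length(s))
  tp <- cumsum(l)[block_end]
  fp <- block_end - tp
  tibble::tibble(
    threshold = c(Inf, s[block_end]),
    fpr = c(0, fp / nneg),
    tpr = c(0, tp / npos)
  )
}

#' Precision--recall curve points
#'
#' One `(recall, precision)` point per distinct score threshold
#' (descending), tied scores as a block.
#'
#' @inheritParams roc_auc
#' @return Tibble with columns `threshold`, `recall`, `precision`.
#' @export
pr_points <- function(scores, labels) {
  labels <- as.numeric(labels)
  npos <- sum(labels == 1)
  if (npos == 0) abort("At least one positive is required.")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  block_end <- which(diff(s) != 0)
  block_end <- c(block_end, length(s))
  tp <- cumsum(l)[block_end]
  tibble::tibble(
    threshold = s[block_end],
    recall = tp / npos,
    precision = tp / block_end
  )
}

#' Repeated negative-sampling k-fold cross-validation
#'
#' Evaluation protocol for the positive-unlabeled setting: in each of
#' `n_repeats` repeats a fresh set of negatives (same count as the
#' positives) is sampled from the non-seed genes, positives and negatives
#' are dealt into `k` stratified folds, the three-member ensemble is
#' trained on k-1 folds and scored on the held-out fold, and AUC/AUPR are
#' recorded per fold. Walk encoding and feature fusion are computed once
#' from the full network and full seed list — the literal protocol of the
#' method — unless `refit_walk_per_fold = TRUE`, which re-runs the walk
#' with only the training-fold positives in the restart vector (the
#' leakage-free variant).
#'
#' All randomness flows from `master_seed` through a fixed derivation
#' rule; the derived per-repeat seeds are recorded in the report, and two
#' runs with the same master seed are identical.
#'
#' @param network A [gene_network()].
#' @param seeds Seed genes (positive class).
#' @param regulation Matrix from [regulation_matrix()].
#' @param gammas Restart probabilities for the three walks.
#' @param n_repeats Number of negative-sampling repeats. Default 10.
#' @param k Folds per repeat. Default 10.
#' @param master_seed Integer master seed. Default 42.
#' @param shuffle_labels Permute the class labels within each repeat's
#'   dataset before folding — a null calibration that should drive AUC to
#'   about 0.5. Default `FALSE`.
#' @param refit_walk_per_fold Re-encode the walk per fold using only
#'   training positives as restart mass. Default `FALSE`.
#' @param width,... Passed to [train_ensemble()] / [rvm_fit()].
#' @return An object of class `cv_report`: `folds` (per-repeat, per-fold
#'   AUC/AUPR tibble), `repeats` (per-repeat mean and sd with the RNG
#'   seed used), `summary` (grand means across repeats), and the
#'   configuration.
#' @export
cross_validate <- function(network, seeds, regulation,
                           gammas = c(0.1, 0.3, 0.5),
                           n_repeats = 10, k = 10, master_seed = 42,
                           shuffle_labels = FALSE,
                           refit_walk_per_fold = FALSE,
                           width = NULL, ...) {
  stopifnot(inherits(network, "gene_network"))
  seeds <- sort(as.character(seeds))
  pool <- setdiff(network$nodes, seeds)
  feature_sets <- build_feature_sets(network, seeds, regulation,
                                     gammas = gammas)
  fold_rows <- vector("list", n_repeats)
  repeat_seeds <- integer(n_repeats)
  for (r in seq_len(n_repeats)) {
    seed_r <- derive_seed(master_seed, r)
    repeat_seeds[r] <- seed_r
    negatives <- sample_negatives(pool, length(seeds), derive_seed(seed_r, 1))
    pos <- seeds
    neg <- negatives
    if (shuffle_labels) {
      # null calibration: permute labels over the dataset, then stratify on
      # the permuted labels so every fold still holds both classes
      genes_r <- c(seeds, negatives)
      lab_r <- with_seed(
        derive_seed(seed_r, 3),
        sample(rep(c(1, 0), c(length(seeds), length(negatives))))
      )
      pos <- genes_r[lab_r == 1]
      neg <- genes_r[lab_r == 0]
    }
    dataset <- kfold_assign(pos, neg, k, derive_seed(seed_r, 2))
    metrics <- purrr::map_dfr(seq_len(k), function(f) {
      train_df <- dataset[dataset$fold != f, c("gene", "label")]
      test_df <- dataset[dataset$fold == f, c("gene", "label")]
      fs <- feature_sets
      if (refit_walk_per_fold) {
        train_pos <- train_df$gene[train_df$label == 1]
        fs <- build_feature_sets(network, train_pos, regulation,
                                 gammas = gammas)
      }
      model <- train_ensemble(train_df, fs, width = width, ...)
      sc <- score_genes(model, fs, genes = test_df$gene)
      joined <- dplyr::left_join(test_df, sc, by = "gene")
      tibble::tibble(
        fold = f,
        auc = roc_auc(joined$score_final, joined$label),
        aupr = pr_auc(joined$score_final, joined$label),
        n_test = nrow(joined)
      )
    })
    fold_rows[[r]] <- dplyr::mutate(metrics, repeat_id = r,
                                    .before = "fold")
  }
  folds <- dplyr::bind_rows(fold_rows)
  repeats <- folds |>
    dplyr::group_by(.data$repeat_id) |>
    dplyr::summarise(
      auc_mean = mean(.data$auc), auc_sd = stats::sd(.data$auc),
      aupr_mean = mean(.data$aupr), aupr_sd = stats::sd(.data$aupr),
      .groups = "drop"
    ) |>
    dplyr::mutate(rng_seed = repeat_seeds)
  summary <- tibble::tibble(
    auc_grand_mean = mean(repeats$auc_mean),
    auc_grand_sd = stats::sd(repeats$auc_mean),
    aupr_grand_mean = mean(repeats$aupr_mean),
    aupr_grand_sd = stats::sd(repeats$aupr_mean),
    n_repeats = n_repeats,
    k = k
  )
  structure(
    list(
      folds = folds, repeats = repeats, summary = summary,
      config = list(
        gammas = gammas, n_repeats = n_repeats, k = k,
        master_seed = master_seed, shuffle_labels = shuffle_labels,
        refit_walk_per_fold = refit_walk_per_fold
      )
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<cv_report> %d repeats x %d folds\n  AUC  %.3f +/- %.3f\n  AUPR %.3f +/- %.3f\n",
    s$n_repeats, s$k, s$auc_grand_mean, s$auc_grand_sd,
    s$aupr_grand_mean, s$aupr_grand_sd
  ))
  invisible(x)
}

#' Tidy a cross-validation report
#'
#' @param x A [cross_validate()] report.
#' @param ... Unused.
#' @return Per-repeat tibble: `repeat_id`, `auc_mean`, `auc_sd`,
#'   `aupr_mean`, `aupr_sd`, `rng_seed` (mean and sd are across the folds
#'   of that repeat).
#' @export
tidy.cv_report <- function(x, ...) {
  x$repeats
}

#' One-line summary of a cross-validation report
#'
#' @param x A [cross_validate()] report.
#' @param ... Unused.
#' @return One-row tibble of grand means and sds across repeats.
#' @export
glance.cv_report <- function(x, ...) {
  x$summary
}
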