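#' Gaussian (RBF) kernel
#'
#' `K(x, y) = exp(-||x - y||^2 / (2 * width^2))`; symmetric, equal to 1 at
#' zero distance and positive everywhere.
#'
#' @param x,y Numeric vectors of equal length.
#' @param width Positive bandwidth.
#' @return Kernel value in (0, 1\].
#' @export
gaussian_kernel <- function(x, y, width) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length.")
  }
  stopifnot_scalar_number(width, "width", positive = TRUE)
  exp(-sum((x - y)^2) / (2 * width^2))
}

#' Kernel design matrix with bias column
#'
#' Row i is `[1, K(x_i, c_1), ..., K(x_i, c_M)]` for basis centres `c_j`.
#' During training the centres are the training inputs themselves, giving
#' the square-plus-bias design of kernel regression.
#'
#' @param X Numeric matrix of query points (rows).
#' @param centers Numeric matrix of basis centres (rows); defaults to `X`.
#' @param width Positive Gaussian bandwidth.
#' @return Numeric matrix, `nrow(X)` x `(nrow(centers) + 1)`.
#' @export
design_matrix <- function(X, centers = X, width) {
  X <- as.matrix(X)
  centers <- as.matrix(centers)
  if (ncol(X) != ncol(centers)) {
    abort("`X` and `centers` must have the same number of columns.")
  }
  stopifnot_scalar_number(width, "width", positive = TRUE)
  K <- exp(-pairwise_sqdist(X, centers) / (2 * width^2))
  Phi <- cbind(1, K)
  dimnames(Phi) <- list(rownames(X), NULL)
  Phi
}

#' Median-heuristic kernel bandwidth
#'
#' The median of all pairwise Euclidean distances among the training
#' inputs — a standard scale-free default for Gaussian kernels. Falls back
#' to 1 when all points coincide.
#'
#' @param X Numeric matrix of inputs (rows).
#' @return Positive scalar bandwidth.
#' @export
median_width <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) return(1)
  d <- sqrt(pairwise_sqdist(X, X))
  d <- d[upper.tri(d)]
  m <- median(d)
  if (!is.finite(m) || m <= 0) 1 else m
}

# Posterior of the weights for fixed hyperparameters:
#   Sigma = (Phi' Phi / sigma2 + diag(alpha))^-1,  mu = Sigma Phi' t / sigma2.
# Solved by Cholesky with jitter escalation on failure.
#' Weight posterior for fixed hyperparameters
#'
#' Computes the Gaussian posterior over weights given the design matrix,
#' targets, per-weight precisions `alpha` and noise variance `sigma2`:
#' covariance `(Phi' Phi / sigma2 + diag(alpha))^-1` and mean
#' `Sigma Phi' t / sigma2`. Exposed mainly so the re-estimation step can be
#' checked against direct dense linear algebra.
#'
#' @param Phi Design matrix (n x m).
#' @param t Numeric target vector (length n).
#' @param alpha Per-weight precisions (length m, or scalar recycled).
#' @param sigma2 Noise variance (positive scalar).
#' @return List with `mu` (length m) and `Sigma` (m x m).
#' @export
rvm_posterior <- function(Phi, t, alpha, sigma2) {
  m <- ncol(Phi)
  alpha <- rep_len(alpha, m)
  H <- crossprod(Phi) / sigma2 + diag(alpha, m)
  L <- NULL
  for (jitter in c(0, 1e-10, 1e-8, 1e-6)) {
    L <- tryCatch(chol(H + diag(jitter, m)), error = function(e) NULL)
    if (!is.null(L)) break
  }
  if (is.null(L)) {
    abort("Posterior precision matrix could not be factorized.")
  }
  Sigma <- chol2inv(L)
  mu <- as.numeric(Sigma %*% crossprod(Phi, t)) / sigma2
  list(mu = mu, Sigma = Sigma)
}

# Log marginal likelihood log p(t | alpha, sigma2) with weights
# integrated out; C = sigma2 I + Phi diag(1/alpha) Phi'.
rvm_log_marginal <- function(Phi, t, alpha, sigma2) {
  n <- nrow(Phi)
  C <- diag(sigma2, n) + Phi %*% (t(Phi) / alpha)
  L <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(L)) return(NA_real_)
  logdet <- 2 * sum(log(diag(L)))
  quad <- sum(backsolve(L, t, transpose = TRUE)^2)
  -0.5 * (n * log(2 * pi) + logdet + quad)
}

#' Fit a relevance vector machine by type-II maximum likelihood
#'
#' Sparse Bayesian kernel regression: targets are modelled as
#' `t = Phi w + eps` with Gaussian noise, each weight carries an
#' independent zero-mean Gaussian prior with its own precision `alpha_i`,
#' and the precisions and noise variance are re-estimated by maximizing
#' the marginal likelihood (Gamma hyperpriors on `alpha` and the noise
#' precision are taken in their flat limit). Precisions driven to
#' infinity prune their basis functions; the surviving training points are
#' the relevance vectors. Re-estimation uses the classical fixed-point
#' updates `alpha_i <- gamma_i / mu_i^2` with `gamma_i = 1 - alpha_i
#' Sigma_ii` and `sigma2 <- ||t - Phi mu||^2 / (n - sum(gamma_i))`.
#'
#' Binary labels in `{0, 1}` are handled as regression targets; predicted
#' means serve directly as ranking scores.
#'
#' @param X Numeric matrix of training inputs (rows), or a data frame of
#'   numeric columns. At least 2 rows.
#' @param t Numeric target vector, one per row of `X`.
#' @param width Gaussian kernel bandwidth; `NULL` (default) uses
#'   [median_width()].
#' @param max_iter Maximum re-estimation iterations. Default 100.
#' @param alpha_init Initial precision for every weight. Default 1.
#' @param sigma2_init Initial noise variance; `NULL` defaults to
#'   `0.1 * var(t)` (floored at 1e-6 for constant targets).
#' @param prune_threshold Precisions above this are pruned. Default 1e12.
#' @param conv_tol Convergence tolerance on the largest absolute change in
#'   `log(alpha)` across surviving bases. Default 1e-3.
#'
#' @return An object of class `rvm_model`: relevance vector indices (into the
#'   training rows), posterior mean `weights` (bias first), surviving
#'   `alpha`, noise variance `sigma2`, posterior covariance, the stored
#'   relevance inputs, the kernel `width`, the log-marginal-likelihood
#'   trace, and convergence information. The bias basis is never pruned.
#' @seealso [predict.rvm_model()], [tidy.rvm_model()], [glance.rvm_model()]
#' @examples
#' set.seed(1)
#' x <- matrix(seq(0, 2 * pi, length.out = 30))
#' fit <- rvm_fit(x, sin(x[, 1]), width = 1)
#' glance(fit)
#' @export
rvm_fit <- function(X, t, width = NULL, max_iter = 100, alpha_init = 1,
                    sigma2_init = NULL, prune_threshold = 1e12,
                    conv_tol = 1e-3) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  t <- as.numeric(t)
  n <- nrow(X)
  if (n < 2) abort("Need at least 2 training samples.")
  if (length(t) != n) abort("`t` must have one target per row of `X`.")
  if (anyNA(t) || any(!is.finite(t))) abort("Targets must be finite.")
  if (max_iter < 1) abort("`max_iter` must be at least 1.")
  stopifnot_scalar_number(alpha_init, "alpha_init", positive = TRUE)
  stopifnot_scalar_number(prune_threshold, "prune_threshold", positive = TRUE)
  if (is.null(width)) width <- median_width(X)
  stopifnot_scalar_number(width, "width", positive = TRUE)
  if (is.null(sigma2_init)) sigma2_init <- max(0.1 * var(t), 1e-6)
  stopifnot_scalar_number(sigma2_init, "sigma2_init", positive = TRUE)

  Phi_full <- design_matrix(X, X, width)
  m_full <- ncol(Phi_full) # n + 1 including bias
  active <- rep(TRUE, m_full)
  alpha <- rep(alpha_init, m_full)
  sigma2 <- sigma2_init
  logml <- numeric(0)
  converged <- FALSE
  iters <- 0L

  for (it in seq_len(max_iter)) {
    iters <- it
    Phi <- Phi_full[, active, drop = FALSE]
    a <- alpha[active]
    post <- rvm_posterior(Phi, t, a, sigma2)
    mu <- post$mu
    Sigma <- post$Sigma
    gam <- 1 - a * diag(Sigma)
    gam <- pmin(pmax(gam, 0), 1)
    # gam == 0 means the weight is fully prior-determined: the basis is
    # uninformative and must be pruned, not given a flat (alpha = 0) prior
    a_new <- ifelse(gam > 0 & mu^2 > 0, gam / mu^2, Inf)
    resid2 <- sum((t - as.numeric(Phi %*% mu))^2)
    denom <- n - sum(gam)
    sigma2 <- if (denom > 1e-8) max(resid2 / denom, 1e-12) else
      max(resid2 / n, 1e-12)
    logml <- c(logml, rvm_log_marginal(Phi, t, pmin(a_new, prune_threshold),
                                       sigma2))
    # convergence on surviving (bias always kept) bases, before pruning
    keep_new <- a_new < prune_threshold
    keep_new[1] <- TRUE
    delta <- suppressWarnings(max(abs(log(pmax(a_new[keep_new], 1e-300)) -
                                        log(pmax(a[keep_new], 1e-300)))))
    alpha[active] <- pmin(a_new, .Machine$double.xmax)
    idx_active <- which(active)
    active[idx_active[!keep_new]] <- FALSE
    if (is.finite(delta) && delta < conv_tol) {
      converged <- TRUE
      break
    }
  }

  # final posterior on the surviving basis
  Phi <- Phi_full[, active, drop = FALSE]
  a <- alpha[active]
  post <- rvm_posterior(Phi, t, a, sigma2)
  rel <- which(active) - 1L # training-sample indices; bias drops out as 0
  rel <- rel[rel > 0]
  if (length(rel) == 0) {
    warn("All kernel bases were pruned; returning a bias-only model.")
  }

  structure(
    list(
      relevance_index = rel,
      weights = setNames(post$mu, c("(bias)", rownames(X)[rel] %||%
                                      as.character(rel))[seq_along(post$mu)]),
      alpha = a,
      sigma2 = sigma2,
      posterior_cov = post$Sigma,
      relevance_points = X[rel, , drop = FALSE],
      width = width,
      log_marginal = logml,
      iterations = iters,
      converged = converged,
      n_train = n
    ),
    class = "rvm_model"
  )
}

#' @export
print.rvm_model <- function(x, ...) {
  cat(sprintf(
    "<rvm> %d relevance vectors of %d samples, width=%.4g, sigma2=%.4g, %s in %d iterations\n",
    length(x$relevance_index), x$n_train, x$width, x$sigma2,
    if (x$converged) "converged" else "not converged", x$iterations
  ))
  invisible(x)
}

#' Predict from a fitted relevance vector machine
#'
#' Posterior predictive mean `mu' phi(x*)` and variance
#' `sigma2 + phi(x*)' Sigma phi(x*)`; the variance is never below the
#' fitted noise floor because the posterior covariance is positive
#' definite.
#'
#' @param object A fitted [rvm_fit()] model.
#' @param newdata Numeric matrix (or data frame) of query points with the
#'   training dimensionality.
#' @param ... Unused.
#' @return Tibble with columns `.pred` (mean) and `.pred_var` (predictive
#'   variance), one row per query.
#' @export
predict.rvm_model <- function(object, newdata, ...) {
  Xq <- as.matrix(newdata)
  storage.mode(Xq) <- "double"
  d_train <- if (nrow(object$relevance_points) > 0) {
    ncol(object$relevance_points)
  } else {
    ncol(Xq)
  }
  if (ncol(Xq) != d_train) {
    abort(sprintf(
      "Query dimension %d does not match training dimension %d.",
      ncol(Xq), d_train
    ))
  }
  if (nrow(object$relevance_points) > 0) {
    Phi <- design_matrix(Xq, object$relevance_points, object$width)
  } else {
    Phi <- matrix(1, nrow(Xq), 1)
  }
  mean <- as.numeric(Phi %*% object$weights)
  var <- object$sigma2 + rowSums((Phi %*% object$posterior_cov) * Phi)
  tibble::tibble(.pred = mean, .pred_var = var)
}

#' Tidy a fitted RVM
#'
#' @param x A fitted [rvm_fit()] model.
#' @param ... Unused.
#' @return Tibble with one row per surviving basis (`term`, posterior
#'   `weight`, precision `alpha`).
#' @export
tidy.rvm_model <- function(x, ...) {
  tibble::tibble(
    term = names(x$weights),
    weight = as.numeric(x$weights),
    alpha = as.numeric(x$alpha)
  )
}

#' One-line summary of a fitted RVM
#'
#' @param x A fitted [rvm_fit()] model.
#' @param ... Unused.
#' @return One-row tibble: sample count, relevance-vector count, kernel
#'   width, noise variance, final log marginal likelihood, iterations,
#'   convergence flag.
#' @export
glance.rvm_model <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    n_relevance = length(x$relevance_index),
    width = x$width,
    sigma2 = x$sigma2,
    log_marginal = if (length(x$log_marginal)) {
      x$log_marginal[length(x$log_marginal)]
    } else {
      NA_real_
    },
    iterations = x$iterations,
    converged = x$converged
  )
}

#' Serialize a fitted RVM to a plain-text file
#'
#' Writes a self-describing JSON document (kernel width, relevance
#' indices, weights, precisions, noise variance, posterior covariance,
#' relevance inputs) so a model can be reloaded and used for scoring
#' without the training data.
#'
#' @param model A fitted [rvm_fit()] model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rvm <- function(model, path) {
  stopifnot(inherits(model, "rvm_model"))
  payload <- list(
    format = "rwrvm/rvm-v1",
    width = model$width,
    sigma2 = model$sigma2,
    n_train = model$n_train,
    relevance_index = model$relevance_index,
    weight_names = names(model$weights),
    weights = as.numeric(model$weights),
    alpha = as.numeric(model$alpha),
    posterior_cov = model$posterior_cov,
    relevance_points = model$relevance_points,
    iterations = model$iterations,
    converged = model$converged
  )
  writeLines(jsonlite::toJSON(payload, digits = NA, matrix = "rowmajor"),
             path)
  invisible(path)
}

#' Reload a serialized RVM
#'
#' @param path File written by [write_rvm()].
#' @return A fitted `rvm` object equivalent to the one serialized.
#' @export
read_rvm <- function(path) {
  p <- jsonlite::fromJSON(readr::read_file(path))
  if (!identical(p$format, "rwrvm/rvm-v1")) {
    abort(sprintf("'%s' is not an rwrvm RVM model file.", path))
  }
  rp <- p$relevance_points
  if (is.null(rp) || length(rp) == 0) rp <- matrix(0, 0, 0)
  structure(
    list(
      relevance_index = as.integer(p$relevance_index),
      weights = setNames(as.numeric(p$weights), p$weight_names),
      alpha = as.numeric(p$alpha),
      sigma2 = as.numeric(p$sigma2),
      posterior_cov = as.matrix(p$posterior_cov),
      relevance_points = as.matrix(rp),
      width = as.numeric(p$width),
      log_marginal = numeric(0),
      iterations = as.integer(p$iterations),
      converged = isTRUE(p$converged),
      n_train = as.integer(p$n_train)
    ),
    class = "rvm_model"
  )
}
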