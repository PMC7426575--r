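#' Gaussian mixture subgrouping of tumor expression
#'
#' Samples are modelled as draws from k multivariate normal components with
#' diagonal covariance, fitted by expectation-maximization on z-scored
#' panel-gene expression (samples are observations, genes are features).
#' Diagonal covariance is forced because the feature count (hundreds of
#' panel genes) routinely exceeds the sample count (~99), making full
#' covariance singular. The best of `n_init` random restarts by final
#' log-likelihood is kept; everything is deterministic given `seed`.
#'
#' @param expr An [expr_matrix], normally `state = "zscore"` and already
#'   subset to the panel genes.
#' @param k Number of mixture components (>= 2).
#' @param seed Integer seed controlling all restarts.
#' @param n_init Number of random restarts.
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param var_floor Lower bound on per-feature variances.
#' @return A `subgroup_model`: component means/variances/weights, the
#'   feature-gene list, per-iteration log-likelihood trace of the winning
#'   restart, and convergence information.
#' @export
fit_gmm <- function(expr, k = 3, seed = 20180907, n_init = 10,
                    max_iter = 500, tol = 1e-8, var_floor = 1e-6) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (k < 2) abort("k must be at least 2")
  x <- t(expr$values) # samples x genes
  n <- nrow(x)
  if (n < k) abort("need at least k samples")
  best <- NULL
  for (i in seq_len(n_init)) {
    fit <- with_seed(
      derive_seed(seed, paste0("gmm-init-", i)),
      em_diag_gmm(x, k, max_iter = max_iter, tol = tol, var_floor = var_floor)
    )
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged) {
    warn("no EM restart converged within max_iter; returning best run")
  }
  structure(
    list(
      k = k,
      means = best$means,
      variances = best$variances,
      weights = best$weights,
      feature_genes = rownames(expr$values),
      seed = seed,
      n_init = n_init,
      loglik = best$loglik,
      loglik_trace = best$trace,
      converged = best$converged,
      n_iter = length(best$trace),
      n_obs = n
    ),
    class = "subgroup_model"
  )
}

# One EM run on an n x d matrix with the current RNG stream.
em_diag_gmm <- function(x, k, max_iter, tol, var_floor) {
  n <- nrow(x)
  d <- ncol(x)
  means <- x[sample.int(n, k), , drop = FALSE]
  v0 <- pmax(apply(x, 2, function(col) mean((col - mean(col))^2)), var_floor)
  variances <- matrix(v0, nrow = k, ncol = d, byrow = TRUE)
  weights <- rep(1 / k, k)
  trace <- numeric(0)
  converged <- FALSE
  prev <- -Inf
  for (iter in seq_len(max_iter)) {
    lr <- gmm_log_resp(x, means, variances, weights)
    ll <- sum(lr$log_norm)
    trace <- c(trace, ll)
    if (is.finite(prev) && abs(ll - prev) <= tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
    prev <- ll
    r <- lr$resp
    nk <- pmax(colSums(r), 1e-10)
    weights <- nk / n
    means <- crossprod(r, x) / nk
    ex2 <- crossprod(r, x^2) / nk
    variances <- pmax(ex2 - means^2, var_floor)
  }
  list(
    means = means, variances = variances, weights = weights,
    loglik = trace[length(trace)], trace = trace, converged = converged
  )
}

# Log responsibilities and per-observation log marginal densities.
gmm_log_resp <- function(x, means, variances, weights) {
  n <- nrow(x)
  k <- nrow(means)
  logp <- matrix(0, n, k)
  for (j in seq_len(k)) {
    inv <- 1 / variances[j, ]
    const <- -0.5 * sum(log(2 * pi * variances[j, ]))
    quad <- x^2 %*% inv - 2 * (x %*% (means[j, ] * inv)) + sum(means[j, ]^2 * inv)
    logp[, j] <- log(weights[j]) + const - 0.5 * as.vector(quad)
  }
  m <- apply(logp, 1, max)
  log_norm <- m + log(rowSums(exp(logp - m)))
  resp <- exp(logp - log_norm)
  list(resp = resp, log_norm = log_norm)
}

#' @export
print.subgroup_model <- function(x, ...) {
  cat(sprintf(
    "<subgroup_model> k=%d, %d features, loglik=%.2f, %s in %d iterations\n",
    x$k, length(x$feature_genes), x$loglik,
    if (x$converged) "converged" else "NOT converged", x$n_iter
  ))
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

# Bayesian information criterion of a fitted diagonal mixture:
# (k - 1) mixing weights + k*d means + k*d variances free parameters.
gmm_bic <- function(model) {
  d <- length(model$feature_genes)
  p <- (model$k - 1) + 2 * model$k * d
  -2 * model$loglik + p * log(model$n_obs)
}

#' Select the number of subgroups by BIC
#'
#' Fits the mixture for every k in `k_range` and returns the argmin-BIC k
#' (ties go to the smallest k). Provided as a check on the default of three
#' subgroups, which is fixed a priori for the main analysis.
#'
#' @inheritParams fit_gmm
#' @param k_range Integer vector of candidate k, each in `[2, n_samples - 1]`.
#' @return The selected k (integer), with the BIC table as attribute `"bic"`.
#' @export
select_k <- function(expr, k_range = 2:6, seed = 20180907, n_init = 10) {
  if (length(k_range) == 0) abort("empty k_range")
  n <- ncol(expr$values)
  if (any(k_range < 2 | k_range > n - 1)) {
    abort("k_range must lie within [2, n_samples - 1]")
  }
  k_range <- sort(unique(as.integer(k_range)))
  bics <- purrr::map_dbl(k_range, function(k) {
    gmm_bic(fit_gmm(expr, k = k, seed = seed, n_init = n_init))
  })
  best <- k_range[which.min(bics)] # which.min takes the first = smallest k on ties
  attr(best, "bic") <- tibble::tibble(k = k_range, bic = bics)
  best
}

#' Assign samples to fitted subgroups
#'
#' Computes posterior membership probabilities under a fitted model and hard
#' labels by posterior argmax (ties broken toward the lowest component
#' index). Phenotype labels are attached later by [label_phenotypes()].
#'
#' @param model A `subgroup_model`.
#' @param expr An [expr_matrix] whose genes match `model$feature_genes`.
#' @return A `subgroup_assignment`: tibble-facing object holding sample ids,
#'   hard cluster labels (1..k), the posterior matrix, and (once labelled)
#'   the per-cluster phenotype table.
#' @export
assign_subgroups <- function(model, expr) {
  stopifnot(inherits(model, "subgroup_model"), inherits(expr, "expr_matrix"))
  if (!identical(rownames(expr$values), model$feature_genes)) {
    abort("expression features do not match the model's feature genes")
  }
  x <- t(expr$values)
  lr <- gmm_log_resp(x, model$means, model$variances, model$weights)
  posteriors <- lr$resp
  rownames(posteriors) <- colnames(expr$values)
  colnames(posteriors) <- paste0("posterior_", seq_len(model$k))
  cluster <- max.col(posteriors, ties.method = "first")
  structure(
    list(
      sample_ids = colnames(expr$values),
      cluster = setNames(cluster, colnames(expr$values)),
      posteriors = posteriors,
      k = model$k,
      phenotypes = NULL
    ),
    class = "subgroup_assignment"
  )
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  cat(sprintf(
    "<subgroup_assignment> %d samples in %d clusters (sizes: %s)\n",
    length(x$sample_ids), x$k,
    paste(tabulate(x$cluster, x$k), collapse = ", ")
  ))
  if (!is.null(x$phenotypes)) {
    cat("  phenotypes:", paste(x$phenotypes$display, collapse = " | "), "\n")
  }
  invisible(x)
}

#' @export
as_tibble.subgroup_assignment <- function(x, ...) {
  out <- tibble::tibble(sample_id = x$sample_ids, cluster = unname(x$cluster))
  if (!is.null(x$phenotypes)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(x$phenotypes, "cluster", "subgroup", phenotype = "display"),
      by = "cluster"
    )
  }
  dplyr::bind_cols(out, tibble::as_tibble(x$posteriors))
}

#' Agreement between two partitions
#'
#' Adjusted Rand Index between a recovered assignment and a reference
#' labelling (e.g. the planted truth of a synthetic cohort), computed with
#' `mclust::adjustedRandIndex`.
#'
#' @param assignment A `subgroup_assignment` (or integer/character vector).
#' @param truth Reference labels, same order/names as the assignment samples.
#' @return The ARI (1 = identical partitions, ~0 = chance).
#' @export
recovery_ari <- function(assignment, truth) {
  labels <- if (inherits(assignment, "subgroup_assignment")) {
    assignment$cluster
  } else {
    assignment
  }
  stopifnot(length(labels) == length(truth))
  mclust::adjustedRandIndex(labels, truth)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.subgroup_model <- function(x, ...) {
  purrr::map_dfr(seq_len(x$k), function(j) {
    tibble::tibble(
      component = j,
      weight = x$weights[j],
      gene = x$feature_genes,
      mean = x$means[j, ],
      variance = x$variances[j, ]
    )
  })
}

#' @export
glance.subgroup_model <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_features = length(x$feature_genes),
    n_obs = x$n_obs,
    loglik = x$loglik,
    bic = gmm_bic(x),
    n_iter = x$n_iter,
    converged = x$converged
  )
}
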