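# Gaussian mixture EM over a lattice of six covariance families with BIC
# model selection. This is the clustering engine applied identically to the
# mtDNA, SNP, phenotype and climate score matrices.
#
# Families follow the standard volume/shape/orientation taxonomy:
#   EII spherical, equal volume          VII spherical, varying volume
#   EEI diagonal, equal                  VVI diagonal, varying
#   EEE full covariance, shared          VVV full covariance, per component
# Covariance eigenvalues are floored at 1e-8 to keep fits non-singular on
# duplicated specimens.

GMM_FAMILIES <- c("EII", "VII", "EEI", "VVI", "EEE", "VVV")
COV_EIGEN_FLOOR <- 1e-8

#' Free covariance parameters of a mixture family
#'
#' @param family one of EII, VII, EEI, VVI, EEE, VVV.
#' @param K number of components.
#' @param d dimension.
#' @return Integer parameter count for the covariance part of the model.
#' @export
cov_param_count <- function(family, K, d) {
  switch(family,
         EII = 1L,
         VII = as.integer(K),
         EEI = as.integer(d),
         VVI = as.integer(K * d),
         EEE = as.integer(d * (d + 1) / 2),
         VVV = as.integer(K * d * (d + 1) / 2),
         cd_stop(sprintf("unknown family '%s'", family), "argument"))
}

# total free parameters: (K-1) mixing weights + K*d means + covariance
gmm_param_count <- function(family, K, d) {
  as.integer(K - 1L + K * d + cov_param_count(family, K, d))
}

# floor the eigenvalues of a symmetric matrix; the common (well-conditioned)
# path is a cheap Cholesky probe, the eigendecomposition only runs on failure
floor_cov <- function(S, floor = COV_EIGEN_FLOOR) {
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (ok) return(S)
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, floor)
  e$vectors %*% (v * t(e$vectors))
}

# Covariances are carried in a compact per-family representation during EM:
#   spherical: lambda, length-K vector of variances
#   diagonal : V, K x d matrix of per-axis variances
#   full     : S, list of K d x d matrices
fam_type <- function(family) {
  switch(family, EII = , VII = "spherical", EEI = , VVI = "diagonal",
         EEE = , VVV = "full",
         cd_stop(sprintf("unknown family '%s'", family), "argument"))
}

expand_cov_pack <- function(pack, d) {
  switch(pack$type,
         spherical = lapply(pack$lambda, function(l) diag(l, d)),
         diagonal = lapply(seq_len(nrow(pack$V)),
                           function(k) diag(pack$V[k, ], d)),
         full = pack$S)
}

# per-component multivariate normal log density, full covariance via Cholesky
log_dmvnorm <- function(X, mu, Sigma) {
  d <- ncol(X)
  R <- chol(Sigma)
  z <- forwardsolve(t(R), t(X) - mu)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(R))) + colSums(z^2))
}

# n x K matrix of log(w_k) + log f_k(x_i) from a covariance pack
component_logdens_pack <- function(X, weights, means, pack) {
  n <- nrow(X); d <- ncol(X); K <- length(weights)
  out <- matrix(0, n, K)
  lw <- log(weights)
  for (k in seq_len(K)) {
    Xc <- X - rep(means[k, ], each = n)
    out[, k] <- lw[k] + switch(
      pack$type,
      spherical = {
        l <- pack$lambda[k]
        -0.5 * (d * log(2 * pi * l) + rowSums(Xc * Xc) / l)
      },
      diagonal = {
        v <- pack$V[k, ]
        -0.5 * (d * log(2 * pi) + sum(log(v)) +
                  rowSums((Xc * Xc) * rep(1 / v, each = n)))
      },
      full = log_dmvnorm(X, means[k, ], pack$S[[k]]))
  }
  out
}

# kept for classify() on expanded covariance lists
component_logdens <- function(X, weights, means, covariances) {
  K <- length(weights)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    out[, k] <- log(weights[k]) + log_dmvnorm(X, means[k, ], covariances[[k]])
  }
  out
}

logsumexp_rows <- function(M) {
  m <- do.call(pmax, lapply(seq_len(ncol(M)), function(j) M[, j]))
  m + log(rowSums(exp(M - m)))
}

# k-means++ seeding: centers are data rows chosen by the D^2 rule
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- integer(K)
  centers[1] <- sample.int(n, 1)
  if (K > 1) {
    d2 <- rowSums((X - matrix(X[centers[1], ], n, ncol(X), byrow = TRUE))^2)
    for (k in 2:K) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[k] <- sample.int(n, 1, prob = prob)
      nd2 <- rowSums((X - matrix(X[centers[k], ], n, ncol(X), byrow = TRUE))^2)
      d2 <- pmin(d2, nd2)
    }
  }
  X[centers, , drop = FALSE]
}

# M-step covariance estimate per family from weighted scatter
mstep_covariances <- function(family, X, resp, means, Nk) {
  n <- nrow(X); d <- ncol(X); K <- ncol(resp)
  type <- fam_type(family)
  if (type == "full") {
    W <- vector("list", K)
    for (k in seq_len(K)) {
      Xc <- X - rep(means[k, ], each = n)
      W[[k]] <- crossprod(Xc * resp[, k], Xc)
    }
    if (family == "VVV") {
      S <- lapply(seq_len(K), function(k) floor_cov(W[[k]] / Nk[k]))
    } else {
      shared <- floor_cov(Reduce(`+`, W) / n)
      S <- rep(list(shared), K)
    }
    return(list(type = "full", S = S))
  }
  # diagonal scatter: per-component weighted column sums of squares
  D <- matrix(0, K, d)
  for (k in seq_len(K)) {
    Xc <- X - rep(means[k, ], each = n)
    D[k, ] <- colSums((Xc * Xc) * resp[, k])
  }
  if (type == "diagonal") {
    V <- if (family == "VVI") D / Nk else
      matrix(colSums(D) / n, K, d, byrow = TRUE)
    return(list(type = "diagonal", V = pmax(V, COV_EIGEN_FLOOR)))
  }
  lambda <- if (family == "VII") rowSums(D) / (d * Nk) else
    rep(sum(D) / (d * n), K)
  list(type = "spherical", lambda = pmax(lambda, COV_EIGEN_FLOOR))
}

#' Fit a Gaussian mixture by EM
#'
#' Expectation-Maximization from a seeded k-means++ initialization. The
#' log-likelihood is non-decreasing across iterations; the fit converges
#' when its increase falls below \code{tol} or after \code{max_iter}
#' iterations. A component that collapses despite the covariance floor is
#' reported on the fit (\code{singular = TRUE}), not raised, so model
#' searches can continue.
#'
#' @param scores numeric matrix (specimens x retained axes) or a
#'   \code{score_set}.
#' @param K number of components (\code{K <= n}).
#' @param family covariance family code (see \code{\link{cov_param_count}}).
#' @param seed integer seed controlling the initialization.
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @return An object of class \code{mixture_fit}: family, K, weights, means,
#'   covariances (list of K matrices), loglik, loglik_trace, n_params, bic,
#'   converged, singular, n, d, seed.
#' @export
em_fit <- function(scores, K, family = "VVV", seed = 1L, tol = 1e-6,
                   max_iter = 500L) {
  X <- if (inherits(scores, "score_set")) retained_scores(scores) else
    as.matrix(scores)
  n <- nrow(X); d <- ncol(X)
  if (K > n) cd_stop(sprintf("K = %d exceeds n = %d", K, n), "argument")
  if (K < 1 || d < 1) cd_stop("K and d must be at least 1", "argument")
  family <- match.arg(family, GMM_FAMILIES)

  centers <- with_seed(seed, kmeanspp_centers(X, K))
  # hard initial assignment to nearest center
  d2 <- vapply(seq_len(K), function(k) {
    rowSums((X - matrix(centers[k, ], n, d, byrow = TRUE))^2)
  }, numeric(n))
  if (n == 1) d2 <- matrix(d2, nrow = 1)
  assign0 <- max.col(-d2, ties.method = "first")
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), assign0)] <- 1

  type <- fam_type(family)
  res <- em_loop_cpp(X, resp,
                     cov_type = match(type, c("spherical", "diagonal",
                                              "full")) - 1L,
                     varying = family %in% c("VII", "VVI", "VVV"),
                     tol = tol, max_iter = as.integer(max_iter),
                     floor_val = COV_EIGEN_FLOOR)
  loglik <- res$loglik
  trace <- as.numeric(res$trace)
  converged <- res$converged
  singular <- res$singular
  weights <- as.numeric(res$weights)
  means <- res$means
  pack <- switch(type,
                 spherical = list(type = "spherical",
                                  lambda = as.numeric(res$lambda)),
                 diagonal = list(type = "diagonal", V = res$V),
                 full = list(type = "full",
                             S = lapply(seq_len(K), function(k) {
                               matrix(res$S[, , k], d, d)
                             })))
  if (length(trace) == 0) pack <- NULL
  covs <- if (is.null(pack)) NULL else expand_cov_pack(pack, d)
  # spurious-maximum guard: the mixture likelihood is unbounded, so EM with
  # aggressive restarts can land on degenerate optima — a varying-covariance
  # component shrink-wrapped around fewer than d+1 points, or a covariance
  # held up only by the eigenvalue floor. Such fits are reported singular
  # and skipped during model search; equal-covariance families pool their
  # covariance across components and may keep singleton clusters.
  if (!singular && !is.null(pack)) {
    if (family %in% c("VII", "VVI", "VVV") &&
        min(weights) * n < d + 1) {
      singular <- TRUE
    } else {
      min_eig <- switch(pack$type,
                        spherical = min(pack$lambda),
                        diagonal = min(pack$V),
                        full = min(vapply(pack$S, function(S) {
                          min(eigen(S, symmetric = TRUE,
                                    only.values = TRUE)$values)
                        }, numeric(1))))
      if (min_eig <= 10 * COV_EIGEN_FLOOR) singular <- TRUE
    }
  }
  n_params <- gmm_param_count(family, K, d)
  fit <- structure(list(family = family, K = as.integer(K),
                        weights = as.numeric(weights), means = means,
                        covariances = covs,
                        loglik = loglik, loglik_trace = trace,
                        n_params = n_params,
                        bic = if (is.finite(loglik))
                          2 * loglik - n_params * log(n) else -Inf,
                        converged = converged, singular = singular,
                        n = n, d = d, seed = seed),
                   class = "mixture_fit")
  fit
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: K=%d, family=%s, loglik=%.3f, BIC=%.3f%s\n",
              x$K, x$family, x$loglik, x$bic,
              if (x$singular) " [singular]" else ""))
  invisible(x)
}

#' Bayesian Information Criterion of a mixture fit
#'
#' Computed as \code{2 * loglik - n_params * log(n)} — larger is better, the
#' convention of the model-based-clustering literature.
#'
#' @param fit a \code{\link{em_fit}} result.
#' @param n number of observations (defaults to the fit's own n).
#' @return The BIC value.
#' @export
gmm_bic <- function(fit, n = fit$n) {
  stopifnot(inherits(fit, "mixture_fit"))
  2 * fit$loglik - fit$n_params * log(n)
}

#' Select the best mixture over a K x family grid
#'
#' Fits every combination of component count and covariance family, each
#' with several seeded restarts (best restart by log-likelihood), and
#' returns the fit with the highest BIC. Ties are broken toward smaller K,
#' then fewer parameters.
#'
#' @param scores numeric matrix or \code{score_set}.
#' @param K_max largest component count (default 12).
#' @param families covariance families to search (default all six).
#' @param restarts seeded restarts per grid cell (default 10).
#' @param seed master seed; restart seeds are derived from it.
#' @param tol,max_iter passed to \code{\link{em_fit}}.
#' @return A list of class \code{model_selection}: \code{best} (the chosen
#'   \code{mixture_fit}) and \code{bic_table} (one row per grid cell:
#'   K, family, bic, loglik, converged, singular).
#' @export
model_select <- function(scores, K_max = 12L, families = GMM_FAMILIES,
                         restarts = 10L, seed = 1L, tol = 1e-6,
                         max_iter = 500L) {
  X <- if (inherits(scores, "score_set")) retained_scores(scores) else
    as.matrix(scores)
  n <- nrow(X)
  if (K_max < 1) cd_stop("K_max must be at least 1", "argument")
  K_max <- min(K_max, n)
  grid <- expand.grid(K = seq_len(K_max), family = families,
                      stringsAsFactors = FALSE)
  best <- NULL
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    K <- grid$K[i]; fam <- grid$family[i]
    cell_best <- NULL
    for (r in seq_len(restarts)) {
      fit <- em_fit(X, K, fam, seed = derive_seed(seed, i * 1000L + r),
                    tol = tol, max_iter = max_iter)
      if (fit$singular) next
      if (is.null(cell_best) || fit$loglik > cell_best$loglik) cell_best <- fit
    }
    if (is.null(cell_best)) {
      rows[[i]] <- data.frame(K = K, family = fam, bic = NA_real_,
                              loglik = NA_real_, converged = FALSE,
                              singular = TRUE)
      next
    }
    rows[[i]] <- data.frame(K = K, family = fam, bic = cell_best$bic,
                            loglik = cell_best$loglik,
                            converged = cell_best$converged,
                            singular = FALSE)
    if (is.null(best) ||
        cell_best$bic > best$bic + 1e-9 ||
        (abs(cell_best$bic - best$bic) <= 1e-9 &&
         (cell_best$K < best$K ||
          (cell_best$K == best$K && cell_best$n_params < best$n_params)))) {
      best <- cell_best
    }
  }
  if (is.null(best)) cd_stop("every candidate fit was singular", "selection")
  structure(list(best = best, bic_table = do.call(rbind, rows)),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("Model selection: best K=%d family=%s BIC=%.3f (grid of %d fits)\n",
              x$best$K, x$best$family, x$best$bic, nrow(x$bic_table)))
  invisible(x)
}

#' Classify specimens under a fitted mixture
#'
#' Labels are the maximum-posterior components, renumbered by descending
#' cluster size; classification uncertainty is one minus the maximum
#' posterior probability.
#'
#' @param fit a \code{\link{em_fit}} result.
#' @param scores matrix of the same dimension the fit was trained on.
#' @param specimen_ids optional ids for the output.
#' @param dataset dataset tag recorded in the partition.
#' @return A list of class \code{partition}: \code{labels} (1..K),
#'   \code{posterior} (n x K, rows on the simplex), \code{uncertainty},
#'   \code{table} (a \code{\link{partition_table}}).
#' @export
classify <- function(fit, scores, specimen_ids = NULL, dataset = "synthetic") {
  stopifnot(inherits(fit, "mixture_fit"))
  X <- if (inherits(scores, "score_set")) retained_scores(scores) else
    as.matrix(scores)
  if (ncol(X) != fit$d) cd_stop("score dimension does not match fit", "argument")
  if (is.null(specimen_ids)) {
    specimen_ids <- rownames(X)
    if (is.null(specimen_ids)) specimen_ids <- paste0("s", seq_len(nrow(X)))
  }
  ld <- component_logdens(X, fit$weights, fit$means, fit$covariances)
  post <- exp(ld - logsumexp_rows(ld))
  raw <- max.col(post, ties.method = "first")
  # renumber by descending cluster size (stable for ties)
  sizes <- tabulate(raw, nbins = fit$K)
  order_k <- order(-sizes, seq_len(fit$K))
  relabel <- integer(fit$K); relabel[order_k] <- seq_len(fit$K)
  labels <- relabel[raw]
  post <- post[, order_k, drop = FALSE]
  unc <- 1 - apply(post, 1, max)
  structure(list(labels = labels, posterior = post,
                 uncertainty = unc,
                 table = partition_table(specimen_ids, dataset, labels, unc)),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("Partition: %d specimens in %d clusters (mean uncertainty %.3f)\n",
              length(x$labels), length(unique(x$labels)),
              mean(x$uncertainty)))
  invisible(x)
}
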