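# Correlation-matrix PCA with the >5% axis-retention rule and screening of
# axes that track missing-data load rather than biology.

#' Principal component analysis on the correlation matrix
#'
#' Columns are standardized to mean 0 / sd 1 and the eigensystem of their
#' correlation matrix is computed via singular value decomposition of the
#' standardized data (numerically stable when features outnumber
#' specimens). Eigenvalues are reported for all \code{ncol(X)} axes (zero
#' beyond the matrix rank), so variance fractions sum to one. The sign of
#' each axis is fixed so that its largest-magnitude loading is positive,
#' making runs reproducible across platforms.
#'
#' @param X a \code{\link{feature_matrix}} (or plain numeric matrix).
#' @return An object of class \code{score_set}: \code{scores}
#'   (specimens x axes, axes only up to the rank), \code{eigenvalues},
#'   \code{variance_fractions}, \code{loadings} (variables x axes),
#'   \code{retained} (filled by \code{\link{retain_axes}}), \code{source}.
#' @export
pca_correlation <- function(X) {
  src <- if (inherits(X, "feature_matrix")) X$source else NA_character_
  vals <- if (inherits(X, "feature_matrix")) X$values else as.matrix(X)
  if (nrow(vals) < 2 || ncol(vals) < 2) {
    cd_stop("PCA needs at least 2 specimens and 2 features", "degenerate")
  }
  Z <- standardize_columns(vals)
  n <- nrow(Z); p <- ncol(Z)
  sv <- svd(Z)
  lambda <- sv$d^2 / (n - 1)
  r <- sum(sv$d > max(sv$d) * 1e-12)
  lambda_all <- c(lambda[seq_len(r)], rep(0, p - r))
  loadings <- sv$v[, seq_len(r), drop = FALSE]
  scores <- Z %*% loadings
  # sign convention: largest-magnitude loading on each axis is positive
  for (j in seq_len(r)) {
    l <- loadings[, j]
    if (l[which.max(abs(l))] < 0) {
      loadings[, j] <- -l
      scores[, j] <- -scores[, j]
    }
  }
  axes <- paste0("pc", seq_len(r))
  dimnames(scores) <- list(rownames(vals), axes)
  dimnames(loadings) <- list(colnames(vals), axes)
  structure(list(scores = scores,
                 eigenvalues = lambda_all,
                 variance_fractions = lambda_all / sum(lambda_all),
                 loadings = loadings,
                 retained = seq_len(r),
                 source = src),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("PCA scores: %d specimens, %d axes (%d retained)\n",
              nrow(x$scores), ncol(x$scores), length(x$retained)))
  vf <- x$variance_fractions[seq_len(min(5, length(x$variance_fractions)))]
  cat("  leading variance fractions:",
      paste(sprintf("%.3f", vf), collapse = " "), "\n")
  invisible(x)
}

#' Retain axes explaining more than a variance threshold
#'
#' Axes whose variance fraction strictly exceeds \code{threshold} are
#' retained, in order. Axis 1 is always retained so clustering has at least
#' one dimension.
#'
#' @param score_set a \code{\link{pca_correlation}} result.
#' @param threshold variance fraction cutoff (default 0.05, i.e. >5%).
#' @return Integer vector of retained axis indices.
#' @export
retain_axes <- function(score_set, threshold = 0.05) {
  stopifnot(inherits(score_set, "score_set"))
  vf <- score_set$variance_fractions[seq_len(ncol(score_set$scores))]
  idx <- which(vf > threshold)
  if (length(idx) == 0) idx <- 1L
  sort(unique(c(1L, idx)))
}

#' Flag retained axes that track missing-data load
#'
#' A principal component whose scores correlate strongly with the per-sample
#' missing-data fraction reflects data completeness rather than population
#' structure and should be excluded before clustering.
#'
#' @param score_set a \code{\link{pca_correlation}} result.
#' @param missing_fraction per-sample missing fraction from
#'   \code{\link{missingness_vector}}, same specimen order as the scores.
#' @param retained axes under consideration (default
#'   \code{score_set$retained}).
#' @param r_threshold absolute Pearson correlation at which an axis is
#'   flagged (default 0.7).
#' @return Integer vector of axis indices to drop (empty when no missing
#'   data).
#' @export
screen_missingness_axes <- function(score_set, missing_fraction,
                                    retained = score_set$retained,
                                    r_threshold = 0.7) {
  stopifnot(inherits(score_set, "score_set"))
  if (length(missing_fraction) != nrow(score_set$scores)) {
    cd_stop("missing_fraction length must match the number of specimens",
            "argument")
  }
  if (stats::sd(missing_fraction) == 0) return(integer(0))
  r <- abs(apply(score_set$scores[, retained, drop = FALSE], 2,
                 stats::cor, y = missing_fraction))
  retained[r >= r_threshold]
}

#' Apply retention and screening, returning the clustering-ready scores
#'
#' @param score_set a \code{\link{pca_correlation}} result.
#' @param missing_fraction optional missing fractions for axis screening.
#' @param threshold,r_threshold passed to \code{\link{retain_axes}} and
#'   \code{\link{screen_missingness_axes}}.
#' @return The \code{score_set} with \code{retained} updated.
#' @export
select_axes <- function(score_set, missing_fraction = NULL,
                        threshold = 0.05, r_threshold = 0.7) {
  keep <- retain_axes(score_set, threshold)
  if (!is.null(missing_fraction)) {
    drop <- screen_missingness_axes(score_set, missing_fraction,
                                    retained = keep,
                                    r_threshold = r_threshold)
    keep2 <- setdiff(keep, drop)
    if (length(keep2)) keep <- keep2  # never screen away every axis
  }
  score_set$retained <- keep
  score_set
}

#' Retained score matrix
#'
#' @param score_set a \code{score_set}.
#' @return Numeric matrix of the retained axes.
#' @export
retained_scores <- function(score_set) {
  score_set$scores[, score_set$retained, drop = FALSE]
}
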