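test_that("covariance parameter counts follow the family formulas", {
  d <- 3; K <- 4
  expect_equal(cov_param_count("EII", K, d), 1L)
  expect_equal(cov_param_count("VII", K, d), K)
  expect_equal(cov_param_count("EEI", K, d), d)
  expect_equal(cov_param_count("VVI", K, d), K * d)
  expect_equal(cov_param_count("EEE", K, d), d * (d + 1) / 2)
  expect_equal(cov_param_count("VVV", K, d), K * d * (d + 1) / 2)
  # positive and increasing with d for every family
  for (fam in c("EII", "VII", "EEI", "VVI", "EEE", "VVV")) {
    counts <- vapply(1:6, function(dd) cov_param_count(fam, 2, dd), integer(1))
    expect_true(all(counts > 0))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("separated point masses are recovered exactly", {
  X <- rbind(matrix(0, 50, 2), matrix(100, 50, 2)) +
    0  # two coincident-point clusters
  fit <- em_fit(X, 2, "VVV", seed = 1)
  m <- fit$means[order(fit$means[, 1]), ]
  expect_lt(max(abs(m - rbind(c(0, 0), c(100, 100)))), 1e-6)
  part <- classify(fit, X)
  expect_true(all(apply(part$posterior, 1, max) >= 1 - 1e-10))
})

test_that("K = 1 matches the closed-form multivariate normal MLE log-likelihood", {
  set.seed(7)
  X <- matrix(rnorm(80 * 3), 80, 3) %*% matrix(runif(9, -1, 1), 3, 3)
  n <- nrow(X); d <- ncol(X)
  S <- cov(X) * (n - 1) / n  # MLE covariance
  closed <- -n / 2 * (d * log(2 * pi) + determinant(S)$modulus[1] + d)
  for (fam in c("EEE", "VVV")) {
    fit <- em_fit(X, 1, fam, seed = 3)
    expect_equal(fit$loglik, as.numeric(closed), tolerance = 1e-8)
    expect_equal(gmm_bic(fit), 2 * fit$loglik - fit$n_params * log(n))
  }
  # spherical / diagonal closed forms
  v <- colMeans(scale(X, scale = FALSE)^2)
  closed_diag <- -n / 2 * (d * log(2 * pi) + sum(log(v)) + d)
  expect_equal(em_fit(X, 1, "EEI", seed = 3)$loglik, closed_diag,
               tolerance = 1e-8)
  lam <- mean(v)
  closed_sph <- -n / 2 * (d * log(2 * pi * lam) + d)
  expect_equal(em_fit(X, 1, "EII", seed = 3)$loglik, closed_sph,
               tolerance = 1e-8)
})

test_that("the BIC follows 2 loglik - m log n by hand computation", {
  # K = 1, EII, d = 1: loglik has a one-line closed form
  x <- matrix(c(1, 2, 3, 6), 4, 1)
  fit <- em_fit(x, 1, "EII", seed = 1)
  lam <- mean((x - mean(x))^2)
  loglik_hand <- -4 / 2 * (log(2 * pi * lam) + 1)
  expect_equal(fit$loglik, loglik_hand, tolerance = 1e-10)
  # n_params = (K-1) + K d + 1 = 2
  expect_equal(fit$n_params, 2L)
  expect_equal(fit$bic, 2 * loglik_hand - 2 * log(4), tolerance = 1e-10)
  # ln(1) = 0: with n = 1 the penalty vanishes
  fake <- structure(list(loglik = -3.21, n_params = 5L, n = 1),
                    class = "mixture_fit")
  expect_equal(gmm_bic(fake), -6.42)
})

test_that("EM log-likelihood is monotone non-decreasing on random instances", {
  set.seed(10)
  for (i in 1:50) {
    n <- sample(20:60, 1); d <- sample(1:3, 1); K <- sample(1:4, 1)
    X <- matrix(rnorm(n * d), n, d)
    fam <- sample(c("EII", "VII", "EEI", "VVI", "EEE", "VVV"), 1)
    fit <- em_fit(X, K, fam, seed = i)
    if (length(fit$loglik_trace) > 1) {
      expect_true(all(diff(fit$loglik_trace) > -1e-8))
    }
  }
})

test_that("adding a component never lowers the best log-likelihood but can lower BIC", {
  set.seed(21)
  X <- matrix(rnorm(200 * 2), 200, 2)
  best <- function(K) {
    fits <- lapply(1:8, function(r) em_fit(X, K, "EEE", seed = r))
    fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]
  }
  f1 <- best(1); f2 <- best(2)
  expect_gte(f2$loglik, f1$loglik - 1e-6)
  expect_lt(f2$bic, f1$bic)  # one Gaussian cloud: the extra component is noise
})

test_that("em_fit validates K and determinism under a fixed seed", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(em_fit(X, 11, "EII", seed = 1), class = "codelim_argument_error")
  f1 <- em_fit(X, 2, "VVI", seed = 42)
  f2 <- em_fit(X, 2, "VVI", seed = 42)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$means, f2$means)
})

test_that("model selection finds 3 separated blobs and 1 for a single cloud", {
  b <- make_blobs(n_per = 50, sigma = 1, seed = 2)
  sel <- model_select(b$X, K_max = 6, restarts = 4, seed = 5)
  expect_equal(sel$best$K, 3L)
  part <- classify(sel$best, b$X)
  expect_equal(adjusted_rand(part$labels, b$labels), 1)
  expect_true(all(part$uncertainty < 1e-4))

  set.seed(3)
  X1 <- matrix(rnorm(200 * 2), 200, 2)
  sel1 <- model_select(X1, K_max = 6, restarts = 4, seed = 5)
  expect_equal(sel1$best$K, 1L)
  # the bic_table records the whole grid
  expect_equal(nrow(sel$bic_table), 6 * 6)
  expect_true(all(c("K", "family", "bic", "converged") %in%
                    colnames(sel$bic_table)))
})

test_that("equal-BIC ties resolve deterministically toward the simpler model", {
  set.seed(4)
  X <- matrix(rnorm(60 * 2), 60, 2)
  # at K = 1, EII and VII are the same model (1 covariance parameter):
  # identical BIC, and the earlier/simpler entry must win
  sel <- model_select(X, K_max = 1, families = c("VII", "EII"),
                      restarts = 2, seed = 9)
  tab <- sel$bic_table
  expect_equal(tab$bic[tab$family == "EII"], tab$bic[tab$family == "VII"],
               tolerance = 1e-12)
  expect_equal(sel$best$K, 1L)
  expect_equal(sel$best$n_params, min(tab$K * 0 + sel$best$n_params))
})

test_that("classification uncertainty behaves under symmetry and separation", {
  # equidistant point between two equal spherical components
  fit <- structure(list(family = "EII", K = 2L,
                        weights = c(0.5, 0.5),
                        means = rbind(c(-1, 0), c(1, 0)),
                        covariances = list(diag(2), diag(2)),
                        n = 2, d = 2, n_params = 6L, loglik = 0, bic = 0,
                        converged = TRUE, singular = FALSE),
                   class = "mixture_fit")
  part <- classify(fit, matrix(c(0, 5), 1, 2))
  expect_equal(part$uncertainty, 0.5, tolerance = 1e-12)
  # mean uncertainty grows as two clusters approach
  uncs <- vapply(c(8, 4, 2, 1), function(delta) {
    set.seed(31)
    X <- rbind(cbind(rnorm(60), rnorm(60)),
               cbind(rnorm(60, delta), rnorm(60)))
    f <- em_fit(X, 2, "EII", seed = 1)
    mean(classify(f, X)$uncertainty)
  }, numeric(1))
  expect_true(all(diff(uncs) > 0))
})

test_that("posteriors live on the simplex and labels are size-ordered", {
  b <- make_blobs(n_per = c(60, 30, 10)[1], seed = 6)  # equal blobs
  set.seed(6)
  X <- rbind(cbind(rnorm(60), rnorm(60)),
             cbind(rnorm(30, 8), rnorm(30)),
             cbind(rnorm(10, 4), rnorm(10, 8)))
  fit <- em_fit(X, 3, "EII", seed = 2)
  part <- classify(fit, X)
  expect_equal(rowSums(part$posterior), rep(1, nrow(X)), tolerance = 1e-9)
  expect_true(all(part$uncertainty <= 1 - 1 / 3 + 1e-12))
  sizes <- table(part$labels)
  expect_true(all(diff(as.integer(sizes)) <= 0))
})

test_that("label permutation leaves BIC and uncertainties unchanged", {
  set.seed(8)
  X <- rbind(cbind(rnorm(40), rnorm(40)), cbind(rnorm(40, 6), rnorm(40)))
  fit <- em_fit(X, 2, "VVV", seed = 3)
  perm <- fit
  perm$weights <- fit$weights[2:1]
  perm$means <- fit$means[2:1, ]
  perm$covariances <- fit$covariances[2:1]
  expect_equal(gmm_bic(perm), gmm_bic(fit))
  a <- classify(fit, X); b <- classify(perm, X)
  expect_equal(a$uncertainty, b$uncertainty, tolerance = 1e-12)
  expect_equal(adjusted_rand(a$labels, b$labels), 1)
})

test_that("for K = 1 every family agrees with mclust's single-component fit", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  # independent engine cross-check on a well-separated mixture
  b <- make_blobs(n_per = 40, sigma = 1, seed = 10)
  ours <- model_select(b$X, K_max = 5, restarts = 4, seed = 2)
  m <- mclust::Mclust(b$X, G = 1:5,
                      modelNames = c("EII", "VII", "EEI", "VVI", "EEE", "VVV"),
                      verbose = FALSE)
  expect_equal(ours$best$K, m$G)
  # mclust reports BIC in the same 2 loglik - m log n convention
  expect_equal(ours$best$bic, max(m$BIC, na.rm = TRUE), tolerance = 1e-3)
})
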