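# Gaussian mixture classifier: closed-form likelihood identities, BIC
# forms, EM behavior, model-order selection and prediction contracts.

test_that("log-likelihood matches closed forms", {
  g1 <- class_gmm(1, matrix(0, 1, 1), list(matrix(1)))
  # standard normal density at 0
  expect_equal(gmm_log_likelihood(g1, matrix(0)), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  # additivity: duplicating every row doubles the value
  X <- matrix(rnorm(20), ncol = 1)
  expect_equal(gmm_log_likelihood(g1, rbind(X, X)),
               2 * gmm_log_likelihood(g1, X), tolerance = 1e-12)
  # mixture degeneracy: identical components at any split collapse
  g2 <- class_gmm(c(0.3, 0.7), matrix(0, 2, 1), list(matrix(1), matrix(1)))
  expect_equal(gmm_log_likelihood(g2, X), gmm_log_likelihood(g1, X),
               tolerance = 1e-12)
})

test_that("BIC forms substitute correctly and penalize K", {
  X <- matrix(rnorm(10), ncol = 1)
  g1 <- class_gmm(1, matrix(0, 1, 1), list(matrix(1)))
  # as-printed form at L = 0: shift the data likelihood out by hand
  L <- gmm_log_likelihood(g1, X)
  expect_equal(gmm_bic(g1, X, mode = "as-printed") + 2 * L,
               2 * log(10), tolerance = 1e-10)
  # standard form: p = (K-1) + K r + K r(r+1)/2
  expect_equal(gmm_bic(g1, X), -2 * L + 2 * log(10), tolerance = 1e-10)
  g2 <- class_gmm(c(0.5, 0.5), matrix(0, 2, 1), list(matrix(1), matrix(1)))
  # equal likelihood, more parameters -> larger standard BIC
  expect_gt(gmm_bic(g2, X), gmm_bic(g1, X))
  # but identical as-printed BIC (no parameter-count term)
  expect_equal(gmm_bic(g2, X, mode = "as-printed"),
               gmm_bic(g1, X, mode = "as-printed"), tolerance = 1e-10)
  expect_error(gmm_bic(g1, matrix(0), ), "usage error")
})

test_that("K=1 EM equals the closed-form mean and covariance", {
  X <- mobidecode:::with_seed(4, matrix(rnorm(600), ncol = 3))
  fit <- fit_class_gmm(X, K_max = 1, seed = 1)
  expect_equal(as.numeric(fit$mu), colMeans(X), tolerance = 1e-8)
  ml_cov <- crossprod(sweep(X, 2, colMeans(X))) / nrow(X)
  expect_equal(fit$Sigma[[1]], ml_cov, tolerance = 1e-8)
})

test_that("EM log-likelihood is non-decreasing and the trace is kept", {
  X <- mobidecode:::with_seed(8, rbind(matrix(rnorm(400), ncol = 2),
                                       matrix(rnorm(400), ncol = 2) + 4))
  fit <- mobidecode:::.fit_gmm_K(X, K = 2, seed = 3)
  expect_gte(length(fit$loglik_trace), 2)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
})

test_that("BIC selects the generating component count", {
  # two well-separated spherical components: K = 2, means recovered
  X <- mobidecode:::with_seed(15, rbind(
    matrix(rnorm(2000), ncol = 2) + 5,
    matrix(rnorm(2000), ncol = 2) - 5))
  fit <- fit_class_gmm(X, K_max = 5, seed = 2)
  expect_equal(fit$K, 2)
  got <- fit$mu[order(fit$mu[, 1]), ]
  expect_lt(max(abs(got - rbind(c(-5, -5), c(5, 5)))), 0.1)
  # single-Gaussian data: K = 1 in at least 8 of 10 seeds
  picks <- vapply(1:10, function(s) {
    X1 <- mobidecode:::with_seed(100 + s, matrix(rnorm(2000), ncol = 2))
    fit_class_gmm(X1, K_max = 5, seed = s)$K
  }, numeric(1))
  expect_gte(sum(picks == 1), 8)
})

test_that("mean recovery improves with sample size", {
  err <- vapply(c(200, 2000), function(n) {
    X <- mobidecode:::with_seed(77, rbind(
      matrix(rnorm(n), ncol = 2) + 3,
      matrix(rnorm(n), ncol = 2) - 3))
    fit <- fit_class_gmm(X, K_max = 3, seed = 5)
    mean(abs(fit$mu[order(fit$mu[, 1]), ] - rbind(c(-3, -3), c(3, 3))))
  }, numeric(1))
  expect_lt(err[2], err[1] + 0.05)
  expect_lt(err[2], 0.1)
})

test_that("degenerate data raises a numeric error", {
  X <- matrix(1, 50, 2)  # identical points: no spread at all
  expect_error(fit_class_gmm(X, K_max = 2, seed = 1), "numeric error")
})

test_that("classifier fitting is deterministic and complete", {
  gc3 <- gaussian_classes(n_per_class = 60, d = 3, seed = 21)
  c1 <- fit_lfda_gmm(gc3$X, gc3$y, r = 2, k_nn = 5, K_max = 3, seed = 9)
  c2 <- fit_lfda_gmm(gc3$X, gc3$y, r = 2, k_nn = 5, K_max = 3, seed = 9)
  expect_identical(c1$models, c2$models)
  expect_gte(mean(predict(c1, gc3$X) == gc3$y), 0.99)
  expect_error(
    fit_lfda_gmm(gc3$X, gc3$y, r = 2, k_nn = 5, seed = 1,
                 classes = c(unique(gc3$y), "ghost")),
    "fit error")
})

test_that("posteriors normalize, localize and tie-break lexicographically", {
  mk <- function(center) {
    g <- class_gmm(1, matrix(center, 1, 2), list(diag(2)))
    g$loglik <- 0
    g
  }
  lfda_id <- structure(list(T = diag(2), r = 2, k_nn = 1, d = 2,
                            class_labels = c("far", "near"),
                            eigenvalues = c(1, 1), affinity = "local"),
                       class = "lfda_model")
  clf <- structure(list(lfda = lfda_id,
                        models = list(aaa = mk(c(0, 0)), zzz = mk(c(50, 0))),
                        classes = c("aaa", "zzz"), K_max = 1, seed = 1),
                   class = "lfda_gmm")
  post <- gmm_posterior(clf, matrix(c(0, 0), 1))
  expect_equal(rowSums(post), 1, tolerance = 1e-9)
  expect_gt(post[1, "aaa"], 0.99)
  # identical models: exact tie, first (lexicographically smallest) label
  clf$models$zzz <- mk(c(0, 0))
  post2 <- gmm_posterior(clf, matrix(c(3, -1), 1))
  expect_equal(as.numeric(post2), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(predict(clf, matrix(c(3, -1), 1)), "aaa")
  # posterior rows always sum to 1
  Xr <- matrix(rnorm(40), ncol = 2)
  expect_equal(rowSums(gmm_posterior(clf, Xr)), rep(1, 20),
               tolerance = 1e-9)
  expect_error(gmm_posterior(clf, matrix(0, 1, 3)), "usage error")
})

test_that("mixture density agrees with an independent implementation", {
  X <- mobidecode:::with_seed(31, rbind(matrix(rnorm(300), ncol = 3),
                                        matrix(rnorm(300), ncol = 3) + 2))
  fit <- fit_class_gmm(X, K_max = 3, seed = 2)
  dens_own <- mobidecode:::gmm_log_density(fit, X)
  chol_arr <- array(unlist(lapply(fit$Sigma, chol)), dim = c(3, 3, fit$K))
  dens_ref <- mclust::dens(
    "VVV", data = X, logarithm = TRUE,
    parameters = list(
      pro = fit$alpha,
      mean = t(fit$mu),
      variance = list(modelName = "VVV", d = 3, G = fit$K,
                      cholsigma = chol_arr)))
  expect_equal(dens_own, dens_ref, tolerance = 1e-8)
})
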