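# Per-class Gaussian mixture models fitted by EM with k-means
# initialization and BIC model-order selection, combined with the LFDA
# transform into a maximum-likelihood classifier.

logsumexp <- function(M) {
  m <- apply(M, 1, max)
  m + log(rowSums(exp(M - m)))
}

#' Construct a class-conditional Gaussian mixture
#'
#' @param alpha Mixing weights (positive, summing to 1).
#' @param mu `K x r` matrix of component means.
#' @param Sigma List of `K` covariance matrices (`r x r`, symmetric
#'   positive definite).
#' @param class_label Label of the class this mixture models.
#' @return An object of class `class_gmm`.
#' @export
class_gmm <- function(alpha, mu, Sigma, class_label = NA_character_) {
  mu <- as.matrix(mu)
  K <- length(alpha)
  if (nrow(mu) != K || length(Sigma) != K) {
    stop("usage error: alpha, mu rows and Sigma must agree in K",
         call. = FALSE)
  }
  if (any(alpha <= 0) || abs(sum(alpha) - 1) > 1e-9) {
    stop("usage error: mixing weights must be positive and sum to 1",
         call. = FALSE)
  }
  structure(list(alpha = as.numeric(alpha), mu = mu, Sigma = Sigma,
                 K = K, r = ncol(mu), class_label = class_label),
            class = "class_gmm")
}

# Per-sample log mixture density, computed in log space via Cholesky
# factors of the component covariances.
gmm_log_density <- function(gmm, X) {
  X <- as.matrix(X)
  if (ncol(X) != gmm$r) {
    stop("usage error: data has ", ncol(X), " columns, mixture expects ",
         gmm$r, call. = FALSE)
  }
  n <- nrow(X)
  logw <- matrix(0, n, gmm$K)
  for (k in seq_len(gmm$K)) {
    R <- tryCatch(chol(gmm$Sigma[[k]]), error = function(e)
      stop("numeric error: component ", k, " covariance not positive ",
           "definite", call. = FALSE))
    Z <- backsolve(R, t(X) - gmm$mu[k, ], transpose = TRUE)
    maha <- colSums(Z^2)
    logdet <- 2 * sum(log(diag(R)))
    logw[, k] <- log(gmm$alpha[k]) -
      0.5 * (gmm$r * log(2 * pi) + logdet + maha)
  }
  logsumexp(logw)
}

#' Log-likelihood of data under a class mixture
#'
#' @param gmm A `class_gmm`.
#' @param X Numeric matrix, rows = samples.
#' @return Scalar sum of per-sample log mixture densities.
#' @export
gmm_log_likelihood <- function(gmm, X) {
  sum(gmm_log_density(gmm, X))
}

#' Bayesian information criterion for a fitted mixture
#'
#' `mode = "standard"` (default) uses `-2 L + p log(n)` with the full
#' free-parameter count `p = (K-1) + K r + K r (r+1)/2`. `mode =
#' "as-printed"` is the reduced form `-2 L + 2 log(n)`, which carries no
#' parameter-count term and therefore never penalizes larger K; it is
#' retained as a fidelity mode only. Model selection minimizes BIC.
#'
#' @param gmm A `class_gmm`.
#' @param X Data matrix the mixture was fitted to.
#' @param mode `"standard"` or `"as-printed"`.
#' @return Scalar BIC.
#' @export
gmm_bic <- function(gmm, X, mode = c("standard", "as-printed")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("usage error: BIC needs n >= 2", call. = FALSE)
  L <- gmm_log_likelihood(gmm, X)
  if (mode == "as-printed") return(-2 * L + 2 * log(n))
  r <- gmm$r
  p <- (gmm$K - 1) + gmm$K * r + gmm$K * r * (r + 1) / 2
  -2 * L + p * log(n)
}

# Covariance with degenerate-data guard and PD jitter. Returns the
# (possibly jittered) matrix with a "jittered" attribute so the EM loop
# can tell regularized steps from exact ones.
.safe_cov <- function(Xc, w = NULL, jitter = 1e-6) {
  n <- nrow(Xc)
  if (is.null(w)) w <- rep(1, n)
  W <- sum(w)
  S <- crossprod(sqrt(w) * Xc) / W
  S <- (S + t(S)) / 2
  if (sum(diag(S)) < 1e-12) {
    stop("numeric error: degenerate covariance (data has no spread)",
         call. = FALSE)
  }
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (!ok) S <- S + diag(jitter, ncol(S))
  attr(S, "jittered") <- !ok
  S
}

# One EM run at fixed K from a seeded k-means partition. Log-likelihood
# monotonicity is asserted every iteration.
.fit_gmm_K <- function(X, K, seed, tol = 1e-6, max_iter = 500,
                       jitter = 1e-6) {
  n <- nrow(X); r <- ncol(X)
  part <- if (K == 1) rep(1L, n) else {
    km <- with_seed(seed, tryCatch(
      stats::kmeans(X, centers = K, nstart = 1, iter.max = 50),
      error = function(e) stop("numeric error: k-means initialization ",
                               "failed: ", conditionMessage(e),
                               call. = FALSE)))
    km$cluster
  }
  alpha <- as.numeric(table(factor(part, levels = seq_len(K)))) / n
  mu <- matrix(0, K, r)
  Sigma <- vector("list", K)
  glob <- .safe_cov(sweep(X, 2, colMeans(X)), jitter = jitter)
  for (k in seq_len(K)) {
    idx <- which(part == k)
    if (length(idx) < 2) {
      mu[k, ] <- if (length(idx)) X[idx, ] else colMeans(X)
      Sigma[[k]] <- glob
      alpha[k] <- max(alpha[k], 1 / n)
    } else {
      mu[k, ] <- colMeans(X[idx, , drop = FALSE])
      Sigma[[k]] <- .safe_cov(sweep(X[idx, , drop = FALSE], 2, mu[k, ]),
                              jitter = jitter)
    }
  }
  alpha <- alpha / sum(alpha)
  Sigma <- lapply(Sigma, function(S) { attr(S, "jittered") <- NULL; S })

  ll_prev <- -Inf
  trace <- numeric(0)
  jittered_last <- FALSE
  prev <- NULL
  for (iter in seq_len(max_iter)) {
    # E-step
    logw <- matrix(0, n, K)
    for (k in seq_len(K)) {
      R <- tryCatch(chol(Sigma[[k]]), error = function(e) NULL)
      if (is.null(R)) {
        Sigma[[k]] <- Sigma[[k]] + diag(jitter, r)
        jittered_last <- TRUE
        R <- tryCatch(chol(Sigma[[k]]), error = function(e)
          stop("numeric error: EM produced a non-PD covariance in ",
               "component ", k, " (iteration ", iter, ")", call. = FALSE))
      }
      Z <- backsolve(R, t(X) - mu[k, ], transpose = TRUE)
      logw[, k] <- log(alpha[k]) -
        0.5 * (r * log(2 * pi) + 2 * sum(log(diag(R))) + colSums(Z^2))
    }
    lse <- logsumexp(logw)
    ll <- sum(lse)
    if (!is.finite(ll)) {
      stop("numeric error: EM log-likelihood diverged (iteration ", iter,
           "); component weights ", paste(signif(alpha, 3), collapse = ", "),
           call. = FALSE)
    }
    if (ll < ll_prev - 1e-8 - 1e-10 * abs(ll_prev)) {
      # an exact EM step never decreases the likelihood; a decrease is
      # legal only right after a covariance was jitter-regularized, in
      # which case the pre-jitter iterate is the fit
      if (jittered_last && !is.null(prev)) {
        alpha <- prev$alpha; mu <- prev$mu; Sigma <- prev$Sigma
        break
      }
      stop("numeric error: EM log-likelihood decreased at iteration ", iter,
           " (", ll_prev, " -> ", ll, ")", call. = FALSE)
    }
    trace <- c(trace, ll)
    conv <- is.finite(ll_prev) &&
      (ll - ll_prev) < tol * max(1, abs(ll_prev))
    ll_prev <- ll
    gam <- exp(logw - lse)
    # M-step
    Nk <- colSums(gam)
    if (any(Nk < 1e-10)) {
      stop("numeric error: EM component collapsed (effective size ~0); ",
           "weights ", paste(signif(Nk / n, 3), collapse = ", "),
           call. = FALSE)
    }
    prev <- list(alpha = alpha, mu = mu, Sigma = Sigma)
    jittered_last <- FALSE
    alpha <- Nk / n
    for (k in seq_len(K)) {
      mu[k, ] <- colSums(gam[, k] * X) / Nk[k]
      Sigma[[k]] <- .safe_cov(sweep(X, 2, mu[k, ]), w = gam[, k],
                              jitter = jitter)
      if (isTRUE(attr(Sigma[[k]], "jittered"))) jittered_last <- TRUE
      attr(Sigma[[k]], "jittered") <- NULL
    }
    if (conv) break
  }
  gmm <- class_gmm(alpha, mu, Sigma)
  gmm$loglik <- ll_prev
  gmm$loglik_trace <- trace
  gmm
}

#' Fit a class-conditional GMM with BIC model-order selection
#'
#' For each candidate component count `K`, runs EM (full covariances,
#' convergence when the relative log-likelihood improvement falls below
#' `tol`, at most `max_iter` iterations) from `n_restarts` seeded k-means
#' initializations, keeping the restart with the highest likelihood; the
#' `K` minimizing BIC is returned. Because BIC is quasi-convex in `K` on
#' the data this classifier targets, the scan stops early once BIC has
#' risen for `k_patience` consecutive values of `K`; set `k_patience =
#' Inf` to force the full scan.
#'
#' @param X Numeric matrix, rows = samples.
#' @param K_max Largest component count considered (default 10).
#' @param seed Integer seed controlling the k-means initializations.
#' @param n_restarts k-means restarts per `K` (default 3).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per run.
#' @param k_patience Consecutive BIC increases tolerated before the K
#'   scan stops.
#' @param bic_mode Passed to [gmm_bic()].
#' @param class_label Optional label stored in the result.
#' @return A `class_gmm` with fields `loglik`, `loglik_trace`, `bic` and
#'   `bic_table` (the per-K scan).
#' @export
fit_class_gmm <- function(X, K_max = 10, seed = 0L, n_restarts = 3,
                          tol = 1e-6, max_iter = 500, k_patience = 2,
                          bic_mode = "standard",
                          class_label = NA_character_) {
  X <- as.matrix(X)
  n <- nrow(X); r <- ncol(X)
  if (n < 2) stop("usage error: need at least 2 samples", call. = FALSE)
  if (n < K_max * (r + 1)) {
    warning("n = ", n, " is below the recommended K_max*(r+1) = ",
            K_max * (r + 1), " samples; large K fits may be unstable")
  }
  best <- NULL
  bic_tab <- data.frame(K = integer(0), loglik = numeric(0),
                        bic = numeric(0))
  rises <- 0
  prev_bic <- Inf
  for (K in seq_len(K_max)) {
    fitK <- NULL
    for (rs in seq_len(if (K == 1) 1 else n_restarts)) {
      # a numerically failed run at K > 1 (component collapse on data
      # with fewer than K modes) removes that candidate rather than
      # aborting model selection; K = 1 failures are real data problems
      f <- if (K == 1) {
        .fit_gmm_K(X, K, seed = child_seed(seed, K * 131 + rs),
                   tol = tol, max_iter = max_iter)
      } else {
        tryCatch(
          .fit_gmm_K(X, K, seed = child_seed(seed, K * 131 + rs),
                     tol = tol, max_iter = max_iter),
          error = function(e) {
            warning("K = ", K, " restart ", rs, " failed: ",
                    conditionMessage(e))
            NULL
          })
      }
      if (!is.null(f) && (is.null(fitK) || f$loglik > fitK$loglik))
        fitK <- f
    }
    if (is.null(fitK)) next
    fitK$bic <- gmm_bic(fitK, X, mode = bic_mode)
    bic_tab <- rbind(bic_tab, data.frame(K = K, loglik = fitK$loglik,
                                         bic = fitK$bic))
    if (is.null(best) || fitK$bic < best$bic) best <- fitK
    rises <- if (fitK$bic > prev_bic) rises + 1 else 0
    prev_bic <- fitK$bic
    if (rises >= k_patience) break
  }
  best$class_label <- class_label
  best$bic_table <- bic_tab
  best
}

#' @export
print.class_gmm <- function(x, ...) {
  cat(sprintf("<class_gmm> %s: K=%d components in %d dims\n",
              x$class_label, x$K, x$r))
  invisible(x)
}

#' Fit the full LFDA-GMM classifier
#'
#' Fits the LFDA transform on the labeled training rows, projects them,
#' then fits one BIC-selected Gaussian mixture per class on that class's
#' reduced rows.
#'
#' @param X Training matrix or labeled `feature_matrix`.
#' @param y Class labels (taken from `X` if it is a `feature_matrix`).
#' @param r Reduced dimension for LFDA.
#' @param k_nn LFDA neighborhood size.
#' @param K_max Maximum mixture components per class.
#' @param seed Integer seed (k-means initializations, LFDA subsampling).
#' @param classes Classes that must be present; defaults to the labels
#'   observed in `y`. A listed class with no training rows is an error.
#' @param ... Passed on to [fit_class_gmm()].
#' @return An object of class `lfda_gmm` holding the `lfda_model` and one
#'   `class_gmm` per class.
#' @export
fit_lfda_gmm <- function(X, y = NULL, r, k_nn = 7, K_max = 10, seed = 1L,
                         classes = NULL, ...) {
  if (inherits(X, "feature_matrix")) {
    if (is.null(y)) y <- X$y
    X <- X$X
  }
  X <- as.matrix(X)
  y <- as.character(y)
  if (is.null(classes)) classes <- sort(unique(y))
  missing_cl <- setdiff(classes, unique(y))
  if (length(missing_cl)) {
    stop("fit error: no training rows for class(es): ",
         paste(missing_cl, collapse = ", "), call. = FALSE)
  }
  lfda <- fit_lfda(X, y, r = r, k_nn = k_nn, seed = child_seed(seed, 1))
  Z <- predict(lfda, X)
  models <- lapply(seq_along(classes), function(i) {
    cl <- classes[i]
    fit_class_gmm(Z[y == cl, , drop = FALSE], K_max = K_max,
                  seed = child_seed(seed, 1000 + i), class_label = cl, ...)
  })
  names(models) <- classes
  structure(list(lfda = lfda, models = models, classes = classes,
                 K_max = K_max, seed = seed),
            class = "lfda_gmm")
}

#' Class posterior probabilities from an LFDA-GMM classifier
#'
#' Posteriors assume equal class priors (the cross-validation design
#' balances classes) and are normalized to sum to one per row.
#'
#' @param clf An `lfda_gmm` classifier.
#' @param X Matrix or `feature_matrix` in the original feature space.
#' @return `n x n_classes` matrix of posterior probabilities, columns in
#'   class-label order.
#' @export
gmm_posterior <- function(clf, X) {
  stopifnot(inherits(clf, "lfda_gmm"))
  Z <- predict(clf$lfda, X)
  logd <- vapply(clf$models, function(m) gmm_log_density(m, Z),
                 numeric(nrow(Z)))
  logd <- matrix(logd, nrow = nrow(Z))
  post <- exp(logd - logsumexp(logd))
  colnames(post) <- clf$classes
  post
}

#' Predict class labels with an LFDA-GMM classifier
#'
#' Maximum-posterior assignment with equal class priors; exact ties break
#' to the lexicographically smallest class label.
#'
#' @param object An `lfda_gmm`.
#' @param newdata Matrix or `feature_matrix`.
#' @param type `"class"` (default) or `"posterior"`.
#' @param ... Unused.
#' @return Character vector of labels, or the posterior matrix.
#' @export
predict.lfda_gmm <- function(object, newdata,
                             type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  post <- gmm_posterior(object, newdata)
  if (type == "posterior") return(post)
  object$classes[apply(post, 1, which.max)]
}

#' @export
print.lfda_gmm <- function(x, ...) {
  cat(sprintf("<lfda_gmm> %d classes, r=%d, k_nn=%d, K in [%s]\n",
              length(x$classes), x$lfda$r, x$lfda$k_nn,
              paste(range(vapply(x$models, `[[`, 0L, "K")), collapse = "-")))
  invisible(x)
}
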