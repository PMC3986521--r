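# Local Fisher discriminant analysis: supervised linear dimensionality
# reduction that maximizes between-class scatter against within-class
# scatter while weighting sample pairs by a local affinity, so
# multimodal or zero-mean classes are not collapsed the way classical
# FDA collapses them.
#
# Affinity (same-class pairs only): A_ij = exp(-||x_i - x_j||^2 /
# (sigma_i sigma_j)), with local scale sigma_i the distance from x_i to
# its k_nn-th nearest same-class neighbor. Pair weights:
#   W^w_ij = A_ij / n_c               (same class c; else 0)
#   W^b_ij = A_ij (1/n - 1/n_c)       (same class), 1/n (different class)
# Scatters S = 1/2 sum_ij W_ij (x_i - x_j)(x_i - x_j)^T; the transform
# consists of the top-r generalized eigenvectors of S^b v = lambda S^w v.

#' Fit a local Fisher discriminant analysis transform
#'
#' @param X Numeric matrix (rows = samples) or a `feature_matrix`.
#' @param y Class labels (ignored if `X` is a labeled `feature_matrix`).
#' @param r Reduced dimension (`<= ncol(X)`).
#' @param k_nn Neighbor index used for the local affinity scale; every
#'   class must have more than `k_nn` members.
#' @param affinity `"local"` (default) or `"uniform"`. With uniform
#'   affinities LFDA reduces exactly to classical Fisher discriminant
#'   analysis.
#' @param subsample_cap Per-class row cap for scatter estimation (the
#'   pairwise affinity is quadratic in class size); capped classes are
#'   subsampled reproducibly.
#' @param ridge Relative ridge added to the within-class scatter when its
#'   Cholesky factorization fails (collinear lag features).
#' @param seed Seed for the per-class subsampling.
#' @return An object of class `lfda_model` with the `d x r` transform `T`
#'   (columns unit-norm, sorted by descending generalized eigenvalue).
#' @export
fit_lfda <- function(X, y = NULL, r, k_nn = 7,
                     affinity = c("local", "uniform"),
                     subsample_cap = 5000, ridge = 1e-9, seed = 0L) {
  affinity <- match.arg(affinity)
  if (inherits(X, "feature_matrix")) {
    if (is.null(y)) y <- X$y
    X <- X$X
  }
  X <- as.matrix(X)
  d <- ncol(X)
  y <- as.character(y)
  if (length(y) != nrow(X)) {
    stop("usage error: length(y) != nrow(X)", call. = FALSE)
  }
  classes <- sort(unique(y))
  if (length(classes) < 2) {
    stop("fit error: need at least 2 classes", call. = FALSE)
  }
  if (r > d || r < 1) {
    stop("usage error: r must lie in [1, ncol(X)]", call. = FALSE)
  }
  sizes <- table(y)
  if (affinity == "local" && any(sizes <= k_nn)) {
    stop("fit error: class(es) ",
         paste(names(sizes)[sizes <= k_nn], collapse = ", "),
         " have <= k_nn = ", k_nn, " members", call. = FALSE)
  }

  # reproducible per-class subsampling for scatter estimation
  idx_by_class <- split(seq_along(y), y)
  idx_by_class <- lapply(seq_along(idx_by_class), function(i) {
    idx <- idx_by_class[[i]]
    if (length(idx) > subsample_cap) {
      with_seed(child_seed(seed, i), sort(sample(idx, subsample_cap)))
    } else idx
  })
  n <- sum(lengths(idx_by_class))

  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  s_tot <- numeric(d)
  gram_cross <- matrix(0, d, d)  # accumulates sum_c s_c s_c^T
  diag_cross <- matrix(0, d, d)  # accumulates sum_c ((n - n_c)/n) X_c'X_c
  for (idx in idx_by_class) {
    Xc <- X[idx, , drop = FALSE]
    nc <- nrow(Xc)
    A <- if (affinity == "uniform") {
      matrix(1, nc, nc)
    } else {
      sq <- rowSums(Xc^2)
      D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(Xc), 0)
      sig <- sqrt(apply(D2, 1, function(row)
        sort(row, partial = k_nn + 1)[k_nn + 1]))
      sig <- pmax(sig, .Machine$double.eps)
      exp(-D2 / outer(sig, sig))
    }
    dA <- rowSums(A)
    Lc <- crossprod(Xc, dA * Xc) - crossprod(Xc, A %*% Xc)
    Lc <- (Lc + t(Lc)) / 2
    Sw <- Sw + Lc / nc
    Sb <- Sb + (1 / n - 1 / nc) * Lc
    sc <- colSums(Xc)
    s_tot <- s_tot + sc
    gram_cross <- gram_cross + tcrossprod(sc)
    diag_cross <- diag_cross + ((n - nc) / n) * crossprod(Xc)
  }
  # different-class pair contribution (constant weight 1/n)
  Sb <- Sb + diag_cross - (tcrossprod(s_tot) - gram_cross) / n
  Sb <- (Sb + t(Sb)) / 2
  Sw <- (Sw + t(Sw)) / 2

  eig <- .generalized_eig(Sb, Sw, r, ridge)
  structure(list(T = eig$vectors, r = r, k_nn = k_nn, d = d,
                 class_labels = classes, eigenvalues = eig$values,
                 affinity = affinity),
            class = "lfda_model")
}

# Top-r generalized eigenvectors of Sb v = lambda Sw v via Cholesky
# whitening, with escalating ridge regularization when Sw is singular.
.generalized_eig <- function(Sb, Sw, r, ridge) {
  d <- ncol(Sw)
  tr <- sum(diag(Sw))
  R <- NULL
  for (eps in c(0, ridge, ridge * 1e3, ridge * 1e6)) {
    Swr <- Sw + diag(eps * tr / d, d)
    R <- tryCatch(chol(Swr), error = function(e) NULL)
    if (!is.null(R)) {
      if (eps > 0) {
        warning("within-class scatter singular; regularized with ridge ",
                format(eps))
      }
      break
    }
  }
  if (is.null(R)) {
    stop("fit error: within-class scatter not positive definite even after ",
         "regularization", call. = FALSE)
  }
  M <- backsolve(R, Sb, transpose = TRUE)   # R^-T Sb
  M <- t(backsolve(R, t(M), transpose = TRUE))
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  V <- backsolve(R, e$vectors[, seq_len(r), drop = FALSE])
  # unit-norm columns with a deterministic sign convention
  V <- apply(V, 2, function(v) {
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) -v else v
  })
  list(vectors = matrix(V, ncol = r), values = e$values[seq_len(r)])
}

#' Project data through a fitted LFDA transform
#'
#' @param object An `lfda_model`.
#' @param newdata Matrix (or `feature_matrix`) with `d` columns.
#' @param ... Unused.
#' @return An `n x r` matrix of reduced features.
#' @export
predict.lfda_model <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d) {
    stop("usage error: newdata has ", ncol(newdata), " columns, model expects ",
         object$d, call. = FALSE)
  }
  newdata %*% object$T
}

#' @export
print.lfda_model <- function(x, ...) {
  cat(sprintf("<lfda_model> d=%d -> r=%d (k_nn=%d, %s affinity)\n",
              x$d, x$r, x$k_nn, x$affinity))
  invisible(x)
}
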