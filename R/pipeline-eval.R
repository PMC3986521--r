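# Cross-validated end-to-end evaluation: balanced random-subsampling CV,
# confusion matrices and per-class metrics, forward channel selection,
# and training-size sweeps.

#' Confusion matrix
#'
#' @param y_true,y_pred Equal-length label vectors (rows = actual,
#'   columns = predicted).
#' @param classes Class set; defaults to the union of observed labels.
#' @return An object of class `confusion_matrix` with integer `counts`
#'   and row-normalized percentages `normalized`.
#' @export
confusion <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("usage error: y_true and y_pred differ in length", call. = FALSE)
  }
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  counts <- table(factor(y_true, levels = classes),
                  factor(y_pred, levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(actual = classes, predicted = classes))
  rs <- rowSums(counts)
  normalized <- 100 * counts / ifelse(rs == 0, 1, rs)
  structure(list(counts = counts, normalized = normalized,
                 classes = classes),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (row-normalized %)\n")
  print(round(x$normalized, 1))
  cat(sprintf("overall accuracy: %.1f%%\n",
              100 * sum(diag(x$counts)) / max(1, sum(x$counts))))
  invisible(x)
}

# Pool two confusion matrices over the same class set.
.pool_confusion <- function(a, b) {
  if (is.null(a)) return(b)
  stopifnot(identical(a$classes, b$classes))
  confusion_from_counts(a$counts + b$counts, a$classes)
}

confusion_from_counts <- function(counts, classes) {
  rs <- rowSums(counts)
  structure(list(counts = counts,
                 normalized = 100 * counts / ifelse(rs == 0, 1, rs),
                 classes = classes),
            class = "confusion_matrix")
}

#' Per-class sensitivity, precision and F score
#'
#' Sensitivity (recall) is the diagonal over the row sum, precision the
#' diagonal over the column sum. The F score is the weighted harmonic
#' mean `(1 + beta^2) s p / (beta^2 p + s)`; `form = "as-printed"` uses
#' `beta` unsquared in the denominator -- the two coincide at the default
#' `beta = 1`, the only weighting used in practice. Empty predicted
#' columns yield precision 0 with a warning, and F is 0 whenever either
#' rate is 0.
#'
#' @param cm A `confusion_matrix`.
#' @param beta Weighting between sensitivity and precision (default 1).
#' @param form `"standard"` or `"as-printed"`.
#' @return `data.frame` with columns `class`, `sensitivity`, `precision`,
#'   `F`.
#' @export
class_metrics <- function(cm, beta = 1, form = c("standard", "as-printed")) {
  form <- match.arg(form)
  stopifnot(inherits(cm, "confusion_matrix"))
  d <- diag(cm$counts)
  rs <- rowSums(cm$counts)
  cs <- colSums(cm$counts)
  if (any(cs == 0 & rs > 0)) {
    warning("class(es) never predicted; precision set to 0: ",
            paste(cm$classes[cs == 0 & rs > 0], collapse = ", "))
  }
  sens <- ifelse(rs == 0, 0, d / rs)
  prec <- ifelse(cs == 0, 0, d / cs)
  denom <- if (form == "standard") beta^2 * prec + sens else
    beta * prec + sens
  f <- ifelse(sens * prec == 0, 0, (1 + beta^2) * sens * prec / denom)
  data.frame(class = cm$classes, sensitivity = sens, precision = prec,
             F = f, row.names = NULL, stringsAsFactors = FALSE)
}

#' Balanced random-subsampling cross-validation
#'
#' Per iteration: `n_train = floor(pct_train/100 * min_class_size)` rows
#' are drawn from every class for training and a disjoint, equally
#' balanced test set of `min_class_size - n_train` rows per class is
#' drawn from the remainder; the full LFDA-GMM classifier is fitted on
#' the training rows only and scored on the test rows. Confusion counts
#' are pooled across iterations.
#'
#' @param fm Labeled `feature_matrix` (or plain matrix with `y`).
#' @param y Labels when `fm` is a plain matrix.
#' @param pct_train Training percentage of the least populated class,
#'   in (0, 100).
#' @param n_iter Number of random subsampling iterations (default 10).
#' @param r,k_nn,K_max Classifier parameters (see [fit_lfda_gmm()]).
#' @param seed Integer seed; iteration `i` uses a derived child seed.
#' @param ... Passed to [fit_lfda_gmm()].
#' @return An object of class `cv_result`: per-iteration accuracies,
#'   mean, SD, standard error (SD/sqrt(n_iter)), pooled confusion
#'   matrix, and the parameters used.
#' @export
random_subsample_cv <- function(fm, y = NULL, pct_train = 50, n_iter = 10,
                                r, k_nn = 7, K_max = 10, seed = 1L, ...) {
  if (inherits(fm, "feature_matrix")) {
    if (is.null(y)) y <- fm$y
    X <- fm$X
  } else X <- as.matrix(fm)
  y <- as.character(y)
  if (!(pct_train > 0 && pct_train < 100)) {
    stop("usage error: pct_train must lie in (0, 100)", call. = FALSE)
  }
  classes <- sort(unique(y))
  sizes <- table(y)
  min_size <- min(sizes)
  n_train <- floor(pct_train / 100 * min_size)
  if (n_train < 1) {
    stop("usage error: pct_train gives an empty training set", call. = FALSE)
  }
  n_test <- min_size - n_train
  if (n_test < 1) {
    stop("usage error: pct_train leaves no test samples", call. = FALSE)
  }
  idx_by_class <- split(seq_along(y), y)
  acc <- numeric(n_iter)
  pooled <- NULL
  for (it in seq_len(n_iter)) {
    sel <- with_seed(child_seed(seed, it), {
      lapply(idx_by_class, function(idx) {
        tr <- sample(idx, n_train)
        te <- sample(setdiff(idx, tr), n_test)
        list(train = tr, test = te)
      })
    })
    tr_idx <- unlist(lapply(sel, `[[`, "train"), use.names = FALSE)
    te_idx <- unlist(lapply(sel, `[[`, "test"), use.names = FALSE)
    clf <- fit_lfda_gmm(X[tr_idx, , drop = FALSE], y[tr_idx], r = r,
                        k_nn = k_nn, K_max = K_max,
                        seed = child_seed(seed, 10000 + it), ...)
    pred <- predict(clf, X[te_idx, , drop = FALSE])
    truth <- y[te_idx]
    acc[it] <- mean(pred == truth)
    pooled <- .pool_confusion(pooled, confusion(truth, pred, classes))
  }
  structure(list(accuracies = acc, mean = mean(acc), sd = stats::sd(acc),
                 se = stats::sd(acc) / sqrt(n_iter), confusion = pooled,
                 params = list(r = r, k_nn = k_nn, K_max = K_max,
                               pct_train = pct_train, n_iter = n_iter,
                               n_train_per_class = n_train,
                               n_test_per_class = n_test, seed = seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> mean accuracy %.1f%% +/- %.2f (SE, %d iterations)\n",
    100 * x$mean, 100 * x$se, x$params$n_iter))
  invisible(x)
}

# Column indices of a channel's lag block in the feature matrix.
.channel_columns <- function(fm, channels) {
  stopifnot(inherits(fm, "feature_matrix"))
  unlist(lapply(match(channels, fm$channel_labels), function(i) {
    (i - 1) * fm$l + seq_len(fm$l)
  }))
}

# A feature_matrix restricted to a channel subset.
.subset_channels <- function(fm, channels) {
  cols <- .channel_columns(fm, channels)
  out <- fm
  out$X <- fm$X[, cols, drop = FALSE]
  out$channel_labels <- channels
  out
}

#' Greedy forward selection of EEG channels
#'
#' Ranks channels by the cross-validated accuracy of the classifier run
#' on each channel's lag block alone, seeds the selected-channels list
#' (SCL) with the best one, then repeatedly adds the channel that
#' maximizes mean CV accuracy alongside the current SCL until all
#' channels are consumed. Candidate evaluations use a light inner CV
#' (`n_iter_search` iterations); the final accuracy curve is re-estimated
#' on the selected nesting with `n_iter_final` iterations. Ties break in
#' channel-label order; the procedure is deterministic for a fixed seed.
#'
#' @param fm Labeled `feature_matrix`.
#' @param r,k_nn,K_max,pct_train Classifier and CV parameters (`r` is
#'   capped at the current feature dimension).
#' @param n_iter_search Inner CV iterations per candidate (default 3).
#' @param n_iter_final CV iterations for the reported curve (default 30).
#' @param seed Integer seed.
#' @return `data.frame` with one row per selection step: `channel`,
#'   `n_channels`, `accuracy`, `sd`, `se`.
#' @export
forward_select <- function(fm, r = 10, k_nn = 7, K_max = 10,
                           pct_train = 50, n_iter_search = 3,
                           n_iter_final = 30, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  channels <- fm$channel_labels
  if (length(channels) < 2) {
    stop("usage error: forward selection needs at least 2 channels",
         call. = FALSE)
  }
  scl <- character(0)
  order_sel <- character(0)
  remaining <- channels
  while (length(remaining)) {
    scores <- vapply(remaining, function(ch) {
      sub <- .subset_channels(fm, c(scl, ch))
      cv <- random_subsample_cv(sub, pct_train = pct_train,
                                n_iter = n_iter_search,
                                r = min(r, ncol(sub$X)), k_nn = k_nn,
                                K_max = K_max, seed = seed)
      cv$mean
    }, numeric(1))
    best <- remaining[which.max(scores)]  # which.max: first max, label order
    scl <- c(scl, best)
    order_sel <- c(order_sel, best)
    remaining <- setdiff(remaining, best)
  }
  curve <- lapply(seq_along(order_sel), function(k) {
    sub <- .subset_channels(fm, order_sel[seq_len(k)])
    cv <- random_subsample_cv(sub, pct_train = pct_train,
                              n_iter = n_iter_final,
                              r = min(r, ncol(sub$X)), k_nn = k_nn,
                              K_max = K_max, seed = child_seed(seed, 777))
    data.frame(channel = order_sel[k], n_channels = k, accuracy = cv$mean,
               sd = cv$sd, se = cv$se, stringsAsFactors = FALSE)
  })
  do.call(rbind, curve)
}

#' Accuracy as a function of training-set size
#'
#' Runs [random_subsample_cv()] at each requested training percentage of
#' the least populated class.
#'
#' @param fm Labeled `feature_matrix`.
#' @param pcts Training percentages (default 20--90 by 10).
#' @param ... Passed to [random_subsample_cv()] (`r`, `k_nn`, `K_max`,
#'   `n_iter`, `seed`, ...).
#' @return `data.frame` with one row per percentage: `pct_train`,
#'   `accuracy`, `sd`, `se`.
#' @export
training_size_sweep <- function(fm, pcts = seq(20, 90, by = 10), ...) {
  if (any(pcts <= 0 | pcts >= 100)) {
    stop("usage error: training percentages must lie in (0, 100)",
         call. = FALSE)
  }
  rows <- lapply(pcts, function(p) {
    cv <- random_subsample_cv(fm, pct_train = p, ...)
    data.frame(pct_train = p, accuracy = cv$mean, sd = cv$sd, se = cv$se)
  })
  do.call(rbind, rows)
}
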