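# Shared fixtures, generated in code at test time.

# A small, fast session: central channels only, EEG already at the
# analysis rate so tests exercise the pipeline without heavy resampling.
small_session_config <- function(..., seed = 101) {
  session_config(n_eeg_channels = 8, eeg_rate = 100, n_sensors = 4,
                 marg_rate = 32, n_trial_blocks = 1,
                 segment_duration_s = 4, seed = seed, ...)
}

# Well-separated Gaussian classes for classifier-level tests (no EEG
# structure, just labeled clouds).
gaussian_classes <- function(n_per_class = 60, d = 4, sep = 6,
                             classes = c("a", "b", "c"), seed = 1) {
  k <- length(classes)
  mobidecode:::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(k), function(i) {
      mu <- numeric(d)
      mu[((i - 1) %% d) + 1] <- sep * i
      matrix(rnorm(n_per_class * d), ncol = d) +
        matrix(mu, n_per_class, d, byrow = TRUE)
    }))
    list(X = X, y = rep(classes, each = n_per_class))
  })
}

# Plain feature_matrix wrapper around a labeled matrix (l = 1) so
# CV-level helpers can be exercised without EEG preprocessing.
as_feature_matrix <- function(X, y, rate = 100) {
  structure(list(X = as.matrix(X), y = as.character(y),
                 row_time = seq_len(nrow(X)) / rate,
                 channel_labels = paste0("V", seq_len(ncol(X))),
                 l = 1, rate = rate),
            class = "feature_matrix")
}
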