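# Shared fixture builders (all generated in code at test time).

utc <- function(x) as.POSIXct(x, tz = "UTC")
t_origin <- utc("2022-01-03 00:00:00")

# sample series at explicit minute offsets
min_series <- function(minutes, values, kind = "hr") {
  sample_series(t_origin + minutes * 60, values, kind)
}

hourly_rs <- function(values) {
  regular_series(values, 60, start = t_origin)
}

# a clean control-like subject, small enough for fast unit tests
small_subject <- function(seed = 1, days = 12, label = 0, profile = NULL,
                          dropout = 0, artifact = 0) {
  prof <- profile %||% calibration_profiles()$control
  acq <- acquisition_model(dropout_rate = dropout, artifact_rate = artifact,
                           record_days = days)
  generate_subject(prof, acq, seed, sprintf("s%03d", seed), label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic label permutation under a local seed
local_perm <- function(labels, seed) {
  set.seed(seed)
  sample(labels)
}

# feature matrix with two well-separated synthetic clusters (for classifier
# harness checks that do not need the full generator)
separable_fm <- function(n_per_class = 16, n_features = 4, delta = 6, seed = 99) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * n_features), n_per_class),
             matrix(rnorm(n_per_class * n_features, mean = delta), n_per_class))
  fm <- as.data.frame(X)
  names(fm) <- paste0("f", seq_len(n_features))
  fm$label <- rep(c(0, 1), each = n_per_class)
  fm
}
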