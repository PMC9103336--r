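# Shared fixtures, all generated in code at test time.

# clean single-component ECG with known beat truth
clean_ecg <- function(bpm, duration_s = 10, fs = 1000, jitter = 0.02,
                      seed = 5, template = ecg_template()) {
  beats <- generate_beat_train(bpm, duration_s, jitter, fs, seed = seed)
  list(x = render_ecg(template, beats, fs, round(duration_s * fs)),
       beats = beats, fs = fs)
}

f1_of <- function(ann, truth, fs = 1000, tol_ms = 50) {
  m <- match_annotations(ann, qrs_annotation(truth, fs), tol_ms)
  den <- 2 * m[["tp"]] + m[["fp"]] + m[["fn"]]
  if (den == 0) return(0)
  2 * m[["tp"]] / den
}

# a small preprocessed synthetic dataset shared across tests (built lazily)
.test_env <- new.env(parent = emptyenv())

small_dataset <- function() {
  if (is.null(.test_env$recs)) {
    .test_env$recs <- generate_dataset(
      6, 6, synth_config(duration_s = 10), seed = 99)
    .test_env$pp <- lapply(.test_env$recs, preprocess_recording)
  }
  list(recs = .test_env$recs, pp = .test_env$pp)
}

# separable toy feature clouds for the classical learners
toy_features <- function(n_per_class = 100, sep = 3, seed = 42) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * 45), ncol = 45),
             matrix(rnorm(n_per_class * 45, mean = sep / sqrt(45)), ncol = 45))
  colnames(X) <- sqi_feature_names()
  list(X = X, y = rep(c("bad", "good"), each = n_per_class))
}

# tiny separable image set for the CNN on a reduced input shape: class 1
# carries a bright patch in a fixed corner
toy_images <- function(n_per_class = 20, shape = c(12, 16), n_paths = 4,
                       seed = 3) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- array(abs(rnorm(shape[1] * shape[2] * n_paths * n, sd = 0.2)),
             c(shape, n_paths, n))
  y <- rep(c("bad", "good"), each = n_per_class)
  for (i in which(y == "good")) {
    X[1:4, 1:4, , i] <- X[1:4, 1:4, , i] + 1
  }
  list(X = X, y = y)
}
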