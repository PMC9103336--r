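# Classical baselines on the 45 SQI features: Gaussian Naive Bayes, linear
# and RBF support vector machines, and random forest, each tuned by an
# exhaustive grid search under inner stratified cross-validation on mean
# AUC. Features are standardized (training-fold statistics) for NB and the
# SVMs; the random forest sees raw features.

#' Hyper-parameter grid specification
#'
#' Default grids: SVMs search cost `{0.1, 1, 10, 100}` (RBF additionally
#' gamma `{1e-3, 1e-2, 1e-1, 1/45}`); random forest searches
#' ntree `{100, 300}` x nodesize `{1, 5}`; Naive Bayes searches the
#' zero-probability floor eps `{1e-9, 1e-7, 1e-5}`.
#'
#' @param model_type one of `"nb"`, `"svm_linear"`, `"svm_rbf"`, `"rf"`.
#' @param grid named list of candidate parameter values; `NULL` for the
#'   default grid.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(model_type = c("nb", "svm_linear", "svm_rbf", "rf"),
                      grid = NULL) {
  model_type <- match.arg(model_type)
  if (is.null(grid)) {
    grid <- switch(model_type,
      nb = list(eps = c(1e-9, 1e-7, 1e-5)),
      svm_linear = list(cost = c(0.1, 1, 10, 100)),
      svm_rbf = list(cost = c(0.1, 1, 10, 100),
                     gamma = c(1e-3, 1e-2, 1e-1, 1 / 45)),
      rf = list(ntree = c(100, 300), nodesize = c(1, 5))
    )
  }
  if (!length(grid) || any(!lengths(grid))) stop("grid must be non-empty")
  structure(list(model_type = model_type, grid = grid), class = "grid_spec")
}

.standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

.standardize_apply <- function(X, sc) {
  sweep(sweep(X, 2, sc$mu, "-"), 2, sc$sd, "/")
}

.fit_one <- function(model_type, X, y, par) {
  yf <- factor(y, levels = c("bad", "good"))
  switch(model_type,
    nb = list(fit = e1071::naiveBayes(X, yf), eps = par$eps),
    svm_linear = list(fit = e1071::svm(X, yf, kernel = "linear",
                                       cost = par$cost, scale = FALSE)),
    svm_rbf = list(fit = e1071::svm(X, yf, kernel = "radial",
                                    cost = par$cost, gamma = par$gamma,
                                    scale = FALSE)),
    rf = list(fit = randomForest::randomForest(X, yf, ntree = par$ntree,
                                               nodesize = par$nodesize))
  )
}

.score_one <- function(model_type, m, X) {
  switch(model_type,
    nb = {
      pr <- stats::predict(m$fit, X, type = "raw", eps = m$eps)
      pr[, "good"]
    },
    svm_linear = ,
    svm_rbf = {
      dvm <- attr(stats::predict(m$fit, X, decision.values = TRUE),
                  "decision.values")
      dv <- dvm[, 1]
      # column name "a/b" means dv > 0 favours class a; orient to "good"
      if (startsWith(colnames(dvm)[1], "good")) stats::plogis(dv)
      else stats::plogis(-dv)
    },
    rf = stats::predict(m$fit, X, type = "prob")[, "good"]
  )
}

.grid_expand <- function(grid) {
  df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Grid-search a classical model under inner stratified CV
#'
#' Every grid point is scored by the mean validation AUC over
#' `inner_folds` stratified folds; the best point (earliest on ties) is
#' refit on all provided data.
#'
#' @param X numeric feature matrix (n x 45).
#' @param y labels `"good"`/`"bad"`.
#' @param grid a `grid_spec`.
#' @param inner_folds number of inner CV folds.
#' @param seed integer seed for the fold assignment.
#' @return List of class `benchmark_model`: `model_type`, `fit`, `params`,
#'   `inner_auc`, `scaler`, `layout_version`.
#' @export
train_benchmark <- function(X, y, grid = grid_spec("rf"), inner_folds = 5,
                            seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  scaler <- if (grid$model_type != "rf") .standardize_fit(X) else NULL
  Xs <- if (is.null(scaler)) X else .standardize_apply(X, scaler)
  folds <- stratified_folds(y, inner_folds, seed = seed)
  points <- .grid_expand(grid$grid)
  aucs <- vapply(points, function(par) {
    fold_auc <- vapply(seq_len(inner_folds), function(f) {
      tr <- folds != f; te <- !tr
      if (length(unique(y[te])) < 2L) return(NA_real_)
      set.seed(seed + f)   # tree fits draw from the RNG
      m <- .fit_one(grid$model_type, Xs[tr, , drop = FALSE], y[tr], par)
      .rank_auc(.score_one(grid$model_type, m, Xs[te, , drop = FALSE]),
                as.integer(y[te] == "good"))
    }, numeric(1))
    mean(fold_auc, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(aucs)   # earliest maximum
  set.seed(seed)
  fit <- .fit_one(grid$model_type, Xs, y, points[[best]])
  structure(list(model_type = grid$model_type, fit = fit,
                 params = points[[best]], inner_auc = aucs[best],
                 grid_aucs = aucs, scaler = scaler,
                 layout_version = "fecgsqi-45-v1"),
            class = "benchmark_model")
}

#' Predict good-quality probabilities from a classical model
#'
#' @param model a `benchmark_model`.
#' @param X feature matrix with 45 columns in the trained layout.
#' @return Numeric vector of probabilities (or squashed decision values)
#'   in \\[0, 1\\].
#' @export
predict_benchmark <- function(model, X) {
  stopifnot(inherits(model, "benchmark_model"))
  X <- as.matrix(X)
  if (nrow(X) == 0L) return(numeric())
  if (ncol(X) != 45L) stop("feature matrix must have exactly 45 columns")
  lv <- attr(X, "layout_version")
  if (!is.null(lv) && !identical(lv, model$layout_version)) {
    stop("feature layout_version mismatch")
  }
  Xs <- if (is.null(model$scaler)) X else .standardize_apply(X, model$scaler)
  as.numeric(.score_one(model$model_type, model$fit, Xs))
}
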