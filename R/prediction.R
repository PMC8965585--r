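# Leave-one-individual-out prediction with fold-wise correlation-based
# feature selection, per-feature-type regressors, and decision-level fusion.
# All statistics applied to a held-out subject are functions of the training
# subjects only.

#' Correlation-based feature selection
#'
#' Selects the columns whose two-sided Pearson-correlation p-value against
#' `train_y` (t-distributed with n - 2 degrees of freedom) is strictly below
#' `p_threshold`. Constant columns are excluded; their count is reported via
#' a message when positive.
#'
#' @param train_X training matrix (subjects x features).
#' @param train_y training response.
#' @param p_threshold selection threshold in (0, 1).
#' @param quiet suppress the constant-column message.
#' @return sorted integer vector of selected column indices.
#' @export
select_features <- function(train_X, train_y, p_threshold = 0.01,
                            quiet = FALSE) {
  train_X <- as.matrix(train_X)
  n <- nrow(train_X)
  if (n < 4) stop("feature selection needs at least 4 training subjects")
  if (stats::sd(train_y) == 0) stop("training response is constant")
  if (p_threshold <= 0 || p_threshold >= 1)
    stop("p_threshold must lie in (0, 1)")
  sds <- matrixStats_colSds(train_X)
  const <- sds == 0
  if (any(const) && !quiet)
    message(sprintf("excluding %d constant column(s) from selection",
                    sum(const)))
  r <- rep(0, ncol(train_X))
  r[!const] <- as.vector(stats::cor(train_X[, !const, drop = FALSE], train_y))
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  p[const] <- 1
  which(p < p_threshold)
}

# column standard deviations without an extra dependency
matrixStats_colSds <- function(X) {
  mu <- colMeans(X)
  sqrt(pmax(colMeans(X^2) - mu^2, 0) * nrow(X) / max(nrow(X) - 1, 1))
}

#' Fit / apply per-feature z-scoring with training statistics
#'
#' `zscore_fit` records per-column mean and sample sd on the training rows;
#' `zscore_apply` transforms any matrix with those statistics, so test
#' subjects never contribute to normalisation.
#'
#' @param train_X training matrix (already restricted to selected columns).
#' @return `zscore_fit`: list with `mean` and `sd`.
#' @export
zscore_fit <- function(train_X) {
  train_X <- as.matrix(train_X)
  mu <- colMeans(train_X)
  sd <- apply(train_X, 2, stats::sd)
  if (any(sd == 0))
    stop(sprintf("zero-sd column(s) reached normalization: %s",
                 paste(which(sd == 0), collapse = ", ")))
  list(mean = mu, sd = sd)
}

#' @rdname zscore_fit
#' @param stats_ statistics from `zscore_fit`.
#' @param X matrix to transform.
#' @export
zscore_apply <- function(stats_, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, stats_$mean), 2, stats_$sd, "/")
}

#' Fit a regression model of one of the four supported families
#'
#' Supported algorithms: `svr_linear` and `svr_rbf` (epsilon-SVR via e1071),
#' `plsr` (partial least squares via mixOmics), `rf` (random forest via
#' randomForest). The surrounding selection / normalisation / cross-validation
#' procedure is the substantive content; the regressor internals are
#' delegated to these established back-ends. Deterministic given `seed`.
#'
#' Default hyperparameters: SVR cost 1, epsilon 0.1; RBF gamma
#' 1 / (d * var(X)); PLSR components min(5, d, n - 1); RF 500 trees.
#'
#' @param X training matrix.
#' @param y training response.
#' @param algorithm one of `"svr_linear"`, `"svr_rbf"`, `"plsr"`, `"rf"`.
#' @param hyper named list of hyperparameter overrides
#'   (`cost`, `epsilon`, `gamma`, `ncomp`, `ntree`).
#' @param seed RNG seed (consumed by the stochastic fitters).
#' @return object of class `pain_regressor` with a [predict][stats::predict]
#'   method.
#' @export
fit_regressor <- function(X, y, algorithm, hyper = list(), seed = 1) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 training rows")
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  set.seed(seed)
  fit <- switch(
    algorithm,
    svr_linear = e1071::svm(
      x = X, y = y, type = "eps-regression", kernel = "linear",
      cost = hyper$cost %||% 1, epsilon = hyper$epsilon %||% 0.1,
      scale = FALSE),
    svr_rbf = {
      v <- stats::var(as.vector(X))
      gamma <- hyper$gamma %||%
        (if (v > 0) 1 / (ncol(X) * v) else 1 / ncol(X))
      e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                 cost = hyper$cost %||% 1, epsilon = hyper$epsilon %||% 0.1,
                 gamma = gamma, scale = FALSE)
    },
    plsr = {
      ncomp <- min(hyper$ncomp %||% 5, ncol(X), nrow(X) - 1)
      mixOmics::pls(X, y, ncomp = ncomp, mode = "regression")
    },
    rf = randomForest::randomForest(x = X, y = y,
                                    ntree = hyper$ntree %||% 500),
    stop(sprintf("unknown algorithm '%s'", algorithm))
  )
  structure(list(algorithm = algorithm, fit = fit,
                 feature_names = colnames(X)),
            class = "pain_regressor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
predict.pain_regressor <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- object$feature_names
  switch(
    object$algorithm,
    svr_linear = ,
    svr_rbf = as.numeric(stats::predict(object$fit, newdata)),
    plsr = {
      p <- stats::predict(object$fit, newdata)$predict
      as.numeric(p[, 1, dim(p)[3]])
    },
    rf = as.numeric(stats::predict(object$fit, newdata))
  )
}

#' Model specification for one feature type
#'
#' @param feature_type one of reho, fa, fc, sc.
#' @param algorithm regression family (see [fit_regressor()]).
#' @param selection_p correlation-selection threshold.
#' @param hyper hyperparameter overrides.
#' @param seed RNG seed.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(feature_type, algorithm = "svr_linear",
                       selection_p = 0.001, hyper = list(), seed = 1) {
  structure(list(feature_types = feature_type, algorithm = algorithm,
                 selection_p = selection_p, hyper = hyper, seed = seed),
            class = "model_spec")
}

#' Leave-one-individual-out prediction for a single feature type
#'
#' For each of the n folds: hold out one subject; run correlation-based
#' feature selection on the remaining n - 1 only; z-score with training
#' statistics; fit the configured regressor; predict the held-out subject.
#' A fold selecting zero features predicts the training mean of y (logged).
#' Selected column indices are recorded per fold.
#'
#' @param table a [feature_table()].
#' @param y numeric vector of true thresholds (J), or a phenotype tibble
#'   with a `threshold_J` column in the table's subject order.
#' @param spec a [model_spec()].
#' @return A `prediction_result`.
#' @export
loocv_predict <- function(table, y, spec) {
  stopifnot(inherits(table, "feature_table"), inherits(spec, "model_spec"))
  if (is.data.frame(y)) y <- y$threshold_J
  X <- table$matrix
  n <- nrow(X)
  if (length(y) != n) stop("y length does not match the number of subjects")
  if (n < 5) stop("leave-one-out prediction needs at least 5 subjects")
  predicted <- numeric(n)
  selected <- vector("list", n)
  n_empty <- 0L
  for (i in seq_len(n)) {
    trX <- X[-i, , drop = FALSE]
    trY <- y[-i]
    sel <- select_features(trX, trY, spec$selection_p, quiet = TRUE)
    selected[[i]] <- sel
    if (!length(sel)) {
      predicted[i] <- mean(trY)
      n_empty <- n_empty + 1L
      next
    }
    zs <- zscore_fit(trX[, sel, drop = FALSE])
    fit <- fit_regressor(zscore_apply(zs, trX[, sel, drop = FALSE]), trY,
                         spec$algorithm, spec$hyper,
                         seed = spec$seed + i)
    predicted[i] <- predict(fit, zscore_apply(zs, X[i, sel, drop = FALSE]))
  }
  if (n_empty > 0)
    message(sprintf("%d fold(s) selected no features; predicted the training mean",
                    n_empty))
  new_prediction_result(predicted, y, table$subject_ids, selected, spec,
                        feature_meta = table$feature_meta)
}

#' Decision-level fusion of prediction results
#'
#' The fused prediction for each subject is the unweighted mean of the
#' constituent models' predictions; feature selection and model fitting of
#' the constituents are untouched. Per-fold selections are kept per
#' constituent feature type.
#'
#' @param results list of `prediction_result`s sharing subjects and true y.
#' @return A fused `prediction_result`.
#' @export
fuse_predictions <- function(results) {
  stopifnot(length(results) >= 1)
  ref <- results[[1]]
  for (r in results[-1]) {
    if (!identical(r$subject_ids, ref$subject_ids) ||
        max(abs(r$true - ref$true)) > 0)
      stop("prediction results to fuse must share subjects and true values")
  }
  pred <- rowMeans(sapply(results, `[[`, "predicted"))
  types <- unlist(lapply(results, function(r) r$model_spec$feature_types))
  per_fold <- lapply(seq_along(ref$true), function(i) {
    sel <- lapply(results, function(r) r$per_fold_selected[[i]])
    names(sel) <- types
    sel
  })
  new_prediction_result(pred, ref$true, ref$subject_ids, per_fold,
                        structure(list(feature_types = types,
                                       algorithm = "fusion_mean",
                                       constituents = lapply(results,
                                                             `[[`, "model_spec")),
                                  class = "model_spec"))
}

#' Default per-type model settings
#'
#' The settings retained for the four single-type models: ReHo and FC use a
#' linear-kernel SVR at selection threshold p < 0.001; FA uses an RBF-kernel
#' SVR at p < 0.01; SC uses an RBF-kernel SVR at p < 0.001.
#'
#' @param seed base RNG seed.
#' @return named list of [model_spec()]s for reho, fc, fa, sc.
#' @export
default_model_specs <- function(seed = 1) {
  list(reho = model_spec("reho", "svr_linear", 0.001, seed = seed + 1L),
       fc = model_spec("fc", "svr_linear", 0.001, seed = seed + 2L),
       fa = model_spec("fa", "svr_rbf", 0.01, seed = seed + 3L),
       sc = model_spec("sc", "svr_rbf", 0.001, seed = seed + 4L))
}

#' Run the nine-model prediction suite
#'
#' Four single-feature-type models (reho, fc, fa, sc) with the default
#' per-type settings, plus five fused models formed only by averaging the
#' single-type predictions: regional (reho + fa), connectivity (fc + sc),
#' fmri (reho + fc), dti (fa + sc), and fused (all four).
#'
#' @param tables named list with feature tables `reho`, `fc`, `fa`, `sc`.
#' @param y true thresholds (vector or phenotype tibble).
#' @param seed base RNG seed.
#' @param specs optional override of [default_model_specs()].
#' @return named list of nine `prediction_result`s.
#' @export
run_model_suite <- function(tables, y, seed = 1, specs = NULL) {
  need <- c("reho", "fc", "fa", "sc")
  missing_t <- setdiff(need, names(tables))
  if (length(missing_t))
    stop(sprintf("missing feature table(s): %s",
                 paste(missing_t, collapse = ", ")))
  if (is.null(specs)) specs <- default_model_specs(seed)
  singles <- lapply(need, function(b) loocv_predict(tables[[b]], y, specs[[b]]))
  names(singles) <- need
  c(singles,
    list(regional = fuse_predictions(singles[c("reho", "fa")]),
         connectivity = fuse_predictions(singles[c("fc", "sc")]),
         fmri = fuse_predictions(singles[c("reho", "fc")]),
         dti = fuse_predictions(singles[c("fa", "sc")]),
         fused = fuse_predictions(singles[need])))
}

#' Model-selection grid for one feature type
#'
#' Screens algorithm x selection-threshold combinations with the same
#' leave-one-out procedure and reports out-of-fold performance for each,
#' replicating the screening that fixed the per-type defaults. Note the
#' caveat: picking the best cell of this grid on the same folds that are
#' later reported is optimistic model selection.
#'
#' @param table a [feature_table()].
#' @param y true thresholds.
#' @param algorithms algorithms to screen.
#' @param thresholds selection p thresholds to screen.
#' @param seed RNG seed.
#' @return tibble with algorithm, selection_p, pcc_r, pcc_p, mae, mae_sd.
#' @export
model_selection_grid <- function(table, y,
                                 algorithms = c("svr_linear", "svr_rbf",
                                                "plsr", "rf"),
                                 thresholds = c(0.05, 0.01, 0.001),
                                 seed = 1) {
  grid <- expand.grid(algorithm = algorithms, selection_p = thresholds,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    sp <- model_spec(table$feature_meta$type[1], grid$algorithm[k],
                     grid$selection_p[k], seed = seed + k)
    res <- loocv_predict(table, y, sp)
    cc <- pcc(res$predicted, res$true)
    m <- mae(res$predicted, res$true)
    tibble::tibble(algorithm = grid$algorithm[k],
                   selection_p = grid$selection_p[k],
                   pcc_r = cc$r, pcc_p = cc$p, mae = m$mean, mae_sd = m$sd)
  })
  do.call(rbind, rows)
}
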