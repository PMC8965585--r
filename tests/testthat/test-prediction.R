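# small planted-signal table for fast checks
tiny_table <- function(n = 60, p = 30, n_planted = 3, noise = 0.3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  s <- rnorm(n)
  X[, seq_len(n_planted)] <- s + matrix(rnorm(n * n_planted, sd = noise),
                                        n, n_planted)
  y <- 2.5 + 0.5 * s + rnorm(n, sd = 0.3)
  list(table = feature_table(X, tibble::tibble(type = "reho",
                                               voxel = seq_len(p))),
       y = y, s = s)
}

test_that("correlation selection keeps signal and drops constants", {
  d <- tiny_table()
  # a column equal to y is always selected
  X <- cbind(d$table$matrix, d$y)
  sel <- select_features(X, d$y, 0.01, quiet = TRUE)
  expect_true(ncol(X) %in% sel)
  # constant columns excluded with a message
  X2 <- cbind(d$table$matrix, 7)
  expect_message(select_features(X2, d$y, 0.01), "constant")
  expect_false(ncol(X2) %in% select_features(X2, d$y, 0.01, quiet = TRUE))
  expect_error(select_features(X, rep(1, nrow(X)), 0.01), "constant")
  # p-values agree with cor.test
  j <- 5
  ct <- cor.test(d$table$matrix[, j], d$y)
  insel_05 <- j %in% select_features(d$table$matrix, d$y, 0.05, quiet = TRUE)
  expect_identical(insel_05, ct$p.value < 0.05)
})

test_that("planted support is recovered at high n", {
  set.seed(10)
  n <- 200; p <- 300
  X <- matrix(rnorm(n * p), n, p)
  sup <- 1:10
  s <- rnorm(n)
  X[, sup] <- s + matrix(rnorm(n * 10, sd = 0.5), n, 10)
  y <- 0.6 * s + rnorm(n, sd = 0.4)
  sel <- select_features(X, y, 0.01, quiet = TRUE)
  expect_gte(length(intersect(sel, sup)) / length(sup), 0.9)
})

test_that("z-scoring uses training statistics only", {
  tr <- matrix(c(0, 2, 0, 2), 2, 2)
  zs <- zscore_fit(tr)
  expect_equal(zscore_apply(zs, matrix(2, 1, 2)),
               matrix(1 / sqrt(2), 1, 2), tolerance = 1e-12)
  set.seed(2)
  M <- matrix(rnorm(100), 20, 5)
  z <- zscore_apply(zscore_fit(M), M)
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-12)
  expect_error(zscore_fit(cbind(1:5, rep(2, 5))), "zero-sd")
})

test_that("the four regressor families honour their contracts", {
  set.seed(3)
  n <- 40
  x <- rnorm(n)
  X <- cbind(x, rnorm(n))
  y <- 1 + 2 * x
  # SVR epsilon-tube: training predictions within epsilon + tolerance
  f <- fit_regressor(X, y, "svr_linear", list(cost = 100, epsilon = 0.01))
  expect_lt(max(abs(predict(f, X) - y)), 0.1)
  # RBF accepts the default gamma and predicts finitely
  f2 <- fit_regressor(X, y, "svr_rbf")
  expect_true(all(is.finite(predict(f2, X))))
  # PLSR with one component on a rank-1 design: near-perfect fit
  t_scores <- rnorm(n)
  Xr1 <- outer(t_scores, c(1, -2, 0.5))
  yr1 <- 3 * t_scores
  f3 <- fit_regressor(Xr1, yr1, "plsr", list(ncomp = 1))
  expect_gt(cor(predict(f3, Xr1), yr1)^2, 0.99)
  # RF is deterministic under the seed
  f4a <- fit_regressor(X, y, "rf", list(ntree = 100), seed = 7)
  f4b <- fit_regressor(X, y, "rf", list(ntree = 100), seed = 7)
  expect_identical(predict(f4a, X), predict(f4b, X))
  expect_error(fit_regressor(X, y, "gbm"), "unknown algorithm")
})

test_that("LOOCV holds one subject out with no label leakage", {
  d <- tiny_table(n = 40, p = 20, seed = 4)
  spec <- model_spec("reho", "svr_linear", 0.05, seed = 1)
  res <- loocv_predict(d$table, d$y, spec)
  expect_identical(length(res$predicted), 40L)
  expect_identical(length(res$per_fold_selected), 40L)
  # leakage contract: perturbing the held-out label changes nothing
  y2 <- d$y
  y2[13] <- y2[13] + 5
  res2 <- loocv_predict(d$table, y2, spec)
  expect_identical(res$predicted[13], res2$predicted[13])
  expect_identical(res$per_fold_selected[[13]], res2$per_fold_selected[[13]])
})

test_that("empty-selection folds fall back to the training mean", {
  set.seed(5)
  X <- matrix(rnorm(20 * 5), 20, 5)
  y <- rnorm(20)
  tab <- feature_table(X, tibble::tibble(type = "fa", voxel = 1:5))
  spec <- model_spec("fa", "svr_rbf", 1e-9, seed = 1)
  expect_message(res <- loocv_predict(tab, y, spec), "training mean")
  expect_equal(res$predicted[1], mean(y[-1]), tolerance = 1e-12)
})

test_that("noise-only tables show no optimistic out-of-fold correlation", {
  # LOOCV with fold-wise selection is pessimistically biased under the null
  # (the training-mean fallback anticorrelates with the held-out label), so
  # the honest-procedure contract is one-sided: no positive bias.
  rs <- sapply(1:25, function(s) {
    set.seed(s)
    X <- matrix(rnorm(100 * 25), 100, 25)
    y <- rnorm(100)
    tab <- feature_table(X, tibble::tibble(type = "fc", roi_a = rep(2, 25),
                                           roi_b = rep(1, 25)))
    res <- suppressMessages(
      loocv_predict(tab, y, model_spec("fc", "svr_linear", 0.05, seed = s)))
    if (sd(res$predicted) == 0) 0 else cor(res$predicted, y)
  })
  expect_lt(mean(rs), 0.1)
})

test_that("fusion is the exact unweighted mean and is idempotent", {
  d <- tiny_table(n = 30, p = 10, seed = 6)
  spec <- model_spec("reho", "svr_linear", 0.05, seed = 1)
  res <- suppressMessages(loocv_predict(d$table, d$y, spec))
  # fusing copies returns the same predictions
  fcopy <- fuse_predictions(list(res, res, res))
  expect_equal(fcopy$predicted, res$predicted, tolerance = 1e-15)
  # hand-built constituents average elementwise
  a <- res; a$predicted <- rep(2, 30)
  b <- res; b$predicted <- rep(4, 30)
  expect_true(all(fuse_predictions(list(a, b))$predicted == 3))
  # mismatched subjects rejected
  c_ <- res; c_$subject_ids <- rev(res$subject_ids)
  expect_error(fuse_predictions(list(res, c_)), "share")
})

test_that("the nine-model suite wires fusions from the four singles", {
  st <- simulate_feature_tables(generator_config(n_subjects = 40,
                                                 n_regional = 40, n_rois = 8,
                                                 n_planted = 4, seed = 7))
  suite <- suppressMessages(run_model_suite(st$tables, st$phenotype, seed = 7))
  expect_setequal(names(suite),
                  c("reho", "fc", "fa", "sc", "regional", "connectivity",
                    "fmri", "dti", "fused"))
  singles <- sapply(suite[c("reho", "fc", "fa", "sc")], `[[`, "predicted")
  expect_equal(suite$fused$predicted, rowMeans(singles), tolerance = 1e-12)
  expect_equal(suite$regional$predicted,
               rowMeans(singles[, c("reho", "fa")]), tolerance = 1e-12)
  expect_equal(suite$connectivity$predicted,
               rowMeans(singles[, c("fc", "sc")]), tolerance = 1e-12)
  expect_equal(suite$fmri$predicted,
               rowMeans(singles[, c("reho", "fc")]), tolerance = 1e-12)
  expect_equal(suite$dti$predicted,
               rowMeans(singles[, c("fa", "sc")]), tolerance = 1e-12)
  expect_error(run_model_suite(st$tables[c("reho", "fc")], st$phenotype),
               "missing feature table")
  # whole-suite reproducibility under the seed
  suite2 <- suppressMessages(run_model_suite(st$tables, st$phenotype, seed = 7))
  expect_identical(suite$fused$predicted, suite2$fused$predicted)
})

test_that("the model-selection grid reports one row per configuration", {
  d <- tiny_table(n = 30, p = 10, seed = 8)
  g <- suppressMessages(
    model_selection_grid(d$table, d$y, algorithms = c("svr_linear", "plsr"),
                         thresholds = c(0.05, 0.01), seed = 1))
  expect_identical(nrow(g), 4L)
  expect_true(all(c("algorithm", "selection_p", "pcc_r", "mae") %in% names(g)))
})
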