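# Performance metrics (PCC, MAE) and the statistical comparisons between
# models: paired t-tests on absolute errors, and the z-test for two
# dependent correlations sharing the true labels.

#' Pearson correlation with two-sided p-value
#'
#' r between predicted and true values; p from
#' t = r sqrt((n - 2) / (1 - r^2)) with n - 2 degrees of freedom.
#'
#' @param pred,true numeric vectors of equal length (n >= 3), non-constant.
#' @return list with `r`, `p`, `n`.
#' @export
pcc <- function(pred, true) {
  if (length(pred) != length(true)) stop("length mismatch")
  n <- length(pred)
  if (n < 3) stop("PCC needs at least 3 pairs")
  if (stats::sd(pred) == 0 || stats::sd(true) == 0)
    stop("PCC is undefined for constant input")
  ct <- stats::cor.test(pred, true)
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Mean absolute error with spread
#'
#' MAE = (1/N) sum |pred_n - true_n|; the spread is the standard deviation
#' of the absolute errors across subjects (sample convention by default,
#' matching "mean +/- std" reporting).
#'
#' @param pred,true numeric vectors of equal length.
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return list with `mean` and `sd`.
#' @export
mae <- function(pred, true, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(pred) != length(true)) stop("length mismatch")
  if (length(pred) < 1) stop("need at least one pair")
  e <- abs(pred - true)
  s <- if (length(e) < 2) 0 else stats::sd(e)
  if (sd_type == "population")
    s <- s * sqrt((length(e) - 1) / length(e))
  list(mean = mean(e), sd = s)
}

#' Paired t-test on absolute errors of two models
#'
#' Tests d_n = |pred_A,n - y_n| - |pred_B,n - y_n| against zero (two-sided).
#' Zero-variance differences are degenerate: p = 1 with a warning (t = 0
#' when all differences are zero, NA otherwise).
#'
#' @param resA,resB `prediction_result`s over the same subjects.
#' @return list with `t` and `p`.
#' @export
paired_t_abs_errors <- function(resA, resB) {
  stopifnot(inherits(resA, "prediction_result"),
            inherits(resB, "prediction_result"))
  if (!identical(resA$subject_ids, resB$subject_ids) ||
      max(abs(resA$true - resB$true)) > 0)
    stop("results must share subjects and true values")
  n <- length(resA$true)
  if (n < 3) stop("paired t-test needs at least 3 subjects")
  d <- abs(resA$predicted - resA$true) - abs(resB$predicted - resB$true)
  if (stats::sd(d) == 0) {
    warning("zero-variance paired differences; p set to 1")
    return(list(t = if (all(d == 0)) 0 else NA_real_, p = 1))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' z-test for two dependent correlations sharing one variable
#'
#' Both models' accuracies r(y, predA) and r(y, predB) are correlations with
#' the same true labels y, so they are not independent and an ordinary
#' t-test does not apply. The implemented statistic is the
#' Meng-Rosenthal-Rubin z for dependent correlations sharing a variable:
#' z = (z_A - z_B) sqrt((n - 3) / (2 (1 - r_AB) h)) with Fisher transforms
#' z_A, z_B of the two accuracy correlations, mean squared correlation
#' rbar2 = (r_Ay^2 + r_By^2) / 2, f = min(1, (1 - r_AB) / (2 (1 - rbar2)))
#' and h = (1 - f rbar2) / (1 - rbar2); two-sided p from the standard
#' normal.
#'
#' @param y true values.
#' @param predA,predB the two models' predictions.
#' @return list with `z`, `p`, `r_ay`, `r_by`, `r_ab`, `n`.
#' @export
compare_dependent_correlations <- function(y, predA, predB) {
  n <- length(y)
  if (length(predA) != n || length(predB) != n) stop("length mismatch")
  if (n < 10) stop("the dependent-correlation test needs at least 10 subjects")
  r_ay <- stats::cor(y, predA)
  r_by <- stats::cor(y, predB)
  r_ab <- stats::cor(predA, predB)
  if (anyNA(c(r_ay, r_by, r_ab)))
    stop("correlations are undefined (constant input)")
  if (r_ab >= 1 - 1e-12 && abs(r_ay - r_by) < 1e-12)
    return(list(z = 0, p = 1, r_ay = r_ay, r_by = r_by, r_ab = r_ab, n = n))
  if (max(abs(c(r_ay, r_by, r_ab))) >= 1 - 1e-12)
    stop("degenerate correlation at +/-1")
  rbar2 <- (r_ay^2 + r_by^2) / 2
  f <- min(1, (1 - r_ab) / (2 * (1 - rbar2)))
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (atanh(r_ay) - atanh(r_by)) * sqrt((n - 3) / (2 * (1 - r_ab) * h))
  list(z = z, p = 2 * stats::pnorm(-abs(z)),
       r_ay = r_ay, r_by = r_by, r_ab = r_ab, n = n)
}

#' Build the evaluation report for a model suite
#'
#' One row per model with MAE (mean +/- sd of absolute errors) and PCC
#' (r with p-value), plus all pairwise comparisons: paired t on absolute
#' errors and the dependent-correlation z-test on the accuracies.
#'
#' Degenerate entries (a constant prediction vector, or an accuracy
#' correlation at +/-1 as happens when every fold of a model falls back to
#' the training mean) are reported as NA rather than aborting the report.
#'
#' @param suite_results named list of `prediction_result`s
#'   (e.g. from [run_model_suite()]).
#' @return object of class `evaluation_report` with tibbles `per_model` and
#'   `pairwise`.
#' @export
build_report <- function(suite_results) {
  stopifnot(length(suite_results) >= 1)
  nm <- names(suite_results)
  per_model <- do.call(rbind, lapply(nm, function(m) {
    r <- suite_results[[m]]
    cc <- tryCatch(pcc(r$predicted, r$true),
                   error = function(e) list(r = NA_real_, p = NA_real_))
    e <- mae(r$predicted, r$true)
    tibble::tibble(model = m, mae = e$mean, mae_sd = e$sd,
                   pcc_r = cc$r, pcc_p = cc$p)
  }))
  pairwise <- NULL
  if (length(nm) >= 2) {
    pairs <- utils::combn(nm, 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- suite_results[[pairs[1, k]]]
      b <- suite_results[[pairs[2, k]]]
      tt <- suppressWarnings(paired_t_abs_errors(a, b))
      zz <- tryCatch(
        compare_dependent_correlations(a$true, a$predicted, b$predicted),
        error = function(e) list(z = NA_real_, p = NA_real_))
      tibble::tibble(model_a = pairs[1, k], model_b = pairs[2, k],
                     mae_t = tt$t, mae_p = tt$p, pcc_z = zz$z, pcc_p = zz$p)
    }))
  } else {
    pairwise <- tibble::tibble(model_a = character(), model_b = character(),
                               mae_t = numeric(), mae_p = numeric(),
                               pcc_z = numeric(), pcc_p = numeric())
  }
  structure(list(per_model = per_model, pairwise = pairwise),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Prediction performance by feature set\n")
  df <- x$per_model
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-12s MAE %.3f +/- %.3f   PCC %.3f (p = %.3g)\n",
                df$model[i], df$mae[i], df$mae_sd[i], df$pcc_r[i], df$pcc_p[i]))
  cat(sprintf("  (%d pairwise comparisons)\n", nrow(x$pairwise)))
  invisible(x)
}
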