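# Validation: regression and classification metrics, LOO cross-validation,
# Y-randomization, DModX applicability domain, prediction-quality categories.

#' Regression validation metrics
#'
#' Computes the standard internal and external QSAR validation statistics:
#' \itemize{
#'   \item R2 = 1 - SS(calc residuals)/SS(train about its mean)
#'   \item Q2_LOO, the same form with leave-one-out predictions
#'   \item MAE_LOO, mean absolute LOO error
#'   \item Q2_F1 = 1 - SS(test residuals)/SS(test about the TRAIN mean)
#'   \item Q2_F2 = 1 - SS(test residuals)/SS(test about the TEST mean)
#'   \item CCC, Lin's concordance correlation coefficient (product form)
#'   \item MAE_test and RMSEp on the test set
#' }
#' Q2_F1 and Q2_F2 coincide exactly when the test mean equals the train mean.
#'
#' @param y_train_obs,y_train_calc observed and calculated (fitted) training
#'   responses.
#' @param y_loo_pred leave-one-out predictions of the training set (optional).
#' @param y_test_obs,y_test_pred observed and predicted test responses
#'   (optional; test metrics are `NA` when absent).
#' @return object of class `metric_report` (a named list).
#' @export
regression_metrics <- function(y_train_obs, y_train_calc, y_loo_pred = NULL,
                               y_test_obs = NULL, y_test_pred = NULL) {
  if (length(y_train_obs) < 3L) stop("need at least 3 training observations")
  if (length(y_train_calc) != length(y_train_obs)) stop("misaligned training vectors")
  sst <- sum((y_train_obs - mean(y_train_obs))^2)
  if (sst == 0) stop("constant training observations; metrics undefined")
  r2 <- 1 - sum((y_train_obs - y_train_calc)^2) / sst
  q2_loo <- mae_loo <- NA_real_
  if (!is.null(y_loo_pred)) {
    q2_loo <- 1 - sum((y_train_obs - y_loo_pred)^2) / sst
    mae_loo <- mean(abs(y_train_obs - y_loo_pred))
  }
  q2_f1 <- q2_f2 <- ccc <- mae_test <- rmsep <- NA_real_
  n_test <- 0L
  if (!is.null(y_test_obs)) {
    if (length(y_test_obs) < 2L) stop("need at least 2 test observations")
    if (length(y_test_pred) != length(y_test_obs)) stop("misaligned test vectors")
    n_test <- length(y_test_obs)
    press <- sum((y_test_obs - y_test_pred)^2)
    den_f2 <- sum((y_test_obs - mean(y_test_obs))^2)
    if (den_f2 == 0) stop("constant test observations; metrics undefined")
    q2_f1 <- 1 - press / sum((y_test_obs - mean(y_train_obs))^2)
    q2_f2 <- 1 - press / den_f2
    mae_test <- mean(abs(y_test_obs - y_test_pred))
    rmsep <- sqrt(press / n_test)
    ccc <- lin_ccc(y_test_obs, y_test_pred)
  }
  structure(list(R2 = r2, Q2_LOO = q2_loo, MAE_LOO = mae_loo,
                 Q2_F1 = q2_f1, Q2_F2 = q2_f2, CCC = ccc,
                 MAE_test = mae_test, RMSEp = rmsep,
                 n_train = length(y_train_obs), n_test = n_test),
            class = "metric_report")
}

# Lin's concordance correlation coefficient, product (covariance) form.
lin_ccc <- function(obs, pred) {
  n <- length(obs)
  mo <- mean(obs); mp <- mean(pred)
  so2 <- sum((obs - mo)^2) / n
  sp2 <- sum((pred - mp)^2) / n
  sop <- sum((obs - mo) * (pred - mp)) / n
  2 * sop / (so2 + sp2 + (mo - mp)^2)
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  v <- unlist(x[c("R2", "Q2_LOO", "MAE_LOO", "Q2_F1", "Q2_F2", "CCC", "MAE_test", "RMSEp")])
  print(round(v, 4))
  cat(sprintf("n_train = %d, n_test = %d\n", x$n_train, x$n_test))
  invisible(x)
}

#' Leave-one-out cross-validated predictions
#'
#' Refits the model without each compound in turn and predicts it. The
#' fitting contract is a function `fit_fn(x, y)` returning an object with a
#' `predict(object, newdata)` method.
#'
#' @param fit_fn model-fitting function.
#' @param x descriptor matrix.
#' @param y response.
#' @return numeric LOO predictions, aligned with rows of `x`.
#' @export
loo_crossval <- function(fit_fn, x, y) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("need n >= 3")
  vapply(seq_len(n), function(i) {
    m <- tryCatch(fit_fn(x[-i, , drop = FALSE], y[-i]),
                  error = function(e) stop("fit failed in fold ", i, ": ",
                                           conditionMessage(e)))
    unname(predict(m, x[i, , drop = FALSE]))[1]
  }, numeric(1))
}

#' Classification metrics from a confusion matrix
#'
#' @param TP,TN,FP,FN confusion-matrix counts.
#' @return list with accuracy, precision, sensitivity, specificity, f1, mcc
#'   and a `degenerate` flag (TRUE when the MCC denominator vanished and MCC
#'   was set to 0).
#' @export
classification_metrics <- function(TP, TN, FP, FN) {
  total <- TP + TN + FP + FN
  if (total <= 0) stop("empty confusion matrix")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  degenerate <- den == 0
  list(accuracy = (TP + TN) / total,
       precision = safe_div(TP, TP + FP),
       sensitivity = safe_div(TP, TP + FN),
       specificity = safe_div(TN, TN + FP),
       f1 = safe_div(2 * TP, 2 * TP + FP + FN),
       mcc = if (degenerate) 0 else (TP * TN - FP * FN) / den,
       degenerate = degenerate)
}

#' Y-randomization (response scrambling) test
#'
#' Permutes the response, refits, and regresses the permuted models' R2 and
#' Q2 against the absolute correlation between permuted and true response
#' (including the unpermuted point at correlation 1). The reported
#' intercepts estimate the fit quality of a model with no real
#' structure-activity relationship; values below 0.3 (R2Y) and 0.05 (Q2Y)
#' indicate the original model is not a chance correlation.
#'
#' @param x descriptor matrix (left untouched).
#' @param y response.
#' @param n_permutations number of scrambles (>= 10, default 100).
#' @param seed RNG seed.
#' @param model `"mlr"` (closed-form LOO) or `"pls"`.
#' @param n_lv latent variables when `model = "pls"`.
#' @return object of class `yrand_result`: per-permutation table, intercepts
#'   `R2Y_int`, `Q2Y_int`, thresholds and pass flags.
#' @export
y_randomization <- function(x, y, n_permutations = 100L, seed = 1L,
                            model = c("mlr", "pls"), n_lv = 2L) {
  model <- match.arg(model)
  if (n_permutations < 10L) stop("n_permutations must be >= 10")
  x <- as.matrix(x)
  if (stats::sd(y) == 0) stop("constant response; metrics undefined")
  set.seed(seed)
  one <- function(y_perm) {
    if (model == "mlr") {
      f <- ols_loo(x, y_perm)
      ss <- sum((y_perm - mean(y_perm))^2)
      c(r2 = f$r2, q2 = f$q2_loo)
    } else {
      m <- fit_pls(x, y_perm, n_lv = n_lv)
      loo <- loo_crossval(function(x2, y2) fit_pls(x2, y2, n_lv = n_lv), x, y_perm)
      ss <- sum((y_perm - mean(y_perm))^2)
      c(r2 = 1 - sum((y_perm - m$fitted)^2) / ss,
        q2 = 1 - sum((y_perm - loo)^2) / ss)
    }
  }
  orig <- one(y)
  tab <- data.frame(correlation = 1, r2 = orig["r2"], q2 = orig["q2"])
  for (p in seq_len(n_permutations)) {
    yp <- sample(y)
    r <- one(yp)
    tab <- rbind(tab, data.frame(correlation = abs(stats::cor(yp, y)),
                                 r2 = r["r2"], q2 = r["q2"]))
  }
  rownames(tab) <- NULL
  r2_int <- unname(stats::coef(stats::lm(r2 ~ correlation, tab))[1])
  q2_int <- unname(stats::coef(stats::lm(q2 ~ correlation, tab))[1])
  structure(list(table = tab, R2Y_int = r2_int, Q2Y_int = q2_int,
                 thresholds = c(R2Y = 0.3, Q2Y = 0.05),
                 pass = r2_int < 0.3 && q2_int < 0.05,
                 n_permutations = n_permutations, seed = seed),
            class = "yrand_result")
}

#' @export
print.yrand_result <- function(x, ...) {
  cat(sprintf("<yrand_result> %d permutations: R2Y intercept %.4f (< 0.3), Q2Y intercept %.4f (< 0.05) -> %s\n",
              x$n_permutations, x$R2Y_int, x$Q2Y_int,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' DModX applicability domain of a PLS model
#'
#' Distance to the model in X: each row's residual SD after the A latent
#' variables, `s_i = sqrt(sum(e_ik^2) / (K - A))`, normalized by the pooled
#' training residual SD `s0`. The mean squared normalized DModX of the
#' training set is ~1 by construction. Rows whose normalized DModX exceeds
#' `sqrt(qf(conf, K - A, (N - A - 1)(K - A)))` lie outside the domain at the
#' given confidence (99% by default).
#'
#' @param model a fitted `pls_model`.
#' @param x descriptor block to assess (original scale).
#' @param is_training TRUE when `x` is the training block (affects only the
#'   small-sample correction applied to training rows in the SIMCA
#'   convention; here the plain ratio is reported for both).
#' @param conf confidence level (default 0.99).
#' @return object of class `ad_report`: data.frame with `dmodx_abs`,
#'   `dmodx_norm`, `outside`; attributes `s0` and `crit`.
#' @export
dmodx <- function(model, x, is_training = FALSE, conf = 0.99) {
  stopifnot(inherits(model, "pls_model"))
  if (model$K - model$A <= 0) stop("no residual degrees of freedom (K = A)")
  x <- as.matrix(x)
  X <- sweep(sweep(x[, names(model$coefficients), drop = FALSE], 2, model$x_mean),
             2, model$x_sd, "/")
  # deflate through the model's weights/loadings
  E <- X
  for (a in seq_len(model$A)) {
    t_ <- drop(E %*% model$weights[, a])
    E <- E - tcrossprod(t_, model$loadings[, a])
  }
  s_i <- sqrt(rowSums(E^2) / (model$K - model$A))
  d <- s_i / model$s0
  df1 <- model$K - model$A
  df2 <- (model$N - model$A - 1) * (model$K - model$A)
  crit <- sqrt(stats::qf(conf, df1, df2))
  out <- data.frame(dmodx_abs = s_i, dmodx_norm = d, outside = d > crit)
  rownames(out) <- rownames(x)
  attr(out, "s0") <- model$s0
  attr(out, "crit") <- crit
  class(out) <- c("ad_report", "data.frame")
  out
}

#' Categorize prediction quality as good / moderate / bad
#'
#' Composite of three reliability rules per query: (a) the query is inside
#' the DModX applicability domain; (b) the mean absolute LOO error of its
#' `n_neighbors` most similar training compounds is below the training-set
#' MAE_LOO; (c) the prediction lies within the training response mean +/- 3
#' SD. All three satisfied -> good; exactly two -> moderate; else bad.
#'
#' @param predictions numeric query predictions.
#' @param inside_ad logical: query inside the applicability domain.
#' @param ra_model a [read_across()] model over the training compounds.
#' @param query_x query descriptor block (original scale) for the
#'   neighbourhood rule.
#' @param train_loo_abs_err absolute LOO errors of the training compounds
#'   (aligned with the `ra_model` sources).
#' @param n_neighbors neighbourhood size (default 10).
#' @return object of class `pq_report`: data.frame with the three rule flags
#'   and `category`.
#' @export
prediction_quality <- function(predictions, inside_ad, ra_model, query_x,
                               train_loo_abs_err, n_neighbors = 10L) {
  stopifnot(inherits(ra_model, "ra_model"))
  zq <- ra_transform(ra_model, query_x)
  train_mae <- mean(train_loo_abs_err)
  mu <- mean(ra_model$y); sd3 <- 3 * stats::sd(ra_model$y)
  err_by_id <- stats::setNames(train_loo_abs_err, rownames(ra_model$z))
  rule_nbr <- vapply(seq_len(nrow(zq)), function(i) {
    d <- sqrt(colSums((t(ra_model$z) - zq[i, ])^2))
    nb <- names(sort(d))[seq_len(min(n_neighbors, length(d)))]
    mean(err_by_id[nb]) < train_mae
  }, logical(1))
  rule_ad <- as.logical(inside_ad)
  rule_range <- predictions >= mu - sd3 & predictions <= mu + sd3
  n_ok <- rule_ad + rule_nbr + rule_range
  category <- ifelse(n_ok == 3L, "good", ifelse(n_ok == 2L, "moderate", "bad"))
  out <- data.frame(inside_ad = rule_ad, good_neighborhood = rule_nbr,
                    in_range = rule_range, category = category)
  rownames(out) <- rownames(zq)
  class(out) <- c("pq_report", "data.frame")
  out
}
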