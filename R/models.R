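# Model fitting: NIPALS PLS (single response), MLR, LDA, bagged trees,
# and the stacking meta-model.

#' Fit a single-response PLS model (NIPALS)
#'
#' NIPALS partial least squares on autoscaled X and centred y. The latent
#' representation is collapsed to regression coefficients on the original
#' scale, and the X-residual statistics after the final component are kept
#' for DModX applicability-domain assessment.
#'
#' @param x descriptor matrix (n x K).
#' @param y numeric response.
#' @param n_lv number of latent variables (>= 1, <= rank of the scaled X).
#' @return object of class `pls_model` with elements `coefficients`
#'   (original-scale, named), `intercept`, `n_lv`, `weights`, `loadings`,
#'   `y_loadings`, `scores`, `x_mean`, `x_sd`, `y_mean`, and the residual
#'   statistics `s0`, `K`, `A`, `N` used by [dmodx()].
#' @examples
#' x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- x[, 1] - 2 * x[, 3] + rnorm(20, sd = 0.1)
#' fit <- fit_pls(x, y, n_lv = 2)
#' coef(fit)
#' @export
fit_pls <- function(x, y, n_lv) {
  x <- as.matrix(x)
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (n_lv < 1L) stop("n_lv must be >= 1")
  n <- nrow(x); K <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(K))
  x_mean <- colMeans(x)
  x_sd <- apply(x, 2, stats::sd)
  if (any(x_sd == 0)) stop("constant column(s): ",
                           paste(colnames(x)[x_sd == 0], collapse = ", "))
  X <- sweep(sweep(x, 2, x_mean), 2, x_sd, "/")
  rk <- qr(X)$rank
  if (n_lv > rk) stop("n_lv = ", n_lv, " exceeds rank(X) = ", rk)
  y_mean <- mean(y)
  u <- y - y_mean
  W <- P <- matrix(0, K, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  E <- X
  f <- u
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(E, f))
    w <- w / sqrt(sum(w^2))
    t_ <- drop(E %*% w)
    p <- drop(crossprod(E, t_)) / sum(t_^2)
    qa <- sum(f * t_) / sum(t_^2)
    E <- E - tcrossprod(t_, p)
    f <- f - qa * t_
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t_; q[a] <- qa
  }
  # collapsed coefficients on the scaled scale: B = W (P'W)^-1 q
  B_scaled <- W %*% solve(crossprod(P, W), q)
  coefficients <- drop(B_scaled) / x_sd
  intercept <- y_mean - sum(coefficients * x_mean)
  names(coefficients) <- colnames(x)
  # pooled X-residual SD after A components (SIMCA convention)
  s0 <- if (n - n_lv - 1 > 0 && K - n_lv > 0)
    sqrt(sum(E^2) / ((n - n_lv - 1) * (K - n_lv))) else NA_real_
  structure(list(coefficients = coefficients, intercept = intercept,
                 n_lv = n_lv, weights = W, loadings = P, y_loadings = q,
                 scores = Tm, x_mean = x_mean, x_sd = x_sd, y_mean = y_mean,
                 fitted = y_mean + drop(Tm %*% q),
                 y = y, s0 = s0, K = K, A = n_lv, N = n),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d descriptors, %d latent variable(s), n = %d\n",
              x$K, x$A, x$N))
  cat("Coefficients (original scale):\n")
  print(round(c(`(Intercept)` = x$intercept, x$coefficients), 5))
  invisible(x)
}

#' @export
coef.pls_model <- function(object, ...) c(`(Intercept)` = object$intercept, object$coefficients)

#' @export
fitted.pls_model <- function(object, ...) object$fitted

#' @export
residuals.pls_model <- function(object, ...) object$y - object$fitted

#' Predict from a PLS (or stacking) model
#'
#' @param object a `pls_model`.
#' @param newdata matrix/data.frame whose columns include the model descriptors.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  miss <- setdiff(names(object$coefficients), colnames(newdata))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  nd <- newdata[, names(object$coefficients), drop = FALSE]
  drop(nd %*% object$coefficients) + object$intercept
}

#' @export
summary.pls_model <- function(object, ...) {
  r2 <- 1 - sum((object$y - object$fitted)^2) / sum((object$y - mean(object$y))^2)
  out <- list(model = object, r2 = r2)
  class(out) <- "summary.pls_model"
  out
}

#' @export
print.summary.pls_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("Training R2: %.4f\n", x$r2))
  invisible(x)
}

#' Fit a multiple linear regression model
#'
#' Thin wrapper around `stats::lm.fit` returning the same interface as the
#' other model objects (named coefficients, intercept, predict method).
#'
#' @param x descriptor matrix.
#' @param y response.
#' @return object of class `mlr_model`.
#' @export
fit_mlr <- function(x, y) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  X1 <- cbind(`(Intercept)` = 1, x)
  fit <- stats::lm.fit(X1, y)
  if (fit$rank < ncol(X1)) stop("rank-deficient design; remove collinear descriptors")
  beta <- fit$coefficients
  structure(list(coefficients = beta[-1], intercept = unname(beta[1]),
                 fitted = drop(X1 %*% beta), y = y, kind = "mlr"),
            class = "mlr_model")
}

#' @export
print.mlr_model <- function(x, ...) {
  cat("<mlr_model>\n")
  print(round(c(`(Intercept)` = x$intercept, x$coefficients), 5))
  invisible(x)
}

#' @export
coef.mlr_model <- function(object, ...) c(`(Intercept)` = object$intercept, object$coefficients)

#' @export
fitted.mlr_model <- function(object, ...) object$fitted

#' @export
residuals.mlr_model <- function(object, ...) object$y - object$fitted

#' @export
predict.mlr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  miss <- setdiff(names(object$coefficients), colnames(newdata))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  nd <- newdata[, names(object$coefficients), drop = FALSE]
  drop(nd %*% object$coefficients) + object$intercept
}

#' Fit a two-class linear discriminant model
#'
#' Fisher discriminant with equal priors (via `MASS::lda`), classification
#' threshold at the midpoint of the projected class means, and Wilk's
#' lambda = within-group SS / total SS of the discriminant scores.
#'
#' @param x descriptor matrix.
#' @param labels two-class factor (second level is the positive class).
#' @return object of class `lda_model` with `coefficients` (discriminant
#'   direction), `threshold`, `wilks_lambda`, `levels`.
#' @export
fit_lda <- function(x, labels) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes required")
  if (any(table(labels) < 2L)) stop("each class needs >= 2 members")
  fit <- tryCatch(MASS::lda(x, grouping = labels, prior = c(0.5, 0.5)),
                  error = function(e)
                    stop("LDA failed (singular within-class covariance? run pretreat()): ",
                         conditionMessage(e)))
  w <- stats::setNames(fit$scaling[, 1], rownames(fit$scaling))
  scores <- drop(x %*% w)
  m <- tapply(scores, labels, mean)
  threshold <- mean(m)
  # orient the direction so the second (positive) level scores higher
  if (m[2] < m[1]) { w <- -w; scores <- -scores; m <- -m; threshold <- -threshold }
  gm <- mean(scores)
  ss_within <- sum(tapply(scores, labels, function(s) sum((s - mean(s))^2)))
  ss_total <- sum((scores - gm)^2)
  structure(list(coefficients = w, threshold = threshold,
                 wilks_lambda = ss_within / ss_total,
                 levels = levels(labels), kind = "lda",
                 scores = scores, labels = labels),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> classes %s | %s; Wilk's lambda %.4f\n",
              x$levels[1], x$levels[2], x$wilks_lambda))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
coef.lda_model <- function(object, ...) object$coefficients

#' Predict classes from an LDA model
#'
#' @param object an `lda_model`.
#' @param newdata descriptor matrix.
#' @param type `"class"` (default) or `"score"` for the raw discriminant value.
#' @param ... unused.
#' @export
predict.lda_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  miss <- setdiff(names(object$coefficients), colnames(newdata))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  s <- drop(newdata[, names(object$coefficients), drop = FALSE] %*% object$coefficients)
  if (type == "score") return(s)
  factor(ifelse(s > object$threshold, object$levels[2], object$levels[1]),
         levels = object$levels)
}

#' Fit a bagged-tree (random-forest) classifier
#'
#' Random-forest ensemble with the conventions of the published setup:
#' bag size 100% of the training set, unlimited tree depth, automatic
#' feature subsampling, 100 trees, fixed seed, and a stratified k-fold
#' cross-validation report (folds reduced with a warning when a class is
#' smaller than the fold count).
#'
#' @param x descriptor matrix.
#' @param labels two-class factor.
#' @param bag_size bootstrap sample size as a percentage of n (default 100).
#' @param n_iterations number of trees (default 100).
#' @param seed RNG seed (default 1).
#' @param cv_folds cross-validation folds (default 10).
#' @return object of class `bagged_trees` with the fitted forest and a
#'   `cv` list (fold assignment, predictions, accuracy).
#' @export
fit_bagged_trees <- function(x, labels, bag_size = 100, n_iterations = 100,
                             seed = 1L, cv_folds = 10L) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two classes required")
  n <- nrow(x)
  min_class <- min(table(labels))
  if (min_class < cv_folds) {
    warning("smallest class (", min_class, ") < cv_folds; reducing folds")
    cv_folds <- max(2L, min_class)
  }
  set.seed(seed)
  forest <- randomForest::randomForest(
    x, labels, ntree = n_iterations,
    sampsize = ceiling(n * bag_size / 100), replace = TRUE)
  # stratified CV
  set.seed(seed)
  fold <- integer(n)
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(cv_folds), length(idx))
  }
  cv_pred <- factor(rep(NA_character_, n), levels = levels(labels))
  for (k in seq_len(cv_folds)) {
    tr <- fold != k
    set.seed(seed + k)
    m <- randomForest::randomForest(x[tr, , drop = FALSE], labels[tr],
                                    ntree = n_iterations,
                                    sampsize = ceiling(sum(tr) * bag_size / 100))
    cv_pred[!tr] <- stats::predict(m, x[!tr, , drop = FALSE])
  }
  structure(list(forest = forest, levels = levels(labels),
                 cv = list(folds = fold, predictions = cv_pred,
                           accuracy = mean(cv_pred == labels))),
            class = "bagged_trees")
}

#' @export
print.bagged_trees <- function(x, ...) {
  cat(sprintf("<bagged_trees> %d trees; CV accuracy %.3f\n",
              x$forest$ntree, x$cv$accuracy))
  invisible(x)
}

#' @export
predict.bagged_trees <- function(object, newdata, ...) {
  stats::predict(object$forest, as.matrix(newdata))
}

#' Fit the stacking meta-model
#'
#' One-latent-variable PLS of the response on the four base-model prediction
#' columns (QSARpred, RASARpred, ARKApred, Hybridpred). Training rows carry
#' the base models' fitted values; test rows carry their predictions.
#'
#' @param inputs data.frame/matrix with exactly the four prediction columns.
#' @param y_train training response.
#' @return a `stack_model` (inherits `pls_model`).
#' @export
stack_models <- function(inputs, y_train) {
  inputs <- as.matrix(inputs)
  if (ncol(inputs) != 4L) stop("expected the four base-model prediction columns")
  if (anyNA(inputs)) stop("prediction columns must be complete")
  sds <- apply(inputs, 2, stats::sd)
  if (any(sds == 0)) stop("constant prediction column(s): ",
                          paste(colnames(inputs)[sds == 0], collapse = ", "))
  fit <- fit_pls(inputs, y_train, n_lv = 1L)
  class(fit) <- c("stack_model", class(fit))
  fit
}
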