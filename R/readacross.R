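# Similarity-based read-across prediction with ED/GK/LK kernels.

#' Read-across hyperparameters
#'
#' @param kernel `"ED"` (inverse-distance similarity 1/(1+d)), `"GK"`
#'   (Gaussian, exp(-d^2 / 2 sigma^2)) or `"LK"` (Laplacian, exp(-d / gamma)).
#' @param sigma Gaussian bandwidth (> 0).
#' @param gamma Laplacian bandwidth (> 0).
#' @param n_close number of close source compounds (>= 2).
#' @return an `ra_hyperparams` object.
#' @export
ra_hyperparams <- function(kernel = c("GK", "LK", "ED"), sigma = 2, gamma = 2, n_close = 10L) {
  kernel <- match.arg(kernel)
  stopifnot(sigma > 0, gamma > 0, n_close >= 2)
  structure(list(kernel = kernel, sigma = sigma, gamma = gamma,
                 n_close = as.integer(n_close)),
            class = "ra_hyperparams")
}

#' @export
print.ra_hyperparams <- function(x, ...) {
  cat(sprintf("<ra_hyperparams> kernel=%s sigma=%g gamma=%g n_close=%d\n",
              x$kernel, x$sigma, x$gamma, x$n_close))
  invisible(x)
}

#' Standardize descriptor blocks with training statistics
#'
#' z = (x - train_mean) / train_sd, using the training block's columnwise
#' statistics for both blocks, so query compounds live on the training scale.
#'
#' @param train_block training descriptor matrix.
#' @param apply_block matrix to transform with the training statistics
#'   (defaults to the training block itself).
#' @return list with `train`, `apply` (z-scored matrices), `mean`, `sd`.
#' @export
standardize_blocks <- function(train_block, apply_block = train_block) {
  train_block <- as.matrix(train_block); apply_block <- as.matrix(apply_block)
  if (!identical(colnames(train_block), colnames(apply_block)))
    stop("blocks must share column names")
  mu <- colMeans(train_block)
  sd <- apply(train_block, 2, stats::sd)
  if (any(sd == 0)) stop("zero training SD in column(s): ",
                         paste(colnames(train_block)[sd == 0], collapse = ", "))
  list(train = sweep(sweep(train_block, 2, mu), 2, sd, "/"),
       apply = sweep(sweep(apply_block, 2, mu), 2, sd, "/"),
       mean = mu, sd = sd)
}

#' Kernel similarity between two standardized vectors
#'
#' With d the Euclidean distance: GK = exp(-d^2/(2 sigma^2)),
#' LK = exp(-d/gamma), ED = 1/(1+d). All lie in (0, 1], equal 1 iff d = 0,
#' and decrease strictly in d.
#'
#' @param z1,z2 numeric vectors of equal length.
#' @param params an [ra_hyperparams()] object.
#' @return similarity in (0, 1].
#' @export
kernel_similarity <- function(z1, z2, params) {
  if (length(z1) != length(z2)) stop("vectors differ in length")
  d <- sqrt(sum((z1 - z2)^2))
  similarity_from_distance(d, params)
}

similarity_from_distance <- function(d, params) {
  switch(params$kernel,
         GK = exp(-d^2 / (2 * params$sigma^2)),
         LK = exp(-d / params$gamma),
         ED = 1 / (1 + d))
}

#' Select the close source compounds for a query
#'
#' Ranks sources by kernel similarity and keeps the top `n_close`;
#' similarity ties break toward the lexicographically lower source id. When
#' the query is itself among the sources (training self-prediction) it must
#' be excluded by the caller via `exclude`.
#'
#' @param query_z standardized query vector.
#' @param source_zs standardized source matrix (rows named by id).
#' @param source_responses numeric responses of the sources.
#' @param source_labels active/inactive labels of the sources (optional;
#'   needed for the class-conditional RASAR columns).
#' @param params an [ra_hyperparams()].
#' @param exclude source ids to leave out (e.g. the query itself).
#' @return object of class `close_source_set`: list with `source_ids`,
#'   `similarities` (sorted descending), `responses`, `labels`.
#' @export
close_sources <- function(query_z, source_zs, source_responses,
                          source_labels = NULL, params, exclude = NULL) {
  source_zs <- as.matrix(source_zs)
  ids <- rownames(source_zs)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(source_zs)))
  keep <- !(ids %in% exclude)
  source_zs <- source_zs[keep, , drop = FALSE]
  source_responses <- source_responses[keep]
  if (!is.null(source_labels)) source_labels <- source_labels[keep]
  ids <- ids[keep]
  d <- sqrt(colSums((t(source_zs) - as.numeric(query_z))^2))
  s <- similarity_from_distance(d, params)
  usable <- s >= 1e-12          # drop numerical dust
  if (sum(usable) < 2L) stop("fewer than 2 usable source compounds")
  ids <- ids[usable]; s <- s[usable]
  source_responses <- source_responses[usable]
  if (!is.null(source_labels)) source_labels <- source_labels[usable]
  ord <- order(-s, ids)
  take <- ord[seq_len(min(params$n_close, length(ord)))]
  structure(list(source_ids = ids[take],
                 similarities = unname(s[take]),
                 responses = unname(source_responses[take]),
                 labels = if (is.null(source_labels)) NULL else unname(source_labels[take])),
            class = "close_source_set")
}

#' Read-across prediction from a close-source set
#'
#' Similarity-weighted mean of the source responses,
#' `sum(s_i * y_i) / sum(s_i)`; with `weighted = FALSE`, the plain mean.
#' The prediction always lies within the range of the source responses.
#'
#' @param css a `close_source_set`.
#' @param weighted use similarity weights (default) or an unweighted mean.
#' @return predicted response.
#' @export
ra_predict <- function(css, weighted = TRUE) {
  stopifnot(inherits(css, "close_source_set"))
  if (weighted) sum(css$similarities * css$responses) / sum(css$similarities)
  else mean(css$responses)
}

#' Fit a read-across predictor
#'
#' Stores the standardized training block, responses and (optionally)
#' activity labels so new compounds can be predicted by similarity-weighted
#' read-across. Not a parametric fit: the "model" is the training set plus
#' the kernel hyperparameters.
#'
#' @param x training descriptor matrix (rows named by id).
#' @param y training responses.
#' @param params an [ra_hyperparams()].
#' @param labels optional active/inactive labels (defaults to thresholding
#'   `y` at its mean, the convention used downstream by the RASAR block).
#' @return object of class `ra_model`.
#' @export
read_across <- function(x, y, params = ra_hyperparams(), labels = NULL) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  std <- standardize_blocks(x)
  if (is.null(labels)) labels <- source_class_labels(y)
  structure(list(z = std$train, mean = std$mean, sd = std$sd,
                 y = y, labels = labels, params = params),
            class = "ra_model")
}

#' @export
print.ra_model <- function(x, ...) {
  cat(sprintf("<ra_model> %d sources, %d descriptors, kernel=%s (n_close=%d)\n",
              nrow(x$z), ncol(x$z), x$params$kernel, x$params$n_close))
  invisible(x)
}

# Standardize new data on the model scale.
ra_transform <- function(object, newdata) {
  newdata <- as.matrix(newdata)
  if (!identical(colnames(newdata), colnames(object$z)))
    stop("newdata columns do not match the model")
  sweep(sweep(newdata, 2, object$mean), 2, object$sd, "/")
}

#' Predict by read-across
#'
#' @param object an `ra_model`.
#' @param newdata descriptor matrix of query compounds (original scale).
#' @param self_exclude exclude a source with the same row id as the query
#'   (leave-self-out, for training-set predictions).
#' @param weighted similarity weighting, see [ra_predict()].
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.ra_model <- function(object, newdata, self_exclude = FALSE, weighted = TRUE, ...) {
  zq <- ra_transform(object, newdata)
  ids <- rownames(zq)
  if (is.null(ids)) ids <- rep(NA_character_, nrow(zq))
  vapply(seq_len(nrow(zq)), function(i) {
    css <- close_sources(zq[i, ], object$z, object$y, object$labels, object$params,
                         exclude = if (self_exclude) ids[i] else NULL)
    ra_predict(css, weighted = weighted)
  }, numeric(1))
}

#' Default read-across hyperparameter grid
#'
#' All three kernels, bandwidths 0.5--3 in steps of 0.5, and 2--10 close
#' sources. The Gaussian setting sigma = 2 with 10 close sources (the
#' published salmon optimum) is a member.
#'
#' @return data.frame with columns kernel, sigma, gamma, n_close.
#' @export
default_ra_grid <- function() {
  bw <- c(0.5, 1, 1.5, 2, 2.5, 3)
  rbind(
    expand.grid(kernel = "GK", sigma = bw, gamma = 1, n_close = 2:10,
                stringsAsFactors = FALSE),
    expand.grid(kernel = "LK", sigma = 1, gamma = bw, n_close = 2:10,
                stringsAsFactors = FALSE),
    expand.grid(kernel = "ED", sigma = 1, gamma = 1, n_close = 2:10,
                stringsAsFactors = FALSE)
  )
}

#' Optimize read-across hyperparameters on a sub-split of the training set
#'
#' The training set is split 75/25 (activity-based) into sub-train and
#' sub-test; every grid point predicts the sub-test from the sub-train and
#' the point with the smallest sub-test RMSE wins (ties: larger Q2_F1, then
#' smaller n_close).
#'
#' @param x training descriptor matrix.
#' @param y training response.
#' @param grid data.frame as from [default_ra_grid()].
#' @param sub_split_seed seed for the sub-division.
#' @param weighted similarity weighting passed through to prediction.
#' @return list with `params` (the winning [ra_hyperparams()]) and `report`
#'   (the grid with rmse and q2_f1 columns).
#' @export
optimize_ra_hyperparams <- function(x, y, grid = default_ra_grid(),
                                    sub_split_seed = 1L, weighted = TRUE) {
  if (nrow(grid) == 0L) stop("empty grid")
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  sp <- split_data(x, y, method = "activity", test_fraction = 0.25, seed = sub_split_seed)
  tr <- rownames(x) %in% sp$train
  if (sum(tr) < 3L || sum(!tr) < 2L) stop("degenerate sub-split")
  y_tr <- y[tr]; y_te <- y[!tr]
  rmse <- q2f1 <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    par <- ra_hyperparams(grid$kernel[g], grid$sigma[g], grid$gamma[g], grid$n_close[g])
    pred <- tryCatch({
      m <- read_across(x[tr, , drop = FALSE], y_tr, par)
      predict(m, x[!tr, , drop = FALSE], weighted = weighted)
    }, error = function(e) rep(NA_real_, sum(!tr)))
    if (anyNA(pred)) { rmse[g] <- Inf; q2f1[g] <- -Inf; next }
    rmse[g] <- sqrt(mean((y_te - pred)^2))
    q2f1[g] <- 1 - sum((y_te - pred)^2) / sum((y_te - mean(y_tr))^2)
  }
  report <- cbind(grid, rmse = rmse, q2_f1 = q2f1)
  ord <- order(rmse, -q2f1, grid$n_close)
  w <- ord[1]
  list(params = ra_hyperparams(grid$kernel[w], grid$sigma[w], grid$gamma[w], grid$n_close[w]),
       report = report)
}
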