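# Descriptor pretreatment, train/test division, and feature selection.

#' Descriptor pretreatment
#'
#' Removes near-constant columns (variance below `variance_threshold`), then
#' walks through inter-correlated pairs (|Pearson r| above `corr_threshold`)
#' dropping, from each offending pair, the member with the larger mean
#' absolute correlation to all remaining columns (ties: the later column).
#'
#' @param x numeric matrix or data.frame (compounds x descriptors).
#' @param variance_threshold variance cut-off, default 1e-4.
#' @param corr_threshold absolute-correlation cut-off, default 0.95.
#' @return list with `x` (reduced matrix) and `log` (data.frame of removed
#'   columns with reasons).
#' @export
pretreat <- function(x, variance_threshold = 1e-4, corr_threshold = 0.95) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  log <- data.frame(column = character(), reason = character(), stringsAsFactors = FALSE)
  v <- apply(x, 2, stats::var)
  const <- v < variance_threshold
  if (any(const)) {
    log <- rbind(log, data.frame(column = colnames(x)[const],
                                 reason = sprintf("variance %.3g < %.3g", v[const], variance_threshold)))
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) == 0L) stop("pretreatment removed all columns")
  repeat {
    if (ncol(x) < 2L) break
    cm <- abs(stats::cor(x))
    diag(cm) <- 0
    mx <- max(cm)
    if (mx <= corr_threshold) break
    idx <- which(cm == mx, arr.ind = TRUE)[1, ]
    # drop the member more correlated on average with everything else
    mean_abs <- colMeans(cm)
    drop_col <- if (mean_abs[idx[1]] >= mean_abs[idx[2]]) idx[1] else idx[2]
    log <- rbind(log, data.frame(
      column = colnames(x)[drop_col],
      reason = sprintf("|r| = %.4f with %s exceeds %.2f", mx,
                       colnames(x)[idx[idx != drop_col][1]], corr_threshold)))
    x <- x[, -drop_col, drop = FALSE]
  }
  if (ncol(x) == 0L) stop("pretreatment removed all columns")
  list(x = x, log = log)
}

#' Divide a dataset into training and test sets
#'
#' Four division schemes:
#' \describe{
#'   \item{activity}{sort by response, send every k-th compound
#'     (k = round(1/test_fraction)) to the test set; the response extremes
#'     are always kept in training.}
#'   \item{kennard_stone}{classical max--min Euclidean algorithm on
#'     standardized descriptors; the selected, most representative
#'     compounds form the training set.}
#'   \item{euclidean}{rank by Euclidean distance to the descriptor
#'     centroid and stride the ranking into the test set.}
#'   \item{kmedoid}{PAM clustering (k = round(1/test_fraction) clusters);
#'     one test compound sampled from each cluster in rotation until the
#'     test size is met.}
#' }
#'
#' @param x descriptor matrix (rows named by compound id).
#' @param response numeric response aligned with rows.
#' @param method one of `"activity"`, `"kennard_stone"`, `"euclidean"`, `"kmedoid"`.
#' @param test_fraction fraction of compounds for the test set, in (0,1).
#' @param seed integer seed (used by the kmedoid sampling).
#' @return object of class `split_dataset`: list with `train`, `test`
#'   (character ids), `method`, `seed`.
#' @export
split_data <- function(x, response, method = c("activity", "kennard_stone", "euclidean", "kmedoid"),
                       test_fraction, seed = 1L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(response) != n) stop("response not aligned with rows")
  if (!(test_fraction > 0 && test_fraction < 1)) stop("test_fraction must be in (0,1)")
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  n_test <- round(n * test_fraction)
  if (n_test < 1L || n_test >= n) stop("test_fraction incompatible with n = ", n)

  test_idx <- switch(method,
    activity = {
      ord <- order(response)
      interior <- ord[-c(1L, length(ord))]          # extremes forced into training
      k <- max(2L, round(1 / test_fraction))
      sel <- interior[seq_along(interior) %% k == (k %/% 2L)]
      if (length(sel) > n_test) sel <- sel[seq_len(n_test)]
      while (length(sel) < n_test) {                 # top up from unselected interior
        pool <- setdiff(interior, sel)
        sel <- c(sel, pool[1])
      }
      sel
    },
    kennard_stone = {
      z <- scale(x)
      z[, attr(z, "scaled:scale") == 0] <- 0
      train_sel <- kennard_stone_select(z, n - n_test)
      setdiff(seq_len(n), train_sel)
    },
    euclidean = {
      z <- scale(x)
      z[, attr(z, "scaled:scale") == 0] <- 0
      d <- sqrt(rowSums(sweep(z, 2, colMeans(z))^2))
      ord <- order(d)
      k <- max(2L, round(1 / test_fraction))
      sel <- ord[seq_along(ord) %% k == (k %/% 2L)]
      if (length(sel) > n_test) sel <- sel[seq_len(n_test)]
      while (length(sel) < n_test) sel <- c(sel, setdiff(ord, sel)[1])
      sel
    },
    kmedoid = {
      set.seed(seed)
      z <- scale(x)
      z[, attr(z, "scaled:scale") == 0] <- 0
      k <- max(2L, min(round(1 / test_fraction), n - 1L))
      cl <- cluster::pam(z, k = k, cluster.only = TRUE)
      sel <- integer(0)
      repeat {
        for (g in seq_len(k)) {
          pool <- setdiff(which(cl == g), sel)
          if (length(pool)) sel <- c(sel, if (length(pool) == 1L) pool else sample(pool, 1L))
          if (length(sel) == n_test) break
        }
        if (length(sel) >= n_test) break
      }
      sel[seq_len(n_test)]
    })

  structure(list(train = ids[setdiff(seq_len(n), test_idx)],
                 test = ids[sort(test_idx)],
                 method = method, seed = as.integer(seed)),
            class = "split_dataset")
}

#' @export
print.split_dataset <- function(x, ...) {
  cat(sprintf("<split_dataset> method=%s: %d train / %d test\n",
              x$method, length(x$train), length(x$test)))
  invisible(x)
}

# Kennard-Stone max-min selection of n_sel representative rows; the first two
# picks are the most mutually distant pair.
kennard_stone_select <- function(z, n_sel) {
  n <- nrow(z)
  d <- as.matrix(stats::dist(z))
  first <- which(d == max(d), arr.ind = TRUE)[1, ]
  sel <- sort(unique(as.integer(first)))[1:2]
  while (length(sel) < n_sel) {
    rest <- setdiff(seq_len(n), sel)
    mind <- apply(d[rest, sel, drop = FALSE], 1, min)
    sel <- c(sel, rest[which.max(mind)])
  }
  sel
}

# Leave-one-out statistics of an OLS fit via the hat matrix (PRESS trick):
# LOO residual e_i/(1-h_ii). Uses a pseudo-inverse so collinear pools
# degrade instead of failing.
ols_loo <- function(X, y) {
  X1 <- cbind(`(Intercept)` = 1, X)
  sv <- svd(X1)
  tol <- max(dim(X1)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  pinv <- sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  beta <- pinv %*% y
  fitted <- drop(X1 %*% beta)
  h <- rowSums((X1 %*% sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)))^2)
  e <- y - fitted
  denom <- pmax(1 - h, 1e-10)
  loo <- y - e / denom
  rank_def <- sum(pos) < ncol(X1)
  ss_tot <- sum((y - mean(y))^2)
  list(beta = drop(beta), fitted = fitted, loo = loo,
       q2_loo = 1 - sum((y - loo)^2) / ss_tot,
       mae_loo = mean(abs(y - loo)),
       r2 = 1 - sum(e^2) / ss_tot,
       rank_deficient = rank_def)
}

#' Exhaustive best-subset selection
#'
#' Fits ordinary least squares for every descriptor combination of the given
#' size and ranks combinations by leave-one-out Q2 (descending; ties broken
#' by LOO mean absolute error ascending). Rank-deficient combinations are
#' fitted through a pseudo-inverse and sink to the bottom of the ranking.
#'
#' @param x training descriptor matrix.
#' @param y training response.
#' @param subset_size combination size.
#' @param criterion ranking criterion (only `"q2_loo"` implemented).
#' @param cap maximum number of combinations to fit (default 200000).
#' @return data.frame of combinations (comma-separated names), `q2_loo`,
#'   `mae_loo`, `r2`, sorted best-first.
#' @export
best_subset_selection <- function(x, y, subset_size, criterion = "q2_loo", cap = 2e5) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (subset_size > p) stop("subset_size exceeds number of columns")
  n_comb <- choose(p, subset_size)
  if (n_comb > cap) stop("combination count ", n_comb, " exceeds cap ", cap,
                         "; use genetic_selection() instead")
  combs <- utils::combn(p, subset_size)
  res <- apply(combs, 2, function(idx) {
    fit <- ols_loo(x[, idx, drop = FALSE], y)
    c(q2 = if (fit$rank_deficient) -Inf else fit$q2_loo,
      mae = fit$mae_loo, r2 = fit$r2)
  })
  out <- data.frame(
    combination = apply(combs, 2, function(idx) paste(colnames(x)[idx], collapse = ",")),
    q2_loo = res["q2", ], mae_loo = res["mae", ], r2 = res["r2", ],
    stringsAsFactors = FALSE)
  out <- out[order(-out$q2_loo, out$mae_loo), ]
  rownames(out) <- NULL
  out
}

#' Genetic-algorithm descriptor selection
#'
#' Fixed-length chromosomes (descriptor index sets) evolved by tournament
#' selection, one-point crossover and per-gene mutation, with single-member
#' elitism so the best fitness never decreases. Regression fitness is
#' leave-one-out Q2 of an OLS fit; classification fitness is the Matthews
#' correlation coefficient of an LDA fit on the selected columns.
#'
#' @param x descriptor matrix.
#' @param y response (numeric) or class labels (factor/character) depending
#'   on `fitness`.
#' @param fitness `"q2_loo"` (regression) or `"mcc"` (classification).
#' @param n_descriptors chromosome length.
#' @param ga_params list overriding defaults `population = 100`,
#'   `generations = 100`, `crossover = 0.8`, `mutation = 0.05`, `elitism = 1`,
#'   `tournament = 2`.
#' @param seed integer seed; results are deterministic given the seed.
#' @return list with `best` (column names), `fitness` (best score) and
#'   `trace` (per-generation best fitness, non-decreasing).
#' @export
genetic_selection <- function(x, y, fitness = c("q2_loo", "mcc"), n_descriptors,
                              ga_params = list(), seed = 1L) {
  fitness <- match.arg(fitness)
  x <- as.matrix(x)
  p <- ncol(x)
  if (n_descriptors > p) stop("n_descriptors exceeds number of columns")
  par <- utils::modifyList(list(population = 100L, generations = 100L, crossover = 0.8,
                                mutation = 0.05, elitism = 1L, tournament = 2L),
                           ga_params)
  set.seed(seed)
  score <- function(idx) {
    if (fitness == "q2_loo") {
      fit <- ols_loo(x[, idx, drop = FALSE], y)
      if (fit$rank_deficient) -Inf else fit$q2_loo
    } else {
      lab <- factor(y)
      m <- tryCatch(fit_lda(x[, idx, drop = FALSE], lab), error = function(e) NULL)
      if (is.null(m)) return(-Inf)
      pred <- predict(m, x[, idx, drop = FALSE])
      cm <- table(factor(pred, levels = levels(lab)), lab)
      classification_metrics(TP = cm[2, 2], TN = cm[1, 1],
                             FP = cm[2, 1], FN = cm[1, 2])$mcc
    }
  }
  repair <- function(ch) {
    ch <- unique(ch)
    while (length(ch) < n_descriptors) ch <- unique(c(ch, sample.int(p, 1L)))
    sort(ch[seq_len(n_descriptors)])
  }
  pop <- replicate(par$population, sort(sample.int(p, n_descriptors)), simplify = FALSE)
  fit <- vapply(pop, score, numeric(1))
  trace <- numeric(0)
  best_idx <- which.max(fit)
  best <- list(ch = pop[[best_idx]], f = fit[best_idx])
  if (par$generations > 0L) {
    for (gen in seq_len(par$generations)) {
      newpop <- list()
      if (par$elitism > 0L) {
        ord <- order(fit, decreasing = TRUE)
        newpop <- pop[ord[seq_len(min(par$elitism, length(pop)))]]
      }
      while (length(newpop) < par$population) {
        pick <- function() {
          cand <- sample.int(length(pop), par$tournament, replace = TRUE)
          pop[[cand[which.max(fit[cand])]]]
        }
        p1 <- pick(); p2 <- pick()
        child <- if (stats::runif(1) < par$crossover && n_descriptors > 1L) {
          cut <- sample.int(n_descriptors - 1L, 1L)
          repair(c(p1[seq_len(cut)], p2[(cut + 1L):n_descriptors]))
        } else p1
        mut <- stats::runif(n_descriptors) < par$mutation
        if (any(mut)) {
          child[mut] <- sample.int(p, sum(mut), replace = TRUE)
          child <- repair(child)
        }
        newpop[[length(newpop) + 1L]] <- child
      }
      pop <- newpop
      fit <- vapply(pop, score, numeric(1))
      gen_best <- which.max(fit)
      if (fit[gen_best] > best$f) best <- list(ch = pop[[gen_best]], f = fit[gen_best])
      trace <- c(trace, best$f)
    }
  }
  list(best = colnames(x)[best$ch], fitness = best$f, trace = trace)
}
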