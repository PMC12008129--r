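# RASAR descriptor block: similarity and error-based measures of the
# close-source neighbourhood of each query compound.

RASAR_NAMES <- c("RA_function", "Avg_Sim", "SD_Similarity", "CV_Sim",
                 "SD_Activity", "CV_Activity", "MaxPos_Sim", "MaxNeg_Sim",
                 "Abs_Diff", "Pos_Avg_Sim", "Neg_Avg_Sim", "sm1", "sm2",
                 "gm", "gm_x_AvgSim", "gm_x_SDSim", "SE_of_sources", "n_pos_frac")

#' Active/inactive labels from a response threshold
#'
#' Labels a compound active iff its response is at or above the threshold
#' (default: the mean training response, the convention used to build the
#' classification endpoint).
#'
#' @param y numeric responses.
#' @param threshold class boundary (default `mean(y)`).
#' @return factor with levels `inactive`, `active`.
#' @export
source_class_labels <- function(y, threshold = mean(y)) {
  if (length(y) == 0L) stop("empty response")
  factor(ifelse(y >= threshold, "active", "inactive"),
         levels = c("inactive", "active"))
}

#' RASAR descriptors of one close-source set
#'
#' Eighteen similarity- and error-based read-across measures of the query's
#' neighbourhood: the weighted read-across prediction (`RA_function`), the
#' similarity mean/SD/CV, the source-response SD/CV and standard error, the
#' class-conditional similarity maxima and means, the Banerjee--Roy
#' coefficients `sm1 = MaxPos_Sim - MaxNeg_Sim` and
#' `sm2 = Pos_Avg_Sim - Neg_Avg_Sim`, the concordance indicator
#' `gm` (1 iff the most similar class is active) with its composites
#' `gm * Avg_Sim` and `gm * SD_Similarity`, and the active fraction.
#' If one class is absent among the close sources its conditional columns
#' are 0 and the row is flagged.
#'
#' @param css a `close_source_set` carrying labels.
#' @return named numeric vector of the 18 descriptors, with attribute
#'   `"missing_class"` TRUE when a class was absent.
#' @export
rasar_descriptors <- function(css) {
  stopifnot(inherits(css, "close_source_set"))
  if (is.null(css$labels)) stop("close-source set carries no class labels")
  s <- css$similarities; y <- css$responses
  act <- css$labels == "active"
  n <- length(s)
  avg_sim <- mean(s)
  sd_sim <- if (n > 1) stats::sd(s) else 0
  sd_act <- if (n > 1) stats::sd(y) else 0
  missing_class <- !any(act) || all(act)
  maxpos <- if (any(act)) max(s[act]) else 0
  maxneg <- if (any(!act)) max(s[!act]) else 0
  posavg <- if (any(act)) mean(s[act]) else 0
  negavg <- if (any(!act)) mean(s[!act]) else 0
  gm <- as.numeric(maxpos > maxneg)
  out <- c(
    RA_function = ra_predict(css),
    Avg_Sim = avg_sim,
    SD_Similarity = sd_sim,
    CV_Sim = sd_sim / avg_sim,
    SD_Activity = sd_act,
    CV_Activity = if (mean(y) != 0) sd_act / mean(y) else 0,
    MaxPos_Sim = maxpos,
    MaxNeg_Sim = maxneg,
    Abs_Diff = abs(maxpos - maxneg),
    Pos_Avg_Sim = posavg,
    Neg_Avg_Sim = negavg,
    sm1 = maxpos - maxneg,
    sm2 = posavg - negavg,
    gm = gm,
    gm_x_AvgSim = gm * avg_sim,
    gm_x_SDSim = gm * sd_sim,
    SE_of_sources = sd_act / sqrt(n),
    n_pos_frac = mean(act)
  )
  attr(out, "missing_class") <- missing_class
  out
}

#' Compute the RASAR block for a query set
#'
#' One row of 18 RASAR descriptors per query compound, from its close-source
#' set in the read-across model. Training compounds (query ids present among
#' the sources) are predicted with themselves excluded.
#'
#' @param model an [read_across()] model fitted on the training set.
#' @param newdata query descriptor matrix on the original scale (rows named
#'   by id); defaults to the model's own training block with self-exclusion.
#' @param self_exclude exclude the query's own row id from the sources.
#' @return data.frame (queries x 18) named per `RASAR_NAMES`, with attribute
#'   `"missing_class"` flagging rows where a class was absent.
#' @export
rasar_block <- function(model, newdata = NULL, self_exclude = is.null(newdata)) {
  stopifnot(inherits(model, "ra_model"))
  force(self_exclude)   # default depends on newdata before it is rebuilt below
  if (is.null(newdata)) {
    newdata <- sweep(sweep(model$z, 2, model$sd, "*"), 2, model$mean, "+")
  }
  zq <- ra_transform(model, newdata)
  ids <- rownames(zq)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(zq)))
  out <- matrix(NA_real_, nrow(zq), length(RASAR_NAMES),
                dimnames = list(ids, RASAR_NAMES))
  flag <- logical(nrow(zq))
  for (i in seq_len(nrow(zq))) {
    css <- close_sources(zq[i, ], model$z, model$y, model$labels, model$params,
                         exclude = if (self_exclude) ids[i] else NULL)
    row <- rasar_descriptors(css)
    out[i, ] <- row
    flag[i] <- attr(row, "missing_class")
  }
  out <- as.data.frame(out)
  attr(out, "missing_class") <- flag
  out
}

#' Fuse QSAR and RASAR descriptor blocks
#'
#' Column-wise concatenation of the structural/physicochemical block and the
#' RASAR block ("data fusion"), by matching row ids.
#'
#' @param qsar_block compounds x descriptors matrix/data.frame.
#' @param rasar_block compounds x RASAR-descriptors block with identical row ids.
#' @return data.frame with all columns of both blocks.
#' @export
fuse <- function(qsar_block, rasar_block) {
  qsar_block <- as.data.frame(qsar_block, check.names = FALSE)
  rasar_block <- as.data.frame(rasar_block, check.names = FALSE)
  if (ncol(rasar_block) == 0L) return(qsar_block)
  if (!identical(rownames(qsar_block), rownames(rasar_block)))
    stop("row ids of the two blocks do not match")
  dup <- intersect(colnames(qsar_block), colnames(rasar_block))
  if (length(dup)) stop("duplicated column name(s): ", paste(dup, collapse = ", "))
  cbind(qsar_block, rasar_block)
}
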