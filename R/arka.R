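# ARKA: arithmetic residuals in K-groups analysis (K = 2), a supervised
# reduction of a z-scored descriptor matrix to two group-averaged scores,
# plus quadrant diagnostics for activity cliffs.

#' Assign descriptors to the two ARKA groups
#'
#' Compounds are classed active/inactive by thresholding the response
#' (default: training mean). A descriptor joins group G1 when its mean
#' z-score over actives exceeds that over inactives (it discriminates
#' toward the active class); otherwise G2 (ties go to G2).
#' Groups and scaling statistics come from the training set only.
#'
#' @param x training descriptor matrix (original scale).
#' @param y training response.
#' @param threshold class boundary on the response (default `mean(y)`).
#' @return object of class `arka_grouping`: list with `group` (named G1/G2
#'   vector), `mean`, `sd` (training scaling), `threshold`.
#' @export
arka_groups <- function(x, y, threshold = mean(y)) {
  x <- as.matrix(x)
  act <- y >= threshold
  if (!any(act) || all(act)) stop("single-class training set; cannot form ARKA groups")
  std <- standardize_blocks(x)
  z <- std$train
  m_act <- colMeans(z[act, , drop = FALSE])
  m_inact <- colMeans(z[!act, , drop = FALSE])
  group <- ifelse(m_act > m_inact, "G1", "G2")
  names(group) <- colnames(x)
  structure(list(group = group, mean = std$mean, sd = std$sd, threshold = threshold),
            class = "arka_grouping")
}

#' @export
print.arka_grouping <- function(x, ...) {
  cat(sprintf("<arka_grouping> %d descriptors: %d in G1, %d in G2 (threshold %.4g)\n",
              length(x$group), sum(x$group == "G1"), sum(x$group == "G2"), x$threshold))
  invisible(x)
}

#' Compute ARKA_1 / ARKA_2 scores
#'
#' ARKA_1 is the mean training-scale z-score over the G1 (active-leaning)
#' descriptors and ARKA_2 the mean over the G2 (inactive-leaning) ones. An
#' empty group yields 0 for its score, with a warning.
#'
#' @param x descriptor matrix on the original scale (columns must match the
#'   grouping).
#' @param grouping an [arka_groups()] object.
#' @return data.frame with columns `ARKA_1`, `ARKA_2`, row names preserved.
#' @export
arka_descriptors <- function(x, grouping) {
  stopifnot(inherits(grouping, "arka_grouping"))
  x <- as.matrix(x)
  if (!identical(colnames(x), names(grouping$group)))
    stop("columns do not match the ARKA grouping")
  z <- sweep(sweep(x, 2, grouping$mean), 2, grouping$sd, "/")
  g1 <- grouping$group == "G1"; g2 <- !g1
  score <- function(sel) {
    if (!any(sel)) { warning("empty ARKA group; score set to 0"); return(rep(0, nrow(z))) }
    rowMeans(z[, sel, drop = FALSE])
  }
  out <- data.frame(ARKA_1 = score(g1), ARKA_2 = score(g2))
  rownames(out) <- rownames(x)
  out
}

#' Activity-cliff and confidence diagnostics on the ARKA plane
#'
#' Quadrants of the (ARKA_1, ARKA_2) plane outside a +/- `buffer` band
#' around each axis: actives are expected in quadrant 4 (ARKA_1 > buffer,
#' ARKA_2 < -buffer) and inactives in quadrant 2. An active in quadrant 2 or
#' an inactive in quadrant 4 is a potential activity cliff; any compound in
#' quadrant 1 or 3 (outside the buffer) is a less-confident data point;
#' points inside the buffer band are unflagged.
#'
#' @param pairs data.frame with `ARKA_1`, `ARKA_2` (from [arka_descriptors()]).
#' @param labels factor/character active/inactive labels.
#' @param buffer half-width of the buffer zone on each axis (default 0.5).
#' @return data.frame with `quadrant` (`1`--`4` or `"buffer"`) and `flag`
#'   (`none`, `potential_cliff`, `less_confident`); attribute `"counts"`
#'   tabulates the flags.
#' @export
cliff_diagnostics <- function(pairs, labels, buffer = 0.5) {
  a1 <- pairs$ARKA_1; a2 <- pairs$ARKA_2
  act <- as.character(labels) == "active"
  quadrant <- rep("buffer", length(a1))
  quadrant[a1 > buffer & a2 > buffer] <- "1"
  quadrant[a1 < -buffer & a2 > buffer] <- "2"
  quadrant[a1 < -buffer & a2 < -buffer] <- "3"
  quadrant[a1 > buffer & a2 < -buffer] <- "4"
  flag <- rep("none", length(a1))
  flag[quadrant %in% c("1", "3")] <- "less_confident"
  flag[quadrant == "2" & act] <- "potential_cliff"
  flag[quadrant == "4" & !act] <- "potential_cliff"
  out <- data.frame(quadrant = quadrant, flag = flag, row.names = rownames(pairs))
  attr(out, "counts") <- table(factor(flag, levels = c("none", "potential_cliff", "less_confident")))
  out
}

#' Fit the two-descriptor ARKA regression model
#'
#' Ordinary least squares of the response on (ARKA_1, ARKA_2). Because both
#' scores are means of training z-scores, they are (near-)centred on the
#' training set and the fitted intercept sits at the training response mean.
#'
#' @param pairs training ARKA scores (data.frame from [arka_descriptors()]).
#' @param y training response.
#' @return an `mlr_model` (see [fit_mlr()]).
#' @export
fit_arka_model <- function(pairs, y) {
  if (nrow(pairs) < 3L) stop("need at least 3 training compounds")
  fit_mlr(as.matrix(pairs[, c("ARKA_1", "ARKA_2")]), y)
}
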