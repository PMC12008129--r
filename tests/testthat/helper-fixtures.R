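# Shared fixtures built in code at test time.

DESC6 <- c("H-053", "NsssCH", "B02[N-N]", "B02[S-S]", "B03[N-O]", "LOGP99")

zero_desc6 <- function() stats::setNames(rep(0, 6), DESC6)

# a small compound CSV on disk; returns the path
write_demo_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

# close-source set constructed directly (bypassing the distance machinery)
make_css <- function(similarities, responses, labels = NULL) {
  structure(list(source_ids = as.character(seq_along(similarities)),
                 similarities = similarities, responses = responses,
                 labels = if (is.null(labels)) NULL else
                   factor(labels, levels = c("inactive", "active"))),
            class = "close_source_set")
}

# brute-force regression metrics with explicit loops (independent oracle)
brute_metrics <- function(tr_obs, tr_calc, loo, te_obs, te_pred) {
  ss <- function(v, m) { s <- 0; for (vi in v) s <- s + (vi - m)^2; s }
  rss <- function(a, b) { s <- 0; for (i in seq_along(a)) s <- s + (a[i] - b[i])^2; s }
  mtr <- sum(tr_obs) / length(tr_obs)
  mte <- sum(te_obs) / length(te_obs)
  mae <- 0; for (i in seq_along(te_obs)) mae <- mae + abs(te_obs[i] - te_pred[i])
  mae <- mae / length(te_obs)
  mo <- mean(te_obs); mp <- mean(te_pred); n <- length(te_obs)
  sxy <- 0; sx2 <- 0; sy2 <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (te_obs[i] - mo) * (te_pred[i] - mp)
    sx2 <- sx2 + (te_obs[i] - mo)^2
    sy2 <- sy2 + (te_pred[i] - mp)^2
  }
  list(R2 = 1 - rss(tr_obs, tr_calc) / ss(tr_obs, mtr),
       Q2_LOO = 1 - rss(tr_obs, loo) / ss(tr_obs, mtr),
       MAE_LOO = mean(abs(tr_obs - loo)),
       Q2_F1 = 1 - rss(te_obs, te_pred) / ss(te_obs, mtr),
       Q2_F2 = 1 - rss(te_obs, te_pred) / ss(te_obs, mte),
       CCC = 2 * sxy / (sx2 + sy2 + n * (mo - mp)^2),
       MAE_test = mae,
       RMSEp = sqrt(rss(te_obs, te_pred) / n))
}
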