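# Synthetic datasets with the statistical structure the modeling framework
# assumes, plus the fixed SMILES fixture set of mechanistically interpreted
# compounds, so every module is testable without external data.

#' Generate a regression dataset (linear response + noise)
#'
#' Descriptors are i.i.d. standard normal (optionally with a given
#' correlation structure); the response is `X beta + N(0, noise_sd)`. The
#' generator parameters are echoed in attributes for recovery tests, and the
#' output is a pure function of the seed.
#'
#' @param n number of compounds (>= 10); default 106, the size of the
#'   curated multispecies salmon dataset this emulates.
#' @param p number of descriptors (default 6, the published model size).
#' @param beta true coefficient vector (recycled/truncated to length `p`);
#'   default alternating +/- 1.
#' @param noise_sd residual SD (default 0.3).
#' @param intercept true intercept (default 5.4, a typical training-mean
#'   pLC50 for this endpoint).
#' @param seed RNG seed.
#' @param sigma optional p x p descriptor covariance matrix.
#' @return list with `x` (matrix, rows `c1..cn`), `y`, `beta`, `intercept`,
#'   `noise_sd`, `seed`.
#' @export
gen_regression_dataset <- function(n = 106L, p = 6L, beta = NULL, noise_sd = 0.3,
                                   intercept = 5.4, seed = 1L, sigma = NULL) {
  if (n < 10L) stop("n must be >= 10")
  if (is.null(beta)) beta <- rep_len(c(1, -1), p)
  beta <- rep_len(beta, p)
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p)
  if (!is.null(sigma)) {
    ch <- chol(sigma)
    x <- x %*% ch
  }
  colnames(x) <- paste0("x", seq_len(p))
  rownames(x) <- paste0("c", seq_len(n))
  y <- intercept + drop(x %*% beta) + stats::rnorm(n, sd = noise_sd)
  list(x = x, y = y, beta = stats::setNames(beta, colnames(x)),
       intercept = intercept, noise_sd = noise_sd, seed = seed)
}

#' Generate a two-class dataset for ARKA/LDA exercises
#'
#' Half the compounds are "active": shifted `+offset` on the first
#' `p %/% 2` descriptors (the G1 set) and `-offset` on the rest (G2),
#' relative to the inactives which are shifted the opposite way by the same
#' amount (symmetric class separation `offset` per descriptor). The
#' response is class-correlated: `base + offset_y` for actives plus noise.
#' Optionally injects deliberate activity cliffs: active compounds placed
#' at the empirical inactive centroid.
#'
#' @param n total compounds (split evenly; both classes >= 5).
#' @param p number of descriptors (default 20, a realistically sized
#'   reduced descriptor pool).
#' @param offset class separation per descriptor (default 1.5).
#' @param noise_sd response noise SD (default 0.3).
#' @param seed RNG seed.
#' @param inject_cliffs number of active compounds to relocate to the
#'   inactive centroid (default 0).
#' @return list with `x`, `labels` (factor inactive/active), `y`,
#'   `g1`, `g2` (true descriptor group names), `cliff_ids`, `seed`.
#' @export
gen_two_class_dataset <- function(n = 106L, p = 20L, offset = 1.5, noise_sd = 0.3,
                                  seed = 1L, inject_cliffs = 0L) {
  n_act <- n %/% 2L
  n_inact <- n - n_act
  if (min(n_act, n_inact) < 5L) stop("both classes need >= 5 members")
  set.seed(seed)
  p1 <- p %/% 2L
  shift <- c(rep(offset / 2, p1), rep(-offset / 2, p - p1))
  x <- matrix(stats::rnorm(n * p), n, p)
  act <- c(rep(TRUE, n_act), rep(FALSE, n_inact))
  x[act, ] <- sweep(x[act, , drop = FALSE], 2, shift, "+")
  x[!act, ] <- sweep(x[!act, , drop = FALSE], 2, shift, "-")
  colnames(x) <- paste0("x", seq_len(p))
  rownames(x) <- paste0("c", seq_len(n))
  y <- 5.4 + ifelse(act, 1, -1) + stats::rnorm(n, sd = noise_sd)
  cliff_ids <- character(0)
  if (inject_cliffs > 0L) {
    centroid <- colMeans(x[!act, , drop = FALSE])
    victims <- which(act)[seq_len(min(inject_cliffs, n_act))]
    for (v in victims) x[v, ] <- centroid
    cliff_ids <- rownames(x)[victims]
  }
  list(x = x,
       labels = factor(ifelse(act, "active", "inactive"), levels = c("inactive", "active")),
       y = y,
       g1 = colnames(x)[seq_len(p1)], g2 = colnames(x)[(p1 + 1):p],
       cliff_ids = cliff_ids, seed = seed)
}

#' Fixture compounds with mechanistically interpreted descriptors
#'
#' A fixed set of named pesticide/industrial compounds whose descriptor
#' presence/absence patterns carry the mechanistic interpretation of the
#' salmon QSAR model (H-053 in 2,2-dichloropropanoic acid but not lindane;
#' B02[N-N] in chlordimeform but not iodopropynyl butylcarbamate; B02[S-S]
#' in dimethoate but not diflubenzuron; B03[N-O] in
#' 2-(digeranylamino)ethanol but not benzocaine; LOGP99 higher in allethrin
#' than hexazinone; NsssCH high in aldrin). SMILES were curated once from
#' public structure registries and shipped as a plain-text table.
#'
#' @return named character vector of SMILES.
#' @export
fixture_compounds <- function() {
  path <- system.file("extdata", "fixture_compounds.csv", package = "rasarstack")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "fixture_compounds.csv")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(tab$smiles, tab$name)
}
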