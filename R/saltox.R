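# Frozen predictor: the published salmon pLC50 model equations, so untested
# compounds can be scored from SMILES alone.

PUBLISHED_MODELS <- list(
  qsar = list(
    intercept = 3.51406,
    coefficients = c(`H-053` = -0.4447, NsssCH = 0.35901, `B02[N-N]` = -1.10792,
                     `B02[S-S]` = 2.13211, `B03[N-O]` = 0.57091, LOGP99 = 0.46142)),
  rasar = list(
    intercept = 3.77066,
    coefficients = c(NsssCH = 0.37126, `B02[S-S]` = 0.66907, `B03[N-O]` = 0.89969,
                     LOGP99 = 0.41638, SD_Similarity = -2.5941, sm2 = 1.10873)),
  arka = list(
    intercept = 5.42393,
    coefficients = c(ARKA_1 = 1.88803, ARKA_2 = -0.46825)),
  hybrid = list(
    intercept = 4.41194,
    coefficients = c(`B03[N-O]` = 1.03204, gm_x_AvgSim = -0.10725,
                     Pos_Avg_Sim = 1.15027, sm2 = 0.42649, ARKA_1 = 1.86677)),
  stack = list(
    intercept = -0.11205,
    coefficients = c(QSARpred = 0.25516, RASARpred = 0.25517,
                     ARKApred = 0.25516, Hybridpred = 0.25516)),
  lda = list(
    intercept = -2.101,
    coefficients = c(`B02[S-S]` = 2.728, NsssCH = 0.337, `H-053` = -0.586,
                     `B02[N-N]` = -1.050, `B03[N-O]` = 0.001, LOGP99 = 0.568))
)

# pLC50 class boundary of the published classification endpoint
# (training-set mean pLC50).
SALMON_TOXIC_THRESHOLD <- 5.424

#' A published salmon pLC50 model
#'
#' Returns the frozen coefficients of one of the six published equations:
#' the global QSAR model, the q-RASAR model, the ARKA model, the hybrid
#' model, the stacking meta-model, or the LDA classification model.
#'
#' @param name one of `"qsar"`, `"rasar"`, `"arka"`, `"hybrid"`, `"stack"`, `"lda"`.
#' @return object of class `published_model` with `name`, `intercept`,
#'   `coefficients` (named, in equation order) and `inputs`.
#' @export
published_model <- function(name = c("qsar", "rasar", "arka", "hybrid", "stack", "lda")) {
  name <- match.arg(name)
  m <- PUBLISHED_MODELS[[name]]
  structure(list(name = name, intercept = m$intercept,
                 coefficients = m$coefficients,
                 inputs = names(m$coefficients)),
            class = "published_model")
}

#' @export
print.published_model <- function(x, ...) {
  cat(sprintf("<published_model> %s\n", x$name))
  print(c(`(Intercept)` = x$intercept, x$coefficients))
  invisible(x)
}

#' @export
coef.published_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' Evaluate a published equation
#'
#' Exact linear evaluation of the printed coefficients on named inputs. For
#' the LDA model the discriminant score is also dichotomized at 0 into
#' toxic/non-toxic.
#'
#' @param model_name which published equation (see [published_model()]).
#' @param inputs named numeric vector/list supplying every required input.
#' @return for regression equations, the predicted pLC50; for `"lda"`, a
#'   list with `score` and `class`.
#' @examples
#' predict_published("qsar", c(`H-053` = 0, NsssCH = 0, `B02[N-N]` = 0,
#'                             `B02[S-S]` = 0, `B03[N-O]` = 0, LOGP99 = 0))
#' @export
predict_published <- function(model_name, inputs) {
  m <- published_model(model_name)
  inputs <- unlist(inputs)
  missing <- setdiff(m$inputs, names(inputs))
  if (length(missing)) stop("missing input(s): ", paste(missing, collapse = ", "))
  val <- m$intercept + sum(m$coefficients * inputs[m$inputs])
  if (model_name == "lda") {
    list(score = val, class = if (val > 0) "toxic" else "non-toxic")
  } else val
}

#' Score a compound from SMILES with the published models
#'
#' Computes the six structural descriptors and evaluates the published QSAR
#' equation (pLC50) and the published LDA equation (toxic/non-toxic). The
#' similarity-dependent routes (q-RASAR, hybrid, stacking) need a source
#' training set and are available through [predict_published()] with
#' user-supplied inputs.
#'
#' @param smiles a single SMILES string.
#' @return list with `descriptors` (named, 6), `plc50_qsar`,
#'   `class_lda`, `lda_score`, and `toxic_threshold` (the pLC50 class
#'   boundary used by the regression route).
#' @export
predict_from_smiles <- function(smiles) {
  g <- parse_smiles(smiles)[[1]]
  if (is.null(g)) stop("unparseable SMILES: ", smiles)
  desc <- c(
    `H-053` = count_H053(g),
    NsssCH = count_NsssCH(g),
    `B02[N-N]` = atom_pair_presence(g, "N", "N", 2),
    `B02[S-S]` = atom_pair_presence(g, "S", "S", 2),
    `B03[N-O]` = atom_pair_presence(g, "N", "O", 3),
    LOGP99 = logp99(g)
  )
  lda <- predict_published("lda", desc)
  list(descriptors = desc,
       plc50_qsar = predict_published("qsar", desc),
       class_lda = lda$class,
       lda_score = lda$score,
       toxic_threshold = SALMON_TOXIC_THRESHOLD)
}
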