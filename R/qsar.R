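# Activity-probability (QSAR) reward: 2048-bit ECFP6 features into a random
# forest classifier; the predicted active-class probability, in [0, 1], is
# the reward the tree search maximizes.

#' Random-forest hyperparameter presets
#'
#' `"toy"` is a small forest for the bundled grammar. The protein presets
#' carry the full-scale selected values (bootstrap off, per-target max
#' depth, max-features fraction, minimum split/leaf sizes and tree counts)
#' for users bringing real activity data.
#'
#' @param preset One of `"toy"`, `"drd2"`, `"akt1"`, `"cxcr4"`.
#' @return List of class `rf_hyperparams`.
#' @export
qsar_hyperparams <- function(preset = c("toy", "drd2", "akt1", "cxcr4")) {
  preset <- match.arg(preset)
  hp <- switch(preset,
    toy = list(bootstrap = TRUE, max_depth = NULL, max_features = 0.1,
               min_split = 2, min_leaf = 1, n_estimators = 100),
    drd2 = list(bootstrap = FALSE, max_depth = 429, max_features = 0.0749,
                min_split = 2, min_leaf = 2, n_estimators = 151),
    akt1 = list(bootstrap = FALSE, max_depth = 410, max_features = 0.0690,
                min_split = 2, min_leaf = 5, n_estimators = 158),
    cxcr4 = list(bootstrap = FALSE, max_depth = 498, max_features = 0.225,
                 min_split = 5, min_leaf = 1, n_estimators = 223))
  structure(c(hp, list(preset = preset)), class = "rf_hyperparams")
}

#' Train the activity-probability model
#'
#' Features are 2048-bit ECFP6 fingerprints; training molecules are
#' deduplicated by canonical SMILES before the stratified 90/10 split so no
#' molecule can sit on both sides. The report carries held-out accuracy and
#' AUC (trapezoidal ROC).
#'
#' @param data Tibble with columns `smiles` and `label` (0/1).
#' @param hp A [qsar_hyperparams()] preset.
#' @param seed Integer seed.
#' @return Object of class `qsar_model` with `forest`, `report`, `hp`.
#' @export
train_qsar <- function(data, hp = qsar_hyperparams("toy"), seed = 1L) {
  stopifnot(all(c("smiles", "label") %in% names(data)))
  data$smiles <- canonical_smiles(data$smiles)
  if (anyNA(data$smiles)) stop("invalid SMILES in activity data")
  dup <- duplicated(data$smiles)
  data <- data[!dup, , drop = FALSE]
  if (length(unique(data$label)) < 2) stop("need both activity classes")
  idx <- withr::with_seed(seed, {
    test <- unlist(lapply(split(seq_len(nrow(data)), data$label),
                          function(ix) {
                            sample(ix, max(1, round(0.1 * length(ix))))
                          }))
    test
  })
  train <- data[-idx, , drop = FALSE]
  test <- data[idx, , drop = FALSE]
  if (length(intersect(train$smiles, test$smiles)) > 0) {
    stop("train/test overlap by canonical SMILES")  # unreachable post-dedup
  }
  X <- fp_matrix(train$smiles, diameter = 6)
  Xt <- fp_matrix(test$smiles, diameter = 6)
  y <- factor(train$label, levels = c(0, 1))
  mtry <- max(1L, floor(hp$max_features * ncol(X)))
  forest <- withr::with_seed(seed, randomForest::randomForest(
    x = X, y = y, ntree = hp$n_estimators, mtry = mtry,
    replace = hp$bootstrap, nodesize = hp$min_leaf,
    maxnodes = hp$max_depth))
  prob <- stats::predict(forest, Xt, type = "prob")[, "1"]
  auc <- as.numeric(pROC::auc(pROC::roc(test$label, prob, quiet = TRUE,
                                        direction = "<")))
  acc <- mean((prob > 0.5) == (test$label == 1))
  structure(
    list(forest = forest, hp = hp, seed = seed,
         report = tibble::tibble(accuracy = acc, auc = auc,
                                 n_train = nrow(train), n_test = nrow(test)),
         cache = new.env(parent = emptyenv())),
    class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf(
    "<qsar_model> %s forest, %d trees; held-out accuracy %.3f, AUC %.3f\n",
    x$hp$preset, x$hp$n_estimators, x$report$accuracy, x$report$auc))
  invisible(x)
}

#' Predict the activity probability of a molecule
#'
#' Pure by construction: results are cached by canonical SMILES, so repeated
#' calls always return the same probability.
#'
#' @param model A `qsar_model`.
#' @param smiles A single SMILES string.
#' @return Probability of the active class, in `[0, 1]`.
#' @export
predict_activity <- function(model, smiles) {
  can <- canonical_smiles(smiles)
  if (is.na(can)) stop("invalid SMILES: ", smiles)
  hit <- model$cache[[can]]
  if (!is.null(hit)) return(hit)
  fp <- matrix(morgan_fp(can, diameter = 6), nrow = 1)
  p <- as.numeric(stats::predict(model$forest, fp, type = "prob")[, "1"])
  model$cache[[can]] <- p
  p
}

#' Wrap a model or function as a search reward
#'
#' The reward contract: canonical SMILES in, real number in `[0, 1]` out,
#' pure (cached by canonical SMILES), invalid SMILES rejected. Every reward
#' used by the tree search goes through this wrapper, which also counts
#' evaluations (`attr(reward, "counter")`).
#'
#' @param x A `qsar_model`, or any `function(smiles) -> [0, 1]`.
#' @return A function of class `reward_function`.
#' @export
as_reward <- function(x) {
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  cache <- new.env(parent = emptyenv())
  base_fn <- if (inherits(x, "qsar_model")) {
    function(s) predict_activity(x, s)
  } else if (is.function(x)) {
    x
  } else {
    stop("reward must be a qsar_model or a function")
  }
  f <- function(smiles) {
    can <- canonical_smiles(smiles)
    if (is.na(can)) stop("invalid SMILES: ", smiles)
    hit <- cache[[can]]
    if (!is.null(hit)) return(hit)
    counter$n <- counter$n + 1L
    v <- as.numeric(base_fn(can))
    if (is.na(v) || v < -1e-9 || v > 1 + 1e-9) {
      stop("reward outside [0, 1]: ", v)
    }
    v <- min(max(v, 0), 1)
    cache[[can]] <- v
    v
  }
  attr(f, "counter") <- counter
  class(f) <- c("reward_function", "function")
  f
}

#' Number of distinct reward evaluations performed so far
#'
#' @param reward A `reward_function`.
#' @return Integer count of cache-miss evaluations.
#' @export
reward_calls <- function(reward) {
  attr(reward, "counter")$n
}
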