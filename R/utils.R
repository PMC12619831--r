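#' Derive a reproducible stage seed from a master seed
#'
#' Every stochastic stage in the pipeline draws its RNG state from the single
#' user-supplied seed, salted with the stage name, so that reruns with the
#' same configuration are bit-identical while stages remain decoupled.
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  salt <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + salt * 16807) %% (2^31 - 1))
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds such that class proportions are
#' preserved as closely as possible. Deterministic given the seed.
#'
#' @param labels factor or vector of class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (k < 2L || k > n) stop("'k' must be between 2 and the number of samples")
  fold <- integer(n)
  set.seed(seed)
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  tab <- table(factor(fold, levels = seq_len(k)), labels)
  if (any(colSums(tab > 0) == 0)) stop("stratification failed: empty class")
  fold
}

# Internal: area under the ROC curve from scores and 0/1 labels via pROC,
# with fixed direction so that higher scores mean the positive class.
.auc <- function(labels, scores) {
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

# Internal: ROC curve points (FPR, TPR) sorted from (0,0) to (1,1).
.roc_points <- function(labels, scores) {
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  data.frame(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
}

# Internal: coerce x to a plain numeric samples x features matrix.
.as_matrix <- function(x) {
  if (inherits(x, "processed_matrix") || inherits(x, "metabolite_table")) {
    return(x$values)
  }
  if (is.data.frame(x)) return(as.matrix(x))
  if (is.matrix(x)) return(x)
  stop("cannot interpret 'x' as a samples x features matrix")
}

# Internal: binary 0/1 vector from labels with the second factor level (or the
# level named by `positive`) as the positive class.
.binary_labels <- function(labels, positive = NULL) {
  f <- as.factor(labels)
  if (nlevels(f) != 2L) stop("binary labels required, got ", nlevels(f), " levels")
  if (is.null(positive)) positive <- levels(f)[2L]
  as.integer(f == positive)
}
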