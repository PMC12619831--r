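#' LASSO-penalized logistic feature selection
#'
#' Fits an L1-penalized logistic regression path (coordinate descent via
#' glmnet), chooses the penalty by stratified k-fold cross-validated deviance
#' (`lambda.min` by default, `lambda.1se` optionally), and returns the
#' features with nonzero coefficients at the chosen penalty, ranked by
#' absolute coefficient.
#'
#' @param x a `processed_matrix` or numeric matrix (samples x features).
#' @param labels binary class labels; the second factor level is the
#'   positive class.
#' @param lambda_grid optional penalty grid; glmnet's default path otherwise.
#' @param folds number of CV folds (default 10).
#' @param seed fold-assignment seed.
#' @param lambda_choice `"min"` (deviance-minimizing) or `"1se"`.
#' @return data.frame of selected features with their penalized coefficients,
#'   ordered by decreasing `abs(coefficient)`; the chosen lambda is attached
#'   as attribute `lambda`.
#' @export
lasso_select <- function(x, labels, lambda_grid = NULL, folds = 10L,
                         seed = 1L, lambda_choice = c("min", "1se")) {
  lambda_choice <- match.arg(lambda_choice)
  X <- .as_matrix(x)
  y <- .binary_labels(labels)
  fold_id <- stratified_folds(y, folds, derive_seed(seed, "lasso_folds"))
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                          lambda = lambda_grid, foldid = fold_id,
                          type.measure = "deviance", standardize = FALSE)
  lam <- if (lambda_choice == "min") cv$lambda.min else cv$lambda.1se
  beta <- as.numeric(stats::coef(cv, s = lam))[-1]
  sel <- which(beta != 0)
  out <- data.frame(feature_id = colnames(X)[sel],
                    coefficient = beta[sel], row.names = NULL)
  out <- out[order(-abs(out$coefficient)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "lambda") <- lam
  out
}

#' Refit a candidate panel by stepwise unpenalized logistic regression
#'
#' Bidirectional stepwise selection minimizing AIC on a standard (maximum
#' likelihood) logistic regression over the candidate features. If the data
#' are perfectly separated (unbounded ML coefficients), the model is refit
#' with a vanishing ridge penalty for numerical stability, with a warning.
#'
#' @inheritParams lasso_select
#' @param candidates character vector of candidate feature ids (columns of
#'   `x`), e.g. from [lasso_select()].
#' @return a `panel_model`: ordered feature ids, intercept, coefficients,
#'   and the model AIC.
#' @export
stepwise_refit <- function(x, labels, candidates) {
  X <- .as_matrix(x)
  if (length(candidates) < 1L) stop("at least one candidate feature required")
  if (!all(candidates %in% colnames(X))) {
    stop("unknown candidate feature(s): ",
         paste(setdiff(candidates, colnames(X)), collapse = ", "))
  }
  candidates <- sort(candidates)  # deterministic scope order
  y <- .binary_labels(labels)
  df <- data.frame(.y = y, X[, candidates, drop = FALSE], check.names = FALSE)
  upper <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", candidates),
                                                 collapse = " + ")))
  sep_warn <- FALSE
  fit0 <- stats::glm(.y ~ 1, family = stats::binomial(), data = df)
  fit <- withCallingHandlers(
    stats::step(fit0, scope = list(lower = ~1, upper = upper),
                direction = "both", trace = 0),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  # guard the selection objective: never return a model worse than the full
  # candidate fit (greedy search from the null model cannot guarantee this)
  full <- suppressWarnings(stats::glm(upper, family = stats::binomial(),
                                      data = df))
  if (stats::AIC(fit) > stats::AIC(full)) fit <- full
  feats <- setdiff(names(stats::coef(fit)), "(Intercept)")
  feats <- gsub("^`|`$", "", feats)
  cf <- stats::coef(fit)
  aic <- stats::AIC(fit)
  if (sep_warn || any(!is.finite(cf)) || any(abs(cf) > 20)) {
    warning("perfect separation detected; refitting with ridge penalty 1e-6")
    if (length(feats)) {
      xr <- X[, feats, drop = FALSE]
      if (ncol(xr) == 1L) xr <- cbind(xr, 0)
      rf <- glmnet::glmnet(xr, y, family = "binomial", alpha = 0,
                           lambda = 1e-6, standardize = FALSE)
      cf <- c(as.numeric(rf$a0), as.numeric(rf$beta)[seq_along(feats)])
      names(cf) <- c("(Intercept)", feats)
    }
  }
  panel_model(feature_ids = feats,
              intercept = unname(cf["(Intercept)"]),
              coefficients = if (length(feats)) unname(cf[-1]) else numeric(0),
              aic = aic)
}

#' Construct a fixed-coefficient logistic panel model
#'
#' A frozen logistic biomarker panel: an ordered feature list, an intercept
#' and one coefficient per feature, operating on inputs already in the
#' scaled space the model was fitted in (creatinine-normalized,
#' log-transformed, Pareto-scaled metabolites; z-scored covariates).
#'
#' @param feature_ids character vector of predictor names.
#' @param intercept,coefficients intercept and per-feature coefficients.
#' @param aic optional AIC recorded at fit time.
#' @param preprocessing_params optional frozen preprocessing record.
#' @return an object of class `panel_model`.
#' @export
panel_model <- function(feature_ids, intercept, coefficients, aic = NA_real_,
                        preprocessing_params = NULL) {
  if (length(coefficients) != length(feature_ids)) {
    stop("one coefficient per feature required")
  }
  structure(list(feature_ids = as.character(feature_ids),
                 intercept = as.numeric(intercept),
                 coefficients = as.numeric(coefficients),
                 aic = aic,
                 preprocessing_params = preprocessing_params),
            class = "panel_model")
}

#' @export
print.panel_model <- function(x, ...) {
  cat("<panel_model> logit(P) =", format(x$intercept, digits = 4))
  if (length(x$feature_ids)) {
    terms <- sprintf("%s %s*%s",
                     ifelse(x$coefficients >= 0, "+", "-"),
                     format(abs(x$coefficients), digits = 4), x$feature_ids)
    cat("", paste(terms, collapse = " "))
  }
  cat("\n")
  invisible(x)
}

#' Predict panel-model probabilities
#'
#' @param object a `panel_model`.
#' @param newdata matrix or data.frame containing the model's feature
#'   columns, already in the model's scaled space.
#' @param ... unused.
#' @return numeric vector of class probabilities in `(0, 1)`.
#' @export
predict.panel_model <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) as.matrix(newdata) else .as_matrix(newdata)
  miss <- setdiff(object$feature_ids, colnames(X))
  if (length(miss)) stop("newdata lacks feature(s): ", paste(miss, collapse = ", "))
  lin <- object$intercept +
    as.numeric(X[, object$feature_ids, drop = FALSE] %*% object$coefficients)
  stats::plogis(lin)
}

#' Evaluate a fixed published-style panel model on processed inputs
#'
#' Applies a frozen logistic equation (such as the printed diagnostic
#' models) to inputs already in the frozen scaled space and returns
#' per-sample probabilities.
#'
#' @param model a `panel_model`.
#' @param processed matrix/data.frame of scaled inputs with the model's
#'   feature columns.
#' @return numeric vector of probabilities.
#' @export
evaluate_published_model <- function(model, processed) {
  predict(model, processed)
}

#' The study's printed DM2-vs-DN logistic panels
#'
#' Two fixed-coefficient diagnostic models reported for discriminating type 2
#' diabetes from diabetic nephropathy, operating on creatinine-normalized,
#' log-transformed, Pareto-scaled metabolite values (and scaled GFR for
#' model 1): model 1 uses beta-alanine, glucose, kynurenine and GFR; model 2
#' uses beta-alanine, argininic acid and kynurenine.
#'
#' @return named list of two `panel_model` objects, `model1` and `model2`.
#' @export
published_models <- function() {
  list(
    model1 = panel_model(
      feature_ids = c("beta_alanine", "glucose", "kynurenine", "GFR"),
      intercept = -0.975,
      coefficients = c(-6.644, -6.875, -8.125, -5.609)),
    model2 = panel_model(
      feature_ids = c("beta_alanine", "argininic_acid", "kynurenine"),
      intercept = -0.066,
      coefficients = c(-6.157, 3.052, -0.959))
  )
}

# Internal: maximum-likelihood logistic refit of a fixed feature set, with a
# vanishing-ridge fallback under perfect separation.
.fit_logistic <- function(X, y, features) {
  features <- intersect(features, colnames(X))
  if (length(features) == 0L) stop("none of the panel features are present")
  df <- data.frame(.y = y, X[, features, drop = FALSE], check.names = FALSE)
  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", features),
                                               collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(), data = df))
  cf <- stats::coef(fit)
  if (any(!is.finite(cf)) || any(abs(cf) > 20)) {
    rf <- glmnet::glmnet(cbind(X[, features, drop = FALSE],
                               if (length(features) == 1L) 0 else NULL),
                         y, family = "binomial", alpha = 0, lambda = 1e-6,
                         standardize = FALSE)
    cf <- c(as.numeric(rf$a0), as.numeric(rf$beta)[seq_along(features)])
    names(cf) <- c("(Intercept)", features)
  }
  panel_model(feature_ids = features, intercept = unname(cf[1]),
              coefficients = unname(cf[-1]))
}

# Internal: turn a model spec (panel_model, feature id vector, or builder
# function) into a builder function(X, y) -> object with predict().
.as_builder <- function(model) {
  if (is.function(model)) return(model)
  features <- if (inherits(model, "panel_model")) model$feature_ids
              else as.character(model)
  function(X, y) .fit_logistic(X, y, features)
}

# Internal: default panel construction (LASSO selection then stepwise AIC
# refit). Falls back to the first feature entering the LASSO path when the
# cross-validated penalty removes everything.
.default_builder <- function(X, y, seed = 1L, folds = 10L) {
  folds_eff <- min(folds, min(table(y)))
  sel <- lasso_select(X, y, folds = max(folds_eff, 3L), seed = seed)
  cand <- sel$feature_id
  if (length(cand) == 0L) {
    path <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                           standardize = FALSE)
    first <- apply(path$beta != 0, 1, function(r) if (any(r)) which(r)[1] else Inf)
    cand <- rownames(path$beta)[which.min(first)]
  }
  suppressWarnings(stepwise_refit(X, y, cand))
}

#' Stratified k-fold cross-validated ROC for a fixed panel specification
#'
#' Assesses the robustness of a chosen panel: inside every training fold the
#' preprocessing chain is refit and frozen onto the held-out fold (when `x`
#' is a raw [metabolite_table]) and the panel's logistic coefficients are
#' re-estimated; the feature list itself is fixed, mirroring the protocol of
#' validating an already-selected panel. Out-of-fold probabilities are
#' pooled into a single ROC curve with a DeLong 95% CI. Passing a builder
#' function instead re-runs the entire selection recipe per fold for a
#' fully nested estimate.
#'
#' @param x a [metabolite_table] or processed matrix.
#' @param labels binary labels.
#' @param model the model specification: a [panel_model()], a character
#'   vector of feature ids (coefficients refit per fold), or a function
#'   `(X_train, y_train)` returning an object with a `predict` method
#'   yielding probabilities. `NULL` re-runs the default LASSO + stepwise
#'   recipe inside every fold.
#' @param folds number of folds (default 10; `folds = n` gives LOO).
#' @param seed integer seed.
#' @param max_missing_frac,use_creatinine preprocessing options for raw input.
#' @return a `roc_summary` list: auc, ci_low, ci_high, curve (FPR/TPR
#'   points), scheme, and the pooled out-of-fold probabilities.
#' @export
kfold_cv_auc <- function(x, labels, model = NULL, folds = 10L, seed = 1L,
                         max_missing_frac = 0.20, use_creatinine = TRUE) {
  y <- .binary_labels(labels)
  n <- length(y)
  raw <- inherits(x, "metabolite_table") && !inherits(x, "processed_matrix")
  builder <- if (is.null(model)) {
    function(X, yy) .default_builder(X, yy, seed = seed)
  } else .as_builder(model)
  fold_id <- if (folds >= n) seq_len(n) else {
    stratified_folds(y, folds, derive_seed(seed, "cv_folds"))
  }
  prob <- rep(NA_real_, n)
  for (f in seq_len(max(fold_id))) {
    tr <- fold_id != f
    if (raw) {
      pm <- fit_preprocess(subset_samples(x, tr), max_missing_frac, use_creatinine)
      Xtr <- pm$values
      Xte <- apply_frozen(pm, subset_samples(x, !tr))$values
    } else {
      X <- .as_matrix(x); Xtr <- X[tr, , drop = FALSE]; Xte <- X[!tr, , drop = FALSE]
    }
    m <- builder(Xtr, y[tr])
    prob[!tr] <- as.numeric(predict(m, Xte))
  }
  roc_summary(prob, y, scheme = "kfold_cv")
}

#' Balanced-subsampling Monte-Carlo cross-validated ROC
#'
#' Each split draws a class-balanced training subsample (a `train_frac`
#' fraction of each class), rebuilds the model, and scores the remaining
#' samples. The AUC point estimate is the mean over splits; the 95% CI is
#' the 2.5/97.5 percentile of the split AUC distribution; the curve pools
#' all held-out scores.
#'
#' @inheritParams kfold_cv_auc
#' @param n_splits number of Monte-Carlo splits (default 500).
#' @param train_frac training fraction per class (default 2/3).
#' @return a `roc_summary` with `scheme = "mccv"` and the per-split AUCs in
#'   `$split_aucs`.
#' @export
mccv_roc <- function(x, labels, model = NULL, n_splits = 500L,
                     train_frac = 2/3, seed = 1L,
                     max_missing_frac = 0.20, use_creatinine = TRUE) {
  if (n_splits < 1L) stop("n_splits must be >= 1")
  y <- .binary_labels(labels)
  raw <- inherits(x, "metabolite_table") && !inherits(x, "processed_matrix")
  builder <- if (is.null(model)) {
    function(X, yy) .default_builder(X, yy, seed = seed)
  } else .as_builder(model)
  idx0 <- which(y == 0); idx1 <- which(y == 1)
  n_tr0 <- max(2L, floor(train_frac * length(idx0)))
  n_tr1 <- max(2L, floor(train_frac * length(idx1)))
  set.seed(derive_seed(seed, "mccv"))
  split_seeds <- sample.int(2^31 - 2, n_splits)
  aucs <- numeric(n_splits)
  pool_prob <- list(); pool_y <- list()
  for (s in seq_len(n_splits)) {
    set.seed(split_seeds[s])
    tr <- c(sample(idx0, n_tr0), sample(idx1, n_tr1))
    te <- setdiff(seq_along(y), tr)
    if (raw) {
      pm <- fit_preprocess(subset_samples(x, tr), max_missing_frac, use_creatinine)
      Xtr <- pm$values
      Xte <- apply_frozen(pm, subset_samples(x, te))$values
    } else {
      X <- .as_matrix(x); Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    }
    m <- builder(Xtr, y[tr])
    pr <- as.numeric(predict(m, Xte))
    aucs[s] <- .auc(y[te], pr)
    pool_prob[[s]] <- pr; pool_y[[s]] <- y[te]
  }
  out <- roc_summary(unlist(pool_prob), unlist(pool_y), scheme = "mccv")
  out$auc <- mean(aucs)
  out$ci_low <- as.numeric(stats::quantile(aucs, 0.025, type = 7))
  out$ci_high <- as.numeric(stats::quantile(aucs, 0.975, type = 7))
  out$split_aucs <- aucs
  out
}

#' Summarize scores and labels as a ROC with AUC and 95% CI
#'
#' @param probs predicted probabilities (or scores).
#' @param labels 0/1 labels (or a two-level factor).
#' @param scheme label describing how the scores were produced
#'   (`"train"`, `"kfold_cv"` or `"mccv"`).
#' @return a `roc_summary` list: auc, ci_low, ci_high (DeLong), curve
#'   data.frame of (fpr, tpr), scheme, probs, labels.
#' @export
roc_summary <- function(probs, labels, scheme = "train") {
  y <- if (all(labels %in% c(0, 1))) as.integer(labels) else .binary_labels(labels)
  r <- pROC::roc(response = y, predictor = probs, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  ci <- tryCatch(suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))),
                 error = function(e) rep(as.numeric(pROC::auc(r)), 3))
  structure(list(auc = as.numeric(pROC::auc(r)),
                 ci_low = max(0, min(ci[1], as.numeric(pROC::auc(r)))),
                 ci_high = min(1, max(ci[3], as.numeric(pROC::auc(r)))),
                 curve = data.frame(fpr = rev(1 - r$specificities),
                                    tpr = rev(r$sensitivities)),
                 scheme = scheme, probs = probs, labels = y),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("<roc_summary: %s> AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$scheme, x$auc, x$ci_low, x$ci_high))
  invisible(x)
}

#' Permutation test comparing two paired ROC AUCs
#'
#' Tests whether classifier A's AUC exceeds classifier B's on the same test
#' samples, by randomly swapping the two classifiers' scores within samples
#' (label-preserving exchange under the null of interchangeable
#' classifiers).
#'
#' @param scores_a,scores_b probability scores from the two models on the
#'   same samples.
#' @param labels 0/1 labels for those samples.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with observed |AUC difference|, p_value, and the two AUCs.
#' @export
compare_rocs <- function(scores_a, scores_b, labels, n_perm = 2000L, seed = 1L) {
  y <- if (all(labels %in% c(0, 1))) as.integer(labels) else .binary_labels(labels)
  stopifnot(length(scores_a) == length(y), length(scores_b) == length(y))
  auc_a <- .auc(y, scores_a); auc_b <- .auc(y, scores_b)
  observed <- abs(auc_a - auc_b)
  set.seed(derive_seed(seed, "compare_rocs"))
  n <- length(y)
  perms <- vapply(seq_len(n_perm), function(i) {
    swap <- stats::runif(n) < 0.5
    sa <- ifelse(swap, scores_b, scores_a)
    sb <- ifelse(swap, scores_a, scores_b)
    abs(.auc(y, sa) - .auc(y, sb))
  }, numeric(1))
  list(auc_a = auc_a, auc_b = auc_b, observed = observed,
       p_value = (1 + sum(perms >= observed)) / (1 + n_perm))
}
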