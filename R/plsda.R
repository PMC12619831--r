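#' Fit a PLS-DA model
#'
#' Partial least squares discriminant analysis via the NIPALS algorithm.
#' Two-class problems use a single 0/1 response column (PLS1); multi-class
#' problems use a one-hot indicator matrix (PLS2). X and Y are mean-centered
#' internally (Pareto-scaled input is already centered, so this is a no-op
#' in the standard pipeline). Deterministic for fixed input.
#'
#' @param x a `processed_matrix`, [metabolite_table] or numeric matrix.
#' @param labels class label per sample (2 or more classes).
#' @param n_components number of latent components to extract.
#' @param tol,max_iter NIPALS convergence tolerance on the score vector and
#'   iteration cap per component.
#' @return an object of class `plsda_fit` with scores `T`, weights `W`
#'   (columns unit-norm), x-loadings `P`, y-loadings `Q`, per-component
#'   explained Y sum-of-squares `ss_y`, cumulative `r2y`, per-metabolite
#'   `vip`, and the centers needed for prediction.
#' @export
fit_plsda <- function(x, labels, n_components = 2L, tol = 1e-10, max_iter = 500L) {
  X <- .as_matrix(x)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("at least 2 classes required")
  if (n_components >= min(nrow(X), ncol(X) + 1L)) {
    stop("n_components must be < min(n_samples, n_metabolites + 1)")
  }
  Y <- .class_indicator(labels)
  x_center <- colMeans(X); y_center <- colMeans(Y)
  Xc <- sweep(X, 2, x_center); Yc <- sweep(Y, 2, y_center)
  if (all(abs(Xc) < 1e-12)) stop("degenerate constant X matrix")
  p <- ncol(Xc); m <- ncol(Yc)
  A <- n_components
  W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- matrix(0, m, A)
  Tm <- matrix(0, nrow(Xc), A)
  ss_y <- numeric(A)
  ss_y_tot <- sum(Yc^2)
  Xd <- Xc; Yd <- Yc
  for (a in seq_len(A)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    t_old <- rep(Inf, nrow(Xd))
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)[, 1]
      w <- w / sqrt(sum(w^2))
      t_new <- Xd %*% w
      q <- crossprod(Yd, t_new)[, 1] / sum(t_new^2)
      if (m > 1L) u <- (Yd %*% q) / sum(q^2) else u <- Yd[, 1]
      if (sqrt(sum((t_new - t_old)^2)) < tol * sqrt(sum(t_new^2))) break
      t_old <- t_new
    }
    t_a <- as.numeric(t_new)
    p_a <- crossprod(Xd, t_a)[, 1] / sum(t_a^2)
    W[, a] <- w; P[, a] <- p_a; Q[, a] <- q; Tm[, a] <- t_a
    ss_y[a] <- sum(t_a^2) * sum(q^2)   # Y sum-of-squares removed by component a
    Xd <- Xd - tcrossprod(t_a, p_a)
    Yd <- Yd - tcrossprod(t_a, q)
  }
  r2y <- cumsum(ss_y) / ss_y_tot
  fit <- structure(list(n_components = A, T = Tm, W = W, P = P, Q = Q,
                        ss_y = ss_y, r2y = r2y,
                        x_center = x_center, y_center = y_center,
                        levels = levels(labels),
                        feature_ids = colnames(X)),
                   class = "plsda_fit")
  fit$vip <- vip_scores(fit)
  fit
}

# Internal: one-hot indicator (or single 0/1 column for 2 classes).
.class_indicator <- function(labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) == 2L) {
    matrix(as.numeric(labels == levels(labels)[2]), ncol = 1,
           dimnames = list(NULL, levels(labels)[2]))
  } else {
    stats::model.matrix(~ labels - 1)
  }
}

#' Predict from a fitted PLS-DA model
#'
#' @param object a `plsda_fit`.
#' @param newdata matrix (or container) with the training feature columns.
#' @param type `"response"` for continuous Y predictions, `"class"` for the
#'   predicted class label.
#' @param ... unused.
#' @return matrix of Y predictions or a factor of class labels.
#' @export
predict.plsda_fit <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  X <- .as_matrix(newdata)
  if (!is.null(object$feature_ids) && !is.null(colnames(X))) {
    X <- X[, object$feature_ids, drop = FALSE]
  }
  Xc <- sweep(X, 2, object$x_center)
  # regression coefficients B = W (P'W)^{-1} Q'
  B <- object$W %*% solve(crossprod(object$P, object$W), t(object$Q))
  Yhat <- sweep(Xc %*% B, 2, object$y_center, "+")
  if (type == "response") return(Yhat)
  if (ncol(Yhat) == 1L) {
    factor(ifelse(Yhat[, 1] >= 0.5, object$levels[2], object$levels[1]),
           levels = object$levels)
  } else {
    factor(object$levels[max.col(Yhat)], levels = object$levels)
  }
}

#' Variable importance in projection (VIP) scores
#'
#' `VIP_j = sqrt( p * sum_a SS_a w_ja^2 / sum_a SS_a )` with unit-norm weight
#' vectors and `SS_a` the Y sum-of-squares explained by component a. The mean
#' of the squared VIPs equals 1 by construction.
#'
#' @param model a fitted `plsda_fit`.
#' @return named numeric vector of per-metabolite VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_fit"))
  p <- nrow(model$W)
  ss <- model$ss_y
  w2 <- model$W^2   # columns already unit norm
  vip <- sqrt(p * as.numeric(w2 %*% ss) / sum(ss))
  stats::setNames(vip, model$feature_ids)
}

#' Cross-validated R2Y and Q2 for PLS-DA
#'
#' Stratified k-fold cross-validation over a range of component counts.
#' When `x` is a raw [metabolite_table], the full preprocessing chain is
#' re-fitted inside every training fold and frozen onto the held-out fold
#' via [apply_frozen()], so no information leaks from test to train. Q² is
#' computed as `1 - PRESS/TSS`, with TSS taken against the training-fold
#' class means.
#'
#' @param x a [metabolite_table] (preprocessing refrozen per fold) or an
#'   already-processed matrix (used as-is).
#' @param labels class labels.
#' @param max_components largest component count assessed (capped at 5 by
#'   default, and always below the smallest training-fold size).
#' @param folds number of folds (`folds = n` gives leave-one-out).
#' @param seed fold-assignment seed.
#' @param max_missing_frac,use_creatinine preprocessing options used when
#'   `x` is a raw table.
#' @return data.frame with columns n_components, r2y, q2.
#' @export
cross_validate <- function(x, labels, max_components = 5L, folds = 10L,
                           seed = 1L, max_missing_frac = 0.20,
                           use_creatinine = TRUE) {
  labels <- as.factor(labels)
  n <- length(labels)
  raw <- inherits(x, "metabolite_table") && !inherits(x, "processed_matrix")
  fold_id <- if (folds >= n) seq_len(n) else stratified_folds(labels, folds, seed)
  nfold <- max(fold_id)
  A <- min(max_components, n - max(table(fold_id)) - 1L)
  if (A < 1L) stop("too few samples for cross-validation")
  press <- numeric(A); tss <- 0
  r2y_full <- NULL
  for (f in seq_len(nfold)) {
    tr <- fold_id != f; te <- !tr
    if (nlevels(droplevels(labels[tr])) < nlevels(labels)) {
      stop("a training fold lost a class; reduce 'folds'")
    }
    if (raw) {
      pm_tr <- fit_preprocess(subset_samples(x, tr), max_missing_frac, use_creatinine)
      Xtr <- pm_tr$values
      Xte <- apply_frozen(pm_tr, subset_samples(x, te))$values
    } else {
      Xall <- .as_matrix(x)
      Xtr <- Xall[tr, , drop = FALSE]; Xte <- Xall[te, , drop = FALSE]
    }
    Yte <- .class_indicator(labels)[te, , drop = FALSE]
    ybar_tr <- colMeans(.class_indicator(labels)[tr, , drop = FALSE])
    tss <- tss + sum(sweep(Yte, 2, ybar_tr)^2)
    for (a in seq_len(A)) {
      fit <- fit_plsda(Xtr, labels[tr], n_components = a)
      Yhat <- predict(fit, Xte)
      press[a] <- press[a] + sum((Yte - Yhat)^2)
    }
  }
  # full-data R2Y per component count
  X_full <- if (raw) fit_preprocess(x, max_missing_frac, use_creatinine)$values else .as_matrix(x)
  full_fit <- fit_plsda(X_full, labels, n_components = A)
  data.frame(n_components = seq_len(A),
             r2y = full_fit$r2y[seq_len(A)],
             q2 = 1 - press / tss)
}

#' Subset a metabolite table by sample index
#'
#' Keeps the metabolite axis, LODs and per-sample creatinine consistent;
#' the building block for all cross-validation splits on raw tables.
#'
#' @param table a [metabolite_table].
#' @param idx integer or logical sample index.
#' @return a [metabolite_table] with the selected samples.
#' @export
subset_samples <- function(table, idx) {
  metabolite_table(table$values[idx, , drop = FALSE],
                   lod = table$lod,
                   creatinine = table$creatinine[idx],
                   sample_ids = table$sample_ids[idx],
                   metabolite_ids = table$metabolite_ids)
}

#' Choose the PLS-DA component count by cross-validated Q2
#'
#' @inheritParams cross_validate
#' @param cap upper bound on the component count (default 5).
#' @return integer component count maximizing Q².
#' @export
choose_components <- function(x, labels, folds = 10L, seed = 1L, cap = 5L) {
  cv <- cross_validate(x, labels, max_components = cap, folds = folds, seed = seed)
  cv$n_components[which.max(cv$q2)]
}

#' Permutation test of PLS-DA class separation
#'
#' Class labels are permuted `n_perm` times; the statistic (cross-validated
#' Q² at the supplied component count by default) is recomputed for each
#' permutation, and the p-value is `(1 + #[perm >= observed]) / (1 + n_perm)`,
#' so it can never fall below `1/(n_perm + 1)`.
#'
#' @inheritParams cross_validate
#' @param n_perm number of label permutations (the study protocol uses 2000).
#' @param n_components component count for the statistic; `"auto"` picks by
#'   cross-validated Q² capped at 5.
#' @param folds folds used for the Q² statistic.
#' @param seed seed controlling the permutation stream.
#' @return list with observed statistic, permuted statistics, and p_value.
#' @export
permutation_test <- function(x, labels, n_perm = 2000L, n_components = "auto",
                             folds = 7L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  labels <- as.factor(labels)
  if (identical(n_components, "auto")) {
    n_components <- choose_components(x, labels, folds = folds, seed = seed)
  }
  stat <- function(lab, s) {
    cv <- cross_validate(x, lab, max_components = n_components,
                         folds = folds, seed = s)
    cv$q2[n_components]
  }
  observed <- stat(labels, derive_seed(seed, "plsda_cv"))
  set.seed(derive_seed(seed, "plsda_perm"))
  perm_seeds <- sample.int(2^31 - 2, n_perm)
  perms <- vapply(seq_len(n_perm), function(i) {
    set.seed(perm_seeds[i])
    lab_p <- sample(labels)
    tryCatch(stat(lab_p, perm_seeds[i]), error = function(e) -Inf)
  }, numeric(1))
  list(observed = observed, permuted = perms,
       n_components = n_components,
       p_value = (1 + sum(perms >= observed)) / (1 + n_perm))
}
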