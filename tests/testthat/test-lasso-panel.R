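test_that("LASSO selection ranks a planted feature first and respects the penalty", {
  hits <- vapply(1:10, function(s) {
    d <- signal_matrix(n_per_class = 20, p = 40, n_signal = 1, delta = 2.5,
                       seed = s)
    sel <- lasso_select(d$x, d$y, seed = s)
    nrow(sel) > 0 && sel$feature_id[1] == "F01"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # a penalty above lambda_max removes everything
  d <- signal_matrix(seed = 99)
  sel <- lasso_select(d$x, d$y, lambda_grid = c(50, 40), seed = 1)
  expect_equal(nrow(sel), 0)
})

test_that("an exactly duplicated predictor is not retained twice at strong penalty", {
  d <- signal_matrix(n_per_class = 20, p = 10, n_signal = 1, delta = 3, seed = 5)
  x <- cbind(d$x, F_dup = d$x[, "F01"])
  path <- glmnet::glmnet(x, d$y, family = "binomial", alpha = 1,
                         standardize = FALSE)
  # moderately strong penalty: an early lambda with few nonzero coefficients
  lam <- path$lambda[min(which(path$df > 0))]
  sel <- lasso_select(x, d$y, lambda_grid = c(lam * 1.0001, lam), seed = 1)
  expect_lte(sum(sel$feature_id %in% c("F01", "F_dup")), 1)
})

test_that("stepwise refitting minimizes AIC and usually discards noise", {
  # two-candidate case: the result must equal the argmin-AIC submodel found
  # by exhaustive enumeration
  for (s in 1:20) {
    d <- signal_matrix(n_per_class = 15, p = 5, n_signal = 1, delta = 1.2,
                       seed = 200 + s)
    m <- suppressWarnings(stepwise_refit(d$x, d$y, c("F01", "F05")))
    models <- list(character(0), "F01", "F05", c("F01", "F05"))
    aics <- vapply(models, function(fs) {
      if (!length(fs)) {
        return(stats::AIC(stats::glm(d$y ~ 1, family = binomial())))
      }
      suppressWarnings(stats::AIC(stats::glm(d$y ~ d$x[, fs, drop = FALSE],
                                             family = binomial())))
    }, numeric(1))
    expect_setequal(m$feature_ids, models[[which.min(aics)]])
  }
  # pure-noise candidates are usually discarded (the AIC retains a noise
  # feature with probability near P(chisq_1 > 2) ~ 0.16)
  kept_noise <- vapply(1:50, function(s) {
    d <- signal_matrix(n_per_class = 20, p = 5, n_signal = 1, delta = 1.5,
                       seed = 100 + s)
    m <- suppressWarnings(stepwise_refit(d$x, d$y, c("F01", "F05")))
    "F05" %in% m$feature_ids
  }, logical(1))
  expect_lte(mean(kept_noise), 0.4)
  # returned AIC no worse than the full candidate model
  d <- signal_matrix(n_per_class = 15, p = 6, n_signal = 2, delta = 1.5, seed = 7)
  m <- suppressWarnings(stepwise_refit(d$x, d$y, colnames(d$x)[1:4]))
  full <- stats::glm(d$y ~ d$x[, 1:4], family = binomial())
  expect_lte(m$aic, stats::AIC(full) + 1e-9)
  # single candidate: either that model or intercept-only
  m1 <- suppressWarnings(stepwise_refit(d$x, d$y, "F01"))
  expect_true(length(m1$feature_ids) <= 1)
})

test_that("fixed panels cross-validate honestly: separable high, null chance-level", {
  d <- signal_matrix(n_per_class = 15, p = 8, n_signal = 1, delta = 6, seed = 8)
  roc <- kfold_cv_auc(d$x, d$y, model = "F01", folds = 5, seed = 1)
  expect_equal(roc$auc, 1)
  expect_true(all(diff(roc$curve$tpr) >= 0) && all(diff(roc$curve$fpr) >= 0))
  expect_equal(roc$curve$fpr[1], 0)
  expect_equal(roc$curve$tpr[nrow(roc$curve)], 1)
  # random labels with a fixed feature set: mean AUC near 0.5
  aucs <- vapply(1:50, function(s) {
    set.seed(s)
    x <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(NULL, paste0("F", 1:6)))
    y <- rep(c(0L, 1L), 15)
    kfold_cv_auc(x, y, model = c("F1", "F2"), folds = 5, seed = s)$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("Monte-Carlo CV summarizes split AUC distributions sensibly", {
  d <- signal_matrix(n_per_class = 12, p = 5, n_signal = 1, delta = 6, seed = 9)
  r <- mccv_roc(d$x, d$y, model = "F01", n_splits = 25, seed = 1)
  expect_equal(r$auc, 1)
  expect_equal(c(r$ci_low, r$ci_high), c(1, 1))
  # null labels: the CI covers 0.5 in most seeds
  covered <- vapply(1:10, function(s) {
    set.seed(s)
    x <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("F", 1:4)))
    y <- rep(c(0L, 1L), 15)
    r <- mccv_roc(x, y, model = c("F1", "F2"), n_splits = 40, seed = s)
    r$ci_low <= 0.5 && r$ci_high >= 0.5
  }, logical(1))
  expect_gte(mean(covered), 0.9)
  # more splits narrow the percentile CI on the same data
  d2 <- signal_matrix(n_per_class = 15, p = 5, n_signal = 1, delta = 1.5, seed = 10)
  widths <- vapply(c(15L, 150L), function(k) {
    r <- mccv_roc(d2$x, d2$y, model = "F01", n_splits = k, seed = 3)
    r$ci_high - r$ci_low
  }, numeric(1))
  expect_lte(widths[2], widths[1] * 1.2)
})

test_that("the fixed published panels evaluate exactly as printed", {
  pm <- published_models()
  zeros1 <- matrix(0, 1, 4,
                   dimnames = list(NULL, pm$model1$feature_ids))
  zeros2 <- matrix(0, 1, 3,
                   dimnames = list(NULL, pm$model2$feature_ids))
  # all-zero scaled inputs recover the sigmoid of the printed intercepts
  expect_equal(evaluate_published_model(pm$model2, zeros2), 0.4835,
               tolerance = 1e-4)
  expect_equal(stats::qlogis(evaluate_published_model(pm$model1, zeros1)),
               -0.975, tolerance = 1e-12)
  # probabilities stay in (0,1) and fall as beta-alanine rises (model 2)
  grid <- seq(-2, 2, length.out = 9)
  probs <- vapply(grid, function(v) {
    z <- zeros2; z[1, "beta_alanine"] <- v
    evaluate_published_model(pm$model2, z)
  }, numeric(1))
  expect_true(all(probs > 0 & probs < 1))
  expect_true(all(diff(probs) < 0))
})

test_that("paired ROC comparison detects real differences and honors its floor", {
  set.seed(11)
  y <- rep(c(0L, 1L), each = 20)
  s_same <- runif(40)
  same <- compare_rocs(s_same, s_same, y, n_perm = 99, seed = 1)
  expect_equal(same$p_value, 1)
  detected <- vapply(1:10, function(s) {
    set.seed(s)
    perfect <- y + rnorm(40, 0, 0.01)
    noise <- runif(40)
    compare_rocs(perfect, noise, y, n_perm = 99, seed = s)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.9)
  expect_gte(same$p_value, 1 / 100)
})

test_that("held-out labels cannot influence out-of-fold predictions", {
  set.seed(12)
  x <- matrix(rnorm(20 * 5), 20, 5, dimnames = list(NULL, paste0("F", 1:5)))
  y <- rep(c(0L, 1L), 10)
  # leave-one-out folds are label-independent, so flipping one label must
  # leave that sample's out-of-fold probability untouched
  r1 <- kfold_cv_auc(x, y, model = c("F1", "F2"), folds = 20, seed = 1)
  y2 <- y; y2[7] <- 1L - y2[7]
  r2 <- kfold_cv_auc(x, y2, model = c("F1", "F2"), folds = 20, seed = 1)
  expect_equal(r1$probs[7], r2$probs[7], tolerance = 1e-12)
})
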