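test_that("elastic-net fits obey the penalty limits and recover planted signs", {
  d <- signal_matrix(n_per_class = 20, p = 6, n_signal = 2, delta = 2, seed = 1)
  # overwhelming penalty: coefficients vanish, intercept = prevalence logit
  m_inf <- en_logistic_fit(d$x, d$y, strength = 1e7)
  expect_true(all(abs(m_inf$coefficients) < 1e-6))
  expect_equal(m_inf$intercept, stats::qlogis(mean(d$y)), tolerance = 1e-3)
  # l1_ratio = 1 agrees with the LASSO path at the same lambda
  lam <- 0.05
  m_l1 <- en_logistic_fit(d$x, d$y, l1_ratio = 1, strength = lam * nrow(d$x))
  ref <- glmnet::glmnet(d$x, d$y, family = "binomial", alpha = 1,
                        lambda = lam, standardize = FALSE, thresh = 1e-9)
  expect_equal(m_l1$coefficients, as.numeric(ref$beta), tolerance = 1e-4)
  # planted direction: positive shift in class 1 gives positive coefficients
  m <- en_logistic_fit(d$x, d$y)
  expect_true(all(m$coefficients[1:2] > 0))
})

test_that("MCC and Brier match hand arithmetic and conventions", {
  expect_equal(mcc(5, 0, 5, 0), 1)
  expect_equal(mcc(0, 5, 0, 5), -1)
  # MCC equals the Pearson correlation of the binary vectors (independent
  # identity): tp=3, fp=1, tn=2, fn=2 -> 4/sqrt(240)
  pred <- c(1, 1, 1, 1, 0, 0, 0, 0)
  truth <- c(1, 1, 1, 0, 0, 0, 1, 1)
  expect_equal(mcc(3, 1, 2, 2), cor(pred, truth))
  expect_equal(mcc(3, 1, 2, 2), 4 / sqrt(240))
  expect_equal(mcc(0, 0, 5, 5), 0)  # zero-denominator convention
  expect_error(mcc(-1, 0, 1, 1))
  expect_equal(brier(c(1, 1, 0, 0), c(1, 1, 0, 0)), 0)
  expect_equal(brier(rep(0.5, 8), rep(c(0, 1), 4)), 0.25)
  set.seed(2)
  pr <- runif(20); y <- rbinom(20, 1, 0.5)
  expect_equal(brier(pr, y), sum((pr - y)^2) / 20)
  expect_error(brier(c(0.5, 1.2), c(0, 1)), "\\[0, 1\\]")
})

test_that("fitness is penalized validation MCC with an empty-mask sentinel", {
  d <- signal_matrix(n_per_class = 16, p = 12, n_signal = 1, delta = 6, seed = 3)
  cfg <- ga_config(profile = "reduced", penalty_weight = 0.05)
  splits <- cv_split_list(d$y, 4, seed = 1)
  mask1 <- c(TRUE, rep(FALSE, 11))
  expect_equal(fitness(mask1, d$x, d$y, splits, cfg), 1.0)
  # ten features including the perfect one: same MCC, penalty 0.05 * 2
  mask10 <- rep(FALSE, 12); mask10[1:10] <- TRUE
  # pad with all-zero columns so predictions are fixed by construction
  x0 <- d$x; x0[, 2:10] <- 0
  f1 <- fitness(mask1, x0, d$y, splits, cfg)
  f10 <- fitness(mask10, x0, d$y, splits, cfg)
  expect_equal(f1 - f10, 0.05 * 2, tolerance = 1e-12)
  expect_equal(fitness(rep(FALSE, 12), d$x, d$y, splits, cfg), -1)
  # pure-noise masks: mean fitness near zero
  null_fit <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(32 * 10), 32, 10)
    y <- rep(c(0L, 1L), 16)
    fitness(c(rep(TRUE, 3), rep(FALSE, 7)), x, y,
            cv_split_list(y, 4, seed = s), cfg)
  }, numeric(1))
  expect_gt(mean(null_fit), -0.2)
  expect_lt(mean(null_fit), 0.2)
})

test_that("the penalty makes fitness strictly decrease beyond max_features", {
  d <- signal_matrix(n_per_class = 16, p = 14, n_signal = 1, delta = 6, seed = 4)
  x0 <- d$x; x0[, 2:14] <- 0   # extra features carry no information
  cfg <- ga_config(profile = "reduced", penalty_weight = 0.05)
  splits <- cv_split_list(d$y, 4, seed = 2)
  fits <- vapply(c(8, 9, 11, 14), function(k) {
    mask <- rep(FALSE, 14); mask[1:k] <- TRUE
    fitness(mask, x0, d$y, splits, cfg)
  }, numeric(1))
  expect_equal(diff(fits), c(-0.05, -0.1, -0.15), tolerance = 1e-12)
})

test_that("the GA is reproducible, elitist, and static without variation operators", {
  landscape <- function(mask) sum(mask * c(3, -1, 2, -1, 1, rep(-0.5, 5)))
  x_dummy <- matrix(0, 4, 10)
  cfg <- ga_config(population_size = 30, max_generations = 10, seed = 5,
                   profile = "reduced")
  r1 <- ga_evolve(x_dummy, fitness_fn = landscape, config = cfg)
  r2 <- ga_evolve(x_dummy, fitness_fn = landscape, config = cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_mask, r2$best_mask)
  # best-so-far fitness never decreases (elitism)
  expect_true(all(diff(r1$trace) >= 0))
  # the deterministic optimum of this landscape is exactly features {1,3,5}
  expect_identical(which(r1$best_mask), c(1L, 3L, 5L))
  # no mutation, no crossover: the final best equals the initial best
  cfg0 <- ga_config(population_size = 20, max_generations = 6,
                    crossover_prob = 0, mutation_prob_start = 0,
                    mutation_prob_end = 0, seed = 6, profile = "reduced")
  r0 <- ga_evolve(x_dummy, fitness_fn = landscape, config = cfg0)
  expect_equal(r0$best_fitness, r0$trace[1])
  expect_error(ga_config(population_size = 1), "population_size")
  expect_error(ga_config(elite_count = 10, population_size = 5), "elite_count")
  expect_error(ga_config(mutation_prob_start = 0.01, mutation_prob_end = 0.2),
               "mutation_prob_end")
})

test_that("the GA recovers a dominant feature through the elastic-net fitness", {
  ok <- vapply(1:5, function(s) {
    d <- signal_matrix(n_per_class = 20, p = 30, n_signal = 1, delta = 6,
                       seed = 20 + s)
    splits <- cv_split_list(d$y, 4, seed = s)
    r <- ga_evolve(d$x, d$y, splits,
                   ga_config(profile = "reduced", seed = s))
    r$best_mask[1]
  }, logical(1))
  expect_equal(mean(ok), 1)
})

test_that("nested cross-validation pools leakage-free predictions with stability", {
  d <- signal_matrix(n_per_class = 10, p = 8, n_signal = 2, delta = 4, seed = 30)
  cfg <- ga_config(population_size = 30, max_generations = 6, seed = 1,
                   profile = "reduced")
  ncv <- nested_cv(d$x, d$y, cfg, outer = 4L, inner = 4L, seed = 1)
  expect_true(all(ncv$stability >= 0 & ncv$stability <= 1))
  expect_true(all(!is.na(ncv$probs)))
  # planted features dominate the stability ranking even with this small GA
  expect_true(any(c("F01", "F02") %in% ncv$stable_features))
  expect_gte(max(ncv$stability[c("F01", "F02")]),
             max(ncv$stability[paste0("F0", 3:8)]))
  # flipping a held-out label leaves that sample's prediction unchanged
  # (leave-one-out outer folds do not depend on labels)
  ncv1 <- nested_cv(d$x, d$y, cfg, outer = "loo", inner = 4L, seed = 2)
  y2 <- d$y; y2[3] <- 1L - y2[3]
  ncv2 <- nested_cv(d$x, y2, cfg, outer = "loo", inner = 4L, seed = 2)
  expect_equal(ncv1$probs[3], ncv2$probs[3], tolerance = 1e-12)
})

test_that("bootstrap metric bundles behave at the extremes and in general", {
  y <- rep(c(0L, 1L), each = 10)
  perfect <- c(rep(0.01, 10), rep(0.99, 10))
  mb <- bootstrap_metrics(perfect, y, n_boot = 50, seed = 1)
  ideal <- c(auc = 1, acc = 1, f1 = 1, sens = 1, spec = 1, mcc = 1, brier = 0)
  expect_equal(stats::setNames(mb$estimate, mb$metric),
               ideal[mb$metric], tolerance = 1e-3)
  expect_equal(mb$ci_low, mb$ci_high, tolerance = 2e-3)
  # a single bootstrap replicate collapses the CI onto itself
  set.seed(2)
  pr <- runif(20)
  mb1 <- bootstrap_metrics(pr, y, n_boot = 1, seed = 3)
  expect_equal(mb1$ci_low, mb1$ci_high)
  # CIs bracket the point estimate for ordinary data
  mb2 <- bootstrap_metrics(plogis(rnorm(20) + 2 * y), y, n_boot = 400, seed = 4)
  expect_true(all(mb2$ci_low <= mb2$estimate + 1e-9))
  expect_true(all(mb2$ci_high >= mb2$estimate - 1e-9))
  expect_error(bootstrap_metrics(pr, rep(1, 20)), "both classes")
})

test_that("AUC equals the pairwise concordance count on a small score set", {
  scores <- c(0.1, 0.4, 0.35, 0.8)
  y <- c(0L, 0L, 1L, 1L)
  # enumeration over all (negative, positive) pairs with 0.5 credit for ties
  conc <- 0
  for (i in which(y == 0)) for (j in which(y == 1)) {
    conc <- conc + (scores[j] > scores[i]) + 0.5 * (scores[j] == scores[i])
  }
  want <- conc / (sum(y == 0) * sum(y == 1))
  mb <- bootstrap_metrics(scores, y, n_boot = 1, seed = 1)
  expect_equal(mb$estimate[mb$metric == "auc"], want)
})
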