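#' Genetic-algorithm configuration
#'
#' Hyperparameters of the wrapper feature-selection GA. The default
#' (`profile = "full"`) matches the full study protocol: 3000 individuals
#' evolved for up to 60 generations with two-point crossover (p = 0.8),
#' adaptive bit-flip mutation decaying linearly from 0.25 to 0.05, tournament
#' selection of size 4, elitism retaining the top 3, a complexity penalty
#' beyond 8 features, and an elastic-net fitness with L1/L2 ratio 0.5. The
#' `"reduced"` profile (population 100, 20 generations) is the desk-scale
#' configuration used for testing and examples.
#'
#' @param population_size number of individuals (full protocol: 3000).
#' @param max_generations generation cap (full protocol: 60).
#' @param crossover_prob two-point crossover probability (default 0.8).
#' @param mutation_prob_start,mutation_prob_end probability that a child
#'   undergoes bit-flip mutation, decaying linearly from the first to the
#'   last generation (0.25 to 0.05); a mutated child flips each bit
#'   independently with probability `1/n_features`.
#' @param tournament_size tournament selection size (default 4).
#' @param elite_count individuals copied unchanged each generation (default 3).
#' @param max_features complexity-penalty threshold (default 8).
#' @param penalty_weight penalty per feature beyond `max_features`
#'   subtracted from the fitness (default 0.05).
#' @param l1_ratio elastic-net mixing parameter (default 0.5).
#' @param en_strength elastic-net penalty strength; the glmnet lambda is
#'   `en_strength / n_train` (so strength 1 matches the common
#'   inverse-regularization default `C = 1`).
#' @param init_prob per-bit inclusion probability of the initial population;
#'   `NULL` means `max_features / n_features`, seeding the search near the
#'   target sparsity.
#' @param plateau_generations,plateau_tol stop early when the best fitness
#'   improves by less than `plateau_tol` for this many consecutive
#'   generations (default 10 and 1e-6).
#' @param seed integer seed.
#' @param profile `"full"` or `"reduced"`; presets population and
#'   generation counts, overridable by the explicit arguments.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(population_size = NULL, max_generations = NULL,
                      crossover_prob = 0.8, mutation_prob_start = 0.25,
                      mutation_prob_end = 0.05, tournament_size = 4L,
                      elite_count = 3L, max_features = 8L,
                      penalty_weight = 0.05, l1_ratio = 0.5,
                      en_strength = 1.0, init_prob = NULL,
                      plateau_generations = 10L, plateau_tol = 1e-6,
                      seed = 1L, profile = c("full", "reduced")) {
  profile <- match.arg(profile)
  if (is.null(population_size)) {
    population_size <- if (profile == "full") 3000L else 100L
  }
  if (is.null(max_generations)) {
    max_generations <- if (profile == "full") 60L else 20L
  }
  cfg <- list(population_size = as.integer(population_size),
              max_generations = as.integer(max_generations),
              crossover_prob = crossover_prob,
              mutation_prob_start = mutation_prob_start,
              mutation_prob_end = mutation_prob_end,
              tournament_size = as.integer(tournament_size),
              elite_count = as.integer(elite_count),
              max_features = as.integer(max_features),
              penalty_weight = penalty_weight,
              l1_ratio = l1_ratio, en_strength = en_strength,
              init_prob = init_prob,
              plateau_generations = as.integer(plateau_generations),
              plateau_tol = plateau_tol,
              seed = as.integer(seed), profile = profile)
  if (cfg$population_size < 2L) stop("population_size must be >= 2")
  if (cfg$elite_count >= cfg$population_size) {
    stop("elite_count must be smaller than population_size")
  }
  if (cfg$mutation_prob_end > cfg$mutation_prob_start) {
    stop("mutation_prob_end must be <= mutation_prob_start")
  }
  if (cfg$crossover_prob < 0 || cfg$crossover_prob > 1) {
    stop("crossover_prob must be in [0, 1]")
  }
  if (cfg$l1_ratio < 0 || cfg$l1_ratio > 1) stop("l1_ratio must be in [0, 1]")
  if (cfg$penalty_weight < 0) stop("penalty_weight must be >= 0")
  class(cfg) <- "ga_config"
  cfg
}

#' Elastic-net regularized logistic regression
#'
#' Penalized logistic fit via glmnet coordinate descent at a single penalty.
#' The glmnet lambda is `strength / n`, so `strength = 1` corresponds to the
#' common inverse-regularization default and `strength -> Inf` shrinks every
#' coefficient to zero, leaving the intercept at the class-prevalence logit.
#'
#' @param x numeric matrix (samples x features) or a processed container.
#' @param labels binary labels.
#' @param l1_ratio elastic-net mixing (1 = lasso, 0 = ridge); default 0.5.
#' @param strength penalty strength (default 1).
#' @return a `panel_model` with the fitted intercept and coefficients
#'   (zeros retained), plus the feature order.
#' @export
en_logistic_fit <- function(x, labels, l1_ratio = 0.5, strength = 1.0) {
  X <- .as_matrix(x)
  y <- .binary_labels(labels)
  n <- nrow(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("F", seq_len(ncol(X)))
  if (ncol(X) == 1L) X2 <- cbind(X, 0) else X2 <- X  # glmnet needs >= 2 cols
  fit <- suppressWarnings(
    glmnet::glmnet(X2, y, family = "binomial", alpha = l1_ratio,
                   lambda = strength / n, standardize = FALSE,
                   thresh = 1e-9))
  beta <- as.numeric(fit$beta)[seq_len(ncol(X))]
  panel_model(feature_ids = colnames(X),
              intercept = as.numeric(fit$a0),
              coefficients = beta)
}

#' Matthews correlation coefficient from a confusion matrix
#'
#' @param tp,fp,tn,fn nonnegative confusion-matrix counts (total > 0).
#' @return MCC in `[-1, 1]`; 0 when any marginal is empty (zero-denominator
#'   convention).
#' @export
mcc <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  denom <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

# Internal: MCC from predicted and true 0/1 vectors.
.mcc_pred <- function(pred, truth) {
  mcc(tp = sum(pred == 1 & truth == 1), fp = sum(pred == 1 & truth == 0),
      tn = sum(pred == 0 & truth == 0), fn = sum(pred == 0 & truth == 1))
}

#' Brier score
#'
#' Mean squared error between predicted probabilities and 0/1 outcomes.
#'
#' @param probs predicted probabilities in `[0, 1]`.
#' @param labels 0/1 outcomes (or a two-level factor).
#' @return the Brier score in `[0, 1]`.
#' @export
brier <- function(probs, labels) {
  y <- if (all(labels %in% c(0, 1))) as.numeric(labels) else .binary_labels(labels)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  mean((probs - y)^2)
}

#' GA fitness: complexity-penalized validation MCC of an elastic-net fit
#'
#' For each supplied train/validation split, an elastic-net logistic model
#' is fitted on the masked features of the training part and its MCC
#' (threshold 0.5) computed on the validation part. The fitness is the mean
#' MCC minus `penalty_weight * max(0, k - max_features)` where `k` is the
#' number of active features. An empty mask scores the sentinel -1.
#'
#' @param mask logical (or 0/1) vector over the feature columns of `x`.
#' @param x feature matrix (samples x features).
#' @param labels binary labels.
#' @param splits list of `list(train = idx, test = idx)` index pairs.
#' @param config a [ga_config()].
#' @return scalar fitness.
#' @export
fitness <- function(mask, x, labels, splits, config = ga_config(profile = "reduced")) {
  X <- .as_matrix(x)
  y <- .binary_labels(labels)
  .fitness_core(as.logical(mask), X, y, splits, config)
}

# Internal hot path: same contract as fitness() but with preconverted inputs
# and a direct glmnet call (single lambda, no wrapper objects) since the GA
# evaluates this tens of thousands of times.
.fitness_core <- function(mask, X, y, splits, config) {
  k <- sum(mask)
  if (k == 0L) return(-1)
  mccs <- vapply(splits, function(sp) .split_mcc(mask, X, y, sp, config),
                 numeric(1))
  mean(mccs) - config$penalty_weight * max(0, k - config$max_features)
}

# Internal: validation MCC of one elastic-net fit on one train/test split.
.split_mcc <- function(mask, X, y, sp, config) {
  k <- sum(mask)
  xtr <- X[sp$train, mask, drop = FALSE]
  if (k == 1L) xtr <- cbind(xtr, 0)
  f <- suppressWarnings(
    glmnet::glmnet(xtr, y[sp$train], family = "binomial",
                   alpha = config$l1_ratio,
                   lambda = config$en_strength / length(sp$train),
                   standardize = FALSE, thresh = 1e-7))
  beta <- as.numeric(f$beta)[seq_len(k)]
  pr <- as.numeric(f$a0) +
    as.numeric(X[sp$test, mask, drop = FALSE] %*% beta)
  .mcc_pred(as.integer(pr >= 0), y[sp$test])
}

#' Evolve feature masks by a genetic algorithm
#'
#' Generational GA over binary feature-inclusion masks: tournament selection,
#' two-point crossover, per-bit mutation whose probability decays linearly
#' across generations, and elitism. Fitness values are cached by mask, so
#' converged populations cost little. Terminates at `max_generations` or
#' when the best fitness has not improved by more than `plateau_tol` for
#' `plateau_generations` generations. Fully reproducible given
#' `config$seed`.
#'
#' @inheritParams fitness
#' @param fitness_fn optional `function(mask)` overriding the default
#'   elastic-net fitness (used for custom landscapes).
#' @return list with `best_mask` (logical), `best_fitness`, `trace` (best
#'   fitness per generation), `hall_of_fame` (top 5 distinct masks with
#'   fitness), `n_generations`, `n_evaluations`.
#' @export
ga_evolve <- function(x = NULL, labels = NULL, splits = NULL,
                      config = ga_config(profile = "reduced"),
                      fitness_fn = NULL) {
  stopifnot(inherits(config, "ga_config"))
  if (is.null(fitness_fn)) {
    if (is.null(x)) stop("either 'x'+'labels'+'splits' or 'fitness_fn' required")
    X <- .as_matrix(x)
    p <- ncol(X)
    y01 <- .binary_labels(labels)
    fitness_fn <- function(mask) .fitness_core(mask, X, y01, splits, config)
  } else {
    if (is.null(x)) stop("'x' (or a matrix giving the feature count) is required")
    p <- ncol(.as_matrix(x))
  }
  pop_n <- config$population_size
  set.seed(config$seed)
  init_prob <- if (is.null(config$init_prob)) {
    min(0.5, config$max_features / p)
  } else config$init_prob
  pop <- matrix(stats::runif(pop_n * p) < init_prob, pop_n, p)

  cache <- new.env(hash = TRUE, parent = emptyenv())
  n_eval <- 0L
  eval_pop <- function(pop) {
    vapply(seq_len(nrow(pop)), function(i) {
      key <- rawToChar(as.raw(45L + as.integer(pop[i, ])))
      got <- get0(key, envir = cache, inherits = FALSE)
      if (!is.null(got)) return(got)
      val <- fitness_fn(pop[i, ])
      assign(key, val, envir = cache)
      n_eval <<- n_eval + 1L
      val
    }, numeric(1))
  }

  # comparisons use a lexicographic tie-break toward parsimony: among masks
  # of equal fitness the one with fewer active features wins (epsilon well
  # below plateau_tol, so reported fitness is unaffected)
  eff <- function(fv, pop) fv - 1e-9 * rowSums(pop)
  fit_vals <- eval_pop(pop)
  eff_vals <- eff(fit_vals, pop)
  best_idx <- which.max(eff_vals)
  best_mask <- pop[best_idx, ]; best_fit <- fit_vals[best_idx]
  best_eff <- eff_vals[best_idx]
  trace <- best_fit
  stall <- 0L
  gens_run <- 0L
  for (g in seq_len(config$max_generations)) {
    gens_run <- g
    mut_p <- config$mutation_prob_start +
      (config$mutation_prob_end - config$mutation_prob_start) *
      (if (config$max_generations > 1) (g - 1) / (config$max_generations - 1) else 0)
    ord <- order(eff_vals, decreasing = TRUE)
    elites <- pop[ord[seq_len(config$elite_count)], , drop = FALSE]
    # tournament selection of parents
    n_child <- pop_n - config$elite_count
    pick <- function() {
      cand <- sample.int(pop_n, config$tournament_size, replace = TRUE)
      cand[which.max(eff_vals[cand])]
    }
    children <- matrix(FALSE, n_child, p)
    for (i in seq_len(ceiling(n_child / 2))) {
      pa <- pop[pick(), ]; pb <- pop[pick(), ]
      if (stats::runif(1) < config$crossover_prob && p >= 2L) {
        cut <- sort(sample.int(p - 1L, 2L, replace = TRUE))
        seg <- (cut[1] + 1L):cut[2]
        if (cut[1] < cut[2]) {
          tmp <- pa[seg]; pa[seg] <- pb[seg]; pb[seg] <- tmp
        }
      }
      children[2L * i - 1L, ] <- pa
      if (2L * i <= n_child) children[2L * i, ] <- pb
    }
    # adaptive mutation: each child mutates with prob mut_p (linear decay);
    # a mutated child flips each bit independently with prob 1/p
    mutated <- stats::runif(n_child) < mut_p
    if (any(mutated)) {
      flip <- matrix(stats::runif(sum(mutated) * p) < 1 / p, sum(mutated), p)
      children[mutated, ] <- xor(children[mutated, , drop = FALSE], flip)
    }
    pop <- rbind(elites, children)
    fit_vals <- eval_pop(pop)
    eff_vals <- eff(fit_vals, pop)
    gen_best <- max(fit_vals)
    if (gen_best > best_fit + config$plateau_tol) {
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (max(eff_vals) > best_eff) {
      best_eff <- max(eff_vals)
      best_fit <- fit_vals[which.max(eff_vals)]
      best_mask <- pop[which.max(eff_vals), ]
    }
    trace <- c(trace, best_fit)
    if (stall >= config$plateau_generations) break
  }
  # hall of fame: top distinct masks from the cache
  keys <- ls(cache)
  vals <- vapply(keys, function(k) get(k, envir = cache), numeric(1))
  top <- utils::head(order(vals, decreasing = TRUE), 5L)
  hof <- lapply(top, function(i) {
    list(mask = as.integer(charToRaw(keys[i])) - 45L == 1L,
         fitness = vals[i])
  })
  list(best_mask = as.logical(best_mask), best_fitness = best_fit,
       trace = trace, hall_of_fame = hof,
       n_generations = gens_run, n_evaluations = n_eval)
}

#' Nested cross-validation with GA feature selection and stability filtering
#'
#' Outer cross-validation (leave-one-out by default) estimates
#' generalization; within each outer training set, an inner stratified
#' k-fold loop (4 folds by default) runs one GA per inner fold, each GA
#' optimizing the cross-validated elastic-net MCC over the inner splits
#' that do not validate on its own fold. Features selected in at
#' least `stability_threshold` of the inner folds are retained, an
#' elastic-net model is retrained on the full outer-training set (with
#' preprocessing frozen on the outer-training data when `x` is a raw
#' table), and the outer held-out sample(s) are scored. Out-of-fold
#' probabilities are pooled across outer folds.
#'
#' @param x a [metabolite_table] (per-fold preprocessing) or processed
#'   matrix.
#' @param labels binary labels.
#' @param config a [ga_config()].
#' @param outer `"loo"` or an integer number of outer folds.
#' @param inner number of inner folds (default 4).
#' @param stability_threshold inner-fold selection frequency required to
#'   retain a feature (default 0.5).
#' @param covariate optional numeric per-sample covariate (e.g. GFR)
#'   z-scored on each outer-training set and forced into the final model.
#' @param seed master seed; per-fold GA seeds are derived from it.
#' @param max_missing_frac,use_creatinine preprocessing options for raw
#'   input.
#' @return a `nested_cv_result`: pooled out-of-fold `probs` and `labels`,
#'   per-feature overall `stability` frequencies, `stable_features`
#'   (frequency >= threshold), and a per-outer-fold record.
#' @export
nested_cv <- function(x, labels, config = ga_config(profile = "reduced"),
                      outer = "loo", inner = 4L, stability_threshold = 0.5,
                      covariate = NULL, seed = config$seed,
                      max_missing_frac = 0.20, use_creatinine = TRUE) {
  y <- .binary_labels(labels)
  n <- length(y)
  if (n < 8L) stop("at least 8 samples required for nested cross-validation")
  raw <- inherits(x, "metabolite_table") && !inherits(x, "processed_matrix")
  outer_id <- if (identical(outer, "loo")) seq_len(n) else {
    stratified_folds(y, as.integer(outer), derive_seed(seed, "outer_folds"))
  }
  n_outer <- max(outer_id)
  freq_list <- vector("list", n_outer)
  prob <- rep(NA_real_, n)
  fold_records <- vector("list", n_outer)
  for (o in seq_len(n_outer)) {
    tr <- which(outer_id != o); te <- which(outer_id == o)
    if (length(unique(y[tr])) < 2L) stop("an outer training fold lost a class")
    if (raw) {
      pm <- fit_preprocess(subset_samples(x, tr), max_missing_frac, use_creatinine)
      Xtr <- pm$values
      Xte <- apply_frozen(pm, subset_samples(x, te))$values
    } else {
      X <- .as_matrix(x)
      Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    }
    inner_id <- stratified_folds(y[tr], inner,
                                 derive_seed(seed, paste0("inner", o)))
    # the inner k-fold CV of this outer-training set defines k train/val
    # splits; GA run i optimizes the cross-validated MCC over the splits
    # that do NOT validate on fold i, so the k selections differ in which
    # validation folds drove them (and in RNG), giving the stability
    # frequencies their meaning. A split-level cache is shared across runs.
    cv_splits <- lapply(seq_len(inner), function(j) {
      list(train = which(inner_id != j), test = which(inner_id == j))
    })
    ytr01 <- y[tr]
    scache <- new.env(hash = TRUE, parent = emptyenv())
    split_mcc_cached <- function(j, mask, mkey) {
      key <- paste0(j, mkey)
      got <- get0(key, envir = scache, inherits = FALSE)
      if (!is.null(got)) return(got)
      v <- .split_mcc(mask, Xtr, ytr01, cv_splits[[j]], config)
      assign(key, v, envir = scache)
      v
    }
    masks <- matrix(FALSE, inner, ncol(Xtr))
    for (i in seq_len(inner)) {
      use <- setdiff(seq_len(inner), i)
      fit_i <- function(mask) {
        k <- sum(mask)
        if (k == 0L) return(-1)
        mkey <- rawToChar(as.raw(45L + as.integer(mask)))
        m <- mean(vapply(use, split_mcc_cached, numeric(1),
                         mask = mask, mkey = mkey))
        m - config$penalty_weight * max(0, k - config$max_features)
      }
      cfg_i <- config
      cfg_i$seed <- derive_seed(seed, paste0("ga_o", o, "_i", i))
      res <- ga_evolve(Xtr, fitness_fn = fit_i, config = cfg_i)
      masks[i, ] <- res$best_mask
    }
    freq <- colMeans(masks)
    retained <- which(freq >= stability_threshold)
    if (length(retained) == 0L) retained <- which.max(freq)
    cn <- colnames(Xtr)
    if (is.null(cn)) cn <- paste0("F", seq_len(ncol(Xtr)))
    freq_list[[o]] <- stats::setNames(freq, cn)
    Xtr_m <- Xtr[, retained, drop = FALSE]
    Xte_m <- Xte[, retained, drop = FALSE]
    if (!is.null(covariate)) {
      mu <- mean(covariate[tr]); sdv <- stats::sd(covariate[tr])
      if (sdv == 0) sdv <- 1
      Xtr_m <- cbind(Xtr_m, covariate = (covariate[tr] - mu) / sdv)
      Xte_m <- cbind(Xte_m, covariate = (covariate[te] - mu) / sdv)
    }
    m <- en_logistic_fit(Xtr_m, y[tr], l1_ratio = config$l1_ratio,
                         strength = config$en_strength)
    prob[te] <- predict(m, Xte_m)
    fold_records[[o]] <- list(train = tr, test = te,
                              inner_masks = masks, frequency = freq,
                              retained = colnames(Xtr)[retained])
  }
  # features not retained by a fold's missingness filter count as unselected
  all_feats <- unique(unlist(lapply(freq_list, names)))
  stability <- stats::setNames(numeric(length(all_feats)), all_feats)
  for (fr in freq_list) stability[names(fr)] <- stability[names(fr)] + fr
  stability <- stability / n_outer
  structure(list(probs = prob, labels = y,
                 stability = stability,
                 stable_features = names(stability)[stability >= stability_threshold],
                 folds = fold_records,
                 config = config, outer = outer, inner = inner),
            class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat("<nested_cv_result> ", length(x$probs), " pooled out-of-fold predictions\n",
      sep = "")
  cat("  stable features (freq >= 0.5):",
      paste(x$stable_features, collapse = ", "), "\n")
  invisible(x)
}

#' Bootstrap confidence intervals for a classifier metric suite
#'
#' Point estimates of AUC, accuracy, F1, sensitivity, specificity, MCC and
#' Brier score from the unresampled (probability, label) pairs, with
#' percentile 95% CIs from nonparametric bootstrap resampling of the pairs.
#' Replicates that lose a class are redrawn.
#'
#' @param probs out-of-fold predicted probabilities.
#' @param labels 0/1 labels (or two-level factor).
#' @param n_boot number of bootstrap replicates (the study protocol uses
#'   2000).
#' @param threshold classification threshold for the thresholded metrics
#'   (default 0.5).
#' @param seed integer seed.
#' @return a data.frame (class `metric_bundle`) with columns metric,
#'   estimate, ci_low, ci_high.
#' @export
bootstrap_metrics <- function(probs, labels, n_boot = 2000L, threshold = 0.5,
                              seed = 1L) {
  y <- if (all(labels %in% c(0, 1))) as.integer(labels) else .binary_labels(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  stopifnot(length(probs) == length(y), n_boot >= 1L)
  one <- function(pr, yy) {
    pred <- as.integer(pr >= threshold)
    tp <- sum(pred == 1 & yy == 1); fp <- sum(pred == 1 & yy == 0)
    tn <- sum(pred == 0 & yy == 0); fn <- sum(pred == 0 & yy == 1)
    sens <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
    c(auc = .auc(yy, pr), acc = (tp + tn) / length(yy), f1 = f1,
      sens = sens, spec = spec, mcc = mcc(tp, fp, tn, fn),
      brier = brier(pr, yy))
  }
  point <- one(probs, y)
  set.seed(derive_seed(seed, "bootstrap_metrics"))
  n <- length(y)
  reps <- matrix(NA_real_, n_boot, length(point),
                 dimnames = list(NULL, names(point)))
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2L) break
    }
    reps[b, ] <- one(probs[idx], y[idx])
  }
  ci <- apply(reps, 2, stats::quantile, probs = c(0.025, 0.975), type = 7)
  out <- data.frame(metric = names(point),
                    estimate = as.numeric(point),
                    ci_low = as.numeric(ci[1, ]),
                    ci_high = as.numeric(ci[2, ]),
                    row.names = NULL)
  class(out) <- c("metric_bundle", class(out))
  out
}
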