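#' Build a pipeline run configuration
#'
#' Collects every knob of the end-to-end analysis into one validated list.
#' Can also be loaded from a YAML file with [read_run_config()]. The
#' `"full"` profile uses the complete study protocol (GA population 3000, 60
#' generations, leave-one-out outer CV, 2000 permutations/bootstraps) and is
#' expensive; the `"reduced"` profile is the desk-scale configuration.
#'
#' @param contrast character vector of the two groups to discriminate
#'   (default `c("DM2", "DN")`; the second entry is the positive class).
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it (mandatory).
#' @param profile `"reduced"` or `"full"`.
#' @param max_missing_frac,use_creatinine preprocessing options.
#' @param n_permutations PLS-DA permutation count (profile default: 2000
#'   full / 200 reduced).
#' @param mccv_splits Monte-Carlo CV split count (500 full / 100 reduced).
#' @param n_boot bootstrap replicate count (2000 full / 500 reduced).
#' @param outer_folds outer CV for the GA engine (`"loo"` full / 5 reduced).
#' @param ga GA settings, a [ga_config()].
#' @param gmt optional path to a GMT file for enrichment.
#' @param covariate name of a metadata column forced into the GA-EN model
#'   alongside the selected metabolites (default `"GFR"`; `NULL` disables).
#' @return a `run_config` list.
#' @export
run_config <- function(contrast = c("DM2", "DN"), seed = 1L,
                       profile = c("reduced", "full"),
                       max_missing_frac = 0.20, use_creatinine = TRUE,
                       n_permutations = NULL, mccv_splits = NULL,
                       n_boot = NULL, outer_folds = NULL,
                       ga = NULL, gmt = NULL, covariate = "GFR") {
  profile <- match.arg(profile)
  if (is.null(seed)) stop("a seed is mandatory")
  full <- profile == "full"
  if (full) {
    message("profile 'full' uses the complete study protocol; ",
            "expect a long runtime on a single CPU")
  }
  cfg <- list(contrast = contrast, seed = as.integer(seed), profile = profile,
              max_missing_frac = max_missing_frac,
              use_creatinine = use_creatinine,
              n_permutations = if (is.null(n_permutations)) {
                if (full) 2000L else 200L } else as.integer(n_permutations),
              mccv_splits = if (is.null(mccv_splits)) {
                if (full) 500L else 100L } else as.integer(mccv_splits),
              n_boot = if (is.null(n_boot)) {
                if (full) 2000L else 500L } else as.integer(n_boot),
              outer_folds = if (is.null(outer_folds)) {
                if (full) "loo" else 5L } else outer_folds,
              ga = if (is.null(ga)) {
                ga_config(profile = if (full) "full" else "reduced",
                          seed = as.integer(seed))
              } else ga,
              gmt = gmt, covariate = covariate)
  if (length(cfg$contrast) != 2L) stop("contrast must name exactly two groups")
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()];
#'   GA settings go under a `ga:` mapping.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ga <- if (!is.null(y$ga)) do.call(ga_config, y$ga) else NULL
  args <- y[setdiff(names(y), "ga")]
  args$ga <- ga
  do.call(run_config, args)
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes preprocessing, univariate statistics (Kruskal-Wallis across all
#' groups, Mann-Whitney on the configured contrast, Spearman correlation of
#' metabolites with GFR), PLS-DA with permutation validation, the LASSO +
#' stepwise panel with 10-fold CV and Monte-Carlo CV ROC, the GA +
#' elastic-net nested-CV engine with bootstrap metrics, and (when a GMT is
#' configured) over-representation analysis of the stable GA features. All
#' artifacts are written to `out_dir` as CSV/JSON with the seed recorded;
#' rerunning with the same configuration reproduces them byte-for-byte.
#'
#' @param data list with `table` (a [metabolite_table]) and `metadata`
#'   (data.frame with sample_id, group, and any covariates), e.g. from
#'   [generate_dataset()] or [read_tables()].
#' @param config a [run_config()].
#' @param out_dir output directory; `NULL` skips writing.
#' @return a named list of stage results, invisibly when writing.
#' @export
run_pipeline <- function(data, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  table <- data$table; metadata <- data$metadata
  groups <- metadata$group
  if (!all(config$contrast %in% groups)) {
    stop("contrast group(s) absent from the data: ",
         paste(setdiff(config$contrast, groups), collapse = ", "))
  }
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  say("seed: ", config$seed, "; profile: ", config$profile)

  ## preprocessing on the full cohort (exploratory stages)
  pm <- fit_preprocess(table, config$max_missing_frac, config$use_creatinine)
  rr <- attr(pm, "removal_report")
  say("preprocess: ", sum(!rr$kept), " metabolite(s) removed by the ",
      100 * config$max_missing_frac, "% missingness filter; ",
      sum(rr$kept), " retained")

  ## univariate statistics
  kw <- test_k_groups(pm, groups)
  ci <- which(groups %in% config$contrast)
  sub_tab <- subset_samples(table, ci)
  sub_groups <- factor(groups[ci], levels = config$contrast)
  pm_sub <- fit_preprocess(sub_tab, config$max_missing_frac, config$use_creatinine)
  mw <- test_two_groups(pm_sub, sub_groups, config$contrast)
  corr <- NULL
  if (!is.null(config$covariate) && config$covariate %in% names(metadata)) {
    corr <- correlate_with_covariate(pm, metadata[[config$covariate]],
                                     covariate_name = config$covariate)
  }
  say("univariate: ", sum(kw$q_value < 0.05), " metabolite(s) with q < 0.05 (",
      nlevels(factor(groups)), "-group Kruskal-Wallis); ",
      sum(mw$q_value < 0.05), " in the ", paste(config$contrast, collapse = " vs "),
      " Mann-Whitney contrast")
  clinical <- summarize_clinical(metadata[setdiff(names(metadata), "sample_id")])

  ## PLS-DA with permutation validation (three-group model)
  ncomp <- choose_components(pm, groups, folds = 7L,
                             seed = derive_seed(config$seed, "plsda_comp"))
  pls <- fit_plsda(pm, groups, n_components = ncomp)
  perm <- permutation_test(pm, groups, n_perm = config$n_permutations,
                           n_components = ncomp, folds = 7L,
                           seed = derive_seed(config$seed, "plsda"))
  say("plsda: ", ncomp, " component(s), Q2 = ",
      format(perm$observed, digits = 4), ", permutation p = ",
      format(perm$p_value, digits = 4), " (", config$n_permutations, " permutations)")

  ## LASSO panel on the contrast (leakage-free CV on the raw table)
  y_bin <- factor(sub_groups, levels = config$contrast)
  sel <- lasso_select(pm_sub, y_bin, seed = derive_seed(config$seed, "lasso"))
  panel <- if (nrow(sel)) {
    suppressWarnings(stepwise_refit(pm_sub, y_bin, sel$feature_id))
  } else NULL
  cv_roc <- kfold_cv_auc(sub_tab, y_bin, model = panel, folds = 10L,
                         seed = derive_seed(config$seed, "lasso_cv"),
                         max_missing_frac = config$max_missing_frac,
                         use_creatinine = config$use_creatinine)
  mccv <- mccv_roc(sub_tab, y_bin, model = panel,
                   n_splits = config$mccv_splits,
                   seed = derive_seed(config$seed, "mccv"),
                   max_missing_frac = config$max_missing_frac,
                   use_creatinine = config$use_creatinine)
  say("lasso_panel: ", nrow(sel), " feature(s) at lambda.min; panel [",
      if (!is.null(panel)) paste(panel$feature_ids, collapse = ", ") else "",
      "]; 10-fold CV AUC = ", format(cv_roc$auc, digits = 4),
      "; MCCV AUC = ", format(mccv$auc, digits = 4),
      " (95% CI ", format(mccv$ci_low, digits = 4), "-",
      format(mccv$ci_high, digits = 4), ")")

  ## GA + elastic-net nested CV with bootstrap metrics
  covar <- if (!is.null(config$covariate) &&
               config$covariate %in% names(metadata)) {
    metadata[[config$covariate]][ci]
  } else NULL
  ncv <- nested_cv(sub_tab, y_bin, config = config$ga,
                   outer = config$outer_folds, inner = 4L,
                   covariate = covar,
                   seed = derive_seed(config$seed, "nested_cv"),
                   max_missing_frac = config$max_missing_frac,
                   use_creatinine = config$use_creatinine)
  metrics <- bootstrap_metrics(ncv$probs, ncv$labels, n_boot = config$n_boot,
                               seed = derive_seed(config$seed, "boot"))
  say("ga_en: stable features [", paste(ncv$stable_features, collapse = ", "),
      "]; pooled out-of-fold AUC = ",
      format(metrics$estimate[metrics$metric == "auc"], digits = 4))

  ## enrichment of the stable GA features, if sets are configured
  enr <- NULL
  if (!is.null(config$gmt)) {
    sets <- read_gmt(config$gmt)
    universe <- pm_sub$metabolite_ids
    selected <- intersect(ncv$stable_features, universe)
    if (length(selected)) {
      enr <- ora(selected, sets, universe)
      say("enrichment: ", sum(enr$q_value < 0.05), " set(s) with q < 0.05")
    } else say("enrichment: skipped (no stable metabolite features)")
  }

  results <- list(processed = pm, removal_report = rr, clinical = clinical,
                  kruskal = kw, mann_whitney = mw, correlations = corr,
                  plsda = pls, plsda_cv_q2 = perm$observed,
                  plsda_permutation = perm,
                  lasso_selected = sel, panel = panel,
                  cv_roc = cv_roc, mccv = mccv,
                  nested_cv = ncv, metrics = metrics,
                  enrichment = enr, log = log_lines, config = config)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wcsv <- function(df, name) {
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], function(v) format(v, digits = 10))
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                       quote = FALSE)
    }
    wcsv(kw, "kruskal_wallis.csv")
    wcsv(mw, "mann_whitney.csv")
    if (!is.null(corr)) wcsv(corr, "correlations.csv")
    wcsv(data.frame(metabolite_id = names(pls$vip), vip = pls$vip),
         "plsda_vip.csv")
    wcsv(metrics, "ga_en_metrics.csv")
    if (!is.null(enr)) wcsv(enr, "enrichment.csv")
    panel_json <- list(
      seed = config$seed, profile = config$profile,
      contrast = config$contrast,
      lasso_panel = if (!is.null(panel)) {
        list(features = panel$feature_ids, intercept = panel$intercept,
             coefficients = panel$coefficients)
      } else NULL,
      cv_auc = cv_roc$auc, mccv_auc = mccv$auc,
      mccv_ci = c(mccv$ci_low, mccv$ci_high),
      plsda_q2 = perm$observed, plsda_permutation_p = perm$p_value,
      ga_stable_features = ncv$stable_features,
      ga_stability = as.list(ncv$stability[ncv$stability > 0]))
    jsonlite::write_json(panel_json, file.path(out_dir, "panel.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    return(invisible(results))
  }
  results
}
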