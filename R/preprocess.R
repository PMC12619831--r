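#' Remove metabolites with excessive missingness
#'
#' Metabolites with strictly more than `max_missing_frac` of their values
#' missing (below LOD) are excluded; a metabolite missing exactly the
#' threshold fraction is retained. The sample axis is unchanged.
#'
#' @param table a [metabolite_table].
#' @param max_missing_frac maximum tolerated missing fraction in `[0, 1)`;
#'   default 0.20.
#' @return the filtered `metabolite_table`, with a `removal_report`
#'   data.frame attached as an attribute (metabolite, missing_frac, kept).
#' @export
filter_missing <- function(table, max_missing_frac = 0.20) {
  if (inherits(table, "processed_matrix")) .check_chain(table, "filter_missing")
  stopifnot(inherits(table, "metabolite_table"))
  if (!is.numeric(max_missing_frac) || max_missing_frac < 0 || max_missing_frac >= 1) {
    stop("'max_missing_frac' must be in [0, 1)")
  }
  .check_chain(table, "filter_missing")
  frac <- colMeans(is.na(table$values))
  keep <- frac <= max_missing_frac
  if (!any(keep)) {
    stop("all metabolites exceed the missingness threshold (",
         max_missing_frac, "); review the threshold or the input data")
  }
  report <- data.frame(metabolite = table$metabolite_ids,
                       missing_frac = as.numeric(frac),
                       kept = as.logical(keep), row.names = NULL)
  out <- table
  out$values <- table$values[, keep, drop = FALSE]
  out$lod <- table$lod[keep]
  out$metabolite_ids <- table$metabolite_ids[keep]
  out$steps_applied <- c(table$steps_applied, "filter_missing")
  attr(out, "removal_report") <- report
  out
}

#' Impute below-LOD values with one fifth of the minimum positive value
#'
#' Left-censored imputation: each missing entry of metabolite *j* is replaced
#' by `min(positive observed values of j) / 5`, computed over all samples in
#' the given table. Observed entries are untouched. The per-metabolite minima
#' are recorded so the identical imputation can be frozen and re-applied to
#' new data (see [apply_frozen()]).
#'
#' @param table a [metabolite_table].
#' @return the imputed `metabolite_table` (no missing values remain).
#' @export
impute_lod <- function(table) {
  if (inherits(table, "processed_matrix")) .check_chain(table, "impute_lod")
  stopifnot(inherits(table, "metabolite_table"))
  .check_chain(table, "impute_lod")
  v <- table$values
  minpos <- apply(v, 2, function(col) {
    pos <- col[!is.na(col) & col > 0]
    if (length(pos) == 0L) NA_real_ else min(pos)
  })
  bad <- which(is.na(minpos) & colSums(is.na(v)) > 0)
  if (length(bad)) {
    stop("metabolite(s) with missing values but no positive observation: ",
         paste(table$metabolite_ids[bad], collapse = ", "))
  }
  for (j in which(colSums(is.na(v)) > 0)) {
    v[is.na(v[, j]), j] <- minpos[j] / 5
  }
  out <- table
  out$values <- v
  out$impute_minima <- stats::setNames(as.numeric(minpos), table$metabolite_ids)
  out$steps_applied <- c(table$steps_applied, "impute_lod")
  out
}

#' Normalize concentrations by urinary creatinine
#'
#' Divides each sample's concentrations by its urinary creatinine, converting
#' µM concentrations into µmol/mmol creatinine and correcting for urine
#' dilution.
#'
#' @param table a [metabolite_table] with no remaining missing values.
#' @return the normalized `metabolite_table`.
#' @export
creatinine_normalize <- function(table) {
  if (inherits(table, "processed_matrix")) .check_chain(table, "creatinine_normalize")
  stopifnot(inherits(table, "metabolite_table"))
  .check_chain(table, "creatinine_normalize")
  if (anyNA(table$values)) {
    stop("missing values remain; impute before creatinine normalization")
  }
  bad <- which(!is.finite(table$creatinine) | table$creatinine <= 0)
  if (length(bad)) {
    stop("nonpositive creatinine for sample(s): ",
         paste(table$sample_ids[bad], collapse = ", "))
  }
  out <- table
  out$values <- table$values / table$creatinine
  out$steps_applied <- c(table$steps_applied, "creatinine_normalize")
  out
}

#' Natural log transformation
#'
#' @param x a [metabolite_table] (no missing values) or `processed_matrix`.
#' @return a `processed_matrix` with log-transformed values.
#' @export
log_transform <- function(x) {
  .check_chain(x, "log_transform")
  v <- .as_matrix(x)
  if (anyNA(v)) stop("missing values remain; impute before log transformation")
  bad <- which(v <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("nonpositive entry at sample '", rownames(v)[bad[1, 1]],
         "', metabolite '", colnames(v)[bad[1, 2]], "'")
  }
  out <- .as_processed(x)
  out$values <- log(v)
  out$steps_applied <- c(out$steps_applied, "log_transform")
  out
}

#' Pareto scaling
#'
#' Mean-centers each metabolite and divides by the square root of its sample
#' standard deviation (denominator `n - 1`), damping the dominance of
#' high-variance metabolites while keeping some of the original variance
#' structure. Constant metabolites map to all-zero columns. The per-column
#' `(mean, sd)` are stored in `scaling_params` so the identical scaling can be
#' frozen for new data.
#'
#' @param x a `processed_matrix` (or [metabolite_table] without missing
#'   values) with at least two samples.
#' @return a `processed_matrix`; each column has mean 0 and variance equal to
#'   the original column standard deviation.
#' @export
pareto_scale <- function(x) {
  .check_chain(x, "pareto_scale")
  v <- .as_matrix(x)
  if (nrow(v) < 2L) stop("Pareto scaling needs at least 2 samples")
  if (anyNA(v)) stop("missing values remain; impute before scaling")
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  scl <- ifelse(sdv > 0, sqrt(sdv), 1)
  sv <- sweep(sweep(v, 2, mu, "-"), 2, scl, "/")
  sv[, sdv == 0] <- 0
  out <- .as_processed(x)
  out$values <- sv
  out$scaling_params <- data.frame(metabolite = colnames(v),
                                   mean = as.numeric(mu),
                                   sd = as.numeric(sdv), row.names = NULL)
  out$steps_applied <- c(out$steps_applied, "pareto_scale")
  out
}

# Internal: promote a metabolite_table to a processed_matrix, carrying over
# provenance needed to freeze the transform.
.as_processed <- function(x) {
  if (inherits(x, "processed_matrix")) return(x)
  stopifnot(inherits(x, "metabolite_table"))
  structure(list(values = x$values,
                 sample_ids = x$sample_ids,
                 metabolite_ids = x$metabolite_ids,
                 steps_applied = x$steps_applied,
                 impute_minima = x$impute_minima,
                 scaling_params = NULL),
            class = "processed_matrix")
}

#' Fit the full preprocessing chain
#'
#' Runs missingness filtering, LOD imputation, optional creatinine
#' normalization, natural log transformation and Pareto scaling in the
#' canonical order, recording every parameter (retained metabolites,
#' imputation minima, scaling means and standard deviations) so the identical
#' transform can be re-applied to held-out data with [apply_frozen()] —
#' the mechanism that keeps cross-validation leakage-free.
#'
#' @param table a [metabolite_table].
#' @param max_missing_frac missingness threshold passed to [filter_missing()].
#' @param use_creatinine logical; divide by urinary creatinine (default TRUE).
#' @return a `processed_matrix` whose `frozen` element holds the learned
#'   parameters.
#' @export
fit_preprocess <- function(table, max_missing_frac = 0.20, use_creatinine = TRUE) {
  stopifnot(inherits(table, "metabolite_table"))
  t1 <- filter_missing(table, max_missing_frac)
  t2 <- impute_lod(t1)
  t3 <- if (use_creatinine) creatinine_normalize(t2) else t2
  pm <- pareto_scale(log_transform(t3))
  pm$frozen <- list(metabolite_ids = t2$metabolite_ids,
                    impute_minima = t2$impute_minima,
                    use_creatinine = use_creatinine,
                    mean = stats::setNames(pm$scaling_params$mean,
                                           pm$scaling_params$metabolite),
                    sd = stats::setNames(pm$scaling_params$sd,
                                         pm$scaling_params$metabolite))
  attr(pm, "removal_report") <- attr(t1, "removal_report")
  pm
}

#' Apply a frozen preprocessing transform to new samples
#'
#' Re-applies imputation minima, creatinine division, log transformation and
#' Pareto scaling parameters learned on training data, without re-estimating
#' anything from the new samples.
#'
#' @param frozen either a `processed_matrix` returned by [fit_preprocess()]
#'   or its `frozen` parameter list.
#' @param table a [metabolite_table] of new samples containing (at least) the
#'   retained metabolites.
#' @return a `processed_matrix` in the training data's scaled space.
#' @export
apply_frozen <- function(frozen, table) {
  if (inherits(frozen, "processed_matrix")) frozen <- frozen$frozen
  if (is.null(frozen)) stop("no frozen parameters; use fit_preprocess() first")
  stopifnot(inherits(table, "metabolite_table"))
  ids <- frozen$metabolite_ids
  missing_ids <- setdiff(ids, table$metabolite_ids)
  if (length(missing_ids)) {
    stop("new table lacks retained metabolite(s): ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  v <- table$values[, ids, drop = FALSE]
  for (j in seq_along(ids)) {
    if (anyNA(v[, j])) {
      if (is.na(frozen$impute_minima[ids[j]])) {
        stop("no training imputation minimum for metabolite ", ids[j])
      }
      v[is.na(v[, j]), j] <- frozen$impute_minima[ids[j]] / 5
    }
  }
  if (isTRUE(frozen$use_creatinine)) v <- v / table$creatinine
  if (any(v <= 0)) stop("nonpositive value after imputation; cannot log-transform")
  v <- log(v)
  scl <- ifelse(frozen$sd[ids] > 0, sqrt(frozen$sd[ids]), 1)
  v <- sweep(sweep(v, 2, frozen$mean[ids], "-"), 2, scl, "/")
  v[, frozen$sd[ids] == 0] <- 0
  structure(list(values = v,
                 sample_ids = table$sample_ids,
                 metabolite_ids = ids,
                 steps_applied = .chain_order,
                 impute_minima = frozen$impute_minima,
                 scaling_params = data.frame(metabolite = ids,
                                             mean = as.numeric(frozen$mean[ids]),
                                             sd = as.numeric(frozen$sd[ids]),
                                             row.names = NULL),
                 frozen = frozen),
            class = "processed_matrix")
}
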