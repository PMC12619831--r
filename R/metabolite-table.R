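#' Construct a metabolite concentration table
#'
#' The central input container: a samples x metabolites matrix of absolute
#' urinary concentrations (µM) with `NA` marking values below the limit of
#' detection, a per-metabolite LOD (µM), and per-sample urinary creatinine
#' (mM) used for dilution correction.
#'
#' @param values numeric matrix, samples in rows, metabolites in columns;
#'   `NA` entries are below-LOD (missing) measurements; present values must
#'   be nonnegative.
#' @param lod numeric vector of per-metabolite limits of detection (µM),
#'   length `ncol(values)`, nonnegative.
#' @param creatinine numeric vector of per-sample urinary creatinine (mM),
#'   length `nrow(values)`, strictly positive.
#' @param sample_ids,metabolite_ids optional identifiers; default to the
#'   dimnames of `values`.
#' @return an object of class `metabolite_table`.
#' @export
metabolite_table <- function(values, lod = NULL, creatinine = NULL,
                             sample_ids = rownames(values),
                             metabolite_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  n <- nrow(values); p <- ncol(values)
  if (n == 0L || p == 0L) stop("'values' must have at least one sample and one metabolite")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("M", seq_len(p))
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  if (anyDuplicated(metabolite_ids)) stop("duplicated metabolite ids")
  if (length(sample_ids) != n) stop("sample_ids length mismatch")
  if (length(metabolite_ids) != p) stop("metabolite_ids length mismatch")
  if (any(values < 0, na.rm = TRUE)) stop("present concentrations must be >= 0")
  if (is.null(lod)) lod <- rep(0, p)
  if (length(lod) != p || any(!is.finite(lod)) || any(lod < 0)) {
    stop("'lod' must be a nonnegative vector of length ncol(values)")
  }
  if (is.null(creatinine)) creatinine <- rep(1, n)
  if (length(creatinine) != n || any(!is.finite(creatinine)) || any(creatinine <= 0)) {
    bad <- which(!is.finite(creatinine) | creatinine <= 0)
    stop("creatinine must be > 0 for all samples; offending sample(s): ",
         paste(sample_ids[utils::head(bad, 5)], collapse = ", "))
  }
  dimnames(values) <- list(sample_ids, metabolite_ids)
  structure(list(values = values,
                 lod = stats::setNames(as.numeric(lod), metabolite_ids),
                 creatinine = stats::setNames(as.numeric(creatinine), sample_ids),
                 sample_ids = sample_ids,
                 metabolite_ids = metabolite_ids,
                 steps_applied = character(0)),
            class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat("<metabolite_table> ", length(x$sample_ids), " samples x ",
      length(x$metabolite_ids), " metabolites\n", sep = "")
  cat("  missing entries: ", sum(is.na(x$values)), " (",
      format(100 * mean(is.na(x$values)), digits = 3), "%)\n", sep = "")
  if (length(x$steps_applied)) {
    cat("  steps applied:", paste(x$steps_applied, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
dim.metabolite_table <- function(x) dim(x$values)

#' @export
print.processed_matrix <- function(x, ...) {
  cat("<processed_matrix> ", nrow(x$values), " samples x ",
      ncol(x$values), " metabolites\n", sep = "")
  cat("  steps applied:", paste(x$steps_applied, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.processed_matrix <- function(x) dim(x$values)

# Canonical preprocessing order; later steps may never precede earlier ones.
.chain_order <- c("filter_missing", "impute_lod", "creatinine_normalize",
                  "log_transform", "pareto_scale")

# Internal: validate that `step` may be applied next given steps already done.
.check_chain <- function(obj, step) {
  done <- obj$steps_applied
  if (step %in% done) stop("step '", step, "' already applied")
  pos <- match(step, .chain_order)
  later <- intersect(done, .chain_order[seq_along(.chain_order) > pos])
  if (length(later)) {
    stop("out-of-order preprocessing: '", step, "' requested after '",
         later[1], "'")
  }
  invisible(TRUE)
}
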