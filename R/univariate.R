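#' Per-metabolite two-group Mann-Whitney U tests
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test for every metabolite,
#' comparing the two requested groups, with Benjamini-Hochberg q-values
#' computed across all tested metabolites. Exact p-values are used where the
#' implementation permits (no ties, moderate n), the tie-corrected normal
#' approximation otherwise.
#'
#' @param x a `processed_matrix`, [metabolite_table] or numeric matrix
#'   (samples x metabolites).
#' @param labels group label per sample.
#' @param groups character vector of the two group levels to compare.
#' @return data.frame with metabolite_id, test_name, statistic (U), p_value,
#'   q_value and direction (sign of the median difference, first group minus
#'   second).
#' @export
test_two_groups <- function(x, labels, groups = NULL) {
  v <- .as_matrix(x)
  labels <- as.factor(labels)
  if (is.null(groups)) {
    if (nlevels(labels) != 2L) stop("specify 'groups' when labels have more than two levels")
    groups <- levels(labels)
  }
  stopifnot(length(groups) == 2L)
  ia <- labels == groups[1]; ib <- labels == groups[2]
  if (sum(ia) < 2L || sum(ib) < 2L) {
    stop("each group needs at least 2 samples (", groups[1], ": ", sum(ia),
         ", ", groups[2], ": ", sum(ib), ")")
  }
  res <- apply(v, 2, function(col) {
    wt <- suppressWarnings(stats::wilcox.test(col[ia], col[ib],
                                              alternative = "two.sided"))
    # fully tied (zero-variance) data carry no evidence: p = 1
    p <- if (is.finite(wt$p.value)) wt$p.value else 1
    c(stat = unname(wt$statistic), p = p,
      dir = sign(stats::median(col[ia]) - stats::median(col[ib])))
  })
  p <- pmin(res["p", ], 1)
  data.frame(metabolite_id = colnames(v),
             test_name = "mann_whitney_u",
             statistic = as.numeric(res["stat", ]),
             p_value = as.numeric(p),
             q_value = bh_fdr(as.numeric(p)),
             direction = as.numeric(res["dir", ]),
             row.names = NULL)
}

#' Per-metabolite Kruskal-Wallis tests across all groups
#'
#' @inheritParams test_two_groups
#' @return data.frame with metabolite_id, test_name, statistic (H), df,
#'   p_value, q_value.
#' @export
test_k_groups <- function(x, labels) {
  v <- .as_matrix(x)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("at least 2 groups required")
  if (any(table(labels) < 2L)) stop("each group needs at least 2 samples")
  res <- apply(v, 2, function(col) {
    kt <- stats::kruskal.test(col, labels)
    c(stat = unname(kt$statistic), df = unname(kt$parameter),
      p = if (is.finite(kt$p.value)) kt$p.value else 1)
  })
  p <- as.numeric(res["p", ])
  data.frame(metabolite_id = colnames(v),
             test_name = "kruskal_wallis",
             statistic = as.numeric(res["stat", ]),
             df = as.numeric(res["df", ]),
             p_value = p,
             q_value = bh_fdr(p),
             row.names = NULL)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH q-values; a thin, named wrapper over [stats::p.adjust()] so the
#' adjustment used throughout the package is a single auditable call.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Correlate metabolites with a clinical covariate
#'
#' Spearman rank correlation of every metabolite with a numeric covariate
#' (e.g. GFR), matching the nonparametric stance of the rest of the
#' pipeline. Exact p-values are used for small n without ties, the
#' t-approximation otherwise.
#'
#' @inheritParams test_two_groups
#' @param covariate numeric vector, one finite value per sample.
#' @param covariate_name label recorded in the output.
#' @param method correlation method, `"spearman"` (default) or `"pearson"`.
#' @return data.frame with metabolite_id, covariate, rho, p_value.
#' @export
correlate_with_covariate <- function(x, covariate, covariate_name = "covariate",
                                     method = c("spearman", "pearson")) {
  method <- match.arg(method)
  v <- .as_matrix(x)
  if (length(covariate) != nrow(v) || any(!is.finite(covariate))) {
    stop("'covariate' must be finite and of length nrow(x)")
  }
  res <- apply(v, 2, function(col) {
    ct <- suppressWarnings(stats::cor.test(col, covariate, method = method))
    c(rho = unname(ct$estimate), p = ct$p.value)
  })
  data.frame(metabolite_id = colnames(v),
             covariate = covariate_name,
             rho = as.numeric(res["rho", ]),
             p_value = as.numeric(res["p", ]),
             row.names = NULL)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed skewness and kurtosis statistics into the K²
#' omnibus statistic, referred to a chi-squared distribution with 2 degrees
#' of freedom. Used descriptively in [summarize_clinical()] to flag
#' non-normal variables; inference in the pipeline is nonparametric
#' regardless.
#'
#' @param x numeric vector, n >= 8.
#' @return list with statistic (K2) and p_value.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) return(list(statistic = NA_real_, p_value = NA_real_))
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 == 0) return(list(statistic = NA_real_, p_value = NA_real_))
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * aa)) -
           ((1 - 2 / aa) / (1 + xx * sqrt(2 / (aa - 4))))^(1/3)) /
    sqrt(2 / (9 * aa))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

#' Summarize clinical metadata by group
#'
#' Numeric variables are reported as mean ± sd per group with a
#' Kruskal-Wallis p-value (a D'Agostino-Pearson normality p is attached for
#' reference); categorical variables as count (%) with a chi-squared test
#' for trend across the ordered groups (two-level variables) or a standard
#' chi-squared test otherwise.
#'
#' @param metadata data.frame with a `group` column plus clinical variables.
#' @param group_col name of the grouping column.
#' @return data.frame with one row per variable: per-group summary strings,
#'   the test used, its p-value, and the normality p for numeric variables.
#' @export
summarize_clinical <- function(metadata, group_col = "group") {
  stopifnot(is.data.frame(metadata), group_col %in% names(metadata))
  grp <- factor(metadata[[group_col]])
  vars <- setdiff(names(metadata), c(group_col, "sample_id"))
  rows <- lapply(vars, function(vn) {
    v <- metadata[[vn]]
    if (all(is.na(v))) {
      return(data.frame(variable = vn, test = NA_character_,
                        p_value = NA_real_, normality_p = NA_real_,
                        t(stats::setNames(rep(NA_character_, nlevels(grp)),
                                          levels(grp))),
                        check.names = FALSE))
    }
    if (is.numeric(v)) {
      summ <- vapply(levels(grp), function(g) {
        vi <- v[grp == g]
        sprintf("%.2f ± %.2f", mean(vi, na.rm = TRUE),
                stats::sd(vi, na.rm = TRUE))
      }, character(1))
      p <- tryCatch(stats::kruskal.test(v, grp)$p.value, error = function(e) NA_real_)
      np <- dagostino_pearson(v)$p_value
      test <- "kruskal_wallis"
    } else {
      v <- factor(v)
      if (nlevels(v) == 2L) {
        events <- tapply(v == levels(v)[2], grp, sum, na.rm = TRUE)
        totals <- tapply(!is.na(v), grp, sum)
        p <- tryCatch(suppressWarnings(
          stats::prop.trend.test(events, totals)$p.value),
          error = function(e) NA_real_)
        test <- "chi2_trend"
      } else {
        p <- tryCatch(suppressWarnings(stats::chisq.test(table(grp, v))$p.value),
                      error = function(e) NA_real_)
        test <- "chi2"
      }
      summ <- vapply(levels(grp), function(g) {
        vi <- v[grp == g]
        lv <- levels(v)[nlevels(v)]
        sprintf("%d (%.0f%%)", sum(vi == lv, na.rm = TRUE),
                100 * mean(vi == lv, na.rm = TRUE))
      }, character(1))
      np <- NA_real_
    }
    out <- data.frame(variable = vn, test = test, p_value = p,
                      normality_p = np, t(summ), check.names = FALSE)
    out
  })
  do.call(rbind, rows)
}
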