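# Builders for small in-memory fixtures used across the test files.

# A tiny metabolite table with controllable missingness.
make_table <- function(values, lod = NULL, creatinine = NULL) {
  metabolite_table(values, lod = lod, creatinine = creatinine)
}

# Random positive concentration table, optionally with missing entries.
random_table <- function(n = 12, p = 6, missing_frac = 0, seed = 1) {
  set.seed(seed)
  v <- matrix(rlnorm(n * p, 1, 0.8), n, p,
              dimnames = list(paste0("S", seq_len(n)), paste0("M", seq_len(p))))
  if (missing_frac > 0) {
    idx <- which(runif(n * p) < missing_frac)
    v[idx] <- NA_real_
  }
  metabolite_table(v, creatinine = rlnorm(n, log(10), 0.3))
}

# Binary-class matrix with planted informative columns: class shifts the
# first `n_signal` columns by `delta` standard deviations.
signal_matrix <- function(n_per_class = 20, p = 30, n_signal = 1, delta = 2,
                          seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n_per_class)
  x <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p,
              dimnames = list(NULL, paste0("F", sprintf("%02d", seq_len(p)))))
  for (j in seq_len(n_signal)) x[y == 1, j] <- x[y == 1, j] + delta
  list(x = x, y = y)
}

# Stratified train/validation splits in the list form fitness() expects.
cv_split_list <- function(y, k, seed = 1) {
  id <- stratified_folds(y, k, seed)
  lapply(seq_len(k), function(j) {
    list(train = which(id != j), test = which(id == j))
  })
}

# Exhaustive-enumeration oracle for the two-sided Mann-Whitney p-value:
# distribution of U over all assignments of the pooled values to groups.
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  combos <- utils::combn(length(pooled), n1)
  ustat <- function(a, b) {
    r <- rank(c(a, b))
    sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  }
  u_all <- apply(combos, 2, function(idx) ustat(pooled[idx], pooled[-idx]))
  u_obs <- ustat(x, y)
  mu <- n1 * length(y) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}
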