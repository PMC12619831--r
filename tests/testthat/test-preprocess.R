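test_that("missingness filter keeps metabolites at exactly the threshold", {
  v <- matrix(rlnorm(60), 20, 3, dimnames = list(NULL, c("A", "B", "C")))
  v[1:5, 2] <- NA   # 25% missing -> dropped
  v[1:4, 3] <- NA   # 20% missing -> kept (strictly-greater rule)
  t1 <- filter_missing(make_table(v))
  expect_identical(t1$metabolite_ids, c("A", "C"))
  rep <- attr(t1, "removal_report")
  expect_equal(rep$kept, c(TRUE, FALSE, TRUE))
  # no missing anywhere -> identity on the metabolite axis
  t2 <- filter_missing(make_table(matrix(rlnorm(40), 10, 4)))
  expect_equal(ncol(t2$values), 4L)
  expect_error(filter_missing(make_table(matrix(c(NA, NA, 1, NA, NA, 2),
                                                3, 2))),
               "threshold")
})

test_that("missingness filter matches a brute-force recount over random masks", {
  for (s in 1:5) {
    tab <- random_table(n = 15, p = 8, missing_frac = 0.25, seed = s)
    for (thr in c(0, 0.2, 0.5)) {
      kept_bf <- which(vapply(seq_len(8), function(j) {
        mean(is.na(tab$values[, j])) <= thr
      }, logical(1)))
      if (length(kept_bf) == 0) {
        expect_error(filter_missing(tab, thr))
      } else {
        expect_identical(filter_missing(tab, thr)$metabolite_ids,
                         tab$metabolite_ids[kept_bf])
      }
    }
  }
  # idempotence
  tab <- random_table(n = 20, p = 6, missing_frac = 0.3, seed = 9)
  f1 <- filter_missing(tab)
  f2 <- filter_missing(tab)
  expect_identical(f1$values, f2$values)
})

test_that("LOD imputation fills with one fifth of the column minimum positive", {
  v <- matrix(c(NA, 5, 10, 1, 2, 3), 3, 2, dimnames = list(NULL, c("A", "B")))
  t1 <- impute_lod(make_table(v))
  expect_equal(t1$values[, "A"], c(1, 5, 10), ignore_attr = TRUE)
  expect_equal(t1$values[, "B"], c(1, 2, 3), ignore_attr = TRUE)
  # random columns match an independent recount
  for (s in 1:5) {
    tab <- random_table(n = 12, p = 5, missing_frac = 0.3, seed = 10 + s)
    imp <- impute_lod(tab)
    for (j in seq_len(5)) {
      obs <- tab$values[, j]
      expected <- ifelse(is.na(obs), min(obs[obs > 0], na.rm = TRUE) / 5, obs)
      expect_equal(imp$values[, j], expected, ignore_attr = TRUE)
    }
  }
  all_na <- matrix(c(NA, NA, NA, 1, 2, 3), 3, 2,
                   dimnames = list(NULL, c("bad", "ok")))
  expect_error(impute_lod(make_table(all_na)), "bad")
})

test_that("creatinine normalization divides rows and reports units correctly", {
  v <- matrix(10, 2, 2)
  t1 <- creatinine_normalize(make_table(v, creatinine = c(2, 5)))
  expect_equal(t1$values[1, ], c(5, 5), ignore_attr = TRUE)
  expect_equal(t1$values[2, ], c(2, 2), ignore_attr = TRUE)
  # creatinine of 1 everywhere is the identity
  t2 <- creatinine_normalize(make_table(v, creatinine = c(1, 1)))
  expect_equal(t2$values, v, ignore_attr = TRUE)
  # scalar-loop oracle on random input
  tab <- random_table(n = 8, p = 4, seed = 21)
  nm <- creatinine_normalize(tab)
  for (i in 1:8) for (j in 1:4) {
    expect_equal(nm$values[i, j],
                 unname(tab$values[i, j] / tab$creatinine[i]))
  }
  expect_error(metabolite_table(v, creatinine = c(2, 0)), "creatinine")
})

test_that("log transform is elementwise natural log with located errors", {
  v <- matrix(c(exp(1), 1, 4, 9), 2, 2, dimnames = list(c("s1", "s2"), c("A", "B")))
  lt <- log_transform(make_table(v))
  expect_equal(lt$values[1, 1], 1)
  expect_equal(lt$values[2, 1], 0)
  expect_equal(lt$values, log(v), ignore_attr = TRUE)
  bad <- make_table(matrix(c(1, 0, 2, 3), 2, 2,
                           dimnames = list(c("s1", "s2"), c("A", "B"))))
  expect_error(log_transform(bad), "s2.*A|A.*s2")
})

test_that("Pareto scaling centers and divides by the root standard deviation", {
  x <- make_table(matrix(c(1, 2, 3, 4, 4, 4), 3, 2,
                         dimnames = list(NULL, c("A", "B"))))
  ps <- pareto_scale(x)
  expect_equal(ps$values[, "A"], c(-1, 0, 1), ignore_attr = TRUE)  # sd = 1
  expect_equal(ps$values[, "B"], c(0, 0, 0), ignore_attr = TRUE)   # constant rule
  expect_equal(ps$scaling_params$sd, c(1, 0))
  # algebraic identity: var(scaled column) equals sd of the original column
  tab <- random_table(n = 30, p = 6, seed = 31)
  ps2 <- pareto_scale(tab)
  for (j in 1:6) {
    expect_equal(stats::var(ps2$values[, j]), stats::sd(tab$values[, j]),
                 tolerance = 1e-9)
    expect_lt(abs(mean(ps2$values[, j])), 1e-9)
  }
  expect_error(pareto_scale(make_table(matrix(1:3, 1, 3))), "2 samples")
})

test_that("chain order is enforced and out-of-order calls fail", {
  tab <- random_table(n = 10, p = 4, missing_frac = 0.2, seed = 41)
  imp <- impute_lod(filter_missing(tab))
  ps <- pareto_scale(log_transform(imp))
  expect_error(filter_missing(ps), "out-of-order|already")
  expect_error(impute_lod(imp), "already")
  expect_error(log_transform(pareto_scale(imp)), "out-of-order")
  expect_error(log_transform(tab), "impute")
})

test_that("transforms are sample-order equivariant", {
  tab <- random_table(n = 12, p = 5, missing_frac = 0.15, seed = 51)
  perm <- sample(12)
  direct <- fit_preprocess(tab)$values[perm, ]
  permuted <- fit_preprocess(subset_samples(tab, perm))$values
  expect_equal(direct, permuted, tolerance = 1e-12)
})

test_that("frozen parameters reproduce the training transform and transfer to new data", {
  tab <- random_table(n = 16, p = 6, missing_frac = 0.2, seed = 61)
  pm <- fit_preprocess(tab)
  again <- apply_frozen(pm, tab)
  expect_equal(again$values, pm$values, tolerance = 1e-12)
  # a new sample identical to a training sample transforms identically
  one <- subset_samples(tab, 3)
  expect_equal(apply_frozen(pm, one)$values[1, ], pm$values[3, ],
               tolerance = 1e-12)
  # frozen vs refit differ when the new distribution differs
  shifted <- tab
  shifted$values <- tab$values * 3
  expect_false(isTRUE(all.equal(apply_frozen(pm, shifted)$values,
                                fit_preprocess(shifted)$values)))
  # unseen metabolite set is rejected
  small <- tab
  small$values <- tab$values[, 1:3]
  small$lod <- tab$lod[1:3]
  small$metabolite_ids <- tab$metabolite_ids[1:3]
  expect_error(apply_frozen(pm, small), "lacks")
})
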