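make_tables <- function(n = 5, p = 3, seed = 1) {
  set.seed(seed)
  ids <- sprintf("S%02d", seq_len(n))
  b <- data.frame(subject_id = ids)
  e <- data.frame(subject_id = ids)
  for (j in seq_len(p)) {
    b[[paste0("f", j)]] <- rnorm(n, 10, 2)
    e[[paste0("f", j)]] <- rnorm(n, 8, 2)
  }
  list(baseline = b, eot = e)
}

test_that("delta definitions: absolute, relative, and the zero guard", {
  b <- data.frame(subject_id = "s1", f = 10)
  e <- data.frame(subject_id = "s1", f = 4)
  expect_equal(compute_delta(b, e, "absolute")$dabs_f, -6)
  expect_equal(compute_delta(b, e, "relative")$drel_f, -0.6)
  b0 <- data.frame(subject_id = "s1", f = 0)
  e5 <- data.frame(subject_id = "s1", f = 5)
  expect_true(is.na(compute_delta(b0, e5, "relative")$drel_f))
})

test_that("delta identities hold exactly on random tables", {
  tb <- make_tables(8, 4, seed = 2)
  dz_abs <- compute_delta(tb$baseline, tb$baseline, "absolute")
  dz_rel <- compute_delta(tb$baseline, tb$baseline, "relative")
  expect_true(all(as.matrix(dz_abs[, -1]) == 0))
  expect_true(all(as.matrix(dz_rel[, -1]) == 0))
  dabs <- compute_delta(tb$baseline, tb$eot, "absolute")
  drel <- compute_delta(tb$baseline, tb$eot, "relative")
  for (j in paste0("f", 1:4)) {
    expect_identical(drel[[paste0("drel_", j)]],
                     dabs[[paste0("dabs_", j)]] / tb$baseline[[j]])
  }
})

test_that("subjects missing a time point are excluded with a warning", {
  tb <- make_tables(5, 2, seed = 3)
  eot <- tb$eot[1:3, ]
  expect_warning(d <- compute_delta(tb$baseline, eot, "absolute"),
                 "excluded")
  expect_equal(d$subject_id, tb$baseline$subject_id[1:3])
})

test_that("feature-set combos concatenate with provenance prefixes", {
  tb <- make_tables(6, 3, seed = 4)
  be <- build_feature_set(tb, "baseline+eot")
  expect_equal(ncol(be), 1 + 6)
  expect_true(all(grepl("^base_|^eot_", names(be)[-1])))
  ad <- build_feature_set(tb, "abs_delta")
  expect_equal(ncol(ad), 1 + 3)
  expect_true(all(grepl("^dabs_", names(ad)[-1])))
  # subject lacking EoT is dropped from combined sets
  tb2 <- tb; tb2$eot <- tb$eot[1:4, ]
  suppressWarnings(brd <- build_feature_set(tb2, "baseline+rel_delta"))
  expect_equal(nrow(brd), 4)
  expect_error(build_feature_set(list(baseline = tb$baseline), "eot"),
               "requires")
})

test_that("mean imputation preserves column means and drops dead columns", {
  t1 <- data.frame(subject_id = c("a", "b", "c"), f = c(1, NA, 3))
  expect_equal(mean_impute(t1)$f, c(1, 2, 3))
  t2 <- data.frame(subject_id = c("a", "b"), f = c(1.5, 2.5))
  expect_identical(mean_impute(t2), t2)
  t3 <- data.frame(subject_id = c("a", "b"), f = c(NA_real_, NA_real_),
                   g = c(1, 2))
  expect_warning(out <- mean_impute(t3), "all-missing")
  expect_false("f" %in% names(out))
  # invariance of the observed-column mean
  set.seed(5)
  t4 <- data.frame(subject_id = letters[1:10], f = rnorm(10))
  t4$f[c(2, 7)] <- NA
  expect_equal(mean(mean_impute(t4)$f), mean(t4$f, na.rm = TRUE))
})

test_that("z-scoring: closed form, constant guard, train-only transform", {
  t1 <- data.frame(subject_id = c("a", "b"), f = c(0, 10))
  expect_equal(zscore(t1)$f, c(-1, 1))        # population sigma = 5
  t2 <- data.frame(subject_id = c("a", "b"), f = c(3, 3))
  expect_equal(zscore(t2)$f, c(0, 0))
  set.seed(6)
  train <- data.frame(subject_id = letters[1:20], f = rnorm(20, 5, 2))
  test <- data.frame(subject_id = LETTERS[1:5], f = rnorm(5, 5, 2))
  zt <- zscore(train)
  ztest <- zscore(test, attr(zt, "fit_stats"))
  fs <- attr(zt, "fit_stats")
  expect_equal(ztest$f * fs$sigma[["f"]] + fs$mu[["f"]], test$f)
  expect_equal(mean(zt$f), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean(zt$f^2)), 1, tolerance = 1e-10)
})

test_that("scanner tests: type-I error near alpha, power against 3-sigma shift", {
  # null: both groups N(0,1); rejection rate over 200 features ~ alpha
  set.seed(7)
  n <- 50
  tab <- as.data.frame(matrix(rnorm(2 * n * 200), 2 * n, 200))
  names(tab) <- paste0("f", 1:200)
  tab$scanner_id <- rep(c("A", "B"), each = n)
  rep0 <- scanner_effect_tests(tab)
  rate_add <- mean(rep0$additive_flag)
  rate_mul <- mean(rep0$multiplicative_flag)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 200)
  expect_gt(rate_add, ci[1] - 0.01); expect_lt(rate_add, ci[2] + 0.01)
  expect_lt(rate_mul, ci[2] + 0.02)
  # additive power: 3 sigma shift, n = 20 per group
  hits <- 0
  for (s in 1:40) {
    b <- simulate_feature_batch(40, 1, scanner_shift = 3, seed = 400 + s)
    r <- scanner_effect_tests(b[, c("scanner_id", "f1")])
    hits <- hits + r$additive_flag
  }
  expect_gt(hits / 40, 0.95)
  # multiplicative: variance ratio 4 flags Bartlett, rarely the t-test
  add <- 0; mul <- 0
  for (s in 1:30) {
    b <- simulate_feature_batch(60, 1, scanner_inflation = 2, seed = 800 + s)
    r <- scanner_effect_tests(b[, c("scanner_id", "f1")])
    add <- add + r$additive_flag; mul <- mul + r$multiplicative_flag
  }
  expect_gt(mul / 30, 0.9)
  expect_lt(add / 30, 0.3)
  expect_error(scanner_effect_tests(data.frame(scanner_id = rep("A", 6),
                                               f1 = rnorm(6))), "two scanner")
})

# longitudinal batch with a known additive scanner-B shift on all features
combat_fixture <- function(n = 40, p = 20, shift = 0, inflation = 1,
                           seed = 1) {
  set.seed(seed)
  ids <- rep(sprintf("S%02d", seq_len(n)), each = 2)
  tp <- rep(c("baseline", "eot"), times = n)
  scanner <- sample(c("A", "B"), 2 * n, replace = TRUE)
  X <- matrix(rnorm(2 * n * p, sd = 1), 2 * n, p) +
    rep(rnorm(n, sd = 1), each = 2) +            # subject intercepts
    rep(c(0, 0.4), times = n)                    # time effect
  isB <- scanner == "B"
  X[isB, ] <- X[isB, ] * inflation + shift
  tab <- data.frame(subject_id = ids, timepoint = tp, scanner_id = scanner)
  cbind(tab, as.data.frame(X))
}

test_that("longitudinal ComBat removes an injected additive shift", {
  tab <- combat_fixture(40, 20, shift = 2, seed = 8)
  adj <- longitudinal_combat(tab)
  gap <- function(t) {
    vapply(feature_columns(t), function(f) {
      abs(diff(tapply(t[[f]], t$scanner_id, mean)))
    }, numeric(1))
  }
  reduction <- 1 - mean(gap(adj)) / mean(gap(tab))
  expect_gt(reduction, 0.8)
})

test_that("longitudinal ComBat equalizes injected variance inflation", {
  tab <- combat_fixture(60, 30, inflation = 2, seed = 9)
  adj <- longitudinal_combat(tab)
  ps <- vapply(feature_columns(adj), function(f) {
    stats::bartlett.test(adj[[f]], factor(adj$scanner_id))$p.value
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.9)
})

test_that("null data passes through nearly unchanged with non-significant KS", {
  tab <- combat_fixture(40, 20, seed = 10)
  adj <- longitudinal_combat(tab)
  rel <- vapply(feature_columns(tab), function(f) {
    mean(abs(adj[[f]] - tab[[f]])) / sd(tab[[f]])
  }, numeric(1))
  expect_lt(mean(rel), 0.25)
  ks <- ks_compare(tab, adj)
  expect_true(all(!ks$flag))
})

test_that("location-only adjustment without shrinkage is exactly idempotent", {
  tab <- combat_fixture(30, 10, shift = 1.5, seed = 11)
  a1 <- longitudinal_combat(tab, eb = FALSE, adjust = "location")
  a2 <- longitudinal_combat(a1, eb = FALSE, adjust = "location")
  for (f in feature_columns(tab)) {
    expect_equal(a2[[f]], a1[[f]], tolerance = 1e-10)
  }
})

test_that("confounded scanner assignment warns but still adjusts", {
  tab <- combat_fixture(20, 5, shift = 2, seed = 12)
  # force each subject onto a single scanner at both time points
  tab$scanner_id <- rep(rep(c("A", "B"), length.out = 20), each = 2)
  set.seed(12)
  isB <- tab$scanner_id == "B"
  for (f in feature_columns(tab)) tab[[f]][isB] <- tab[[f]][isB] + 2
  expect_warning(adj <- longitudinal_combat(tab), "confounded")
  expect_equal(dim(adj), dim(tab))
})

test_that("KS comparison: identical tables, shifted column, null rate", {
  set.seed(13)
  t1 <- data.frame(subject_id = 1:40, f1 = rnorm(40), f2 = rnorm(40))
  expect_true(all(ks_compare(t1, t1)$p == 1))
  t2 <- t1; t2$f1 <- t2$f1 + 5
  ks <- ks_compare(t1, t2)
  expect_lt(ks$p[ks$feature == "f1"], 0.001)
  expect_gt(ks$p[ks$feature == "f2"], 0.05)
  # type-I: independent same-distribution samples
  rej <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    a <- data.frame(subject_id = 1:30, f = rnorm(30))
    b <- data.frame(subject_id = 1:30, f = rnorm(30))
    rej <- rej + ks_compare(a, b)$flag
  }
  expect_lt(rej / 100, 0.12)
})
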