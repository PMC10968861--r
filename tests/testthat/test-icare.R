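test_that("AUC via midranks equals the pair-counting oracle, with ties", {
  set.seed(1)
  for (i in 1:20) {
    n <- sample(6:25, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq_len(5), n, replace = TRUE) / 2   # many ties
    expect_equal(auc_mw(s, y), oracle_auc(s, y), tolerance = 1e-12)
  }
})

test_that("a perfectly ranking feature yields w = +1 and training AUC 1", {
  y <- rep(c(0, 1), each = 10)
  X <- cbind(sig = c(rnorm(10, 0), rnorm(10, 10)))
  m <- icare_fit_single(X, y, icare_params(F_features = 5, Cmin = 0.1))
  expect_equal(m$w, 1)
  expect_equal(auc_mw(predict(m, X), y), 1.0)
})

test_that("duplicated features are decorrelated down to one copy", {
  set.seed(2)
  x <- rnorm(40)
  y <- as.integer(x + rnorm(40, sd = 0.5) > 0)
  X <- cbind(a = x, b = x)                     # r = 1
  m <- icare_fit_single(X, y, icare_params(F_features = 5, Cmin = 0,
                                           rho = 0.9))
  expect_length(m$features, 1)
})

test_that("pure-noise features with a high margin almost never survive", {
  # each feature must reach AUC <= 0.05 or >= 0.95 by chance at n = 200
  set.seed(3)
  survivors <- 0
  for (i in 1:20) {
    X <- matrix(rnorm(200 * 10), 200, 10)
    y <- rbinom(200, 1, 0.5)
    m <- suppressWarnings(
      icare_fit_single(X, y, icare_params(F_features = 10, Cmin = 0.45)))
    survivors <- survivors + length(m$features)
  }
  expect_equal(survivors, 0)
})

test_that("single-model fit matches the direct-definition oracle", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(15:30, 1); p <- sample(3:6, 1)
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("f", seq_len(p))
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    prm <- icare_params(F_features = p, Cmin = 0.05, rho = 0.8)
    m <- suppressWarnings(icare_fit_single(X, y, prm))
    got <- predict(m, X)
    want <- oracle_icare_single(X, y, Cmin = 0.05, rho = 0.8)
    expect_equal(got, unname(want), tolerance = 1e-10)
  }
})

test_that("predictions are scale invariant and sign equivariant", {
  set.seed(5)
  n <- 40; p <- 6
  X <- matrix(rnorm(n * p), n, p); colnames(X) <- paste0("f", 1:p)
  y <- as.integer(X[, 1] - X[, 2] + rnorm(n, sd = 0.8) > 0)
  prm <- icare_params(F_features = p, Cmin = 0, rho = 0.95)
  Xnew <- matrix(rnorm(10 * p), 10, p); colnames(Xnew) <- colnames(X)
  m <- suppressWarnings(icare_fit_single(X, y, prm, seed = 7))
  base_pred <- predict(m, Xnew)
  # positive rescaling of a feature is absorbed by the z-scoring
  Xs <- X; Xs[, 3] <- X[, 3] * 42
  Xns <- Xnew; Xns[, 3] <- Xnew[, 3] * 42
  ms <- suppressWarnings(icare_fit_single(Xs, y, prm, seed = 7))
  expect_equal(predict(ms, Xns), base_pred, tolerance = 1e-12)
  # negating a feature flips its weight, predictions unchanged
  Xn <- X; Xn[, 1] <- -X[, 1]
  Xnn <- Xnew; Xnn[, 1] <- -Xnew[, 1]
  mn <- suppressWarnings(icare_fit_single(Xn, y, prm, seed = 7))
  if ("f1" %in% m$features && "f1" %in% mn$features) {
    expect_equal(mn$w[mn$features == "f1"], -m$w[m$features == "f1"])
  }
  expect_equal(predict(mn, Xnn), base_pred, tolerance = 1e-12)
})

test_that("ensemble aggregation is the member median and order invariant", {
  const_model <- function(v) {
    structure(list(features = "f1", w = v, mu = 0, sd = 1),
              class = "icare_model")
  }
  X <- data.frame(f1 = c(1, 1))
  ms <- list(const_model(-1), const_model(0 + 1e-12), const_model(1))
  # members predict about -1, 0, 1 per sample
  expect_equal(icare_predict_ensemble(ms, X), c(1e-12, 1e-12))
  expect_equal(icare_predict_ensemble(rev(ms), X),
               icare_predict_ensemble(ms, X))
  same <- list(const_model(1), const_model(1), const_model(1))
  expect_equal(icare_predict_ensemble(same, X), predict(same[[1]], X))
})

test_that("bagged ensemble: separable data learned, permuted labels not", {
  set.seed(6)
  n <- 100
  y <- rbinom(n, 1, 0.5)
  X <- matrix(rnorm(n * 5), n, 5) + outer(y, rep(3, 5))
  colnames(X) <- paste0("f", 1:5)
  ens <- icare_fit_bagged(X, y, icare_params(F_features = 3, Cmin = 0.05,
                                             n_models = 60), seed = 8)
  # out-of-sample check on a fresh draw from the same process
  y2 <- rbinom(n, 1, 0.5)
  X2 <- matrix(rnorm(n * 5), n, 5) + outer(y2, rep(3, 5))
  colnames(X2) <- colnames(X)
  expect_gt(auc_mw(predict(ens, X2), y2), 0.9)
  # pure-noise features and labels: held-out AUC inside the null band
  X0 <- matrix(rnorm(n * 5), n, 5); colnames(X0) <- paste0("f", 1:5)
  y0 <- rbinom(n, 1, 0.5)
  tr <- seq_len(n / 2)
  a0 <- replicate(10, {
    y0p <- sample(y0)
    ens0 <- suppressWarnings(
      icare_fit_bagged(X0[tr, ], y0p[tr],
                       icare_params(F_features = 3, Cmin = 0.05,
                                    n_models = 40), seed = sample.int(1e6, 1)))
    auc_mw(predict(ens0, X0[-tr, ]), y0p[-tr])
  })
  expect_gt(mean(a0), 0.38); expect_lt(mean(a0), 0.62)
})

test_that("bagged ensembles are reproducible from the seed", {
  set.seed(7)
  X <- matrix(rnorm(60 * 8), 60, 8); colnames(X) <- paste0("f", 1:8)
  y <- rbinom(60, 1, 0.4)
  e1 <- suppressWarnings(icare_fit_bagged(X, y, icare_params(n_models = 20),
                                          seed = 10))
  e2 <- suppressWarnings(icare_fit_bagged(X, y, icare_params(n_models = 20),
                                          seed = 10))
  expect_identical(predict(e1, X), predict(e2, X))
})

test_that("informative features dominate ensemble selection frequency", {
  # 5 informative of 40 at d = 1.5: the informative block should fill the
  # top-5 selection-frequency ranks for the large majority of seeds
  ok <- 0
  for (s in 1:5) {
    b <- simulate_feature_batch(80, 40, class_effect_d = 1.5,
                                n_informative = 5, seed = 60 + s)
    X <- as.matrix(b[, paste0("f", 1:40)])
    ens <- icare_fit_bagged(X, b$class,
                            icare_params(F_features = 10, Cmin = 0.1,
                                         n_models = 150), seed = s)
    freq <- table(factor(unlist(lapply(ens$models, `[[`, "features")),
                         levels = paste0("f", 1:40)))
    top5 <- names(sort(freq, decreasing = TRUE))[1:5]
    ok <- ok + (length(intersect(top5, paste0("f", 1:5))) == 5)
  }
  expect_gte(ok / 5, 0.8)
})

test_that("tuning returns candidate ranking and improves or matches defaults", {
  b <- simulate_feature_batch(60, 10, class_effect_d = 1.5,
                              n_informative = 3, seed = 42)
  X <- as.matrix(b[, paste0("f", 1:10)])
  y <- b$class
  tuned <- suppressWarnings(
    icare_tune_bagged(X, y, n_candidate_sets = 20, n_models = 60,
                      B_grid = c(1L, 3L), mc_splits = 3, mc_models = 8,
                      seed = 1))
  expect_s3_class(tuned, "icare_ensemble")
  expect_equal(nrow(tuned$tuning), 20)
  expect_true(tuned$B %in% c(1L, 3L))
  # determinism of the whole tuning path
  tuned2 <- suppressWarnings(
    icare_tune_bagged(X, y, n_candidate_sets = 20, n_models = 60,
                      B_grid = c(1L, 3L), mc_splits = 3, mc_models = 8,
                      seed = 1))
  expect_identical(predict(tuned, X), predict(tuned2, X))
  expect_identical(tuned$selected_sets, tuned2$selected_sets)
})

test_that("survival orientation: anti-concordant risks score 1, reversed 0", {
  time <- c(5, 3, 8, 1, 9); event <- rep(1, 5)
  expect_equal(icare_survival_direction(-time, time, event), 1.0)
  expect_equal(icare_survival_direction(time, time, event), 0.0)
  set.seed(8)
  r <- replicate(200, icare_survival_direction(rnorm(5), time, event))
  expect_equal(mean(r), 0.5, tolerance = 0.06)
})

test_that("ICARE models serialize to JSON and back-read consistently", {
  set.seed(9)
  X <- matrix(rnorm(30 * 4), 30, 4); colnames(X) <- paste0("f", 1:4)
  y <- rbinom(30, 1, 0.5)
  m <- suppressWarnings(icare_fit_single(X, y, icare_params(Cmin = 0)))
  js <- icare_to_json(m)
  obj <- jsonlite::fromJSON(js)
  expect_equal(obj$features, m$features)
  expect_equal(obj$w, m$w)
})
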