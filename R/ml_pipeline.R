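# Relapse/progression classification protocol: correlation filtering,
# SMOTE class balancing, sequential forward feature selection, KNN / LDA /
# RF / ICARE classifiers, and the nested cross-validation harness.
#
# In the default `within_fold` mode every data-dependent step (correlation
# filter, SMOTE, z-scoring, SFS) is fitted on the outer-training portion
# only; the literal `before_split` ordering (balance the whole dataset
# first) is available for comparison but leaks information.

#' Nested cross-validation configuration
#'
#' Defaults: 10 outer folds x 5 repetitions and
#' 5 inner folds x 20 repetitions on 85% of the data, with 15% held out.
#' Tests and examples use smaller settings; all sizes are free parameters.
#'
#' @param outer_folds,outer_repeats outer CV geometry.
#' @param inner_folds,inner_repeats inner CV geometry (feature selection).
#' @param holdout_fraction fraction reserved as unseen test data (0 to
#'   disable).
#' @param stratified stratify folds by class (default TRUE).
#' @param max_features SFS cap on selected features.
#' @param seed integer seed driving fold draws and model randomness.
#' @return a list of class `cv_config`.
#' @export
cv_config <- function(outer_folds = 10L, outer_repeats = 5L,
                      inner_folds = 5L, inner_repeats = 20L,
                      holdout_fraction = 0.15, stratified = TRUE,
                      max_features = 5L, seed = 1L) {
  stopifnot(outer_folds >= 2, inner_folds >= 2,
            holdout_fraction >= 0, holdout_fraction < 0.5)
  structure(as.list(environment()), class = "cv_config")
}

#' Greedy correlation filter
#'
#' Drops constant columns, then scans columns in order and drops any
#' feature whose absolute Pearson correlation with an already-retained
#' feature exceeds the threshold.
#'
#' @param X numeric matrix or data.frame of features.
#' @param threshold absolute correlation threshold (default 0.8).
#' @return character vector of retained feature names.
#' @export
correlation_filter <- function(X, threshold = 0.8) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  keep_idx <- which(!is.na(sds) & sds > 0)
  retained <- integer(0)
  for (j in keep_idx) {
    if (length(retained) == 0L) { retained <- j; next }
    r <- abs(suppressWarnings(stats::cor(X[, j], X[, retained])))
    r[is.na(r)] <- 0
    if (all(r <= threshold)) retained <- c(retained, j)
  }
  colnames(X)[retained]
}

#' SMOTE class balancing
#'
#' Synthetic minority samples `x_new = x_i + lambda * (x_nn - x_i)` with
#' `lambda ~ U(0, 1)` and `x_nn` one of the k nearest minority neighbours,
#' generated until the classes are balanced. Already-balanced input is
#' returned unchanged.
#'
#' @param X numeric matrix of features.
#' @param y 0/1 labels.
#' @param k_neighbors neighbourhood size (capped at minority count - 1).
#' @param seed integer seed.
#' @return list with balanced `X` and `y` (synthetic rows appended).
#' @export
smote <- function(X, y, k_neighbors = 5L, seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  tab <- table(factor(y, levels = c(0, 1)))
  if (tab[1] == tab[2]) return(list(X = X, y = y))
  minority <- as.integer(names(tab)[which.min(tab)])
  n_min <- min(tab); n_needed <- max(tab) - n_min
  if (n_min < 2L) stop("SMOTE requires at least 2 minority samples",
                       call. = FALSE)
  k <- min(k_neighbors, n_min - 1L)
  Xm <- X[y == minority, , drop = FALSE]
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  nn <- apply(d, 1, function(r) order(r)[seq_len(k)])
  nn <- if (k == 1L) matrix(nn, ncol = 1) else t(nn)
  set.seed(derive_seed(seed, "smote"))
  base_i <- sample.int(n_min, n_needed, replace = TRUE)
  nbr_i <- nn[cbind(base_i, sample.int(k, n_needed, replace = TRUE))]
  lam <- stats::runif(n_needed)
  Xnew <- Xm[base_i, , drop = FALSE] +
    lam * (Xm[nbr_i, , drop = FALSE] - Xm[base_i, , drop = FALSE])
  list(X = rbind(X, Xnew), y = c(y, rep(minority, n_needed)))
}

# fit `model` on (Xtr, ytr) and return predicted scores on Xte; scores are
# class-1 probabilities except for icare (centered risk, threshold 0)
fit_predict_scores <- function(model, Xtr, ytr, Xte, params = list(),
                               seed = 1L) {
  yf <- factor(ytr, levels = c(0, 1))
  Xtr <- as.matrix(Xtr); Xte <- as.matrix(Xte)
  switch(model,
    knn = {
      k <- params$knn_k %||% 5L
      fit <- caret::knn3(x = Xtr, y = yf, k = min(k, nrow(Xtr) - 1L))
      stats::predict(fit, Xte, type = "prob")[, "1"]
    },
    lda = {
      fit <- tryCatch(suppressWarnings(MASS::lda(Xtr, grouping = yf)),
                      error = function(e) NULL)
      if (is.null(fit)) {
        # degenerate covariance (e.g. a feature constant within a group):
        # diagonal nearest-centroid discriminant as the limiting case
        mu1 <- colMeans(Xtr[ytr == 1, , drop = FALSE])
        mu0 <- colMeans(Xtr[ytr == 0, , drop = FALSE])
        s <- apply(Xtr, 2, stats::sd); s[s == 0 | is.na(s)] <- 1
        w <- (mu1 - mu0) / s^2
        stats::plogis(as.numeric(Xte %*% w) -
                        as.numeric((mu1 + mu0) %*% w) / 2)
      } else {
        stats::predict(fit, Xte)$posterior[, "1"]
      }
    },
    rf = {
      set.seed(seed)
      fit <- randomForest::randomForest(x = Xtr, y = yf,
                                        ntree = params$rf_ntree %||% 500L)
      stats::predict(fit, Xte, type = "prob")[, "1"]
    },
    icare = {
      pr <- params$icare_params %||% icare_params(n_models = 50L)
      ens <- icare_fit_bagged(Xtr, as.integer(as.character(yf)), pr,
                              seed = seed)
      predict(ens, Xte)
    },
    stop("unknown model: ", model, call. = FALSE))
}

score_threshold <- function(model) if (model == "icare") 0 else 0.5

#' Classification metrics
#'
#' Accuracy, F1 (harmonic mean of precision and recall), recall
#' (TP / (TP + FN)), precision (TP / (TP + FP)) and ROC AUC (Mann-Whitney,
#' tied pairs 0.5). With a one-class truth vector the AUC is `NA` and the
#' other metrics are still computed.
#'
#' @param y_true 0/1 labels.
#' @param scores numeric scores.
#' @param threshold decision threshold (0.5 for probabilities, 0 for
#'   centered risk scores).
#' @return named numeric vector: `accuracy`, `f1`, `recall`, `precision`,
#'   `roc_auc`.
#' @export
classification_metrics <- function(y_true, scores, threshold = 0.5) {
  y_true <- as.integer(y_true)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y_true == 1); fp <- sum(pred == 1 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1); tn <- sum(pred == 0 & y_true == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  c(accuracy = (tp + tn) / length(y_true), f1 = f1, recall = recall,
    precision = precision, roc_auc = auc_mw(scores, y_true))
}

# stratified fold assignment; returns integer fold id per sample
stratified_folds <- function(y, k, stratified = TRUE) {
  folds <- integer(length(y))
  if (stratified) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    folds <- sample(rep_len(seq_len(k), length(y)))
  }
  folds
}

#' Sequential forward feature selection
#'
#' Starts from the empty set and repeatedly adds the feature that maximizes
#' the inner-CV score (F1 by default); stops when no addition improves the
#' score or `max_features` is reached. Ties break toward the lowest column
#' index, so the procedure is deterministic given the seed.
#'
#' @param X numeric matrix (samples x features).
#' @param y 0/1 labels.
#' @param estimator model name (`"knn"`, `"lda"`, `"rf"`, `"icare"`).
#' @param inner_folds,inner_repeats inner CV geometry.
#' @param max_features cap on the subset size.
#' @param metric `"f1"` or `"accuracy"`.
#' @param params model parameters (see [nested_cv_classify()]).
#' @param seed integer seed.
#' @return character vector of selected feature names (column order of
#'   selection).
#' @export
sequential_forward_selection <- function(X, y, estimator = "lda",
                                         inner_folds = 5L,
                                         inner_repeats = 1L,
                                         max_features = 5L,
                                         metric = "f1", params = list(),
                                         seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  p <- ncol(X)
  thr <- score_threshold(estimator)
  midx <- match(metric, c("accuracy", "f1"))
  set.seed(derive_seed(seed, "sfs"))
  fold_draws <- lapply(seq_len(inner_repeats), function(r) {
    stratified_folds(y, inner_folds)
  })
  cv_score <- function(cols) {
    sc <- c()
    for (folds in fold_draws) {
      for (k in seq_len(inner_folds)) {
        tr <- folds != k
        if (length(unique(y[tr])) < 2L || sum(!tr) == 0L) next
        s <- tryCatch(
          fit_predict_scores(estimator, X[tr, cols, drop = FALSE], y[tr],
                             X[!tr, cols, drop = FALSE], params,
                             seed = derive_seed(seed, paste0("sfs", k))),
          error = function(e) NULL)
        if (is.null(s)) next
        m <- classification_metrics(y[!tr], s, thr)[midx]
        if (!is.na(m)) sc <- c(sc, m)
      }
    }
    if (length(sc) == 0L) -Inf else mean(sc)
  }
  selected <- integer(0)
  best <- -Inf
  while (length(selected) < min(max_features, p)) {
    cands <- setdiff(seq_len(p), selected)
    gains <- vapply(cands, function(j) cv_score(c(selected, j)), numeric(1))
    jbest <- cands[which.max(gains)]          # which.max = lowest index tie
    if (max(gains) <= best) break
    best <- max(gains)
    selected <- c(selected, jbest)
  }
  if (length(selected) == 0L) selected <- 1L   # degenerate: keep something
  colnames(X)[selected]
}

#' Nested cross-validated relapse/progression classification
#'
#' The study protocol: optional stratified holdout; repeated stratified
#' outer folds; within each outer-training set, correlation filtering,
#' SMOTE balancing (per `smote_mode`), z-scoring and SFS with inner CV;
#' metrics computed on the outer-test folds and aggregated as mean and SD
#' over all outer-fold x repeat evaluations.
#'
#' @param X feature matrix or data.frame (samples x features).
#' @param y 0/1 labels.
#' @param model `"knn"`, `"lda"`, `"rf"` or `"icare"`.
#' @param cfg a [cv_config()].
#' @param smote_mode `"within_fold"` (leak-free, default), `"before_split"`
#'   (the literal balance-first ordering; leaky, for comparison) or
#'   `"none"`.
#' @param corr_threshold correlation-filter threshold.
#' @param params model parameters: `knn_k`, `rf_ntree`, `icare_params`.
#' @param sfs run sequential forward selection (default TRUE).
#' @return a list of class `cv_report`: `summary` (mean/sd per metric),
#'   `per_fold`, `holdout`, `selected_features`, `model`.
#' @export
nested_cv_classify <- function(X, y, model = c("lda", "knn", "rf", "icare"),
                               cfg = cv_config(),
                               smote_mode = c("within_fold", "before_split",
                                              "none"),
                               corr_threshold = 0.8, params = list(),
                               sfs = TRUE) {
  model <- match.arg(model)
  smote_mode <- match.arg(smote_mode)
  X <- as.matrix(X); y <- as.integer(y)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (length(unique(y)) < 2L) stop("both classes must be present",
                                   call. = FALSE)
  thr <- score_threshold(model)
  set.seed(derive_seed(cfg$seed, "nested_cv"))
  if (smote_mode == "before_split") {
    sm <- smote(X, y, seed = derive_seed(cfg$seed, "smote_global"))
    X <- sm$X; y <- sm$y
  }
  n <- nrow(X)
  holdout_idx <- integer(0)
  if (cfg$holdout_fraction > 0) {
    n_h <- floor(cfg$holdout_fraction * n)
    if (n_h >= 2L) {
      holdout_idx <- unlist(lapply(unique(y), function(cl) {
        idx <- which(y == cl)
        sample(idx, max(1L, round(length(idx) * cfg$holdout_fraction)))
      }))
    }
  }
  cv_idx <- setdiff(seq_len(n), holdout_idx)
  Xcv <- X[cv_idx, , drop = FALSE]; ycv <- y[cv_idx]

  run_fold <- function(tr_idx, te_idx, fold_seed) {
    Xtr <- Xcv[tr_idx, , drop = FALSE]; ytr <- ycv[tr_idx]
    keep <- correlation_filter(Xtr, corr_threshold)
    Xtr <- Xtr[, keep, drop = FALSE]
    Xte <- Xcv[te_idx, keep, drop = FALSE]
    if (smote_mode == "within_fold") {
      sm <- tryCatch(smote(Xtr, ytr, seed = fold_seed),
                     error = function(e) {
                       warning("fold left unbalanced: ",
                               conditionMessage(e), call. = FALSE)
                       list(X = Xtr, y = ytr)
                     })
      Xtr <- sm$X; ytr <- sm$y
    }
    mu <- colMeans(Xtr); sd_ <- apply(Xtr, 2, stats::sd)
    sd_[sd_ == 0 | is.na(sd_)] <- 1
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sd_, "/")
    Xte <- sweep(sweep(Xte, 2, mu), 2, sd_, "/")
    feats <- if (sfs) {
      sequential_forward_selection(Xtr, ytr, model, cfg$inner_folds,
                                   cfg$inner_repeats, cfg$max_features,
                                   params = params, seed = fold_seed)
    } else colnames(Xtr)
    sc <- fit_predict_scores(model, Xtr[, feats, drop = FALSE], ytr,
                             Xte[, feats, drop = FALSE], params,
                             seed = fold_seed)
    list(metrics = classification_metrics(ycv[te_idx], sc, thr),
         features = feats)
  }

  per_fold <- list(); sel_feats <- list()
  for (rep in seq_len(cfg$outer_repeats)) {
    redraws <- 0L
    repeat {
      folds <- stratified_folds(ycv, cfg$outer_folds, cfg$stratified)
      ok <- all(vapply(seq_len(cfg$outer_folds), function(k) {
        length(unique(ycv[folds != k])) == 2L && sum(folds == k) > 0L
      }, logical(1)))
      if (ok || redraws >= 20L) break
      redraws <- redraws + 1L
    }
    if (redraws > 0L) warning("outer folds re-drawn ", redraws, " time(s)",
                              call. = FALSE)
    for (k in seq_len(cfg$outer_folds)) {
      fr <- run_fold(which(folds != k), which(folds == k),
                     derive_seed(cfg$seed, paste0("fold", rep, "_", k)))
      per_fold[[length(per_fold) + 1L]] <-
        data.frame(repeat_ = rep, fold = k, t(fr$metrics))
      sel_feats[[length(sel_feats) + 1L]] <- fr$features
    }
  }
  pf <- do.call(rbind, per_fold)
  mets <- c("accuracy", "f1", "recall", "precision", "roc_auc")
  summary <- data.frame(
    metric = mets,
    mean = vapply(mets, function(m) mean(pf[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(mets, function(m) stats::sd(pf[[m]], na.rm = TRUE),
                numeric(1)),
    row.names = NULL)
  holdout <- NULL
  if (length(holdout_idx) > 0L) {
    # refit on all CV data, evaluate on the untouched holdout
    keep <- correlation_filter(Xcv, corr_threshold)
    Xtr <- Xcv[, keep, drop = FALSE]; ytr <- ycv
    if (smote_mode == "within_fold") {
      sm <- smote(Xtr, ytr, seed = derive_seed(cfg$seed, "smote_ho"))
      Xtr <- sm$X; ytr <- sm$y
    }
    mu <- colMeans(Xtr); sd_ <- apply(Xtr, 2, stats::sd)
    sd_[sd_ == 0 | is.na(sd_)] <- 1
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sd_, "/")
    Xho <- sweep(sweep(X[holdout_idx, keep, drop = FALSE], 2, mu), 2,
                 sd_, "/")
    feats <- if (sfs) {
      sequential_forward_selection(Xtr, ytr, model, cfg$inner_folds,
                                   cfg$inner_repeats, cfg$max_features,
                                   params = params,
                                   seed = derive_seed(cfg$seed, "sfs_ho"))
    } else colnames(Xtr)
    sc <- fit_predict_scores(model, Xtr[, feats, drop = FALSE], ytr,
                             Xho[, feats, drop = FALSE], params,
                             seed = derive_seed(cfg$seed, "fit_ho"))
    holdout <- classification_metrics(y[holdout_idx], sc, thr)
    holdout_features <- feats
  } else holdout_features <- NULL
  structure(list(summary = summary, per_fold = pf, holdout = holdout,
                 holdout_idx = holdout_idx,
                 holdout_features = holdout_features,
                 selected_features = sel_feats, model = model),
            class = "cv_report")
}

#' @method print cv_report
#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>", x$model, "- mean +/- SD over",
      nrow(x$per_fold), "outer evaluations\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-9s %.3f +/- %.3f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  invisible(x)
}

#' Compare feature-set combinations across classifiers
#'
#' Runs [nested_cv_classify()] for each feature-set combination and model
#' and assembles a long table of mean +/- SD metrics
#' (rows = feature set x model x metric).
#'
#' @param feature_sets named list of feature matrices (same rows / subjects).
#' @param y 0/1 labels.
#' @param models character vector of model names.
#' @param cfg a [cv_config()].
#' @param ... passed to [nested_cv_classify()].
#' @return data.frame with columns `feature_set`, `model`, `metric`,
#'   `mean`, `sd`.
#' @export
classify_compare <- function(feature_sets, y, models = c("icare", "knn",
                                                         "lda", "rf"),
                             cfg = cv_config(), ...) {
  rows <- list()
  for (fs in names(feature_sets)) {
    for (m in models) {
      rep <- nested_cv_classify(feature_sets[[fs]], y, m, cfg, ...)
      s <- rep$summary
      s$feature_set <- fs; s$model <- m
      rows[[length(rows) + 1L]] <- s[, c("feature_set", "model", "metric",
                                         "mean", "sd")]
    }
  }
  do.call(rbind, rows)
}
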