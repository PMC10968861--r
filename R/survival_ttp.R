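# Time-to-progression analysis: Harrell concordance, elastic-net Cox
# (CoxNet) with five feature-selection front-ends, ICARE-survival
# comparison, and recurrence-volume regression with gradient boosting.

#' Harrell's concordance index
#'
#' Comparable pairs are `(i, j)` with `time_i < time_j` and `event_i = 1`;
#' a pair is concordant when `risk_i > risk_j` (higher risk, shorter
#' time - the anti-concordant risk orientation); tied risks count 0.5.
#' Censored-before-event pairs are incomparable, and tied event times
#' contribute only through the event/censoring asymmetry of the
#' `time_i < time_j` rule.
#'
#' @param risk numeric risk scores.
#' @param time event/censoring times.
#' @param event 0/1 event indicators.
#' @param warn warn when no comparable pair exists.
#' @return concordance in `[0, 1]`, or `NA` if no pair is comparable.
#' @export
harrell_cindex <- function(risk, time, event, warn = TRUE) {
  n <- length(risk)
  cmp <- outer(time, time, "<") & matrix(event == 1, n, n)
  diag(cmp) <- FALSE
  npairs <- sum(cmp)
  if (npairs == 0) {
    if (warn) warning("no comparable pair; c-index undefined", call. = FALSE)
    return(NA_real_)
  }
  rd <- outer(risk, risk, "-")
  conc <- sum(cmp & rd > 0) + 0.5 * sum(cmp & rd == 0)
  conc / npairs
}

#' Concordance of ICARE-survival predictions
#'
#' ICARE survival models predict a risk score that is anti-concordant with
#' the time target (higher risk, shorter time); this evaluates that
#' orientation, i.e. it is [harrell_cindex()] applied to the predictions.
#'
#' @param predictions risk scores.
#' @inheritParams harrell_cindex
#' @return concordance in `[0, 1]`.
#' @export
icare_survival_direction <- function(predictions, time, event) {
  harrell_cindex(predictions, time, event, warn = FALSE)
}

#' CoxNet configuration
#'
#' @param l1_ratio_grid elastic-net mixing values (1 = lasso).
#' @param alpha_min_ratio smallest-to-largest penalty ratio of the path.
#' @param n_alphas number of penalty values on the path.
#' @param max_iter maximum coordinate-descent iterations.
#' @param cv_folds,shuffle cross-validation geometry (shuffled k-fold).
#' @param seed integer seed.
#' @return a list of class `coxnet_config`.
#' @export
coxnet_config <- function(l1_ratio_grid = c(0.5, 0.9, 1.0),
                          alpha_min_ratio = 0.01, n_alphas = 50L,
                          max_iter = 1e5, cv_folds = 10L, shuffle = TRUE,
                          seed = 1L) {
  stopifnot(all(l1_ratio_grid > 0), all(l1_ratio_grid <= 1), cv_folds >= 2)
  structure(as.list(environment()), class = "coxnet_config")
}

#' Elastic-net Cox path
#'
#' Thin wrapper fitting the penalized Cox model over a penalty path on
#' standardized features.
#'
#' @param X feature matrix.
#' @param time,event survival outcome.
#' @param l1_ratio elastic-net mixing parameter.
#' @param cfg a [coxnet_config()].
#' @return a `glmnet` fit.
#' @export
coxnet_path <- function(X, time, event, l1_ratio = 1,
                        cfg = coxnet_config()) {
  glmnet::glmnet(as.matrix(X), survival::Surv(time, event), family = "cox",
                 alpha = l1_ratio, nlambda = cfg$n_alphas,
                 lambda.min.ratio = cfg$alpha_min_ratio,
                 maxit = cfg$max_iter, standardize = TRUE)
}

#' Cross-validated elastic-net Cox time-to-progression model
#'
#' Standardizes the features, fits the elastic-net Cox model over a penalty
#' path for each mixing value, selects the (mixing, penalty) pair
#' maximizing the mean shuffled k-fold cross-validated Harrell c-index,
#' and reports the c-index mean and SD at the selected pair together with
#' the nonzero coefficients of the full-data refit.
#'
#' @param X feature matrix (samples x features).
#' @param time,event survival outcome (>= 2 events required).
#' @param cfg a [coxnet_config()].
#' @return list of class `coxnet_result`: `cindex_mean`, `cindex_sd`,
#'   `per_fold`, `best_l1_ratio`, `best_lambda`, `coefficients`
#'   (nonzero), `selected_features`.
#' @export
coxnet_ttp <- function(X, time, event, cfg = coxnet_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (sum(event) < 2) stop("need >= 2 events", call. = FALSE)
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  X <- X[, keep, drop = FALSE]
  Xs <- scale(X)
  n <- nrow(Xs)
  set.seed(derive_seed(cfg$seed, "coxnet_cv"))
  ord <- if (cfg$shuffle) sample.int(n) else seq_len(n)
  folds <- integer(n); folds[ord] <- rep_len(seq_len(cfg$cv_folds), n)
  best <- list(score = -Inf)
  for (l1 in cfg$l1_ratio_grid) {
    full <- coxnet_path(Xs, time, event, l1, cfg)
    lam <- full$lambda
    cmat <- matrix(NA_real_, cfg$cv_folds, length(lam))
    for (k in seq_len(cfg$cv_folds)) {
      tr <- folds != k
      if (sum(event[tr]) < 2 || sum(!tr) < 2) next
      fit <- tryCatch(
        glmnet::glmnet(Xs[tr, , drop = FALSE],
                       survival::Surv(time[tr], event[tr]), family = "cox",
                       alpha = l1, lambda = lam, maxit = cfg$max_iter),
        error = function(e) NULL)
      if (is.null(fit)) next
      lp <- stats::predict(fit, Xs[!tr, , drop = FALSE], s = lam,
                           type = "link")
      for (j in seq_along(lam)) {
        cmat[k, j] <- harrell_cindex(lp[, min(j, ncol(lp))], time[!tr],
                                     event[!tr], warn = FALSE)
      }
    }
    mean_c <- colMeans(cmat, na.rm = TRUE)
    jbest <- which.max(mean_c)
    if (length(jbest) && mean_c[jbest] > best$score) {
      best <- list(score = mean_c[jbest], l1 = l1, lambda = lam[jbest],
                   per_fold = cmat[, jbest], fit = full)
    }
  }
  cf <- as.matrix(stats::coef(best$fit, s = best$lambda))
  nz <- cf[cf[, 1] != 0, 1, drop = TRUE]
  structure(list(cindex_mean = best$score,
                 cindex_sd = stats::sd(best$per_fold, na.rm = TRUE),
                 per_fold = best$per_fold,
                 best_l1_ratio = best$l1, best_lambda = best$lambda,
                 coefficients = nz,
                 selected_features = names(nz)),
            class = "coxnet_result")
}

# sklearn-style chi-square statistic of nonnegative feature mass vs class
chi2_scores <- function(X, y) {
  X <- sweep(as.matrix(X), 2, apply(X, 2, min))   # shift to >= 0
  classes <- sort(unique(y))
  tot <- colSums(X)
  stat <- rep(0, ncol(X))
  for (cl in classes) {
    obs <- colSums(X[y == cl, , drop = FALSE])
    exp_ <- tot * mean(y == cl)
    ok <- exp_ > 0
    stat[ok] <- stat[ok] + (obs[ok] - exp_[ok])^2 / exp_[ok]
  }
  stat
}

# plug-in mutual information between a discretized feature and the label
mi_scores <- function(X, y, bins = 8L) {
  apply(as.matrix(X), 2, function(v) {
    if (length(unique(v)) <= bins) {
      d <- factor(v)                       # discrete feature: use values
    } else {
      br <- unique(stats::quantile(v, probs = seq(0, 1,
                                                  length.out = bins + 1)))
      if (length(br) < 2) return(0)
      d <- cut(v, br, include.lowest = TRUE)
    }
    tab <- table(d, y) / length(v)
    px <- rowSums(tab); py <- colSums(tab)
    mi <- 0
    for (i in seq_along(px)) for (j in seq_along(py)) {
      if (tab[i, j] > 0) mi <- mi + tab[i, j] * log(tab[i, j] / (px[i] * py[j]))
    }
    mi
  })
}

#' Feature selection front-ends for survival analysis
#'
#' Each method ranks or selects features against the *binary* progression
#' label (by design: selection on the classification outcome, the
#' survival model on the selected features). Methods: `"sfs"` (wrapper,
#' LDA-scored), `"chi2"` (on features shifted to be nonnegative),
#' `"mutual_info"` (quantile-binned plug-in MI), `"rf_importance"`
#' (Gini importance), `"lasso"` (order of entry along the L1 path).
#'
#' @param X feature matrix.
#' @param y 0/1 labels.
#' @param method selection method.
#' @param k target subset size.
#' @param seed integer seed.
#' @return character vector of selected feature names.
#' @export
survival_feature_select <- function(X, y,
                                    method = c("sfs", "chi2", "mutual_info",
                                               "rf_importance", "lasso"),
                                    k = 10L, seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  k <- min(k, ncol(X))
  if (k == ncol(X) && method != "lasso") return(colnames(X))
  switch(method,
    sfs = sequential_forward_selection(X, y, "lda", inner_folds = 3L,
                                       max_features = k, seed = seed),
    chi2 = colnames(X)[order(chi2_scores(X, y), decreasing = TRUE)[1:k]],
    mutual_info = colnames(X)[order(mi_scores(X, y),
                                    decreasing = TRUE)[1:k]],
    rf_importance = {
      set.seed(derive_seed(seed, "rf_imp"))
      fit <- randomForest::randomForest(x = X, y = factor(y), ntree = 500L)
      imp <- randomForest::importance(fit)[, 1]
      colnames(X)[order(imp, decreasing = TRUE)[1:k]]
    },
    lasso = {
      fit <- glmnet::glmnet(X, y, family = "binomial")
      entry <- apply(as.matrix(fit$beta) != 0, 1, function(r) {
        if (any(r)) which(r)[1] else Inf
      })
      sel <- names(sort(entry))[seq_len(k)]
      sel <- sel[is.finite(entry[sel])]
      if (length(sel) == 0L) {
        stop("lasso selected no feature; decrease the penalty", call. = FALSE)
      }
      sel
    })
}

#' Compare TTP models across feature sets
#'
#' Evaluates ICARE-survival and CoxNet with each feature-selection
#' front-end on each feature-set combination by k-fold cross-validation:
#' per fold, features are selected on the training split (using the binary
#' label), the survival model is fitted on the training split, and the
#' Harrell c-index is computed on the test split.
#'
#' @param feature_sets named list of feature matrices (same subjects).
#' @param time,event survival outcome.
#' @param y binary progression labels (drives feature selection).
#' @param methods subset of `"icare"`, `"sfs"`, `"chi2"`, `"mutual_info"`,
#'   `"rf_importance"`, `"lasso"`.
#' @param k features per selection.
#' @param cv_folds,cv_repeats outer CV geometry.
#' @param cfg a [coxnet_config()] for the CoxNet fits (its
#'   `l1_ratio_grid`/path settings; inner fold count is reduced to 3).
#' @param icare_n_models ensemble size for the ICARE rows.
#' @param seed integer seed.
#' @return data.frame: `feature_set`, `method`, `cindex_mean`, `cindex_sd`.
#' @export
ttp_compare <- function(feature_sets, time, event, y,
                        methods = c("icare", "sfs", "chi2", "mutual_info",
                                    "rf_importance", "lasso"),
                        k = 10L, cv_folds = 5L, cv_repeats = 1L,
                        cfg = coxnet_config(), icare_n_models = 100L,
                        seed = 1L) {
  rows <- list()
  for (fs in names(feature_sets)) {
    X <- as.matrix(feature_sets[[fs]])
    if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
    n <- nrow(X)
    for (m in methods) {
      cs <- c()
      for (rep in seq_len(cv_repeats)) {
        set.seed(derive_seed(seed, paste0("ttp", fs, m, rep)))
        folds <- sample(rep_len(seq_len(cv_folds), n))
        for (kf in seq_len(cv_folds)) {
          tr <- folds != kf
          if (sum(event[tr]) < 2 || length(unique(y[tr])) < 2) next
          ci <- tryCatch({
            if (m == "icare") {
              ens <- icare_fit_bagged(
                X[tr, , drop = FALSE],
                list(time = time[tr], event = event[tr]),
                icare_params(n_models = icare_n_models),
                seed = derive_seed(seed, paste0("ic", fs, rep, kf)))
              pr <- predict(ens, X[!tr, , drop = FALSE])
              icare_survival_direction(pr, time[!tr], event[!tr])
            } else {
              sel <- survival_feature_select(
                X[tr, , drop = FALSE], y[tr], m, k,
                seed = derive_seed(seed, paste0("sel", fs, rep, kf)))
              inner_cfg <- cfg; inner_cfg$cv_folds <- 3L
              inner_cfg$seed <- derive_seed(seed, paste0("cx", fs, rep, kf))
              fit <- coxnet_ttp(X[tr, sel, drop = FALSE], time[tr],
                                event[tr], inner_cfg)
              full <- coxnet_path(scale(X[tr, sel, drop = FALSE]), time[tr],
                                  event[tr], fit$best_l1_ratio, inner_cfg)
              mu <- colMeans(X[tr, sel, drop = FALSE])
              sd_ <- apply(X[tr, sel, drop = FALSE], 2, stats::sd)
              sd_[sd_ == 0] <- 1
              Xte <- sweep(sweep(X[!tr, sel, drop = FALSE], 2, mu), 2,
                           sd_, "/")
              lp <- stats::predict(full, Xte, s = fit$best_lambda,
                                   type = "link")
              harrell_cindex(as.numeric(lp), time[!tr], event[!tr],
                             warn = FALSE)
            }
          }, error = function(e) NA_real_)
          cs <- c(cs, ci)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature_set = fs, method = m,
        cindex_mean = mean(cs, na.rm = TRUE),
        cindex_sd = stats::sd(cs, na.rm = TRUE), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Recurrence-volume regression with gradient boosting
#'
#' Predicts the end-of-treatment total metabolic tumor volume from
#' baseline features with a gradient-boosting regressor. Features and
#' target are standardized first; a cross-validated grid search over the
#' boosting hyperparameters (number of trees, learning rate, tree depth,
#' minimum child weight) selects the best setting; cross-validated R2,
#' MAE and MAPE are reported on the standardized scale (raw-scale MAE is
#' also returned). Standardized targets with magnitude below `mape_eps`
#' are excluded from MAPE, with the excluded count reported.
#'
#' @param X baseline feature matrix (n >= 10).
#' @param tmtv_eot target volumes (nonzero variance).
#' @param grid data.frame of hyperparameter combinations with columns
#'   `nrounds`, `eta`, `max_depth`, `min_child_weight`; a small default
#'   grid is used when NULL.
#' @param cv_folds CV folds of the grid search.
#' @param mape_eps MAPE exclusion threshold on the standardized target.
#' @param seed integer seed.
#' @return list: `R2`, `MAE`, `MAPE`, their per-fold SDs, `MAE_raw`,
#'   `best_params`, `n_mape_excluded`.
#' @export
recurrence_volume_regression <- function(X, tmtv_eot, grid = NULL,
                                         cv_folds = 5L, mape_eps = 0.01,
                                         seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 10L) stop("need n >= 10", call. = FALSE)
  if (stats::sd(tmtv_eot) == 0) stop("zero-variance target", call. = FALSE)
  keep <- correlation_filter(X, 0.8)
  Xs <- scale(X[, keep, drop = FALSE])
  y_mu <- mean(tmtv_eot); y_sd <- stats::sd(tmtv_eot)
  ys <- (tmtv_eot - y_mu) / y_sd
  if (is.null(grid)) {
    grid <- expand.grid(nrounds = c(100L, 300L), eta = c(0.05, 0.1),
                        max_depth = c(2L, 3L), min_child_weight = c(1, 3))
  }
  set.seed(derive_seed(seed, "gbr_cv"))
  folds <- sample(rep_len(seq_len(cv_folds), n))
  eval_combo <- function(g) {
    pred <- rep(NA_real_, n)
    for (k in seq_len(cv_folds)) {
      tr <- folds != k
      fit <- xgboost::xgboost(
        x = Xs[tr, , drop = FALSE], y = ys[tr],
        nrounds = g$nrounds, learning_rate = g$eta,
        max_depth = g$max_depth, min_child_weight = g$min_child_weight,
        verbosity = 0, nthreads = 1)
      pred[!tr] <- stats::predict(fit, Xs[!tr, , drop = FALSE])
    }
    pred
  }
  best <- list(r2 = -Inf)
  for (i in seq_len(nrow(grid))) {
    pred <- eval_combo(grid[i, ])
    r2 <- 1 - sum((ys - pred)^2) / sum((ys - mean(ys))^2)
    if (r2 > best$r2) best <- list(r2 = r2, pred = pred, params = grid[i, ])
  }
  pred <- best$pred
  per_fold <- lapply(seq_len(cv_folds), function(k) {
    te <- folds == k
    mape_ok <- te & abs(ys) >= mape_eps
    c(r2 = 1 - sum((ys[te] - pred[te])^2) / sum((ys[te] - mean(ys))^2),
      mae = mean(abs(ys[te] - pred[te])),
      mape = if (any(mape_ok)) {
        mean(abs((ys[mape_ok] - pred[mape_ok]) / ys[mape_ok]))
      } else NA_real_)
  })
  pf <- do.call(rbind, per_fold)
  list(R2 = best$r2,
       R2_sd = stats::sd(pf[, "r2"], na.rm = TRUE),
       MAE = mean(pf[, "mae"], na.rm = TRUE),
       MAE_sd = stats::sd(pf[, "mae"], na.rm = TRUE),
       MAPE = mean(pf[, "mape"], na.rm = TRUE),
       MAPE_sd = stats::sd(pf[, "mape"], na.rm = TRUE),
       MAE_raw = mean(abs(ys - pred)) * y_sd,
       best_params = best$params,
       n_mape_excluded = sum(abs(ys) < mape_eps))
}
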