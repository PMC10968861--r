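# ICARE: binary-weighted risk models and their bagged ensemble.
#
# Each member model z-scores its training features, scores every feature by
# univariate performance (AUC for classification, Harrell concordance for
# survival), keeps only features whose margin |u - 0.5| clears Cmin,
# greedily decorrelates the survivors, retains a random subset of at most F
# of them, and predicts the mean of the sign-weighted z-scored features.
# The ensemble aggregates member predictions with the median.

#' Mann-Whitney AUC of a score against a binary label
#'
#' Tied score pairs count 0.5 (the standard Mann-Whitney convention).
#'
#' @param score numeric scores.
#' @param y 0/1 labels (both classes present).
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(score, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)                      # midranks handle ties as 0.5 pairs
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ICARE hyperparameters
#'
#' @param F_features number of features retained per member model.
#' @param Cmin univariate-performance margin in `[0, 0.5)`: features with
#'   `|u - 0.5| < Cmin` are dropped.
#' @param rho decorrelation threshold in `(0, 1]` on absolute Pearson
#'   correlation.
#' @param n_models ensemble size.
#' @return a named list.
#' @export
icare_params <- function(F_features = 10L, Cmin = 0.05, rho = 0.8,
                         n_models = 1000L) {
  stopifnot(F_features >= 1, Cmin >= 0, Cmin < 0.5, rho > 0, rho <= 1,
            n_models >= 1)
  list(F_features = as.integer(F_features), Cmin = Cmin, rho = rho,
       n_models = as.integer(n_models))
}

# univariate performance of each feature: AUC vs binary y, or Harrell c of
# the feature used directly as a risk score vs (time, event)
icare_univariate <- function(X, target) {
  if (is.list(target) && !is.null(target$time)) {
    apply(X, 2, function(x) {
      harrell_cindex(x, target$time, target$event, warn = FALSE)
    })
  } else {
    apply(X, 2, auc_mw, y = target)
  }
}

#' Fit a single binary-weighted (ICARE) model
#'
#' @param X numeric matrix (samples x features) with column names.
#' @param target either a 0/1 label vector (classification) or a list with
#'   `time` and `event` (survival; higher risk means shorter time).
#' @param params an [icare_params()] list.
#' @param seed integer seed for the random feature subsample.
#' @return an object of class `icare_model` storing per retained feature
#'   the sign weight and training mean/SD.
#' @export
icare_fit_single <- function(X, target, params = icare_params(), seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0 | is.na(sd_)] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  u <- icare_univariate(Z, target)
  u[is.na(u)] <- 0.5
  w <- ifelse(u > 0.5, 1, -1)
  margin <- abs(u - 0.5)
  keep <- which(margin >= params$Cmin & margin > 0)
  if (length(keep) > 1L) {                 # greedy decorrelation
    ord <- keep[order(margin[keep], decreasing = TRUE)]
    retained <- ord[1]
    for (j in ord[-1]) {
      r <- suppressWarnings(abs(stats::cor(Z[, j], Z[, retained])))
      r[is.na(r)] <- 0
      if (all(r <= params$rho)) retained <- c(retained, j)
    }
    keep <- retained
  }
  if (length(keep) > params$F_features) {
    set.seed(seed)
    keep <- sample(keep, params$F_features)
  }
  if (length(keep) == 0L) {
    warning("no feature cleared the Cmin margin; model predicts constant 0",
            call. = FALSE)
  }
  structure(list(features = colnames(X)[keep], w = unname(w[keep]),
                 mu = unname(mu[keep]), sd = unname(sd_[keep]),
                 u = unname(u[keep])),
            class = "icare_model")
}

#' Predict risk scores from a single ICARE model
#'
#' @param object an `icare_model`.
#' @param newdata matrix or data.frame with the model's feature columns.
#' @param ... unused.
#' @return numeric risk scores (mean of sign-weighted z-scored features;
#'   0 for an empty model).
#' @export
predict.icare_model <- function(object, newdata, ...) {
  if (length(object$features) == 0L) return(rep(0, nrow(newdata)))
  Xs <- as.matrix(newdata[, object$features, drop = FALSE])
  Z <- sweep(sweep(Xs, 2, object$mu), 2, object$sd, "/")
  as.numeric(Z %*% object$w) / length(object$w)
}

#' Median-aggregated ensemble prediction
#'
#' Each member is applied with its own stored normalization; per-sample
#' member predictions are aggregated with the median.
#'
#' @param models list of `icare_model`s (or an `icare_ensemble`).
#' @param newdata matrix or data.frame of features.
#' @return numeric risk scores.
#' @export
icare_predict_ensemble <- function(models, newdata) {
  if (inherits(models, "icare_ensemble")) models <- models$models
  stopifnot(length(models) >= 1L)
  preds <- vapply(models, predict, numeric(nrow(newdata)),
                  newdata = newdata)
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  apply(preds, 1, stats::median)
}

#' Fit a bagged ICARE ensemble
#'
#' `n_models` members, each fit on an independent bootstrap resample of the
#' training set with its own random feature subsample. When `param_sets`
#' (a list of [icare_params()]) is given, each member draws one set
#' uniformly — this is how the tuned top-B hyperparameter sets enter.
#'
#' @inheritParams icare_fit_single
#' @param param_sets optional list of hyperparameter sets.
#' @return an object of class `icare_ensemble`.
#' @export
icare_fit_bagged <- function(X, target, params = icare_params(), seed = 1L,
                             param_sets = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  n <- nrow(X)
  surv <- is.list(target) && !is.null(target$time)
  models <- vector("list", params$n_models)
  set.seed(derive_seed(seed, "icare_bagged"))
  member_seeds <- sample.int(2^30, params$n_models)
  for (m in seq_len(params$n_models)) {
    set.seed(member_seeds[m])
    idx <- sample.int(n, n, replace = TRUE)
    p_m <- if (is.null(param_sets)) params else
      param_sets[[sample.int(length(param_sets), 1)]]
    tgt <- if (surv) list(time = target$time[idx], event = target$event[idx])
      else target[idx]
    models[[m]] <- suppressWarnings(
      icare_fit_single(X[idx, , drop = FALSE], tgt, p_m,
                       seed = member_seeds[m]))
  }
  structure(list(models = models, params = params, survival = surv),
            class = "icare_ensemble")
}

#' @export
predict.icare_ensemble <- function(object, newdata, ...) {
  icare_predict_ensemble(object, newdata)
}

# Monte Carlo CV score (AUC or c-index) of a small ensemble under one
# hyperparameter set
icare_mc_cv_score <- function(X, target, params, n_splits, test_frac,
                              n_models_eval, seed) {
  n <- nrow(X)
  surv <- is.list(target) && !is.null(target$time)
  set.seed(seed)
  split_seeds <- sample.int(2^30, n_splits)
  scores <- numeric(n_splits)
  for (s in seq_len(n_splits)) {
    set.seed(split_seeds[s])
    test <- sample.int(n, max(2, round(test_frac * n)))
    train <- setdiff(seq_len(n), test)
    tgt_tr <- if (surv) list(time = target$time[train],
                             event = target$event[train]) else target[train]
    p <- params; p$n_models <- n_models_eval
    ens <- icare_fit_bagged(X[train, , drop = FALSE], tgt_tr, p,
                            seed = split_seeds[s])
    pr <- predict(ens, X[test, , drop = FALSE])
    scores[s] <- if (surv) {
      harrell_cindex(pr, target$time[test], target$event[test], warn = FALSE)
    } else {
      auc_mw(pr, target[test])
    }
  }
  mean(scores, na.rm = TRUE)
}

#' Randomized hyperparameter tuning for the bagged ensemble
#'
#' Samples `n_candidate_sets` hyperparameter sets (F uniform on
#' `1..min(30, p)`, Cmin uniform on `[0, 0.2]`, rho uniform on
#' `[0.3, 1]`), scores each with Monte Carlo CV, keeps the top `B`, and
#' fits a final ensemble whose members each draw one of the top-B sets
#' uniformly. `B` itself is chosen from `B_grid` by an extra CV loop.
#'
#' @inheritParams icare_fit_single
#' @param n_candidate_sets number of random hyperparameter sets.
#' @param n_models ensemble size of the final model.
#' @param B_grid candidate values of B.
#' @param mc_splits,mc_test_frac,mc_models Monte Carlo CV settings used to
#'   score candidates (splits, held-out fraction, members per evaluation).
#' @return an `icare_ensemble` with elements `tuning` (candidate table) and
#'   `B` attached.
#' @export
icare_tune_bagged <- function(X, target, n_candidate_sets = 1000L,
                              n_models = 1000L, B_grid = c(1L, 3L, 5L, 10L),
                              mc_splits = 5L, mc_test_frac = 0.25,
                              mc_models = 10L, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 20L) stop("tuning needs n >= 20", call. = FALSE)
  p <- ncol(X)
  set.seed(derive_seed(seed, "icare_tune"))
  cand <- data.frame(
    F_features = sample.int(min(30L, p), n_candidate_sets, replace = TRUE),
    Cmin = stats::runif(n_candidate_sets, 0, 0.2),
    rho = stats::runif(n_candidate_sets, 0.3, 1))
  cand_seeds <- sample.int(2^30, n_candidate_sets)
  cand$score <- vapply(seq_len(n_candidate_sets), function(i) {
    pr <- icare_params(cand$F_features[i], cand$Cmin[i], cand$rho[i],
                       n_models = mc_models)
    icare_mc_cv_score(X, target, pr, mc_splits, mc_test_frac, mc_models,
                      cand_seeds[i])
  }, numeric(1))
  ord <- order(cand$score, decreasing = TRUE)
  B_grid <- B_grid[B_grid <= n_candidate_sets]
  b_scores <- vapply(B_grid, function(B) {
    sets <- lapply(ord[seq_len(B)], function(i) {
      icare_params(cand$F_features[i], cand$Cmin[i], cand$rho[i])
    })
    # extra CV loop over B: small ensemble drawing among the top-B sets
    n <- nrow(X)
    surv <- is.list(target) && !is.null(target$time)
    set.seed(derive_seed(seed, paste0("icare_B", B)))
    folds <- sample(rep_len(seq_len(3L), n))
    sc <- vapply(1:3, function(k) {
      tr <- folds != k
      tgt <- if (surv) list(time = target$time[tr], event = target$event[tr])
        else target[tr]
      ens <- icare_fit_bagged(X[tr, , drop = FALSE], tgt,
                              icare_params(n_models = 5L * mc_models),
                              seed = derive_seed(seed, paste0("Bf", B, k)),
                              param_sets = sets)
      prd <- predict(ens, X[!tr, , drop = FALSE])
      if (surv) harrell_cindex(prd, target$time[!tr], target$event[!tr],
                               warn = FALSE)
      else auc_mw(prd, target[!tr])
    }, numeric(1))
    mean(sc, na.rm = TRUE)
  }, numeric(1))
  B <- B_grid[which.max(b_scores)]
  top_sets <- lapply(ord[seq_len(B)], function(i) {
    icare_params(cand$F_features[i], cand$Cmin[i], cand$rho[i])
  })
  ens <- icare_fit_bagged(X, target, icare_params(n_models = n_models),
                          seed = derive_seed(seed, "icare_final"),
                          param_sets = top_sets)
  ens$tuning <- cand
  ens$B <- B
  ens$selected_sets <- top_sets
  ens
}

#' Serialize an ICARE model or ensemble to JSON
#'
#' @param model an `icare_model` or `icare_ensemble`.
#' @param path optional output path; if NULL the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
icare_to_json <- function(model, path = NULL) {
  strip <- function(m) m[c("features", "w", "mu", "sd")]
  obj <- if (inherits(model, "icare_ensemble")) {
    list(type = "ensemble", models = lapply(model$models, strip))
  } else {
    c(list(type = "single"), strip(model))
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
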