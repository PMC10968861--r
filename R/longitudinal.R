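# Longitudinal analysis: delta features (absolute / relative), imputation,
# z-scoring, scanner-effect testing and a longitudinal ComBat-style
# harmonization with a Kolmogorov-Smirnov post-check.

ANNOTATION_COLS <- c("subject_id", "timepoint", "scanner_id", "class")

#' Names of the feature columns of a feature table
#'
#' Everything except the annotation columns (`subject_id`, `timepoint`,
#' `scanner_id`, `class`).
#'
#' @param table a feature table data.frame.
#' @return character vector of feature names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), ANNOTATION_COLS)
}

#' Between-time-point feature changes (delta radiomics)
#'
#' Absolute change `EoT - baseline` or relative change
#' `(EoT - baseline) / baseline` per feature, for subjects present at both
#' time points. In relative mode a baseline magnitude below `eps` times the
#' column scale yields a missing value (to be mean-imputed downstream)
#' rather than a fabricated huge ratio.
#'
#' @param baseline,eot feature tables for the two time points (must share
#'   subjects by `subject_id`; extras are dropped with a warning).
#' @param mode `"absolute"` or `"relative"`.
#' @param eps relative guard threshold (fraction of the column median
#'   absolute value).
#' @return a feature table of deltas, columns prefixed `dabs_` / `drel_`.
#' @export
compute_delta <- function(baseline, eot, mode = c("absolute", "relative"),
                          eps = 1e-8) {
  mode <- match.arg(mode)
  common <- intersect(baseline$subject_id, eot$subject_id)
  extra <- setdiff(union(baseline$subject_id, eot$subject_id), common)
  if (length(extra)) {
    warning("subject(s) present at one time point only, excluded: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  b <- baseline[match(common, baseline$subject_id), , drop = FALSE]
  e <- eot[match(common, eot$subject_id), , drop = FALSE]
  feats <- intersect(feature_columns(baseline), feature_columns(eot))
  out <- data.frame(subject_id = common, stringsAsFactors = FALSE)
  pre <- if (mode == "absolute") "dabs_" else "drel_"
  for (f in feats) {
    d <- e[[f]] - b[[f]]
    if (mode == "relative") {
      scale_f <- stats::median(abs(b[[f]]), na.rm = TRUE)
      guard <- eps * max(scale_f, 1)
      d <- ifelse(abs(b[[f]]) < guard, NA_real_, d / b[[f]])
    }
    out[[paste0(pre, f)]] <- d
  }
  out
}

#' Assemble one of the analysis feature-set combinations
#'
#' The seven combinations the pipeline analyses per task: `baseline`, `eot`,
#' `baseline+eot`, `rel_delta`, `abs_delta`, `baseline+rel_delta`,
#' `baseline+abs_delta`. Columns are concatenated with provenance prefixes;
#' subjects are intersected across the required inputs.
#'
#' @param tables named list with elements `baseline` and/or `eot` (feature
#'   tables per time point).
#' @param combo one of the seven combination names.
#' @param eps relative-delta guard, see [compute_delta()].
#' @return a feature table with a `subject_id` column.
#' @export
build_feature_set <- function(tables,
                              combo = c("baseline", "eot", "baseline+eot",
                                        "rel_delta", "abs_delta",
                                        "baseline+rel_delta",
                                        "baseline+abs_delta"),
                              eps = 1e-8) {
  combo <- match.arg(combo)
  need_base <- grepl("baseline", combo) || grepl("delta", combo)
  need_eot <- grepl("eot", combo) || grepl("delta", combo)
  if (need_base && is.null(tables$baseline)) {
    stop("combo `", combo, "` requires a baseline table", call. = FALSE)
  }
  if (need_eot && is.null(tables$eot)) {
    stop("combo `", combo, "` requires an eot table", call. = FALSE)
  }
  prefix_tab <- function(tab, pre) {
    feats <- feature_columns(tab)
    out <- tab[, c("subject_id", feats), drop = FALSE]
    names(out)[-1] <- paste0(pre, feats)
    out
  }
  parts <- list()
  if (combo %in% c("baseline", "baseline+eot", "baseline+rel_delta",
                   "baseline+abs_delta")) {
    parts <- c(parts, list(prefix_tab(tables$baseline, "base_")))
  }
  if (combo %in% c("eot", "baseline+eot")) {
    parts <- c(parts, list(prefix_tab(tables$eot, "eot_")))
  }
  if (grepl("rel_delta", combo)) {
    parts <- c(parts, list(compute_delta(tables$baseline, tables$eot,
                                         "relative", eps)))
  }
  if (grepl("abs_delta", combo)) {
    parts <- c(parts, list(compute_delta(tables$baseline, tables$eot,
                                         "absolute", eps)))
  }
  ids <- Reduce(intersect, lapply(parts, `[[`, "subject_id"))
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (p in parts) {
    p <- p[match(ids, p$subject_id), , drop = FALSE]
    out <- cbind(out, p[, -1, drop = FALSE])
  }
  out
}

#' Mean imputation of missing feature values
#'
#' Missing cells are replaced by the column mean over observed values;
#' all-missing columns are dropped with a warning.
#'
#' @param table a feature table.
#' @return the imputed table.
#' @export
mean_impute <- function(table) {
  drop <- character(0)
  for (f in feature_columns(table)) {
    v <- table[[f]]
    if (all(is.na(v))) { drop <- c(drop, f); next }
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    table[[f]] <- v
  }
  if (length(drop)) {
    warning("dropping all-missing column(s): ", paste(drop, collapse = ", "),
            call. = FALSE)
    table <- table[, setdiff(names(table), drop), drop = FALSE]
  }
  table
}

#' Z-score normalization
#'
#' `(x - mu) / sigma` per feature column. When `fit_stats` is supplied
#' (from a training partition) its means/SDs are used, so held-out data is
#' transformed without leakage; otherwise statistics are computed from the
#' table itself and attached as attribute `fit_stats`. Zero-SD columns map
#' to 0.
#'
#' @param table a feature table.
#' @param fit_stats optional list with `mu` and `sigma` named vectors.
#' @return the normalized table (attribute `fit_stats` holds the
#'   statistics used).
#' @export
zscore <- function(table, fit_stats = NULL) {
  feats <- feature_columns(table)
  if (is.null(fit_stats)) {
    mu <- vapply(table[feats], function(v) mean(v, na.rm = TRUE), numeric(1))
    # population SD so a two-point column [0, 10] maps to [-1, 1]
    sigma <- vapply(table[feats], function(v) {
      v <- v[!is.na(v)]
      sqrt(mean((v - mean(v))^2))
    }, numeric(1))
    fit_stats <- list(mu = mu, sigma = sigma)
  }
  for (f in feats) {
    s <- fit_stats$sigma[[f]]
    table[[f]] <- if (is.na(s) || s == 0) {
      rep(0, nrow(table))
    } else {
      (table[[f]] - fit_stats$mu[[f]]) / s
    }
  }
  attr(table, "fit_stats") <- fit_stats
  table
}

#' Per-feature scanner-effect tests
#'
#' Welch two-sample t-test for an additive (mean-shift) scanner effect and
#' Bartlett's test for a multiplicative (heteroscedasticity) effect,
#' feature by feature, for exactly two scanner groups. Raw p-values are
#' flagged at `alpha`; Benjamini-Hochberg-adjusted flags are also reported.
#'
#' @param table a feature table.
#' @param scanner_ids vector of scanner labels, one per row (defaults to
#'   the table's `scanner_id` column).
#' @param alpha significance level for the flags.
#' @return data.frame with one row per feature: t/Bartlett statistics and
#'   p-values, flags, and BH-adjusted flags.
#' @export
scanner_effect_tests <- function(table, scanner_ids = table$scanner_id,
                                 alpha = 0.05) {
  g <- factor(scanner_ids)
  if (nlevels(g) != 2L) {
    stop("exactly two scanner groups required, got ", nlevels(g),
         call. = FALSE)
  }
  if (any(tabulate(g) < 3L)) stop("each scanner group needs n >= 3",
                                  call. = FALSE)
  feats <- feature_columns(table)
  res <- lapply(feats, function(f) {
    v <- table[[f]]
    tt <- stats::t.test(v ~ g)                       # Welch by default
    bt <- stats::bartlett.test(v, g)
    data.frame(feature = f, t_stat = unname(tt$statistic),
               t_p = tt$p.value, bartlett_stat = unname(bt$statistic),
               bartlett_p = bt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$additive_flag <- out$t_p < alpha
  out$multiplicative_flag <- out$bartlett_p < alpha
  out$additive_flag_bh <- stats::p.adjust(out$t_p, "BH") < alpha
  out$multiplicative_flag_bh <- stats::p.adjust(out$bartlett_p, "BH") < alpha
  out
}

# ComBat parametric empirical-Bayes iteration (location gamma, scale
# delta^2) for one batch across features. Standard aprior/bprior moments.
combat_eb_solve <- function(gamma_hat, delta2_hat, n_b, tol = 1e-6,
                            max_iter = 200) {
  g_bar <- mean(gamma_hat); t2 <- stats::var(gamma_hat)
  if (!is.finite(t2) || t2 == 0) t2 <- 1e-8
  m <- mean(delta2_hat); v <- stats::var(delta2_hat)
  if (!is.finite(v) || v == 0) v <- 1e-8
  a_prior <- (2 * v + m^2) / v
  b_prior <- (m * v + m^3) / v
  g_star <- gamma_hat; d_star <- delta2_hat
  for (it in seq_len(max_iter)) {
    g_new <- (n_b * t2 * gamma_hat + d_star * g_bar) / (n_b * t2 + d_star)
    sum2 <- delta2_hat * (n_b - 1) + n_b * (gamma_hat - g_new)^2
    d_new <- (0.5 * sum2 + b_prior) / (n_b / 2 + a_prior - 1)
    change <- max(abs(g_new - g_star), abs(d_new - d_star))
    g_star <- g_new; d_star <- d_new
    if (change < tol) break
  }
  list(gamma_star = g_star, delta2_star = d_star)
}

#' Longitudinal ComBat-style scanner harmonization
#'
#' Per feature, fits an additive linear model with subject intercepts, a
#' time-point effect and a scanner (batch) term; the batch location is
#' estimated from within-subject contrasts where subjects were scanned on
#' different scanners, batch scale from per-batch residual variances.
#' Batch parameters are shrunk across features by parametric empirical
#' Bayes (normal prior on locations, inverse-gamma on scales), and the
#' adjusted table is the non-batch fit plus standardized residuals with
#' batch effects removed.
#'
#' @param table a feature table.
#' @param scanner_ids,subject_ids,timepoints row annotations (default: the
#'   table's columns).
#' @param eb apply empirical-Bayes shrinkage of batch parameters across
#'   features (default TRUE); with `eb = FALSE` the raw per-batch estimates
#'   are removed exactly.
#' @param adjust `"location_scale"` (default) removes both the batch mean
#'   shift and the batch variance inflation; `"location"` removes only the
#'   shift, and combined with `eb = FALSE` is exactly idempotent.
#' @return the harmonized table; attribute `batch_params` holds the
#'   shrunken per-batch location/scale estimates.
#' @export
longitudinal_combat <- function(table, scanner_ids = table$scanner_id,
                                subject_ids = table$subject_id,
                                timepoints = table$timepoint, eb = TRUE,
                                adjust = c("location_scale", "location")) {
  adjust <- match.arg(adjust)
  batch <- factor(scanner_ids)
  subj <- factor(subject_ids)
  tp <- factor(timepoints)
  if (nlevels(batch) < 2L) stop(">= 2 scanners required", call. = FALSE)
  mixed <- any(tapply(as.integer(batch), subj,
                      function(b) length(unique(b))) > 1)
  if (!mixed) {
    warning("scanner perfectly confounded with subject; batch location ",
            "estimated from between-subject means", call. = FALSE)
  }
  feats <- feature_columns(table)
  nb <- nlevels(batch)
  n_f <- length(feats)
  gamma_hat <- matrix(0, n_f, nb)
  delta2_hat <- matrix(1, n_f, nb)
  nonbatch_fit <- matrix(0, nrow(table), n_f)
  sigma_f <- numeric(n_f)
  for (j in seq_along(feats)) {
    y <- table[[feats[j]]]
    # batch location from within-subject contrasts where available
    fit_b <- if (mixed) {
      stats::lm(y ~ subj + tp + batch)
    } else {
      stats::lm(y ~ tp + batch)
    }
    cf <- stats::coef(fit_b)
    bcoef <- cf[grep("^batch", names(cf))]
    bcoef[is.na(bcoef)] <- 0
    gb <- c(0, bcoef)                         # effect per batch level
    gb <- gb - mean(gb[as.integer(batch)])    # center over observations
    # non-batch fit: time-point model only, so residuals keep the
    # between-subject variability the scale estimate must see
    fit_tp <- stats::lm(y ~ tp)
    nonbatch_fit[, j] <- stats::fitted(fit_tp)
    resid_nb <- y - nonbatch_fit[, j]         # batch shift + subject + noise
    s <- stats::sd(resid_nb - gb[as.integer(batch)])
    if (!is.finite(s) || s == 0) s <- 1
    sigma_f[j] <- s
    z <- resid_nb / s
    gz <- gb / s
    gamma_hat[j, ] <- gz
    for (b in seq_len(nb)) {
      zb <- z[as.integer(batch) == b] - gz[b]
      delta2_hat[j, b] <- if (length(zb) > 1) stats::var(zb) else 1
    }
  }
  gamma_star <- gamma_hat; delta2_star <- delta2_hat
  if (eb && n_f >= 3) {                        # EB shrinkage needs spread
    for (b in seq_len(nb)) {
      n_b <- sum(as.integer(batch) == b)
      eb <- combat_eb_solve(gamma_hat[, b], delta2_hat[, b], n_b)
      gamma_star[, b] <- eb$gamma_star
      delta2_star[, b] <- eb$delta2_star
    }
  }
  out <- table
  for (j in seq_along(feats)) {
    y <- table[[feats[j]]]
    z <- (y - nonbatch_fit[, j]) / sigma_f[j]
    zadj <- z - gamma_star[j, as.integer(batch)]
    if (adjust == "location_scale") {
      zadj <- zadj / sqrt(pmax(delta2_star[j, as.integer(batch)], 1e-12))
    }
    out[[feats[j]]] <- nonbatch_fit[, j] + zadj * sigma_f[j]
  }
  attr(out, "batch_params") <- list(levels = levels(batch),
                                    gamma = gamma_star,
                                    delta2 = delta2_star,
                                    features = feats)
  out
}

#' Kolmogorov-Smirnov comparison of two feature tables
#'
#' Two-sample KS test per shared feature column; used as the post-check
#' that harmonization did not distort feature distributions.
#'
#' @param before,after feature tables of the same shape.
#' @param alpha flag level.
#' @return data.frame with per-feature KS statistic, p-value and flag.
#' @export
ks_compare <- function(before, after, alpha = 0.05) {
  feats <- intersect(feature_columns(before), feature_columns(after))
  res <- lapply(feats, function(f) {
    k <- suppressWarnings(stats::ks.test(before[[f]], after[[f]]))
    data.frame(feature = f, ks_stat = unname(k$statistic), p = k$p.value,
               flag = k$p.value < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
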