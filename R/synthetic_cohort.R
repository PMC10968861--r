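# Synthetic two-time-point PET/CT cohort with known ground truth.
#
# Lesions are spheres (optionally perturbed by a low-frequency radial
# modulation) with a radial uptake gradient; "treatment" shrinks the lesion
# and changes its heterogeneity; a latent response score built from the true
# (noise-free) relative TLG change plus a heterogeneity-change term drives
# both the progression probability (logistic) and the time-to-progression
# hazard (Weibull). Optional per-scanner additive and noise-inflation
# effects emulate multi-scanner acquisition.

#' Specification of a synthetic cohort
#'
#' Defaults emulate a two-time-point PMBCL-like
#' cohort: 31 subjects, 4 mm isotropic PET grids, a single bulky mediastinal
#' lesion per subject with peak SUV 6-20, strong responders in the large
#' majority, a marginal progression rate near 16%, TTP on a months scale
#' with moderate censoring, and two scanners with no injected scanner effect
#' (the harmonization knobs default off and are turned on in tests).
#'
#' @param n_subjects number of subjects.
#' @param grid_shape integer length-3 grid dimensions.
#' @param spacing voxel spacing in mm.
#' @param radius_range_mm baseline lesion radius range (uniform draw).
#' @param peak_suv_range lesion peak SUV above background (uniform draw).
#' @param gradient_exponent radial uptake gradient exponent g in
#'   `peak * (1 - (r/R)^g)`.
#' @param irregularity amplitude of the low-frequency radial modulation of
#'   the lesion surface (0 = perfect sphere).
#' @param background_suv,noise_sd_pet PET background level and Gaussian
#'   noise SD.
#' @param tissue_hu,lesion_offset_hu,noise_sd_ct CT soft-tissue level,
#'   lesion HU offset and noise SD.
#' @param responder_rate fraction of subjects whose lesion shrinks strongly.
#' @param shrink_responder,shrink_nonresponder uniform ranges for the EoT /
#'   baseline lesion *volume* ratio in each response group.
#' @param het_change_responder,het_change_nonresponder uniform ranges for
#'   the multiplicative change in the gradient exponent (heterogeneity).
#' @param beta0,beta logistic intercept and slope linking the latent score
#'   to progression probability.
#' @param het_weight weight of the relative heterogeneity change in the
#'   latent score (score = relative delta TLG + het_weight * relative
#'   delta g).
#' @param weibull_shape,weibull_scale0,hazard_slope TTP model: T ~ Weibull
#'   with shape k and scale `scale0 * exp(-hazard_slope * score / k)` so the
#'   hazard is proportional to `exp(hazard_slope * score)`.
#' @param censor_rate probability that a subject is censored (uniformly
#'   before the event time).
#' @param scanner_ids two scanner labels.
#' @param scanner_probs per-scan assignment probabilities.
#' @param scanner_shift additive global PET shift per scanner.
#' @param scanner_noise_inflation multiplicative PET noise-SD factor per
#'   scanner.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 31L,
                        grid_shape = c(32L, 32L, 32L),
                        spacing = c(4, 4, 4),
                        radius_range_mm = c(14, 30),
                        peak_suv_range = c(6, 20),
                        gradient_exponent = 2,
                        irregularity = 0,
                        background_suv = 1.0,
                        noise_sd_pet = 0.15,
                        tissue_hu = 40,
                        lesion_offset_hu = 25,
                        noise_sd_ct = 8,
                        responder_rate = 0.8,
                        shrink_responder = c(0.05, 0.35),
                        shrink_nonresponder = c(0.6, 1.1),
                        het_change_responder = c(0.7, 1.0),
                        het_change_nonresponder = c(1.0, 1.6),
                        beta0 = 0.7, beta = 4, het_weight = 0.5,
                        weibull_shape = 1.5, weibull_scale0 = 60,
                        hazard_slope = 2,
                        censor_rate = 0.3,
                        scanner_ids = c("D690", "D600"),
                        scanner_probs = c(0.5, 0.5),
                        scanner_shift = c(0, 0),
                        scanner_noise_inflation = c(1, 1),
                        seed = 1L) {
  stopifnot(censor_rate >= 0, censor_rate < 1,
            abs(sum(scanner_probs) - 1) < 1e-12,
            length(scanner_ids) == 2L)
  spec <- as.list(environment())
  class(spec) <- "cohort_spec"
  spec
}

# noise-free lesion PET/CT/mask on the grid; returns list(pet, ct, mask)
build_lesion_volumes <- function(spec, center_mm, R_mm, peak, g) {
  d <- spec$grid_shape; sp <- spec$spacing
  ax <- lapply(1:3, function(a) ((seq_len(d[a]) - 0.5) * sp[a]) - center_mm[a])
  X <- array(rep(ax[[1]], times = d[2] * d[3]), d)
  Y <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d)
  Z <- array(rep(ax[[3]], each = d[1] * d[2]), d)
  r <- sqrt(X^2 + Y^2 + Z^2)
  R_eff <- R_mm
  if (spec$irregularity > 0) {
    P <- 2 * R_mm
    R_eff <- R_mm * (1 + spec$irregularity *
                       (sin(2 * pi * X / P) + sin(2 * pi * Y / P) +
                          sin(2 * pi * Z / P)) / 3)
  }
  mask <- (r <= R_eff) * 1L
  if (sum(mask) == 0L || any(center_mm - R_mm < 0) ||
      any(center_mm + R_mm > d * sp)) {
    stop("lesion does not fit in grid (R = ", R_mm, " mm)", call. = FALSE)
  }
  pet <- array(spec$background_suv, d)
  Rv <- if (spec$irregularity > 0) R_eff[mask == 1] else R_mm
  pet[mask == 1] <- spec$background_suv +
    peak * (1 - pmin(r[mask == 1] / Rv, 1)^g)
  ct <- array(spec$tissue_hu, d)
  ct[mask == 1] <- spec$tissue_hu + spec$lesion_offset_hu
  list(pet = pet, ct = ct, mask = mask)
}

#' Simulate a two-time-point PET/CT cohort
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `scans` (per subject, a list with `baseline`
#'   and `eot` [scan_pair()]s), `outcomes` (outcome records data.frame) and
#'   `truth` (per-subject latent ground truth data.frame).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(derive_seed(spec$seed, "simulate_cohort"))
  d <- spec$grid_shape; sp <- spec$spacing
  center_mm <- d * sp / 2
  scans <- vector("list", spec$n_subjects)
  truth <- vector("list", spec$n_subjects)
  outcomes <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    sid <- sprintf("S%03d", i)
    R0 <- stats::runif(1, spec$radius_range_mm[1], spec$radius_range_mm[2])
    peak <- stats::runif(1, spec$peak_suv_range[1], spec$peak_suv_range[2])
    g0 <- spec$gradient_exponent
    responder <- stats::runif(1) < spec$responder_rate
    shr_rng <- if (responder) spec$shrink_responder else spec$shrink_nonresponder
    shrink <- stats::runif(1, shr_rng[1], shr_rng[2])
    het_rng <- if (responder) spec$het_change_responder else
      spec$het_change_nonresponder
    g1 <- g0 * stats::runif(1, het_rng[1], het_rng[2])
    R1 <- max(R0 * shrink^(1 / 3), 2 * min(sp))   # radius floor: 2 voxels
    base <- build_lesion_volumes(spec, center_mm, R0, peak, g0)
    eot <- build_lesion_volumes(spec, center_mm, R1, peak, g1)
    vox_ml <- prod(sp) / 1000
    tlg0 <- mean(base$pet[base$mask == 1]) * sum(base$mask) * vox_ml
    tlg1 <- mean(eot$pet[eot$mask == 1]) * sum(eot$mask) * vox_ml
    rel_dtlg <- (tlg1 - tlg0) / tlg0
    rel_dg <- (g1 - g0) / g0
    score <- rel_dtlg + spec$het_weight * rel_dg
    p_prog <- stats::plogis(spec$beta0 + spec$beta * score)
    progression <- as.integer(stats::runif(1) < p_prog)
    scale_i <- spec$weibull_scale0 *
      exp(-spec$hazard_slope * score / spec$weibull_shape)
    t_event <- stats::rweibull(1, shape = spec$weibull_shape, scale = scale_i)
    censored <- stats::runif(1) < spec$censor_rate
    ttp <- if (censored) stats::runif(1, 0, t_event) else t_event
    event <- as.integer(!censored)
    scn <- sample(spec$scanner_ids, 2, replace = TRUE,
                  prob = spec$scanner_probs)
    mk_scan <- function(vols, tp, scanner) {
      s_idx <- match(scanner, spec$scanner_ids)
      nsd <- spec$noise_sd_pet * spec$scanner_noise_inflation[s_idx]
      pet <- vols$pet + spec$scanner_shift[s_idx]
      if (nsd > 0) pet <- pet + stats::rnorm(length(pet), 0, nsd)
      ct <- vols$ct
      if (spec$noise_sd_ct > 0) {
        ct <- ct + stats::rnorm(length(ct), 0, spec$noise_sd_ct)
      }
      pet[pet < 0] <- 0
      scan_pair(sid, tp, pet = array(pet, d), ct = array(ct, d),
                mask = vols$mask, spacing = sp, scanner_id = scanner)
    }
    scans[[i]] <- list(baseline = mk_scan(base, "baseline", scn[1]),
                       eot = mk_scan(eot, "eot", scn[2]))
    truth[[i]] <- data.frame(
      subject_id = sid, responder = responder, shrinkage = shrink,
      R_baseline_mm = R0, R_eot_mm = R1, peak_suv = peak,
      g_baseline = g0, g_eot = g1, true_rel_delta_tlg = rel_dtlg,
      true_rel_delta_g = rel_dg, score = score, p_progression = p_prog,
      scanner_baseline = scn[1], scanner_eot = scn[2],
      stringsAsFactors = FALSE)
    outcomes[[i]] <- data.frame(
      subject_id = sid, progression = progression,
      ttp_months = ttp, event = event, scanner_id = scn[2],
      stringsAsFactors = FALSE)
  }
  list(scans = scans,
       outcomes = validate_outcomes(do.call(rbind, outcomes)),
       truth = do.call(rbind, truth))
}

#' Simulate a tabular feature batch (no images)
#'
#' Direct Gaussian feature generator for exercising harmonization and the
#' model stack without image synthesis: optional per-scanner mean shift and
#' noise inflation, optional class-linked effect sizes on a subset of
#' features, and an optional longitudinal layout (two time points per
#' subject with subject-specific intercepts).
#'
#' @param n subjects (>= 4).
#' @param n_features number of features.
#' @param scanner_shift additive shift applied to features on the second
#'   scanner (scalar or per-feature vector).
#' @param scanner_inflation SD multiplier on the second scanner.
#' @param class_effect_d standardized mean difference between classes on the
#'   informative features.
#' @param n_informative how many leading features carry the class effect.
#' @param class_rate P(class = 1).
#' @param longitudinal if TRUE, two rows per subject (baseline/eot) with
#'   N(0, subject_sd^2) subject intercepts; scanners are assigned per row.
#' @param subject_sd SD of the subject random intercepts.
#' @param seed integer seed.
#' @return a data.frame with annotation columns `subject_id`, `scanner_id`,
#'   `class` (and `timepoint` when longitudinal) followed by feature
#'   columns `f1..fp`.
#' @export
simulate_feature_batch <- function(n, n_features,
                                   scanner_shift = 0, scanner_inflation = 1,
                                   class_effect_d = 0, n_informative = 0,
                                   class_rate = 0.5,
                                   longitudinal = FALSE, subject_sd = 1,
                                   seed = 1L) {
  stopifnot(n >= 4)
  set.seed(derive_seed(seed, "simulate_feature_batch"))
  shift <- rep(scanner_shift, length.out = n_features)
  sids <- sprintf("S%03d", seq_len(n))
  y <- as.integer(stats::runif(n) < class_rate)
  reps <- if (longitudinal) 2L else 1L
  rows <- n * reps
  scanner <- sample(c("A", "B"), rows, replace = TRUE)
  X <- matrix(stats::rnorm(rows * n_features), rows, n_features)
  if (longitudinal) {
    b <- stats::rnorm(n, 0, subject_sd)
    X <- X + b[rep(seq_len(n), each = 2L)]      # subject intercepts
    X <- X + rep(c(0, 0.5), times = n)           # time-point effect
  }
  if (n_informative > 0 && class_effect_d != 0) {
    yy <- y[rep(seq_len(n), each = reps)]
    X[, seq_len(n_informative)] <- X[, seq_len(n_informative)] +
      outer(yy, rep(class_effect_d, n_informative))
  }
  isB <- scanner == "B"
  if (any(isB)) {
    X[isB, ] <- X[isB, , drop = FALSE] * scanner_inflation +
      matrix(shift, sum(isB), n_features, byrow = TRUE)
  }
  colnames(X) <- paste0("f", seq_len(n_features))
  ann <- data.frame(subject_id = sids[rep(seq_len(n), each = reps)],
                    scanner_id = scanner,
                    class = y[rep(seq_len(n), each = reps)],
                    stringsAsFactors = FALSE)
  if (longitudinal) ann$timepoint <- rep(c("baseline", "eot"), times = n)
  cbind(ann, as.data.frame(X))
}

#' Write a simulated cohort to disk
#'
#' NIfTI volumes per subject/time point plus outcomes and ground-truth CSVs.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory.
#' @param compress write .nii.gz volumes.
#' @return the manifest data.frame (one row per scan with file paths),
#'   invisibly; also written as `manifest.csv`.
#' @export
write_cohort <- function(cohort, dir, compress = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (sub in cohort$scans) {
    for (tp in c("baseline", "eot")) {
      s <- sub[[tp]]
      paths <- write_scan_pair(s, file.path(dir, "volumes"), compress)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s$subject_id, timepoint = tp, scanner_id = s$scanner_id,
        pet = paths[["pet"]], ct = paths[["ct"]], mask = paths[["mask"]],
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
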