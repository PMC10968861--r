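# Single-time-point radiomic features: first-order SUV/HU statistics,
# MTV/TLG, Dmax, AUC-CSH, intensity entropy, NGTDM and GLRLM texture
# features on discretized intensities.

#' Discretization settings for texture features
#'
#' Fixed-bin-width discretization: PET bins of 0.3125 SUV into 64 grey
#' levels, CT bins of 10 HU into 400 levels. The anchor is either the ROI
#' minimum (`roi_min`, the default, matching common radiomics-library
#' behaviour) or absolute zero (`zero`); levels are clipped to the
#' configured count.
#'
#' @param pet_bin_width bin width in SUV.
#' @param pet_levels number of PET grey levels.
#' @param ct_bin_width bin width in HU.
#' @param ct_levels number of CT grey levels.
#' @param anchor `"roi_min"` or `"zero"`.
#' @return a list of class `discretization_config`.
#' @export
discretization_config <- function(pet_bin_width = 0.3125, pet_levels = 64L,
                                  ct_bin_width = 10, ct_levels = 400L,
                                  anchor = c("roi_min", "zero")) {
  anchor <- match.arg(anchor)
  stopifnot(pet_bin_width > 0, ct_bin_width > 0,
            pet_levels >= 2, ct_levels >= 2)
  structure(list(pet_bin_width = pet_bin_width,
                 pet_levels = as.integer(pet_levels),
                 ct_bin_width = ct_bin_width,
                 ct_levels = as.integer(ct_levels),
                 anchor = anchor),
            class = "discretization_config")
}

#' Discretize intensities into integer grey levels
#'
#' `level(v) = min(levels, floor((v - anchor_value) / bin_width) + 1)`,
#' clipped below at 1. Under `anchor = "roi_min"` the anchor value is the
#' minimum of the supplied intensities (pass `anchor_value` to reuse a
#' ROI-derived anchor for a whole volume).
#'
#' @param intensities numeric vector or array.
#' @param config a [discretization_config()].
#' @param modality `"pet"` or `"ct"`.
#' @param anchor_value optional explicit anchor.
#' @return integer levels, same shape as the input.
#' @export
discretize <- function(intensities, config = discretization_config(),
                       modality = c("pet", "ct"), anchor_value = NULL) {
  modality <- match.arg(modality)
  if (length(intensities) == 0L) stop("empty-ROI: no intensities", call. = FALSE)
  width <- if (modality == "pet") config$pet_bin_width else config$ct_bin_width
  nlev <- if (modality == "pet") config$pet_levels else config$ct_levels
  if (is.null(anchor_value)) {
    anchor_value <- if (config$anchor == "roi_min") min(intensities) else 0
  }
  lev <- floor((intensities - anchor_value) / width) + 1
  lev <- pmin(pmax(lev, 1), nlev)
  storage.mode(lev) <- "integer"
  if (!is.null(dim(intensities))) dim(lev) <- dim(intensities)
  lev
}

#' First-order statistics of a masked volume
#'
#' Max, mean, metabolic volume (ml), total lesion glycolysis
#' (mean x volume; meaningful for PET) and grey-level entropy
#' (base-2, over the discretized-level histogram).
#'
#' @param volume 3D numeric array (SUV or HU).
#' @param mask 3D 0/1 array, same shape.
#' @param spacing voxel spacing (mm).
#' @param config discretization used for the entropy histogram.
#' @param modality `"pet"` or `"ct"`.
#' @return named list: `max`, `mean`, `MTV_ml`, `TLG`, `entropy`.
#' @export
first_order <- function(volume, mask, spacing,
                        config = discretization_config(),
                        modality = c("pet", "ct")) {
  modality <- match.arg(modality)
  vals <- volume[mask > 0]
  if (length(vals) == 0L) stop("empty-ROI: mask has no voxels", call. = FALSE)
  vox_ml <- prod(spacing) / 1000
  mtv <- length(vals) * vox_ml
  mu <- mean(vals)
  lev <- discretize(vals, config, modality)
  p <- tabulate(lev)
  p <- p[p > 0] / length(lev)
  list(max = max(vals), mean = mu, MTV_ml = mtv, TLG = mu * mtv,
       entropy = -sum(p * log2(p)))
}

#' Area under the cumulative SUV-volume histogram
#'
#' `CSH(t)` is the fraction of ROI volume with SUV at least `t * SUVmax`,
#' evaluated on a uniform grid of `n_thresholds` points on `[0, 1]`;
#' the trapezoidal area is returned. Values near 1 indicate homogeneous
#' uptake, lower values more heterogeneity.
#'
#' @param pet 3D SUV array.
#' @param mask 3D 0/1 array.
#' @param n_thresholds number of threshold grid points (default 100).
#' @return scalar in (0, 1].
#' @export
auc_csh <- function(pet, mask, n_thresholds = 100L) {
  vals <- pet[mask > 0]
  if (length(vals) == 0L) stop("empty-ROI: mask has no voxels", call. = FALSE)
  smax <- max(vals)
  if (smax <= 0) stop("auc_csh requires SUVmax > 0", call. = FALSE)
  t <- seq(0, 1, length.out = n_thresholds)
  csh <- vapply(t, function(ti) mean(vals >= ti * smax), numeric(1))
  sum((csh[-1] + csh[-n_thresholds]) / 2) * (t[2] - t[1])
}

# 26-connected component labelling of a 3D mask; returns integer array
# with 0 outside and 1..K per component.
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask > 0)
  if (length(idx) == 0L) return(lab)
  coord <- arrayInd(idx, d)
  inmask <- array(FALSE, d); inmask[idx] <- TRUE
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  comp <- 0L
  for (k in seq_along(idx)) {
    if (lab[idx[k]] != 0L) next
    comp <- comp + 1L
    queue <- matrix(coord[k, ], nrow = 1)
    lab[idx[k]] <- comp
    while (nrow(queue) > 0) {
      v <- queue[1, , drop = TRUE]
      queue <- queue[-1, , drop = FALSE]
      for (o in seq_len(nrow(off))) {
        w <- v + off[o, ]
        if (any(w < 1) || any(w > d)) next
        if (inmask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- comp
          queue <- rbind(queue, w)
        }
      }
    }
  }
  lab
}

#' Tumor dissemination (Dmax)
#'
#' Largest pairwise Euclidean distance (mm) between centroids of
#' 26-connected lesion components; 0 for a single lesion.
#'
#' @param mask 3D 0/1 array.
#' @param spacing voxel spacing (mm).
#' @return scalar distance in mm.
#' @export
dmax <- function(mask, spacing) {
  lab <- label_components(mask)
  k <- max(lab)
  if (k <= 1L) return(0)
  cent <- t(vapply(seq_len(k), function(ci) {
    colMeans(arrayInd(which(lab == ci), dim(mask))) * spacing
  }, numeric(3)))
  max(stats::dist(cent))
}

# enumerate grey-level runs for one integer direction d over the masked,
# discretized volume. Returns data.frame(level, length). Voxels outside the
# mask break runs. Used for all 13 unique 3D directions.
glrlm_runs_dir <- function(levels, mask, d) {
  dims <- dim(levels)
  idx <- which(mask > 0)
  if (length(idx) == 0L) return(data.frame(level = integer(), length = integer()))
  co <- arrayInd(idx, dims)
  # steps back to the line's canonical start voxel inside the grid
  kb <- rep(.Machine$integer.max, length(idx))
  for (a in 1:3) {
    if (d[a] > 0) kb <- pmin(kb, co[, a] - 1L)
    if (d[a] < 0) kb <- pmin(kb, dims[a] - co[, a])
  }
  rep_co <- co - outer(kb, d)                   # canonical line representative
  line <- (rep_co[, 1] - 1) + dims[1] * ((rep_co[, 2] - 1) +
            dims[2] * (rep_co[, 3] - 1))
  lv <- levels[idx]
  ord <- order(line, kb)
  line <- line[ord]; kb <- kb[ord]; lv <- lv[ord]
  n <- length(lv)
  newrun <- c(TRUE, line[-1] != line[-n] | kb[-1] != kb[-n] + 1L |
                lv[-1] != lv[-n])
  starts <- which(newrun)
  lens <- diff(c(starts, n + 1L))
  data.frame(level = lv[starts], length = lens)
}

glrlm_directions <- function() {
  rbind(c(1,0,0), c(0,1,0), c(0,0,1),
        c(1,1,0), c(1,-1,0), c(1,0,1), c(1,0,-1), c(0,1,1), c(0,1,-1),
        c(1,1,1), c(1,1,-1), c(1,-1,1), c(1,-1,-1))
}

#' Grey-level run-length matrix
#'
#' Runs are enumerated per 3D direction (the 13 unique directions) and the
#' per-direction matrices summed into one run matrix `r(i, j)` over grey
#' level i and run length j. Voxels outside the mask break runs.
#'
#' @param levels 3D integer array of discretized grey levels.
#' @param mask 3D 0/1 array.
#' @param directions integer matrix of directions (rows); default all 13.
#' @return matrix of run counts (rows = grey level 1..max, cols = run length).
#' @export
glrlm_matrix <- function(levels, mask, directions = glrlm_directions()) {
  if (sum(mask) == 0L) stop("empty-ROI", call. = FALSE)
  runs <- do.call(rbind, lapply(seq_len(nrow(directions)), function(i) {
    glrlm_runs_dir(levels, mask, directions[i, ])
  }))
  nl <- max(levels[mask > 0])
  nr <- max(runs$length)
  m <- matrix(0, nl, nr)
  for (r in seq_len(nrow(runs))) {
    m[runs$level[r], runs$length[r]] <- m[runs$level[r], runs$length[r]] + 1
  }
  m
}

#' GLRLM non-uniformity features
#'
#' Grey-level non-uniformity `GLN = (1/Nr) sum_i (sum_j r(i,j))^2` and
#' run-length non-uniformity `RLN = (1/Nr) sum_j (sum_i r(i,j))^2`, with
#' `Nr` the total number of runs over all directions.
#'
#' @inheritParams glrlm_matrix
#' @return named list `GLN`, `RLN`.
#' @export
glrlm_features <- function(levels, mask, directions = glrlm_directions()) {
  m <- glrlm_matrix(levels, mask, directions)
  nr <- sum(m)
  list(GLN = sum(rowSums(m)^2) / nr, RLN = sum(colSums(m)^2) / nr)
}

# per-voxel mean neighbour grey level over the in-mask 26-neighbourhood,
# computed by shifting accumulated sums; returns list(nbr_mean, valid)
ngtdm_neighbour_means <- function(levels, mask) {
  d <- dim(levels)
  lv <- levels; lv[mask == 0] <- 0L
  nsum <- array(0, d); ncnt <- array(0, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (max(1, 1 + dx) > min(d[1], d[1] + dx) ||
        max(1, 1 + dy) > min(d[2], d[2] + dy) ||
        max(1, 1 + dz) > min(d[3], d[3] + dz)) next
    sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
    sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
    sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
    tx <- sx - dx; ty <- sy - dy; tz <- sz - dz
    nsum[tx, ty, tz] <- nsum[tx, ty, tz] + lv[sx, sy, sz]
    ncnt[tx, ty, tz] <- ncnt[tx, ty, tz] + (mask[sx, sy, sz] > 0)
  }
  valid <- mask > 0 & ncnt > 0
  nbr_mean <- array(NA_real_, d)
  nbr_mean[valid] <- nsum[valid] / ncnt[valid]
  list(nbr_mean = nbr_mean, valid = valid)
}

#' NGTDM texture features
#'
#' Neighbourhood grey-tone difference features (busyness, coarseness,
#' complexity, contrast, strength) following the Amadasun/IBSI definitions.
#' For each ROI voxel with at least one in-mask 26-neighbour, the absolute
#' difference between its level and the mean neighbour level accumulates
#' into `s(i)` per level i; `p_i` is the level probability over valid
#' voxels. Degenerate denominators return documented guard values:
#' coarseness 1e6 and strength 0 when `sum(s) = 0`, busyness 0 when its
#' denominator vanishes, contrast 0 with a single occupied level.
#'
#' @param levels 3D integer array of discretized grey levels.
#' @param mask 3D 0/1 array.
#' @return named list: `busyness`, `coarseness`, `complexity`, `contrast`,
#'   `strength`.
#' @export
ngtdm_features <- function(levels, mask) {
  if (sum(mask) == 0L) stop("empty-ROI", call. = FALSE)
  nb <- ngtdm_neighbour_means(levels, mask)
  guard <- list(busyness = 0, coarseness = 1e6, complexity = 0,
                contrast = 0, strength = 0)
  if (!any(nb$valid)) return(guard)
  lv <- levels[nb$valid]
  am <- nb$nbr_mean[nb$valid]
  N <- length(lv)
  nlev <- max(lv)
  n_i <- tabulate(lv, nbins = nlev)
  s_i <- vapply(seq_len(nlev), function(i) sum(abs(i - am)[lv == i]), numeric(1))
  p_i <- n_i / N
  pres <- which(p_i > 0)
  i <- pres
  pi_ <- p_i[pres]; si_ <- s_i[pres]
  ngp <- length(pres)
  ps <- sum(pi_ * si_)
  coarseness <- if (ps > 0) 1 / ps else guard$coarseness
  dif2 <- outer(i, i, function(a, b) (a - b)^2)
  contrast <- if (ngp > 1) {
    (sum(outer(pi_, pi_) * dif2) / (ngp * (ngp - 1))) * (sum(si_) / N)
  } else 0
  ipi <- i * pi_
  bden <- sum(abs(outer(ipi, ipi, "-")))
  busyness <- if (bden > 0) ps / bden else 0
  absdif <- outer(i, i, function(a, b) abs(a - b))
  psum <- outer(pi_, pi_, "+")
  pssum <- outer(pi_ * si_, pi_ * si_, "+")
  complexity <- sum(absdif * pssum / psum) / N
  ssum <- sum(si_)
  strength <- if (ssum > 0) sum(psum * dif2) / ssum else 0
  list(busyness = busyness, coarseness = coarseness, complexity = complexity,
       contrast = contrast, strength = strength)
}

# crop arrays to the mask bounding box (with no margin) for texture speed
crop_to_roi <- function(volume, mask) {
  co <- arrayInd(which(mask > 0), dim(mask))
  rng <- lapply(1:3, function(a) min(co[, a]):max(co[, a]))
  list(volume = volume[rng[[1]], rng[[2]], rng[[3]], drop = FALSE],
       mask = mask[rng[[1]], rng[[2]], rng[[3]], drop = FALSE])
}

#' Extract the full per-scan feature vector
#'
#' Applies all single-time-point operations on PET (SUV statistics, MTV,
#' TLG, AUC-CSH, Dmax, entropy, NGTDM, GLRLM) and CT (HU first-order,
#' entropy, NGTDM, GLRLM) with modality-specific discretization, plus
#' optional radial shell (RIM) features on both modalities.
#'
#' @param scan a [scan_pair()].
#' @param config a [discretization_config()].
#' @param include_rim append RIM shell features (default TRUE).
#' @param rim_k number of shell positions kept per indexing direction
#'   (see [rim_feature_vector()]).
#' @return a named numeric vector with `PET_` / `CT_` prefixes.
#' @export
extract_features <- function(scan, config = discretization_config(),
                             include_rim = TRUE, rim_k = 6L) {
  stopifnot(inherits(scan, "scan_pair"))
  sp <- scan$spacing
  out <- c()
  for (mod in c("pet", "ct")) {
    vol <- if (mod == "pet") scan$pet else scan$ct
    cr <- crop_to_roi(vol, scan$mask)
    fo <- first_order(cr$volume, cr$mask, sp, config, mod)
    lev <- discretize(cr$volume, config, mod,
                      anchor_value = if (config$anchor == "roi_min")
                        min(cr$volume[cr$mask > 0]) else 0)
    ng <- ngtdm_features(lev, cr$mask)
    gl <- if (sum(cr$mask) > 0) glrlm_features(lev, cr$mask) else
      list(GLN = NA_real_, RLN = NA_real_)
    pre <- toupper(mod)
    v <- c(max = fo$max, mean = fo$mean, entropy = fo$entropy,
           NGTDM_busyness = ng$busyness, NGTDM_coarseness = ng$coarseness,
           NGTDM_complexity = ng$complexity, NGTDM_contrast = ng$contrast,
           NGTDM_strength = ng$strength,
           GLRLM_GLN = gl$GLN, GLRLM_RLN = gl$RLN)
    if (mod == "pet") {
      v <- c(SUVmax = fo$max, SUVmean = fo$mean, MTV_ml = fo$MTV_ml,
             TLG = fo$TLG, entropy = fo$entropy,
             Dmax_mm = dmax(scan$mask, sp),
             AUC_CSH = auc_csh(scan$pet, scan$mask),
             v[-(1:3)])
    }
    names(v) <- paste0(pre, "_", names(v))
    out <- c(out, v)
    if (include_rim) {
      shells <- peel_shells(cr$mask)
      prof <- shell_statistics(cr$volume, shells, sp)
      rim <- rim_feature_vector(prof, K_fixed = rim_k)
      names(rim) <- paste0(pre, "_", names(rim))
      out <- c(out, rim)
    }
  }
  out
}

#' Extract a feature table for a list of scans
#'
#' @param scans list of [scan_pair()] objects (one time point each).
#' @param config a [discretization_config()].
#' @param ... passed to [extract_features()].
#' @return a feature table data.frame with `subject_id`, `timepoint`,
#'   `scanner_id` annotation columns.
#' @export
extract_feature_table <- function(scans, config = discretization_config(),
                                  ...) {
  rows <- lapply(scans, function(s) {
    fv <- extract_features(s, config, ...)
    cbind(data.frame(subject_id = s$subject_id, timepoint = s$timepoint,
                     scanner_id = s$scanner_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(fv), check.names = FALSE))
  })
  do.call(rbind, rows)
}
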