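# Radial intensity mean (RIM) shell features: the ROI is peeled one voxel
# layer at a time by iterated 3D binary erosion, from the outermost envelope
# to the core, and per-shell intensity statistics are recorded.

# one binary erosion step; "6" keeps a voxel only if all six face
# neighbours are foreground (out-of-grid counts as background), "26"
# requires the full 26-neighbourhood.
erode_mask <- function(mask, connectivity = c("6", "26")) {
  connectivity <- match.arg(connectivity)
  d <- dim(mask)
  keep <- mask > 0
  offsets <- if (connectivity == "6") {
    list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    o <- o[rowSums(abs(o)) > 0, , drop = FALSE]
    lapply(seq_len(nrow(o)), function(i) o[i, ])
  }
  for (off in offsets) {
    shifted <- array(FALSE, d)
    if (max(1, 1 + off[1]) > min(d[1], d[1] + off[1]) ||
        max(1, 1 + off[2]) > min(d[2], d[2] + off[2]) ||
        max(1, 1 + off[3]) > min(d[3], d[3] + off[3])) {
      keep <- keep & FALSE
      next
    }
    sx <- max(1, 1 + off[1]):min(d[1], d[1] + off[1])
    sy <- max(1, 1 + off[2]):min(d[2], d[2] + off[2])
    sz <- max(1, 1 + off[3]):min(d[3], d[3] + off[3])
    shifted[sx - off[1], sy - off[2], sz - off[3]] <-
      mask[sx, sy, sz] > 0
    keep <- keep & shifted
  }
  keep * 1L
}

#' Peel a mask into one-voxel-thick shells
#'
#' Iterated binary erosion: with `M_0` the input mask and
#' `M_(k+1) = erode(M_k)`, shell k is `M_k \ M_(k+1)`; peeling stops when
#' the eroded mask is empty. The shells are disjoint and partition the ROI,
#' shell 0 being the outermost envelope. Face-adjacency (6-connected)
#' erosion is the default so each layer is one voxel of face thickness.
#'
#' @param mask 3D 0/1 array with at least one foreground voxel.
#' @param connectivity `"6"` (default) or `"26"`.
#' @return list of 0/1 shell masks, outermost first.
#' @export
peel_shells <- function(mask, connectivity = "6") {
  if (sum(mask) == 0L) stop("empty-ROI: nothing to peel", call. = FALSE)
  shells <- list()
  cur <- (mask > 0) * 1L
  while (sum(cur) > 0L) {
    nxt <- erode_mask(cur, connectivity)
    shells[[length(shells) + 1L]] <- cur - nxt
    cur <- nxt
  }
  shells
}

#' Per-shell intensity statistics
#'
#' For each shell: minimum, mean, standard deviation and maximum of
#' intensity, the voxel count, an approximate volume (ml) and the intensity
#' sum. Single-voxel shells report sd 0.
#'
#' @param intensities 3D numeric array on the same grid as the shells.
#' @param shells list of shell masks from [peel_shells()].
#' @param spacing voxel spacing (mm).
#' @return a data.frame of class `shell_profile`, one row per shell
#'   (outermost first) with columns `shell`, `min`, `mean`, `sd`, `max`,
#'   `count`, `volume_ml`, `sum`.
#' @export
shell_statistics <- function(intensities, shells, spacing) {
  vox_ml <- prod(spacing) / 1000
  rows <- lapply(seq_along(shells), function(k) {
    v <- intensities[shells[[k]] > 0]
    data.frame(shell = k - 1L, min = min(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               max = max(v), count = length(v),
               volume_ml = length(v) * vox_ml, sum = sum(v))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("shell_profile", "data.frame")
  out
}

#' Flatten a shell profile into a fixed-length named feature vector
#'
#' Emits `RIM_<stat>_<k>` for k = 0..K_fixed-1 indexed from the outermost
#' shell, plus mirrored `RIMcore_<stat>_<k>` indexed from the innermost
#' shell outward (stable naming for core-proximal shells across lesions of
#' different depth). Profiles shorter than `K_fixed` are padded with
#' missing values (mean-imputed downstream); longer profiles are truncated.
#'
#' @param profile a `shell_profile` from [shell_statistics()].
#' @param K_fixed number of shell positions per indexing direction.
#' @return named numeric vector of length `7 * 2 * K_fixed`.
#' @export
rim_feature_vector <- function(profile, K_fixed = 6L) {
  stats_ <- c("min", "mean", "sd", "max", "count", "volume_ml", "sum")
  K <- nrow(profile)
  out <- numeric(0)
  for (st in stats_) {
    v <- profile[[st]]
    outer_v <- rep(NA_real_, K_fixed)
    core_v <- rep(NA_real_, K_fixed)
    kk <- min(K, K_fixed)
    outer_v[seq_len(kk)] <- v[seq_len(kk)]
    core_v[seq_len(kk)] <- rev(v)[seq_len(kk)]
    names(outer_v) <- paste0("RIM_", st, "_", seq_len(K_fixed) - 1L)
    names(core_v) <- paste0("RIMcore_", st, "_", seq_len(K_fixed) - 1L)
    out <- c(out, outer_v, core_v)
  }
  out
}
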