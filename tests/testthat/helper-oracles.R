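# Independent brute-force oracles: direct-definition implementations with
# explicit loops, sharing no code with the package internals.

# enumerate grey-level runs by walking each lattice line voxel by voxel
oracle_glrlm_runs <- function(levels, mask, d) {
  dims <- dim(levels)
  inb <- function(v) all(v >= 1) && all(v <= dims)
  runs <- list()
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[3])) {
      v <- c(x, y, z)
      if (mask[x, y, z] == 0) next
      prev <- v - d
      # start of a run: predecessor absent, outside mask, or other level
      if (inb(prev) && mask[prev[1], prev[2], prev[3]] == 1 &&
          levels[prev[1], prev[2], prev[3]] == levels[x, y, z]) next
      len <- 1L
      nxt <- v + d
      while (inb(nxt) && mask[nxt[1], nxt[2], nxt[3]] == 1 &&
             levels[nxt[1], nxt[2], nxt[3]] == levels[x, y, z]) {
        len <- len + 1L
        nxt <- nxt + d
      }
      runs[[length(runs) + 1L]] <- c(levels[x, y, z], len)
    }
  if (length(runs) == 0L) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, runs)
}

oracle_glrlm <- function(levels, mask, directions = NULL) {
  if (is.null(directions)) {
    directions <- rbind(c(1,0,0), c(0,1,0), c(0,0,1),
                        c(1,1,0), c(1,-1,0), c(1,0,1), c(1,0,-1),
                        c(0,1,1), c(0,1,-1),
                        c(1,1,1), c(1,1,-1), c(1,-1,1), c(1,-1,-1))
  }
  runs <- do.call(rbind, lapply(seq_len(nrow(directions)), function(i) {
    oracle_glrlm_runs(levels, mask, directions[i, ])
  }))
  nr <- nrow(runs)
  gln <- sum(table(runs[, 1])^2) / nr
  rln <- sum(table(runs[, 2])^2) / nr
  list(GLN = gln, RLN = rln, n_runs = nr,
       voxel_sum = sum(runs[, 2]))
}

# NGTDM via per-voxel neighbourhood loops and direct double sums
oracle_ngtdm <- function(levels, mask) {
  dims <- dim(levels)
  nlev <- max(levels[mask > 0])
  n_i <- rep(0, nlev); s_i <- rep(0, nlev)
  N <- 0
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[3])) {
      if (mask[x, y, z] == 0) next
      nb <- c()
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        xx <- x + dx; yy <- y + dy; zz <- z + dz
        if (xx < 1 || yy < 1 || zz < 1 || xx > dims[1] || yy > dims[2] ||
            zz > dims[3]) next
        if (mask[xx, yy, zz] == 1) nb <- c(nb, levels[xx, yy, zz])
      }
      if (length(nb) == 0) next
      i <- levels[x, y, z]
      N <- N + 1
      n_i[i] <- n_i[i] + 1
      s_i[i] <- s_i[i] + abs(i - mean(nb))
    }
  if (N == 0) {
    return(list(busyness = 0, coarseness = 1e6, complexity = 0,
                contrast = 0, strength = 0))
  }
  p_i <- n_i / N
  pres <- which(p_i > 0)
  ngp <- length(pres)
  ps <- sum(p_i * s_i)
  coarseness <- if (ps > 0) 1 / ps else 1e6
  contrast <- 0; bden <- 0; complexity <- 0; strength <- 0
  for (i in pres) for (j in pres) {
    contrast <- contrast + p_i[i] * p_i[j] * (i - j)^2
    bden <- bden + abs(i * p_i[i] - j * p_i[j])
    complexity <- complexity +
      abs(i - j) * (p_i[i] * s_i[i] + p_i[j] * s_i[j]) / (p_i[i] + p_i[j])
    strength <- strength + (p_i[i] + p_i[j]) * (i - j)^2
  }
  contrast <- if (ngp > 1) contrast / (ngp * (ngp - 1)) * sum(s_i) / N else 0
  busyness <- if (bden > 0) ps / bden else 0
  complexity <- complexity / N
  strength <- if (sum(s_i) > 0) strength / sum(s_i) else 0
  list(busyness = busyness, coarseness = coarseness,
       complexity = complexity, contrast = contrast, strength = strength)
}

# ROC AUC by exhaustive pair counting, ties 0.5
oracle_auc <- function(score, y) {
  pos <- score[y == 1]; neg <- score[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Harrell c by exhaustive pair enumeration
oracle_cindex <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      num <- num + if (risk[i] > risk[j]) 1 else if (risk[i] == risk[j])
        0.5 else 0
    }
  }
  if (den == 0) NA_real_ else num / den
}

# direct single-model ICARE re-implementation for small instances
oracle_icare_single <- function(X, y, Cmin, rho) {
  Z <- scale(X)
  sds <- attr(Z, "scaled:scale")
  Z[, sds == 0] <- 0
  u <- apply(Z, 2, oracle_auc, y = y)
  w <- ifelse(u > 0.5, 1, -1)
  m <- abs(u - 0.5)
  keep <- which(m >= Cmin & m > 0)
  if (length(keep) > 1) {
    ord <- keep[order(m[keep], decreasing = TRUE)]
    ret <- ord[1]
    for (j in ord[-1]) {
      ok <- TRUE
      for (r in ret) {
        cc <- suppressWarnings(cor(Z[, j], Z[, r]))
        if (!is.na(cc) && abs(cc) > rho) ok <- FALSE
      }
      if (ok) ret <- c(ret, j)
    }
    keep <- ret
  }
  if (length(keep) == 0) return(rep(0, nrow(X)))
  rowMeans(sweep(Z[, keep, drop = FALSE], 2, w[keep], "*"))
}
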