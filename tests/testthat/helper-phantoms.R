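# Geometric phantoms built in code at test time.

# solid sphere mask of radius R_vox (voxels) centered in a cubic grid
sphere_mask <- function(n = 21L, R_vox = 7) {
  c0 <- (n + 1) / 2
  ax <- seq_len(n) - c0
  X <- array(rep(ax, times = n * n), c(n, n, n))
  Y <- array(rep(rep(ax, each = n), times = n), c(n, n, n))
  Z <- array(rep(ax, each = n * n), c(n, n, n))
  r <- sqrt(X^2 + Y^2 + Z^2)
  list(mask = (r <= R_vox) * 1L, r = r)
}

# radial-gradient PET phantom: background + peak * (1 - (r/R)^g) inside
sphere_phantom <- function(n = 21L, R_vox = 7, peak = 10, g = 1,
                           background = 0) {
  s <- sphere_mask(n, R_vox)
  pet <- array(background, dim(s$mask))
  ins <- s$mask == 1
  pet[ins] <- background + peak * (1 - pmin(s$r[ins] / R_vox, 1)^g)
  list(pet = pet, mask = s$mask, r = s$r)
}

# random discretized ROI on a small grid: levels in 1..n_levels, random mask
random_roi <- function(dims = c(4, 4, 4), n_levels = 4, p_mask = 0.7) {
  lev <- array(sample.int(n_levels, prod(dims), replace = TRUE), dims)
  mask <- array(as.integer(runif(prod(dims)) < p_mask), dims)
  if (sum(mask) == 0) mask[1, 1, 1] <- 1L
  list(levels = lev, mask = mask)
}

# proportional-hazards survival simulator: 3 informative of p features
simulate_ph_data <- function(n = 150, p = 20, beta_nonzero = c(1, -1, 0.8),
                             censor_frac = 0.25, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  beta <- c(beta_nonzero, rep(0, p - length(beta_nonzero)))
  lp <- X %*% beta
  t_event <- rexp(n, rate = exp(lp) / 20)
  cens <- runif(n) < censor_frac
  time <- ifelse(cens, runif(n, 0, t_event), t_event)
  list(X = X, time = time, event = as.integer(!cens),
       true_features = paste0("f", seq_along(beta_nonzero)))
}
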