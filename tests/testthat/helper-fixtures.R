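# Shared fixtures and independent oracles used across the test files.

# Random strictly positive abundance matrix.
random_positive_table <- function(n, D, seed = 1) {
  set.seed(seed)
  abundance_table(matrix(exp(rnorm(n * D)), n, D))
}

# Direct-formula balance oracle, written independently of compute_balance:
# per-sample products and explicit roots, no shared helper code.
balance_oracle <- function(values, num_idx, den_idx) {
  unname(apply(values, 1, function(row) {
    ga <- prod(row[num_idx])^(1 / length(num_idx))
    gb <- prod(row[den_idx])^(1 / length(den_idx))
    log(ga / gb)
  }))
}

# Naive TFCE oracle: explicit threshold loop with fresh connected-component
# labeling (igraph) at every threshold.
tfce_oracle <- function(stat, E, H, dh, connectivity = 26) {
  dims <- dim(stat)
  out <- array(0, dims)
  maxv <- max(stat)
  if (maxv <= 0) return(out)
  K <- floor(maxv / dh + 1e-9)
  eps <- 1e-12 * maxv
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  for (k in seq_len(K)) {
    h <- k * dh
    supra <- which(stat >= h - eps)
    if (length(supra) == 0) next
    coords <- arrayInd(supra, dims)
    key <- function(m) (m[, 3] - 1) * dims[1] * dims[2] +
      (m[, 2] - 1) * dims[1] + m[, 1]
    edges <- NULL
    idx_of <- integer(prod(dims)); idx_of[supra] <- seq_along(supra)
    for (o in seq_len(nrow(offs))) {
      nb <- sweep(coords, 2, offs[o, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb_lin <- key(nb[ok, , drop = FALSE])
      src <- which(ok)
      keep <- idx_of[nb_lin] > 0
      if (any(keep))
        edges <- rbind(edges, cbind(src[keep], idx_of[nb_lin[keep]]))
    }
    g <- igraph::graph_from_edgelist(
      rbind(matrix(rep(seq_along(supra), 2), ncol = 2), edges),
      directed = FALSE)
    comp <- igraph::components(g)$membership[seq_along(supra)]
    sizes <- table(comp)
    out[supra] <- out[supra] +
      as.numeric(sizes[as.character(comp)])^E * h^H * dh
  }
  out
}

# Reference voxel-wise t via lm(), one voxel at a time.
lm_tmap_oracle <- function(Y, X, cvec) {
  vapply(seq_len(ncol(Y)), function(v) {
    fit <- lm(Y[, v] ~ X - 1)
    b <- coef(fit)
    vc <- vcov(fit)
    sum(cvec * b) / sqrt(drop(t(cvec) %*% vc %*% cvec))
  }, numeric(1))
}

# Seed/network geometry that fits inside small test grids (the default
# hypothalamic coordinates need the full-size grid).
small_seeds <- function() {
  list(MH = seed_spec("MH", rbind(c(2, 2, -4), c(-2, 2, -4)), radius = 2),
       LH = seed_spec("LH", rbind(c(4, -4, -2), c(-4, -4, -2)), radius = 2))
}

# Small synthetic stack for structcov tests: known template + noise.
tiny_stack <- function(n = 12, dims = c(10, 10, 10), seed = 1, noise = 0.1) {
  set.seed(seed)
  data <- array(0.5 + rnorm(prod(dims) * n, 0, noise), c(dims, n))
  volume_stack(data, default_affine(dims, 2))
}

# Freedman-Lane permutation cross-check in plain R (independent of the C++
# engine): build Y*, refit, TFCE-enhance, return per-permutation values.
fl_perm_oracle <- function(fit, cvec, perms, params) {
  Z <- fit$X[, -fit$tested_cols, drop = FALSE]
  Hz <- Z %*% solve(crossprod(Z), t(Z))
  fitZ <- Hz %*% fit$Y
  resZ <- fit$Y - fitZ
  idx <- which(fit$mask)
  lapply(seq_len(ncol(perms)), function(b) {
    Ystar <- fitZ + resZ[perms[, b], , drop = FALSE]
    tv <- gutbraincov:::glm_tmap(Ystar, fit$X, cvec)
    vol <- array(0, fit$dims); vol[idx] <- tv
    tfce_transform(vol, params, mask = fit$mask)
  })
}
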