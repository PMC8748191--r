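test_that("the GM mask keeps exactly the voxels above threshold", {
  dims <- c(6, 6, 6)
  ones <- volume_stack(array(1, c(dims, 3)), default_affine(dims))
  expect_true(all(make_gm_mask(ones, 0.2)))
  zeros <- volume_stack(array(0, c(dims, 3)), default_affine(dims))
  expect_error(make_gm_mask(zeros, 0.2), "empty")
  half <- array(0.1, c(dims, 3)); half[1:3, , , ] <- 0.5
  hs <- volume_stack(half, default_affine(dims))
  m <- make_gm_mask(hs, 0.2)
  expect_true(all(m[1:3, , ]) && !any(m[4:6, , ]))
})

test_that("a 2-mm seed sphere on the 2-mm grid is the 7-voxel neighbourhood", {
  dims <- c(12, 12, 12)
  aff <- default_affine(dims, 2)
  vals <- array(seq_len(prod(dims)), dims)
  st <- volume_stack(array(rep(vals, 2), c(dims, 2)), aff)
  sd_ <- seed_spec("MH", rbind(c(0, 0, 0)), radius = 2)
  got <- extract_seed(st, sd_)
  ctr <- c(6, 6, 6)  # voxel at the mm origin (floor(dims / 2) offset)
  expect_equal(drop(voxel_to_mm(aff, matrix(ctr, 1))), c(0, 0, 0))
  nb <- rbind(ctr, ctr + c(1, 0, 0), ctr - c(1, 0, 0), ctr + c(0, 1, 0),
              ctr - c(0, 1, 0), ctr + c(0, 0, 1), ctr - c(0, 0, 1))
  expect_equal(unname(got[1]), mean(vals[nb]))
  # a constant image returns the constant for any radius
  cst <- volume_stack(array(3.5, c(dims, 2)), aff)
  expect_equal(unname(extract_seed(cst, seed_spec("s", rbind(c(2, -4, 6)),
                                                  radius = 5))),
               c(3.5, 3.5))
  # a tiny radius reduces to the nearest voxel
  tiny <- extract_seed(st, seed_spec("s", rbind(c(0, 0, 0)), radius = 0.1))
  expect_equal(unname(tiny[1]), vals[6, 6, 6])
  # bilateral seeds average the two hemisphere values
  bil <- extract_seed(st, seed_spec("s", rbind(c(4, 0, 0), c(-4, 0, 0)),
                                    radius = 0.1))
  expect_equal(unname(bil[1]), mean(vals[c(8, 4), 6, 6]))
  expect_error(extract_seed(st, seed_spec("s", rbind(c(99, 0, 0)))),
               "outside")
})

test_that("global grey-matter volume is the modulated voxel sum in ml", {
  dims <- c(4, 4, 4)
  st <- volume_stack(array(rep(c(1, 2), each = prod(dims)), c(dims, 2)),
                     default_affine(dims, 2))
  expect_equal(global_gmv(st), c(64 * 8, 128 * 8) / 1000)
})

test_that("sequential orthogonalization leaves orthogonal columns alone and purges shared variance", {
  set.seed(10)
  n <- 40
  M <- matrix(rnorm(n * 5), n, 5)
  M <- sweep(M, 2, colMeans(M))          # centered columns
  base <- qr.Q(qr(M))                    # orthonormal, still centered
  d0 <- design_matrix(base[, 1], base[, 2], base[, 3], base[, 4], base[, 5],
                      rep(c("a", "b"), n / 2))
  o0 <- orthogonalize_design(d0)
  expect_lt(max(abs(o0$values - base)), 1e-12)

  V <- matrix(rnorm(n * 5), n, 5)
  d1 <- design_matrix(V[, 1], V[, 2], V[, 3], V[, 4], V[, 5],
                      rep(c("a", "b"), n / 2))
  o1 <- orthogonalize_design(d1)
  W <- o1$values
  for (j in 2:5) for (k in seq_len(j - 1))
    expect_lt(abs(sum(W[, j] * W[, k])), 1e-8)
  # final seed column equals the OLS residual of seed on earlier columns
  res <- resid(lm(V[, 5] ~ V[, 1:4]))
  expect_equal(unname(W[, 5]), unname(res), tolerance = 1e-8)

  # a seed that is an exact combination of earlier columns is flagged
  d2 <- design_matrix(V[, 1], V[, 2], V[, 3], V[, 4],
                      V[, 1] - 2 * V[, 3], rep(c("a", "b"), n / 2))
  expect_error(orthogonalize_design(d2), "seed")
})

test_that("voxel-wise interaction t equals the single-voxel lm oracle", {
  set.seed(22)
  n <- 12
  dims <- c(3, 3, 1)
  seed_v <- rnorm(n)
  grp <- rep(c("g1", "g2"), each = n / 2)
  data <- array(rnorm(prod(dims) * n, 0.5, 0.2), c(dims, n))
  for (i in which(grp == "g2")) data[1, 1, 1, i] <- 0.5 + 0.8 * seed_v[i]
  st <- volume_stack(data, default_affine(dims))
  des <- design_matrix(rnorm(n), rep(0:1, 6), rnorm(n), rnorm(n), seed_v,
                       grp)
  fit <- fit_interaction_glm(st, des, array(TRUE, dims))
  tv <- fit$tmaps[[1]]$values
  Y <- fit$Y
  tor <- lm_tmap_oracle(Y, fit$X, fit$contrasts[[1]])
  expect_equal(as.vector(tv), tor, tolerance = 1e-8)
  expect_equal(fit$df, n - ncol(fit$X))
})

test_that("interaction t maps ignore a constant added to every image", {
  set.seed(23)
  n <- 20
  dims <- c(4, 4, 2)
  st <- tiny_stack(n, dims, seed = 3)
  seed_v <- rnorm(n)
  des <- design_matrix(rnorm(n), rep(0:1, n / 2), rnorm(n), rnorm(n),
                       seed_v, rep(c("a", "b"), each = n / 2))
  f1 <- fit_interaction_glm(st, des, array(TRUE, dims))
  st2 <- st; st2$data <- st$data + 5
  f2 <- fit_interaction_glm(st2, des, array(TRUE, dims))
  expect_equal(f1$tmaps[[1]]$values, f2$tmaps[[1]]$values, tolerance = 1e-8)
})

test_that("orthogonalization does not move the interaction map when the seed is already clean", {
  # covariates constructed exactly orthogonal to the seed: the Gram-Schmidt
  # pass then only recenters, which the intercept and group columns absorb
  set.seed(24)
  n <- 24
  dims <- c(4, 4, 2)
  st <- tiny_stack(n, dims, seed = 5)
  seed_v <- rnorm(n)
  mkorth <- function(x) resid(lm(x ~ seed_v))
  des_raw <- design_matrix(mkorth(rnorm(n)), mkorth(rep(0:1, n / 2)),
                           mkorth(rnorm(n)), mkorth(rnorm(n)), seed_v,
                           rep(c("a", "b"), each = n / 2))
  des_o <- orthogonalize_design(des_raw)
  msk <- array(TRUE, dims)
  f_raw <- fit_interaction_glm(st, des_raw, msk)
  f_o <- fit_interaction_glm(st, des_o, msk)
  expect_equal(f_raw$tmaps[[1]]$values, f_o$tmaps[[1]]$values,
               tolerance = 1e-8)
})

test_that("planted slope differences are estimated within sampling error", {
  sp <- cohort_spec(n_subjects = 60, rng_seed = 12)
  ph <- gen_microbiome(sp)$phenotypes
  nw <- list(list(name = "net", seed = "MH", center = c(-10, 10, 8),
                  radius = 6,
                  group_slopes = c("non-obese" = 0.9,
                                   "obese-no-dysbiosis" = 0.3,
                                   "obese-dysbiosis" = 0.3)))
  vs <- volume_spec(dims = c(24, 24, 24), networks = nw, noise_sd = 1,
                    rng_seed = 13)
  st <- gen_volume_stack(vs, ph)
  tr <- attr(st, "truth")
  grp <- factor(ifelse(tr$stratum == "non-obese", "non-obese", "obese"),
                levels = c("non-obese", "obese"))
  des <- design_matrix(ph$age, ph$sex, global_gmv(st),
                       extract_seed(st, default_seeds()$LH),
                       extract_seed(st, default_seeds()$MH), grp)
  mask <- make_gm_mask(st)
  fit <- fit_interaction_glm(st, des, mask)
  # interaction coefficient inside the network ~ slope difference -0.6
  cvec <- fit$contrasts[[1]]
  XtXinv <- chol2inv(chol(crossprod(fit$X)))
  beta <- XtXinv %*% crossprod(fit$X, fit$Y)
  est <- drop(t(cvec) %*% beta)
  sigma2 <- colSums((fit$Y - fit$X %*% beta)^2) / fit$df
  se <- sqrt(sigma2 * drop(t(cvec) %*% XtXinv %*% cvec))
  idx_net <- which(tr$network_masks$net[mask])
  expect_true(all(abs(est[idx_net] - (-0.6)) < 2.5 * se[idx_net]))
  # within-group maps carry the per-group slopes
  wg <- within_group_tmaps(fit)
  expect_named(wg, c("non-obese", "obese"))
  vox <- which(mask & tr$network_masks$net)[1]
  expect_gt(wg[["non-obese"]]$values[vox], wg[["obese"]]$values[vox])
})
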