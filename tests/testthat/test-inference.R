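# Small planted-effect fixture shared by the inference tests.
make_fwe_fixture <- function(n = 40, dims = c(14, 14, 14), strong = TRUE,
                             seed = 50, n_perm = 200) {
  sp <- cohort_spec(n_subjects = n, rng_seed = seed)
  ph <- gen_microbiome(sp)$phenotypes
  nw <- list(list(name = "net", seed = "MH", center = c(-6, 6, 4), radius = 6,
                  group_slopes = c("non-obese" = if (strong) 1.0 else 0.3,
                                   "obese-no-dysbiosis" = 0.3,
                                   "obese-dysbiosis" = 0.3)))
  vs <- volume_spec(dims = dims, seeds = small_seeds(), networks = nw,
                    rng_seed = seed + 1)
  st <- gen_volume_stack(vs, ph)
  mask <- make_gm_mask(st)
  grp <- factor(ifelse(attr(st, "truth")$stratum == "non-obese",
                       "non-obese", "obese"),
                levels = c("non-obese", "obese"))
  des <- design_matrix(ph$age, ph$sex, global_gmv(st),
                       extract_seed(st, small_seeds()$LH),
                       extract_seed(st, small_seeds()$MH), grp)
  fit <- fit_interaction_glm(st, des, mask)
  fwe <- permutation_fwe(fit, scheme = permutation_scheme(n_perm,
                                                          rng_seed = seed + 2))
  list(fit = fit, fwe = fwe, truth = attr(st, "truth"), mask = mask)
}

test_that("the smallest attainable FWE p is 1/(B+1) and maps are monotone in TFCE", {
  fx <- make_fwe_fixture()
  B <- nrow(fx$fwe$null_max)
  pn <- fx$fwe$p_fwe_neg[fx$mask]
  expect_gte(min(pn, na.rm = TRUE), 1 / (B + 1) - 1e-12)
  # strong planted effect reaches the floor
  expect_equal(min(pn, na.rm = TRUE), 1 / (B + 1))
  # monotone: larger observed TFCE never has larger p
  tf <- pmax(-fx$fwe$tfce_map$values[fx$mask], 0)
  ord <- order(tf)
  expect_true(all(diff(pn[ord]) <= 1e-12))
})

test_that("permutation inference is a pure function of the scheme seed", {
  fx1 <- make_fwe_fixture(n = 30, dims = c(10, 10, 10), n_perm = 50)
  fwe_a <- permutation_fwe(fx1$fit,
                           scheme = permutation_scheme(50, rng_seed = 123))
  fwe_b <- permutation_fwe(fx1$fit,
                           scheme = permutation_scheme(50, rng_seed = 123))
  expect_identical(fwe_a$p_fwe_pos, fwe_b$p_fwe_pos)
  expect_identical(fwe_a$null_max, fwe_b$null_max)
  fwe_c <- permutation_fwe(fx1$fit,
                           scheme = permutation_scheme(50, rng_seed = 124))
  expect_false(identical(fwe_a$null_max, fwe_c$null_max))
})

test_that("tiny samples fall back to exhaustive enumeration with a warning", {
  expect_warning(p <- gutbraincov:::make_permutations(
    4, permutation_scheme(500, rng_seed = 1)), "enumerating")
  expect_equal(ncol(p), 24)
  expect_equal(nrow(unique(t(p))), 24)
})

test_that("the engine agrees with a plain-R Freedman-Lane replication", {
  fx <- make_fwe_fixture(n = 24, dims = c(10, 10, 10), n_perm = 25,
                         seed = 60)
  fit <- fx$fit
  fwe <- fx$fwe
  params <- fwe$params
  oracle_maps <- fl_perm_oracle(fit, fit$contrasts[[1]], fwe$perms, params)
  idx <- which(fit$mask)
  omax <- t(vapply(oracle_maps, function(m) {
    v <- m[idx]
    c(max(c(v[v > 0], 0)), max(c(-v[v < 0], 0)))
  }, numeric(2)))
  expect_equal(unname(fwe$null_max), unname(omax), tolerance = 1e-6)
})

test_that("label exchange gives a usable (if slower) null as well", {
  fx <- make_fwe_fixture(n = 24, dims = c(8, 8, 8), n_perm = 30, seed = 61)
  fwe <- permutation_fwe(fx$fit,
                         scheme = permutation_scheme(
                           30, rng_seed = 5, strategy = "label_exchange"))
  expect_true(all(fwe$null_max >= 0))
  expect_true(any(fwe$p_fwe_neg < 0.2, na.rm = TRUE))
})

test_that("small-volume correction reduces to whole-brain inference on the full mask", {
  fx <- make_fwe_fixture(n = 30, dims = c(12, 12, 12), n_perm = 60, seed = 62)
  # a sphere covering the entire grid reproduces the whole-brain p values
  svc <- small_volume_correction(fx$fwe, c(0, 0, 0), radius = 100)
  idx <- which(fx$mask)
  expect_equal(svc$p_fwe_pos[idx], fx$fwe$p_fwe_pos[idx])
  expect_equal(svc$p_fwe_neg[idx], fx$fwe$p_fwe_neg[idx])
})

test_that("restricting the search volume never increases the corrected p", {
  fx <- make_fwe_fixture(n = 30, dims = c(12, 12, 12), n_perm = 60, seed = 63)
  svc <- small_volume_correction(fx$fwe, c(-6, 6, 4), radius = 5)
  sidx <- which(svc$sphere)
  expect_true(all(svc$p_fwe_neg[sidx] <= fx$fwe$p_fwe_neg[sidx] + 1e-12))
  expect_error(small_volume_correction(fx$fwe, c(200, 0, 0), radius = 3),
               "intersect")
})

test_that("a single-voxel sphere equals the direct voxel-level permutation count", {
  fx <- make_fwe_fixture(n = 24, dims = c(10, 10, 10), n_perm = 40, seed = 64)
  fit <- fx$fit; fwe <- fx$fwe
  vox_mm <- c(-2, 2, 0)
  svc <- small_volume_correction(fwe, vox_mm, radius = 0.1)
  sidx <- which(svc$sphere)
  expect_length(sidx, 1)
  # independent count: re-run the permutations in plain R, read off the
  # voxel's TFCE value each time
  oracle_maps <- fl_perm_oracle(fit, fit$contrasts[[1]], fwe$perms,
                                fwe$params)
  vals_neg <- vapply(oracle_maps, function(m) max(-m[sidx], 0), numeric(1))
  obs <- max(-fwe$tfce_map$values[sidx], 0)
  B <- length(vals_neg)
  expect_equal(svc$p_fwe_neg[sidx], (1 + sum(vals_neg >= obs)) / (B + 1),
               tolerance = 1e-12)
})

test_that("region-class defaults pick the stated sphere radii", {
  fx <- make_fwe_fixture(n = 24, dims = c(10, 10, 10), n_perm = 20, seed = 65)
  expect_equal(small_volume_correction(fx$fwe, c(0, 0, 0),
                                       "subcortical")$radius, 3)
  expect_equal(small_volume_correction(fx$fwe, c(0, 0, 0),
                                       "cortical")$radius, 5)
})
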