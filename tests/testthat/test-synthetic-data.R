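test_that("the microbiome generator is a pure function of its spec", {
  sp <- cohort_spec(n_subjects = 100, n_taxa = 31, rng_seed = 7)
  a <- gen_microbiome(sp)
  b <- gen_microbiome(sp)
  expect_identical(a$table, b$table)
  expect_identical(a$phenotypes, b$phenotypes)
  # and different seeds give different draws
  expect_false(identical(gen_microbiome(cohort_spec(rng_seed = 8))$table,
                         a$table))
})

test_that("generated tables are compositional and exercise the zero filter", {
  sp <- cohort_spec(rng_seed = 3, depth = NULL)
  mg <- gen_microbiome(sp)
  expect_true(all(mg$table >= 0))
  expect_equal(unname(rowSums(mg$table)), rep(1, nrow(mg$table)),
               tolerance = 1e-12)
  zero_frac <- colMeans(mg$table == 0)
  expect_true(any(zero_frac > 0.2))           # structural-zero taxa
  expect_true(all(zero_frac[c(sp$planted_numerator,
                              sp$planted_denominator)] == 0))
  # count sampling at the configured depth
  mgc <- gen_microbiome(cohort_spec(rng_seed = 3))
  expect_equal(unname(rowSums(mgc$table)), rep(5000, 104))
})

test_that("overlapping planted groups are rejected", {
  expect_error(cohort_spec(planted_numerator = 1:3,
                           planted_denominator = 3:5), "overlap")
})

test_that("a zero balance effect leaves BMI uncorrelated with the balance", {
  rs <- vapply(1:20, function(r) {
    sp <- cohort_spec(n_subjects = 100, balance_effect = 0, rng_seed = r)
    mg <- gen_microbiome(sp)
    cor(mg$phenotypes$bmi, mg$phenotypes$planted_balance)
  }, numeric(1))
  expect_true(all(abs(rs) < 0.25))
})

test_that("calibrating the slope to R^2 = 0.32 lands the correlation near 0.57", {
  rs <- vapply(1:10, function(r) {
    sp <- cohort_spec(n_subjects = 104, rng_seed = 400 + r)
    sp$balance_effect <- balance_effect_for_r2(sp, 0.32)
    mg <- gen_microbiome(sp)
    cor(mg$phenotypes$bmi, mg$phenotypes$planted_balance)
  }, numeric(1))
  expect_gte(sum(abs(rs - 0.57) < 0.12), 8)
  expect_lt(abs(mean(rs) - 0.57), 0.08)
})

test_that("volumes reduce to the template when all effects and noise vanish", {
  sp <- cohort_spec(n_subjects = 10, rng_seed = 5)
  ph <- gen_microbiome(sp)$phenotypes
  vs <- volume_spec(dims = c(16, 16, 16), seed_signal_sd = 0,
                    confound_effects = c(age = 0, sex = 0, global = 0),
                    noise_sd = 0,
                    networks = list(), rng_seed = 2)
  st <- gen_volume_stack(vs, ph)
  tmpl <- attr(st, "truth")$template
  for (i in seq_len(10))
    expect_equal(st$data[, , , i], tmpl, tolerance = 1e-12)
})

test_that("planted group slopes shift the seed-network covariance as specified", {
  sp <- cohort_spec(n_subjects = 80, rng_seed = 6)
  ph <- gen_microbiome(sp)$phenotypes
  nw <- list(list(name = "net", seed = "MH", center = c(-10, 10, 8),
                  radius = 8,
                  group_slopes = c("non-obese" = 1.0,
                                   "obese-no-dysbiosis" = 0.1,
                                   "obese-dysbiosis" = 0.1)))
  vs <- volume_spec(dims = c(24, 24, 24), networks = nw, noise_sd = 0.5,
                    rng_seed = 9)
  st <- gen_volume_stack(vs, ph)
  tr <- attr(st, "truth")
  mask <- tr$network_masks$net
  net_mean <- apply(st$data, 4, function(v) mean(v[mask]))
  s <- tr$seed_signals[, "MH"]
  grp <- tr$stratum
  cov_non <- cov(s[grp == "non-obese"], net_mean[grp == "non-obese"])
  cov_ob <- cov(s[grp != "non-obese"], net_mean[grp != "non-obese"])
  expect_gt(cov_non, cov_ob)
  # slopes recovered by regression at low noise
  fit_non <- coef(lm(net_mean[grp == "non-obese"] ~ s[grp == "non-obese"]))[2]
  expect_equal(unname(fit_non), 1.0, tolerance = 0.15)
})

test_that("the global-volume loading acts linearly on the images", {
  sp <- cohort_spec(n_subjects = 24, rng_seed = 11)
  ph <- gen_microbiome(sp)$phenotypes
  mk <- function(gl) {
    vs <- volume_spec(dims = c(16, 16, 16), seed_signal_sd = 0,
                      confound_effects = c(age = 0, sex = 0, global = gl),
                      noise_sd = 0, networks = list(), rng_seed = 4)
    st <- gen_volume_stack(vs, ph)
    u <- attr(st, "truth")$global_factor
    vol_mean <- apply(st$data, 4, mean)
    unname(coef(lm(vol_mean ~ u))[2])
  }
  b1 <- mk(0.05); b2 <- mk(0.10)
  expect_equal(b2, 2 * b1, tolerance = 1e-10)
})

test_that("seed coordinates outside the grid are rejected", {
  sp <- cohort_spec(n_subjects = 10, rng_seed = 2)
  ph <- gen_microbiome(sp)$phenotypes
  bad <- volume_spec(dims = c(16, 16, 16), rng_seed = 1,
                     seeds = list(MH = seed_spec("MH",
                                                 rbind(c(200, 0, 0)))),
                     networks = list())
  expect_error(gen_volume_stack(bad, ph), "outside")
})

test_that("volume generation is reproducible from the spec seed", {
  sp <- cohort_spec(n_subjects = 8, rng_seed = 3)
  ph <- gen_microbiome(sp)$phenotypes
  vs <- volume_spec(dims = c(16, 16, 16), rng_seed = 21)
  expect_identical(gen_volume_stack(vs, ph)$data,
                   gen_volume_stack(vs, ph)$data)
})
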