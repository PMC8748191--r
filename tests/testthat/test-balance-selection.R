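test_that("score_balance is the R-squared of the least-squares fit", {
  set.seed(21)
  bal <- rnorm(30)
  expect_equal(score_balance(bal, 2 * bal + 3), 1)
  expect_equal(score_balance(bal, rep(5, 30)), 0)
  expect_error(score_balance(rep(1, 30), rnorm(30)), "degenerate")
  # against lm() with covariates
  cov <- matrix(rnorm(60), 30, 2)
  y <- 0.5 * bal + cov %*% c(1, -2) + rnorm(30)
  expect_equal(score_balance(bal, y, cov),
               summary(lm(y ~ cov + bal))$r.squared, tolerance = 1e-10)
  # invariance to affine rescaling of the response
  expect_equal(score_balance(bal, y), score_balance(bal, 3 * y - 7))
})

test_that("first-pair search equals exhaustive enumeration and orients by sign", {
  set.seed(31)
  for (rep in 1:5) {
    D <- sample(4:8, 1)
    tab <- random_positive_table(50, D, seed = 100 + rep)
    y <- rnorm(50)
    got <- select_first_pair(tab, y)
    best <- -Inf; best_pair <- NULL
    for (i in seq_len(D)) for (j in seq_len(D)) {
      if (i == j) next
      bal <- log(tab[, i] / tab[, j])
      r2 <- summary(lm(y ~ bal))$r.squared
      if (r2 > best + 1e-12) { best <- r2; best_pair <- c(i, j) }
    }
    expect_equal(got$score, best, tolerance = 1e-10)
    expect_setequal(c(got$numerator, got$denominator),
                    colnames(tab)[best_pair])
    # orientation: positive association with the response
    expect_gt(cor(compute_balance(tab, got), y), 0)
  }
})

test_that("exactly tied pairs resolve to the lexicographically smaller one", {
  set.seed(41)
  m <- matrix(exp(rnorm(60)), 20, 3)
  m <- cbind(m, m[, 3])   # t004 duplicates t003: (t1,t3) ties (t1,t4) etc.
  tab <- abundance_table(m)
  y <- rnorm(20)
  got <- select_first_pair(tab, y)
  expect_false("t004" %in% c(got$numerator, got$denominator))
})

test_that("two-taxon tables return the only pair", {
  tab <- random_positive_table(25, 2, seed = 5)
  y <- stats::rnorm(25)
  got <- select_first_pair(tab, y)
  expect_setequal(c(got$numerator, got$denominator), c("t001", "t002"))
  expect_error(select_first_pair(tab[, 1, drop = FALSE], y), "two taxa")
})

test_that("forward selection recovers a noiseless planted balance exactly", {
  tab <- random_positive_table(60, 10, seed = 8)
  planted <- balance_signature(c("t002", "t007"), c("t001", "t005", "t009"))
  y <- drop(compute_balance(tab, planted))
  fs <- forward_select(tab, y, max_size = 5)
  expect_setequal(fs$signature$numerator, planted$numerator)
  expect_setequal(fs$signature$denominator, planted$denominator)
  expect_equal(fs$signature$score, 1, tolerance = 1e-9)
})

test_that("an infinite improvement requirement stops at the first pair", {
  tab <- random_positive_table(40, 6, seed = 12)
  y <- rnorm(40)
  fs <- forward_select(tab, y, min_improvement = Inf)
  expect_equal(length(fs$signature$numerator) +
                 length(fs$signature$denominator), 2)
})

test_that("accepted step scores are non-decreasing and re-score consistently", {
  for (rep in 1:4) {
    tab <- random_positive_table(40, 6, seed = 200 + rep)
    set.seed(300 + rep)
    y <- rnorm(40) + log(tab[, 1])
    fs <- forward_select(tab, y, max_size = 4)
    sc <- fs$trace$steps$score_after[-1]
    expect_true(all(diff(sc) >= 0))
    # every accepted step's score matches re-scoring the stored signature
    for (k in 2:length(fs$path)) {
      sig_k <- gutbraincov:::truncate_path(fs$path, k)
      expect_equal(score_balance(compute_balance(tab, sig_k), y),
                   fs$trace$steps$score_after[k], tolerance = 1e-10)
    }
    # final R^2 at least the best single pair's
    expect_gte(fs$signature$score +  1e-12,
               select_first_pair(tab, y)$score)
  }
})

test_that("cross-validation is reproducible and ranks planted taxa on top", {
  spec <- cohort_spec(n_subjects = 100, n_taxa = 12, rng_seed = 33)
  mg <- gen_microbiome(spec)
  tab <- replace_zeros(filter_prevalence(mg$table))
  y <- mg$phenotypes$bmi
  cv1 <- cross_validate_signature(tab, y, folds = 5, repeats = 2,
                                  rng_seed = 99)
  cv2 <- cross_validate_signature(tab, y, folds = 5, repeats = 2,
                                  rng_seed = 99)
  expect_identical(cv1$robustness, cv2$robustness)
  expect_identical(cv1$optimal_size, cv2$optimal_size)
  expect_gte(cv1$optimal_size, 2)
  planted <- c(spec$planted_numerator, spec$planted_denominator)
  top <- names(sort(cv1$robustness$per_taxon_frequency, decreasing = TRUE))
  expect_true(all(spec$planted_numerator %in% top[1:4]))
  # frequencies are proportions and the MSE curve covers sizes 2..max
  expect_true(all(cv1$robustness$per_taxon_frequency >= 0 &
                    cv1$robustness$per_taxon_frequency <= 1))
  expect_lte(sum(cv1$robustness$per_balance_frequency), 1 + 1e-12)
  expect_equal(cv1$robustness$cv_score_by_size$size, 2:8)
})
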