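#' Specify a synthetic cohort
#'
#' Defines the generative model for a phylum-level abundance table with a
#' planted BMI-associated balance, plus the accompanying phenotypes. Baseline
#' taxon intensities are independent log-normals (closed to proportions),
#' which yields the heavy-tailed phylum distributions a balance statistic
#' assumes. BMI is linear in the planted balance plus Gaussian noise; the
#' default slope is calibrated so the population balance-BMI correlation is
#' `target_r` (0.57 by default). A subset of rare, non-planted taxa receives
#' structural zeros at a rate that trips the 20%-zeros prevalence filter, so
#' the filtering stage is exercised on every generated table.
#'
#' @param n_subjects cohort size (default 104).
#' @param n_taxa number of phyla (default 31).
#' @param planted_numerator,planted_denominator indices (into the taxon list)
#'   of the planted balance groups; must be disjoint and non-empty.
#' @param log_mean,log_sd per-taxon baseline log-intensity parameters;
#'   defaults put the numerator phyla among the dominant taxa and the
#'   denominator phyla among the rare ones (while keeping the latter
#'   abundant enough to survive the prevalence filter at the default read
#'   depth), giving a planted balance around 5.3 with standard deviation
#'   about 0.65 on the natural-log scale, with each signature taxon
#'   carrying a comparable share of the balance variance.
#' @param structural_zero_taxa indices of taxa given structural zeros.
#' @param structural_zero_rate per-sample probability of a structural zero in
#'   those taxa (default 0.3, i.e. above the 20% filter threshold).
#' @param depth multinomial read depth for count sampling (default 5000
#'   reads); `NULL` emits the closed proportions directly.
#' @param balance_effect slope of BMI on the planted balance (kg/m^2 per
#'   log-unit); `NULL` (default) calibrates it to `target_r`.
#' @param target_r target balance-BMI Pearson correlation used when
#'   `balance_effect` is `NULL`.
#' @param bmi_noise_sd residual BMI standard deviation (kg/m^2).
#' @param bmi_intercept intercept of the BMI model; `NULL` places the cohort
#'   so the expected obesity (BMI >= 30) prevalence is `obese_fraction`.
#' @param obese_fraction target obesity prevalence used when `bmi_intercept`
#'   is `NULL` (default 0.55, a mixed-weight adult cohort).
#' @param rng_seed integer seed; the generator output is a pure function of
#'   the spec including this seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 104, n_taxa = 31,
                        planted_numerator = 1:2, planted_denominator = 3:5,
                        log_mean = NULL, log_sd = NULL,
                        structural_zero_taxa = NULL,
                        structural_zero_rate = 0.3,
                        depth = 5000,
                        balance_effect = NULL, target_r = 0.57,
                        bmi_noise_sd = 8.1, bmi_intercept = NULL,
                        obese_fraction = 0.55,
                        rng_seed = 1) {
  if (length(planted_numerator) < 1 || length(planted_denominator) < 1)
    stop("planted numerator and denominator must be non-empty")
  if (length(intersect(planted_numerator, planted_denominator)) > 0)
    stop("planted numerator and denominator overlap")
  if (n_taxa < length(planted_numerator) + length(planted_denominator))
    stop("n_taxa smaller than the planted signature")
  taxon_ids <- sprintf("phy%02d", seq_len(n_taxa))
  planted <- c(planted_numerator, planted_denominator)
  if (is.null(log_mean)) {
    log_mean <- rep(NA_real_, n_taxa)
    log_mean[planted_numerator] <-
      seq(3.4, 2.7, length.out = length(planted_numerator))
    log_mean[planted_denominator] <-
      seq(-1.7, -2.7, length.out = length(planted_denominator))
    free <- setdiff(seq_len(n_taxa), planted)
    log_mean[free] <- seq(0.5, -4.5, length.out = max(length(free), 1))[
      seq_along(free)]
  }
  if (is.null(log_sd)) {
    # planted log-sds are set so each signature taxon carries an
    # approximately equal share of the balance variance
    # (sd_B = 1.5 sd_A for a 2-vs-3 split)
    log_sd <- rep(0.9, n_taxa)
    log_sd[planted_numerator] <- 0.6
    log_sd[planted_denominator] <- 0.85
  }
  if (is.null(structural_zero_taxa)) {
    free <- setdiff(seq_len(n_taxa), planted)
    # rarest non-planted taxa carry the structural zeros
    structural_zero_taxa <- free[order(log_mean[free])][
      seq_len(min(6, length(free)))]
  }
  if (length(intersect(structural_zero_taxa, planted)) > 0)
    stop("structural zeros cannot be planted in the signature taxa")
  var_balance <- sum(log_sd[planted_numerator]^2) /
    length(planted_numerator)^2 +
    sum(log_sd[planted_denominator]^2) / length(planted_denominator)^2
  mean_balance <- mean(log_mean[planted_numerator]) -
    mean(log_mean[planted_denominator])
  if (is.null(balance_effect)) {
    # r^2 = b^2 Var(B) / (b^2 Var(B) + sigma^2)  =>  b
    balance_effect <- sqrt(target_r^2 / (1 - target_r^2)) *
      bmi_noise_sd / sqrt(var_balance)
  }
  if (is.null(bmi_intercept)) {
    sd_bmi <- sqrt(balance_effect^2 * var_balance + bmi_noise_sd^2)
    bmi_intercept <- 30 + stats::qnorm(obese_fraction) * sd_bmi -
      balance_effect * mean_balance
  }
  structure(
    list(n_subjects = n_subjects, n_taxa = n_taxa, taxon_ids = taxon_ids,
         planted_numerator = taxon_ids[planted_numerator],
         planted_denominator = taxon_ids[planted_denominator],
         log_mean = stats::setNames(log_mean, taxon_ids),
         log_sd = stats::setNames(log_sd, taxon_ids),
         structural_zero_taxa = taxon_ids[structural_zero_taxa],
         structural_zero_rate = structural_zero_rate,
         depth = depth, balance_effect = balance_effect,
         bmi_noise_sd = bmi_noise_sd, bmi_intercept = bmi_intercept,
         mean_balance = mean_balance, var_balance = var_balance,
         rng_seed = as.integer(rng_seed)),
    class = "cohort_spec"
  )
}

#' Calibrate the BMI slope for a target explained variance
#'
#' Computes the slope `b` such that the theoretical proportion of BMI
#' variance explained by the planted balance,
#' `R^2 = b^2 Var(B) / (b^2 Var(B) + sigma^2)`, equals `r2`. `Var(B)` is
#' estimated empirically by simulating the baseline composition (no BMI
#' link) at large n.
#'
#' @param spec a [cohort_spec()].
#' @param r2 target theoretical R-squared.
#' @param n_sim number of baseline draws used to estimate `Var(B)`.
#' @return The calibrated slope (kg/m^2 per balance log-unit).
#' @export
balance_effect_for_r2 <- function(spec, r2, n_sim = 20000) {
  stopifnot(inherits(spec, "cohort_spec"), r2 > 0, r2 < 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$rng_seed + 1000003L)
  idx_a <- match(spec$planted_numerator, spec$taxon_ids)
  idx_b <- match(spec$planted_denominator, spec$taxon_ids)
  la <- sapply(idx_a, function(j)
    stats::rnorm(n_sim, spec$log_mean[j], spec$log_sd[j]))
  lb <- sapply(idx_b, function(j)
    stats::rnorm(n_sim, spec$log_mean[j], spec$log_sd[j]))
  bal <- rowMeans(la) - rowMeans(lb)
  sqrt(r2 / (1 - r2)) * spec$bmi_noise_sd / stats::sd(bal)
}

#' Generate a synthetic microbiome cohort
#'
#' Draws the baseline composition, plants the balance-BMI association, adds
#' structural zeros, optionally resamples multinomial read counts at the
#' configured depth, and generates the phenotype table (BMI, obesity status
#' at the BMI >= 30 threshold, age, sex, Stroop interference, PHQ-9). The
#' Stroop and PHQ-9 scores are linked linearly to the planted balance so that
#' subsequent dysbiosis stratification shows group differences of realistic
#' size. The planted per-subject balance is returned in the phenotype column
#' `planted_balance` as ground truth for tests.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `table` (an [abundance_table()]; counts at
#'   `spec$depth` reads, or closed proportions when `depth` is `NULL`) and
#'   `phenotypes` (a data frame).
#' @export
gen_microbiome <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$rng_seed)
  n <- spec$n_subjects; D <- spec$n_taxa
  intens <- exp(sweep(matrix(stats::rnorm(n * D), n, D) %*%
                        diag(spec$log_sd, D), 2, spec$log_mean, "+"))
  colnames(intens) <- spec$taxon_ids
  # planted balance from the baseline intensities (closure-invariant, so it
  # equals the balance of the closed proportions exactly)
  sig <- balance_signature(spec$planted_numerator, spec$planted_denominator)
  planted_balance <- compute_balance(intens, sig)
  # structural zeros in designated rare taxa
  for (t in spec$structural_zero_taxa) {
    z <- stats::runif(n) < spec$structural_zero_rate
    intens[z, t] <- 0
  }
  props <- intens / rowSums(intens)
  if (is.null(spec$depth)) {
    tab <- abundance_table(props, sprintf("sub%03d", seq_len(n)))
  } else {
    counts <- t(vapply(seq_len(n), function(i)
      as.numeric(stats::rmultinom(1, spec$depth, props[i, ])),
      numeric(D)))
    colnames(counts) <- spec$taxon_ids
    tab <- abundance_table(counts, sprintf("sub%03d", seq_len(n)))
  }
  bmi <- spec$bmi_intercept + spec$balance_effect * planted_balance +
    stats::rnorm(n, 0, spec$bmi_noise_sd)
  age <- stats::rnorm(n, 47, 10.5)
  sex <- ifelse(stats::runif(n) < 0.66, "female", "male")
  ctr <- planted_balance - spec$mean_balance
  stroop <- 46 - 7 * ctr + stats::rnorm(n, 0, 8)
  phq9 <- round(pmin(27, pmax(0, 5 + 2.2 * ctr + stats::rnorm(n, 0, 3.5))))
  pheno <- data.frame(
    subject_id = rownames(tab),
    bmi = bmi, age = age, sex = sex,
    obesity = ifelse(bmi >= 30, "obese", "non-obese"),
    balance_value = NA_real_,
    planted_balance = planted_balance,
    stroop_interference = stroop, phq9 = phq9,
    stringsAsFactors = FALSE)
  rownames(pheno) <- NULL
  list(table = tab, phenotypes = pheno)
}
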