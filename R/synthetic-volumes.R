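#' Default hypothalamic seed definitions
#'
#' Bilateral medial (MH, x = +/-4, y = 2, z = -12) and lateral
#' (LH, x = +/-6, y = -10, z = -10) hypothalamus, 2-mm-radius spheres.
#'
#' @return Named list of [seed_spec()] objects.
#' @export
default_seeds <- function() {
  list(
    MH = seed_spec("MH", rbind(c(4, 2, -12), c(-4, 2, -12)), radius = 2),
    LH = seed_spec("LH", rbind(c(6, -10, -10), c(-6, -10, -10)), radius = 2)
  )
}

#' Specify a synthetic volume cohort
#'
#' Generative model for per-subject modulated grey-matter maps on a
#' desk-scale MNI-like grid. Each subject volume is a shared smooth template
#' plus (i) a subject-level seed signal placed in the hypothalamic seed
#' spheres, (ii) planted covariance networks whose coupling to the seed
#' signal depends on the group (stratum), (iii) additive age/sex confound
#' fields and a global-volume scaling factor, and (iv) smoothed Gaussian
#' voxel noise. Planted effects are added after smoothing so the support of
#' every planted network is exactly its mask; only the noise field carries
#' the smoothing kernel.
#'
#' @param dims voxel counts per axis (default `c(32, 38, 32)` at 2 mm, large
#'   enough to contain the hypothalamic seeds and disjoint networks).
#' @param voxel_size mm (default 2).
#' @param seeds named list of [seed_spec()]s (default [default_seeds()]).
#' @param networks list of planted networks; each is a list with `name`,
#'   `seed` (name of the driving seed), `center` (mm), `radius` (mm), and
#'   `group_slopes` (named per-stratum covariance slope).
#' @param seed_signal_sd sd of the subject-level seed signal (image units).
#' @param seed_cor correlation between the MH and LH subject signals.
#' @param confound_effects named loadings `age`, `sex`, `global` for the
#'   confound fields (image units per unit of the standardized covariate).
#' @param noise_sd sd of the voxel noise before smoothing.
#' @param smoothing_fwhm mm, applied to the noise field (default 8).
#' @param rng_seed integer seed.
#' @return A `volume_spec` list.
#' @export
volume_spec <- function(dims = c(32, 38, 32), voxel_size = 2,
                        seeds = default_seeds(),
                        networks = default_networks(),
                        seed_signal_sd = 1, seed_cor = 0.4,
                        confound_effects = c(age = 0.002, sex = 0.01,
                                             global = 0.05),
                        noise_sd = 2, smoothing_fwhm = 8,
                        rng_seed = 1) {
  stopifnot(all(dims > 0), voxel_size > 0)
  for (nw in networks) {
    stopifnot(all(c("name", "seed", "center", "radius", "group_slopes")
                  %in% names(nw)))
    if (!all(is.finite(nw$group_slopes))) stop("group slopes must be finite")
    if (!nw$seed %in% names(seeds))
      stop("network '", nw$name, "' references unknown seed '", nw$seed, "'")
  }
  structure(
    list(dims = as.integer(dims), voxel_size = voxel_size,
         affine = default_affine(dims, voxel_size),
         seeds = seeds, networks = networks,
         seed_signal_sd = seed_signal_sd, seed_cor = seed_cor,
         confound_effects = confound_effects,
         noise_sd = noise_sd, smoothing_fwhm = smoothing_fwhm,
         rng_seed = as.integer(rng_seed)),
    class = "volume_spec"
  )
}

#' Default planted covariance networks
#'
#' Two disjoint spherical target regions: a frontal-like region whose
#' MH-seed covariance is stronger in the non-obese stratum, and a
#' posterior region whose LH-seed covariance is specific to the
#' obese-dysbiosis stratum. Slopes are kept moderate so that the planted
#' regions remain a small share of global grey-matter volume; much larger
#' couplings make the global-GMV covariate itself carry a group-dependent
#' seed component, which induces real interaction signal outside the
#' declared masks and would falsify the generator's own ground truth.
#'
#' @param strength multiplies the between-group slope separation.
#' @return List of network definitions for [volume_spec()].
#' @export
default_networks <- function(strength = 1) {
  list(
    list(name = "frontal", seed = "MH", center = c(-10, 10, 8), radius = 7,
         group_slopes = c("non-obese" = 0.1 + 0.4 * strength,
                          "obese-no-dysbiosis" = 0.1,
                          "obese-dysbiosis" = 0.1)),
    list(name = "posterior", seed = "LH", center = c(10, -14, 2), radius = 7,
         group_slopes = c("non-obese" = 0.1,
                          "obese-no-dysbiosis" = 0.1,
                          "obese-dysbiosis" = 0.1 + 0.45 * strength))
  )
}

# Smooth ellipsoidal GM-probability template spanning the grid.
gm_template <- function(dims, affine) {
  half <- abs(voxel_to_mm(affine, matrix(dims, 1)) -
                voxel_to_mm(affine, matrix(c(1, 1, 1), 1))) / 2
  ctr <- (voxel_to_mm(affine, matrix(dims, 1)) +
            voxel_to_mm(affine, matrix(c(1, 1, 1), 1))) / 2
  grid <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                                seq_len(dims[3])))
  mm <- voxel_to_mm(affine, grid)
  r2 <- rowSums(sweep(sweep(mm, 2, ctr), 2, half, "/")^2)
  array(0.65 * exp(-1.8 * r2), dims)
}

#' Generate a synthetic grey-matter volume stack
#'
#' See [volume_spec()] for the generative model. Subject strata are taken
#' from a `stratum` column of `phenotypes` when present; otherwise they are
#' derived from the generator's ground truth (`planted_balance`) by the same
#' median-split rule the analysis applies, so planted group effects align
#' with the analysis strata.
#'
#' @param spec a [volume_spec()].
#' @param phenotypes phenotype data frame from [gen_microbiome()] (needs
#'   `age`, `sex`, `obesity`, and `stratum` or `planted_balance`).
#' @return A [volume_stack()] with an attribute `truth` carrying the seed
#'   signals, global factors, strata, and network masks used.
#' @export
gen_volume_stack <- function(spec, phenotypes) {
  stopifnot(inherits(spec, "volume_spec"))
  need <- c("age", "sex", "obesity")
  stopifnot(all(need %in% names(phenotypes)))
  n <- nrow(phenotypes)
  if ("stratum" %in% names(phenotypes)) {
    stratum <- as.character(phenotypes$stratum)
  } else {
    stopifnot("planted_balance" %in% names(phenotypes))
    ph <- phenotypes
    ph$balance_value <- ph$planted_balance
    stratum <- as.character(stratify_by_median(ph)$stratum)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$rng_seed)
  dims <- spec$dims; aff <- spec$affine
  # seed coordinates must fall inside the grid
  for (sd_ in spec$seeds) {
    vox <- mm_to_voxel(aff, sd_$mni_coords)
    if (any(vox < 0.5) || any(sweep(vox, 2, dims + 0.5) > 0))
      stop("seed '", sd_$name, "' falls outside the volume grid")
  }
  template <- gm_template(dims, aff)
  seed_fields <- lapply(spec$seeds, function(sd_) {
    m <- array(FALSE, dims)
    for (r in seq_len(nrow(sd_$mni_coords)))
      m <- m | sphere_mask(dims, aff, sd_$mni_coords[r, ], sd_$radius)
    m
  })
  net_masks <- lapply(spec$networks, function(nw)
    sphere_mask(dims, aff, nw$center, nw$radius))
  names(net_masks) <- vapply(spec$networks, `[[`, "", "name")
  # correlated subject-level seed signals
  k <- length(spec$seeds)
  R <- matrix(spec$seed_cor, k, k); diag(R) <- 1
  z <- matrix(stats::rnorm(n * k), n, k) %*% chol(R) * spec$seed_signal_sd
  colnames(z) <- names(spec$seeds)
  glob <- stats::rnorm(n)
  age_z <- as.numeric(scale(phenotypes$age))
  sex_z <- ifelse(phenotypes$sex == "male", 1, 0) -
    mean(phenotypes$sex == "male")
  # fixed smooth confound fields, deterministic given the seed
  conf_age <- gaussian_smooth_3d(array(stats::rnorm(prod(dims)), dims),
                                 spec$smoothing_fwhm * 2, spec$voxel_size)
  conf_sex <- gaussian_smooth_3d(array(stats::rnorm(prod(dims)), dims),
                                 spec$smoothing_fwhm * 2, spec$voxel_size)
  conf_age <- conf_age / stats::sd(conf_age)
  conf_sex <- conf_sex / stats::sd(conf_sex)
  ce <- spec$confound_effects
  data <- array(0, c(dims, n))
  for (i in seq_len(n)) {
    vol <- template
    for (s in names(spec$seeds))
      vol <- vol + z[i, s] * seed_fields[[s]]
    for (w in seq_along(spec$networks)) {
      nw <- spec$networks[[w]]
      slope <- nw$group_slopes[[stratum[i]]]
      vol <- vol + slope * z[i, nw$seed] * net_masks[[w]]
    }
    vol <- vol + ce[["age"]] * age_z[i] * conf_age +
      ce[["sex"]] * sex_z[i] * conf_sex +
      ce[["global"]] * glob[i] * template
    if (spec$noise_sd > 0) {
      vol <- vol + gaussian_smooth_3d(
        array(stats::rnorm(prod(dims), 0, spec$noise_sd), dims),
        spec$smoothing_fwhm, spec$voxel_size)
    }
    data[, , , i] <- vol
  }
  stack <- volume_stack(data, aff, phenotypes$subject_id)
  attr(stack, "truth") <- list(seed_signals = z, global_factor = glob,
                               stratum = stratum, network_masks = net_masks,
                               seed_fields = seed_fields, template = template)
  stack
}
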