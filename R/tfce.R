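#' TFCE parameters
#'
#' Canonical defaults for grey-matter VBM-style analyses: height exponent
#' H = 2, extent exponent E = 0.5, 26-voxel connectivity, and an integration
#' step of `max(|stat|) / 100` chosen per map (`dh = NULL`).
#'
#' @param E extent exponent (>= 0).
#' @param H height exponent (>= 0).
#' @param dh integration step in statistic units; `NULL` uses
#'   `max(|stat|) / n_steps` per map.
#' @param n_steps number of integration steps when `dh` is `NULL`.
#' @param connectivity 6, 18, or 26 neighbourhood.
#' @return A `tfce_params` object.
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = NULL, n_steps = 100,
                        connectivity = 26) {
  stopifnot(E >= 0, H >= 0, is.null(dh) || dh > 0,
            connectivity %in% c(6, 18, 26))
  structure(list(E = E, H = H, dh = dh, n_steps = as.integer(n_steps),
                 connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement
#'
#' For every voxel v, `TFCE(v) = sum over h of e_h(v)^E * h^H * dh`, where
#' the sum runs over thresholds `h = dh, 2 dh, ...` up to the voxel's
#' statistic value and `e_h(v)` is the voxel count of the connected
#' suprathreshold component containing v at threshold h. Positive and
#' negative tails are enhanced separately and recombined with the sign of
#' the input, sharing one `dh` derived from `max(|stat|)`.
#'
#' @param x a `stat_map` or a 3D numeric array.
#' @param params a [tfce_params()].
#' @param mask optional logical array (required when `x` is a bare array
#'   with non-finite values outside the mask; defaults to the map's mask or
#'   all finite voxels).
#' @return Same type as `x`: a `stat_map` of kind `"TFCE"`, or an array.
#' @export
tfce_transform <- function(x, params = tfce_params(), mask = NULL) {
  is_map <- inherits(x, "stat_map")
  vol <- if (is_map) x$values else x
  stopifnot(length(dim(vol)) == 3)
  if (is.null(mask)) mask <- if (is_map) x$mask else is.finite(vol)
  stat <- vol
  stat[!mask | !is.finite(stat)] <- 0
  dims <- dim(stat)
  maxabs <- max(abs(stat))
  if (maxabs == 0) {
    out <- array(0, dims)
  } else {
    dh <- if (is.null(params$dh)) maxabs / params$n_steps else params$dh
    pos <- tfce_one_sided_cpp(pmax(stat, 0), dims, params$E, params$H,
                              dh, params$n_steps, params$connectivity)
    neg <- tfce_one_sided_cpp(pmax(-stat, 0), dims, params$E, params$H,
                              dh, params$n_steps, params$connectivity)
    out <- array(pos - neg, dims)
  }
  out[!mask] <- NA_real_
  if (is_map) {
    structure(list(values = out, kind = "TFCE", contrast = x$contrast,
                   df = x$df, n_permutations = x$n_permutations,
                   mask = mask),
              class = "stat_map")
  } else out
}

#' Permutation scheme
#'
#' @param n_permutations number of random permutations (>= 1). 5000 matches
#'   full-study inference; 500 is a desk-scale default.
#' @param rng_seed integer seed for the permutation draws.
#' @param strategy `"freedman_lane"` (exchange residuals under the reduced,
#'   nuisance-only model; default) or `"label_exchange"` (permute group
#'   labels and rebuild the interaction columns).
#' @return A `permutation_scheme` object.
#' @export
permutation_scheme <- function(n_permutations = 500, rng_seed = 1,
                               strategy = c("freedman_lane",
                                            "label_exchange")) {
  stopifnot(n_permutations >= 1)
  structure(list(n_permutations = as.integer(n_permutations),
                 rng_seed = as.integer(rng_seed),
                 strategy = match.arg(strategy)),
            class = "permutation_scheme")
}

# Permutation index matrix (n x B). For tiny samples where n! does not
# exceed the request, all n! permutations are enumerated instead (with a
# warning), making the test exact.
make_permutations <- function(n, scheme) {
  nperm_avail <- factorial(n)
  if (n <= 8 && nperm_avail <= scheme$n_permutations) {
    warning(sprintf(
      "only %d distinct permutations exist for n = %d; enumerating all",
      nperm_avail, n))
    all_perms <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
      out
    }
    return(do.call(cbind, all_perms(seq_len(n))))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(scheme$rng_seed)
  vapply(seq_len(scheme$n_permutations), function(b) sample.int(n),
         integer(n))
}

#' Max-statistic permutation FWE inference on TFCE maps
#'
#' Computes the observed t and TFCE maps for the requested interaction
#' contrast, then builds the permutation null distribution of the maximum
#' TFCE statistic (positive and negative tails separately) and converts it
#' to family-wise-error-corrected p-values:
#' `p_fwe(v) = (1 + #[perm max >= TFCE_obs(v)]) / (n_permutations + 1)`.
#' The default Freedman-Lane scheme permutes residuals under the reduced
#' model that excludes all seed-by-group interaction columns.
#'
#' @param fit a `structcov_fit` from [fit_interaction_glm()].
#' @param contrast name of a contrast in `fit$contrasts` (default: first).
#' @param params a [tfce_params()].
#' @param scheme a [permutation_scheme()].
#' @param roi_masks optional named list of logical arrays; per-permutation
#'   maxima restricted to each region are recorded for small-volume
#'   correction.
#' @return An `fwe_result` with the observed `t_map` and `tfce_map`
#'   (`stat_map`s), `p_fwe_pos`/`p_fwe_neg` maps, the null maxima
#'   (`null_max`, B x 2), per-ROI null maxima, and the permutation matrix.
#' @export
permutation_fwe <- function(fit, contrast = NULL, params = tfce_params(),
                            scheme = permutation_scheme(),
                            roi_masks = NULL) {
  stopifnot(inherits(fit, "structcov_fit"))
  if (is.null(contrast)) contrast <- names(fit$contrasts)[1]
  if (!contrast %in% names(fit$contrasts))
    stop("unknown contrast '", contrast, "'")
  cvec <- fit$contrasts[[contrast]]
  n <- nrow(fit$X)
  perms <- make_permutations(n, scheme)
  B <- ncol(perms)
  idx <- which(fit$mask)
  t_map <- fit$tmaps[[contrast]]
  tfce_map <- tfce_transform(t_map, params)
  # one integration step shared by the observed and every permuted map, so
  # all maps are enhanced on the same threshold grid
  dh_obs <- params$dh %||%
    (max(abs(t_map$values[idx]), 0) / params$n_steps)
  if (dh_obs <= 0) dh_obs <- 1
  params_fixed <- params; params_fixed$dh <- dh_obs
  rois <- if (is.null(roi_masks)) list() else lapply(roi_masks, which)
  if (scheme$strategy == "freedman_lane") {
    Z <- fit$X[, -fit$tested_cols, drop = FALSE]
    nm <- perm_max_tfce_cpp(fit$Y, fit$X, cvec, Z, perms, idx,
                            fit$dims, params$E, params$H, dh_obs,
                            params$n_steps, params$connectivity, rois)
  } else {
    nm <- label_exchange_maxima(fit, cvec, perms, params_fixed, rois)
  }
  obs <- tfce_map$values
  pmap_from_null <- function(null_vec, obs_tail) {
    p <- array(NA_real_, fit$dims)
    ov <- obs_tail[idx]
    cnt <- vapply(ov, function(o)
      if (is.na(o) || o <= 0) B else sum(null_vec >= o), numeric(1))
    p[idx] <- (1 + cnt) / (B + 1)
    p
  }
  obs_pos <- pmax(obs, 0); obs_neg <- pmax(-obs, 0)
  p_pos <- pmap_from_null(nm[, 1], obs_pos)
  p_neg <- pmap_from_null(nm[, 2], obs_neg)
  roi_null <- NULL
  if (length(rois) > 0) {
    roi_null <- lapply(seq_along(rois), function(r)
      nm[, 2 + 2 * (r - 1) + (1:2), drop = FALSE])
    names(roi_null) <- names(roi_masks)
  }
  structure(
    list(contrast = contrast, t_map = t_map, tfce_map = tfce_map,
         p_fwe_pos = p_pos, p_fwe_neg = p_neg,
         null_max = nm[, 1:2, drop = FALSE], roi_null_max = roi_null,
         perms = perms, params = params_fixed, scheme = scheme,
         fit = fit),
    class = "fwe_result"
  )
}

# Fallback permutation strategy: permute the group labels, rebuild group
# and interaction columns, refit, and enhance. Pure R; intended for small
# problems and cross-checks.
label_exchange_maxima <- function(fit, cvec, perms, params, rois) {
  n <- nrow(fit$X)
  X <- fit$X
  g <- fit$design$group_factor
  seed <- fit$design$values[, "seed"]
  covs <- X[, setdiff(colnames(X), c("intercept",
                                     grep("^grp_|^seedxgrp_|^seed$",
                                          colnames(X), value = TRUE))),
            drop = FALSE]
  B <- ncol(perms)
  out <- matrix(0, B, 2 + 2 * length(rois))
  idx <- which(fit$mask)
  for (b in seq_len(B)) {
    gp <- g[perms[, b]]
    Gd <- stats::model.matrix(~ gp)[, -1, drop = FALSE]
    inter <- seed * Gd
    Xb <- cbind(1, covs, Gd, seed = seed, inter)
    tv <- glm_tmap(fit$Y, Xb, cvec)
    vol <- array(0, fit$dims); vol[idx] <- tv
    tf <- tfce_transform(vol, params, mask = fit$mask)
    tfv <- tf[idx]
    out[b, 1] <- max(c(tfv[tfv > 0], 0))
    out[b, 2] <- max(c(-tfv[tfv < 0], 0))
    for (r in seq_along(rois)) {
      rv <- array(NA_real_, fit$dims); rv[idx] <- tfv
      rr <- rv[rois[[r]]]
      out[b, 2 + 2 * (r - 1) + 1] <- max(c(rr[rr > 0 & !is.na(rr)], 0))
      out[b, 2 + 2 * (r - 1) + 2] <- max(c(-rr[rr < 0 & !is.na(rr)], 0))
    }
  }
  out
}

#' @export
print.fwe_result <- function(x, ...) {
  idx <- which(x$fit$mask)
  cat(sprintf("<fwe_result> contrast '%s', %d permutations (%s)\n",
              x$contrast, nrow(x$null_max), x$scheme$strategy))
  cat(sprintf("  min p_fwe: positive tail %.4f, negative tail %.4f\n",
              min(x$p_fwe_pos[idx]), min(x$p_fwe_neg[idx])))
  invisible(x)
}

#' Small-volume correction
#'
#' FWE inference restricted to an a-priori sphere: the null distribution is
#' the per-permutation maximum TFCE within the sphere (3-mm radius for
#' subcortical regions, 5-mm for cortical, unless `radius` is given), reusing
#' the exact permutation sequence of the whole-brain analysis.
#'
#' @param fwe an `fwe_result` from [permutation_fwe()].
#' @param center_mm sphere center, mm.
#' @param region_class `"subcortical"` (3 mm) or `"cortical"` (5 mm).
#' @param radius explicit radius in mm, overriding `region_class`.
#' @return A list with `p_fwe_pos`/`p_fwe_neg` maps defined inside the
#'   sphere-mask intersection, and the sphere mask used.
#' @export
small_volume_correction <- function(fwe, center_mm,
                                    region_class = c("subcortical",
                                                     "cortical"),
                                    radius = NULL) {
  stopifnot(inherits(fwe, "fwe_result"))
  region_class <- match.arg(region_class)
  if (is.null(radius))
    radius <- if (region_class == "subcortical") 3 else 5
  fit <- fwe$fit
  sph <- sphere_mask(fit$dims, fit$affine, center_mm, radius) & fit$mask
  if (!any(sph)) stop("sphere does not intersect the analysis mask")
  cvec <- fit$contrasts[[fwe$contrast]]
  rois <- list(sphere = which(sph))
  if (fwe$scheme$strategy == "freedman_lane") {
    Z <- fit$X[, -fit$tested_cols, drop = FALSE]
    nm <- perm_max_tfce_cpp(fit$Y, fit$X, cvec, Z, fwe$perms,
                            which(fit$mask), fit$dims, fwe$params$E,
                            fwe$params$H, fwe$params$dh,
                            fwe$params$n_steps,
                            fwe$params$connectivity, rois)
  } else {
    nm <- label_exchange_maxima(fit, cvec, fwe$perms, fwe$params, rois)
  }
  B <- nrow(nm)
  obs <- fwe$tfce_map$values
  sidx <- which(sph)
  mk <- function(null_vec, obs_tail) {
    p <- array(NA_real_, fit$dims)
    ov <- obs_tail[sidx]
    cnt <- vapply(ov, function(o)
      if (is.na(o) || o <= 0) B else sum(null_vec >= o), numeric(1))
    p[sidx] <- (1 + cnt) / (B + 1)
    p
  }
  list(p_fwe_pos = mk(nm[, 3], pmax(obs, 0)),
       p_fwe_neg = mk(nm[, 4], pmax(-obs, 0)),
       sphere = sph, radius = radius)
}
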