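#' Define a seed region
#'
#' @param name short label (e.g. `"MH"`, `"LH"`).
#' @param mni_coords numeric matrix, one row of (x, y, z) mm per hemisphere.
#' @param radius sphere radius in mm (> 0).
#' @return A `seed_spec` object.
#' @export
seed_spec <- function(name, mni_coords, radius = 2) {
  mni_coords <- matrix(as.numeric(mni_coords), ncol = 3)
  stopifnot(radius > 0, all(is.finite(mni_coords)))
  structure(list(name = name, mni_coords = mni_coords, radius = radius),
            class = "seed_spec")
}

#' Grey-matter analysis mask
#'
#' Marks voxels whose mean value across subjects exceeds `threshold`,
#' implementing the usual "probability of being GM > 0.2" inclusion rule on
#' modulated GM maps.
#'
#' @param stack a [volume_stack()].
#' @param threshold inclusion threshold in `[0, 1)`.
#' @return Logical 3D array.
#' @export
make_gm_mask <- function(stack, threshold = 0.2) {
  stopifnot(inherits(stack, "volume_stack"),
            threshold >= 0, threshold < 1)
  m <- apply(stack$data, 1:3, mean) > threshold
  if (!any(m)) stop("empty grey-matter mask at threshold ", threshold)
  m
}

#' Extract per-subject seed values
#'
#' The seed coordinate is snapped to the nearest voxel center (a message is
#' emitted when snapping moves the center by more than half a voxel), the
#' sphere is the set of voxels whose centers lie within `radius` mm
#' (inclusive) of the snapped center, and the subject value is the mean GM
#' over those voxels. With `mode = "bilateral"` (default) the per-hemisphere
#' values are averaged into a single regressor per subject.
#'
#' @param stack a [volume_stack()].
#' @param seed a [seed_spec()].
#' @param mode `"bilateral"` or `"per-hemisphere"`.
#' @return Numeric vector (bilateral) or matrix with one column per
#'   hemisphere.
#' @export
extract_seed <- function(stack, seed, mode = c("bilateral", "per-hemisphere")) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "volume_stack"), inherits(seed, "seed_spec"))
  dims <- dim(stack$data)[1:3]
  vals <- matrix(NA_real_, dim(stack$data)[4], nrow(seed$mni_coords))
  flat <- matrix(stack$data, prod(dims), dim(stack$data)[4])
  for (r in seq_len(nrow(seed$mni_coords))) {
    target <- seed$mni_coords[r, ]
    vox <- drop(mm_to_voxel(stack$affine, matrix(target, 1)))
    snapped <- round(vox)
    if (any(snapped < 1) || any(snapped > dims))
      stop(sprintf("seed '%s' center (%s) mm is outside the volume grid",
                   seed$name, paste(target, collapse = ", ")))
    if (any(abs(snapped - vox) > 0.5))
      message(sprintf("seed '%s': snapped center moved > 0.5 voxel", seed$name))
    center_mm <- drop(voxel_to_mm(stack$affine, matrix(snapped, 1)))
    sph <- sphere_mask(dims, stack$affine, center_mm, seed$radius)
    idx <- which(sph)
    if (length(idx) == 0)
      stop(sprintf("seed '%s' sphere at (%s) mm contains no voxels",
                   seed$name, paste(target, collapse = ", ")))
    vals[, r] <- colMeans(flat[idx, , drop = FALSE])
  }
  if (mode == "bilateral") rowMeans(vals) else vals
}

#' Global grey-matter volume per subject
#'
#' Sum of all modulated voxel values, scaled by the voxel volume, in ml.
#'
#' @param stack a [volume_stack()].
#' @return Numeric vector (ml).
#' @export
global_gmv <- function(stack) {
  stopifnot(inherits(stack, "volume_stack"))
  vox_ml <- prod(stack$voxel_size) / 1000
  apply(stack$data, 4, sum) * vox_ml
}

#' Assemble the structural covariance design matrix
#'
#' Columns in the fixed entry order used for sequential orthogonalization:
#' age, sex (0 = female, 1 = male), global GMV, the other hypothalamic seed
#' from the same model, and finally the seed of interest. The group factor
#' is carried alongside (reference level first) and enters the GLM as
#' indicator columns, not as part of the orthogonalization chain.
#'
#' @param age,global_gmv,other_seed,seed numeric vectors (one per subject).
#' @param sex character (`"female"`/`"male"`) or 0/1 numeric.
#' @param group factor (or coercible) of group labels; the first level is
#'   the reference.
#' @return A `design_matrix` object.
#' @export
design_matrix <- function(age, sex, global_gmv, other_seed, seed, group) {
  if (is.character(sex)) sex <- as.numeric(sex == "male")
  group <- as.factor(group)
  group <- droplevels(group)
  values <- cbind(age = age, sex = sex, global_gmv = global_gmv,
                  other_seed = other_seed, seed = seed)
  stopifnot(nrow(values) == length(group), all(is.finite(values)))
  structure(list(values = values, group_factor = group,
                 orthogonalized = FALSE),
            class = "design_matrix")
}

#' Sequential Gram-Schmidt orthogonalization of the design
#'
#' Each column is centered and then residualized on all previously entered
#' (already orthogonalized) columns, in entry order. The final seed column
#' is thereby purged of the variance it shares with age, sex, global GMV,
#' and the other hypothalamic seed, so collinear measurements never coexist
#' in the fitted model.
#'
#' @param design a [design_matrix()].
#' @return The orthogonalized `design_matrix` (`orthogonalized = TRUE`).
#' @export
orthogonalize_design <- function(design) {
  stopifnot(inherits(design, "design_matrix"))
  V <- design$values
  n <- nrow(V)
  out <- matrix(0, n, ncol(V), dimnames = dimnames(V))
  for (j in seq_len(ncol(V))) {
    v <- V[, j] - mean(V[, j])
    if (j > 1) {
      prev <- out[, seq_len(j - 1), drop = FALSE]
      v <- v - prev %*% (crossprod(prev, v) / colSums(prev^2))
      # reorthogonalization pass for numerical stability
      v <- v - prev %*% (crossprod(prev, v) / colSums(prev^2))
    }
    if (sqrt(sum(v^2)) < 1e-10 * max(1, sqrt(sum(V[, j]^2))))
      stop("rank deficiency while orthogonalizing column '",
           colnames(V)[j], "'")
    out[, j] <- v
  }
  design$values <- out
  design$orthogonalized <- TRUE
  design
}

#' Voxel-wise seed-by-group interaction GLM
#'
#' Fits, at every masked voxel, GM value on an intercept, the orthogonalized
#' covariates (age, sex, global GMV, other seed), group indicator columns,
#' the seed regressor, and seed-by-group interaction terms. Returns t maps
#' for the slope-difference (interaction) contrasts: the single signed
#' contrast for two groups, or all pairwise contrasts under three groups.
#' Per-group seed-slope t maps (the within-group covariance maps) are also
#' available from the same fit via [within_group_tmaps()].
#'
#' @param stack a [volume_stack()].
#' @param design a [design_matrix()] (orthogonalized or not; it is
#'   orthogonalized here unless already done).
#' @param mask logical 3D analysis mask (see [make_gm_mask()]).
#' @return A `structcov_fit` with elements `X` (the full model matrix),
#'   `tested_cols` (interaction columns), `contrasts` (named contrast
#'   vectors), `tmaps` (named list of `stat_map`s), `Y`, `df`, `mask`,
#'   `dims`, `affine`, `group_levels`.
#' @export
fit_interaction_glm <- function(stack, design, mask) {
  stopifnot(inherits(stack, "volume_stack"), inherits(design, "design_matrix"))
  if (!design$orthogonalized) design <- orthogonalize_design(design)
  g <- design$group_factor
  lev <- levels(g)
  if (any(table(g) < 3)) stop("each group needs at least 3 subjects")
  n <- nrow(design$values)
  seed <- design$values[, "seed"]
  covs <- design$values[, c("age", "sex", "global_gmv", "other_seed"),
                        drop = FALSE]
  Gd <- stats::model.matrix(~ g)[, -1, drop = FALSE]
  colnames(Gd) <- paste0("grp_", lev[-1])
  inter <- seed * Gd
  colnames(inter) <- paste0("seedx", colnames(Gd))
  X <- cbind(intercept = 1, covs, Gd, seed = seed, inter)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  tested <- which(colnames(X) %in% colnames(inter))
  dims <- dim(stack$data)[1:3]
  idx <- which(mask)
  Y <- t(matrix(stack$data, prod(dims), n)[idx, , drop = FALSE])
  df <- n - ncol(X)
  contrasts <- list()
  p <- ncol(X)
  if (length(lev) == 2) {
    cv <- numeric(p); cv[tested] <- 1
    contrasts[[paste0(lev[2], "_vs_", lev[1])]] <- cv
  } else {
    for (a in 2:length(lev)) {
      cv <- numeric(p)
      cv[which(colnames(X) == paste0("seedxgrp_", lev[a]))] <- 1
      contrasts[[paste0(lev[a], "_vs_", lev[1])]] <- cv
    }
    for (a in 2:(length(lev) - 1)) for (b in (a + 1):length(lev)) {
      cv <- numeric(p)
      cv[which(colnames(X) == paste0("seedxgrp_", lev[b]))] <- 1
      cv[which(colnames(X) == paste0("seedxgrp_", lev[a]))] <- -1
      contrasts[[paste0(lev[b], "_vs_", lev[a])]] <- cv
    }
  }
  tmaps <- lapply(names(contrasts), function(nm) {
    tv <- glm_tmap(Y, X, contrasts[[nm]])
    vol <- array(NA_real_, dims); vol[idx] <- tv
    structure(list(values = vol, kind = "t",
                   contrast = paste("seed slope:", nm), df = df,
                   n_permutations = NA_integer_, mask = mask),
              class = "stat_map")
  })
  names(tmaps) <- names(contrasts)
  structure(list(X = X, tested_cols = tested, contrasts = contrasts,
                 tmaps = tmaps, Y = Y, df = df, mask = mask, dims = dims,
                 affine = stack$affine, group_levels = lev,
                 design = design),
            class = "structcov_fit")
}

#' @export
print.structcov_fit <- function(x, ...) {
  cat(sprintf("<structcov_fit> n = %d, %d masked voxels, groups: %s\n",
              nrow(x$X), ncol(x$Y), paste(x$group_levels, collapse = ", ")))
  cat("  contrasts:", paste(names(x$contrasts), collapse = ", "), "\n")
  invisible(x)
}

# Vectorized per-voxel t statistics for contrast `cvec` (R reference path;
# the permutation engine repeats the same computation in C++).
glm_tmap <- function(Y, X, cvec) {
  XtXinv <- chol2inv(chol(crossprod(X)))
  A <- XtXinv %*% t(X)
  B <- A %*% Y
  E <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(E^2) / df
  ccc <- drop(t(cvec) %*% XtXinv %*% cvec)
  num <- drop(t(cvec) %*% B)
  se <- sqrt(sigma2 * ccc)
  tv <- ifelse(se > 0, num / se, 0)
  tv
}

#' Per-group seed-slope t maps
#'
#' Within-group structural covariance maps: the t statistic of the seed
#' slope in each group (`seed` for the reference group, `seed + seedxgrp_g`
#' otherwise), from the interaction fit.
#'
#' @param fit a `structcov_fit` from [fit_interaction_glm()].
#' @return Named list of `stat_map`s, one per group level.
#' @export
within_group_tmaps <- function(fit) {
  stopifnot(inherits(fit, "structcov_fit"))
  lev <- fit$group_levels
  p <- ncol(fit$X)
  idx <- which(fit$mask)
  out <- lapply(lev, function(gr) {
    cv <- numeric(p)
    cv[which(colnames(fit$X) == "seed")] <- 1
    j <- which(colnames(fit$X) == paste0("seedxgrp_", gr))
    if (length(j)) cv[j] <- 1
    tv <- glm_tmap(fit$Y, fit$X, cv)
    vol <- array(NA_real_, fit$dims); vol[idx] <- tv
    structure(list(values = vol, kind = "t",
                   contrast = paste("seed slope within", gr), df = fit$df,
                   n_permutations = NA_integer_, mask = fit$mask),
              class = "stat_map")
  })
  names(out) <- lev
  out
}

#' @export
print.stat_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<stat_map> kind %s, contrast '%s', df %s\n", x$kind,
              x$contrast, format(x$df)))
  cat(sprintf("  range inside mask: [%.3f, %.3f]\n",
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}
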