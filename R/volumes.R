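#' Construct a volume stack
#'
#' Holds per-subject 3D grey-matter volumes on one shared grid with a single
#' voxel-to-mm affine. The affine maps 1-based voxel indices `(i, j, k)` to
#' stereotactic (MNI-style) millimetre coordinates.
#'
#' @param data 4D numeric array `[x, y, z, subject]`.
#' @param affine 4x4 matrix mapping 1-based voxel indices to mm.
#' @param subject_ids character vector, one id per subject.
#' @return A `volume_stack` object.
#' @export
volume_stack <- function(data, affine, subject_ids = NULL) {
  stopifnot(length(dim(data)) == 4, is.matrix(affine),
            all(dim(affine) == c(4, 4)))
  if (anyNA(data) || any(!is.finite(data))) stop("volumes must be finite")
  n <- dim(data)[4]
  if (n < 2) stop("a volume stack needs at least 2 subjects")
  if (is.null(subject_ids)) subject_ids <- sprintf("sub%03d", seq_len(n))
  stopifnot(length(subject_ids) == n)
  structure(list(data = data, affine = affine,
                 voxel_size = abs(diag(affine)[1:3]),
                 subject_ids = subject_ids),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_stack> %d subjects, %dx%dx%d voxels at %g mm\n",
              d[4], d[1], d[2], d[3], x$voxel_size[1]))
  invisible(x)
}

#' Default scanner grid affine
#'
#' Builds the affine used by the synthetic generator: isotropic voxels with
#' the mm origin placed on the voxel at index `floor(dims / 2)` along each
#' axis, so that coordinate (0, 0, 0) lies on a voxel center near mid-grid
#' and the stated hypothalamic seed coordinates fall on voxel centers.
#'
#' @param dims integer voxel counts per axis.
#' @param voxel_size isotropic voxel edge in mm (default 2).
#' @return 4x4 affine (1-based voxel index to mm).
#' @export
default_affine <- function(dims, voxel_size = 2) {
  i0 <- floor(dims / 2)
  aff <- diag(c(rep(voxel_size, 3), 1))
  aff[1:3, 4] <- -voxel_size * i0
  aff
}

voxel_to_mm <- function(affine, vox) {
  vox <- rbind(t(as.matrix(vox)), 1)
  t((affine %*% vox)[1:3, , drop = FALSE])
}

mm_to_voxel <- function(affine, mm) {
  mm <- rbind(t(as.matrix(mm)), 1)
  t((solve(affine) %*% mm)[1:3, , drop = FALSE])
}

#' Boolean sphere mask in mm space
#'
#' Marks every voxel whose center lies within `radius` mm (inclusive) of
#' `center_mm`.
#'
#' @param dims grid dimensions.
#' @param affine voxel-to-mm affine (1-based).
#' @param center_mm length-3 mm coordinate.
#' @param radius sphere radius in mm.
#' @return Logical 3D array.
#' @export
sphere_mask <- function(dims, affine, center_mm, radius) {
  vox <- mm_to_voxel(affine, matrix(center_mm, 1))
  # bounding box in voxel units to avoid scanning the full grid
  vsz <- abs(diag(affine)[1:3])
  lo <- pmax(1, floor(vox - radius / vsz - 1))
  hi <- pmin(dims, ceiling(vox + radius / vsz + 1))
  out <- array(FALSE, dims)
  if (any(lo > hi)) return(out)
  gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
  grid <- as.matrix(expand.grid(gx, gy, gz))
  mm <- voxel_to_mm(affine, grid)
  d2 <- rowSums(sweep(mm, 2, center_mm)^2)
  inside <- grid[d2 <= radius^2 + 1e-9, , drop = FALSE]
  if (nrow(inside) > 0) out[inside] <- TRUE
  out
}

#' Separable Gaussian smoothing of a 3D volume
#'
#' Convolves each axis with a truncated (3 sd) Gaussian kernel of standard
#' deviation `fwhm / 2.3548` in voxel units, renormalized at the edges so
#' constant images stay constant.
#'
#' @param arr 3D numeric array.
#' @param fwhm full width at half maximum, mm.
#' @param voxel_size voxel edge, mm.
#' @return Smoothed array of the same dimensions.
#' @export
gaussian_smooth_3d <- function(arr, fwhm, voxel_size = 2) {
  if (fwhm <= 0) return(arr)
  sigma <- fwhm / 2.3548 / voxel_size
  d <- dim(arr)
  kernels <- lapply(d, function(len) {
    K <- outer(seq_len(len), seq_len(len), function(i, j) {
      dd <- abs(i - j)
      ifelse(dd <= ceiling(3 * sigma), exp(-dd^2 / (2 * sigma^2)), 0)
    })
    K / rowSums(K)
  })
  # axis 1
  x <- matrix(arr, d[1]) ; x <- kernels[[1]] %*% x
  arr <- array(x, d)
  # axis 2
  arr <- aperm(arr, c(2, 1, 3))
  x <- matrix(arr, d[2]); x <- kernels[[2]] %*% x
  arr <- aperm(array(x, d[c(2, 1, 3)]), c(2, 1, 3))
  # axis 3
  arr <- aperm(arr, c(3, 1, 2))
  x <- matrix(arr, d[3]); x <- kernels[[3]] %*% x
  aperm(array(x, d[c(3, 1, 2)]), c(2, 3, 1))
}

#' Write a volume stack as one NIfTI-1 file per subject
#'
#' @param stack a [volume_stack()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return Invisibly, the path of the tab-separated subject manifest
#'   (`subject_id`, `file`).
#' @export
write_volume_stack <- function(stack, dir, prefix = "gm") {
  stopifnot(inherits(stack, "volume_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # NIfTI sforms use 0-based indices: shift the translation accordingly
  sf <- stack$affine
  sf[1:3, 4] <- sf[1:3, 4] + sf[1:3, 1:3] %*% rep(1, 3)
  files <- character(length(stack$subject_ids))
  for (i in seq_along(stack$subject_ids)) {
    im <- RNifti::asNifti(stack$data[, , , i])
    im <- RNifti::`sform<-`(im, structure(sf, code = 2L))
    files[i] <- file.path(dir, sprintf("%s_%s.nii", prefix,
                                       stack$subject_ids[i]))
    RNifti::writeNifti(im, files[i])
  }
  manifest <- file.path(dir, paste0(prefix, "_manifest.tsv"))
  utils::write.table(data.frame(subject_id = stack$subject_ids,
                                file = basename(files)),
                     manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a volume stack from a subject manifest
#'
#' @param manifest path to a TSV with columns `subject_id` and `file`
#'   (paths relative to the manifest directory or absolute).
#' @return A [volume_stack()].
#' @export
read_volume_stack <- function(manifest) {
  tab <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "file") %in% names(tab)))
  base <- dirname(manifest)
  paths <- ifelse(file.exists(tab$file), tab$file, file.path(base, tab$file))
  vols <- lapply(paths, RNifti::readNifti)
  d <- dim(vols[[1]])
  data <- array(0, c(d, length(vols)))
  for (i in seq_along(vols)) data[, , , i] <- vols[[i]]
  sf <- RNifti::xform(vols[[1]])
  aff <- unclass(sf)
  attributes(aff) <- list(dim = c(4, 4))
  # back to 1-based voxel convention
  aff[1:3, 4] <- aff[1:3, 4] - aff[1:3, 1:3] %*% rep(1, 3)
  volume_stack(data, aff, tab$subject_id)
}
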