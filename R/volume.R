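#' CT volume container
#'
#' A `ct_volume` is a 3-D grid of Hounsfield-unit (HU) values on a uniform,
#' axis-aligned grid. The third array index is the axial (slice) axis. World
#' position of voxel `(i, j, k)` (0-based) is `origin_mm + c(i, j, k) * spacing_mm`.
#'
#' @param voxels numeric 3-D array of HU values.
#' @param spacing_mm positive numeric triple, voxel size in mm (x, y, z).
#' @param origin_mm numeric triple, world position of voxel (0, 0, 0) in mm.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three positive finite numbers", call. = FALSE)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be three finite numbers", call. = FALSE)
  structure(
    list(voxels = voxels, spacing_mm = spacing_mm, origin_mm = origin_mm),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume> %d x %d x %d voxels, spacing %g x %g x %g mm, HU range [%g, %g]\n",
    d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
    min(x$voxels), max(x$voxels)
  ))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Full calibrated HU range
#'
#' The full 12-bit CT range: air at -1024 HU up to 3071 HU.
#' @return Numeric length-2 vector `c(-1024, 3071)`.
#' @export
hu_range <- function() c(-1024, 3071)

#' Read a CT volume from a NIfTI file
#'
#' Voxel values are interpreted as HU. Spacing is taken from `pixdim`, origin
#' from the translation column of the stored transform. Only axis-aligned
#' volumes are supported (no direction cosines).
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3-D scalar image.
#' @return A [ct_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D scalar image, got ", length(d), " dimensions", call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  origin <- if (is.null(xf)) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  vox <- array(as.numeric(img), dim = d)
  ct_volume(vox, spacing_mm = spacing, origin_mm = origin)
}

#' Write a CT volume to a NIfTI file
#'
#' HU values are stored as 32-bit floats; spacing and origin go to the
#' header's `pixdim` and qform/sform translation (diagonal affine).
#'
#' @param vol a [ct_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$voxels)
  img <- RNifti::`pixdim<-`(img, vol$spacing_mm)
  aff <- diag(c(vol$spacing_mm, 1))
  aff[1:3, 4] <- vol$origin_mm
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Clip a volume to the calibrated HU range
#'
#' Clamps every voxel to \[-1024, 3071\], the full range used throughout the
#' pipeline; spacing and origin are unchanged.
#'
#' @param vol a [ct_volume].
#' @return A [ct_volume] with clamped voxels.
#' @export
clip_hu <- function(vol) {
  stopifnot(inherits(vol, "ct_volume"))
  r <- hu_range()
  vol$voxels[] <- pmin(pmax(vol$voxels, r[1]), r[2])
  vol
}

#' Resample a volume to a target spacing
#'
#' The output grid has `ceil(n_in * spacing_in / spacing_out)` voxels per
#' axis, so the physical extent is preserved to within one output voxel.
#' Output voxel centres are at `origin + index * target_spacing` and values
#' are interpolated from the input grid; samples falling outside the input
#' grid take the nearest edge value.
#'
#' @param vol a [ct_volume].
#' @param target_spacing_mm positive numeric triple (mm).
#' @param interpolation `"linear"` (trilinear, for images) or `"nearest"`
#'   (for masks/label maps).
#' @return A resampled [ct_volume].
#' @export
resample_volume <- function(vol, target_spacing_mm, interpolation = c("linear", "nearest")) {
  stopifnot(inherits(vol, "ct_volume"))
  interpolation <- match.arg(interpolation)
  ts <- as.numeric(target_spacing_mm)
  if (length(ts) != 3L || any(!is.finite(ts)) || any(ts <= 0))
    stop("`target_spacing_mm` must be three positive numbers", call. = FALSE)
  d_in <- dim(vol$voxels)
  if (isTRUE(all.equal(ts, vol$spacing_mm))) {
    vol$spacing_mm <- ts
    return(vol)
  }
  d_out <- pmax(1L, as.integer(ceiling(d_in * vol$spacing_mm / ts)))
  # continuous source index of each output voxel centre
  idx <- lapply(1:3, function(a) (seq_len(d_out[a]) - 1) * ts[a] / vol$spacing_mm[a])
  out <- if (interpolation == "nearest") {
    near <- lapply(1:3, function(a) pmin(pmax(round(idx[[a]]) + 1, 1), d_in[a]))
    vol$voxels[near[[1]], near[[2]], near[[3]], drop = FALSE]
  } else {
    trilinear_sample(vol$voxels, idx[[1]], idx[[2]], idx[[3]])
  }
  ct_volume(out, spacing_mm = ts, origin_mm = vol$origin_mm)
}

# Separable trilinear interpolation on a per-axis grid of continuous 0-based
# indices; out-of-range samples clamp to the edge.
trilinear_sample <- function(vox, ix, iy, iz) {
  d <- dim(vox)
  axis_w <- function(i, n) {
    i <- pmin(pmax(i, 0), n - 1)
    lo <- pmin(floor(i), n - 1)
    hi <- pmin(lo + 1, n - 1)
    list(lo = as.integer(lo) + 1L, hi = as.integer(hi) + 1L, w = i - lo)
  }
  ax <- axis_w(ix, d[1]); ay <- axis_w(iy, d[2]); az <- axis_w(iz, d[3])
  acc <- array(0, c(length(ix), length(iy), length(iz)))
  for (cz in 1:2) {
    kz <- if (cz == 1) az$lo else az$hi
    wz <- if (cz == 1) 1 - az$w else az$w
    for (cy in 1:2) {
      ky <- if (cy == 1) ay$lo else ay$hi
      wy <- if (cy == 1) 1 - ay$w else ay$w
      for (cx in 1:2) {
        kx <- if (cx == 1) ax$lo else ax$hi
        wx <- if (cx == 1) 1 - ax$w else ax$w
        corner <- vox[kx, ky, kz, drop = FALSE]
        w <- outer(outer(wx, wy), wz)
        acc <- acc + corner * w
      }
    }
  }
  acc
}
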