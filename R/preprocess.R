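#' Otsu auto-threshold
#'
#' Histogram thresholding that maximises the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2} over candidate thresholds placed
#' at the interior edges of an equal-width histogram. Values strictly below
#' the returned threshold form the lower class. Ties are broken by the
#' smallest qualifying threshold.
#'
#' @param values numeric vector of HU samples (at least two distinct values).
#' @param n_bins number of equal-width histogram bins (default 256).
#' @return A list of class `otsu_result` with elements `threshold`,
#'   `between_class_variance` and `n_bins`.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) < 2L || diff(range(values)) == 0)
    stop("Otsu threshold requires at least two distinct finite values", call. = FALSE)
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 2L)
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  # bin counts; right-closed last bin
  bin <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(bin, n_bins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu_cum <- cumsum(p * mids)
  mu_tot <- mu_cum[n_bins]
  # candidate threshold after bin t (edge t+1); classes must be non-empty
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_tot * w0[valid] - mu_cum[valid])^2 / (w0[valid] * w1[valid])
  t_best <- which.max(sigma_b)  # first max: smallest qualifying threshold
  structure(
    list(
      threshold = edges[t_best + 1L],
      between_class_variance = sigma_b[t_best],
      n_bins = n_bins
    ),
    class = "otsu_result"
  )
}

#' Binary body mask
#'
#' @param voxels logical or 0/1 integer 3-D array, same grid as its source volume.
#' @param spacing_mm voxel spacing of the source grid.
#' @return An object of class `body_mask` with integer `{0,1}` voxels.
#' @export
body_mask <- function(voxels, spacing_mm = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("mask voxels must form a 3-D array", call. = FALSE)
  v <- array(as.integer(voxels != 0), dim = dim(voxels))
  structure(list(voxels = v, spacing_mm = as.numeric(spacing_mm)), class = "body_mask")
}

#' @export
print.body_mask <- function(x, ...) {
  cat(sprintf("<body_mask> %s voxels, %d foreground\n",
              paste(dim(x$voxels), collapse = " x "), sum(x$voxels)))
  invisible(x)
}

#' Extract the body mask of a CT volume
#'
#' Thresholds the volume with Otsu's method, keeps the largest 6-connected
#' 3-D component (the patient body) and fills internal cavities slice-wise,
#' so gas pockets stay inside the mask. Structures not connected to the body
#' in 3-D — in particular the treatment couch — are excluded.
#'
#' @param vol a [ct_volume] containing both air-like and tissue-like values.
#' @param n_bins histogram bins passed to [otsu_threshold()].
#' @return A [body_mask] on the same grid.
#' @export
extract_body_mask <- function(vol, n_bins = 256L) {
  stopifnot(inherits(vol, "ct_volume"))
  ot <- otsu_threshold(as.numeric(vol$voxels), n_bins = n_bins)
  fg <- vol$voxels >= ot$threshold
  if (!any(fg)) stop("no foreground voxels above the Otsu threshold", call. = FALSE)
  lab <- label_components_3d(as.logical(fg), dim(vol$voxels))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  m <- array(lab == keep, dim = dim(vol$voxels))
  for (k in seq_len(dim(m)[3])) {
    m[, , k] <- fill_holes_2d(m[, , k])
  }
  body_mask(m, spacing_mm = vol$spacing_mm)
}

#' Apply a body mask to a volume
#'
#' Voxels outside the mask are replaced by `fill` (default -1024 HU, air, so
#' removed regions encode to all-zero channels); voxels inside are unchanged.
#'
#' @param vol a [ct_volume].
#' @param mask a [body_mask] on the same grid.
#' @param fill HU value for masked-out voxels.
#' @return A masked [ct_volume].
#' @export
apply_mask <- function(vol, mask, fill = -1024) {
  stopifnot(inherits(vol, "ct_volume"), inherits(mask, "body_mask"))
  if (!identical(dim(vol$voxels), dim(mask$voxels)))
    stop("volume and mask grids disagree", call. = FALSE)
  vol$voxels[mask$voxels == 0L] <- fill
  vol
}

#' Write a body mask as integer NIfTI
#' @param mask a [body_mask].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "body_mask"))
  write_volume(ct_volume(mask$voxels + 0, spacing_mm = mask$spacing_mm), path)
}

#' Read a body mask from NIfTI
#' @param path path to a mask written by [write_mask()].
#' @return A [body_mask].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  body_mask(v$voxels != 0, spacing_mm = v$spacing_mm)
}
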