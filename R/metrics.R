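#' Mean absolute error over a mask, in HU
#'
#' @param a,b [ct_volume]s on the same grid.
#' @param mask a [body_mask]; only its foreground voxels are compared.
#' @return Mean of `|a - b|` over mask voxels, in HU.
#' @export
mae <- function(a, b, mask) {
  diffs <- masked_diffs(a, b, mask)
  mean(abs(diffs))
}

#' Root-mean-square error over a mask, in HU
#'
#' @inheritParams mae
#' @return Quadratic mean of the voxel-wise errors, in HU.
#' @export
rmse <- function(a, b, mask) {
  diffs <- masked_diffs(a, b, mask)
  sqrt(mean(diffs^2))
}

masked_diffs <- function(a, b, mask) {
  stopifnot(inherits(a, "ct_volume"), inherits(b, "ct_volume"),
            inherits(mask, "body_mask"))
  if (!identical(dim(a$voxels), dim(b$voxels)) ||
      !identical(dim(a$voxels), dim(mask$voxels)))
    stop("volumes and mask must share one grid", call. = FALSE)
  sel <- mask$voxels == 1L
  if (!any(sel)) stop("empty mask", call. = FALSE)
  a$voxels[sel] - b$voxels[sel]
}

#' SSIM parameters
#'
#' Stabilisation constants `c1 = (k1 L)^2`, `c2 = (k2 L)^2` with the
#' conventional `k1 = 0.01`, `k2 = 0.03` and the full HU dynamic range
#' `L = 4095` (from -1024 to 3071).
#'
#' @param k1,k2 luminance/contrast stabilisers.
#' @param dynamic_range value range `L`, in HU.
#' @return An object of class `ssim_params` with fields `c1`, `c2`.
#' @export
ssim_params <- function(k1 = 0.01, k2 = 0.03, dynamic_range = 4095) {
  structure(list(k1 = k1, k2 = k2, dynamic_range = dynamic_range,
                 c1 = (k1 * dynamic_range)^2, c2 = (k2 * dynamic_range)^2),
            class = "ssim_params")
}

#' Structural similarity over a mask (global statistics)
#'
#' The single-expression SSIM with uniform weights,
#' \deqn{\mathrm{SSIM} = \frac{(2\mu_x\mu_y + c_1)(2\sigma_{xy} + c_2)}
#' {(\mu_x^2+\mu_y^2+c_1)(\sigma_x^2+\sigma_y^2+c_2)},}
#' computed from the global moments (population, n-denominator) of the two
#' volumes over the mask voxels. A windowed mean-of-local-SSIM variant is
#' available via `window`.
#'
#' @inheritParams mae
#' @param params an [ssim_params()].
#' @param window optional odd integer; when given, SSIM is instead the mean
#'   over axial-slice local windows of that side length (body-mask centre
#'   voxels only).
#' @return Unitless scalar, 1 for identical inputs.
#' @export
ssim <- function(a, b, mask, params = ssim_params(), window = NULL) {
  stopifnot(inherits(params, "ssim_params"))
  if (!is.null(window)) return(ssim_windowed(a, b, mask, params, window))
  sel <- mask$voxels == 1L
  if (sum(sel) < 2L) stop("SSIM needs at least two mask voxels", call. = FALSE)
  x <- a$voxels[sel]; y <- b$voxels[sel]
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  ((2 * mx * my + params$c1) * (2 * cxy + params$c2)) /
    ((mx^2 + my^2 + params$c1) * (vx + vy + params$c2))
}

ssim_windowed <- function(a, b, mask, params, window) {
  stopifnot(window %% 2 == 1, window >= 3)
  r <- (window - 1L) / 2L
  d <- dim(a$voxels)
  vals <- c()
  for (k in seq_len(d[3])) {
    sel <- which(mask$voxels[, , k] == 1L, arr.ind = TRUE)
    if (!nrow(sel)) next
    ok <- sel[, 1] > r & sel[, 1] <= d[1] - r & sel[, 2] > r & sel[, 2] <= d[2] - r
    sel <- sel[ok, , drop = FALSE]
    if (!nrow(sel)) next
    sl_a <- a$voxels[, , k]; sl_b <- b$voxels[, , k]
    v <- vapply(seq_len(nrow(sel)), function(i) {
      ii <- (sel[i, 1] - r):(sel[i, 1] + r)
      jj <- (sel[i, 2] - r):(sel[i, 2] + r)
      x <- as.numeric(sl_a[ii, jj]); y <- as.numeric(sl_b[ii, jj])
      mx <- mean(x); my <- mean(y)
      vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
      cxy <- mean((x - mx) * (y - my))
      ((2 * mx * my + params$c1) * (2 * cxy + params$c2)) /
        ((mx^2 + my^2 + params$c1) * (vx + vy + params$c2))
    }, 0)
    vals <- c(vals, v)
  }
  if (!length(vals)) stop("no usable windows inside the mask", call. = FALSE)
  mean(vals)
}

#' Frechet distance between Gaussian feature fits
#'
#' `||mu_a - mu_b||^2 + Tr(S_a + S_b - 2 (S_a S_b)^{1/2})` where the means
#' and covariances (n-1 denominator) are fitted to the two feature sets; the
#' matrix square root is taken symmetrically and tiny negative eigenvalues
#' are clamped to zero.
#'
#' @param features_a,features_b numeric matrices, one feature vector per row
#'   (at least 2 rows each).
#' @return Non-negative scalar distance.
#' @export
fid <- function(features_a, features_b) {
  A <- as.matrix(features_a); B <- as.matrix(features_b)
  if (nrow(A) < 2L || nrow(B) < 2L)
    stop("FID needs at least two feature vectors per set", call. = FALSE)
  if (ncol(A) != ncol(B)) stop("feature dimensions disagree", call. = FALSE)
  mu_a <- colMeans(A); mu_b <- colMeans(B)
  Sa <- stats::cov(A); Sb <- stats::cov(B)
  # tr((Sa Sb)^{1/2}) via the symmetric form Sa^{1/2} Sb Sa^{1/2}
  ea <- eigen(0.5 * (Sa + t(Sa)), symmetric = TRUE)
  sqrt_a <- ea$vectors %*% (sqrt(pmax(ea$values, 0)) * t(ea$vectors))
  M <- sqrt_a %*% Sb %*% sqrt_a
  em <- eigen(0.5 * (M + t(M)), symmetric = TRUE)
  tr_sqrt <- sum(sqrt(pmax(em$values, 0)))
  val <- sum((mu_a - mu_b)^2) + sum(diag(Sa)) + sum(diag(Sb)) - 2 * tr_sqrt
  max(val, 0)
}

#' Deep-feature extractor for FID
#'
#' The published protocol uses the deepest pooling layer of an ImageNet
#' Inception v3 network. Pretrained inception weights are not shipped with
#' this package, so the `"inception-imagenet"` backend raises a capability
#' error unless a compatible scorer function is registered; the default
#' `"fixed-projection"` backend is self-contained and deterministic: slices
#' are average-pooled to a coarse grid and passed through a seeded random
#' Gaussian linear projection, giving a distribution-sensitive embedding
#' suitable for comparing image sets without any downloaded weights.
#'
#' @param images list of 2-D numeric matrices (masked axial slices), or a
#'   3-D array interpreted slice-wise along the third axis.
#' @param backend `"fixed-projection"` or `"inception-imagenet"`.
#' @param width embedding width of the fixed projection.
#' @param pool_to side length of the average-pooled grid fed to the
#'   projection.
#' @param seed seed of the fixed random projection (a protocol constant:
#'   change it and distances are no longer comparable across runs).
#' @return Numeric matrix, one feature vector per slice.
#' @export
feature_extractor <- function(images, backend = c("fixed-projection", "inception-imagenet"),
                              width = 64L, pool_to = 16L, seed = 1234L) {
  backend <- match.arg(backend)
  if (backend == "inception-imagenet")
    stop("the inception-imagenet backend requires pretrained weights that are ",
         "not available; use backend = \"fixed-projection\"", call. = FALSE)
  if (is.array(images) && length(dim(images)) == 3L)
    images <- lapply(seq_len(dim(images)[3]), function(k) images[, , k])
  pooled <- vapply(images, function(im) as.numeric(pool_mean(im, pool_to)),
                   numeric(pool_to * pool_to))
  P <- with_seed_local(seed,
                       matrix(stats::rnorm(pool_to * pool_to * width), pool_to * pool_to, width))
  t(pooled) %*% (P / sqrt(pool_to * pool_to))
}

# average-pool a matrix onto an n x n grid
pool_mean <- function(im, n) {
  d <- dim(im)
  gi <- cut(seq_len(d[1]), n, labels = FALSE)
  gj <- cut(seq_len(d[2]), n, labels = FALSE)
  rs <- rowsum(im, gi)              # n x d2, sums
  cnt_i <- tabulate(gi, n)
  rs <- rs / cnt_i
  cs <- rowsum(t(rs), gj)           # n x n
  cnt_j <- tabulate(gj, n)
  t(cs / cnt_j)
}

#' Fold-wise mean and standard error
#'
#' Cross-validation summary: arithmetic mean with the standard error
#' `sd(values) / sqrt(k)` (sample standard deviation, n-1 denominator).
#'
#' @param values numeric vector of per-fold metric values (k >= 2).
#' @return An object of class `fold_summary` with `mean`, `se`, `k`,
#'   `values`.
#' @export
aggregate_folds <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least two folds", call. = FALSE)
  structure(list(mean = mean(values), se = stats::sd(values) / sqrt(length(values)),
                 k = length(values), values = values),
            class = "fold_summary")
}

#' @export
print.fold_summary <- function(x, ...) {
  cat(sprintf("%.2f (%.2f) over %d folds\n", x$mean, x$se, x$k))
  invisible(x)
}

#' Per-volume metrics report
#'
#' Computes MAE, RMSE and SSIM for each aligned volume pair over its mask,
#' plus one set-level FID from the pooled masked axial slices of all
#' synthetic volumes against all reference volumes.
#'
#' @param synth,reference lists of [ct_volume]s, aligned element-wise.
#' @param masks list of [body_mask]s, one per pair.
#' @param ids optional character vector of volume ids.
#' @param ssim_parameters an [ssim_params()].
#' @return An object of class `metrics_report`: list with `per_volume`
#'   (data.frame: id, mae_hu, rmse_hu, ssim, n_voxels) and `fid`.
#' @export
evaluate_volumes <- function(synth, reference, masks, ids = NULL,
                             ssim_parameters = ssim_params()) {
  stopifnot(length(synth) == length(reference), length(synth) == length(masks))
  ids <- ids %||% sprintf("vol%03d", seq_along(synth))
  rows <- lapply(seq_along(synth), function(i) {
    data.frame(id = ids[i],
               mae_hu = mae(synth[[i]], reference[[i]], masks[[i]]),
               rmse_hu = rmse(synth[[i]], reference[[i]], masks[[i]]),
               ssim = ssim(synth[[i]], reference[[i]], masks[[i]], ssim_parameters),
               n_voxels = sum(masks[[i]]$voxels))
  })
  slices_of <- function(vols) {
    do.call(c, lapply(vols, function(v)
      lapply(seq_len(dim(v$voxels)[3]), function(k) v$voxels[, , k])))
  }
  f <- fid(feature_extractor(slices_of(synth)), feature_extractor(slices_of(reference)))
  structure(list(per_volume = do.call(rbind, rows), fid = f),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d volumes: MAE %.2f HU, RMSE %.2f HU, SSIM %.3f, FID %.2f\n",
              nrow(x$per_volume), mean(x$per_volume$mae_hu),
              mean(x$per_volume$rmse_hu), mean(x$per_volume$ssim), x$fid))
  invisible(x)
}

#' Write a metrics report and fold summary as CSV
#'
#' @param report a `metrics_report`.
#' @param path output CSV path for the per-volume table; a companion
#'   `*_set.csv` carries the set-level FID.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  utils::write.csv(report$per_volume, path, row.names = FALSE)
  utils::write.csv(data.frame(metric = "fid", value = report$fid),
                   sub("\\.csv$", "_set.csv", path), row.names = FALSE)
  invisible(path)
}
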