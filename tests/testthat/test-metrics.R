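vol_of <- function(values) ct_volume(array(values, c(length(values), 1, 1)))

test_that("MAE and RMSE match hand-computed values", {
  a <- vol_of(c(0, 10)); b <- vol_of(c(2, 6))
  m <- full_mask(a)
  expect_equal(mae(a, b, m), 3)
  expect_equal(rmse(a, b, m), sqrt(10))
  expect_equal(mae(a, a, m), 0)
  expect_equal(rmse(a, a, m), 0)
  # constant offset forces mae == |offset|
  off <- a; off$voxels <- a$voxels + 17
  expect_equal(mae(a, off, m), 17)
  empty <- body_mask(array(0L, dim(a$voxels)) * 0L)
  expect_error(mae(a, b, body_mask(array(0L, c(2, 1, 1)))), "grid|empty")
})

test_that("MAE never exceeds RMSE on random volume pairs", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(4:32, 1)
    a <- ct_volume(array(rnorm(n * 2 * 2, sd = 300), c(n, 2, 2)))
    b <- ct_volume(array(rnorm(n * 2 * 2, sd = 300), c(n, 2, 2)))
    m <- full_mask(a)
    expect_lte(mae(a, b, m), rmse(a, b, m) + 1e-12)
  }
})

test_that("mask restriction: only foreground voxels enter the error", {
  a <- vol_of(c(0, 0, 0, 0)); b <- vol_of(c(1, 2, 1000, -1000))
  m <- body_mask(array(c(1L, 1L, 0L, 0L), c(4, 1, 1)))
  expect_equal(mae(a, b, m), 1.5)
  expect_equal(rmse(a, b, m), sqrt(2.5))
})

test_that("global SSIM matches the direct formula and its symmetries", {
  set.seed(42)
  a <- ct_volume(array(rnorm(500, 100, 80), c(10, 10, 5)))
  b <- ct_volume(array(rnorm(500, 120, 90), c(10, 10, 5)))
  m <- full_mask(a)
  pp <- ssim_params()
  # independent oracle: plain evaluation of the definition
  x <- as.numeric(a$voxels); y <- as.numeric(b$voxels)
  n <- length(x)
  vx <- mean((x - mean(x))^2); vy <- mean((y - mean(y))^2)
  cxy <- mean((x - mean(x)) * (y - mean(y)))
  want <- ((2 * mean(x) * mean(y) + pp$c1) * (2 * cxy + pp$c2)) /
    ((mean(x)^2 + mean(y)^2 + pp$c1) * (vx + vy + pp$c2))
  expect_equal(ssim(a, b, m, pp), want, tolerance = 1e-12)
  expect_equal(ssim(a, b, m, pp), ssim(b, a, m, pp))
  expect_equal(ssim(a, a, m, pp), 1)
  # same-sign means: bounded above by 1
  expect_lte(ssim(a, b, m, pp), 1)
  # stabilisation constants follow (k L)^2
  expect_equal(pp$c1, (0.01 * 4095)^2)
  expect_equal(pp$c2, (0.03 * 4095)^2)
  expect_error(ssim(a, b, body_mask(array(c(1L, rep(0L, 499)), c(10, 10, 5)))),
               "two mask voxels")
})

test_that("windowed SSIM equals the global value on homogeneous fields", {
  a <- ct_volume(array(rnorm(16 * 16 * 2, 0, 10), c(16, 16, 2)))
  m <- full_mask(a)
  expect_equal(ssim(a, a, m, window = 5), 1)
})

test_that("FID matches the 1-D closed form and is symmetric", {
  set.seed(43)
  x <- matrix(rnorm(4000, 1, 2), ncol = 1)
  y <- matrix(rnorm(4000, 3, 5), ncol = 1)
  got <- fid(x, y)
  closed <- (mean(x) - mean(y))^2 + (sd(x) - sd(y))^2
  expect_equal(got, closed, tolerance = 1e-9)
  expect_equal(fid(x, y), fid(y, x), tolerance = 1e-9)
  expect_equal(fid(x, x), 0, tolerance = 1e-8)
  expect_error(fid(x[1, , drop = FALSE], y), "at least two")
})

test_that("FID matches an independent non-symmetric matrix-square-root oracle", {
  oracle <- function(A, B) {
    mu <- colMeans(A) - colMeans(B)
    Sa <- cov(A); Sb <- cov(B)
    # general (non-symmetric) eigendecomposition of the product Sa Sb
    e <- eigen(Sa %*% Sb)
    tr_sqrt <- sum(Re(sqrt(as.complex(e$values))))
    sum(mu^2) + sum(diag(Sa)) + sum(diag(Sb)) - 2 * tr_sqrt
  }
  set.seed(44)
  for (i in 1:10) {
    d <- sample(2:6, 1)
    A <- matrix(rnorm(60 * d, sd = runif(1, 0.5, 3)), 60, d)
    B <- matrix(rnorm(80 * d, mean = runif(1, -1, 1)), 80, d)
    expect_equal(fid(A, B), oracle(A, B), tolerance = 1e-6)
  }
})

test_that("the fixed-projection feature extractor is deterministic and sized", {
  set.seed(45)
  imgs <- lapply(1:5, function(i) matrix(rnorm(32 * 32), 32))
  f1 <- feature_extractor(imgs, width = 24)
  f2 <- feature_extractor(imgs, width = 24)
  expect_identical(f1, f2)
  expect_identical(dim(f1), c(5L, 24L))
  expect_equal(f1[1, ], feature_extractor(imgs[1], width = 24)[1, ],
               tolerance = 1e-12)
  expect_error(feature_extractor(imgs, backend = "inception-imagenet"),
               "fixed-projection")
})

test_that("fold aggregation computes mean and standard error correctly", {
  fs <- aggregate_folds(c(10, 12, 14, 16, 18))
  expect_equal(fs$mean, 14)
  expect_equal(fs$se, sd(c(10, 12, 14, 16, 18)) / sqrt(5))
  expect_equal(aggregate_folds(rep(7, 4))$se, 0)
  expect_error(aggregate_folds(3), "two folds")
})

test_that("evaluate_volumes assembles a coherent report", {
  set.seed(46)
  ref <- lapply(1:3, function(i) make_phantom(small_spec(), seed = 50 + i)$volume)
  synth <- lapply(ref, function(v) {
    v$voxels <- v$voxels + rnorm(length(v$voxels), 0, 20); clip_hu(v)
  })
  masks <- lapply(ref, extract_body_mask)
  rep <- evaluate_volumes(synth, ref, masks)
  expect_identical(nrow(rep$per_volume), 3L)
  expect_true(all(rep$per_volume$mae_hu <= rep$per_volume$rmse_hu))
  expect_true(all(rep$per_volume$ssim <= 1))
  expect_gte(rep$fid, 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(rep, path)
  expect_true(file.exists(path))
  expect_true(file.exists(sub("\\.csv$", "_set.csv", path)))
  back <- utils::read.csv(path)
  expect_equal(back$mae_hu, rep$per_volume$mae_hu, tolerance = 1e-9)
})
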