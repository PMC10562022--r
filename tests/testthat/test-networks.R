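test_that("reference architectures reproduce their exact parameter counts", {
  g <- build_generator(seed = 1)
  d <- build_discriminator(seed = 1)
  h <- build_projector(seed = 1)
  expect_identical(count_parameters(g), 11378179)
  expect_identical(count_parameters(d), 2764737)
  expect_identical(count_parameters(h), 560384)
  expect_identical(count_parameters(g) + count_parameters(d) + count_parameters(h),
                   14703300)
  expect_identical(2 * (count_parameters(g) + count_parameters(d)), 28285832)
  # an empty network counts zero
  empty <- identity_generator()
  expect_identical(count_parameters(empty), 0)
})

test_that("single-tap projector arithmetic", {
  h <- build_projector(projector_spec(tap_layer_ids = 0L, tap_channel_dims = 3L,
                                      width = 256L), seed = 1)
  expect_identical(count_parameters(h), 66816)
})

test_that("builds are deterministic given a seed", {
  g1 <- build_generator(generator_spec(base_filters = 8, n_resblocks = 1), seed = 42)
  g2 <- build_generator(generator_spec(base_filters = 8, n_resblocks = 1), seed = 42)
  p1 <- cutct:::layers_get_params(g1$layers)
  p2 <- cutct:::layers_get_params(g2$layers)
  expect_identical(p1, p2)
  g3 <- build_generator(generator_spec(base_filters = 8, n_resblocks = 1), seed = 43)
  expect_false(identical(p1, cutct:::layers_get_params(g3$layers)))
})

test_that("generator preserves spatial shape and bounds its output", {
  g <- build_generator(generator_spec(base_filters = 8, n_resblocks = 1), seed = 2)
  x <- array(runif(32 * 32 * 3, -1, 1), c(32, 32, 3))
  y <- net_apply(g, x)
  expect_identical(dim(y), dim(x))
  expect_true(all(abs(y) <= 1))
})

test_that("discriminator returns a spatial patch-score map", {
  d <- build_discriminator(discriminator_spec(base_filters = 8), seed = 3)
  x <- array(runif(64 * 64 * 3, -1, 1), c(64, 64, 3))
  s <- net_apply(d, x)
  expect_identical(dim(s), c(6L, 6L, 1L))   # 64 -> 32 -> 16 -> 8 -> 7 -> 6
  expect_true(all(is.finite(s)))
  # constant input also yields a finite map
  expect_true(all(is.finite(net_apply(d, array(0.5, c(64, 64, 3))))))
})

test_that("a 256x256 input yields the 30x30 patch map of the 70x70 stack", {
  d <- build_discriminator(discriminator_spec(base_filters = 4), seed = 1)
  s <- net_apply(d, array(0.1, c(256, 256, 3)))
  expect_identical(dim(s), c(30L, 30L, 1L))
})

test_that("encoder taps: tap 0 is the input, deeper taps are coarser", {
  g <- build_generator(generator_spec(base_filters = 8, n_resblocks = 2), seed = 4)
  x <- array(runif(32 * 32 * 3, -1, 1), c(32, 32, 3))
  f <- extract_features(g, x)
  expect_identical(f[["0"]], x)
  hs <- vapply(f, function(a) dim(a)[1], 0L)
  expect_true(all(diff(hs) <= 0))
  expect_identical(dim(f[["4"]])[3], 16L)   # 2 x base
  expect_identical(dim(f[["8"]])[3], 32L)   # 4 x base
  # determinism in evaluation mode
  expect_identical(extract_features(g, x), f)
  expect_error(extract_features(g, x, taps = "99"), "unknown tap")
})

test_that("patch sampling honours supplied locations, seeds and exhaustion", {
  g <- build_generator(generator_spec(base_filters = 8, n_resblocks = 1), seed = 5)
  x <- array(runif(32 * 32 * 3, -1, 1), c(32, 32, 3))
  f <- extract_features(g, x)
  s1 <- sample_patches(f, n_patches = 16, seed = 7)
  s2 <- sample_patches(f, n_patches = 16, seed = 7)
  expect_identical(s1, s2)
  s3 <- sample_patches(f, locations = s1$locations)
  expect_identical(s3$locations, s1$locations)
  expect_identical(s3$patches, s1$patches)
  # exhaustive sampling is a permutation of all locations
  grid8 <- dim(f[["8"]])[1] * dim(f[["8"]])[2]
  s4 <- sample_patches(f["8"], n_patches = grid8, seed = 8)
  expect_setequal(s4$locations[["8"]], seq_len(grid8))
  expect_error(sample_patches(f["8"], n_patches = grid8 + 1), "exceeds")
})

test_that("projected patch vectors are unit length", {
  gs <- generator_spec(base_filters = 8, n_resblocks = 1)
  g <- build_generator(gs, seed = 6)
  p <- build_projector(projector_spec_for(gs), seed = 6)
  x <- array(runif(32 * 32 * 3, -1, 1), c(32, 32, 3))
  f <- extract_features(g, x)
  s <- sample_patches(f, n_patches = 12, seed = 9)
  z <- project_patches(p, s$patches)
  for (m in z) expect_equal(sqrt(rowSums(m^2)), rep(1, nrow(m)), tolerance = 1e-6)
})

test_that("checkpoints restore weights and validate the spec", {
  gs <- generator_spec(base_filters = 8, n_resblocks = 1)
  g <- build_generator(gs, seed = 10)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(list(gen = g), path, meta = list(note = "test"))
  got <- load_checkpoint(path)
  expect_identical(cutct:::layers_get_params(got$nets$gen$layers),
                   cutct:::layers_get_params(g$layers))
  expect_identical(got$meta$note, "test")
  x <- array(runif(16 * 16 * 3, -1, 1), c(16, 16, 3))
  expect_identical(net_apply(got$nets$gen, x), net_apply(g, x))
})
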