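test_that("phantom generation is seed-deterministic and label-consistent", {
  a <- make_phantom(small_spec(), seed = 7)
  b <- make_phantom(small_spec(), seed = 7)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$volume$voxels, make_phantom(small_spec(), seed = 8)$volume$voxels))
  # every voxel's HU equals its label's table entry
  sp <- small_spec()
  table_hu <- c(sp$hu, couch = sp$couch_hu)
  codes <- phantom_labels()
  for (nm in names(codes)) {
    sel <- a$labels == codes[[nm]]
    if (any(sel)) expect_true(all(a$volume$voxels[sel] == table_hu[[nm]]))
  }
  expect_true(all(a$volume$voxels >= -1024 & a$volume$voxels <= 3071))
})

test_that("body and couch are distinct connected components", {
  ph <- make_phantom(small_spec(), seed = 9)
  fg <- ph$labels != phantom_labels()[["air"]]
  lab <- cutct:::label_components_3d(as.logical(fg), dim(fg))
  expect_identical(max(lab), 2L)
  couch_labels <- unique(lab[ph$labels == phantom_labels()[["couch"]]])
  body_labels <- unique(lab[ph$labels == phantom_labels()[["muscle"]]])
  expect_length(couch_labels, 1L)
  expect_length(body_labels, 1L)
  expect_false(couch_labels == body_labels)
})

test_that("zero degradation is the identity; single knobs act as designed", {
  ph <- make_phantom(small_spec(), seed = 11)$volume
  m <- full_mask(ph)
  none <- degrade_params(shading_amp = 0, scatter_fraction = 0, noise_sd = 0,
                         offset_hu = 0)
  expect_identical(degrade_to_cbct(ph, none)$voxels, ph$voxels)
  # offset only (interior voxels unaffected by clipping)
  off <- degrade_params(shading_amp = 0, scatter_fraction = 0, noise_sd = 0,
                        offset_hu = 25)
  inner <- body_mask(array(ph$voxels > -1000 & ph$voxels < 3000, dim(ph$voxels)))
  expect_equal(mae(degrade_to_cbct(ph, off), ph, inner), 25)
  # noise only: rmse approximates the noise SD on a large phantom
  big <- make_phantom(phantom_spec(dims = c(64L, 64L, 16L)), seed = 12)$volume
  noise <- degrade_params(shading_amp = 0, scatter_fraction = 0, noise_sd = 15,
                          offset_hu = 0, seed = 3)
  inner_big <- body_mask(array(big$voxels > -1000 & big$voxels < 3000, dim(big$voxels)))
  r <- rmse(degrade_to_cbct(big, noise), big, inner_big)
  expect_lt(abs(r - 15) / 15, 0.05)
})

test_that("any nonzero degradation increases the error against the clean phantom", {
  ph <- make_phantom(small_spec(), seed = 13)$volume
  m <- extract_body_mask(ph)
  grid <- list(
    degrade_params(shading_amp = 0.05, scatter_fraction = 0, noise_sd = 0, offset_hu = 0),
    degrade_params(shading_amp = 0, scatter_fraction = 0.1, noise_sd = 0, offset_hu = 0),
    degrade_params(shading_amp = 0, scatter_fraction = 0, noise_sd = 8, offset_hu = 0),
    degrade_params(shading_amp = 0, scatter_fraction = 0, noise_sd = 0, offset_hu = -20),
    degrade_params()
  )
  for (p in grid) {
    d <- degrade_to_cbct(ph, p)
    expect_gt(mae(d, ph, m), 0)
    expect_gt(rmse(d, ph, m), 0)
    expect_true(all(d$voxels >= -1024 & d$voxels <= 3071))
  }
})

test_that("unpaired dataset manifest keeps training domains unpaired and eval aligned", {
  ds <- make_unpaired_dataset(4, small_spec(), degrade_params(), seed = 21)
  mf <- ds$manifest
  expect_setequal(unique(mf$role), c("train_fbct", "train_cbct", "eval_clean", "eval_cbct"))
  for (p in unique(mf$patient)) {
    gs <- function(role) mf$geometry_seed[mf$patient == p & mf$role == role]
    expect_false(gs("train_cbct") == gs("train_fbct"))   # unpaired by geometry
    expect_identical(gs("eval_clean"), gs("eval_cbct"))  # aligned by construction
  }
  # evaluation pairs are voxel-aligned: same geometry, degraded copy
  v1 <- ds$volumes[["P001_eval_clean"]]
  v2 <- ds$volumes[["P001_eval_cbct"]]
  expect_identical(dim(v1$voxels), dim(v2$voxels))
  # determinism of the whole dataset
  ds2 <- make_unpaired_dataset(4, small_spec(), degrade_params(), seed = 21)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$volumes[["P002_train_cbct"]]$voxels,
                   ds2$volumes[["P002_train_cbct"]]$voxels)
  expect_error(make_unpaired_dataset(1), "two patients")
})

test_that("dataset export writes NIfTI volumes plus a JSON manifest", {
  out <- withr::local_tempdir()
  ds <- make_unpaired_dataset(2, small_spec(), degrade_params(), seed = 22,
                              out_dir = out)
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(all(file.exists(ds$manifest$file)))
  v <- read_volume(ds$manifest$file[1])
  expect_identical(dim(v$voxels), small_spec()$dims)
})
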