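test_that("patient folds partition without leakage and group replans", {
  pts <- data.frame(patient = sprintf("P%02d", 1:10),
                    n_volumes = c(3, rep(1, 8), 2))
  fs <- make_patient_folds(pts, k = 5, seed = 1)
  expect_length(fs$folds, 5)
  expect_true(all(vapply(fs$folds, length, 0L) == 2L))
  all_ids <- unlist(fs$folds)
  expect_setequal(all_ids, pts$patient)
  expect_identical(anyDuplicated(all_ids), 0L)       # no patient leaks
  # volumes follow their patient: fold volume counts sum to the total
  expect_equal(sum(fs$n_volumes), sum(pts$n_volumes))
  # determinism
  expect_identical(make_patient_folds(pts, k = 5, seed = 1)$folds, fs$folds)
  expect_false(identical(make_patient_folds(pts, k = 5, seed = 2)$folds, fs$folds))
  expect_error(make_patient_folds(pts, k = 11), "more folds")
})

test_that("learning-rate schedule: constant phase, linear decay, exact zero end", {
  cfg <- train_config(epochs_constant = 3, epochs_decay = 3, base_lr = 2e-4)
  expect_equal(lr_at(0, cfg), 2e-4)
  expect_equal(lr_at(2.9, cfg), 2e-4)
  expect_equal(lr_at(3, cfg), 2e-4)
  expect_equal(lr_at(4.5, cfg), 1e-4)
  expect_identical(lr_at(6, cfg), 0)
  eps <- seq(0, 6, by = 0.25)
  lrs <- lr_at(eps, cfg)
  expect_true(all(diff(lrs) <= 0))                    # non-increasing
  expect_true(all(lrs >= 0))
  expect_error(lr_at(6.1, cfg), "range")
  expect_error(lr_at(-0.1, cfg), "range")
})

test_that("a tiny training run is finite, checkpointed and bit-reproducible", {
  set.seed(99)
  mk <- function() array(runif(32 * 32 * 3, -1, 1), c(32, 32, 3))
  xs <- list(mk(), mk())
  ys <- list(mk(), mk())
  cfg <- train_config(epochs_constant = 1, epochs_decay = 1, seed = 5,
                      nce = nce_config(n_patches = 8))
  ckdir <- withr::local_tempdir()
  run1 <- train_cut(xs, ys, cfg,
                    gen_spec = generator_spec(base_filters = 4, n_resblocks = 1),
                    dis_spec = discriminator_spec(base_filters = 4),
                    checkpoint_dir = ckdir)
  expect_true(all(is.finite(as.matrix(run1$log))))
  expect_identical(nrow(run1$log), 4L)                # 2 epochs x 2 slices
  expect_true(file.exists(file.path(ckdir, "epoch_2.ckpt")))
  # identical config + seed => identical loss log, bit for bit
  run2 <- train_cut(xs, ys, cfg,
                    gen_spec = generator_spec(base_filters = 4, n_resblocks = 1),
                    dis_spec = discriminator_spec(base_filters = 4))
  expect_identical(run1$log, run2$log)
  expect_identical(cutct:::layers_get_params(run1$gen$layers),
                   cutct:::layers_get_params(run2$gen$layers))
  # a different seed changes the run
  cfg3 <- cfg; cfg3$seed <- 6L
  run3 <- train_cut(xs, ys, cfg3,
                    gen_spec = generator_spec(base_filters = 4, n_resblocks = 1),
                    dis_spec = discriminator_spec(base_filters = 4))
  expect_false(identical(run1$log$loss_total, run3$log$loss_total))
  expect_error(train_cut(list(), ys, cfg), "non-empty")
})

test_that("one optimisation step moves every trainable parameter set", {
  gs <- generator_spec(base_filters = 4, n_resblocks = 1)
  gen <- build_generator(gs, seed = 1)
  dis <- build_discriminator(discriminator_spec(base_filters = 4), seed = 2)
  proj <- build_projector(projector_spec_for(gs), seed = 3)
  before <- list(g = cutct:::layers_get_params(gen$layers),
                 d = cutct:::layers_get_params(dis$layers),
                 p = cutct:::layers_get_params(proj$layers))
  set.seed(7)
  x <- array(runif(32 * 32 * 3, -1, 1), c(32, 32, 3))
  y <- array(runif(32 * 32 * 3, -1, 1), c(32, 32, 3))
  cfg <- train_config(nce = nce_config(n_patches = 8))
  res <- cutct:::cut_step(gen, dis, proj, x, y, cfg, lr = 1e-3)
  expect_true(all(vapply(res, is.finite, TRUE)))
  moved <- function(a, b) any(mapply(function(u, v)
    any(unlist(u) != unlist(v)), a, b))
  expect_true(moved(before$g, cutct:::layers_get_params(gen$layers)))
  expect_true(moved(before$d, cutct:::layers_get_params(dis$layers)))
  expect_true(moved(before$p, cutct:::layers_get_params(proj$layers)))
})
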