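#' Training configuration
#'
#' The published schedule holds the learning rate constant for 3 epochs and
#' then decays it linearly to exactly 0 over 3 further epochs; training uses
#' batch size 1 on axial 2-D slices with an Adam-type optimiser with
#' momentum parameters (0.5, 0.999). The default base rate is 2e-4, the
#' stable convention for this architecture family; any other value
#' (including larger published ones) can be supplied.
#'
#' @param epochs_constant epochs at the base learning rate.
#' @param epochs_decay epochs of linear decay to 0.
#' @param base_lr base learning rate (> 0).
#' @param batch_size fixed at 1 (one unpaired slice pair per step).
#' @param seed integer seed controlling shuffling, patch sampling and
#'   weight initialisation.
#' @param augment_flip horizontal-flip augmentation (off by default so runs
#'   are bit-reproducible across configurations).
#' @param nce an [nce_config()].
#' @param weights an [objective_weights()].
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs_constant = 3L, epochs_decay = 3L,
                         base_lr = 2e-4, batch_size = 1L, seed = 1L,
                         augment_flip = FALSE, nce = nce_config(),
                         weights = objective_weights()) {
  stopifnot(epochs_constant >= 1L, epochs_decay >= 0L, base_lr > 0, batch_size == 1L)
  structure(list(epochs_constant = as.integer(epochs_constant),
                 epochs_decay = as.integer(epochs_decay),
                 base_lr = base_lr, batch_size = 1L, seed = as.integer(seed),
                 augment_flip = isTRUE(augment_flip), nce = nce, weights = weights),
            class = "train_config")
}

#' Learning rate at a (possibly fractional) epoch
#'
#' Constant at `base_lr` through the constant phase, then linear to exactly
#' 0 at the final epoch boundary.
#'
#' @param epoch real value in `[0, epochs_constant + epochs_decay]`.
#' @param cfg a [train_config()].
#' @return Non-negative learning rate.
#' @export
lr_at <- function(epoch, cfg = train_config()) {
  total <- cfg$epochs_constant + cfg$epochs_decay
  if (any(epoch < 0 | epoch > total))
    stop("epoch out of range [0, ", total, "]", call. = FALSE)
  ifelse(epoch <= cfg$epochs_constant, cfg$base_lr,
         cfg$base_lr * (total - epoch) / cfg$epochs_decay)
}

#' Random patient-level cross-validation folds
#'
#' Partitions patients into `k` near-equal folds; all volumes of a patient
#' (including replans) stay in one fold, so no patient leaks across folds.
#'
#' @param patients data.frame with columns `patient` (id) and optionally
#'   `n_volumes`, or a character vector of patient ids.
#' @param k number of folds.
#' @param seed integer seed.
#' @return An object of class `fold_split`: list with `folds` (list of
#'   patient-id vectors) and `n_volumes` per fold.
#' @export
make_patient_folds <- function(patients, k = 5L, seed = 1L) {
  if (is.character(patients)) patients <- data.frame(patient = patients, n_volumes = 1L)
  if (is.null(patients$n_volumes)) patients$n_volumes <- 1L
  ids <- unique(patients$patient)
  k <- as.integer(k)
  if (k > length(ids)) stop("more folds than patients", call. = FALSE)
  perm <- with_seed_local(seed, sample(ids))
  assign_fold <- rep(seq_len(k), length.out = length(ids))
  folds <- split(perm, assign_fold)
  names(folds) <- paste0("fold", seq_len(k))
  nv <- vapply(folds, function(f)
    sum(patients$n_volumes[patients$patient %in% f]), 0)
  structure(list(folds = folds, n_volumes = nv, k = k, seed = seed),
            class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("<fold_split> %d folds: %s patients, %s volumes\n", x$k,
              paste(vapply(x$folds, length, 0L), collapse = "/"),
              paste(x$n_volumes, collapse = "/")))
  invisible(x)
}

# ---- slice preparation ------------------------------------------------------

#' Convert a masked, clipped volume into network-ready slice arrays
#'
#' Each axial slice is channel-encoded with the HU partition and linearly
#' mapped from `[0, 255]` to the network value domain `[-1, 1]`.
#'
#' @param vol a [ct_volume] (already masked and clipped).
#' @param part an [partition_edges()] partition.
#' @return List of `H x W x n_segments` arrays in `[-1, 1]`.
#' @export
volume_to_slices <- function(vol, part = partition_edges()) {
  stopifnot(inherits(vol, "ct_volume"))
  lapply(seq_len(dim(vol$voxels)[3]), function(k) {
    channels_to_net(encode_slice(vol$voxels[, , k], part)$channels)
  })
}

channels_to_net <- function(ch) ch / 127.5 - 1
net_to_channels <- function(x) pmin(pmax((x + 1) * 127.5, 0), 255)

# ---- the training loop ------------------------------------------------------

#' Train a CUT model on unpaired slice streams
#'
#' One iteration draws one unpaired (CBCT, FBCT) slice pair, updates the
#' discriminator on its least-squares real/fake terms (halved, as is
#' conventional), then updates generator and projector jointly on the total
#' objective: adversarial term towards the real label, the multi-layer
#' PatchNCE between the input and its translation, and the identity PatchNCE
#' on the target-domain slice, at shared sampled patch locations. Everything
#' is driven by the config seed, so a run is exactly reproducible.
#'
#' @param cbct_slices,fbct_slices lists of `H x W x C` arrays in `[-1, 1]`
#'   (see [volume_to_slices()]); the two streams are unpaired.
#' @param cfg a [train_config()].
#' @param gen_spec,dis_spec network specs; the projector spec is derived
#'   from `gen_spec` via [projector_spec_for()].
#' @param checkpoint_dir if non-`NULL`, `epoch_<n>.ckpt` files are written
#'   there after each epoch.
#' @param verbose print a one-line summary per epoch.
#' @return An object of class `cut_checkpoint`: list with `gen`, `dis`,
#'   `proj`, `cfg`, `log` (one row per iteration: step, epoch, lr, loss_d,
#'   loss_g_adv, loss_nce_x, loss_nce_y, loss_total).
#' @export
train_cut <- function(cbct_slices, fbct_slices, cfg = train_config(),
                      gen_spec = generator_spec(), dis_spec = discriminator_spec(),
                      checkpoint_dir = NULL, verbose = FALSE) {
  if (!length(cbct_slices) || !length(fbct_slices))
    stop("both slice streams must be non-empty", call. = FALSE)
  with_seed_local(cfg$seed, {
    gen <- build_generator(gen_spec)
    dis <- build_discriminator(dis_spec)
    proj <- build_projector(projector_spec_for(gen_spec))
    n_total <- cfg$epochs_constant + cfg$epochs_decay
    n_iter_epoch <- length(cbct_slices)
    log <- vector("list", n_total * n_iter_epoch)
    step <- 0L
    for (epoch in seq_len(n_total)) {
      lr <- lr_at(epoch - 1L, cfg)
      ord_x <- sample.int(length(cbct_slices))
      ord_y <- sample.int(length(fbct_slices))
      for (it in seq_len(n_iter_epoch)) {
        step <- step + 1L
        x <- cbct_slices[[ord_x[it]]]
        y <- fbct_slices[[ord_y[((it - 1L) %% length(fbct_slices)) + 1L]]]
        if (cfg$augment_flip) {
          if (stats::runif(1) < 0.5) x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
          if (stats::runif(1) < 0.5) y <- y[rev(seq_len(dim(y)[1])), , , drop = FALSE]
        }
        res <- cut_step(gen, dis, proj, x, y, cfg, lr)
        if (!all(is.finite(unlist(res))))
          stop("non-finite loss at step ", step,
               " (d=", res$loss_d, ", g=", res$loss_g_adv, ")", call. = FALSE)
        log[[step]] <- data.frame(step = step, epoch = epoch, lr = lr,
                                  loss_d = res$loss_d, loss_g_adv = res$loss_g_adv,
                                  loss_nce_x = res$loss_nce_x,
                                  loss_nce_y = res$loss_nce_y,
                                  loss_total = res$loss_total)
      }
      if (verbose) {
        recent <- do.call(rbind, log[(step - n_iter_epoch + 1L):step])
        message(sprintf("epoch %d/%d lr=%.2e D=%.3f G=%.3f NCEx=%.3f NCEy=%.3f",
                        epoch, n_total, lr, mean(recent$loss_d),
                        mean(recent$loss_g_adv), mean(recent$loss_nce_x),
                        mean(recent$loss_nce_y)))
      }
      if (!is.null(checkpoint_dir)) {
        dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
        save_checkpoint(list(gen = gen, dis = dis, proj = proj),
                        file.path(checkpoint_dir, sprintf("epoch_%d.ckpt", epoch)),
                        meta = list(cfg = cfg, epoch = epoch, seed = cfg$seed))
      }
    }
    structure(list(gen = gen, dis = dis, proj = proj, cfg = cfg,
                   log = do.call(rbind, log)),
              class = "cut_checkpoint")
  })
}

#' @export
print.cut_checkpoint <- function(x, ...) {
  cat(sprintf("<cut_checkpoint> %d steps, final losses D=%.3f G=%.3f NCEx=%.3f NCEy=%.3f\n",
              nrow(x$log), utils::tail(x$log$loss_d, 1),
              utils::tail(x$log$loss_g_adv, 1),
              utils::tail(x$log$loss_nce_x, 1), utils::tail(x$log$loss_nce_y, 1)))
  invisible(x)
}

# One optimisation step: D on (real y, fake G(x)), then G + projector on the
# total objective. Returns the loss components.
cut_step <- function(gen, dis, proj, x, y, cfg, lr) {
  w <- cfg$weights
  # generator forward passes
  fA <- net_forward(gen, x, collect_taps = TRUE)   # fake + encoder taps of x
  fB <- net_forward(gen, y, collect_taps = TRUE)   # idt  + encoder taps of y
  fake <- fA$y
  idt <- fB$y

  # ---- discriminator update (fake detached) ----
  zero_grads(dis$layers)
  dr <- net_forward(dis, y)
  df <- net_forward(dis, fake)
  loss_d <- 0.5 * (adversarial_loss(dr$y, TRUE) + adversarial_loss(df$y, FALSE))
  net_backward(dis, dr, 0.5 * adversarial_loss_grad(dr$y, TRUE))
  net_backward(dis, df, 0.5 * adversarial_loss_grad(df$y, FALSE))
  adam_step(dis$layers, lr)

  # ---- generator + projector update ----
  zero_grads(gen$layers)
  zero_grads(proj$layers)

  dg <- net_forward(dis, fake)
  loss_g_adv <- adversarial_loss(dg$y, TRUE)
  d_fake <- net_backward(dis, dg, adversarial_loss_grad(dg$y, TRUE),
                         accumulate = FALSE)

  # PatchNCE x: keys from enc(x) (taps of fA), queries from enc(fake)
  fC <- net_forward(gen, fake, upto = gen$n_enc, collect_taps = TRUE)
  sx <- multilayer_nce(proj, fA$taps, fC$taps, cfg$nce)
  gx <- multilayer_nce_backward(proj, fA$taps, fC$taps, sx, weight = w$lambda_x)
  d_fake_nce <- net_backward(gen, fC, tap_grads = gx$dst, upto = gen$n_enc)
  if (!is.null(d_fake_nce)) d_fake <- d_fake + d_fake_nce

  # identity PatchNCE y: keys from enc(y) (taps of fB), queries from enc(idt)
  fD <- net_forward(gen, idt, upto = gen$n_enc, collect_taps = TRUE)
  sy <- multilayer_nce(proj, fB$taps, fD$taps, cfg$nce)
  gy <- multilayer_nce_backward(proj, fB$taps, fD$taps, sy, weight = w$lambda_y)
  d_idt <- net_backward(gen, fD, tap_grads = gy$dst, upto = gen$n_enc)

  # full generator backward: x path gets adversarial + NCE-query gradients at
  # the output and NCE-key gradients injected at its encoder taps; the y path
  # gets the identity-NCE gradients likewise
  net_backward(gen, fA, d_fake, tap_grads = gx$src)
  net_backward(gen, fB, d_idt, tap_grads = gy$src)
  adam_step(gen$layers, lr)
  adam_step(proj$layers, lr)

  list(loss_d = loss_d, loss_g_adv = loss_g_adv,
       loss_nce_x = sx$loss, loss_nce_y = sy$loss,
       loss_total = total_objective(loss_g_adv, sx$loss, sy$loss, w))
}
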