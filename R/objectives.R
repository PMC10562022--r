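#' PatchNCE configuration
#'
#' @param temperature softmax temperature of the contrastive loss (> 0).
#' @param n_patches patch locations sampled per tap.
#' @return An object of class `nce_config`.
#' @export
nce_config <- function(temperature = 0.07, n_patches = 256L) {
  stopifnot(is.finite(temperature), temperature > 0, n_patches >= 1L)
  structure(list(temperature = temperature, n_patches = as.integer(n_patches)),
            class = "nce_config")
}

#' Objective weights
#'
#' Weights of the two PatchNCE terms in the total objective; the default is
#' the equally weighted setting `lambda_x = lambda_y = 1`.
#'
#' @param lambda_x weight of the PatchNCE term on the source (CBCT) domain.
#' @param lambda_y weight of the identity PatchNCE term on the target
#'   (FBCT) domain.
#' @return An object of class `objective_weights`.
#' @export
objective_weights <- function(lambda_x = 1, lambda_y = 1) {
  stopifnot(lambda_x >= 0, lambda_y >= 0)
  structure(list(lambda_x = lambda_x, lambda_y = lambda_y),
            class = "objective_weights")
}

#' Least-squares adversarial loss
#'
#' Mean squared deviation of the discriminator's patch scores from the
#' target label (1 for real, 0 for fake) — the least-squares GAN form.
#'
#' @param patch_scores numeric array/matrix of patch scores.
#' @param target_is_real logical; which label the scores are pushed towards.
#' @return Non-negative scalar loss.
#' @export
adversarial_loss <- function(patch_scores, target_is_real) {
  if (any(!is.finite(patch_scores))) stop("non-finite patch scores", call. = FALSE)
  target <- if (isTRUE(target_is_real)) 1 else 0
  mean((patch_scores - target)^2)
}

# gradient of adversarial_loss wrt scores
adversarial_loss_grad <- function(patch_scores, target_is_real) {
  target <- if (isTRUE(target_is_real)) 1 else 0
  2 * (patch_scores - target) / length(patch_scores)
}

#' Patch-wise noise-contrastive (PatchNCE) loss, single query
#'
#' The (N+1)-way classification cross-entropy of selecting the positive
#' patch over N negatives from the same image:
#' `-log( exp(q.p/tau) / (exp(q.p/tau) + sum_n exp(q.v_n/tau)) )`.
#'
#' @param query,positive unit vectors.
#' @param negatives matrix with one unit negative vector per row.
#' @param temperature softmax temperature.
#' @return Non-negative scalar loss.
#' @export
patch_nce_loss <- function(query, positive, negatives, temperature = 0.07) {
  negatives <- rbind(negatives)
  if (any(!is.finite(query)) || any(!is.finite(positive)) || any(!is.finite(negatives)))
    stop("non-finite inputs to patch_nce_loss", call. = FALSE)
  if (sum(query^2) == 0 || sum(positive^2) == 0)
    stop("zero-length vector in patch_nce_loss", call. = FALSE)
  logits <- c(sum(query * positive), as.numeric(negatives %*% query)) / temperature
  m <- max(logits)
  -(logits[1] - m - log(sum(exp(logits - m))))
}

# Batched PatchNCE with diagonal positives: rows of Q are queries, rows of K
# the keys from the other domain at the same locations; off-diagonal keys are
# the within-image negatives. Returns loss and gradients wrt Q and K.
nce_loss_batch <- function(Q, K, temperature) {
  n <- nrow(Q)
  logits <- (Q %*% t(K)) / temperature
  m <- apply(logits, 1, max)
  ex <- exp(logits - m)
  P <- ex / rowSums(ex)
  loss <- -mean(log(pmax(diag(P), 1e-300)))
  dL <- (P - diag(n)) / n
  list(loss = loss,
       dQ = (dL %*% K) / temperature,
       dK = (t(dL) %*% Q) / temperature)
}

# Multi-tap PatchNCE between two images: features of `src` provide keys
# (positives/negatives), features of `dst` provide queries; shared sampled
# locations per tap. Used for both the x-domain term (src = x, dst = G(x))
# and the identity y-domain term (src = y, dst = G(y)).
# Returns the mean loss over taps plus everything needed for backprop.
multilayer_nce <- function(proj, taps_src, taps_dst, cfg) {
  n_tap <- length(taps_src)
  samp <- sample_patches(taps_dst,
                         n_patches = min(cfg$n_patches,
                                         min(vapply(taps_dst, function(f)
                                           dim(f)[1] * dim(f)[2], 0))))
  keys <- sample_patches(taps_src, locations = samp$locations)
  per_tap <- vector("list", n_tap)
  total <- 0
  for (i in seq_len(n_tap)) {
    pq <- proj_forward(proj, i, samp$patches[[i]])
    pk <- proj_forward(proj, i, keys$patches[[i]])
    r <- nce_loss_batch(pq$y, pk$y, cfg$temperature)
    total <- total + r$loss
    per_tap[[i]] <- list(pq = pq, pk = pk, r = r,
                         locs = samp$locations[[i]])
  }
  list(loss = total / n_tap, per_tap = per_tap)
}

# Backward pass of multilayer_nce. `weight` scales the loss. Returns named
# lists of tap gradients (arrays shaped like the feature grids) for the
# src and dst feature stacks; projector gradients are accumulated.
multilayer_nce_backward <- function(proj, taps_src, taps_dst, state, weight = 1) {
  n_tap <- length(state$per_tap)
  gsrc <- vector("list", n_tap); names(gsrc) <- names(taps_src)
  gdst <- vector("list", n_tap); names(gdst) <- names(taps_dst)
  for (i in seq_len(n_tap)) {
    st <- state$per_tap[[i]]
    w <- weight / n_tap
    dpatch_q <- proj_backward(proj, i, st$pq$cache, w * st$r$dQ)
    dpatch_k <- proj_backward(proj, i, st$pk$cache, w * st$r$dK)
    scatter <- function(f, dp) {
      d <- dim(f)
      g <- matrix(0, d[1] * d[2], d[3])
      g[st$locs, ] <- dp
      array(g, d)
    }
    gdst[[i]] <- scatter(taps_dst[[i]], dpatch_q)
    gsrc[[i]] <- scatter(taps_src[[i]], dpatch_k)
  }
  list(src = gsrc, dst = gdst)
}

#' Identity-domain PatchNCE loss
#'
#' The PatchNCE loss applied to a target-domain image: queries come from the
#' encoder features of `G(y)` and positives from those of `y` at shared
#' locations, discouraging the generator from changing images already in the
#' target domain.
#'
#' @param gen generator `cut_network`.
#' @param projector projector `cut_network`.
#' @param y_image `H x W x C` array in `[-1, 1]` from the target domain.
#' @param config an [nce_config()].
#' @param seed optional seed for the patch sampling.
#' @return Non-negative scalar loss.
#' @export
identity_nce_loss <- function(gen, projector, y_image, config = nce_config(),
                              seed = NULL) {
  run <- function() {
    idt <- net_apply(gen, y_image)
    taps_y <- extract_features(gen, y_image)
    taps_i <- extract_features(gen, idt)
    multilayer_nce(projector, taps_y, taps_i, config)$loss
  }
  if (is.null(seed)) run() else with_seed_local(seed, run())
}

#' Total CUT objective
#'
#' The scalar learning objective: adversarial term plus the two weighted
#' PatchNCE terms,
#' `l_gan + lambda_x * l_nce_x + lambda_y * l_nce_y`.
#'
#' @param l_gan adversarial component.
#' @param l_nce_x source-domain PatchNCE component.
#' @param l_nce_y identity (target-domain) PatchNCE component.
#' @param w an [objective_weights()].
#' @return Scalar objective value.
#' @export
total_objective <- function(l_gan, l_nce_x, l_nce_y, w = objective_weights()) {
  stopifnot(is.finite(l_gan), is.finite(l_nce_x), is.finite(l_nce_y))
  l_gan + w$lambda_x * l_nce_x + w$lambda_y * l_nce_y
}
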