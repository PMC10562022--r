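#' Generator specification
#'
#' The ResNet translation generator: a 7x7 convolution stem, two stride-2
#' downsampling convolutions, `n_resblocks` residual blocks at 4x the base
#' width, two stride-2 transposed convolutions back up, and a 7x7 output
#' convolution squashed by tanh. Reflection padding throughout the
#' full-resolution convolutions; instance normalisation without learned
#' affine; biases on every convolution. The default reproduces the standard
#' 9-block, 64-filter architecture with 11,378,179 trainable parameters.
#'
#' @param in_channels,out_channels image channels (3 for the HU codec).
#' @param base_filters stem width (64 for the reference architecture).
#' @param n_resblocks number of residual blocks (9 for the reference).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(in_channels = 3L, out_channels = 3L,
                           base_filters = 64L, n_resblocks = 9L) {
  s <- list(in_channels = as.integer(in_channels),
            out_channels = as.integer(out_channels),
            base_filters = as.integer(base_filters),
            n_resblocks = as.integer(n_resblocks),
            norm = "instance-no-affine", padding = "reflection")
  if (s$base_filters < 1L || s$n_resblocks < 1L || s$in_channels < 1L || s$out_channels < 1L)
    stop("invalid generator spec", call. = FALSE)
  structure(s, class = "generator_spec")
}

#' Discriminator specification
#'
#' The 70x70 patch discriminator: 4x4 convolutions with widths
#' `base_filters * c(1, 2, 4, 8)` and strides 2, 2, 2, 1 followed by a
#' 1-channel 4x4 scoring convolution (stride 1); leaky rectifier slope 0.2;
#' instance normalisation (no affine) on the middle layers. Its output is a
#' spatial map of patch scores, not a scalar. The default has 2,764,737
#' parameters.
#'
#' @param in_channels image channels.
#' @param base_filters first-layer width (64 for the reference).
#' @param n_layers number of stride-2 stages after the first (3 for 70x70
#'   receptive fields).
#' @return An object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(in_channels = 3L, base_filters = 64L, n_layers = 3L) {
  s <- list(in_channels = as.integer(in_channels),
            base_filters = as.integer(base_filters),
            n_layers = as.integer(n_layers), norm = "instance-no-affine")
  if (s$base_filters < 1L || s$n_layers < 1L) stop("invalid discriminator spec", call. = FALSE)
  structure(s, class = "discriminator_spec")
}

#' Projector (patch MLP) specification
#'
#' One two-layer perceptron per encoder tap, mapping tap channels to a
#' common embedding width with a rectifier in between; projected patch
#' vectors are normalised to unit length. The default taps
#' `[0, 4, 8, 12, 16]` with channel widths `[3, 128, 256, 256, 256]` and
#' width 256 give 560,384 parameters.
#'
#' @param tap_layer_ids integer ids naming the generator taps.
#' @param tap_channel_dims channel width of each tap.
#' @param width hidden/output width of each perceptron.
#' @return An object of class `projector_spec`.
#' @export
projector_spec <- function(tap_layer_ids = c(0L, 4L, 8L, 12L, 16L),
                           tap_channel_dims = c(3L, 128L, 256L, 256L, 256L),
                           width = 256L) {
  if (length(tap_layer_ids) != length(tap_channel_dims))
    stop("tap ids and channel dims must have equal length", call. = FALSE)
  structure(list(tap_layer_ids = as.integer(tap_layer_ids),
                 tap_channel_dims = as.integer(tap_channel_dims),
                 width = as.integer(width)),
            class = "projector_spec")
}

#' Default projector spec matching a generator spec
#'
#' Tap widths follow the encoder: the raw input, the two downsampling
#' convolutions (2x and 4x base width) and two residual blocks about one and
#' two thirds of the way through the stack.
#'
#' @param gspec a [generator_spec()].
#' @return A [projector_spec()].
#' @export
projector_spec_for <- function(gspec) {
  f <- gspec$base_filters
  projector_spec(
    tap_layer_ids = c(0L, 4L, 8L, 12L, 16L),
    tap_channel_dims = c(gspec$in_channels, 2L * f, 4L * f, 4L * f, 4L * f),
    width = min(256L, 4L * f)
  )
}

new_network <- function(kind, spec, layers, tap_pos = integer(), seed = NA_integer_,
                        extra = list()) {
  structure(c(list(kind = kind, spec = spec, layers = layers,
                   tap_pos = tap_pos, seed = seed), extra),
            class = "cut_network")
}

#' @export
print.cut_network <- function(x, ...) {
  cat(sprintf("<cut_network:%s> %s parameters\n", x$kind,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Build the translation generator
#'
#' @param spec a [generator_spec()].
#' @param seed optional integer; when given, weight initialisation
#'   (zero-mean Gaussian, sd 0.02) is reproducible.
#' @return A `cut_network` handle with encoder tap positions
#'   `c(0, 4, 8, 12, 16)` (0 denotes the raw input).
#' @export
build_generator <- function(spec = generator_spec(), seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  build <- function() {
    f <- spec$base_filters
    nb <- spec$n_resblocks
    layers <- list(
      layer_conv2d(7, 7, spec$in_channels, f, stride = 1, pad = 3, pad_mode = "reflect"),
      layer_instancenorm(), layer_relu(),
      layer_conv2d(3, 3, f, 2L * f, stride = 2, pad = 1),
      layer_instancenorm(), layer_relu(),
      layer_conv2d(3, 3, 2L * f, 4L * f, stride = 2, pad = 1),
      layer_instancenorm(), layer_relu()
    )
    for (i in seq_len(nb)) layers <- c(layers, list(layer_resblock(4L * f)))
    n_enc <- length(layers)  # encoder ends after the residual stack
    layers <- c(layers, list(
      layer_convtranspose2d(4L * f, 2L * f),
      layer_instancenorm(), layer_relu(),
      layer_convtranspose2d(2L * f, f),
      layer_instancenorm(), layer_relu(),
      layer_conv2d(7, 7, f, spec$out_channels, stride = 1, pad = 3, pad_mode = "reflect"),
      layer_tanh()
    ))
    # taps: input; first down-conv; second down-conv's norm; residual blocks
    # one-third and two-thirds through the stack (blocks 3 and 7 of 9)
    b1 <- max(1L, as.integer(round(nb / 3)))
    b2 <- min(nb, max(b1, as.integer(round(7 * nb / 9))))
    tap_pos <- c(`0` = 0L, `4` = 4L, `8` = 8L, `12` = 9L + b1, `16` = 9L + b2)
    new_network("generator", spec, layers, tap_pos = tap_pos,
                seed = seed %||% NA_integer_, extra = list(n_enc = n_enc))
  }
  if (is.null(seed)) build() else with_seed_local(seed, build())
}

#' Build the patch discriminator
#'
#' @param spec a [discriminator_spec()].
#' @param seed optional integer for reproducible initialisation.
#' @return A `cut_network` handle; its forward pass returns a spatial map of
#'   patch scores.
#' @export
build_discriminator <- function(spec = discriminator_spec(), seed = NULL) {
  stopifnot(inherits(spec, "discriminator_spec"))
  build <- function() {
    f <- spec$base_filters
    layers <- list(layer_conv2d(4, 4, spec$in_channels, f, stride = 2, pad = 1),
                   layer_lrelu())
    mult_prev <- 1L
    for (n in seq_len(spec$n_layers)) {
      mult <- min(2L^n, 8L)
      stride <- if (n < spec$n_layers) 2L else 1L
      layers <- c(layers, list(
        layer_conv2d(4, 4, f * mult_prev, f * mult, stride = stride, pad = 1),
        layer_instancenorm(), layer_lrelu()
      ))
      mult_prev <- mult
    }
    layers <- c(layers, list(layer_conv2d(4, 4, f * mult_prev, 1L, stride = 1, pad = 1)))
    new_network("discriminator", spec, layers, seed = seed %||% NA_integer_)
  }
  if (is.null(seed)) build() else with_seed_local(seed, build())
}

#' Build the multi-layer patch projector
#'
#' @param spec a [projector_spec()].
#' @param seed optional integer for reproducible initialisation.
#' @return A `cut_network` handle whose `layers` hold one two-layer
#'   perceptron per tap.
#' @export
build_projector <- function(spec = projector_spec(), seed = NULL) {
  stopifnot(inherits(spec, "projector_spec"))
  build <- function() {
    mlps <- lapply(spec$tap_channel_dims, function(d) {
      list(layer_linear(d, spec$width), layer_relu(), layer_linear(spec$width, spec$width))
    })
    layers <- do.call(c, mlps)
    new_network("projector", spec, layers,
                seed = seed %||% NA_integer_,
                extra = list(n_taps = length(spec$tap_channel_dims)))
  }
  if (is.null(seed)) build() else with_seed_local(seed, build())
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars in a built network; deterministic and a
#' pure function of the spec. The reference configuration gives 11,378,179
#' (generator), 2,764,737 (discriminator) and 560,384 (projector); their sum,
#' 14,703,300, is the CUT total, while the cycle-consistent accounting of two
#' generators plus two discriminators gives 28,285,832.
#'
#' @param net a `cut_network` handle.
#' @return Non-negative integer count.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "cut_network"))
  layers_n_params(net$layers)
}

# ---- whole-network forward / backward --------------------------------------

net_forward <- function(net, x, upto = length(net$layers), collect_taps = FALSE) {
  caches <- vector("list", upto)
  taps <- if (collect_taps && length(net$tap_pos)) {
    t0 <- net$tap_pos == 0L
    out <- vector("list", sum(net$tap_pos <= upto))
    names(out) <- names(net$tap_pos)[net$tap_pos <= upto]
    if (any(t0)) out[[which(t0)]] <- x
    out
  } else NULL
  h <- x
  for (i in seq_len(upto)) {
    r <- layer_forward(net$layers[[i]], h)
    h <- r$y
    caches[[i]] <- r$cache
    if (!is.null(taps)) {
      hit <- names(net$tap_pos)[net$tap_pos == i]
      for (nm in hit) taps[[nm]] <- h
    }
  }
  list(y = h, caches = caches, taps = taps)
}

# Backward from layer `upto` down to the input. `dy` is the gradient at the
# output of layer `upto` (NULL for a zero start); `tap_grads` is a named list
# of gradients injected at tap positions (name "0" applies to the input and
# is added to the returned input gradient).
net_backward <- function(net, fw, dy = NULL, tap_grads = NULL,
                         upto = length(fw$caches), accumulate = TRUE) {
  g <- dy
  inject <- function(g, pos) {
    if (is.null(tap_grads)) return(g)
    hit <- names(net$tap_pos)[net$tap_pos == pos]
    for (nm in hit) {
      if (!is.null(tap_grads[[nm]])) {
        g <- if (is.null(g)) tap_grads[[nm]] else g + tap_grads[[nm]]
      }
    }
    g
  }
  g <- inject(g, upto)
  for (i in rev(seq_len(upto))) {
    if (is.null(g)) {
      g <- inject(NULL, i - 1L)
      next
    }
    g <- layer_backward(net$layers[[i]], fw$caches[[i]], g, accumulate = accumulate)
    if (i > 1L) g <- inject(g, i - 1L)
  }
  g <- inject(g, 0L)
  g
}

#' Run a network forward on one image
#'
#' @param net a `cut_network` handle (generator or discriminator).
#' @param x numeric array `H x W x C` in the network value domain `[-1, 1]`.
#' @return The output array.
#' @export
net_apply <- function(net, x) {
  stopifnot(inherits(net, "cut_network"))
  net_forward(net, x)$y
}

#' Extract encoder feature taps
#'
#' Runs the generator's encoder (stem, downsampling stack and residual
#' blocks) and returns the activations at the requested taps. Tap `0` is the
#' raw input itself; deeper taps have coarser spatial grids, so each feature
#' location corresponds to a larger input patch.
#'
#' @param gen a generator `cut_network`.
#' @param image numeric array `H x W x C` in `[-1, 1]`.
#' @param taps integer tap ids (default: all taps of the generator).
#' @return Named list of `h x w x c` activation arrays, one per tap.
#' @export
extract_features <- function(gen, image, taps = NULL) {
  stopifnot(inherits(gen, "cut_network"), gen$kind == "generator")
  ids <- names(gen$tap_pos)
  taps <- if (is.null(taps)) ids else as.character(taps)
  if (!all(taps %in% ids))
    stop("unknown tap id(s): ", paste(setdiff(taps, ids), collapse = ", "), call. = FALSE)
  fw <- net_forward(gen, image, upto = gen$n_enc, collect_taps = TRUE)
  fw$taps[taps]
}

#' Sample patch locations from per-tap feature grids
#'
#' Draws `n_patches` spatial locations uniformly without replacement per tap
#' and gathers the feature vectors at those locations. When `locations` are
#' supplied (to pair queries from the translated image with positives from
#' the input at identical positions) they are reused exactly.
#'
#' @param features named list of `h x w x c` arrays (one per tap).
#' @param n_patches locations per tap; capped at the tap's grid size must
#'   not exceed it.
#' @param locations optional named list of integer location vectors to reuse.
#' @param seed optional integer seed for reproducible sampling.
#' @return A list with `patches` (per-tap `n x c` matrices) and `locations`
#'   (per-tap integer vectors into the flattened `h*w` grid).
#' @export
sample_patches <- function(features, n_patches = 256L, locations = NULL, seed = NULL) {
  draw <- function() {
    locs <- vector("list", length(features))
    names(locs) <- names(features)
    patches <- locs
    for (nm in names(features)) {
      f <- features[[nm]]
      d <- dim(f)
      npix <- d[1] * d[2]
      li <- if (!is.null(locations)) {
        locations[[nm]]
      } else {
        if (n_patches > npix)
          stop("n_patches exceeds the ", npix, "-location grid of tap ", nm, call. = FALSE)
        sample.int(npix, n_patches)
      }
      locs[[nm]] <- li
      patches[[nm]] <- matrix(f, npix, d[3])[li, , drop = FALSE]
    }
    list(patches = patches, locations = locs)
  }
  if (is.null(seed)) draw() else with_seed_local(seed, draw())
}

# ---- projector application --------------------------------------------------

# forward patches [n, d] through tap t's MLP + L2 normalisation
proj_forward <- function(proj, tap_index, patches) {
  base <- (tap_index - 1L) * 3L
  f1 <- layer_forward(proj$layers[[base + 1L]], patches)
  f2 <- layer_forward(proj$layers[[base + 2L]], f1$y)
  f3 <- layer_forward(proj$layers[[base + 3L]], f2$y)
  r <- sqrt(rowSums(f3$y^2))
  r <- pmax(r, 1e-12)
  list(y = f3$y / r, cache = list(f1 = f1, f2 = f2, f3 = f3, z = f3$y, r = r))
}

proj_backward <- function(proj, tap_index, cache, dy, accumulate = TRUE) {
  base <- (tap_index - 1L) * 3L
  yn <- cache$z / cache$r
  dz <- (dy - yn * rowSums(dy * yn)) / cache$r
  g <- layer_backward(proj$layers[[base + 3L]], cache$f3$cache, dz, accumulate)
  g <- layer_backward(proj$layers[[base + 2L]], cache$f2$cache, g, accumulate)
  layer_backward(proj$layers[[base + 1L]], cache$f1$cache, g, accumulate)
}

#' Project sampled patches to the contrastive embedding
#'
#' @param proj a projector `cut_network`.
#' @param patches per-tap list of `n x c` matrices from [sample_patches()].
#' @return Per-tap list of unit-row-norm `n x width` matrices.
#' @export
project_patches <- function(proj, patches) {
  stopifnot(inherits(proj, "cut_network"), proj$kind == "projector")
  out <- vector("list", length(patches))
  names(out) <- names(patches)
  for (i in seq_along(patches)) out[[i]] <- proj_forward(proj, i, patches[[i]])$y
  out
}

# ---- checkpoints ------------------------------------------------------------

#' Save networks to a checkpoint file
#'
#' Stores weights, specs and seeds; [load_checkpoint()] validates spec
#' equality before restoring weights into freshly built networks.
#'
#' @param nets named list of `cut_network` handles.
#' @param path output file.
#' @param meta optional list of run metadata (config, epoch, losses).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(nets, path, meta = list()) {
  payload <- list(
    meta = meta,
    nets = lapply(nets, function(n) list(
      kind = n$kind, spec = n$spec, seed = n$seed,
      params = layers_get_params(n$layers)
    ))
  )
  saveRDS(payload, path)
  invisible(path)
}

#' Load networks from a checkpoint file
#'
#' @param path checkpoint written by [save_checkpoint()].
#' @return A list with `nets` (named list of rebuilt handles) and `meta`.
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  nets <- lapply(payload$nets, function(rec) {
    net <- switch(rec$kind,
      generator = build_generator(rec$spec),
      discriminator = build_discriminator(rec$spec),
      projector = build_projector(rec$spec),
      stop("unknown network kind in checkpoint: ", rec$kind)
    )
    if (!identical(unclass(net$spec), unclass(rec$spec)))
      stop("checkpoint spec does not match rebuilt network", call. = FALSE)
    layers_set_params(net$layers, rec$params)
    net$seed <- rec$seed
    net
  })
  list(nets = nets, meta = payload$meta)
}
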