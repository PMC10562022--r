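# Minimal CNN layer framework with explicit forward/backward passes.
# Feature maps are numeric arrays [H, W, C]; patch-vector sets are matrices
# [n, d]. Layers are environments holding parameters, accumulated gradients
# and Adam state; forward passes return an explicit cache so several
# activations of the same network can coexist within one training step.

new_layer <- function(type, params = list(), cfg = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- params
  e$grads <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  e$cfg <- cfg
  class(e) <- "cutct_layer"
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gauss_init <- function(dims, sd = 0.02) array(stats::rnorm(prod(dims), sd = sd), dims)

layer_conv2d <- function(kh, kw, cin, cout, stride = 1L, pad = 0L,
                         pad_mode = c("zero", "reflect"), init_sd = 0.02) {
  pad_mode <- match.arg(pad_mode)
  new_layer("conv2d",
            params = list(W = gauss_init(c(kh, kw, cin, cout), init_sd),
                          b = numeric(cout)),
            cfg = list(kh = kh, kw = kw, cin = cin, cout = cout,
                       stride = as.integer(stride), pad = as.integer(pad),
                       pad_mode = pad_mode))
}

layer_convtranspose2d <- function(cin, cout, init_sd = 0.02) {
  # fixed geometry: kernel 3, stride 2, pad 1, output padding 1 (doubles H, W)
  new_layer("convt2d",
            params = list(W = gauss_init(c(3, 3, cout, cin), init_sd),
                          b = numeric(cout)),
            cfg = list(cin = cin, cout = cout))
}

layer_instancenorm <- function(eps = 1e-5) new_layer("inorm", cfg = list(eps = eps))
layer_relu <- function() new_layer("relu")
layer_lrelu <- function(slope = 0.2) new_layer("lrelu", cfg = list(slope = slope))
layer_tanh <- function() new_layer("tanh")

layer_linear <- function(din, dout, init_sd = 0.02) {
  new_layer("linear",
            params = list(W = gauss_init(c(din, dout), init_sd), b = numeric(dout)),
            cfg = list(din = din, dout = dout))
}

layer_resblock <- function(ch, init_sd = 0.02) {
  subs <- list(
    layer_conv2d(3, 3, ch, ch, stride = 1, pad = 1, pad_mode = "reflect", init_sd = init_sd),
    layer_instancenorm(),
    layer_relu(),
    layer_conv2d(3, 3, ch, ch, stride = 1, pad = 1, pad_mode = "reflect", init_sd = init_sd),
    layer_instancenorm()
  )
  new_layer("resblock", cfg = list(layers = subs))
}

conv_out_hw <- function(hw, k, stride, pad) (hw + 2L * pad - k) %/% stride + 1L

# ---- forward ----------------------------------------------------------------

layer_forward <- function(layer, x) {
  cfg <- layer$cfg
  switch(layer$type,
    conv2d = {
      reflect <- cfg$pad_mode == "reflect"
      padc <- if (reflect) 0L else cfg$pad
      oh <- conv_out_hw(dim(x)[1] + if (reflect) 2L * cfg$pad else 0L,
                        cfg$kh, cfg$stride, padc)
      if (oh < 1L) stop("input spatial size too small for this network", call. = FALSE)
      K <- matrix(layer$params$W, cfg$kh * cfg$kw * cfg$cin, cfg$cout)
      y <- conv2d_fwd_cpp(x, K, layer$params$b, cfg$kh, cfg$kw, cfg$stride,
                          cfg$pad, reflect)
      list(y = y, cache = list(x = x))
    },
    convt2d = {
      y <- convt2d_fwd_cpp(x, matrix(layer$params$W, 9L * cfg$cout, cfg$cin),
                           layer$params$b)
      list(y = y, cache = list(x = x))
    },
    inorm = {
      r <- inorm_fwd_cpp(x, cfg$eps)
      list(y = r$y, cache = list(xhat = r$y, istd = r$istd))
    },
    relu = {
      m <- x > 0
      list(y = x * m, cache = list(m = m))
    },
    lrelu = {
      neg <- x < 0
      y <- x
      y[neg] <- cfg$slope * x[neg]
      list(y = y, cache = list(neg = neg))
    },
    tanh = {
      y <- tanh(x)
      list(y = y, cache = list(y = y))
    },
    linear = {
      y <- x %*% layer$params$W
      y <- sweep(y, 2, layer$params$b, "+")
      list(y = y, cache = list(x = x))
    },
    resblock = {
      h <- x
      caches <- vector("list", length(cfg$layers))
      for (i in seq_along(cfg$layers)) {
        r <- layer_forward(cfg$layers[[i]], h)
        h <- r$y
        caches[[i]] <- r$cache
      }
      list(y = x + h, cache = list(sub = caches))
    },
    stop("unknown layer type: ", layer$type)
  )
}

# ---- backward ---------------------------------------------------------------
# Accumulates parameter gradients into layer$grads unless accumulate = FALSE;
# returns the gradient with respect to the layer input.

layer_backward <- function(layer, cache, dy, accumulate = TRUE) {
  cfg <- layer$cfg
  switch(layer$type,
    conv2d = {
      K <- matrix(layer$params$W, cfg$kh * cfg$kw * cfg$cin, cfg$cout)
      r <- conv2d_bwd_cpp(dy, cache$x, K, cfg$kh, cfg$kw, cfg$stride, cfg$pad,
                          cfg$pad_mode == "reflect", accumulate)
      if (accumulate) {
        layer$grads$W <- layer$grads$W + array(r$dW, dim(layer$params$W))
        layer$grads$b <- layer$grads$b + as.numeric(r$db)
      }
      r$dx
    },
    convt2d = {
      r <- convt2d_bwd_cpp(dy, cache$x,
                           matrix(layer$params$W, 9L * cfg$cout, cfg$cin),
                           accumulate)
      if (accumulate) {
        layer$grads$W <- layer$grads$W + array(r$dW, dim(layer$params$W))
        layer$grads$b <- layer$grads$b + as.numeric(r$db)
      }
      r$dx
    },
    inorm = inorm_bwd_cpp(dy, cache$xhat, cache$istd),
    relu = dy * cache$m,
    lrelu = {
      g <- dy
      g[cache$neg] <- cfg$slope * dy[cache$neg]
      g
    },
    tanh = dy * (1 - cache$y^2),
    linear = {
      if (accumulate) {
        layer$grads$W <- layer$grads$W + crossprod(cache$x, dy)
        layer$grads$b <- layer$grads$b + colSums(dy)
      }
      dy %*% t(layer$params$W)
    },
    resblock = {
      g <- dy
      for (i in rev(seq_along(cfg$layers))) {
        g <- layer_backward(cfg$layers[[i]], cache$sub[[i]], g, accumulate)
      }
      dy + g
    },
    stop("unknown layer type: ", layer$type)
  )
}

# ---- parameter utilities ----------------------------------------------------

layer_children <- function(layer) {
  if (layer$type == "resblock") layer$cfg$layers else list()
}

walk_layers <- function(layers, f) {
  for (l in layers) {
    f(l)
    kids <- layer_children(l)
    if (length(kids)) walk_layers(kids, f)
  }
  invisible(NULL)
}

layers_n_params <- function(layers) {
  n <- 0
  walk_layers(layers, function(l) {
    n <<- n + sum(vapply(l$params, length, 0L))
  })
  n
}

zero_grads <- function(layers) {
  walk_layers(layers, function(l) {
    for (nm in names(l$grads)) l$grads[[nm]][] <- 0
  })
}

# Adam with momentum parameters (beta1, beta2); state lives on the layer.
adam_step <- function(layers, lr, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  walk_layers(layers, function(l) {
    if (!length(l$params)) return(invisible(NULL))
    if (is.null(l$adam_t)) {
      l$adam_t <- 0L
      l$adam_m <- lapply(l$grads, function(g) g * 0)
      l$adam_v <- lapply(l$grads, function(g) g * 0)
    }
    l$adam_t <- l$adam_t + 1L
    bc1 <- 1 - beta1^l$adam_t
    bc2 <- 1 - beta2^l$adam_t
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      l$adam_m[[nm]] <- beta1 * l$adam_m[[nm]] + (1 - beta1) * g
      l$adam_v[[nm]] <- beta2 * l$adam_v[[nm]] + (1 - beta2) * g^2
      step <- lr * (l$adam_m[[nm]] / bc1) / (sqrt(l$adam_v[[nm]] / bc2) + eps)
      l$params[[nm]] <- l$params[[nm]] - step
    }
  })
}

# flat list of parameter arrays (for serialization); stable walk order
layers_get_params <- function(layers) {
  out <- list()
  walk_layers(layers, function(l) out[[length(out) + 1L]] <<- l$params)
  out
}

layers_set_params <- function(layers, flat) {
  i <- 0L
  walk_layers(layers, function(l) {
    i <<- i + 1L
    stopifnot(identical(lapply(l$params, dim), lapply(flat[[i]], dim)))
    l$params <- flat[[i]]
  })
  invisible(NULL)
}
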