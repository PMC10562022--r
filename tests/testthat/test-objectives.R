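test_that("least-squares adversarial loss matches its closed forms", {
  expect_equal(adversarial_loss(array(1, c(4, 4, 1)), TRUE), 0)
  expect_equal(adversarial_loss(array(0, c(4, 4, 1)), TRUE), 1)
  expect_equal(adversarial_loss(array(0.5, c(4, 4, 1)), TRUE), 0.25)
  expect_equal(adversarial_loss(array(0.5, c(4, 4, 1)), FALSE), 0.25)
  expect_error(adversarial_loss(c(1, NaN), TRUE), "finite")
})

test_that("PatchNCE reduces to log 2 in the symmetric two-way case", {
  # q.p == q.v for a single negative: uniform 2-way choice at any temperature
  q <- c(1, 0); p <- c(0, 1); v <- matrix(c(0, 1), 1)
  for (tau in c(0.07, 0.5, 1, 5)) {
    expect_equal(patch_nce_loss(q, p, v, tau), log(2), tolerance = 1e-12)
  }
})

test_that("PatchNCE at similarity 1 vs an orthogonal negative, tau = 1", {
  q <- c(1, 0)
  val <- patch_nce_loss(q, q, matrix(c(0, 1), 1), temperature = 1)
  expect_equal(val, -log(exp(1) / (exp(1) + 1)), tolerance = 1e-12)
  expect_equal(val, 0.3132617, tolerance = 1e-6)
})

test_that("PatchNCE agrees with a brute-force softmax cross-entropy oracle", {
  oracle <- function(q, p, negs, tau) {
    sims <- c(sum(q * p), apply(negs, 1, function(v) sum(q * v)))
    probs <- exp(sims / tau) / sum(exp(sims / tau))
    -log(probs[1])
  }
  set.seed(31)
  for (i in 1:30) {
    d <- sample(2:8, 1)
    unit <- function() { v <- rnorm(d); v / sqrt(sum(v^2)) }
    q <- unit(); p <- unit()
    negs <- t(replicate(sample(1:6, 1), unit()))
    tau <- runif(1, 0.05, 2)
    expect_equal(patch_nce_loss(q, p, negs, tau), oracle(q, p, negs, tau),
                 tolerance = 1e-10)
  }
})

test_that("uniform similarities give log(N+1) for any temperature", {
  d <- 6
  q <- rep(1 / sqrt(d), d)
  for (N in c(1, 3, 9)) {
    negs <- matrix(rep(q, N), N, byrow = TRUE)
    for (tau in c(0.07, 1)) {
      expect_equal(patch_nce_loss(q, q, negs, tau), log(N + 1), tolerance = 1e-12)
    }
  }
})

test_that("loss strictly decreases as query-positive similarity grows", {
  negs <- matrix(c(0, 1, 0, 0, 0, 1), 2, 3, byrow = TRUE)
  sims <- seq(-0.9, 0.9, by = 0.2)
  losses <- vapply(sims, function(s) {
    p <- c(s, sqrt(1 - s^2), 0)
    patch_nce_loss(c(1, 0, 0), p, negs, 0.5)
  }, 0)
  expect_true(all(diff(losses) < 0))
})

test_that("batched NCE matches the single-query formula and its gradients", {
  set.seed(32)
  n <- 5; d <- 4
  unit_rows <- function(m) m / sqrt(rowSums(m^2))
  Q <- unit_rows(matrix(rnorm(n * d), n))
  K <- unit_rows(matrix(rnorm(n * d), n))
  tau <- 0.3
  got <- cutct:::nce_loss_batch(Q, K, tau)
  want <- mean(vapply(seq_len(n), function(i)
    patch_nce_loss(Q[i, ], K[i, ], K[-i, , drop = FALSE], tau), 0))
  expect_equal(got$loss, want, tolerance = 1e-12)
  # finite-difference check of dQ and dK
  eps <- 1e-6
  for (probe in list(c(2, 3), c(5, 1))) {
    i <- probe[1]; j <- probe[2]
    Qp <- Q; Qp[i, j] <- Q[i, j] + eps
    Qm <- Q; Qm[i, j] <- Q[i, j] - eps
    num <- (cutct:::nce_loss_batch(Qp, K, tau)$loss -
              cutct:::nce_loss_batch(Qm, K, tau)$loss) / (2 * eps)
    expect_equal(got$dQ[i, j], num, tolerance = 1e-5)
    Kp <- K; Kp[i, j] <- K[i, j] + eps
    Km <- K; Km[i, j] <- K[i, j] - eps
    num_k <- (cutct:::nce_loss_batch(Q, Kp, tau)$loss -
                cutct:::nce_loss_batch(Q, Km, tau)$loss) / (2 * eps)
    expect_equal(got$dK[i, j], num_k, tolerance = 1e-5)
  }
})

test_that("identity NCE is non-negative, seed-stable, and reduces for identity G", {
  gs <- generator_spec(base_filters = 8, n_resblocks = 1)
  gen <- build_generator(gs, seed = 11)
  proj <- build_projector(projector_spec_for(gs), seed = 11)
  y <- array(runif(32 * 32 * 3, -1, 1), c(32, 32, 3))
  cfgn <- nce_config(n_patches = 16)
  l1 <- identity_nce_loss(gen, proj, y, cfgn, seed = 5)
  l2 <- identity_nce_loss(gen, proj, y, cfgn, seed = 5)
  expect_identical(l1, l2)
  expect_gte(l1, 0)
  # for an exact identity generator the queries equal the positives: the loss
  # collapses to the q = p PatchNCE at every location
  gid <- identity_generator()
  pid <- build_projector(projector_spec(tap_layer_ids = 0L, tap_channel_dims = 3L,
                                        width = 16L), seed = 12)
  l_id <- identity_nce_loss(gid, pid, y, cfgn, seed = 5)
  f <- list(`0` = y)
  s <- cutct:::with_seed_local(5, {
    samp <- sample_patches(f, n_patches = 16)
    z <- project_patches(pid, samp$patches)[[1]]
    mean(vapply(seq_len(nrow(z)), function(i)
      patch_nce_loss(z[i, ], z[i, ], z[-i, , drop = FALSE], cfgn$temperature), 0))
  })
  expect_equal(l_id, s, tolerance = 1e-12)
})

test_that("the total objective is the stated weighted sum and is linear", {
  expect_equal(total_objective(1, 2, 3, objective_weights(1, 1)), 6)
  expect_equal(total_objective(1, 2, 3, objective_weights(0, 0)), 1)
  expect_equal(total_objective(0, 0, 0), 0)
  w <- objective_weights(0.5, 2)
  a <- total_objective(1, 2, 3, w)
  b <- total_objective(10, 20, 30, w)
  expect_equal(total_objective(11, 22, 33, w), a + b)
})
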