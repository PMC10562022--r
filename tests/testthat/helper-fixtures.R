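# Shared fixtures: everything is generated in code at test time.

tiny_volume <- function(values, spacing = c(1, 1, 1)) {
  ct_volume(array(values, c(2, 2, 2)), spacing_mm = spacing)
}

# small phantom used across preprocessing and simulation tests
small_spec <- function() phantom_spec(dims = c(32L, 32L, 8L))

full_mask <- function(vol) body_mask(array(1L, dim(vol$voxels)), vol$spacing_mm)

# an "identity" generator: a network with no layers maps x to x exactly
identity_generator <- function() {
  g <- cutct:::new_network("generator", generator_spec(), list(),
                           tap_pos = c(`0` = 0L), extra = list(n_enc = 0L))
  g
}

# Brute-force Otsu oracle: for every candidate interior bin edge, split the
# histogram classes explicitly and compute omega0*omega1*(mu0-mu1)^2 over
# bin midpoints; ties go to the smallest threshold.
otsu_bruteforce <- function(values, n_bins = 256L) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  bin <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(bin, n_bins)
  best <- -Inf
  best_t <- NA_real_
  for (t in seq_len(n_bins - 1L)) {     # class 0 = bins 1..t, threshold edges[t+1]
    n0 <- sum(counts[1:t])
    n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    w0 <- n0 / sum(counts); w1 <- 1 - w0
    mu0 <- sum(counts[1:t] * mids[1:t]) / n0
    mu1 <- sum(counts[(t + 1):n_bins] * mids[(t + 1):n_bins]) / n1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; best_t <- edges[t + 1L] }
  }
  list(threshold = best_t, between_class_variance = best)
}
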