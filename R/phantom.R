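#' Pelvic phantom specification
#'
#' Describes a simplified pelvic cross-section built from ellipse composites:
#' an elliptical body (fat background) with per-slice jitter of its axes, an
#' interior muscle compartment, a bladder, two femoral heads and a sacral arc
#' (cortical shell with trabecular core), an optional set of prostate
#' fiducial seeds, and a treatment couch slab disconnected from the body by
#' an air gap. Every tissue is painted at a single nominal HU value and the
#' matching label map is returned alongside, so the phantom provides exact
#' ground truth for masking, encoding and translation.
#'
#' @param dims integer triple: grid size (x, y, z). Default `c(64, 64, 16)`.
#' @param spacing_mm voxel spacing in mm. Default `c(4, 4, 8)` gives a
#'   256 x 256 mm field of view, pelvis-like at this coarse grid.
#' @param hu named tissue HU table.
#' @param body_axes_frac body semi-axes as fractions of the half field of view.
#' @param jitter_frac per-slice relative jitter of the body semi-axes.
#' @param n_fiducials_range inclusive range for the number of fiducial seeds.
#' @param fiducial_radius_range inclusive voxel-radius range for seeds.
#' @param couch_hu,couch_gap_vox couch slab HU and minimum air gap (voxels)
#'   between couch and body.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(64L, 64L, 16L),
                         spacing_mm = c(4, 4, 8),
                         hu = c(air = -1000, fat = -100, muscle = 40,
                                bladder = 0, trabecular = 200,
                                cortical = 700, fiducial = 3000),
                         body_axes_frac = c(0.80, 0.62),
                         jitter_frac = 0.04,
                         n_fiducials_range = c(0L, 3L),
                         fiducial_radius_range = c(1L, 3L),
                         couch_hu = 150,
                         couch_gap_vox = 2L) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 8L))
  structure(
    list(dims = dims, spacing_mm = as.numeric(spacing_mm), hu = hu,
         body_axes_frac = body_axes_frac, jitter_frac = jitter_frac,
         n_fiducials_range = as.integer(n_fiducials_range),
         fiducial_radius_range = as.integer(fiducial_radius_range),
         couch_hu = couch_hu, couch_gap_vox = as.integer(couch_gap_vox)),
    class = "phantom_spec"
  )
}

#' Tissue label codes used by [make_phantom()]
#' @return Named integer vector mapping tissue names to label values.
#' @export
phantom_labels <- function() {
  c(air = 0L, fat = 1L, muscle = 2L, bladder = 3L, trabecular = 4L,
    cortical = 5L, fiducial = 6L, couch = 7L)
}

#' Generate a clean pelvic phantom
#'
#' Deterministic given `seed`. Returns the HU volume together with its tissue
#' label map; each voxel's HU equals its label's table entry.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed for the per-phantom geometry.
#' @return A list with elements `volume` (a [ct_volume]) and `labels`
#'   (integer 3-D array of [phantom_labels()] codes).
#' @export
make_phantom <- function(spec = phantom_spec(), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  hu <- spec$hu
  lab_code <- phantom_labels()
  with_seed_local(seed, {
    nx <- d[1]; ny <- d[2]; nz <- d[3]
    cx <- (nx + 1) / 2
    # body centre sits slightly posterior (towards the couch at high y)
    cy <- ny * 0.52
    xg <- matrix(seq_len(nx), nx, ny)
    yg <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
    labs <- array(lab_code[["air"]], d)

    a0 <- spec$body_axes_frac[1] * nx / 2
    b0 <- spec$body_axes_frac[2] * ny / 2
    jit <- 1 + spec$jitter_frac * stats::rnorm(nz)
    n_fid <- sample(seq(spec$n_fiducials_range[1], spec$n_fiducials_range[2]), 1L)
    fid <- if (n_fid > 0) {
      data.frame(
        x = cx + stats::runif(n_fid, -0.08, 0.08) * nx,
        y = cy + stats::runif(n_fid, -0.02, 0.06) * ny,
        z = sample(seq(max(1L, round(nz * 0.3)), min(nz, round(nz * 0.7))), n_fid, replace = TRUE),
        r = sample(seq(spec$fiducial_radius_range[1], spec$fiducial_radius_range[2]),
                   n_fid, replace = TRUE)
      )
    } else NULL

    inside <- function(cxx, cyy, a, b) ((xg - cxx) / a)^2 + ((yg - cyy) / b)^2 <= 1
    for (k in seq_len(nz)) {
      a <- a0 * jit[k]; b <- b0 * jit[k]
      sl <- matrix(lab_code[["air"]], nx, ny)
      sl[inside(cx, cy, a, b)] <- lab_code[["fat"]]
      sl[inside(cx, cy, 0.80 * a, 0.78 * b)] <- lab_code[["muscle"]]
      # bladder, anterior midline (low y)
      sl[inside(cx, cy - 0.38 * b, 0.30 * a, 0.26 * b)] <- lab_code[["bladder"]]
      # femoral heads: cortical shell with trabecular core
      for (s in c(-1, 1)) {
        fx <- cx + s * 0.52 * a
        sl[inside(fx, cy, 0.18 * a, 0.22 * b)] <- lab_code[["cortical"]]
        sl[inside(fx, cy, 0.11 * a, 0.13 * b)] <- lab_code[["trabecular"]]
      }
      # sacral arc, posterior midline (high y)
      sac <- inside(cx, cy + 0.52 * b, 0.30 * a, 0.22 * b) &
        !inside(cx, cy + 0.56 * b, 0.20 * a, 0.13 * b)
      sl[sac] <- lab_code[["cortical"]]
      labs[, , k] <- sl
    }
    # prostate fiducials (painted after tissues so they stay visible)
    if (!is.null(fid)) {
      for (i in seq_len(nrow(fid))) {
        zmask <- inside(fid$x[i], fid$y[i], fid$r[i] + 0.4, fid$r[i] + 0.4)
        sl <- labs[, , fid$z[i]]
        sl[zmask & sl %in% c(lab_code[["muscle"]], lab_code[["bladder"]])] <-
          lab_code[["fiducial"]]
        labs[, , fid$z[i]] <- sl
      }
    }
    # couch: flat slab below the body (high y), separated by an air gap
    ymax_body <- max(which(apply(labs != lab_code[["air"]], 2, any)))
    y0 <- min(ny - 1L, ymax_body + spec$couch_gap_vox + 1L)
    couch_rows <- y0:min(ny, y0 + max(2L, round(ny * 0.05)))
    couch_cols <- round(nx * 0.15):round(nx * 0.85)
    labs[couch_cols, couch_rows, ] <- lab_code[["couch"]]

    hu_of <- c(hu, couch = spec$couch_hu)
    name_by_code <- names(lab_code)[order(lab_code)]
    vox <- array(hu_of[name_by_code][labs + 1L], d)
    list(volume = clip_hu(ct_volume(vox, spacing_mm = spec$spacing_mm)),
         labels = labs)
  })
}

#' CBCT degradation parameters
#'
#' Phenomenological cone-beam degradations applied to a clean phantom, in
#' order: multiplicative low-order shading/cupping of the attenuation-like
#' quantity HU + 1000, additive scatter-like leakage of a Gaussian-blurred
#' copy, white HU noise, a global HU offset; the result is clipped to the
#' calibrated range. All-zero parameters give the identity.
#'
#' @param shading_amp peak relative amplitude of the radial cupping field
#'   (0.08 = +/-8 percent).
#' @param scatter_fraction fraction of the signal replaced by its blurred copy.
#' @param blur_sigma_mm Gaussian sigma of the scatter blur, in mm.
#' @param noise_sd additive white noise standard deviation, HU.
#' @param offset_hu global HU bias.
#' @param streaks add a few low-amplitude sinusoidal streak bands.
#' @param seed integer seed for the noise field.
#' @return An object of class `degrade_params`.
#' @export
degrade_params <- function(shading_amp = 0.08, scatter_fraction = 0.08,
                           blur_sigma_mm = 12, noise_sd = 10, offset_hu = 30,
                           streaks = FALSE, seed = 1L) {
  p <- list(shading_amp = shading_amp, scatter_fraction = scatter_fraction,
            blur_sigma_mm = blur_sigma_mm, noise_sd = noise_sd,
            offset_hu = offset_hu, streaks = isTRUE(streaks), seed = as.integer(seed))
  stopifnot(all(vapply(p[1:5], function(v) is.finite(v) && length(v) == 1L, TRUE)))
  structure(p, class = "degrade_params")
}

#' Degrade a clean volume into a CBCT-like volume
#'
#' @param vol a clean [ct_volume].
#' @param p a [degrade_params()].
#' @return A degraded [ct_volume] on the same grid.
#' @export
degrade_to_cbct <- function(vol, p = degrade_params()) {
  stopifnot(inherits(vol, "ct_volume"), inherits(p, "degrade_params"))
  d <- dim(vol$voxels)
  mu <- vol$voxels + 1000  # attenuation-like, >= 0 for tissue
  with_seed_local(p$seed, {
    if (p$shading_amp != 0) {
      # radial cupping: centre suppressed, periphery mildly enhanced
      r2 <- function(n) ((seq_len(n) - (n + 1) / 2) / (n / 2))^2
      fld <- outer(r2(d[1]), r2(d[2]), "+")
      fld <- 1 + p$shading_amp * (pmin(fld, 1) - 0.5) * 2  # in [1-a, 1+a]
      mu <- mu * array(rep(fld, d[3]), d)
    }
    if (p$scatter_fraction != 0) {
      blur <- gauss_blur3(mu, p$blur_sigma_mm / vol$spacing_mm)
      mu <- (1 - p$scatter_fraction) * mu + p$scatter_fraction * blur
    }
    if (p$streaks) {
      ph <- stats::runif(3, 0, 2 * pi)
      fr <- sample(3:7, 3, replace = TRUE)
      st <- Reduce(`+`, lapply(1:3, function(i)
        sin(2 * pi * fr[i] * seq_len(d[1]) / d[1] + ph[i])))
      mu <- mu + array(rep(10 * st, times = d[2] * d[3]), d)
    }
    if (p$noise_sd != 0) {
      mu <- mu + array(stats::rnorm(prod(d), sd = p$noise_sd), d)
    }
  })
  out <- mu - 1000 + p$offset_hu
  vol$voxels <- out
  clip_hu(vol)
}

# separable Gaussian blur along each axis; sigma in voxels per axis
gauss_blur3 <- function(x, sigma_vox) {
  d <- dim(x)
  kernel1 <- function(s) {
    if (s <= 0) return(1)
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k / sum(k)
  }
  band <- function(n, k) {
    r <- (length(k) - 1L) / 2L
    B <- matrix(0, n, n)
    for (o in -r:r) {
      idx <- seq_len(n)
      src <- pmin(pmax(idx + o, 1L), n)  # replicate edges
      B[cbind(idx, src)] <- B[cbind(idx, src)] + k[o + r + 1L]
    }
    B
  }
  # axis 1
  x <- array(band(d[1], kernel1(sigma_vox[1])) %*% matrix(x, d[1]), d)
  # axis 2
  xp <- aperm(x, c(2, 1, 3))
  xp <- array(band(d[2], kernel1(sigma_vox[2])) %*% matrix(xp, d[2]), dim(xp))
  x <- aperm(xp, c(2, 1, 3))
  # axis 3
  xp <- aperm(x, c(3, 1, 2))
  xp <- array(band(d[3], kernel1(sigma_vox[3])) %*% matrix(xp, d[3]), dim(xp))
  aperm(xp, c(2, 3, 1))
}

#' Build an unpaired phantom dataset
#'
#' For each simulated patient the manifest lists: a clean FBCT-domain
#' training volume; a CBCT-domain training volume degraded from an
#' *independent* geometry (different seed), so the training sets are truly
#' unpaired; and an aligned evaluation pair (the same clean geometry and its
#' degraded copy) kept apart for evaluation only.
#'
#' @param n_patients number of simulated patients (>= 2).
#' @param spec a [phantom_spec()].
#' @param degrade a [degrade_params()]; its `seed` field is re-derived per
#'   volume from `seed`.
#' @param seed master seed; all geometry and noise seeds derive from it.
#' @param out_dir if non-`NULL`, volumes are written there as NIfTI and a
#'   `manifest.json` is emitted; otherwise volumes are kept in memory.
#' @return A list of class `phantom_dataset`: `manifest` (data.frame with
#'   patient, role, geometry_seed, noise_seed, file) and `volumes` (named
#'   list of [ct_volume], empty when `out_dir` is used).
#' @export
make_unpaired_dataset <- function(n_patients, spec = phantom_spec(),
                                  degrade = degrade_params(), seed = 1L,
                                  out_dir = NULL) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 2L) stop("need at least two patients", call. = FALSE)
  base <- as.integer(seed) %% 1000000L
  rows <- list(); vols <- list()
  add <- function(patient, role, gseed, nseed, vol) {
    key <- sprintf("%s_%s", patient, role)
    file <- if (is.null(out_dir)) NA_character_ else file.path(out_dir, paste0(key, ".nii.gz"))
    rows[[length(rows) + 1L]] <<- data.frame(
      patient = patient, role = role, geometry_seed = gseed,
      noise_seed = ifelse(is.na(nseed), NA_integer_, nseed), file = file,
      stringsAsFactors = FALSE)
    if (is.null(out_dir)) vols[[key]] <<- vol else write_volume(vol, file)
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%03d", i)
    g_clean <- base + 13L * i
    g_alt <- base + 13L * i + 7L          # independent geometry for the CBCT domain
    n_train <- base + 101L * i
    n_eval <- base + 101L * i + 51L
    clean <- make_phantom(spec, seed = g_clean)$volume
    alt <- make_phantom(spec, seed = g_alt)$volume
    dg_train <- degrade; dg_train$seed <- n_train
    dg_eval <- degrade; dg_eval$seed <- n_eval
    add(pid, "train_fbct", g_clean, NA_integer_, clean)
    add(pid, "train_cbct", g_alt, n_train, degrade_to_cbct(alt, dg_train))
    add(pid, "eval_clean", g_clean, NA_integer_, clean)
    add(pid, "eval_cbct", g_clean, n_eval, degrade_to_cbct(clean, dg_eval))
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  structure(list(manifest = manifest, volumes = vols, spec = spec,
                 degrade = degrade, seed = seed),
            class = "phantom_dataset")
}

# run code under a local RNG seed, restoring the caller's RNG state
with_seed_local <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}
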