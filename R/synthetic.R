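#' Synthetic phantom specification
#'
#' Parameters of the fixture generator: smooth multi-structure intensity
#' phantoms (soft-edged ellipsoids inside a head-like envelope) plus
#' ground-truth smooth displacement fields, standing in for real brain MR
#' pairs at desk scale.  All three generators are fully deterministic per
#' seed.
#'
#' @param shape spatial shape (default 32^3; use multiples of 16 for
#'   network work).
#' @param n_structures number of labelled internal structures (>= 1).
#' @param deform_amplitude maximum displacement magnitude in voxels.
#' @param deform_smoothness correlation length of the deformation in voxels
#'   (Gaussian smoothing sigma); must be positive.
#' @param noise_sd additive Gaussian intensity noise on the moving image
#'   (default 0.01 on [0,1] intensities).
#' @param seed RNG seed.
#' @return A `mh_phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(32, 32, 32), n_structures = 3,
                         deform_amplitude = 3, deform_smoothness = 8,
                         noise_sd = 0.01, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 4),
            n_structures >= 1, deform_amplitude >= 0,
            deform_smoothness > 0, noise_sd >= 0)
  structure(list(shape = shape, n_structures = as.integer(n_structures),
                 deform_amplitude = deform_amplitude,
                 deform_smoothness = deform_smoothness,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "mh_phantom_spec")
}

# Normalized coordinates in [-1, 1] per axis.
coord_grids <- function(shape) {
  gx <- seq(-1, 1, length.out = shape[1])
  gy <- seq(-1, 1, length.out = shape[2])
  gz <- seq(-1, 1, length.out = shape[3])
  list(x = array(rep(gx, times = shape[2] * shape[3]), shape),
       y = array(rep(rep(gy, each = shape[1]), times = shape[3]), shape),
       z = array(rep(gz, each = shape[1] * shape[2]), shape))
}

#' Generate a labelled intensity phantom
#'
#' A soft-edged head envelope containing `n_structures` non-overlapping
#' soft-edged ellipsoids with distinct intensities; the companion label map
#' carries labels `1..n_structures` (0 = background/envelope).
#'
#' @param spec a [phantom_spec()].
#' @return A list with `volume` (a [volume()], intensities in [0, 1]) and
#'   `labels` (a [label_map()]).
#' @export
make_phantom <- function(spec) {
  with_seed(spec$seed, {
    g <- coord_grids(spec$shape)
    edge <- 4 / mean(spec$shape)   # soft edge ~2 voxels
    head_r <- c(0.85, 0.85, 0.85)
    dhead <- sqrt((g$x / head_r[1])^2 + (g$y / head_r[2])^2 + (g$z / head_r[3])^2)
    img <- 0.25 / (1 + exp((dhead - 1) / edge))
    labels <- array(0L, spec$shape)

    centers <- matrix(NA_real_, spec$n_structures, 3)
    radii <- matrix(NA_real_, spec$n_structures, 3)
    for (i in seq_len(spec$n_structures)) {
      ok <- FALSE
      for (try in 1:200) {
        ctr <- runif(3, -0.45, 0.45)
        rad <- runif(3, 0.16, 0.30)
        ok <- TRUE
        if (i > 1) {
          for (j in seq_len(i - 1)) {
            gap <- sqrt(sum((ctr - centers[j, ])^2))
            if (gap < max(rad) + max(radii[j, ]) + 0.05) { ok <- FALSE; break }
          }
        }
        if (ok) break
      }
      if (!ok) stop("could not place ", spec$n_structures,
                    " non-overlapping structures; reduce n_structures")
      centers[i, ] <- ctr; radii[i, ] <- rad
      d <- sqrt(((g$x - ctr[1]) / rad[1])^2 + ((g$y - ctr[2]) / rad[2])^2 +
                ((g$z - ctr[3]) / rad[3])^2)
      level <- 0.4 + 0.55 * i / spec$n_structures
      img <- pmax(img, level / (1 + exp((d - 1) / edge)))
      labels[d <= 1] <- i
    }
    list(volume = normalize(volume(img)), labels = label_map(labels))
  })
}

#' Generate a smooth random displacement field
#'
#' Component-wise Gaussian smoothing of white noise at the requested
#' correlation length, rescaled so the maximum displacement magnitude equals
#' `deform_amplitude` voxels (a zero field for amplitude 0).
#'
#' @param spec a [phantom_spec()].
#' @return A [displacement_field()].
#' @export
make_smooth_field <- function(spec) {
  with_seed(spec$seed + 1000L, {
    d <- spec$shape
    if (spec$deform_amplitude == 0) return(zero_field(d))
    sigma <- spec$deform_smoothness
    half <- max(1L, as.integer(ceiling(2.5 * sigma)))
    kern <- stats::dnorm(seq(-half, half), sd = sigma)
    kern <- kern / sum(kern)
    # smooth on a padded domain and crop the stationary interior, so the
    # field's variance is homogeneous across the volume
    dp <- d + 2L * half
    u <- array(0, c(d, 3L))
    for (comp in 1:3) {
      noise <- array(stats::rnorm(prod(dp)), dp)
      sm <- cpp_smooth_separable(noise, dp, kern)
      u[, , , comp] <- sm[half + seq_len(d[1]), half + seq_len(d[2]),
                          half + seq_len(d[3])]
    }
    mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
    u <- u * (spec$deform_amplitude / max(mag))
    displacement_field(u)
  })
}

#' Generate a registration fixture pair with known ground truth
#'
#' The moving image is the fixed phantom warped by a known smooth field
#' plus additive Gaussian noise; the moving labels are the fixed labels
#' warped by the same field (nearest neighbour).  Both registration quality
#' (Dice, NCC) and field recovery are therefore measurable.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `fixed`, `moving` ([volume()]s), `fixed_labels`,
#'   `moving_labels` ([label_map()]s) and `truth` (the
#'   [displacement_field()] used).
#' @export
make_pair <- function(spec) {
  ph <- make_phantom(spec)
  truth <- make_smooth_field(spec)
  moving <- warp(ph$volume, truth)
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed + 2000L,
                       array(stats::rnorm(prod(spec$shape), sd = spec$noise_sd),
                             spec$shape))
    moving <- volume(pmin(pmax(unclass(moving) + noise, 0), 1),
                     vol_spacing(moving))
  }
  list(fixed = ph$volume, moving = moving,
       fixed_labels = ph$labels,
       moving_labels = warp_labels(ph$labels, truth),
       truth = truth)
}
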