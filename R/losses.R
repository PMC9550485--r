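#' Loss configuration
#'
#' Weights and window for the unsupervised training objective
#' \eqn{L = \alpha L_{sim} + \lambda L_{smooth}}.
#'
#' @param alpha non-negative weight on the similarity term (default 1).
#' @param lambda non-negative weight on the smoothness term (default 3).
#' @param ncc_window odd cubic window edge for the local NCC (default 9).
#' @param eps small positive stabilizer for the NCC denominator; windows with
#'   (near-)zero variance contribute correlation 0.
#' @return A `mh_loss_config` list.
#' @export
loss_config <- function(alpha = 1, lambda = 3, ncc_window = 9, eps = 1e-5) {
  stopifnot(alpha >= 0, lambda >= 0, eps > 0,
            ncc_window >= 1, ncc_window %% 2 == 1)
  structure(list(alpha = alpha, lambda = lambda,
                 ncc_window = as.integer(ncc_window), eps = eps),
            class = "mh_loss_config")
}

# Clipped-window local sums; near the border the window is the intersection
# with the domain, so self-correlation is exactly 1 everywhere.
ncc_terms <- function(f, w, r) {
  d <- dim(f)[1:3]
  ones <- array(1, d)
  list(n   = cpp_boxsum3d(ones, d, r),
       sf  = cpp_boxsum3d(f, d, r),
       sw  = cpp_boxsum3d(w, d, r),
       sff = cpp_boxsum3d(f * f, d, r),
       sww = cpp_boxsum3d(w * w, d, r),
       sfw = cpp_boxsum3d(f * w, d, r))
}

ncc_with_grad <- function(f, w, cfg = loss_config(), grad = FALSE) {
  check_same_shape(f, w, "reference image", "warped image")
  f <- unclass(f); w <- unclass(w)
  r <- (cfg$ncc_window - 1L) %/% 2L
  t <- ncc_terms(f, w, r)
  cross <- t$sfw - t$sf * t$sw / t$n
  fv <- pmax(t$sff - t$sf^2 / t$n, 0)
  wv <- pmax(t$sww - t$sw^2 / t$n, 0)
  D <- fv * wv + cfg$eps
  cc <- cross^2 / D
  val <- mean(cc)
  if (!grad) return(list(value = val))
  d <- dim(f)[1:3]
  g_sfw <- 2 * cross / D
  g_sww <- -cross^2 * fv / D^2
  g_sw <- g_sfw * (-t$sf / t$n) + g_sww * (-2 * t$sw / t$n)
  grad_w <- (cpp_boxsum3d(g_sfw, d, r) * f +
             cpp_boxsum3d(g_sww, d, r) * 2 * w +
             cpp_boxsum3d(g_sw, d, r)) / length(f)
  list(value = val, grad_w = grad_w)
}

#' Local windowed normalized cross-correlation
#'
#' Mean over voxels of the squared zero-mean local cross-correlation between
#' two volumes, computed in a cubic window of edge `cfg$ncc_window`.  The
#' value lies in \eqn{[0, 1]}: it is 1 iff one image is a non-degenerate
#' local affine rescaling of the other within every window, and 0 where
#' either window is constant.  Negated, it is the similarity loss used for
#' training.
#'
#' @param f,w [volume()]s of the same shape.
#' @param cfg a [loss_config()].
#' @return A scalar in \eqn{[0, 1]} (up to the `eps` stabilizer).
#' @examples
#' f <- volume(array(runif(8^3), c(8, 8, 8)))
#' ncc(f, f)            # ~1
#' ncc(f, volume(2 * unclass(f) + 3))  # affine-invariant, ~1
#' @export
ncc <- function(f, w, cfg = loss_config()) {
  ncc_with_grad(f, w, cfg)$value
}

#' Similarity loss: negative NCC of the reference and the warped moving image
#'
#' @param f reference [volume()].
#' @param m moving [volume()].
#' @param phi a [displacement_field()].
#' @param cfg a [loss_config()].
#' @param warp_cfg a [warp_config()].
#' @return A scalar in \eqn{[-1, 0]}.
#' @export
similarity_loss <- function(f, m, phi, cfg = loss_config(), warp_cfg = warp_config()) {
  -ncc(f, warp(m, phi, warp_cfg), cfg)
}

#' Diffusion smoothness of a displacement field
#'
#' For each of the 3 displacement components and each of the 3 axes, the
#' squared forward difference is averaged over the voxels that have a forward
#' neighbour along that axis, and the 9 means are summed.  Averaging (rather
#' than summing) makes the weight `lambda` independent of image resolution;
#' only the ratio `alpha:lambda` is identifiable anyway.
#'
#' @param phi a [displacement_field()].
#' @return A non-negative scalar, 0 iff the field is constant.
#' @export
smoothness_loss <- function(phi) {
  smoothness_with_grad(phi)$value
}

smoothness_with_grad <- function(phi, grad = FALSE) {
  u <- unclass(phi)
  d <- dim(u)
  X <- d[1]; Y <- d[2]; Z <- d[3]
  val <- 0
  g <- if (grad) array(0, d) else NULL
  for (comp in 1:3) {
    uc <- u[, , , comp]
    if (X > 1) {
      dx <- uc[-1, , , drop = FALSE] - uc[-X, , , drop = FALSE]
      val <- val + mean(dx^2)
      if (grad) {
        s <- 2 * dx / length(dx)
        g[-X, , , comp] <- g[-X, , , comp] - s
        g[-1, , , comp] <- g[-1, , , comp] + s
      }
    }
    if (Y > 1) {
      dy <- uc[, -1, , drop = FALSE] - uc[, -Y, , drop = FALSE]
      val <- val + mean(dy^2)
      if (grad) {
        s <- 2 * dy / length(dy)
        g[, -Y, , comp] <- g[, -Y, , comp] - s
        g[, -1, , comp] <- g[, -1, , comp] + s
      }
    }
    if (Z > 1) {
      dz <- uc[, , -1, drop = FALSE] - uc[, , -Z, drop = FALSE]
      val <- val + mean(dz^2)
      if (grad) {
        s <- 2 * dz / length(dz)
        g[, , -Z, comp] <- g[, , -Z, comp] - s
        g[, , -1, comp] <- g[, , -1, comp] + s
      }
    }
  }
  list(value = val, grad_phi = g)
}

#' Total training objective
#'
#' \eqn{L = \alpha\, L_{sim}(F, M, \phi) + \lambda\, L_{smooth}(\phi)},
#' differentiable with respect to the field.
#'
#' @inheritParams similarity_loss
#' @return A scalar.
#' @export
total_loss <- function(f, m, phi, cfg = loss_config(), warp_cfg = warp_config()) {
  total_loss_with_grad(f, m, phi, cfg, warp_cfg)$value
}

# Value and gradient with respect to phi (and the warped image en route);
# the workhorse behind both network training and the iterative backend.
total_loss_with_grad <- function(f, m, phi, cfg = loss_config(),
                                 warp_cfg = warp_config(), grad = TRUE) {
  w <- warp(m, phi, warp_cfg)
  nc <- ncc_with_grad(f, w, cfg, grad = grad)
  sm <- smoothness_with_grad(phi, grad = grad)
  val <- cfg$alpha * (-nc$value) + cfg$lambda * sm$value
  if (!grad) return(list(value = val, ncc = nc$value, smooth = sm$value))
  wb <- warp_backward(m, phi, cfg$alpha * (-nc$grad_w), warp_cfg)
  list(value = val, ncc = nc$value, smooth = sm$value,
       grad_phi = wb$grad_phi + cfg$lambda * sm$grad_phi)
}
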