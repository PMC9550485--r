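#' Warp configuration
#'
#' @param boundary_mode how sample locations outside the image domain are
#'   handled: `"clamp"` (clamp-to-border, the default, avoids artificial
#'   zero halos on brain images) or `"zeros"` (out-of-domain corners
#'   contribute zero intensity).
#' @return A `mh_warp_config` list.
#' @export
warp_config <- function(boundary_mode = c("clamp", "zeros")) {
  boundary_mode <- match.arg(boundary_mode)
  structure(list(boundary_mode = boundary_mode), class = "mh_warp_config")
}

boundary_code <- function(cfg) if (cfg$boundary_mode == "clamp") 0L else 1L

#' Spatial-transformer warp of a volume by a displacement field
#'
#' Resamples the moving image at `i + u(i)` for every voxel `i` (0-based
#' index space, displacements in voxel units) using trilinear interpolation
#' over the 8 integer neighbours, with weights
#' \eqn{\prod_d (1 - |j_d - i'_d|)}.  The operation is differentiable with
#' respect to both the image and the field; gradients are available through
#' the internal backward pass used in training.
#'
#' @param m a [volume()] (the moving image).
#' @param phi a [displacement_field()] of the same spatial shape.
#' @param cfg a [warp_config()].
#' @return The warped [volume()].
#' @examples
#' v <- volume(array(runif(4^3), c(4, 4, 4)))
#' identical_out <- warp(v, zero_field(c(4, 4, 4)))
#' all.equal(unclass(identical_out), unclass(v), check.attributes = FALSE)
#' @export
warp <- function(m, phi, cfg = warp_config()) {
  check_same_shape(m, phi, "moving image", "displacement field")
  out <- cpp_warp_trilinear(as.double(unclass(m)), as.integer(dim(m)[1:3]),
                            as.double(unclass(phi)), boundary_code(cfg))
  volume(out, vol_spacing(m))
}

#' Warp an integer label map
#'
#' Uses nearest-neighbour sampling at `i + u(i)` so labels stay integral
#' (trilinear interpolation would blend label identities).
#'
#' @param l a [label_map()].
#' @param phi a [displacement_field()] of the same spatial shape.
#' @param cfg a [warp_config()].
#' @return The warped [label_map()].
#' @export
warp_labels <- function(l, phi, cfg = warp_config()) {
  check_same_shape(l, phi, "label map", "displacement field")
  out <- cpp_warp_nn(as.integer(unclass(l)), as.integer(dim(l)[1:3]),
                     as.double(unclass(phi)), boundary_code(cfg))
  label_map(out)
}

# Backward pass of the trilinear warp; internal, used by the losses and the
# iterative registration backend.
warp_backward <- function(m, phi, grad_out, cfg = warp_config()) {
  res <- cpp_warp_trilinear_backward(as.double(unclass(m)), as.integer(dim(m)[1:3]),
                                     as.double(unclass(phi)),
                                     as.double(grad_out), boundary_code(cfg))
  list(grad_m = res$gm, grad_phi = res$gu)
}
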