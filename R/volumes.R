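#' 3D scalar volume
#'
#' A `mh_volume` is a numeric 3D array with a voxel spacing attribute (mm per
#' voxel per axis).  Volumes are used in the array index space of the file as
#' stored: no reorientation is ever performed, so reference and moving images
#' are assumed to be affinely pre-aligned and stored in the same orientation.
#'
#' @param data numeric 3D array of intensities.
#' @param spacing numeric length-3, mm per voxel along each axis.
#' @return An object of class `mh_volume` (a 3D array with a `spacing`
#'   attribute).
#' @examples
#' v <- volume(array(runif(64), c(4, 4, 4)))
#' dim(v)
#' @export
volume <- function(data, spacing = c(1, 1, 1)) {
  data <- as_array3d(data, "volume data")
  if (!all(is.finite(data))) stop("volume data contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers")
  structure(data, spacing = spacing, class = "mh_volume")
}

#' Dense displacement vector field
#'
#' A per-voxel 3-vector of displacements in voxel units, stored as a 4D array
#' of shape (X, Y, Z, 3) with components along the last dimension.  Adding
#' the field to the integer identity grid maps each output voxel into the
#' moving image (see [warp()]).
#'
#' @param u numeric 4D array (X, Y, Z, 3), displacements in voxels.
#' @return An object of class `mh_field`.
#' @export
displacement_field <- function(u) {
  u <- unclass(u)
  if (!is.array(u) || length(dim(u)) != 4L || dim(u)[4] != 3L)
    stop("displacement field must be a 4D array with last dimension 3, got dims (",
         paste(dim(u), collapse = ","), ")")
  if (!all(is.finite(u))) stop("displacement field contains non-finite values")
  storage.mode(u) <- "double"
  structure(u, class = "mh_field")
}

#' Zero displacement field for a given spatial shape
#'
#' @param shape integer length-3 spatial shape (X, Y, Z).
#' @return An all-zero [displacement_field()].
#' @export
zero_field <- function(shape) {
  displacement_field(array(0, c(as.integer(shape), 3L)))
}

#' Integer label map
#'
#' A segmentation aligned to a companion [volume()].  Label 0 is reserved for
#' background; structures carry positive integer labels.
#'
#' @param labels non-negative integer 3D array.
#' @return An object of class `mh_labels`.
#' @export
label_map <- function(labels) {
  labels <- as_array3d(labels, "label map")
  if (any(!is.finite(labels)) || any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  structure(labels, class = "mh_labels")
}

as_array3d <- function(x, what) {
  x <- unclass(x)
  if (is.null(dim(x)) || length(dim(x)) != 3L)
    stop(what, " must be a 3D array, got dimensionality ",
         if (is.null(dim(x))) 1L else length(dim(x)))
  storage.mode(x) <- "double"
  x
}

#' @export
print.mh_volume <- function(x, ...) {
  cat("<mh_volume> ", paste(dim(x), collapse = " x "),
      " voxels, spacing ", paste(attr(x, "spacing"), collapse = " x "),
      " mm, intensity range [", signif(min(x), 4), ", ", signif(max(x), 4), "]\n",
      sep = "")
  invisible(x)
}

#' @export
print.mh_field <- function(x, ...) {
  mag <- sqrt(x[, , , 1]^2 + x[, , , 2]^2 + x[, , , 3]^2)
  cat("<mh_field> ", paste(dim(x)[1:3], collapse = " x "),
      " voxels, max |u| = ", signif(max(mag), 4), " voxels\n", sep = "")
  invisible(x)
}

#' @export
print.mh_labels <- function(x, ...) {
  cat("<mh_labels> ", paste(dim(x), collapse = " x "),
      " voxels, labels {", paste(sort(unique(as.vector(x))), collapse = ", "),
      "}\n", sep = "")
  invisible(x)
}

vol_spacing <- function(v) attr(v, "spacing") %||% c(1, 1, 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_same_shape <- function(a, b, what_a, what_b) {
  da <- dim(a)[1:3]; db <- dim(b)[1:3]
  if (!identical(as.integer(da), as.integer(db)))
    stop(what_a, " shape (", paste(da, collapse = ","), ") does not match ",
         what_b, " shape (", paste(db, collapse = ","), ")")
  invisible(TRUE)
}

#' Read a 3D NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume()] with shape and spacing taken from the header and data
#'   cast to double.
#' @export
read_volume <- function(path) {
  img <- read_nifti3d(path)
  volume(img$data, img$spacing)
}

#' Read a 3D NIfTI label map
#'
#' @param path path to a `.nii` or `.nii.gz` file with integer labels.
#' @return A [label_map()].
#' @export
read_labels <- function(path) {
  img <- read_nifti3d(path)
  label_map(round(img$data))
}

read_nifti3d <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.double(arr), dim(arr))  # drop RNifti header attributes
  nd <- length(dim(arr))
  if (nd == 4L && dim(arr)[4] == 1L) { arr <- arr[, , , 1, drop = TRUE]; nd <- 3L }
  if (nd != 3L) stop("expected a 3D image, got dimensionality ", nd, ": ", path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
  list(data = arr, spacing = sp)
}

#' Write a volume or label map as NIfTI
#'
#' @param v a [volume()] or [label_map()].
#' @param path output path (`.nii` or `.nii.gz`); the parent directory must
#'   exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(v, path) {
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  sp <- vol_spacing(v)
  img <- RNifti::asNifti(unclass(v))
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
write_labels <- function(v, path) {
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(array(as.integer(v), dim(v)))
  RNifti::pixdim(img) <- c(1, 1, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read/write a displacement field as 4D NIfTI
#'
#' Fields are stored as a 4D NIfTI with last dimension 3 and displacements in
#' voxel units.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return [read_field()] returns a [displacement_field()].
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 4L || dim(arr)[4] != 3L)
    stop("expected a 4D field with last dimension 3, got dims (",
         paste(dim(arr), collapse = ","), ")")
  displacement_field(arr)
}

#' @rdname read_field
#' @param phi a [displacement_field()].
#' @export
write_field <- function(phi, path) {
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  RNifti::writeNifti(RNifti::asNifti(unclass(phi)), path)
  invisible(path)
}

#' Centered crop of a volume or label map
#'
#' Extracts a centered sub-volume; the left margin along each axis is
#' `floor((in - out) / 2)` voxels, matching the preprocessing used to bring
#' whole-head scans (e.g. 181 x 217 x 181) to a network-friendly shape such
#' as 160 x 192 x 160.
#'
#' @param v a [volume()] or [label_map()].
#' @param target_shape integer length-3, at most `dim(v)` per axis.
#' @return The cropped object of the same class.
#' @export
crop_center <- function(v, target_shape) {
  ts <- as.integer(target_shape)
  if (length(ts) != 3L || any(ts < 1L)) stop("target_shape must be 3 positive integers")
  d <- dim(v)
  if (any(ts > d))
    stop("target shape (", paste(ts, collapse = ","),
         ") exceeds input shape (", paste(d, collapse = ","), ")")
  off <- (d - ts) %/% 2L
  out <- unclass(v)[off[1] + seq_len(ts[1]), off[2] + seq_len(ts[2]),
                    off[3] + seq_len(ts[3]), drop = FALSE]
  if (inherits(v, "mh_labels")) label_map(out) else volume(out, vol_spacing(v))
}

#' Intensity normalization
#'
#' Rescales intensities to \eqn{[0, 1]} (min-max, the default) or to zero
#' mean and unit variance (`"zscore"`).  A constant volume maps to all zeros.
#'
#' @param v a [volume()].
#' @param method `"minmax"` or `"zscore"`.
#' @return The normalized [volume()].
#' @export
normalize <- function(v, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  x <- unclass(v)
  if (method == "minmax") {
    rng <- range(x)
    out <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else array(0, dim(x))
  } else {
    s <- stats::sd(as.vector(x))
    out <- if (s > 0) (x - mean(x)) / s else array(0, dim(x))
  }
  volume(out, vol_spacing(v))
}
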