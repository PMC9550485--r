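#' Dice overlap of one label in two segmentations
#'
#' \eqn{Dice(A, B) = 2 |A \cap B| / (|A| + |B|)} for the voxel sets carrying
#' `label`.  Conventions keeping the metric total: both sets empty gives 1
#' (vacuous agreement), exactly one empty gives 0.
#'
#' @param a,b [label_map()]s of the same shape.
#' @param label the integer label to compare.
#' @return A scalar in \eqn{[0, 1]}; symmetric in its arguments.
#' @export
dice <- function(a, b, label) {
  check_same_shape(a, b, "first label map", "second label map")
  in_a <- unclass(a) == label
  in_b <- unclass(b) == label
  na <- sum(in_a); nb <- sum(in_b)
  if (na + nb == 0L) return(1.0)
  2 * sum(in_a & in_b) / (na + nb)
}

#' Dice-based registration evaluation
#'
#' Warps the moving segmentation by the field (nearest neighbour), then
#' computes the Dice score against the reference segmentation for every
#' label present in the reference (background 0 excluded), optionally merges
#' left/right hemisphere label pairs into single structure scores (their
#' arithmetic mean), and averages.
#'
#' @param ref_labels reference [label_map()].
#' @param moving_labels moving [label_map()].
#' @param phi a [displacement_field()] (use [zero_field()] for the
#'   pre-registration baseline).
#' @param label_pairs optional named list mapping a structure name to an
#'   integer vector of the labels to merge, e.g.
#'   `list(putamen = c(3, 34))`.
#' @param warp_cfg a [warp_config()].
#' @return An object of class `mh_dice_report`: `per_label` (named numeric),
#'   `merged` (named numeric, possibly empty), `avg` (unweighted mean over
#'   the evaluated labels).
#' @export
evaluate_registration <- function(ref_labels, moving_labels, phi,
                                  label_pairs = NULL,
                                  warp_cfg = warp_config()) {
  check_same_shape(ref_labels, moving_labels, "reference labels", "moving labels")
  warped <- warp_labels(moving_labels, phi, warp_cfg)
  labels <- sort(setdiff(unique(as.vector(unclass(ref_labels))), 0L))
  if (length(labels) == 0) stop("reference label map contains only background")
  per_label <- vapply(labels, function(l) dice(ref_labels, warped, l), 0)
  names(per_label) <- labels
  merged <- numeric(0)
  if (!is.null(label_pairs)) {
    merged <- vapply(label_pairs, function(ls) {
      mean(per_label[as.character(ls)])
    }, 0)
  }
  structure(list(per_label = per_label, merged = merged,
                 avg = mean(per_label)),
            class = "mh_dice_report")
}

#' @export
print.mh_dice_report <- function(x, ...) {
  cat("<mh_dice_report> ", length(x$per_label), " labels, avg Dice ",
      sprintf("%.4f", x$avg), "\n", sep = "")
  invisible(x)
}

#' Flatten a Dice report to a data.frame
#'
#' @param x a `mh_dice_report`.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return A data.frame with columns `kind` (`label`/`merged`/`average`),
#'   `name`, `dice`.
#' @export
as.data.frame.mh_dice_report <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- data.frame(kind = "label", name = names(x$per_label),
                     dice = unname(x$per_label))
  if (length(x$merged))
    rows <- rbind(rows, data.frame(kind = "merged", name = names(x$merged),
                                   dice = unname(x$merged)))
  rbind(rows, data.frame(kind = "average", name = "all", dice = x$avg))
}
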