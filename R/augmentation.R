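#' Plan pairwise cross-registration augmentation
#'
#' For N distinct training volumes, every ordered pair of distinct images
#' (reference, moving) defines one registration task whose warped moving
#' image becomes a new training image: `N * (N - 1)` tasks, so the merged
#' training set grows to `N^2`.
#'
#' @param ids character vector of distinct volume identifiers.
#' @return An object of class `mh_augmentation_plan` with `originals` and a
#'   data.frame `tasks` (`reference`, `moving`, `new_id`), in deterministic
#'   order.
#' @examples
#' nrow(plan_augmentation(sprintf("s%02d", 1:25))$tasks)  # 600
#' @export
plan_augmentation <- function(ids) {
  ids <- as.character(ids)
  if (length(ids) < 1) stop("need at least one identifier")
  if (anyDuplicated(ids)) stop("identifiers must be distinct")
  grid <- expand.grid(moving = ids, reference = ids,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$reference != grid$moving, c("reference", "moving")]
  rownames(grid) <- NULL
  grid$new_id <- if (nrow(grid)) paste0(grid$moving, "_to_", grid$reference)
                 else character(0)
  if (any(grid$new_id %in% ids))
    stop("derived identifiers collide with originals")
  structure(list(originals = ids, tasks = grid), class = "mh_augmentation_plan")
}

#' @export
print.mh_augmentation_plan <- function(x, ...) {
  n <- length(x$originals)
  cat("<mh_augmentation_plan> ", n, " originals -> ", nrow(x$tasks),
      " tasks (", n, "^2 = ", n^2, " total images after merge)\n", sep = "")
  invisible(x)
}

#' Registration backends for augmentation
#'
#' A backend is a function `(fixed, moving) -> list(field, warped)`.
#' `backend_identity()` returns the moving image unchanged (zero field;
#' useful for plumbing tests).  `backend_iterative()` directly minimizes the
#' total loss over a per-pair displacement field with ADAM -- a
#' self-contained instance-wise optimizer needing no trained model.
#' `backend_model()` wraps a trained network via [register_pair()].
#'
#' @param iters iterative backend: number of ADAM steps (default 60).
#' @param lr iterative backend: ADAM step size in voxels (default 0.2).
#' @param loss a [loss_config()] for the iterative objective.
#' @param warp_cfg a [warp_config()].
#' @return A backend function.
#' @export
backend_identity <- function() {
  function(fixed, moving) {
    list(field = zero_field(dim(moving)[1:3]), warped = moving)
  }
}

#' @rdname backend_identity
#' @export
backend_iterative <- function(iters = 60, lr = 0.2, loss = loss_config(),
                              warp_cfg = warp_config()) {
  force(iters); force(lr); force(loss); force(warp_cfg)
  function(fixed, moving) {
    u <- array(0, c(dim(moving)[1:3], 3L))
    m1 <- array(0, dim(u)); v1 <- array(0, dim(u))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (t in seq_len(iters)) {
      lg <- total_loss_with_grad(fixed, moving, displacement_field(u),
                                 loss, warp_cfg)
      g <- lg$grad_phi
      m1 <- b1 * m1 + (1 - b1) * g
      v1 <- b2 * v1 + (1 - b2) * g^2
      u <- u - lr * (m1 / (1 - b1^t)) / (sqrt(v1 / (1 - b2^t)) + eps)
    }
    phi <- displacement_field(u)
    list(field = phi, warped = warp(moving, phi, warp_cfg))
  }
}

#' @rdname backend_identity
#' @param net a trained network (or [train()] result).
#' @export
backend_model <- function(net, warp_cfg = warp_config()) {
  if (inherits(net, "mh_train_result")) net <- net$network
  force(net)
  function(fixed, moving) {
    r <- register_pair(net, fixed, moving, warp_cfg)
    list(field = r$field, warped = r$warped)
  }
}

#' @rdname backend_identity
#' @param command a shell command template for an external registration
#'   tool; the placeholders `{fixed}`, `{moving}` and `{warped}` are
#'   replaced by NIfTI paths.  The command must write the warped moving
#'   image to `{warped}`.  No displacement field is recovered from external
#'   tools, so `field` is `NULL` in the result.
#' @export
backend_command <- function(command) {
  force(command)
  function(fixed, moving) {
    tmp <- tempfile("mhnet-backend-")
    dir.create(tmp)
    on.exit(unlink(tmp, recursive = TRUE))
    paths <- c(fixed = file.path(tmp, "fixed.nii.gz"),
               moving = file.path(tmp, "moving.nii.gz"),
               warped = file.path(tmp, "warped.nii.gz"))
    write_volume(fixed, paths[["fixed"]])
    write_volume(moving, paths[["moving"]])
    cmd <- command
    for (nm in names(paths))
      cmd <- gsub(paste0("{", nm, "}"), paths[[nm]], cmd, fixed = TRUE)
    status <- system(cmd)
    if (status != 0L) stop("backend command failed with status ", status)
    if (!file.exists(paths[["warped"]]))
      stop("backend command did not produce ", paths[["warped"]])
    list(field = NULL, warped = read_volume(paths[["warped"]]))
  }
}

#' Run an augmentation plan
#'
#' Executes every task of the plan: the backend registers the moving volume
#' to the reference and the warped moving image is stored under the derived
#' identifier.  A failing task is recorded and the run continues.
#'
#' @param plan a [plan_augmentation()] result.
#' @param volumes named list mapping every original id to its [volume()].
#' @param backend a backend function (see [backend_identity()]).
#' @return A list with `volumes` (named list of the new images) and
#'   `manifest` (data.frame: `new_id`, `reference`, `moving`, `status`,
#'   `message`); attribute `ok` is `FALSE` if any task failed.
#' @export
run_augmentation <- function(plan, volumes, backend = backend_iterative()) {
  missing_ids <- setdiff(plan$originals, names(volumes))
  if (length(missing_ids))
    stop("volumes missing for ids: ", paste(missing_ids, collapse = ", "))
  out <- list()
  manifest <- plan$tasks
  manifest$status <- "ok"
  manifest$message <- ""
  for (i in seq_len(nrow(plan$tasks))) {
    task <- plan$tasks[i, ]
    res <- tryCatch(
      backend(volumes[[task$reference]], volumes[[task$moving]]),
      error = function(e) e)
    if (inherits(res, "error")) {
      manifest$status[i] <- "failed"
      manifest$message[i] <- conditionMessage(res)
    } else {
      out[[task$new_id]] <- res$warped
    }
  }
  n_fail <- sum(manifest$status == "failed")
  if (n_fail > 0)
    warning(n_fail, " augmentation task(s) failed; see manifest")
  structure(list(volumes = out, manifest = manifest), ok = n_fail == 0L)
}
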