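#' Training configuration
#'
#' Reproduces the published training regime by default: ADAM, batch size 1,
#' learning rate 1e-4 halved from a scheduled epoch, 70 epochs.  Desk-scale
#' runs on synthetic fixtures typically use far fewer epochs and a larger
#' learning rate (see the vignette).
#'
#' @param epochs number of passes over the training pairs (default 70).
#' @param lr initial ADAM learning rate (default 1e-4).
#' @param lr_halve_epoch epoch from whose start the learning rate is halved
#'   (default 40); must be at most `epochs`.
#' @param batch_size gradients are averaged over this many pairs per update
#'   (default 1).
#' @param seed RNG seed controlling initialization and epoch shuffling.
#' @param loss a [loss_config()].
#' @param network a [network_config()].
#' @param shuffle reshuffle pair order each epoch (seeded)?
#' @param grad_clip optional positive cap on the global gradient L2 norm
#'   (`Inf` = off, the default).
#' @param checkpoint_every write a checkpoint every this many epochs when a
#'   `checkpoint_dir` is given to [train()] (0 = only at the end).
#' @param verbose print per-epoch progress?
#' @return A `mh_train_config` list.
#' @export
train_config <- function(epochs = 70, lr = 1e-4, lr_halve_epoch = 40,
                         batch_size = 1, seed = 0L,
                         loss = loss_config(), network = network_config(),
                         shuffle = TRUE, grad_clip = Inf,
                         checkpoint_every = 0, verbose = FALSE) {
  stopifnot(epochs >= 1, lr > 0, lr_halve_epoch >= 1, batch_size >= 1,
            grad_clip > 0)
  if (lr_halve_epoch > epochs)
    stop("lr_halve_epoch (", lr_halve_epoch, ") must be <= epochs (", epochs, ")")
  structure(list(epochs = as.integer(epochs), lr = lr,
                 lr_halve_epoch = as.integer(lr_halve_epoch),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 loss = loss, network = network, shuffle = isTRUE(shuffle),
                 grad_clip = grad_clip,
                 checkpoint_every = as.integer(checkpoint_every),
                 verbose = isTRUE(verbose)),
            class = "mh_train_config")
}

#' Learning-rate schedule and iteration accounting
#'
#' One optimization step is taken per pair per epoch (batch size 1), so the
#' total number of steps is `epochs * n_pairs`; the learning rate is halved
#' from the start of `lr_halve_epoch`.
#'
#' @param cfg a [train_config()].
#' @param n_pairs number of training pairs.
#' @return A data.frame with one row per epoch (`epoch`, `lr`, `steps`) and
#'   attribute `total_steps`.
#' @examples
#' sched <- train_schedule(train_config(epochs = 70), n_pairs = 625)
#' attr(sched, "total_steps")  # 43750
#' @export
train_schedule <- function(cfg, n_pairs) {
  stopifnot(n_pairs >= 1)
  epoch <- seq_len(cfg$epochs)
  lr <- ifelse(epoch >= cfg$lr_halve_epoch, cfg$lr / 2, cfg$lr)
  steps <- rep(as.integer(n_pairs), cfg$epochs)
  structure(data.frame(epoch = epoch, lr = lr, steps = steps),
            total_steps = sum(steps))
}

# ---- ADAM -------------------------------------------------------------------

adam_init <- function(params) {
  st <- list(t = 0L, m = list(), v = list())
  for (nm in names(params)) {
    st$m[[nm]] <- list(W = array(0, dim(params[[nm]]$W)),
                       b = numeric(length(params[[nm]]$b)))
    st$v[[nm]] <- st$m[[nm]]
  }
  st
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (slot in c("W", "b")) {
      g <- grads[[nm]][[slot]]
      state$m[[nm]][[slot]] <- beta1 * state$m[[nm]][[slot]] + (1 - beta1) * g
      state$v[[nm]][[slot]] <- beta2 * state$v[[nm]][[slot]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]][[slot]] / bc1
      vhat <- state$v[[nm]][[slot]] / bc2
      params[[nm]][[slot]] <- params[[nm]][[slot]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

zero_like_grads <- function(params) {
  lapply(params, function(p) list(W = array(0, dim(p$W)), b = numeric(length(p$b))))
}

add_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]]$W <- a[[nm]]$W + b[[nm]]$W
    a[[nm]]$b <- a[[nm]]$b + b[[nm]]$b
  }
  a
}

scale_grads <- function(a, s) {
  lapply(a, function(g) list(W = g$W * s, b = g$b * s))
}

grad_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g$W^2) + sum(g$b^2), 0)))
}

# ---- training loop ----------------------------------------------------------

#' Train the registration network on reference/moving pairs
#'
#' Unsupervised training: per step the network predicts the field for one
#' pair, the total loss (negative local NCC of the warped moving image plus
#' the weighted diffusion penalty on the field, both on `phi_final`) is
#' backpropagated through the spatial transformer and the network, and ADAM
#' updates the parameters.  Fully reproducible given `cfg$seed`.
#'
#' @param pairs list of pairs; each element is a list with components
#'   `fixed` and `moving`, both [volume()]s of one common spatial shape
#'   divisible by 16.
#' @param cfg a [train_config()].
#' @param net optionally, an existing network to continue training;
#'   by default a fresh one is built from `cfg$network` and `cfg$seed`.
#' @param checkpoint_dir optional directory for epoch checkpoints.
#' @param monitor_pairs optional held-out pairs (same structure as `pairs`);
#'   their mean loss is evaluated after each epoch without updates and
#'   recorded as `monitor_loss` in the history.  Off by default.
#' @return A list of class `mh_train_result` with `network`, `history`
#'   (data.frame: `epoch`, `loss`, `ncc`, `lr`, and `monitor_loss` when
#'   monitoring) and `config`.
#' @export
train <- function(pairs, cfg = train_config(), net = NULL, checkpoint_dir = NULL,
                  monitor_pairs = NULL) {
  if (length(pairs) == 0) stop("no training pairs given")
  shapes <- lapply(pairs, function(p) dim(p$fixed)[1:3])
  if (length(unique(vapply(shapes, paste, "", collapse = "x"))) != 1L)
    stop("all training pairs must share one spatial shape")
  for (p in pairs) check_net_input(p$fixed, p$moving)

  with_seed(cfg$seed, {
    if (is.null(net)) net <- build_network(cfg$network)
    state <- adam_init(net$params)
    sched <- train_schedule(cfg, length(pairs))
    history <- data.frame(epoch = integer(), loss = numeric(),
                          ncc = numeric(), lr = numeric())
    for (ep in seq_len(cfg$epochs)) {
      lr <- sched$lr[ep]
      ord <- if (cfg$shuffle) sample(length(pairs)) else seq_along(pairs)
      ep_loss <- 0; ep_ncc <- 0
      acc <- NULL; acc_n <- 0L
      for (idx in ord) {
        p <- pairs[[idx]]
        d <- dim(p$fixed)[1:3]
        x0 <- cat_channels(array(unclass(p$fixed), c(d, 1L)),
                           array(unclass(p$moving), c(d, 1L)))
        fw <- net_forward(net, x0, keep_cache = TRUE)
        phi <- displacement_field(fw$fields$phi_final)
        lg <- total_loss_with_grad(p$fixed, p$moving, phi, cfg$loss)
        if (!is.finite(lg$value))
          stop("non-finite loss at epoch ", ep, ", pair ", idx)
        grads <- net_backward(net, fw$cache, lg$grad_phi)
        acc <- if (is.null(acc)) grads else add_grads(acc, grads)
        acc_n <- acc_n + 1L
        ep_loss <- ep_loss + lg$value
        ep_ncc <- ep_ncc + lg$ncc
        if (acc_n == cfg$batch_size || idx == ord[length(ord)]) {
          g <- if (acc_n > 1L) scale_grads(acc, 1 / acc_n) else acc
          if (is.finite(cfg$grad_clip)) {
            gn <- grad_norm(g)
            if (gn > cfg$grad_clip) g <- scale_grads(g, cfg$grad_clip / gn)
          }
          upd <- adam_step(net$params, g, state, lr)
          net$params <- upd$params
          state <- upd$state
          acc <- NULL; acc_n <- 0L
        }
      }
      row <- data.frame(epoch = ep, loss = ep_loss / length(pairs),
                        ncc = ep_ncc / length(pairs), lr = lr)
      if (!is.null(monitor_pairs) && length(monitor_pairs)) {
        row$monitor_loss <- mean(vapply(monitor_pairs, function(p) {
          d <- dim(p$fixed)[1:3]
          xm <- cat_channels(array(unclass(p$fixed), c(d, 1L)),
                             array(unclass(p$moving), c(d, 1L)))
          fwm <- net_forward(net, xm)
          total_loss(p$fixed, p$moving,
                     displacement_field(fwm$fields$phi_final), cfg$loss)
        }, 0))
      }
      history <- rbind(history, row)
      if (cfg$verbose)
        message(sprintf("epoch %3d  loss %.5f  ncc %.4f  lr %g",
                        ep, ep_loss / length(pairs), ep_ncc / length(pairs), lr))
      if (!is.null(checkpoint_dir) && cfg$checkpoint_every > 0 &&
          ep %% cfg$checkpoint_every == 0L)
        save_network(net, file.path(checkpoint_dir, sprintf("epoch_%03d.rds", ep)))
    }
    if (!is.null(checkpoint_dir))
      save_network(net, file.path(checkpoint_dir, "final.rds"))
    structure(list(network = net, history = history, config = cfg),
              class = "mh_train_result")
  })
}

#' @export
print.mh_train_result <- function(x, ...) {
  n <- nrow(x$history)
  cat("<mh_train_result> ", n, " epochs, loss ",
      signif(x$history$loss[1], 4), " -> ", signif(x$history$loss[n], 4),
      ", final NCC ", signif(x$history$ncc[n], 4), "\n", sep = "")
  invisible(x)
}

#' Register one pair with a trained network
#'
#' A single forward pass followed by a warp; no parameters are updated.
#' Repeated calls are deterministic.
#'
#' @param net a trained network (or a [train()] result).
#' @param f,m reference and moving [volume()]s.
#' @param warp_cfg a [warp_config()].
#' @return A list with `field` (the predicted [displacement_field()]),
#'   `warped` (the moving image resampled through it) and `fields` (all
#'   forecast fields).
#' @export
register_pair <- function(net, f, m, warp_cfg = warp_config()) {
  if (inherits(net, "mh_train_result")) net <- net$network
  fields <- mhnet_forward(net, f, m)
  phi <- fields$phi_final
  list(field = phi, warped = warp(m, phi, warp_cfg), fields = fields)
}

#' Save / load a network checkpoint
#'
#' Checkpoints carry the full configuration alongside the weights so a
#' network can be rebuilt and reloaded exactly.
#'
#' @param net a network from [build_network()] or [train()].
#' @param path checkpoint path (`.rds`).
#' @return [load_network()] returns the `mh_network`.
#' @export
save_network <- function(net, path) {
  if (inherits(net, "mh_train_result")) net <- net$network
  saveRDS(list(cfg = net$cfg, params = net$params,
               package_version = as.character(utils::packageVersion("mhnet"))),
          path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- readRDS(path)
  structure(list(cfg = obj$cfg, params = obj$params), class = "mh_network")
}
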