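#' Network architecture configuration
#'
#' All architecture hyperparameters of the registration network.  The input
#' is the reference and moving volume concatenated along the channel
#' dimension (2 channels); the output is a dense 3-channel displacement
#' field of the same spatial shape.
#'
#' @param enc_channels 4 positive ints: feature channels after each
#'   stride-2 downsampling level.
#' @param dec_channels 4 positive ints: feature channels after each decoder
#'   level (coarsest first).
#' @param inception_branch_out output channels per Inception branch
#'   (default 4).
#' @param inception_kernels odd cubic kernel edges of the parallel branches
#'   (default 1, 3, 5, 7).
#' @param bottleneck_channels channels of the 1x1x1 bottleneck placed before
#'   each branch with kernel > 1 (default 1).
#' @param leaky_slope negative slope of the LeakyReLU after each feature
#'   convolution (default 0.2).
#' @param use_inception if `FALSE`, the multiscale block is replaced by a
#'   single plain 3x3x3 convolution with the same in/out channels (the
#'   "w/o Incep" ablation).
#' @param use_hierarchical if `FALSE`, the hierarchical forecast heads are
#'   removed and the final field is the end-of-decoder prediction (the
#'   "w/o HF" ablation).
#' @param head_kernel cubic kernel edge of the forecast-head convolutions
#'   (default 3, matching the decoder convolutions).
#' @param init_fields initialization of the field-producing convolutions:
#'   `"small"` (weights ~ N(0, 1e-5^2); near-identity start and gradient
#'   flow to every parameter from the first step) or `"zero"` (exactly zero,
#'   so the untrained network is exactly the identity transform).
#' @return A `mh_network_config` list.
#' @export
network_config <- function(enc_channels = c(16, 32, 32, 32),
                           dec_channels = c(32, 32, 32, 16),
                           inception_branch_out = 4,
                           inception_kernels = c(1, 3, 5, 7),
                           bottleneck_channels = 1,
                           leaky_slope = 0.2,
                           use_inception = TRUE,
                           use_hierarchical = TRUE,
                           head_kernel = 3,
                           init_fields = c("small", "zero")) {
  stopifnot(length(enc_channels) == 4, all(enc_channels >= 1),
            length(dec_channels) == 4, all(dec_channels >= 1),
            inception_branch_out >= 1, bottleneck_channels >= 1,
            leaky_slope > 0, leaky_slope < 1,
            head_kernel >= 1, head_kernel %% 2 == 1)
  if (any(inception_kernels %% 2 != 1) || any(inception_kernels < 1))
    stop("inception kernels must be odd and >= 1")
  structure(list(enc_channels = as.integer(enc_channels),
                 dec_channels = as.integer(dec_channels),
                 inception_branch_out = as.integer(inception_branch_out),
                 inception_kernels = as.integer(inception_kernels),
                 bottleneck_channels = as.integer(bottleneck_channels),
                 leaky_slope = leaky_slope,
                 use_inception = isTRUE(use_inception),
                 use_hierarchical = isTRUE(use_hierarchical),
                 head_kernel = as.integer(head_kernel),
                 init_fields = match.arg(init_fields)),
            class = "mh_network_config")
}

# ---- primitive layers -------------------------------------------------------

conv_param <- function(k, cin, cout, init = "he") {
  n <- k^3 * cin * cout
  W <- switch(init,
    he    = array(stats::rnorm(n, sd = sqrt(2 / (k^3 * cin))), c(k, k, k, cin, cout)),
    small = array(stats::rnorm(n, sd = 1e-5), c(k, k, k, cin, cout)),
    zero  = array(0, c(k, k, k, cin, cout)),
    stop("unknown init ", init))
  list(W = W, b = numeric(cout))
}

# 1x1x1 fusion conv initialized to average the stacked candidate fields:
# output component o is the mean over fields of their component o.
fuse_param <- function(n_fields) {
  W <- array(0, c(1, 1, 1, 3 * n_fields, 3))
  for (fld in seq_len(n_fields))
    for (o in 1:3) W[1, 1, 1, 3 * (fld - 1) + o, o] <- 1 / n_fields
  list(W = W, b = numeric(3))
}

conv_fwd <- function(p, x, stride = 1L) {
  k <- dim(p$W)[1]; cin <- dim(p$W)[4]; cout <- dim(p$W)[5]
  Wm <- p$W; dim(Wm) <- c(k^3 * cin, cout)
  cpp_conv3d_forward(x, dim(x), Wm, p$b, k, as.integer(stride), (k - 1L) %/% 2L)$y
}

conv_bwd <- function(p, x, gy, stride = 1L) {
  k <- dim(p$W)[1]; cin <- dim(p$W)[4]; cout <- dim(p$W)[5]
  Wm <- p$W; dim(Wm) <- c(k^3 * cin, cout)
  res <- cpp_conv3d_backward(x, dim(x), Wm, k, as.integer(stride),
                             (k - 1L) %/% 2L, gy, dim(gy))
  gW <- res$gW; dim(gW) <- dim(p$W)
  list(gx = res$gx, gW = gW, gb = res$gb)
}

leaky_fwd <- function(x, slope) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  x
}

leaky_bwd <- function(pre, g, slope) {
  neg <- pre < 0
  g[neg] <- g[neg] * slope
  g
}

resize4d <- function(x, oshape) {
  cpp_resize_trilinear(x, dim(x), as.integer(oshape))
}

resize4d_bwd <- function(gy, xshape) {
  cpp_resize_trilinear_backward(gy, dim(gy), as.integer(xshape))
}

cat_channels <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])[1:3]
  array(unlist(arrs, use.names = FALSE), c(d, sum(vapply(arrs, function(a) dim(a)[4], 0L))))
}

# ---- parameter accounting ---------------------------------------------------

#' Closed-form parameter count of the multiscale Inception block
#'
#' A 3D convolution with kernel \eqn{H \times W \times D} mapping
#' \eqn{C_{in}} to \eqn{C_{out}} channels has
#' \eqn{C_{in} H W D\, C_{out}} weights (bias terms excluded).  Without
#' bottlenecks every branch maps the block input directly; with bottlenecks
#' every branch with kernel > 1 first passes through a 1x1x1 reduction to
#' `bottleneck_channels`, while the 1x1x1 branch keeps its direct mapping
#' (a bottleneck there would only add parameters).
#'
#' @param cfg a [network_config()].
#' @param with_bottleneck count the bottlenecked variant?
#' @param in_channels block input channels (2 for a reference/moving pair).
#' @return Integer number of weight parameters.
#' @examples
#' count_inception_params(network_config(), with_bottleneck = FALSE)  # 3968
#' count_inception_params(network_config(), with_bottleneck = TRUE)   # 1994
#' @export
count_inception_params <- function(cfg = network_config(), with_bottleneck = TRUE,
                                   in_channels = 2L) {
  out <- cfg$inception_branch_out
  bott <- cfg$bottleneck_channels
  total <- 0L
  for (k in cfg$inception_kernels) {
    total <- total + if (!with_bottleneck || k == 1L) {
      in_channels * k^3 * out
    } else {
      in_channels * 1L * bott + bott * k^3 * out
    }
  }
  as.integer(total)
}

# ---- inception block --------------------------------------------------------

inception_param_list <- function(cfg, in_channels, use_bottleneck = TRUE) {
  ps <- list()
  for (k in cfg$inception_kernels) {
    nm <- paste0("b", k)
    if (k == 1L || !use_bottleneck) {
      ps[[nm]] <- conv_param(k, in_channels, cfg$inception_branch_out)
    } else {
      ps[[paste0(nm, "_bott")]] <- conv_param(1L, in_channels, cfg$bottleneck_channels)
      ps[[nm]] <- conv_param(k, cfg$bottleneck_channels, cfg$inception_branch_out)
    }
  }
  ps
}

#' Instantiate a standalone multiscale Inception block
#'
#' Parallel convolution branches, one per kernel size, each padded to
#' preserve the spatial shape, with 1x1x1 bottleneck reductions before the
#' large-kernel branches; branch outputs are concatenated along the channel
#' dimension.  Every convolution is followed by a LeakyReLU.
#'
#' @param cfg a [network_config()].
#' @param in_channels input channels (default 2).
#' @param use_bottleneck include the bottleneck layers (default `TRUE`).
#' @param seed optional RNG seed for reproducible initialization.
#' @return An object of class `mh_inception_block`.
#' @export
inception_block <- function(cfg = network_config(), in_channels = 2L,
                            use_bottleneck = TRUE, seed = NULL) {
  make <- function() inception_param_list(cfg, in_channels, use_bottleneck)
  params <- if (is.null(seed)) make() else with_seed(seed, make())
  structure(list(params = params, cfg = cfg, in_channels = as.integer(in_channels),
                 use_bottleneck = isTRUE(use_bottleneck)),
            class = "mh_inception_block")
}

#' Programmatic parameter count of a block or network
#'
#' @param x an [inception_block()] or a network built by [build_network()].
#' @param include_bias count bias terms too?
#' @return Integer parameter count.
#' @export
n_params <- function(x, include_bias = TRUE) {
  ps <- if (inherits(x, "mh_network")) x$params else x$params
  total <- 0L
  for (p in ps) {
    total <- total + length(p$W)
    if (include_bias) total <- total + length(p$b)
  }
  as.integer(total)
}

incep_fwd <- function(params, cfg, x, slope, keep = FALSE) {
  outs <- list()
  cache <- if (keep) list(x = x, branches = list()) else NULL
  for (k in cfg$inception_kernels) {
    nm <- paste0("b", k)
    bnm <- paste0(nm, "_bott")
    inb <- x
    br <- list()
    if (!is.null(params[[bnm]])) {
      pre_b <- conv_fwd(params[[bnm]], x)
      inb <- leaky_fwd(pre_b, slope)
      if (keep) { br$pre_b <- pre_b; br$inb <- inb }
    }
    pre <- conv_fwd(params[[nm]], inb, stride = 1L)
    outs[[nm]] <- leaky_fwd(pre, slope)
    if (keep) { br$pre <- pre; br$inb_final <- inb; cache$branches[[nm]] <- br }
  }
  y <- do.call(cat_channels, outs)
  list(y = y, cache = cache)
}

incep_bwd <- function(params, cfg, cache, gy, slope) {
  grads <- list()
  gx <- array(0, dim(cache$x))
  off <- 0L
  for (k in cfg$inception_kernels) {
    nm <- paste0("b", k)
    bnm <- paste0(nm, "_bott")
    br <- cache$branches[[nm]]
    cout <- cfg$inception_branch_out
    g_out <- gy[, , , off + seq_len(cout), drop = FALSE]
    off <- off + cout
    g_pre <- leaky_bwd(br$pre, g_out, slope)
    cb <- conv_bwd(params[[nm]], br$inb_final, g_pre)
    grads[[nm]] <- list(W = cb$gW, b = cb$gb)
    if (!is.null(params[[bnm]])) {
      g_inb <- leaky_bwd(br$pre_b, cb$gx, slope)
      bb <- conv_bwd(params[[bnm]], cache$x, g_inb)
      grads[[bnm]] <- list(W = bb$gW, b = bb$gb)
      gx <- gx + bb$gx
    } else {
      gx <- gx + cb$gx
    }
  }
  list(gx = gx, grads = grads)
}

#' Apply an Inception block to a 4D feature map
#'
#' @param block an [inception_block()].
#' @param x numeric 4D array (X, Y, Z, C) with `C == block$in_channels`.
#' @return A 4D array with `length(kernels) * inception_branch_out` channels
#'   and unchanged spatial shape.
#' @export
block_forward <- function(block, x) {
  if (dim(x)[4] != block$in_channels)
    stop("block expects ", block$in_channels, " channels, got ", dim(x)[4])
  incep_fwd(block$params, block$cfg, x, block$cfg$leaky_slope)$y
}

# ---- full network -----------------------------------------------------------

#' Build the registration network
#'
#' Constructs the trainable network: a multiscale Inception block on the
#' 2-channel (reference, moving) input, a 4-level encoder of stride-2 +
#' stride-1 3x3x3 convolutions (each followed by LeakyReLU), a decoder of
#' four (trilinear x2 upsample, skip concatenation, convolution) stages, and
#' -- unless disabled -- hierarchical forecast heads that read the three
#' coarsest decoder maps, upsample them by factors 8, 4 and 2, and convolve
#' each to a 3-channel field; the final field fuses the three intermediate
#' fields and the end-of-decoder field through a 1x1x1 convolution.
#'
#' Input spatial dimensions must be divisible by 16 (the bottom feature map
#' is 1/16 of the input per axis).
#'
#' @param cfg a [network_config()].
#' @param seed optional RNG seed; two builds with the same seed have
#'   identical initial parameters.
#' @return An object of class `mh_network`.
#' @export
build_network <- function(cfg = network_config(), seed = NULL) {
  make <- function() {
    nfeat <- length(cfg$inception_kernels) * cfg$inception_branch_out
    ps <- list()
    if (cfg$use_inception) {
      ps <- inception_param_list(cfg, 2L, use_bottleneck = TRUE)
      names(ps) <- paste0("incep_", names(ps))
    } else {
      ps$incep_plain <- conv_param(3L, 2L, nfeat)
    }
    ec <- cfg$enc_channels
    prev <- nfeat
    for (l in 1:4) {
      ps[[paste0("enc", l, "_down")]] <- conv_param(3L, prev, ec[l])
      ps[[paste0("enc", l, "_same")]] <- conv_param(3L, ec[l], ec[l])
      prev <- ec[l]
    }
    dc <- cfg$dec_channels
    skip <- c(ec[3], ec[2], ec[1], nfeat)
    prev <- ec[4]
    for (l in 1:4) {
      ps[[paste0("dec", l)]] <- conv_param(3L, prev + skip[l], dc[l])
      prev <- dc[l]
    }
    fi <- if (cfg$init_fields == "small") "small" else "zero"
    ps$head_end <- conv_param(cfg$head_kernel, dc[4], 3L, init = fi)
    if (cfg$use_hierarchical) {
      ps$head_low  <- conv_param(cfg$head_kernel, dc[1], 3L, init = fi)
      ps$head_mid  <- conv_param(cfg$head_kernel, dc[2], 3L, init = fi)
      ps$head_high <- conv_param(cfg$head_kernel, dc[3], 3L, init = fi)
      ps$fuse <- fuse_param(4L)
    }
    ps
  }
  params <- if (is.null(seed)) make() else with_seed(seed, make())
  structure(list(cfg = cfg, params = params), class = "mh_network")
}

#' @export
print.mh_network <- function(x, ...) {
  cat("<mh_network> ", length(x$params), " conv layers, ",
      n_params(x), " parameters (",
      if (x$cfg$use_inception) "inception" else "plain first block", ", ",
      if (x$cfg$use_hierarchical) "hierarchical heads" else "end head only",
      ")\n", sep = "")
  invisible(x)
}

check_net_input <- function(f, m) {
  check_same_shape(f, m, "reference image", "moving image")
  d <- dim(f)[1:3]
  if (any(d %% 16L != 0L))
    stop("input spatial dimensions (", paste(d, collapse = ","),
         ") must be divisible by 16")
  invisible(d)
}

# Forward pass; with keep_cache the per-layer inputs and pre-activations are
# retained for the analytic backward pass.
net_forward <- function(net, x0, keep_cache = FALSE) {
  cfg <- net$cfg; ps <- net$params; sl <- cfg$leaky_slope
  cc <- list(x0 = x0)
  if (cfg$use_inception) {
    inames <- grep("^incep_", names(ps), value = TRUE)
    ipar <- ps[inames]; names(ipar) <- sub("^incep_", "", inames)
    ic <- incep_fwd(ipar, cfg, x0, sl, keep = keep_cache)
    xI <- ic$y
    cc$incep <- ic$cache
  } else {
    pre <- conv_fwd(ps$incep_plain, x0)
    xI <- leaky_fwd(pre, sl)
    cc$incep_plain_pre <- pre
  }
  cc$xI <- xI
  enc_out <- vector("list", 4)
  h <- xI
  for (l in 1:4) {
    pre_d <- conv_fwd(ps[[paste0("enc", l, "_down")]], h, stride = 2L)
    hd <- leaky_fwd(pre_d, sl)
    pre_s <- conv_fwd(ps[[paste0("enc", l, "_same")]], hd)
    h <- leaky_fwd(pre_s, sl)
    cc[[paste0("e", l)]] <- list(pre_d = pre_d, hd = hd, pre_s = pre_s, out = h)
    enc_out[[l]] <- h
  }
  skips <- list(enc_out[[3]], enc_out[[2]], enc_out[[1]], xI)
  h <- enc_out[[4]]
  dec_out <- vector("list", 4)
  for (l in 1:4) {
    up <- resize4d(h, dim(skips[[l]])[1:3])
    catx <- cat_channels(up, skips[[l]])
    pre <- conv_fwd(ps[[paste0("dec", l)]], catx)
    h <- leaky_fwd(pre, sl)
    cc[[paste0("d", l)]] <- list(catx = catx, pre = pre, out = h)
    dec_out[[l]] <- h
  }
  full <- dim(x0)[1:3]
  phi_end <- conv_fwd(ps$head_end, dec_out[[4]])
  fields <- list(phi_end = phi_end)
  if (cfg$use_hierarchical) {
    ups <- list()
    for (nm in c("low", "mid", "high")) {
      l <- match(nm, c("low", "mid", "high"))
      up <- resize4d(dec_out[[l]], full)
      ups[[nm]] <- up
      fields[[paste0("phi_", nm)]] <- conv_fwd(ps[[paste0("head_", nm)]], up)
    }
    cc$head_ups <- ups
    fcat <- cat_channels(fields$phi_low, fields$phi_mid, fields$phi_high, phi_end)
    cc$fcat <- fcat
    fields$phi_final <- conv_fwd(ps$fuse, fcat)
  } else {
    fields$phi_final <- phi_end
  }
  cc$dec_out <- if (keep_cache) dec_out else NULL
  list(fields = fields, cache = if (keep_cache) cc else NULL)
}

# Backward pass from a gradient on phi_final; returns per-layer W/b grads.
net_backward <- function(net, cache, g_final) {
  cfg <- net$cfg; ps <- net$params; sl <- cfg$leaky_slope
  grads <- list()
  dec_out <- cache$dec_out
  g_dec_head <- list(NULL, NULL, NULL)  # head gradients into decoder maps 1..3
  if (cfg$use_hierarchical) {
    fb <- conv_bwd(ps$fuse, cache$fcat, g_final)
    grads$fuse <- list(W = fb$gW, b = fb$gb)
    g_end <- fb$gx[, , , 10:12, drop = FALSE]
    for (nm in c("low", "mid", "high")) {
      l <- match(nm, c("low", "mid", "high"))
      gf <- fb$gx[, , , 3 * (l - 1) + 1:3, drop = FALSE]
      hb <- conv_bwd(ps[[paste0("head_", nm)]], cache$head_ups[[nm]], gf)
      grads[[paste0("head_", nm)]] <- list(W = hb$gW, b = hb$gb)
      g_dec_head[[l]] <- resize4d_bwd(hb$gx, dim(dec_out[[l]]))
    }
  } else {
    g_end <- g_final
  }
  eb <- conv_bwd(ps$head_end, dec_out[[4]], g_end)
  grads$head_end <- list(W = eb$gW, b = eb$gb)

  skip_ch <- c(cfg$enc_channels[3], cfg$enc_channels[2], cfg$enc_channels[1],
               length(cfg$inception_kernels) * cfg$inception_branch_out)
  g_skip <- vector("list", 4)
  g_h <- eb$gx  # gradient flowing into decoder output 4
  for (l in 4:1) {
    dcache <- cache[[paste0("d", l)]]
    g_pre <- leaky_bwd(dcache$pre, g_h, sl)
    cb <- conv_bwd(ps[[paste0("dec", l)]], dcache$catx, g_pre)
    grads[[paste0("dec", l)]] <- list(W = cb$gW, b = cb$gb)
    nup <- dim(dcache$catx)[4] - skip_ch[l]
    g_up <- cb$gx[, , , seq_len(nup), drop = FALSE]
    g_skip[[l]] <- cb$gx[, , , nup + seq_len(skip_ch[l]), drop = FALSE]
    src_dim <- if (l == 1) dim(cache$e4$out) else dim(dec_out[[l - 1]])
    g_h <- resize4d_bwd(g_up, src_dim)
    if (l > 1 && !is.null(g_dec_head[[l - 1]])) g_h <- g_h + g_dec_head[[l - 1]]
  }
  # g_h now targets encoder level-4 output; skips feed levels 3,2,1 and xI
  g_enc_out <- list(g_skip[[3]], g_skip[[2]], g_skip[[1]], g_h)
  g_xI <- g_skip[[4]]
  enc_in <- list(cache$xI, cache$e1$out, cache$e2$out, cache$e3$out)
  g_next <- NULL
  for (l in 4:1) {
    ecache <- cache[[paste0("e", l)]]
    g_out <- g_enc_out[[l]]
    if (!is.null(g_next)) g_out <- g_out + g_next
    g_pre_s <- leaky_bwd(ecache$pre_s, g_out, sl)
    sb <- conv_bwd(ps[[paste0("enc", l, "_same")]], ecache$hd, g_pre_s)
    grads[[paste0("enc", l, "_same")]] <- list(W = sb$gW, b = sb$gb)
    g_pre_d <- leaky_bwd(ecache$pre_d, sb$gx, sl)
    db <- conv_bwd(ps[[paste0("enc", l, "_down")]], enc_in[[l]], g_pre_d, stride = 2L)
    grads[[paste0("enc", l, "_down")]] <- list(W = db$gW, b = db$gb)
    g_next <- db$gx
  }
  g_xI <- g_xI + g_next
  if (cfg$use_inception) {
    inames <- grep("^incep_", names(ps), value = TRUE)
    ipar <- ps[inames]; names(ipar) <- sub("^incep_", "", inames)
    ib <- incep_bwd(ipar, cfg, cache$incep, g_xI, sl)
    names(ib$grads) <- paste0("incep_", names(ib$grads))
    grads <- c(grads, ib$grads)
  } else {
    g_pre <- leaky_bwd(cache$incep_plain_pre, g_xI, sl)
    pb <- conv_bwd(ps$incep_plain, cache$x0, g_pre)
    grads$incep_plain <- list(W = pb$gW, b = pb$gb)
  }
  grads
}

#' Run the network on a reference/moving pair
#'
#' Concatenates the two volumes along the channel dimension and produces the
#' forecast fields: the three intermediate fields `phi_low`, `phi_mid`,
#' `phi_high` (upsampled to full resolution; `NULL` when hierarchical
#' forecasting is disabled), the end-of-decoder field `phi_end`, and the
#' fused output `phi_final`.  Deterministic given parameters and inputs.
#'
#' @param net a network from [build_network()].
#' @param f,m reference and moving [volume()]s; equal spatial shapes,
#'   divisible by 16 per axis.
#' @return A list of class `mh_forecast` with elements `phi_low`, `phi_mid`,
#'   `phi_high`, `phi_end`, `phi_final`, each a [displacement_field()] (or
#'   `NULL` for disabled heads).
#' @export
mhnet_forward <- function(net, f, m) {
  d <- check_net_input(f, m)
  x0 <- cat_channels(array(unclass(f), c(d, 1L)), array(unclass(m), c(d, 1L)))
  fw <- net_forward(net, x0, keep_cache = FALSE)
  out <- lapply(fw$fields, function(ph) if (is.null(ph)) NULL else displacement_field(ph))
  out <- out[c(intersect(c("phi_low", "phi_mid", "phi_high"), names(out)),
               "phi_end", "phi_final")]
  structure(out, class = "mh_forecast")
}
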