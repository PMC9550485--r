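test_that("inception parameter counts reproduce the closed forms", {
  cfg <- network_config()
  expect_identical(count_inception_params(cfg, with_bottleneck = FALSE), 3968L)
  expect_identical(count_inception_params(cfg, with_bottleneck = TRUE), 1994L)

  # single 1x1x1 branch: 2 * 1 * 4 weights, bottleneck immaterial
  cfg1 <- network_config(inception_kernels = 1)
  expect_identical(count_inception_params(cfg1, FALSE), 8L)
  expect_identical(count_inception_params(cfg1, TRUE), 8L)

  # bottleneck always reduces when some kernel > 1 and bottleneck < input
  for (kern in list(c(1, 3), c(3, 5), c(1, 3, 5, 7), c(7))) {
    cfgk <- network_config(inception_kernels = kern)
    if (any(kern > 1)) {
      expect_lt(count_inception_params(cfgk, TRUE),
                count_inception_params(cfgk, FALSE))
    }
  }
})

test_that("instantiated block's weight count matches the formula exactly", {
  cfg <- network_config()
  blk_b <- inception_block(cfg, in_channels = 2, use_bottleneck = TRUE, seed = 1)
  blk_n <- inception_block(cfg, in_channels = 2, use_bottleneck = FALSE, seed = 1)
  expect_identical(n_params(blk_b, include_bias = FALSE), 1994L)
  expect_identical(n_params(blk_n, include_bias = FALSE), 3968L)

  cfg2 <- network_config(inception_kernels = c(1, 3, 5),
                         inception_branch_out = 6, bottleneck_channels = 2)
  blk2 <- inception_block(cfg2, in_channels = 4, use_bottleneck = TRUE, seed = 2)
  expect_identical(n_params(blk2, include_bias = FALSE),
                   count_inception_params(cfg2, TRUE, in_channels = 4))
})

test_that("inception block preserves spatial shape and concatenates branches", {
  cfg <- network_config()
  blk <- inception_block(cfg, in_channels = 2, seed = 3)
  set.seed(4)
  x <- array(rnorm(6 * 8 * 10 * 2), c(6, 8, 10, 2))
  y <- block_forward(blk, x)
  expect_identical(dim(y), c(6L, 8L, 10L, 16L))
  expect_error(block_forward(blk, array(0, c(6, 8, 10, 3))), "channels")
})

test_that("network output fields have the input shape; builds are seeded", {
  cfg <- network_config(enc_channels = c(4, 8, 8, 8), dec_channels = c(8, 8, 8, 4))
  net1 <- build_network(cfg, seed = 11)
  net2 <- build_network(cfg, seed = 11)
  expect_identical(net1$params, net2$params)
  net3 <- build_network(cfg, seed = 12)
  expect_false(identical(net3$params, net1$params))

  f <- rand_volume(c(32, 16, 16), seed = 13)
  m <- rand_volume(c(32, 16, 16), seed = 14)
  ff <- mhnet_forward(net1, f, m)
  for (nm in c("phi_low", "phi_mid", "phi_high", "phi_end", "phi_final"))
    expect_identical(dim(ff[[nm]]), c(32L, 16L, 16L, 3L))

  # deterministic forward
  ff2 <- mhnet_forward(net1, f, m)
  expect_identical(unclass(ff2$phi_final), unclass(ff$phi_final))

  bad <- rand_volume(c(30, 16, 16), seed = 15)
  expect_error(mhnet_forward(net1, bad, bad), "divisible by 16")
})

test_that("zero-initialized field convs make the untrained net the identity", {
  cfg <- network_config(enc_channels = c(4, 8, 8, 8), dec_channels = c(8, 8, 8, 4),
                        init_fields = "zero")
  net <- build_network(cfg, seed = 21)
  f <- rand_volume(c(16, 16, 16), seed = 22)
  m <- rand_volume(c(16, 16, 16), seed = 23)
  ff <- mhnet_forward(net, f, m)
  expect_true(all(unclass(ff$phi_final) == 0))
  expect_equal(unclass(warp(m, ff$phi_final)), unclass(m), ignore_attr = TRUE)

  # the default small-normal init is a near-identity start
  netd <- build_network(network_config(enc_channels = c(4, 8, 8, 8),
                                       dec_channels = c(8, 8, 8, 4)), seed = 21)
  ffd <- mhnet_forward(netd, f, m)
  expect_lt(max(abs(unclass(ffd$phi_final))), 1e-3)
})

test_that("hierarchical ablation collapses phi_final onto phi_end", {
  cfg <- network_config(enc_channels = c(4, 8, 8, 8), dec_channels = c(8, 8, 8, 4),
                        use_hierarchical = FALSE)
  net <- build_network(cfg, seed = 31)
  f <- rand_volume(c(16, 16, 16), seed = 32)
  m <- rand_volume(c(16, 16, 16), seed = 33)
  ff <- mhnet_forward(net, f, m)
  expect_identical(unclass(ff$phi_final), unclass(ff$phi_end))
  expect_null(ff$phi_low)

  # all four ablation variants construct and run forward without error
  for (ui in c(TRUE, FALSE)) for (uh in c(TRUE, FALSE)) {
    cfgv <- network_config(enc_channels = c(4, 8, 8, 8),
                           dec_channels = c(8, 8, 8, 4),
                           use_inception = ui, use_hierarchical = uh)
    netv <- build_network(cfgv, seed = 34)
    ffv <- mhnet_forward(netv, f, m)
    expect_identical(dim(ffv$phi_final), c(16L, 16L, 16L, 3L))
  }
})

test_that("one backward pass reaches every parameter with exact gradients", {
  cfg <- network_config(enc_channels = c(4, 8, 8, 8), dec_channels = c(8, 8, 8, 4))
  net <- build_network(cfg, seed = 41)
  pair <- make_pair(phantom_spec(shape = c(16, 16, 16), seed = 42))
  x0 <- net_input(pair$fixed, pair$moving)
  lcfg <- loss_config(ncc_window = 5)

  fw <- mhnet:::net_forward(net, x0, keep_cache = TRUE)
  lg <- mhnet:::total_loss_with_grad(pair$fixed, pair$moving,
                                     displacement_field(fw$fields$phi_final), lcfg)
  gr <- mhnet:::net_backward(net, fw$cache, lg$grad_phi)

  # gradient-presence audit: every layer, weights and biases
  expect_setequal(names(gr), names(net$params))
  for (nm in names(gr)) {
    expect_gt(sum(abs(gr[[nm]]$W)), 0)
    expect_gt(sum(abs(gr[[nm]]$b)), 0)
  }

  # finite-difference spot check away from the interpolation kinks: offset
  # the end-head bias so predicted displacements avoid integer crossings
  net$params$head_end$b <- c(0.31, -0.27, 0.23)
  fw <- mhnet:::net_forward(net, x0, keep_cache = TRUE)
  lg <- mhnet:::total_loss_with_grad(pair$fixed, pair$moving,
                                     displacement_field(fw$fields$phi_final), lcfg)
  gr <- mhnet:::net_backward(net, fw$cache, lg$grad_phi)
  lossat <- function(nt) {
    fwx <- mhnet:::net_forward(nt, x0)
    total_loss(pair$fixed, pair$moving,
               displacement_field(fwx$fields$phi_final), lcfg)
  }
  set.seed(43)
  for (lay in c("incep_b7_bott", "enc2_down", "dec3", "head_mid", "fuse")) {
    i <- sample(length(net$params[[lay]]$W), 1)
    h <- 1e-5
    np <- net; np$params[[lay]]$W[i] <- np$params[[lay]]$W[i] + h
    nm_ <- net; nm_$params[[lay]]$W[i] <- nm_$params[[lay]]$W[i] - h
    fd <- (lossat(np) - lossat(nm_)) / (2 * h)
    expect_equal(gr[[lay]]$W[i], fd, tolerance = 1e-2)
  }
})
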