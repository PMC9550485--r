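light_net <- function(...) {
  network_config(enc_channels = c(4, 8, 8, 8), dec_channels = c(8, 8, 8, 4), ...)
}

test_that("iteration accounting and learning-rate schedule", {
  cfg <- train_config(epochs = 70, lr = 1e-4, lr_halve_epoch = 40)
  sched <- train_schedule(cfg, n_pairs = 625)
  expect_identical(attr(sched, "total_steps"), 43750L)
  expect_equal(sched$lr[sched$epoch < 40], rep(1e-4, 39))
  expect_equal(sched$lr[sched$epoch == 40], 5e-5)
  expect_equal(sched$lr[sched$epoch == 70], 5e-5)

  expect_error(train_config(epochs = 10, lr_halve_epoch = 20), "<= epochs")
})

test_that("one pair, one epoch takes exactly one optimization step", {
  pair <- make_pair(phantom_spec(shape = c(16, 16, 16), seed = 51))
  cfg <- train_config(epochs = 1, lr = 1e-3, lr_halve_epoch = 1, seed = 52,
                      network = light_net(),
                      loss = loss_config(ncc_window = 5))
  fit <- train(list(list(fixed = pair$fixed, moving = pair$moving)), cfg)
  expect_identical(nrow(fit$history), 1L)
  expect_true(is.finite(fit$history$loss))
  expect_equal(fit$history$lr, 5e-4)  # halved from epoch 1 = lr_halve_epoch
})

test_that("training is reproducible and reduces the loss on a fixture pair", {
  pair <- make_pair(phantom_spec(shape = c(16, 16, 16), seed = 61))
  pairs <- list(list(fixed = pair$fixed, moving = pair$moving))
  cfg <- train_config(epochs = 10, lr = 2e-3, lr_halve_epoch = 8, seed = 62,
                      network = light_net(),
                      loss = loss_config(ncc_window = 5))
  fit1 <- train(pairs, cfg)
  fit2 <- train(pairs, cfg)
  expect_identical(fit1$history$loss, fit2$history$loss)
  expect_identical(fit1$network$params, fit2$network$params)

  expect_lt(fit1$history$loss[10], fit1$history$loss[1])

  # a different seed gives a different trajectory
  cfg3 <- cfg; cfg3$seed <- 63L
  fit3 <- train(pairs, cfg3)
  expect_false(identical(fit3$history$loss, fit1$history$loss))
})

test_that("register_pair warps deterministically and beats misalignment", {
  pair <- make_pair(phantom_spec(shape = c(16, 16, 16), seed = 71,
                                 deform_amplitude = 2))
  pairs <- list(list(fixed = pair$fixed, moving = pair$moving))
  cfg <- train_config(epochs = 15, lr = 2e-3, lr_halve_epoch = 12, seed = 72,
                      network = light_net(),
                      loss = loss_config(ncc_window = 5))
  fit <- train(pairs, cfg)

  r1 <- register_pair(fit, pair$fixed, pair$moving)
  r2 <- register_pair(fit$network, pair$fixed, pair$moving)
  expect_identical(unclass(r1$field), unclass(r2$field))
  expect_identical(dim(r1$field), c(16L, 16L, 16L, 3L))

  # registration must improve on the unregistered NCC
  ncc_before <- ncc(pair$fixed, pair$moving)
  ncc_after <- ncc(pair$fixed, r1$warped)
  expect_gt(ncc_after, ncc_before)

  # and on self-registration the predicted warp must not hurt alignment
  rs <- register_pair(fit, pair$fixed, pair$fixed)
  expect_gte(ncc(pair$fixed, rs$warped) + 1e-3, ncc_before)
})

test_that("training guards inputs: empty sets and heterogeneous shapes", {
  expect_error(train(list(), train_config()), "no training pairs")
  p1 <- make_pair(phantom_spec(shape = c(16, 16, 16), seed = 81))
  p2 <- make_pair(phantom_spec(shape = c(32, 32, 32), seed = 82))
  expect_error(train(list(list(fixed = p1$fixed, moving = p1$moving),
                          list(fixed = p2$fixed, moving = p2$moving)),
                     train_config(network = light_net())),
               "share one spatial shape")
})

test_that("checkpoints reload to an identical network", {
  tmp <- make_tempdir()
  net <- build_network(light_net(), seed = 91)
  save_network(net, file.path(tmp, "ck.rds"))
  net2 <- load_network(file.path(tmp, "ck.rds"))
  expect_identical(net2$params, net$params)
  expect_identical(net2$cfg, net$cfg)
})

test_that("held-out monitor records per-epoch validation loss", {
  p1 <- make_pair(phantom_spec(shape = c(16, 16, 16), seed = 95))
  p2 <- make_pair(phantom_spec(shape = c(16, 16, 16), seed = 96))
  cfg <- train_config(epochs = 2, lr = 1e-3, lr_halve_epoch = 2, seed = 97,
                      network = light_net(),
                      loss = loss_config(ncc_window = 5))
  fit <- train(list(list(fixed = p1$fixed, moving = p1$moving)), cfg,
               monitor_pairs = list(list(fixed = p2$fixed, moving = p2$moving)))
  expect_true("monitor_loss" %in% names(fit$history))
  expect_true(all(is.finite(fit$history$monitor_loss)))

  # monitoring must not perturb the training trajectory
  fit0 <- train(list(list(fixed = p1$fixed, moving = p1$moving)), cfg)
  expect_identical(fit0$history$loss, fit$history$loss)
})
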