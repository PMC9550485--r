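test_that("ncc self-similarity, affine invariance and degenerate cases", {
  f <- rand_volume(c(10, 10, 10), seed = 61)
  cfg <- loss_config(ncc_window = 5)

  expect_equal(ncc(f, f, cfg), 1, tolerance = 1e-4)
  expect_equal(ncc(f, volume(2 * unclass(f) + 3), cfg), 1, tolerance = 1e-4)
  expect_equal(ncc(f, volume(-0.5 * unclass(f) + 1), cfg), 1, tolerance = 1e-4)

  # constant second image: zero correlation by the eps convention
  const <- volume(array(0.7, dim(f)))
  expect_equal(ncc(f, const, cfg), 0, tolerance = 1e-10)

  # bounded in [0,1] for arbitrary pairs
  for (seed in 1:6) {
    w <- rand_volume(dim(f), seed = 400 + seed)
    v <- ncc(f, w, cfg)
    expect_true(v >= 0 && v <= 1 + 1e-9)
  }
})

test_that("ncc matches the explicit-window oracle and is symmetric", {
  for (seed in 1:5) {
    f <- rand_volume(c(5, 5, 5), seed = 500 + seed)
    w <- rand_volume(c(5, 5, 5), seed = 600 + seed)
    cfg <- loss_config(ncc_window = 3)
    expect_equal(ncc(f, w, cfg), oracle_ncc(unclass(f), unclass(w), 3),
                 tolerance = 1e-10)
    expect_lt(abs(ncc(f, w, cfg) - ncc(w, f, cfg)), 1e-6)
  }
  # single 3^3 window with hand-listed values
  vals_f <- array(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 2, 4, 1, 3, 5, 2, 4, 1, 3,
                    5, 3, 1, 2, 4, 6, 1, 3, 5), c(3, 3, 3))
  vals_w <- array(c(2, 1, 4, 3, 6, 5, 8, 7, 9, 1, 2, 3, 1, 2, 3, 1, 2, 3,
                    4, 4, 4, 2, 2, 2, 6, 6, 6), c(3, 3, 3))
  expect_equal(ncc(volume(vals_f), volume(vals_w), loss_config(ncc_window = 3)),
               oracle_ncc(vals_f, vals_w, 3), tolerance = 1e-12)
})

test_that("similarity loss is -NCC of the warped pair", {
  pair <- make_pair(phantom_spec(shape = c(16, 16, 16), seed = 9,
                                 noise_sd = 0))
  cfg <- loss_config()
  # self-registration of a volume that is non-constant in every window
  f <- rand_volume(c(16, 16, 16), seed = 90)
  expect_equal(similarity_loss(f, f, zero_field(c(16, 16, 16)), cfg),
               -1, tolerance = 1e-3)

  # uncorrelated constant moving image
  const <- volume(array(0.3, c(16, 16, 16)))
  expect_equal(similarity_loss(pair$fixed, const, zero_field(c(16, 16, 16)), cfg),
               0, tolerance = 1e-8)

  # improves monotonically along the path phi_t = t * truth from the moving
  # image back toward alignment (truth generated the pair)
  ls <- vapply(c(0, 0.5, 1), function(t) {
    phi <- displacement_field(t * unclass(pair$truth))
    # registering moving to fixed means resampling fixed-side grid; evaluate
    # alignment of the re-warped fixed image against moving
    -ncc(pair$moving, warp(pair$fixed, phi), cfg)
  }, 0)
  expect_true(ls[2] < ls[1] && ls[3] < ls[2])
})

test_that("smoothness loss closed forms: constants, ramps, invariance", {
  d <- c(6, 6, 6)
  const <- zero_field(d)
  const[, , , 1] <- 2.5; const[, , , 2] <- -1; const[, , , 3] <- 0.25
  expect_equal(smoothness_loss(displacement_field(unclass(const))), 0)

  # u_x(x,y,z) = x: unit forward difference along x only -> total 1
  ramp <- zero_field(d)
  ramp[, , , 1] <- array(rep(0:(d[1] - 1), times = prod(d[2:3])), d)
  expect_equal(smoothness_loss(displacement_field(unclass(ramp))), 1)

  # adding a global constant changes nothing
  phi <- rand_field(d, seed = 71, max_disp = 2)
  shifted <- displacement_field(unclass(phi) + 3.14)
  expect_equal(smoothness_loss(shifted), smoothness_loss(phi), tolerance = 1e-12)

  # zero iff constant
  expect_gt(smoothness_loss(phi), 0)
})

test_that("total loss is the weighted sum of its parts", {
  pair <- make_pair(phantom_spec(shape = c(16, 16, 16), seed = 13))
  phi <- displacement_field(0.4 * unclass(pair$truth))
  for (prm in list(c(1, 3), c(1, 0), c(2.5, 0.7))) {
    cfg <- loss_config(alpha = prm[1], lambda = prm[2])
    expect_equal(total_loss(pair$fixed, pair$moving, phi, cfg),
                 prm[1] * similarity_loss(pair$fixed, pair$moving, phi, cfg) +
                   prm[2] * smoothness_loss(phi),
                 tolerance = 1e-12)
  }
  # perfectly aligned pair with alpha=1, lambda=3: components -1 and 0
  f <- rand_volume(c(16, 16, 16), seed = 91)
  expect_equal(total_loss(f, f, zero_field(c(16, 16, 16)),
                          loss_config(alpha = 1, lambda = 3)),
               -1, tolerance = 1e-3)
})

test_that("total loss gradient w.r.t. the field matches finite differences", {
  d <- c(6, 6, 6)
  f <- rand_volume(d, seed = 81)
  m <- rand_volume(d, seed = 82)
  phi <- rand_field(d, seed = 83, max_disp = 0.8)
  cfg <- loss_config(ncc_window = 3)
  lg <- mhnet:::total_loss_with_grad(f, m, phi, cfg)
  u0 <- unclass(phi)
  set.seed(84)
  for (i in sample(length(u0), 30)) {
    h <- 1e-5
    up <- u0; up[i] <- up[i] + h
    um <- u0; um[i] <- um[i] - h
    fd <- (total_loss(f, m, displacement_field(up), cfg) -
             total_loss(f, m, displacement_field(um), cfg)) / (2 * h)
    expect_equal(lg$grad_phi[i], fd, tolerance = 1e-3)
  }
})
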