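test_that("identity and integer-shift displacements behave exactly", {
  v <- rand_volume(c(6, 6, 6), seed = 21)
  d <- dim(v)

  expect_equal(unclass(warp(v, zero_field(d))), unclass(v), ignore_attr = TRUE)

  shift <- zero_field(d); shift[, , , 1] <- 1
  w <- warp(v, displacement_field(unclass(shift)))
  expect_equal(unclass(w)[1:5, , ], unclass(v)[2:6, , ], ignore_attr = TRUE)
  # clamp boundary repeats the border plane
  expect_equal(unclass(w)[6, , ], unclass(v)[6, , ], ignore_attr = TRUE)

  zf <- warp(v, displacement_field(unclass(shift)), warp_config("zeros"))
  expect_equal(unclass(zf)[1:5, , ], unclass(v)[2:6, , ], ignore_attr = TRUE)
  expect_true(all(unclass(zf)[6, , ] == 0))
})

test_that("half-voxel shift of a ramp interpolates linearly", {
  d <- c(8, 6, 6)
  ramp <- volume(array(rep(0:(d[1] - 1), times = prod(d[2:3])), d))
  u <- zero_field(d); u[, , , 1] <- 0.5
  w <- warp(ramp, displacement_field(unclass(u)))
  interior <- unclass(w)[1:(d[1] - 1), , ]
  expected <- array(rep(0:(d[1] - 2) + 0.5, times = prod(d[2:3])),
                    c(d[1] - 1, d[2:3]))
  expect_equal(interior, expected, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("warp matches the explicit-loop trilinear oracle on random cases", {
  for (seed in 1:12) {
    shape <- c(6, 8, 10)[1 + (seed + 0:2) %% 3]
    v <- rand_volume(shape, seed = 100 + seed)
    phi <- rand_field(shape, seed = 200 + seed, max_disp = 3)
    got <- unclass(warp(v, phi))
    want <- oracle_warp(unclass(v), unclass(phi))
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("warp under clamp is convex and linear in the image", {
  shape <- c(7, 7, 7)
  phi <- rand_field(shape, seed = 31, max_disp = 2.5)
  m1 <- rand_volume(shape, seed = 32)
  m2 <- rand_volume(shape, seed = 33)

  w1 <- unclass(warp(m1, phi))
  expect_true(all(w1 >= min(m1) - 1e-12 & w1 <= max(m1) + 1e-12))

  lhs <- warp(volume(2 * unclass(m1) - 3 * unclass(m2) + 4), phi)
  rhs <- 2 * unclass(warp(m1, phi)) - 3 * unclass(warp(m2, phi)) + 4
  expect_equal(unclass(lhs), rhs, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("warp gradients match central finite differences", {
  shape <- c(6, 6, 6)
  m <- rand_volume(shape, seed = 41)
  phi <- rand_field(shape, seed = 42, max_disp = 1.5)
  set.seed(43)
  gy <- array(rnorm(prod(shape)), shape)
  loss <- function(u) sum(gy * unclass(warp(m, displacement_field(u))))
  gr <- mhnet:::warp_backward(m, phi, gy)

  u0 <- unclass(phi)
  idx <- sample(length(u0), 25)
  h <- 1e-6
  for (i in idx) {
    up <- u0; up[i] <- up[i] + h
    um <- u0; um[i] <- um[i] - h
    fd <- (loss(up) - loss(um)) / (2 * h)
    expect_equal(gr$grad_phi[i], fd, tolerance = 1e-3)
  }
  # gradient w.r.t. the image: warp is linear in m, so FD is exact
  m0 <- unclass(m)
  for (i in sample(length(m0), 10)) {
    mp <- m0; mp[i] <- mp[i] + 1
    fd <- sum(gy * unclass(warp(volume(mp), phi))) - loss(u0)
    expect_equal(gr$grad_m[i], fd, tolerance = 1e-8)
  }
})

test_that("label warping is nearest-neighbour and closed over the label set", {
  pair <- make_pair(phantom_spec(shape = c(16, 16, 16), seed = 7))
  l <- pair$fixed_labels
  d <- dim(l)

  expect_identical(unclass(warp_labels(l, zero_field(d))), unclass(l),
                   ignore_attr = TRUE)

  shift <- zero_field(d); shift[, , , 2] <- 1
  wl <- warp_labels(l, displacement_field(unclass(shift)))
  expect_identical(unclass(wl)[, 1:15, ], unclass(l)[, 2:16, ],
                   ignore_attr = TRUE)

  for (seed in 1:8) {
    phi <- rand_field(c(8, 8, 8), seed = 300 + seed, max_disp = 3)
    small <- label_map(unclass(l)[1:8, 1:8, 1:8])
    wl <- warp_labels(small, phi)
    expect_true(all(unique(as.vector(unclass(wl))) %in%
                      unique(as.vector(unclass(small)))))
  }
})

test_that("shape mismatches raise shape errors naming both operands", {
  v <- rand_volume(c(6, 6, 6), seed = 51)
  phi <- zero_field(c(8, 8, 8))
  expect_error(warp(v, phi), "6,6,6.*8,8,8")
  expect_error(warp_labels(label_map(array(0L, c(6, 6, 6))), phi), "8,8,8")
})
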