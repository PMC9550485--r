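# Independent reference implementations used to validate the fast kernels.
# Deliberately naive: explicit loops, no shared code with the package paths.

# Explicit-loop trilinear warp oracle, clamp-to-border boundary.
oracle_warp <- function(m, u) {
  d <- dim(m)
  out <- array(0, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    px <- (x - 1) + u[x, y, z, 1]
    py <- (y - 1) + u[x, y, z, 2]
    pz <- (z - 1) + u[x, y, z, 3]
    px <- min(max(px, 0), d[1] - 1)
    py <- min(max(py, 0), d[2] - 1)
    pz <- min(max(pz, 0), d[3] - 1)
    x0 <- floor(px); y0 <- floor(py); z0 <- floor(pz)
    fx <- px - x0; fy <- py - y0; fz <- pz - z0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      # corner weight prod_d (1 - |j_d - p_d|); at a border where the two
      # corners coincide the pair of weights still sums to 1
      w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
           (if (dz) fz else 1 - fz)
      jx <- min(x0 + dx, d[1] - 1); jy <- min(y0 + dy, d[2] - 1)
      jz <- min(z0 + dz, d[3] - 1)
      acc <- acc + w * m[jx + 1, jy + 1, jz + 1]
    }
    out[x, y, z] <- acc
  }
  out
}

# Explicit windowed squared local cross-correlation, border-clipped windows.
oracle_ncc <- function(f, w, win, eps = 1e-5) {
  d <- dim(f)
  r <- (win - 1) %/% 2
  total <- 0
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    xs <- max(1, x - r):min(d[1], x + r)
    ys <- max(1, y - r):min(d[2], y + r)
    zs <- max(1, z - r):min(d[3], z + r)
    fw_ <- f[xs, ys, zs]; ww_ <- w[xs, ys, zs]
    fc <- fw_ - mean(fw_); wc <- ww_ - mean(ww_)
    cross <- sum(fc * wc)
    total <- total + cross^2 / (sum(fc^2) * sum(wc^2) + eps)
  }
  total / prod(d)
}

# Small deterministic random volume/field builders for parameterised tests.
rand_volume <- function(shape, seed) {
  set.seed(seed)
  volume(array(runif(prod(shape)), shape))
}

rand_field <- function(shape, seed, max_disp = 3) {
  set.seed(seed)
  displacement_field(array(runif(prod(shape) * 3, -max_disp, max_disp),
                           c(shape, 3L)))
}

net_input <- function(f, m) {
  d <- dim(f)[1:3]
  mhnet:::cat_channels(array(unclass(f), c(d, 1L)), array(unclass(m), c(d, 1L)))
}

make_tempdir <- function() {
  d <- tempfile("mhnet-test-")
  dir.create(d)
  d
}
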