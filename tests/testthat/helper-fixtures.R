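# Fixtures built in code; all deterministic.

# solid sphere of radius r centred in an n^3 domain (voxel-centre membership)
sphere_mask <- function(n, r, center = rep((n + 1) / 2, 3)) {
  cx <- seq_len(n) - 0.5 - (center[1] - 0.5)
  arr <- array(FALSE, c(n, n, n))
  for (k in seq_len(n)) {
    dz2 <- (k - 0.5 - (center[3] - 0.5))^2
    arr[, , k] <- outer(cx^2, cx^2, `+`) + dz2 <= r^2
  }
  arr
}

# laminate: solid plates of thickness `t` alternating with pores, normal z
laminate_mask <- function(n, t) {
  pattern <- rep(rep(c(TRUE, FALSE), each = t), length.out = n)
  arr <- array(FALSE, c(n, n, n))
  for (k in seq_len(n)) arr[, , k] <- pattern[k]
  arr
}

# L-shaped single-voxel channel: straight run then a diagonal staircase;
# 26-connected geodesic length (50 + 50 sqrt(2)) voxels over extent 100
l_channel <- function() {
  d <- c(60, 8, 101)
  solid <- array(TRUE, d)
  for (k in 1:51) solid[4, 4, k] <- FALSE
  for (i in 0:50) solid[4 + i, 4, 51 + i] <- FALSE
  binary_microstructure(solid, 1)
}

# rectangular L-channel (axial 50, lateral 50, axial 50): 6-connected
# geodesic length 150 voxels over extent 100
l_channel_rect <- function() {
  d <- c(60, 8, 101)
  solid <- array(TRUE, d)
  for (k in 1:51) solid[4, 4, k] <- FALSE
  for (i in 4:54) solid[i, 4, 51] <- FALSE
  for (k in 51:101) solid[54, 4, k] <- FALSE
  binary_microstructure(solid, 1)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
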