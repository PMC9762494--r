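# Exact 3D Euclidean distance transform.
#
# Distance from every foreground (TRUE) voxel to the nearest background
# voxel centre, in voxel units. Computed separably: an axial two-pass
# chamfer along the first dimension gives exact 1D distances, then the
# squared-distance minimization D2(i) = min_s (D2(i+s) + s^2) is applied
# along the remaining dimensions by scanning shifts up to the current
# maximum distance (exact, since the 1D lower envelope is realized at some
# integer shift).
edt3 <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  d <- dim(mask)
  big <- sum(d)^2
  # 1D distances along dim 1
  n <- d[1]
  D <- array(ifelse(mask, Inf, 0), d)
  for (i in 2:n) {
    D <- assign_dim(D, 1L, i, pmin(index_dim(D, 1L, i), index_dim(D, 1L, i - 1L) + 1))
  }
  for (i in (n - 1):1) {
    D <- assign_dim(D, 1L, i, pmin(index_dim(D, 1L, i), index_dim(D, 1L, i + 1L) + 1))
  }
  g <- D^2
  g[!is.finite(g)] <- big
  for (dd in 2:3) {
    # shifts up to the largest current distance suffice; lines with no
    # background at all (g == big) force a full scan
    bound <- if (any(g >= big)) d[dd] - 1L else ceiling(sqrt(max(g, 0)))
    smax <- min(d[dd] - 1L, bound)
    if (smax >= 1) {
      out <- g
      for (s in c(-(smax:1), 1:smax)) {
        out <- pmin(out, shift3(g, dd, s, fill = big) + s^2)
      }
      g <- out
    }
  }
  sqrt(g)
}
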