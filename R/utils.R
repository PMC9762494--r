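# Internal array helpers shared across modules.

# Shift a 3D array by `s` voxels along dimension `d`, filling with `fill`.
shift3 <- function(a, d, s, fill = 0) {
  if (s == 0) return(a)
  n <- dim(a)[d]
  if (abs(s) >= n) return(array(fill, dim(a)))
  out <- array(fill, dim(a))
  src <- if (s > 0) 1:(n - s) else (1 - s):n
  dst <- if (s > 0) (1 + s):n else 1:(n + s)
  idx_src <- rep(list(quote(expr = )), 3)
  idx_dst <- idx_src
  idx_src[[d]] <- src
  idx_dst[[d]] <- dst
  out_call <- as.call(c(list(quote(`[<-`), quote(out)), idx_dst,
                        list(as.call(c(list(quote(`[`), quote(a)), idx_src)))))
  eval(out_call)
}

# Running (clipped-window) sum along dimension d with half-width r,
# via cumulative sums; window shrinks at the edges.
box_sum_1d <- function(a, d, r) {
  if (r == 0) return(a)
  n <- dim(a)[d]
  cs <- apply_along(a, d, function(v) cumsum(v))
  hi <- pmin(seq_len(n) + r, n)
  lo <- seq_len(n) - r - 1
  take <- function(arr, idx) index_dim(arr, d, idx)
  upper <- take(cs, hi)
  lower <- array(0, dim(a))
  pos <- lo >= 1
  if (any(pos)) {
    sel <- which(pos)
    lower <- assign_dim(lower, d, sel, take(cs, lo[sel]))
  }
  upper - lower
}

# Apply a vectorized function along dimension d of a 3D array (keeps shape).
apply_along <- function(a, d, f) {
  p <- c(d, setdiff(1:3, d))
  ap <- aperm(a, p)
  m <- matrix(ap, nrow = dim(a)[d])
  m <- apply(m, 2, f)
  aperm(array(m, dim(a)[p]), order(p))
}

# a[, idx along dim d, ] generalized.
index_dim <- function(a, d, idx) {
  args <- rep(list(quote(expr = )), 3)
  args[[d]] <- idx
  do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

assign_dim <- function(a, d, idx, value) {
  args <- rep(list(quote(expr = )), 3)
  args[[d]] <- idx
  do.call(`[<-`, c(list(a), args, list(value)))
}

# Voxel-center coordinate grids (micrometres), centre of voxel i at (i - 0.5) * h.
voxel_centers <- function(n, h) (seq_len(n) - 0.5) * h

# 26-neighbourhood offsets (excluding origin) and their Euclidean lengths.
neighbor_offsets_26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  list(offsets = g, lengths = sqrt(rowSums(g^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
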