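# 3D marker-based watershed on a distance map.
#
# Markers are the h-maxima of the distance transform: regional maxima that
# survive after morphological reconstruction of (D - h) under D, which
# merges any maximum whose prominence above its connecting saddle is less
# than h (suppressing spurious splits from voxelization). Labels are then
# flooded downhill level by level; within a level, labels propagate across
# plateaus until stable. Deterministic throughout (ties resolved toward
# the larger label id).
#
# All stages run on a sparse representation of the phase: a vector of
# phase voxels plus a precomputed neighbour-index matrix, which keeps the
# per-pass cost proportional to the phase size rather than the volume.

# neighbour-index matrix: NB[i, j] = position (in idx) of the j-th
# 26-neighbour of phase voxel i, or 0
phase_neighbors <- function(mask, connectivity = 26) {
  d <- dim(mask)
  idx <- which(mask)
  n <- length(idx)
  pos <- array(0L, d)
  pos[idx] <- seq_len(n)
  offs <- neighbor_offsets_26()$offsets
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  NB <- matrix(0L, n, nrow(offs))
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    sh <- pos
    for (dd in 1:3) if (o[dd] != 0) sh <- shift3(sh, dd, -o[dd], 0L)
    NB[, r] <- sh[idx]
  }
  list(idx = idx, n = n, NB = NB, dim = d)
}

# max over neighbours of a value vector (absent neighbour contributes `fill`)
nb_max_vec <- function(v, NB, fill = 0) {
  out <- rep(fill, length(v))
  vf <- c(fill, v)
  for (j in seq_len(ncol(NB))) out <- pmax(out, vf[NB[, j] + 1L])
  out
}

# morphological reconstruction by dilation of seed under maskv (vectors)
reconstruct_vec <- function(seed, maskv, NB, max_iter = 4096L) {
  R <- seed
  for (i in seq_len(max_iter)) {
    Rn <- pmin(pmax(R, nb_max_vec(R, NB)), maskv)
    if (max(abs(Rn - R)) == 0) break
    R <- Rn
  }
  R
}

# plateau-aware regional maxima on the sparse phase; returns marker labels
regional_maxima_vec <- function(H, nbs, tol = 1e-9) {
  NB <- nbs$NB
  nbm <- nb_max_vec(H, NB, fill = -Inf)
  cand <- H >= nbm - tol
  n <- nbs$n
  # plateau grouping: edges between equal-H neighbours, candidates only
  from <- integer(0); to <- integer(0)
  cidx <- which(cand)
  cpos <- integer(n); cpos[cidx] <- seq_along(cidx)
  for (j in seq_len(ncol(NB))) {
    nb <- NB[cidx, j]
    ok <- nb > 0L
    ok[ok] <- cand[nb[ok]] & abs(H[cidx[ok]] - H[nb[ok]]) <= tol & nb[ok] > cidx[ok]
    if (any(ok)) { from <- c(from, cpos[cidx[ok]]); to <- c(to, cpos[nb[ok]]) }
  }
  g <- igraph::make_empty_graph(n = length(cidx), directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  # a plateau leaking into a non-candidate voxel of equal height is not a
  # regional maximum (that voxel sees higher ground)
  nmemb <- max(memb)
  bad <- logical(nmemb)
  for (j in seq_len(ncol(NB))) {
    nb <- NB[cidx, j]
    ok <- nb > 0L
    leak <- ok
    leak[ok] <- !cand[nb[ok]] & abs(H[cidx[ok]] - H[nb[ok]]) <= tol
    if (any(leak)) bad[memb[cpos[cidx[leak]]]] <- TRUE
  }
  keep <- which(!bad)
  relab <- integer(nmemb)
  relab[keep] <- seq_along(keep)
  lab <- integer(n)
  lab[cidx] <- relab[memb]
  lab
}

# watershed of the distance map D over mask; returns integer label array
watershed3 <- function(D, mask, h = 2, level_step = 0.25) {
  d <- dim(D)
  nbs <- phase_neighbors(mask, 26)
  if (nbs$n == 0) return(array(0L, d))
  Dv <- D[nbs$idx]
  nbs6 <- phase_neighbors(mask, 6)
  H <- reconstruct_vec(pmax(Dv - h, 0), Dv, nbs6$NB)
  lab <- regional_maxima_vec(H, nbs)
  n_marker <- max(lab)
  if (n_marker == 0L) {
    out <- array(0L, d)
    out[nbs$idx] <- 1L
    return(out)
  }
  # downhill flooding, level by level
  NB <- nbs$NB
  levels <- rev(seq(0, max(Dv) + level_step, by = level_step))
  for (lv in levels) {
    active <- Dv >= lv
    repeat {
      nbl <- nb_max_vec(as.numeric(lab), NB)
      take <- active & lab == 0L & nbl > 0
      if (!any(take)) break
      lab[take] <- as.integer(nbl[take])
    }
  }
  left <- lab == 0L
  if (any(left)) {
    # isolated flat pockets with no marker: give each component its own label
    lm <- array(FALSE, d)
    lm[nbs$idx[left]] <- TRUE
    extra <- label_components26(lm)
    lab[left] <- n_marker + extra[nbs$idx[left]]
  }
  out <- array(0L, d)
  out[nbs$idx] <- lab
  out
}

# connected components (26-connectivity) of a logical mask via igraph
label_components26 <- function(mask) {
  d <- dim(mask)
  n <- sum(mask)
  out <- array(0L, d)
  if (n == 0) return(out)
  idm <- array(0L, d)
  idm[mask] <- seq_len(n)
  offs <- neighbor_offsets_26()$offsets
  half <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), , drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(half))) {
    o <- half[r, ]
    sh <- idm
    for (dd in 1:3) if (o[dd] != 0) sh <- shift3(sh, dd, o[dd], 0L)
    ok <- idm > 0L & sh > 0L
    if (any(ok)) { from <- c(from, idm[ok]); to <- c(to, sh[ok]) }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  out[mask] <- as.integer(igraph::components(g)$membership)
  out
}
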