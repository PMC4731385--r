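# Internal 3D grid utilities: neighbourhood offsets, shifts, binary
# morphology, hole filling and connected-component labeling. Components are
# found by building the voxel adjacency edge list with vectorized array
# shifts and taking igraph components; labels are densified in order of
# first (lowest linear index) occurrence so results are deterministic.

neighbour_offsets <- function(connectivity = 26) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  r <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6"  = r == 1,
                 "18" = r <= 2,
                 "26" = rep(TRUE, nrow(g)))
  g[keep, , drop = FALSE]
}

# offsets with a positive lexicographic direction (one per unordered pair)
half_offsets <- function(connectivity = 26) {
  o <- neighbour_offsets(connectivity)
  keep <- o[, 3] > 0 | (o[, 3] == 0 & o[, 2] > 0) |
    (o[, 3] == 0 & o[, 2] == 0 & o[, 1] > 0)
  o[keep, , drop = FALSE]
}

# logical-array shift by an integer offset, filling exposed voxels
shift_logical <- function(m, off, fill = FALSE) {
  d <- dim(m)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) {
      dst[[ax]] <- seq_len(d[ax] - o) + o
      src[[ax]] <- seq_len(d[ax] - o)
    } else {
      dst[[ax]] <- seq_len(d[ax] + o)
      src[[ax]] <- seq_len(d[ax] + o) - o
    }
    if (length(src[[ax]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

binary_dilate <- function(m, connectivity = 26) {
  out <- m
  for (i in seq_len(nrow(o <- neighbour_offsets(connectivity))))
    out <- out | shift_logical(m, o[i, ], fill = FALSE)
  out
}

binary_erode <- function(m, connectivity = 26) {
  out <- m
  for (i in seq_len(nrow(o <- neighbour_offsets(connectivity))))
    out <- out & shift_logical(m, o[i, ], fill = FALSE)
  out
}

binary_close <- function(m, connectivity = 26) {
  binary_erode(binary_dilate(m, connectivity), connectivity)
}

# fill interior cavities: background is flood-filled (6-connectivity) from
# the array border; unreached background becomes foreground
fill_holes <- function(m) {
  bg <- !m
  lab <- label_components(bg, connectivity = 6)$labels
  d <- dim(m)
  border <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  border <- border[border > 0]
  m | (bg & !(lab %in% border))
}

# connected-component labeling of a logical 3D array; returns labels
# (integer array, 0 = background, ids dense 1..n by first occurrence),
# n, and voxel counts per id
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  nv <- sum(mask)
  labels <- array(0L, d)
  if (nv == 0L)
    return(list(labels = labels, n = 0L, sizes = integer(0)))
  pos <- array(0L, d)
  pos[mask] <- seq_len(nv)
  idx <- array(seq_len(prod(d)), d)
  offs <- half_offsets(connectivity)
  from <- to <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    off <- offs[i, ]
    rng_a <- rng_b <- vector("list", 3)
    ok <- TRUE
    for (ax in 1:3) {
      o <- off[ax]
      lo <- max(1L, 1L - o); hi <- min(d[ax], d[ax] - o)
      if (lo > hi) { ok <- FALSE; break }
      rng_a[[ax]] <- lo:hi
      rng_b[[ax]] <- (lo:hi) + o
    }
    if (!ok) next
    ma <- mask[rng_a[[1]], rng_a[[2]], rng_a[[3]], drop = FALSE]
    mb <- mask[rng_b[[1]], rng_b[[2]], rng_b[[3]], drop = FALSE]
    both <- ma & mb
    if (!any(both)) next
    ia <- idx[rng_a[[1]], rng_a[[2]], rng_a[[3]], drop = FALSE][both]
    ib <- idx[rng_b[[1]], rng_b[[2]], rng_b[[3]], drop = FALSE][both]
    from[[i]] <- pos[ia]
    to[[i]] <- pos[ib]
  }
  from <- unlist(from); to <- unlist(to)
  if (length(from) == 0L) {
    memb <- seq_len(nv)
  } else {
    g <- igraph::make_graph(rbind(from, to), n = nv, directed = FALSE)
    memb <- igraph::components(g)$membership
  }
  # densify ids in order of first voxel occurrence
  first_seen <- !duplicated(memb)
  remap <- integer(max(memb))
  remap[memb[first_seen]] <- seq_len(sum(first_seen))
  memb <- remap[memb]
  labels[mask] <- memb
  list(labels = labels, n = max(memb), sizes = tabulate(memb))
}

# separable convolution along the first axis with reflect (edge-repeating)
# padding; w is an odd-length kernel
conv_axis1 <- function(a, w) {
  d <- dim(a)
  n <- d[1]
  r <- (length(w) - 1L) %/% 2L
  if (r == 0L) return(a * w)
  if (r >= n) stop("kernel wider than axis")
  pad <- c(rev(seq_len(r)), seq_len(n), seq(n, n - r + 1L))
  ap <- a[pad, , , drop = FALSE]
  out <- array(0, d)
  for (k in seq_along(w))
    out <- out + w[k] * ap[k:(k + n - 1L), , , drop = FALSE]
  out
}

gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  x <- (-r):r
  w <- exp(-0.5 * (x / sigma_vox)^2)
  w / sum(w)
}
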