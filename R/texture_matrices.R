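## Gray-level texture matrices on 3D quantized ROIs.
##
## All builders take a 3D integer array `vol` whose voxels outside the ROI
## are NA and whose in-ROI voxels hold gray levels in 1..n_levels. Only
## in-ROI voxel pairs / runs / zones / neighbourhoods enter any matrix.

#' The 13 unique 3D direction offsets at distance 1
#'
#' Half of the 26-neighbourhood: one representative per +/- direction pair,
#' used for co-occurrence and run-length analysis.
#'
#' @return 13 x 3 integer matrix of (dx, dy, dz) offsets.
#' @export
directions_3d <- function() {
  d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), ]
  ## keep one representative of each +/- pair: first nonzero component positive
  keep <- apply(d, 1, function(v) { nz <- v[v != 0]; nz[1] > 0 })
  as.matrix(d[keep, , drop = FALSE])
}

## linear-index blocks of a volume shifted by an offset; returns the linear
## indices of the base block and of the shifted block (no wrap-around)
shift_blocks <- function(dims, off) {
  rng <- lapply(1:3, function(a) {
    s <- off[a]
    lo <- max(1, 1 - s); hi <- min(dims[a], dims[a] - s)
    if (hi < lo) integer(0) else lo:hi
  })
  lin <- array(seq_len(prod(dims)), dims)
  base <- lin[rng[[1]], rng[[2]], rng[[3]]]
  shifted <- lin[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3]]
  list(base = as.integer(base), shifted = as.integer(shifted))
}

#' Gray-level co-occurrence matrix for one direction
#'
#' Counts ordered pairs in both directions (the matrix is symmetric); only
#' pairs with both voxels inside the ROI contribute.
#'
#' @param vol 3D integer array, NA outside the ROI.
#' @param n_levels number of gray levels.
#' @param direction integer offset (dx, dy, dz), distance-1 neighbour step.
#' @return n_levels x n_levels count matrix (symmetric).
#' @export
glcm_3d <- function(vol, n_levels, direction) {
  b <- shift_blocks(dim(vol), direction)
  a <- vol[b$base]; z <- vol[b$shifted]
  ok <- !is.na(a) & !is.na(z)
  a <- a[ok]; z <- z[ok]
  counts <- tabulate((a - 1L) * n_levels + z, nbins = n_levels^2)
  m <- matrix(counts, n_levels, n_levels, byrow = TRUE)
  m + t(m)
}

#' Gray-level run-length matrix for one direction
#'
#' A run is a maximal set of collinear, contiguous ROI voxels sharing one
#' gray level. Runs are extracted along every lattice line parallel to the
#' direction; NA (out-of-ROI) voxels break runs.
#'
#' @inheritParams glcm_3d
#' @return n_levels x max-run-length count matrix.
#' @export
glrlm_3d <- function(vol, n_levels, direction) {
  dims <- dim(vol)
  n <- prod(dims)
  cx <- as.integer(slice.index(array(0L, dims), 1))
  cy <- as.integer(slice.index(array(0L, dims), 2))
  cz <- as.integer(slice.index(array(0L, dims), 3))
  coord <- list(cx, cy, cz)
  ## position along the line: stepping by `direction` increments it by 1
  ax <- which(direction != 0)[1]
  t_pos <- if (direction[ax] > 0) coord[[ax]] else dims[ax] + 1L - coord[[ax]]
  ## per-line anchor: constant along a line, distinct between lines
  anchor <- cbind(coord[[1]] - direction[1] * t_pos,
                  coord[[2]] - direction[2] * t_pos,
                  coord[[3]] - direction[3] * t_pos)
  ## anchors are constant per line; encode the triple as one numeric key
  md <- max(dims)
  M <- 4 * md + 2
  key <- (anchor[, 1] + 2 * md + 1) + (anchor[, 2] + 2 * md + 1) * M +
    (anchor[, 3] + 2 * md + 1) * M^2
  ord <- order(key, t_pos)
  v <- as.integer(vol)[ord]
  k <- key[ord]
  v[is.na(v)] <- 0L
  newrun <- c(TRUE, k[-1] != k[-n] | v[-1] != v[-n])
  runid <- cumsum(newrun)
  lens <- tabulate(runid)
  vals <- v[newrun]
  keep <- vals > 0L
  lens <- lens[keep]; vals <- vals[keep]
  if (length(lens) == 0) return(matrix(0, n_levels, 1))
  maxlen <- max(lens)
  counts <- tabulate((lens - 1L) * n_levels + vals, nbins = n_levels * maxlen)
  matrix(counts, n_levels, maxlen)
}

#' Gray-level size-zone matrix
#'
#' A zone is a 26-connected component of ROI voxels sharing one gray level.
#' Direction-free by construction.
#'
#' @inheritParams glcm_3d
#' @return n_levels x max-zone-size count matrix.
#' @export
glszm_3d <- function(vol, n_levels) {
  roi <- which(!is.na(vol))
  m <- length(roi)
  if (m == 0) return(matrix(0, n_levels, 1))
  id <- integer(length(vol))
  id[roi] <- seq_len(m)
  dirs <- directions_3d()
  ei <- vector("list", nrow(dirs)); ej <- ei
  for (r in seq_len(nrow(dirs))) {
    b <- shift_blocks(dim(vol), dirs[r, ])
    a <- vol[b$base]; z <- vol[b$shifted]
    sel <- !is.na(a) & !is.na(z) & a == z
    ei[[r]] <- id[b$base[sel]]
    ej[[r]] <- id[b$shifted[sel]]
  }
  edges <- rbind(unlist(ei), unlist(ej))
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, as.vector(edges))
  comp <- igraph::components(g)
  sizes <- comp$csize
  lev <- as.integer(vol[roi])[match(seq_len(comp$no), comp$membership)]
  maxsize <- max(sizes)
  counts <- tabulate((sizes - 1L) * n_levels + lev, nbins = n_levels * maxsize)
  matrix(counts, n_levels, maxsize)
}

#' Neighbourhood gray-tone difference summaries
#'
#' For each ROI voxel with at least one in-ROI 26-neighbour, the absolute
#' difference between its gray level and the mean level of those neighbours
#' is accumulated per gray level.
#'
#' @inheritParams glcm_3d
#' @return list with `s` (per-level summed absolute differences), `n`
#'   (per-level voxel counts), both length n_levels.
#' @export
ngtdm_3d <- function(vol, n_levels) {
  dims <- dim(vol)
  nsum <- array(0, dims)
  ncnt <- array(0L, dims)
  v0 <- vol
  v0[is.na(v0)] <- 0L
  inroi <- !is.na(vol)
  for (r in seq_len(nrow(directions_3d()))) {
    b <- shift_blocks(dims, directions_3d()[r, ])
    ## neighbour contribution in both directions of the offset pair
    nsum[b$base] <- nsum[b$base] + v0[b$shifted] * inroi[b$shifted]
    ncnt[b$base] <- ncnt[b$base] + inroi[b$shifted]
    nsum[b$shifted] <- nsum[b$shifted] + v0[b$base] * inroi[b$base]
    ncnt[b$shifted] <- ncnt[b$shifted] + inroi[b$base]
  }
  use <- inroi & ncnt > 0
  g <- as.integer(vol[use])
  dif <- abs(g - nsum[use] / ncnt[use])
  s <- vapply(seq_len(n_levels), function(i) sum(dif[g == i]), 0)
  n <- tabulate(g, nbins = n_levels)
  list(s = s, n = n)
}
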