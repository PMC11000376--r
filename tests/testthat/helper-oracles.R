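## Independent brute-force oracles: naive per-voxel enumeration of pairs,
## runs, zones, neighbourhoods and score concordance. Deliberately slow and
## simple; used only on tiny fixtures.

in_grid <- function(p, dims) all(p >= 1) && all(p <= dims)

## symmetric co-occurrence counts by enumerating every ordered voxel pair
brute_glcm <- function(vol, n_levels, dir) {
  dims <- dim(vol)
  m <- matrix(0, n_levels, n_levels)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    a <- vol[x, y, z]
    if (is.na(a)) next
    for (s in c(1, -1)) {
      q <- c(x, y, z) + s * dir
      if (!in_grid(q, dims)) next
      b <- vol[q[1], q[2], q[3]]
      if (is.na(b)) next
      m[a, b] <- m[a, b] + 1
    }
  }
  m
}

## maximal runs by walking every lattice line parallel to dir
brute_glrlm <- function(vol, n_levels, dir) {
  dims <- dim(vol)
  runs <- list()
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    p <- c(x, y, z)
    if (in_grid(p - dir, dims)) next  # not a line start
    line <- c()
    while (in_grid(p, dims)) {
      line <- c(line, vol[p[1], p[2], p[3]])
      p <- p + dir
    }
    r <- rle(ifelse(is.na(line), 0, line))
    keep <- r$values > 0
    if (any(keep)) runs[[length(runs) + 1]] <- cbind(r$values[keep], r$lengths[keep])
  }
  runs <- do.call(rbind, runs)
  if (is.null(runs)) return(matrix(0, n_levels, 1))
  m <- matrix(0, n_levels, max(runs[, 2]))
  for (i in seq_len(nrow(runs))) m[runs[i, 1], runs[i, 2]] <- m[runs[i, 1], runs[i, 2]] + 1
  m
}

## zones by naive BFS over the 26-neighbourhood
brute_glszm <- function(vol, n_levels) {
  dims <- dim(vol)
  seen <- array(FALSE, dims)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  zones <- list()
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (seen[x, y, z] || is.na(vol[x, y, z])) next
    lev <- vol[x, y, z]
    queue <- list(c(x, y, z)); seen[x, y, z] <- TRUE; size <- 0
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]; size <- size + 1
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (!in_grid(q, dims) || seen[q[1], q[2], q[3]]) next
        vq <- vol[q[1], q[2], q[3]]
        if (!is.na(vq) && vq == lev) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lev, size)
  }
  zones <- do.call(rbind, zones)
  m <- matrix(0, n_levels, max(zones[, 2]))
  for (i in seq_len(nrow(zones))) m[zones[i, 1], zones[i, 2]] <- m[zones[i, 1], zones[i, 2]] + 1
  m
}

## per-voxel neighbourhood gray-tone differences
brute_ngtdm <- function(vol, n_levels) {
  dims <- dim(vol)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  s <- numeric(n_levels); n <- integer(n_levels)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    g <- vol[x, y, z]
    if (is.na(g)) next
    nb <- c()
    for (r in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[r, ]
      if (!in_grid(q, dims)) next
      vq <- vol[q[1], q[2], q[3]]
      if (!is.na(vq)) nb <- c(nb, vq)
    }
    if (length(nb) == 0) next
    n[g] <- n[g] + 1L
    s[g] <- s[g] + abs(g - mean(nb))
  }
  list(s = s, n = n)
}

## AUC as the Mann-Whitney pairwise concordance fraction
brute_auc <- function(y, scores) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  conc <- 0
  for (p in pos) for (q in neg) conc <- conc + (p > q) + 0.5 * (p == q)
  conc / (length(pos) * length(neg))
}

## a small random NA-masked quantized toy ROI
random_toy_roi <- function(dims = c(4, 4, 2), n_levels = 4, p_na = 0.2, seed = 1) {
  set.seed(seed)
  v <- array(sample.int(n_levels, prod(dims), replace = TRUE), dims)
  v[runif(prod(dims)) < p_na] <- NA
  if (all(is.na(v))) v[1, 1, 1] <- 1L
  v
}
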