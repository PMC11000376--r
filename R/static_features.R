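## The static radiomics feature bank: 7 intensity + 53 texture features
## (22 GLCM + 13 GLRLM + 13 GLSZM + 5 NGTDM), computed per ROI per phase;
## the texture bank is repeated on the 8 wavelet sub-bands for 424 wavelet
## features, giving 484 in total.

log2z <- function(p) ifelse(p > 0, log2(p), 0)

#' The static texture feature roster
#'
#' The fixed 53-feature roster: 22 co-occurrence (GLCM), 13 run-length
#' (GLRLM), 13 size-zone (GLSZM) and 5 neighbourhood gray-tone difference
#' (NGTDM) features. Names follow the field's conventions; where the same
#' statistic exists in two families the non-signature family is qualified
#' (e.g. the GLCM inertia vs the NGTDM \code{Contrast}).
#'
#' @return data.frame with columns `name` and `family`.
#' @export
texture_feature_roster <- function() {
  rbind(
    data.frame(name = c(
      "Autocorrelation", "Cluster prominence", "Cluster shade",
      "Cluster tendency", "Inertia", "Correlation1", "Correlation2",
      "Difference average", "Difference entropy", "Difference variance",
      "Joint energy", "Joint entropy", "Homogeneity1", "Homogeneity2",
      "IMC1", "IMC2", "IDMN", "IDN", "Inverse variance",
      "Maximum probability", "Sum average", "Sum entropy"),
      family = "GLCM"),
    data.frame(name = c(
      "Short run emphasis", "Long run emphasis", "Gray-level nonuniformity",
      "Run-length nonuniformity", "Run percentage",
      "Low gray-level run emphasis", "High gray-level run emphasis",
      "Short run low gray-level emphasis", "Short run high gray-level emphasis",
      "Long run low gray-level emphasis", "Long run high gray-level emphasis",
      "Gray-level variance", "Run-length variance"),
      family = "GLRLM"),
    data.frame(name = c(
      "Small zone emphasis", "Large zone emphasis",
      "Zone gray-level nonuniformity", "Zone-size nonuniformity",
      "Zone percentage", "Low gray-level zone emphasis",
      "High gray-level zone emphasis", "Small zone low gray-level emphasis",
      "Small zone high gray-level emphasis", "Large zone low gray-level emphasis",
      "Large zone high gray-level emphasis", "Zone gray-level variance",
      "Zone-size variance"),
      family = "GLSZM"),
    data.frame(name = c("Coarseness", "Contrast", "Busyness", "Complexity",
                        "Strength"),
      family = "NGTDM")
  )
}

#' Intensity (first-order) features
#'
#' Seven histogram/moment statistics of the ROI intensities: mean,
#' population variance, skewness and kurtosis (standardised central
#' moments; the kurtosis is not excess-corrected), energy (sum of squared
#' intensities), Shannon entropy of a 64-bin min--max histogram (bits), and
#' range. A zero-variance ROI reports skewness and kurtosis as 0.
#'
#' @param x numeric vector of ROI voxel intensities (normalised scale).
#' @param entropy_bins number of histogram bins for the entropy estimate.
#' @return named numeric vector of length 7.
#' @export
intensity_features <- function(x, entropy_bins = 64L) {
  x <- as.numeric(x)
  stopifnot(length(x) >= 1)
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v > 0) {
    skew <- mean((x - m)^3) / v^1.5
    kurt <- mean((x - m)^4) / v^2
  } else {
    skew <- 0; kurt <- 0
  }
  rng <- max(x) - min(x)
  if (rng > 0) {
    h <- tabulate(pmin(entropy_bins, floor((x - min(x)) / rng * entropy_bins) + 1L),
                  nbins = entropy_bins)
    p <- h / sum(h)
    ent <- -sum(p * log2z(p))
  } else ent <- 0
  c(Mean = m, Variance = v, Skewness = skew, Kurtosis = kurt,
    Energy = sum(x^2), Entropy = ent, Range = rng)
}

## ---- per-matrix feature formulas ------------------------------------------

glcm_features <- function(counts) {
  nm <- texture_feature_roster()$name[texture_feature_roster()$family == "GLCM"]
  total <- sum(counts)
  if (total == 0) return(stats::setNames(rep(0, 22), nm))
  L <- nrow(counts)
  P <- counts / total
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:L) * px); muy <- sum((1:L) * py)
  sx <- sqrt(sum(((1:L) - mux)^2 * px)); sy <- sqrt(sum(((1:L) - muy)^2 * py))
  ## difference and sum distributions
  ## difference |i-j| spans 0..L-1 and sum i+j spans 2..2L over the full grid
  pd <- as.vector(rowsum(as.vector(P), as.vector(abs(i - j))))
  ps <- as.vector(rowsum(as.vector(P), as.vector(i + j)))
  kd <- 0:(L - 1); ks <- 2:(2 * L)
  da <- sum(kd * pd)
  hxy <- -sum(P * log2z(P))
  hx <- -sum(px * log2z(px)); hy <- -sum(py * log2z(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(P * log2z(pxy))
  hxy2 <- -sum(pxy * log2z(pxy))
  corr <- if (sx > 0 && sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else 0
  corr2 <- if (sx > 0 && sy > 0) sum((i - mux) * (j - muy) * P) / (sx * sy) else 0
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  off <- i != j
  stats::setNames(c(
    sum(i * j * P),
    sum((i + j - mux - muy)^4 * P),
    sum((i + j - mux - muy)^3 * P),
    sum((i + j - mux - muy)^2 * P),
    sum((i - j)^2 * P),
    corr, corr2,
    da,
    -sum(pd * log2z(pd)),
    sum((kd - da)^2 * pd),
    sum(P^2),
    hxy,
    sum(P / (1 + abs(i - j))),
    sum(P / (1 + (i - j)^2)),
    imc1, imc2,
    sum(P / (1 + (i - j)^2 / L^2)),
    sum(P / (1 + abs(i - j) / L)),
    sum(P[off] / (i[off] - j[off])^2),
    max(P),
    sum(ks * ps),
    -sum(ps * log2z(ps))
  ), nm)
}

## shared formulas for run-length and size-zone matrices: rows are gray
## levels, columns are run lengths / zone sizes
rl_type_features <- function(counts, n_voxels) {
  total <- sum(counts)
  if (total == 0) return(rep(0, 13))
  L <- nrow(counts); K <- ncol(counts)
  g <- seq_len(L); l <- seq_len(K)
  rg <- rowSums(counts); rl <- colSums(counts)
  P <- counts / total
  pg <- rg / total; pl <- rl / total
  mug <- sum(g * pg); mul <- sum(l * pl)
  c(sum(rl / l^2) / total,
    sum(rl * l^2) / total,
    sum(rg^2) / total,
    sum(rl^2) / total,
    total / n_voxels,
    sum(rg / g^2) / total,
    sum(rg * g^2) / total,
    sum(t(counts / g^2) / l^2) / total,
    sum(t(counts * g^2) / l^2) / total,
    sum(t(counts / g^2) * l^2) / total,
    sum(t(counts * g^2) * l^2) / total,
    sum(pg * (g - mug)^2),
    sum(pl * (l - mul)^2))
}

glrlm_features <- function(counts, n_voxels) {
  nm <- texture_feature_roster()$name[texture_feature_roster()$family == "GLRLM"]
  stats::setNames(rl_type_features(counts, n_voxels), nm)
}

glszm_features <- function(counts, n_voxels) {
  nm <- texture_feature_roster()$name[texture_feature_roster()$family == "GLSZM"]
  stats::setNames(rl_type_features(counts, n_voxels), nm)
}

ngtdm_features <- function(s, n) {
  nm <- texture_feature_roster()$name[texture_feature_roster()$family == "NGTDM"]
  N <- sum(n)
  if (N == 0) return(stats::setNames(rep(0, 5), nm))
  L <- length(n)
  p <- n / N
  act <- which(p > 0)
  ngp <- length(act)
  coarse <- if (sum(p * s) > 0) 1 / sum(p * s) else 1e6
  if (ngp > 1) {
    ii <- rep(act, each = ngp); jj <- rep(act, ngp)
    contrast <- (sum(p[ii] * p[jj] * (ii - jj)^2) / (ngp * (ngp - 1))) * (sum(s) / N)
    busy_den <- sum(abs(ii * p[ii] - jj * p[jj]))
    busy <- if (busy_den > 0) sum(p * s) / busy_den else 0
    complexity <- sum(abs(ii - jj) * (p[ii] * s[ii] + p[jj] * s[jj]) /
                        (p[ii] + p[jj])) / N
    strength <- if (sum(s) > 0) sum((p[ii] + p[jj]) * (ii - jj)^2) / sum(s) else 0
  } else {
    contrast <- 0; busy <- 0; complexity <- 0; strength <- 0
  }
  stats::setNames(c(coarse, contrast, busy, complexity, strength), nm)
}

#' Texture features of a quantized ROI
#'
#' The fixed 53-feature texture bank on one quantized ROI: GLCM and GLRLM
#' features are computed per direction over the 13 unique distance-1 3D
#' directions and averaged; GLSZM and NGTDM are direction-free. Matrices are
#' built only from in-ROI voxels. Single-voxel and constant ROIs degrade to
#' documented conventions (degenerate matrices, no errors).
#'
#' @param roi a \code{QuantizedROI} from \code{\link{quantize_gray_levels}},
#'   or a 3D integer array with NA outside the ROI.
#' @param n_levels number of gray levels (taken from the QuantizedROI if
#'   given).
#' @return named numeric vector of length 53.
#' @export
texture_features <- function(roi, n_levels = 64L) {
  if (inherits(roi, "QuantizedROI")) {
    n_levels <- roi$n_levels
    vol <- roi$array
  } else vol <- roi
  vol <- crop_to_roi(vol)
  n_vox <- sum(!is.na(vol))
  dirs <- directions_3d()
  glcm_acc <- 0; glrlm_acc <- 0
  for (r in seq_len(nrow(dirs))) {
    glcm_acc <- glcm_acc + glcm_features(glcm_3d(vol, n_levels, dirs[r, ]))
    glrlm_acc <- glrlm_acc + glrlm_features(glrlm_3d(vol, n_levels, dirs[r, ]), n_vox)
  }
  c(glcm_acc / nrow(dirs),
    glrlm_acc / nrow(dirs),
    glszm_features(glszm_3d(vol, n_levels), n_vox),
    ngtdm_features2(vol, n_levels))
}

ngtdm_features2 <- function(vol, n_levels) {
  nd <- ngtdm_3d(vol, n_levels)
  ngtdm_features(nd$s, nd$n)
}

## crop an NA-masked volume to the ROI bounding box (texture is unaffected;
## run/line bookkeeping gets much cheaper)
crop_to_roi <- function(vol) {
  idx <- which(!is.na(vol), arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty ROI")
  rng <- lapply(1:3, function(a) min(idx[, a]):max(idx[, a]))
  vol[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
}

#' Extract the full 484-feature static vector for one phase
#'
#' Concatenates the 7 intensity features of the (normalised) ROI
#' intensities, the 53 texture features of the quantized ROI, and the 53
#' texture features of each of the 8 stationary-wavelet sub-band ROIs
#' (quantized per sub-band), for 7 + 53 + 8 x 53 = 484 features. Wavelet
#' feature names carry the sub-band suffix, e.g.
#' \code{"Cluster prominence_wavelet.LLH"}.
#'
#' @param volume 3D numeric array (one phase, intensity-normalised).
#' @param mask binary 3D array of the same dimensions (the tumour ROI).
#' @param n_levels gray levels for quantization (default 64).
#' @param wavelet wavelet family for the sub-band decomposition.
#' @return named numeric vector of length 484 with a `category` attribute
#'   (intensity / texture / wavelet).
#' @export
extract_static_vector <- function(volume, mask, n_levels = 64L, wavelet = "coif1") {
  stopifnot(identical(dim(volume), dim(mask)))
  mask <- mask > 0
  if (!any(mask)) stop("empty ROI")
  out_int <- intensity_features(volume[mask])
  q <- quantize_gray_levels(volume, mask, n_levels)
  out_tex <- texture_features(q)
  bands <- wavelet_decompose(volume, wavelet = wavelet, mode = "stationary")
  out_wav <- unlist(lapply(names(bands), function(bn) {
    qb <- quantize_gray_levels(bands[[bn]], mask, n_levels)
    f <- texture_features(qb)
    names(f) <- paste0(names(f), "_wavelet.", bn)
    f
  }))
  out <- c(out_int, out_tex, out_wav)
  attr(out, "category") <- c(rep("intensity", length(out_int)),
                             rep("texture", length(out_tex)),
                             rep("wavelet", length(out_wav)))
  out
}
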