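## Single-level separable 3D discrete wavelet transform.
##
## The stationary (undecimated) form keeps every sub-band on the input grid
## so the tumour mask applies voxel-for-voxel; the decimated form is the
## orthogonal transform used to verify energy conservation.

#' Wavelet filter coefficients
#'
#' Decomposition low-pass filters for the supported orthogonal wavelets;
#' the high-pass filter is derived by the quadrature-mirror relation
#' g[k] = (-1)^k h[L - 1 - k].
#'
#' @param wavelet one of "coif1", "haar", "db2".
#' @return list with `lo` and `hi` numeric filter taps.
#' @export
wavelet_filters <- function(wavelet = c("coif1", "haar", "db2")) {
  wavelet <- match.arg(wavelet)
  lo <- switch(wavelet,
    coif1 = c(-0.015655728135465e0, -0.072732619512854e0, 0.384864846864203e0,
              0.852572020212255e0, 0.337897662457809e0, -0.072732619512854e0),
    haar = c(1, 1) / sqrt(2),
    db2 = c(0.482962913144690, 0.836516303737469,
            0.224143868041857, -0.129409522550921))
  L <- length(lo)
  hi <- (-1)^(seq_len(L) - 1) * rev(lo)
  list(lo = lo, hi = hi)
}

## periodic convolution along the first array axis, same length (stationary)
axis_filter_stationary <- function(v, h) {
  n <- dim(v)[1]
  centre <- floor((length(h) - 1) / 2)
  out <- 0
  for (k in seq_along(h)) {
    idx <- ((seq_len(n) - 1 + k - 1 - centre) %% n) + 1
    out <- out + h[k] * v[idx, , , drop = FALSE]
  }
  out
}

## periodic convolution + dyadic downsampling along the first axis
axis_filter_decimated <- function(v, h) {
  n <- dim(v)[1]
  if (n %% 2 != 0) stop("decimated transform requires even dimensions")
  out <- 0
  starts <- 2 * (seq_len(n / 2) - 1)
  for (k in seq_along(h)) {
    idx <- ((starts + k - 1) %% n) + 1
    out <- out + h[k] * v[idx, , , drop = FALSE]
  }
  out
}

rotate_axes <- function(v) aperm(v, c(2, 3, 1))

#' Single-level 3D wavelet decomposition
#'
#' Applies the low (L) and high (H) pass filters of an orthogonal wavelet
#' along x, y and z in turn, producing the 8 sub-bands LLL ... HHH (the
#' first letter is the x-axis filter). The default stationary mode omits
#' downsampling, so every sub-band has the dimensions of the input and the
#' ROI mask can be applied directly; the decimated mode is the orthogonal
#' transform (halved dimensions, energy preserved exactly).
#'
#' @param volume 3D numeric array; every dimension must be at least the
#'   filter length (and even, in decimated mode).
#' @param wavelet wavelet family (default "coif1").
#' @param mode "stationary" (same-size, default) or "decimated".
#' @return named list of 8 sub-band arrays.
#' @export
wavelet_decompose <- function(volume, wavelet = "coif1",
                              mode = c("stationary", "decimated")) {
  mode <- match.arg(mode)
  stopifnot(length(dim(volume)) == 3)
  f <- wavelet_filters(wavelet)
  if (any(dim(volume) < length(f$lo)))
    stop("volume too small for the wavelet filter")
  flt <- if (mode == "stationary") axis_filter_stationary else axis_filter_decimated
  bands <- list(volume)
  band_names <- ""
  for (axis in 1:3) {
    nxt <- vector("list", 2 * length(bands))
    nxt_names <- character(2 * length(bands))
    for (i in seq_along(bands)) {
      nxt[[2 * i - 1]] <- rotate_axes(flt(bands[[i]], f$lo))
      nxt[[2 * i]] <- rotate_axes(flt(bands[[i]], f$hi))
      nxt_names[2 * i - 1] <- paste0(band_names[i], "L")
      nxt_names[2 * i] <- paste0(band_names[i], "H")
    }
    bands <- nxt
    band_names <- nxt_names
  }
  names(bands) <- band_names
  ## three rotations restore the original axis order; letters are x,y,z
  order8 <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  bands[order8]
}
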