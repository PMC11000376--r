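## Loading, spatial harmonisation, intensity normalisation and gray-level
## quantization of 4-phase stacks.

PHASE_NAMES <- c("plain", "arterial", "portal", "equilibrium")

#' Construct a validated 4-phase stack
#'
#' A PhaseStack bundles the four co-acquired phases of one examination
#' (plain/"mask", arterial, portal venous, equilibrium) with their binary
#' tumour masks, the voxel spacing in mm, and the time grid the dynamic
#' features are fitted against (phase indices 1:4 by default).
#'
#' @param volumes list of 4 three-dimensional numeric arrays, phase order
#'   plain, arterial, portal venous, equilibrium.
#' @param masks list of 4 binary arrays, each on the grid of its volume.
#' @param spacing voxel edge lengths in mm (length 3).
#' @param time_grid strictly increasing numeric vector of length 4.
#' @return object of class \code{PhaseStack}.
#' @export
phase_stack <- function(volumes, masks, spacing = c(1, 1, 1), time_grid = 1:4) {
  if (length(volumes) != 4 || length(masks) != 4)
    stop("exactly 4 phases required")
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be 3 positive voxel edge lengths")
  time_grid <- as.numeric(time_grid)
  if (length(time_grid) != 4 || any(diff(time_grid) <= 0))
    stop("time_grid must be 4 strictly increasing values")
  for (i in 1:4) {
    v <- volumes[[i]]; m <- masks[[i]]
    if (length(dim(v)) != 3) stop("volumes must be 3D arrays")
    if (!identical(dim(v), dim(m))) stop("grid mismatch between volume and mask")
    if (!all(m %in% c(0, 1))) stop("non-binary mask")
    if (sum(m) < 1) stop("mask must contain at least 1 foreground voxel")
  }
  names(volumes) <- PHASE_NAMES
  names(masks) <- PHASE_NAMES
  structure(list(volumes = volumes, masks = masks,
                 spacing = as.numeric(spacing), time_grid = time_grid),
            class = "PhaseStack")
}

#' @export
print.PhaseStack <- function(x, ...) {
  cat("PhaseStack: 4 phases (", paste(PHASE_NAMES, collapse = ", "), ")\n", sep = "")
  cat("  grid:", paste(dim(x$volumes[[1]]), collapse = " x "),
      " spacing:", paste(signif(x$spacing, 3), collapse = " x "), "mm\n")
  cat("  time grid:", paste(x$time_grid, collapse = ", "), "\n")
  invisible(x)
}

#' Load a 4-phase stack from NIfTI files
#'
#' @param volume_paths character vector of 4 NIfTI (.nii/.nii.gz) volume
#'   paths, phase order plain, arterial, portal venous, equilibrium.
#' @param mask_paths character vector of 4 NIfTI binary mask paths.
#' @param time_grid strictly increasing numeric vector of length 4.
#' @return a \code{\link{phase_stack}}.
#' @export
load_phase_stack <- function(volume_paths, mask_paths, time_grid = 1:4) {
  if (length(volume_paths) != 4 || length(mask_paths) != 4)
    stop("exactly 4 phases required")
  missing <- c(volume_paths, mask_paths)[!file.exists(c(volume_paths, mask_paths))]
  if (length(missing) > 0)
    stop("missing file: ", paste(missing, collapse = ", "))
  vols <- lapply(volume_paths, function(p) {
    img <- RNifti::readNifti(p)
    structure(as.array(img), pixdim = RNifti::pixdim(img))
  })
  masks <- lapply(mask_paths, function(p) as.array(RNifti::readNifti(p)))
  spacing <- attr(vols[[1]], "pixdim")[1:3]
  vols <- lapply(vols, function(v) { attr(v, "pixdim") <- NULL; v })
  phase_stack(vols, masks, spacing = spacing, time_grid = time_grid)
}

## separable 1D linear interpolation along the first axis to a new length
interp_axis <- function(v, n_new, ratio, nearest = FALSE) {
  n <- dim(v)[1]
  s <- (seq_len(n_new) - 1) * ratio
  if (nearest) {
    i <- pmin(pmax(round(s) + 1, 1), n)
    return(v[i, , , drop = FALSE])
  }
  i0 <- pmin(pmax(floor(s) + 1, 1), n)
  i1 <- pmin(i0 + 1, n)
  f <- s - (i0 - 1)
  f[i1 == i0] <- 0
  v[i0, , , drop = FALSE] * (1 - f) + v[i1, , , drop = FALSE] * f
}

resample_array <- function(v, spacing, target, nearest = FALSE) {
  for (axis in 1:3) {
    extent <- (dim(v)[1] - 1) * spacing[axis]
    n_new <- max(2L, floor(extent / target[axis]) + 1L)
    v <- rotate_axes(interp_axis(v, n_new, target[axis] / spacing[axis],
                                 nearest = nearest))
  }
  v
}

#' Resample a stack to isotropic voxels
#'
#' Volumes are resampled with trilinear interpolation, masks with
#' nearest-neighbour interpolation (so they remain binary), onto a grid of
#' the target spacing (1 x 1 x 1 mm by default) covering the same physical
#' extent.
#'
#' @param stack a \code{\link{phase_stack}}.
#' @param target_spacing mm triple, default c(1, 1, 1).
#' @return resampled \code{PhaseStack} with spacing equal to the target.
#' @export
resample_isotropic <- function(stack, target_spacing = c(1, 1, 1)) {
  stopifnot(inherits(stack, "PhaseStack"))
  if (any(target_spacing <= 0)) stop("non-positive spacing")
  if (isTRUE(all.equal(stack$spacing, as.numeric(target_spacing))))
    return(stack)
  vols <- lapply(stack$volumes, resample_array, spacing = stack$spacing,
                 target = target_spacing)
  masks <- lapply(stack$masks, resample_array, spacing = stack$spacing,
                  target = target_spacing, nearest = TRUE)
  phase_stack(vols, masks, spacing = target_spacing, time_grid = stack$time_grid)
}

#' Intensity z-score normalisation of a volume
#'
#' Applies x' = (x - mu) / sigma, where mu and sigma are taken over the
#' whole volume (default) or over the masked region only.
#'
#' @param volume 3D numeric array.
#' @param region statistics region, "whole-volume" or "mask-only".
#' @param mask binary array, required for "mask-only".
#' @return normalised array (whole volume transformed in either case).
#' @export
znormalize <- function(volume, region = c("whole-volume", "mask-only"), mask = NULL) {
  region <- match.arg(region)
  x <- if (region == "whole-volume") as.numeric(volume) else {
    if (is.null(mask)) stop("mask required for mask-only normalisation")
    as.numeric(volume[mask > 0])
  }
  mu <- mean(x)
  sigma <- stats::sd(x)
  if (!is.finite(sigma) || sigma == 0)
    stop("constant region: sigma = 0, cannot normalise")
  (volume - mu) / sigma
}

#' Quantize ROI intensities to discrete gray levels
#'
#' Equal-width binning of the ROI intensities between the ROI minimum and
#' maximum into \code{n_levels} bins labelled 1..n_levels (the ROI minimum
#' maps to level 1, the maximum to level n_levels). A constant ROI maps
#' entirely to level 1 (documented convention). The result is invariant to
#' any positive affine rescaling of the input intensities.
#'
#' @param volume 3D numeric array.
#' @param mask binary array of the same dimensions.
#' @param n_levels number of gray levels (default 64).
#' @return object of class \code{QuantizedROI}: list with `values` (integer
#'   levels of the ROI voxels), `n_levels`, `geometry` (voxel coordinates),
#'   and `array` (full-size integer array, NA outside the ROI).
#' @export
quantize_gray_levels <- function(volume, mask, n_levels = 64L) {
  stopifnot(identical(dim(volume), dim(mask)))
  mask <- mask > 0
  if (!any(mask)) stop("mask non-empty required")
  x <- as.numeric(volume[mask])
  lo <- min(x); hi <- max(x)
  if (hi > lo) {
    lev <- pmin(as.integer(floor((x - lo) / (hi - lo) * n_levels)) + 1L,
                as.integer(n_levels))
  } else {
    lev <- rep(1L, length(x))
  }
  arr <- array(NA_integer_, dim(volume))
  arr[mask] <- lev
  structure(list(values = lev, n_levels = as.integer(n_levels),
                 geometry = which(mask, arr.ind = TRUE), array = arr),
            class = "QuantizedROI")
}

#' Preprocess a stack: resample, then normalise
#'
#' Resamples to isotropic voxels and z-score normalises every phase volume.
#' The order (resample first) is the package default; set
#' \code{normalize_first = TRUE} to normalise on the acquisition grid.
#'
#' @param stack a \code{\link{phase_stack}}.
#' @param target_spacing mm triple for resampling.
#' @param region normalisation statistics region (see \code{\link{znormalize}}).
#' @param normalize_first normalise before resampling instead of after.
#' @return preprocessed \code{PhaseStack}; the per-phase normalisation
#'   statistics are attached as attribute "norm_stats".
#' @export
preprocess_stack <- function(stack, target_spacing = c(1, 1, 1),
                             region = "whole-volume", normalize_first = FALSE) {
  norm_all <- function(st) {
    stats_out <- list()
    vols <- lapply(seq_len(4), function(i) {
      v <- st$volumes[[i]]
      x <- if (region == "whole-volume") as.numeric(v) else as.numeric(v[st$masks[[i]] > 0])
      stats_out[[PHASE_NAMES[i]]] <<- c(mean = mean(x), sd = stats::sd(x))
      znormalize(v, region = region, mask = st$masks[[i]])
    })
    out <- phase_stack(vols, st$masks, st$spacing, st$time_grid)
    attr(out, "norm_stats") <- stats_out
    out
  }
  if (normalize_first) {
    st <- norm_all(stack)
    ns <- attr(st, "norm_stats")
    st <- resample_isotropic(st, target_spacing)
    attr(st, "norm_stats") <- ns
    st
  } else {
    norm_all(resample_isotropic(stack, target_spacing))
  }
}

#' Write a stack to NIfTI files plus a JSON sidecar
#'
#' @param stack a \code{\link{phase_stack}}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (e.g. a patient id).
#' @return invisibly, the sidecar path.
#' @export
save_phase_stack <- function(stack, dir, prefix) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  as_img <- function(arr) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- stack$spacing
    img
  }
  for (i in 1:4) {
    RNifti::writeNifti(as_img(stack$volumes[[i]]),
                       file.path(dir, paste0(prefix, "_", PHASE_NAMES[i], ".nii.gz")))
    RNifti::writeNifti(as_img(stack$masks[[i]] * 1L),
                       file.path(dir, paste0(prefix, "_", PHASE_NAMES[i], "_mask.nii.gz")))
  }
  sidecar <- file.path(dir, paste0(prefix, "_stack.json"))
  meta <- list(spacing = stack$spacing, time_grid = stack$time_grid,
               norm_stats = attr(stack, "norm_stats"))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}
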