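## Synthetic 4-phase phantom cohorts and lightweight feature-series
## fixtures. The generators are pure functions of (config, seed) so every
## pipeline stage is testable without any external data.

#' Configuration for a synthetic 4-phase cohort
#'
#' The phantom emulates the structure the analysis assumes: per patient,
#' four co-registered phases containing one ellipsoidal lesion whose mean
#' intensity follows a class-dependent enhancement trajectory
#' (wash-in/washout of contrast agent) and whose interior carries a
#' class-dependent correlated random-field texture, on a quiet background,
#' with additive per-phase noise. Defaults: an MVI-negative-like class with
#' moderate arterial wash-in and slow washout, and an MVI-positive-like
#' class with stronger wash-in, faster washout and coarser, stronger
#' intra-lesion heterogeneity.
#'
#' @param n_patients cohort size.
#' @param prevalence positive-class fraction (exact allocation).
#' @param volume_shape voxel triple (default 48^3 at 1 mm isotropic).
#' @param lesion_radius_range mm range the per-axis ellipsoid radii are
#'   drawn from.
#' @param kinetics_by_class list with `neg` and `pos` 4-vectors: lesion mean
#'   intensity at the plain, arterial, portal venous and equilibrium phases.
#' @param texture_heterogeneity_by_class list with `neg`/`pos` lists holding
#'   `amplitude` (sd of the intra-lesion random field, intensity units) and
#'   `corr_vox` (Gaussian correlation length in voxels).
#' @param noise_sigma per-phase noise sd.
#' @param noise_model "gaussian" (default) or "rician".
#' @param background mean background intensity.
#' @param seed integer seed.
#' @return list of class \code{SyntheticCohortConfig}.
#' @export
synthetic_cohort_config <- function(n_patients = 20,
                                    prevalence = 0.34,
                                    volume_shape = c(48, 48, 48),
                                    lesion_radius_range = c(5, 9),
                                    kinetics_by_class = list(
                                      neg = c(100, 160, 140, 120),
                                      pos = c(100, 180, 130, 105)),
                                    texture_heterogeneity_by_class = list(
                                      neg = list(amplitude = 10, corr_vox = 1.5),
                                      pos = list(amplitude = 18, corr_vox = 2.5)),
                                    noise_sigma = 5,
                                    noise_model = c("gaussian", "rician"),
                                    background = 80,
                                    seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_patients >= 4, prevalence > 0, prevalence < 1,
            all(volume_shape > 0), all(lesion_radius_range > 0),
            noise_sigma >= 0)
  n_pos <- round(prevalence * n_patients)
  if (n_pos < 2 || n_patients - n_pos < 2)
    stop("each class needs at least 2 patients")
  structure(as.list(environment()), class = "SyntheticCohortConfig")
}

gaussian_smooth_3d <- function(v, sigma_vox) {
  if (sigma_vox <= 0) return(v)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  for (axis in 1:3) v <- rotate_axes(axis_filter_stationary(v, k))
  v
}

ellipsoid_mask <- function(dims, centre, radii) {
  x <- (seq_len(dims[1]) - centre[1]) / radii[1]
  y <- (seq_len(dims[2]) - centre[2]) / radii[2]
  z <- (seq_len(dims[3]) - centre[3]) / radii[3]
  d2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  (d2 <= 1) * 1L
}

#' Generate a synthetic 4-phase cohort
#'
#' @param config a \code{\link{synthetic_cohort_config}}.
#' @return list with `stacks` (list of \code{PhaseStack}), `labels`
#'   (integer 0/1, exactly round(prevalence * n) positives), and `manifest`
#'   (data.frame with patient_id and label).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "SyntheticCohortConfig"))
  set.seed(config$seed)
  n <- config$n_patients
  n_pos <- round(config$prevalence * n)
  labels <- sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
  dims <- config$volume_shape
  if (2 * max(config$lesion_radius_range) + 4 > min(dims))
    stop("lesion larger than volume")
  stacks <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- if (labels[i] == 1) "pos" else "neg"
    kin <- config$kinetics_by_class[[cls]]
    tex <- config$texture_heterogeneity_by_class[[cls]]
    radii <- stats::runif(3, config$lesion_radius_range[1], config$lesion_radius_range[2])
    centre <- dims / 2 + stats::runif(3, -2, 2)
    mask <- ellipsoid_mask(dims, centre, radii)
    inles <- mask == 1
    ## one patient-specific heterogeneity field shared by all phases
    field <- gaussian_smooth_3d(array(stats::rnorm(prod(dims)), dims), tex$corr_vox)
    fs <- stats::sd(field[inles])
    if (is.finite(fs) && fs > 0) {
      ## zero-mean inside the lesion so the trajectory stays on the kinetics
      field <- (field - mean(field[inles])) / fs * tex$amplitude
    } else field <- field * 0
    vols <- lapply(seq_len(4), function(p) {
      v <- array(config$background, dims)
      v[inles] <- kin[p] + field[inles]
      noise <- array(stats::rnorm(prod(dims), 0, config$noise_sigma), dims)
      if (config$noise_model == "rician" && config$noise_sigma > 0) {
        n2 <- array(stats::rnorm(prod(dims), 0, config$noise_sigma), dims)
        sqrt((v + noise)^2 + n2^2)
      } else v + noise
    })
    stacks[[i]] <- phase_stack(vols, rep(list(mask), 4))
  }
  ids <- sprintf("P%03d", seq_len(n))
  list(stacks = stacks, labels = labels,
       manifest = data.frame(patient_id = ids, label = labels))
}

shift_or <- function(mask, off) {
  out <- array(FALSE, dim(mask))
  b <- shift_blocks(dim(mask), off)
  out[b$base] <- mask[b$shifted] > 0
  out
}

dilate6 <- function(mask) {
  m <- mask > 0
  for (off in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    m <- m | shift_or(mask, off)
  m * 1L
}

erode6 <- function(mask) {
  m <- mask > 0
  for (off in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
    shifted <- array(FALSE, dim(mask))
    b <- shift_blocks(dim(mask), off)
    shifted[b$base] <- mask[b$shifted] > 0
    m <- m & shifted
  }
  m * 1L
}

jitter_mask <- function(mask, jitter_vox, grow) {
  k <- floor(jitter_vox)
  frac <- jitter_vox - k
  m <- mask
  op <- if (grow) dilate6 else erode6
  if (k > 0) for (i in seq_len(k)) m <- op(m)
  if (frac > 0) {
    full <- op(m)
    boundary <- which(full != m)
    flip <- boundary[stats::runif(length(boundary)) < frac]
    m[flip] <- full[flip]
  }
  if (sum(m) == 0) stop("jitter collapses mask to empty")
  m
}

#' Simulate two-reader segmentation variants
#'
#' Produces two mask variants of a stack (volumes unchanged) by
#' morphological dilation (variant 1) and erosion (variant 2) of magnitude
#' \code{jitter_mm}, with probabilistic boundary flips for the fractional
#' part. jitter_mm = 0 returns the stack unchanged twice, so downstream
#' intra-observer ICCs equal 1.
#'
#' @param stack a \code{\link{phase_stack}}.
#' @param jitter_mm boundary perturbation magnitude in mm.
#' @param seed integer seed.
#' @return list of two \code{PhaseStack}s.
#' @export
generate_reader_variants <- function(stack, jitter_mm, seed = 1L) {
  stopifnot(inherits(stack, "PhaseStack"), jitter_mm >= 0)
  set.seed(seed)
  jv <- jitter_mm / mean(stack$spacing)
  m1 <- lapply(stack$masks, jitter_mask, jitter_vox = jv, grow = TRUE)
  m2 <- lapply(stack$masks, jitter_mask, jitter_vox = jv, grow = FALSE)
  list(phase_stack(stack$volumes, m1, stack$spacing, stack$time_grid),
       phase_stack(stack$volumes, m2, stack$spacing, stack$time_grid))
}

#' Generate per-phase feature matrices without images
#'
#' Emits 4 per-phase static-feature matrices directly, for modeling tests
#' that do not need the image pipeline. Three designs:
#' \itemize{
#'   \item "none": every value iid N(base_mean, base_sd); an exchangeable
#'     null with no class signal anywhere.
#'   \item "marginal": the positive class is shifted by
#'     \code{marginal_shift} in every phase (a static signal).
#'   \item "temporal-only": per patient and feature, 4 iid
#'     N(base_mean, base_sd) draws are order-sorted; class 0 places them
#'     monotonically across phases (rising or falling, probability 1/2
#'     each), class 1 in a zigzag order (rank patterns (1,3,2,4) or
#'     (4,2,3,1), probability 1/2 each). Each phase receives the same
#'     distribution over order-statistic ranks in both classes, so the
#'     per-phase class marginals are matched exactly; only the ordering
#'     across phases carries the label.
#' }
#'
#' @param n_features number of static features.
#' @param class_effect "temporal-only", "marginal" or "none".
#' @param n_patients cohort size.
#' @param seed integer seed.
#' @param prevalence positive fraction (exact allocation).
#' @param base_mean,base_sd distribution of the feature values.
#' @param marginal_shift class mean shift for the "marginal" design.
#' @param noise_sd extra iid noise added to every value.
#' @return list with `phases` (list of 4 n x p matrices named plain,
#'   arterial, portal, equilibrium) and `labels`.
#' @export
generate_feature_series <- function(n_features, class_effect = c("temporal-only", "marginal", "none"),
                                    n_patients, seed = 1L, prevalence = 0.5,
                                    base_mean = 10, base_sd = 1.5,
                                    marginal_shift = 0.8, noise_sd = 0) {
  class_effect <- match.arg(class_effect)
  set.seed(seed)
  n <- n_patients; p <- n_features
  n_pos <- round(prevalence * n)
  labels <- sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
  fn <- sprintf("F%03d", seq_len(p))
  phases <- lapply(1:4, function(k) matrix(0, n, p, dimnames = list(NULL, fn)))

  if (class_effect %in% c("none", "marginal")) {
    for (k in 1:4) {
      m <- matrix(stats::rnorm(n * p, base_mean, base_sd), n, p)
      if (class_effect == "marginal") m <- m + labels * marginal_shift
      phases[[k]][, ] <- m
    }
  } else {
    ## rank patterns: rows = which order statistic each phase receives
    pat <- rbind(c(1, 2, 3, 4), c(4, 3, 2, 1),   # class 0: monotone
                 c(1, 3, 2, 4), c(4, 2, 3, 1))   # class 1: zigzag
    draws <- matrix(stats::rnorm(4 * n * p, base_mean, base_sd), nrow = 4)
    sorted <- apply(draws, 2, sort)               # 4 x (n*p), order stats
    pick <- ifelse(rep(labels, times = p) == 1, 3L, 1L) +
      (stats::runif(n * p) < 0.5)
    for (k in 1:4) {
      ranks <- pat[cbind(pick, k)]
      phases[[k]][, ] <- matrix(sorted[cbind(ranks, seq_len(n * p))], n, p)
    }
  }
  if (noise_sd > 0)
    phases <- lapply(phases, function(m) m + stats::rnorm(length(m), 0, noise_sd))
  names(phases) <- PHASE_NAMES
  list(phases = phases, labels = labels)
}
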