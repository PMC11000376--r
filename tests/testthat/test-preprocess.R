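make_stack <- function(dims = c(10, 10, 10), spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  vols <- lapply(1:4, function(i) array(rnorm(prod(dims), 50, 10), dims))
  m <- array(0L, dims)
  m[4:7, 4:7, 4:7] <- 1L
  phase_stack(vols, rep(list(m), 4), spacing = spacing)
}

test_that("phase stack construction validates its invariants", {
  st <- make_stack()
  expect_s3_class(st, "PhaseStack")
  expect_length(st$volumes, 4)
  expect_identical(names(st$volumes), c("plain", "arterial", "portal", "equilibrium"))

  dims <- c(6, 6, 6)
  v <- array(0, dims); m <- array(0L, dims); m[3, 3, 3] <- 1L
  bad <- m; bad[2, 2, 2] <- 2L
  expect_error(phase_stack(rep(list(v), 4), rep(list(bad), 4)), "non-binary mask")
  expect_error(phase_stack(rep(list(v), 3), rep(list(m), 3)), "exactly 4 phases")
  m2 <- array(0L, dims + 1)
  expect_error(phase_stack(rep(list(v), 4), list(m, m, m, m2)), "grid mismatch")
  expect_error(phase_stack(rep(list(v), 4), rep(list(array(0L, dims)), 4)),
               "foreground")
  expect_error(phase_stack(rep(list(v), 4), rep(list(m), 4), time_grid = c(1, 2, 2, 3)),
               "strictly increasing")
})

test_that("NIfTI round trip preserves a stack", {
  st <- make_stack(spacing = c(2, 2, 2))
  dir <- withr::local_tempdir()
  save_phase_stack(st, dir, "pt1")
  vols <- file.path(dir, paste0("pt1_", c("plain", "arterial", "portal", "equilibrium"), ".nii.gz"))
  masks <- file.path(dir, paste0("pt1_", c("plain", "arterial", "portal", "equilibrium"), "_mask.nii.gz"))
  st2 <- load_phase_stack(vols, masks, time_grid = c(1, 2, 3, 4))
  expect_equal(st2$spacing, c(2, 2, 2))
  expect_equal(st2$volumes[[2]], st$volumes[[2]], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(st2$masks[[1]] > 0, st$masks[[1]] > 0)

  expect_error(load_phase_stack(vols[c(1, 2, 3)], masks[c(1, 2, 3)]), "exactly 4 phases")
  expect_error(load_phase_stack(replace(vols, 1, "nope.nii.gz"), masks), "missing file")
})

test_that("isotropic resampling maps grids and keeps masks binary", {
  st <- make_stack(spacing = c(2, 2, 2))
  out <- resample_isotropic(st)
  expect_equal(dim(out$volumes[[1]]), c(19, 19, 19))
  expect_equal(out$spacing, c(1, 1, 1))
  expect_true(all(out$masks[[1]] %in% c(0, 1)))
  ## already isotropic: untouched
  st1 <- make_stack(spacing = c(1, 1, 1))
  expect_identical(resample_isotropic(st1)$volumes, st1$volumes)
  ## idempotent on the grid shape
  again <- resample_isotropic(out)
  expect_equal(dim(again$volumes[[1]]), dim(out$volumes[[1]]))
  expect_error(resample_isotropic(st, c(0, 1, 1)), "non-positive")
})

test_that("z-normalisation follows the closed form and rejects constants", {
  v <- array(c(2, 4, 6), c(3, 1, 1))
  z <- znormalize(v)
  expect_equal(mean(z), 0)
  expect_equal(sd(as.numeric(z)), 1)
  ## a voxel at the mean maps to zero
  expect_equal(z[2, 1, 1], 0)
  expect_error(znormalize(array(5, c(3, 3, 3))), "constant region")

  ## invertible: x = z * sigma + mu recovers the input
  set.seed(3)
  x <- array(rnorm(64, 10, 4), c(4, 4, 4))
  z <- znormalize(x)
  back <- z * sd(as.numeric(x)) + mean(x)
  expect_equal(as.numeric(back), as.numeric(x), tolerance = 1e-10)

  ## mask-only statistics
  m <- array(0L, c(4, 4, 4)); m[1:2, 1, 1] <- 1L
  zm <- znormalize(x, region = "mask-only", mask = m)
  expect_equal(mean(zm[m > 0]), 0)
})

test_that("gray-level quantization uses equal-width bins labelled from 1", {
  dims <- c(4, 4, 2)
  m <- array(1L, dims)
  v <- array(seq(0, 630, length.out = prod(dims)), dims)
  q <- quantize_gray_levels(v, m)
  expect_s3_class(q, "QuantizedROI")
  expect_equal(q$n_levels, 64L)                  # the default
  expect_equal(min(q$values), 1L)                # ROI min -> level 1
  expect_equal(max(q$values), 64L)               # ROI max -> level 64
  expect_equal(q$array[which(v == 0)[1]], 1L)
  expect_equal(q$array[which(v == 630)[1]], 64L)

  ## constant ROI: all level 1 by convention
  qc <- quantize_gray_levels(array(7, dims), m)
  expect_true(all(qc$values == 1L))

  ## invariant under positive affine rescaling of the intensities
  for (seed in 1:3) {
    set.seed(seed)
    x <- array(rnorm(prod(dims)), dims)
    q1 <- quantize_gray_levels(x, m, 16)
    q2 <- quantize_gray_levels(3.7 * x + 11, m, 16)
    expect_identical(q1$values, q2$values)
  }
  expect_error(quantize_gray_levels(v, array(0L, dims)), "non-empty")
})

test_that("preprocess_stack resamples then normalises, recording statistics", {
  st <- make_stack(spacing = c(2, 2, 2))
  out <- preprocess_stack(st)
  expect_equal(out$spacing, c(1, 1, 1))
  expect_equal(mean(out$volumes[[1]]), 0, tolerance = 1e-12)
  ns <- attr(out, "norm_stats")
  expect_named(ns, c("plain", "arterial", "portal", "equilibrium"))
  expect_true(all(vapply(ns, function(s) s["sd"] > 0, TRUE)))
})
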