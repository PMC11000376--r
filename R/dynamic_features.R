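#' Dynamic radiomics features from a 4-phase feature trajectory
#'
#' A "dynamic" radiomics feature summarises how a single static radiomics
#' feature evolves over the phases of a multi-phase (DCE-MRI) examination.
#' For a trajectory of k = 4 phase values, 20 dynamic feature types are
#' produced in three families:
#'
#' \itemize{
#'   \item integrated (3): mean, population variance, and coefficient of
#'     variation of the 4 values;
#'   \item discrete (6): relative change rate (RCR) and relative average
#'     change rate (RACR) over the three consecutive phase segments
#'     (plain--arterial, arterial--portal venous, portal venous--equilibrium);
#'   \item parameter fitting (11): least-squares linear (slope \code{k},
#'     intercept \code{d}), quadratic (\code{a}, \code{b}, \code{c} plus the
#'     time of maximal curvature \code{T_maxQK} and the curvature at the
#'     observed feature maximum \code{QK_max_feature}) and exponential
#'     (\code{alpha}, \code{beta} in \eqn{\alpha e^t + \beta}, plus
#'     \code{T_maxEK} and \code{EK_max_feature}) fits against the time grid.
#' }
#'
#' Degenerate inputs never raise errors: zero denominators produce NaN
#' (imputed later during modeling) and a vanishing quadratic coefficient
#' yields the documented zero-curvature convention.
#'
#' @param series numeric vector of length 4: the static feature value at each
#'   phase, ordered (plain, arterial, portal venous, equilibrium).
#' @param time_grid strictly increasing numeric vector of length 4; defaults
#'   to the phase indices 1:4.
#' @param racr_denominator how the RACR denominator is formed: the mean of
#'   all four phase values (default) or the mean of the two segment endpoint
#'   values.
#' @param corrected_curvature if TRUE the exponential curvature uses the
#'   mathematically exact curvature of \eqn{\alpha e^t + \beta} (with
#'   \eqn{\alpha^2 e^{2t}} in the denominator); the default uses
#'   \eqn{\alpha e^{2t}}, the form the construction was defined with.
#' @return named numeric vector of length 20.
#' @examples
#' dynamic_feature_block(c(10, 20, 30, 30))
#' @export
dynamic_feature_block <- function(series, time_grid = 1:4,
                                  racr_denominator = c("four-phase-mean", "segment-midpoint"),
                                  corrected_curvature = FALSE) {
  m <- dynamic_features_matrix(matrix(as.numeric(series), nrow = 4), time_grid,
                               racr_denominator = racr_denominator,
                               corrected_curvature = corrected_curvature)
  stats::setNames(as.numeric(m), rownames(m))
}

#' @rdname dynamic_feature_block
#' @export
dynamic_feature_names <- function() {
  c("integrated__mean", "integrated__variance", "integrated__cv",
    "discrete__RCR_seg1", "discrete__RCR_seg2", "discrete__RCR_seg3",
    "discrete__RACR_seg1", "discrete__RACR_seg2", "discrete__RACR_seg3",
    "linear__k", "linear__d",
    "quadratic__a", "quadratic__b", "quadratic__c",
    "quadratic__T_maxQK", "quadratic__QK_max_feature",
    "exponential__alpha", "exponential__beta",
    "exponential__T_maxEK", "exponential__EK_max_feature")
}

#' Vectorised dynamic feature construction
#'
#' Computes the 20 dynamic feature types for many feature series at once.
#' All least-squares fits share the same design matrix (the time grid), so
#' the coefficients for every series are obtained with one pseudoinverse
#' multiplication per model family.
#'
#' @param series_matrix 4 x N numeric matrix; each column is one feature
#'   series over the 4 phases.
#' @inheritParams dynamic_feature_block
#' @return 20 x N numeric matrix with rownames \code{dynamic_feature_names()}.
#' @export
dynamic_features_matrix <- function(series_matrix, time_grid = 1:4,
                                    racr_denominator = c("four-phase-mean", "segment-midpoint"),
                                    corrected_curvature = FALSE) {
  racr_denominator <- match.arg(racr_denominator)
  stopifnot(is.matrix(series_matrix), nrow(series_matrix) == 4)
  t <- as.numeric(time_grid)
  if (length(t) != 4 || any(diff(t) <= 0))
    stop("time_grid must be 4 strictly increasing values")
  Y <- series_matrix
  n <- ncol(Y)

  ## integrated: mean, population variance, coefficient of variation
  mu <- colMeans(Y)
  v <- colMeans(Y^2) - mu^2
  v <- pmax(v, 0)
  cv <- ifelse(mu == 0, NaN, sqrt(v) / mu)

  ## discrete: RCR / RACR over the three consecutive segments
  d1 <- abs(Y[2, ] - Y[1, ]); d2 <- abs(Y[3, ] - Y[2, ]); d3 <- abs(Y[4, ] - Y[3, ])
  rcr <- rbind(safe_div(d1, Y[1, ]), safe_div(d2, Y[2, ]), safe_div(d3, Y[3, ]))
  if (racr_denominator == "four-phase-mean") {
    racr <- rbind(safe_div(d1, mu), safe_div(d2, mu), safe_div(d3, mu))
  } else {
    racr <- rbind(safe_div(d1, (Y[1, ] + Y[2, ]) / 2),
                  safe_div(d2, (Y[2, ] + Y[3, ]) / 2),
                  safe_div(d3, (Y[3, ] + Y[4, ]) / 2))
  }

  ## least-squares fits: shared pseudoinverses
  P_lin <- ls_pinv(cbind(t, 1))
  P_quad <- ls_pinv(cbind(t^2, t, 1))
  P_exp <- ls_pinv(cbind(exp(t), 1))
  lin <- P_lin %*% Y          # rows: k, d
  quad <- P_quad %*% Y        # rows: a, b, c
  ex <- P_exp %*% Y           # rows: alpha, beta

  ## time of the observed series maximum (earliest on ties)
  imax <- max.col(t(Y), ties.method = "first")
  tmax_obs <- t[imax]

  ## quadratic curvature QK(t) = |2a| / (1 + (2at + b)^2)^(3/2)
  a <- quad[1, ]; b <- quad[2, ]
  adeg <- abs(a) < 1e-12
  T_maxQK <- ifelse(adeg, t[1], -b / (2 * a))
  QK_maxfeat <- ifelse(adeg, 0, qk_curvature(a, b, tmax_obs))

  ## exponential curvature EK(t) = |alpha e^t| / (1 + alpha e^{2t})^(3/2)
  ## (corrected form uses alpha^2 e^{2t})
  alpha <- ex[1, ]
  T_maxEK <- ek_argmax(alpha, t[1], t[4], corrected = corrected_curvature)
  T_maxEK[abs(alpha) < 1e-12] <- t[1]
  EK_maxfeat <- ek_curvature(alpha, tmax_obs, corrected = corrected_curvature)
  EK_maxfeat[abs(alpha) < 1e-12] <- 0

  out <- rbind(mu, v, cv,
               rcr, racr,
               lin,
               quad, T_maxQK, QK_maxfeat,
               ex, T_maxEK, EK_maxfeat)
  rownames(out) <- dynamic_feature_names()
  colnames(out) <- colnames(series_matrix)
  out
}

safe_div <- function(num, den) ifelse(den == 0, NaN, num / den)

## pseudoinverse (X'X)^{-1} X' for a full-rank design
ls_pinv <- function(X) solve(crossprod(X), t(X))

qk_curvature <- function(a, b, t) {
  abs(2 * a) / (1 + (2 * a * t + b)^2)^1.5
}

ek_curvature <- function(alpha, t, corrected = FALSE) {
  base <- if (corrected) 1 + alpha^2 * exp(2 * t) else 1 + alpha * exp(2 * t)
  out <- abs(alpha * exp(t)) / base^1.5
  out[base <= 0] <- NaN
  out
}

## numeric argmax of EK over [lo, hi] by iterative grid refinement,
## vectorised over alpha; grid step is refined below 1e-6
ek_argmax <- function(alpha, lo, hi, corrected = FALSE, n_grid = 101L) {
  n <- length(alpha)
  los <- rep(lo, n); his <- rep(hi, n)
  offs <- seq(0, 1, length.out = n_grid)
  best <- rep(NaN, n)
  repeat {
    step <- (his - los) / (n_grid - 1)
    tg <- los + outer(his - los, offs)          # n x n_grid time grid
    ek <- ek_curvature(rep(alpha, n_grid), as.numeric(tg), corrected = corrected)
    ek <- matrix(ek, nrow = n)
    ek[is.na(ek)] <- -Inf
    idx <- max.col(ek, ties.method = "first")
    ok <- ek[cbind(seq_len(n), idx)] > -Inf
    centre <- tg[cbind(seq_len(n), idx)]
    best[ok] <- centre[ok]
    if (all(step < 1e-7)) break
    los <- pmax(lo, centre - step)
    his <- pmin(hi, centre + step)
  }
  best
}

#' Integrated dynamic features (mean, variance, coefficient of variation)
#'
#' @inheritParams dynamic_feature_block
#' @return named numeric vector of length 3. Variance is the population
#'   variance over the 4 phase values; CV is population sd / mean (NaN when
#'   the mean is 0).
#' @export
integrated_features <- function(series) {
  dynamic_feature_block(series)[1:3]
}

#' Discrete dynamic features (RCR and RACR per consecutive segment)
#'
#' RCR over segment (i, i+1) is |v[i+1] - v[i]| / v[i]; RACR divides the same
#' absolute change by the mean of all four phase values (default reading) or
#' by the segment midpoint mean.
#'
#' @inheritParams dynamic_feature_block
#' @return named numeric vector of length 6.
#' @export
discrete_features <- function(series, racr_denominator = c("four-phase-mean", "segment-midpoint")) {
  dynamic_feature_block(series, racr_denominator = racr_denominator)[4:9]
}

#' Linear fit of a feature trajectory
#'
#' Ordinary least squares of value on time: value = k * t + d.
#'
#' @inheritParams dynamic_feature_block
#' @return named numeric vector c(k, d).
#' @export
fit_linear <- function(series, time_grid = 1:4) {
  out <- dynamic_feature_block(series, time_grid)[10:11]
  stats::setNames(out, c("k", "d"))
}

#' Quadratic fit and curvature features
#'
#' Least-squares fit of value = a t^2 + b t + c, plus the time of maximal
#' curvature of the parabola (its vertex, -b / 2a) and the curvature
#' evaluated at the time point of the observed series maximum (earliest on
#' ties). When a = 0 the curvature is identically zero: T_maxQK is reported
#' as t1 and QK_max_feature as 0.
#'
#' @inheritParams dynamic_feature_block
#' @return named numeric vector c(a, b, c, T_maxQK, QK_max_feature).
#' @export
fit_quadratic <- function(series, time_grid = 1:4) {
  out <- dynamic_feature_block(series, time_grid)[12:16]
  stats::setNames(out, c("a", "b", "c", "T_maxQK", "QK_max_feature"))
}

#' Exponential fit and curvature features
#'
#' The model value = alpha * e^t + beta is linear in (alpha, beta) and is
#' fitted by least squares on the basis (e^t, 1). The curvature profile
#' EK(t) = |alpha e^t| / (1 + alpha e^{2t})^(3/2) is maximised numerically
#' on [t1, t4] (grid refinement to 1e-6); points where the base
#' 1 + alpha e^{2t} is non-positive are excluded as NaN.
#'
#' @inheritParams dynamic_feature_block
#' @return named numeric vector c(alpha, beta, T_maxEK, EK_max_feature).
#' @export
fit_exponential <- function(series, time_grid = 1:4, corrected_curvature = FALSE) {
  out <- dynamic_feature_block(series, time_grid, corrected_curvature = corrected_curvature)[17:20]
  stats::setNames(out, c("alpha", "beta", "T_maxEK", "EK_max_feature"))
}

#' Build the per-patient dynamic feature vector
#'
#' Assembles, for each of the static features shared by the four phase
#' vectors, its 4-phase trajectory, and emits the 20 dynamic feature types
#' for each; a 484-feature static bank therefore yields 20 x 484 = 9680
#' dynamic features per patient. Names follow
#' \code{"<family>__<type>__<static feature name>"}.
#'
#' @param static_vectors list of 4 named numeric vectors (one per phase,
#'   identical names and ordering).
#' @inheritParams dynamic_feature_block
#' @return named numeric vector of length 20 * length(static_vectors[[1]]).
#' @export
build_dynamic_vector <- function(static_vectors, time_grid = 1:4,
                                 racr_denominator = c("four-phase-mean", "segment-midpoint"),
                                 corrected_curvature = FALSE) {
  stopifnot(length(static_vectors) == 4)
  nm <- names(static_vectors[[1]])
  lens <- vapply(static_vectors, length, 1L)
  if (length(unique(lens)) != 1)
    stop("phase vectors must have identical lengths")
  for (v in static_vectors[-1])
    if (!identical(names(v), nm)) stop("phase vectors must share feature names and ordering")
  S <- do.call(rbind, lapply(static_vectors, as.numeric))  # 4 x p
  colnames(S) <- nm
  D <- dynamic_features_matrix(S, time_grid,
                               racr_denominator = racr_denominator,
                               corrected_curvature = corrected_curvature)
  out <- as.numeric(D)
  names(out) <- as.character(outer(rownames(D), colnames(D), paste, sep = "__"))
  out
}
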