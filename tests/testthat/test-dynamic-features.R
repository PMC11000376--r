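test_that("integrated features match closed forms and degrade to NaN safely", {
  f <- integrated_features(c(1, 2, 3, 4))
  expect_equal(unname(f), c(2.5, 1.25, sqrt(1.25) / 2.5))
  fc <- integrated_features(c(3, 3, 3, 3))
  expect_equal(unname(fc), c(3, 0, 0))
  fz <- integrated_features(c(-1, 1, -1, 1))   # mean zero
  expect_true(is.nan(fz["integrated__cv"]))
})

test_that("discrete change rates follow the segment definitions", {
  f <- discrete_features(c(10, 20, 30, 30))
  expect_equal(unname(f["discrete__RCR_seg1"]), 1.0)
  expect_equal(unname(f["discrete__RCR_seg3"]), 0.0)
  expect_equal(unname(f["discrete__RACR_seg1"]), 10 / 22.5)
  expect_equal(unname(discrete_features(c(5, 5, 5, 5))), rep(0, 6))
  ## zero denominator -> NaN, no exception
  expect_true(is.nan(discrete_features(c(0, 1, 2, 3))["discrete__RCR_seg1"]))
  ## invariance under positive scaling
  for (seed in 1:5) {
    set.seed(seed)
    s <- runif(4, 1, 10)
    expect_equal(discrete_features(7.3 * s), discrete_features(s))
  }
  ## alternative RACR denominator: segment midpoint mean
  fm <- discrete_features(c(10, 20, 30, 30), racr_denominator = "segment-midpoint")
  expect_equal(unname(fm["discrete__RACR_seg1"]), 10 / 15)
})

test_that("linear fits are exact least squares", {
  expect_equal(unname(fit_linear(c(2, 4, 6, 8))), c(2, 0))
  expect_equal(unname(fit_linear(c(5, 5, 5, 5))), c(0, 5))
  s <- 3 * (1:4) - 1
  expect_equal(unname(fit_linear(s)), c(3, -1), tolerance = 1e-10)
})

test_that("quadratic fit recovers parameters and its printed curvature", {
  f <- fit_quadratic((1:4)^2)
  expect_equal(unname(f[c("a", "b", "c")]), c(1, 0, 0), tolerance = 1e-10)
  expect_equal(unname(f["T_maxQK"]), 0)     # vertex of t^2
  ## QK at t = 0 for a=1,b=0: |2|/1^{3/2} = 2
  expect_equal(abs(2 * f["a"]) / (1 + (2 * f["a"] * 0 + f["b"])^2)^1.5, 2,
               ignore_attr = TRUE, tolerance = 1e-10)
  fc <- fit_quadratic(rep(4, 4))
  expect_equal(unname(fc[c("a", "b", "c", "T_maxQK", "QK_max_feature")]),
               c(0, 0, 4, 1, 0))
  ## random series vs an independent normal-equations solution
  for (seed in 1:5) {
    set.seed(seed)
    y <- rnorm(4)
    X <- cbind((1:4)^2, 1:4, 1)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(unname(fit_quadratic(y)[c("a", "b", "c")]), as.numeric(beta),
                 tolerance = 1e-8)
  }
  ## noiseless model-generated series: exact recovery
  y <- 2.5 * (1:4)^2 - 1.2 * (1:4) + 0.7
  expect_equal(unname(fit_quadratic(y)[c("a", "b", "c")]), c(2.5, -1.2, 0.7),
               tolerance = 1e-8)
})

test_that("exponential fit recovers parameters; curvature follows the printed form", {
  f <- fit_exponential(exp(1:4))
  expect_equal(unname(f[c("alpha", "beta")]), c(1, 0), tolerance = 1e-8)
  y <- 0.8 * exp(1:4) + 2.5
  expect_equal(unname(fit_exponential(y)[c("alpha", "beta")]), c(0.8, 2.5),
               tolerance = 1e-8)
  ## alpha = 0: EK identically zero
  fz <- fit_exponential(rep(3, 4))
  expect_equal(unname(fz[c("alpha", "EK_max_feature")]), c(0, 0), tolerance = 1e-12)
  ## alpha = 1, t = 0: EK = 1 / 2^(3/2)
  ek <- function(alpha, t) abs(alpha * exp(t)) / (1 + alpha * exp(2 * t))^1.5
  expect_equal(ek(1, 0), 2^-1.5)
  ## numeric argmax matches the analytic interior optimum for alpha > 0
  for (alpha in c(0.05, 0.2, 1)) {
    y <- alpha * exp(1:4) + 1
    f <- fit_exponential(y)
    t_star <- min(max(-0.5 * log(2 * alpha), 1), 4)
    expect_equal(unname(f["T_maxEK"]), t_star, tolerance = 1e-4)
    expect_gte(f["T_maxEK"], 1); expect_lte(f["T_maxEK"], 4)
  }
})

test_that("the dynamic block has 20 entries in the documented families", {
  nm <- dynamic_feature_names()
  expect_length(nm, 20)
  fam <- sub("__.*", "", nm)
  expect_equal(unname(table(fam)[c("integrated", "discrete", "linear",
                                   "quadratic", "exponential")]),
               c(3L, 6L, 2L, 5L, 4L), ignore_attr = TRUE)
})

test_that("per-patient dynamic vectors concatenate to 20 x p", {
  set.seed(8)
  p <- 25
  fn <- sprintf("F%02d", 1:p)
  sv <- lapply(1:4, function(k) setNames(runif(p, 1, 10), fn))
  dv <- build_dynamic_vector(sv)
  expect_length(dv, 20 * p)
  expect_true(all(grepl("__F", names(dv))))
  expect_identical(names(dv)[1:2], c("integrated__mean__F01", "integrated__variance__F01"))
  ## identical phases: constant-series cascade
  dz <- build_dynamic_vector(rep(list(setNames(rep(2, p), fn)), 4))
  expect_lt(max(abs(dz[grep("variance|RCR|RACR|linear__k|quadratic__a", names(dz))])),
            1e-10)
  ## permuting phases changes discrete/fit features, not integrated ones
  dp <- build_dynamic_vector(sv[c(3, 1, 4, 2)])
  expect_equal(dp[grep("^integrated__(mean|variance)", names(dp))],
               dv[grep("^integrated__(mean|variance)", names(dv))])
  expect_false(isTRUE(all.equal(dp[grep("RCR_seg1", names(dp))],
                                dv[grep("RCR_seg1", names(dv))])))
  ## mismatches are rejected
  expect_error(build_dynamic_vector(sv[1:3]))
  bad <- sv; names(bad[[2]])[1] <- "other"
  expect_error(build_dynamic_vector(bad), "share feature names")
})

test_that("vectorised and scalar paths agree", {
  set.seed(10)
  S <- matrix(runif(4 * 30, 1, 20), 4, 30)
  D <- dynamic_features_matrix(S)
  for (j in c(1, 7, 30))
    expect_equal(D[, j], dynamic_feature_block(S[, j]), ignore_attr = TRUE)
})

test_that("curvature of the fitted parabola matches the analytic curvature", {
  ## QK(t) = |2a| / (1 + (2at + b)^2)^{3/2} is the curvature of at^2+bt+c
  for (seed in 1:5) {
    set.seed(seed)
    a <- runif(1, -2, 2); b <- runif(1, -2, 2); tt <- runif(1, 0, 4)
    y2 <- 2 * a                       # f''
    y1 <- 2 * a * tt + b              # f'
    kappa <- abs(y2) / (1 + y1^2)^1.5
    expect_equal(abs(2 * a) / (1 + (2 * a * tt + b)^2)^1.5, kappa, tolerance = 1e-12)
  }
})
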