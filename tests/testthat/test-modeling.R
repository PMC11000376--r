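test_that("ICC(2,1) matches a two-way ANOVA computation and flags agreement", {
  set.seed(21)
  n <- 40
  truth <- rnorm(n, 10, 3)
  a <- matrix(truth + rnorm(n, 0, 0.3), ncol = 1)
  b <- matrix(truth + rnorm(n, 0, 0.3) + 0.1, ncol = 1)
  got <- icc21(a, b)
  ## independent route: mean squares from aov on the long layout
  d <- data.frame(y = c(a, b), subj = factor(rep(1:n, 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(aov(y ~ subj + rater, data = d))[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  ref <- (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
  expect_equal(got, ref, tolerance = 1e-10)
  expect_gt(got, 0.9)
})

test_that("the ICC filter keeps reproducible features only", {
  set.seed(22)
  n <- 40; p <- 6
  base <- matrix(rnorm(n * p, 0, 2), n, p, dimnames = list(NULL, paste0("F", 1:p)))
  r1a <- base
  r1b <- base; r1b[, 1:3] <- base[, 1:3] + rnorm(n * 3, 0, 0.05)   # stable
  r1b[, 4:6] <- matrix(rnorm(n * 3, 0, 2), n, 3)                   # independent
  r2 <- r1b
  tab <- icc_filter(r1a, r1b, r2)
  expect_true(all(tab$pass[1:3]))
  expect_false(any(tab$pass[4:6]))
  ## exact repeat: intra ICC = 1
  tab2 <- icc_filter(r1a, r1a, r1a)
  expect_equal(tab2$intra_observer_icc, rep(1, p), tolerance = 1e-12)
  expect_true(all(tab2$pass))
  ## zero between-subject variance: undefined, fails
  cst <- matrix(5, n, 1, dimnames = list(NULL, "C"))
  expect_false(icc_filter(cst, cst, cst)$pass)
})

test_that("standardisation derives from the training data only", {
  set.seed(23)
  tr <- matrix(rnorm(50 * 4, 7, 3), 50, 4, dimnames = list(NULL, paste0("F", 1:4)))
  va <- matrix(rnorm(30 * 4, 9, 3), 30, 4, dimnames = list(NULL, paste0("F", 1:4)))
  ztr <- standardize(tr)
  expect_equal(unname(colMeans(ztr)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(ztr, 2, sd)), rep(1, 4), tolerance = 1e-12)
  zva <- standardize(tr, va)
  expect_false(isTRUE(all.equal(unname(colMeans(zva)), rep(0, 4))))
  expect_equal(attr(zva, "means"), colMeans(tr))
})

test_that("F-test screening keeps class-associated features at the stated level", {
  set.seed(24)
  n <- 200
  y <- rep(0:1, each = n / 2)
  p_null <- 1000
  X <- matrix(rnorm(n * (p_null + 10)), n,
              dimnames = list(NULL, paste0("F", 1:(p_null + 10))))
  X[, 1:10] <- X[, 1:10] + y * 1.2          # planted signals
  keep <- f_test_screen(X, y)
  expect_true(all(paste0("F", 1:10) %in% keep))
  n_false <- length(setdiff(keep, paste0("F", 1:10)))
  ## null keep count ~ Binomial(1000, 0.05): generous 4-sigma band
  expect_gt(n_false, 50 - 4 * sqrt(50 * 0.95))
  expect_lt(n_false, 50 + 4 * sqrt(50 * 0.95))
  ## a feature identical across classes is dropped
  Xc <- cbind(X[, 1:5], Same = rep(c(1, 2), n / 2))
  expect_false("Same" %in% f_test_screen(Xc, y))
})

test_that("LASSO selection finds a planted predictor and is reproducible", {
  set.seed(25)
  n <- 300
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * 30), n, dimnames = list(NULL, paste0("F", 1:30)))
  X[, 7] <- y * 3 + rnorm(n, 0, 0.4)
  Z <- standardize(X)
  set.seed(99); sel1 <- lasso_select(Z, y)
  expect_true("F7" %in% sel1)
  set.seed(99); sel2 <- lasso_select(Z, y)
  expect_identical(sel1, sel2)
})

test_that("evaluation AUC equals pairwise concordance and behaves at the null", {
  ## toy list via a degenerate single-feature model
  y <- c(0, 0, 1, 1)
  s <- c(0.1, 0.4, 0.35, 0.8)
  model <- structure(list(signature_type = "SR", features = "F1",
                          impute_medians = c(F1 = 0), means = c(F1 = 0),
                          sds = c(F1 = 1), coefficients = c(F1 = 1),
                          intercept = 0, threshold = 0.5),
                     class = "SignatureModel")
  X <- matrix(qlogis(s), ncol = 1, dimnames = list(NULL, "F1"))
  ev <- evaluate(model, X, y)
  expect_equal(ev$auc, brute_auc(y, s))
  expect_equal(ev$auc, 0.75)
  expect_true(all(diff(ev$roc$fpr) >= 0) && all(diff(ev$roc$tpr) >= 0))
  ## perfect scores
  Xp <- matrix(qlogis(c(0.02, 0.03, 0.97, 0.98)), ncol = 1, dimnames = list(NULL, "F1"))
  expect_equal(evaluate(model, Xp, y)$auc, 1.0)
  expect_error(evaluate(model, Xp, c(1, 1, 1, 1)), "single-class")
  ## random scores at n = 2000 sit near 0.5
  set.seed(26)
  y2 <- rep(0:1, 1000)
  X2 <- matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "F1"))
  expect_lt(abs(evaluate(model, X2, y2)$auc - 0.5), 0.03)
})

test_that("DeLong comparison is symmetric, calibrated and degeneracy-safe", {
  set.seed(27)
  n <- 500
  y <- rep(0:1, n / 2)
  good <- y * 2 + rnorm(n)
  noise <- rnorm(n)
  cmp <- compare_auc(good, noise, y)
  expect_lt(cmp$p_value, 0.05)
  swapped <- compare_auc(noise, good, y)
  expect_equal(swapped$statistic, -cmp$statistic, tolerance = 1e-12)
  expect_equal(swapped$p_value, cmp$p_value)
  ## identical scores: AUC difference 0, p = 1
  same <- compare_auc(good, good, y)
  expect_equal(same$p_value, 1)
  ## power under repeated sampling
  hits <- 0
  for (r in 1:10) {
    set.seed(100 + r)
    yr <- rep(0:1, n / 2)
    pr <- compare_auc(yr * 2 + rnorm(n), rnorm(n), yr)$p_value
    hits <- hits + (pr < 0.05)
  }
  expect_gte(hits, 9)
})

test_that("signature construction composes the pipeline without leakage", {
  set.seed(28)
  tr <- generate_feature_series(30, "marginal", 120, seed = 301)
  va <- generate_feature_series(30, "marginal", 60, seed = 302)
  Xtr <- static_matrix_from_phases(tr$phases)
  Xva <- static_matrix_from_phases(va$phases)
  expect_equal(ncol(Xtr), 4 * 30)
  ## inject NaN: imputation must come from training medians
  Xtr[3, 5] <- NaN; Xva[2, 5] <- NaN
  set.seed(77)
  m <- build_signature(Xtr, tr$labels, "SR")
  expect_s3_class(m, "SignatureModel")
  expect_gt(length(m$features), 0)
  expect_true(m$threshold > 0 && m$threshold < 1)
  expect_equal(length(m$coefficients), length(m$features))
  ev <- evaluate(m, Xva, va$labels)
  expect_gt(ev$auc, 0.6)   # marginal signal is detectable statically
  ## leakage guard: permuting validation labels changes nothing trained
  set.seed(77)
  m2 <- build_signature(Xtr, tr$labels, "SR")
  yperm <- sample(va$labels)
  expect_identical(m$features, m2$features)
  expect_identical(m$impute_medians, m2$impute_medians)
  expect_identical(m$means, m2$means)
  expect_identical(m$threshold, m2$threshold)
  expect_equal(predict(m, Xva), predict(m2, Xva))
  ## DSR union bound
  suite <- fit_signature_suite(tr, va, cv_repeats = 2)
  expect_lte(length(suite$DSR$model$features),
             length(suite$SR$model$features) + length(suite$DR$model$features))
  expect_true(all(c("SR", "DR", "DSR") %in% names(suite)))
})
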