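## Reproducibility filtering, feature screening, signature construction
## (SR / DR / DSR) and evaluation.

#' Intraclass correlation, ICC(2,1), per feature
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' between two rating matrices (subjects x features), computed from the
#' two-way ANOVA mean squares. Features with zero between-subject variance
#' have an undefined ICC and are reported as NA.
#'
#' @param a,b numeric matrices of identical dimension: the same features on
#'   the same subjects under two segmentations/readers.
#' @return numeric vector, one ICC per feature (column).
#' @export
icc21 <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  n <- nrow(a); k <- 2
  S <- (a + b) / 2                              # subject means
  mA <- colMeans(a); mB <- colMeans(b)          # rater means
  grand <- (mA + mB) / 2
  MSR <- 2 * colSums(sweep(S, 2, grand)^2) / (n - 1)
  MSC <- n * ((mA - grand)^2 + (mB - grand)^2)
  resid2 <- sweep(a - S, 2, mA - grand)^2 + sweep(b - S, 2, mB - grand)^2
  MSE <- colSums(resid2) / (n - 1)
  den <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  icc <- (MSR - MSE) / den
  icc[den <= 0 | !is.finite(icc)] <- NA_real_
  icc
}

#' Reproducibility filter on intra- and inter-observer ICC
#'
#' @param features_r1a reader 1, first segmentation: subjects x features.
#' @param features_r1b reader 1, repeat segmentation.
#' @param features_r2 reader 2.
#' @param threshold both ICCs must exceed this to pass (default 0.8).
#' @return data.frame with feature, intra_observer_icc, inter_observer_icc
#'   and pass; features with undefined ICC fail.
#' @export
icc_filter <- function(features_r1a, features_r1b, features_r2, threshold = 0.8) {
  intra <- icc21(features_r1a, features_r1b)
  inter <- icc21(features_r1a, features_r2)
  pass <- !is.na(intra) & !is.na(inter) & intra > threshold & inter > threshold
  data.frame(feature = colnames(features_r1a) %||% paste0("V", seq_along(intra)),
             intra_observer_icc = intra, inter_observer_icc = inter,
             pass = pass, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## training-derived transforms ------------------------------------------------

fit_imputer <- function(train) {
  med <- apply(train, 2, function(col) stats::median(col[is.finite(col)]))
  med[!is.finite(med)] <- 0
  med
}

apply_imputer <- function(x, medians) {
  bad <- !is.finite(x)
  if (any(bad)) x[bad] <- medians[col(x)][bad]
  x
}

#' Z-score standardisation with training statistics only
#'
#' Column means and sds are estimated on \code{train} and applied unchanged
#' to \code{apply_to} (no leakage: validation data never influence the
#' transform).
#'
#' @param train training matrix.
#' @param apply_to matrix to transform (defaults to the training matrix).
#' @return transformed \code{apply_to}, with attributes "means" and "sds".
#' @export
standardize <- function(train, apply_to = train) {
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  out <- sweep(sweep(apply_to, 2, mu), 2, ifelse(sd > 0, sd, 1), "/")
  attr(out, "means") <- mu
  attr(out, "sds") <- sd
  out
}

#' F-test screening of features against a binary label
#'
#' One-way ANOVA F statistic per feature; features with p < alpha are kept.
#' With two groups this is equivalent to the pooled two-sample t-test.
#'
#' @param X samples x features matrix (imputed; non-finite values are
#'   median-imputed internally).
#' @param y binary labels (0/1).
#' @param alpha significance level (default 0.05).
#' @return character vector of selected feature names, with the per-feature
#'   p-values as attribute "p_values".
#' @export
f_test_screen <- function(X, y, alpha = 0.05) {
  y <- as.integer(y)
  stopifnot(all(y %in% 0:1), sum(y == 1) >= 2, sum(y == 0) >= 2)
  X <- apply_imputer(X, fit_imputer(X))
  n1 <- sum(y == 1); n0 <- sum(y == 0); n <- n1 + n0
  m1 <- colMeans(X[y == 1, , drop = FALSE])
  m0 <- colMeans(X[y == 0, , drop = FALSE])
  m <- colMeans(X)
  ss_b <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ss_w <- colSums(sweep(X[y == 1, , drop = FALSE], 2, m1)^2) +
    colSums(sweep(X[y == 0, , drop = FALSE], 2, m0)^2)
  Fstat <- ss_b / (ss_w / (n - 2))
  p <- stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  p[!is.finite(p)] <- 1
  keep <- colnames(X)[p < alpha]
  attr(keep, "p_values") <- stats::setNames(p, colnames(X))
  keep
}

stratified_folds <- function(y, k) {
  fid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fid[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fid
}

#' LASSO feature selection with repeated cross-validated penalty choice
#'
#' Fits an L1-penalised logistic path (glmnet) on standardised features and
#' chooses the penalty maximising the mean AUC over \code{cv_repeats}
#' repeats of stratified \code{cv_folds}-fold cross-validation. Features
#' with nonzero coefficients at the chosen penalty are returned; if the
#' selection is empty, the smallest penalty yielding at least one feature
#' is used instead.
#'
#' @param X standardised samples x features matrix.
#' @param y binary labels (0/1).
#' @param cv_folds folds per repeat (default 5).
#' @param cv_repeats repeats (default 5).
#' @return character vector of selected feature names, with the chosen
#'   penalty as attribute "lambda".
#' @export
lasso_select <- function(X, y, cv_folds = 5, cv_repeats = 5) {
  y <- as.integer(y)
  if (ncol(X) < 2) return(colnames(X))
  fit <- suppressWarnings(
    glmnet::glmnet(X, y, family = "binomial", alpha = 1, standardize = FALSE))
  lambda <- fit$lambda
  k <- min(cv_folds, min(table(y)))
  if (k >= 4) {
    auc_sum <- numeric(length(lambda)); auc_n <- numeric(length(lambda))
    for (r in seq_len(cv_repeats)) {
      fid <- stratified_folds(y, k)
      cv <- suppressWarnings(
        glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                          standardize = FALSE, lambda = lambda,
                          foldid = fid, type.measure = "auc"))
      idx <- match(round(cv$lambda, 10), round(lambda, 10))
      auc_sum[idx] <- auc_sum[idx] + cv$cvm
      auc_n[idx] <- auc_n[idx] + 1
    }
    mean_auc <- ifelse(auc_n > 0, auc_sum / auc_n, -Inf)
    best <- which.max(mean_auc)
  } else {
    ## cohort too small to cross-validate: BIC along the path instead
    n <- length(y)
    dev <- (1 - fit$dev.ratio) * fit$nulldev
    best <- which.min(dev + log(n) * fit$df)
  }
  cf <- as.matrix(stats::coef(fit, s = lambda[best]))[-1, 1]
  sel <- names(cf)[cf != 0]
  if (length(sel) == 0) {
    nz <- fit$df > 0
    if (!any(nz)) return(character(0))
    s_fb <- min(lambda[nz])
    cf <- as.matrix(stats::coef(fit, s = s_fb))[-1, 1]
    sel <- names(cf)[cf != 0]
    attr(sel, "lambda") <- s_fb
    attr(sel, "fallback") <- TRUE
    return(sel)
  }
  attr(sel, "lambda") <- lambda[best]
  sel
}

#' Build a radiomics signature (SR, DR or DSR)
#'
#' The full training pipeline on a feature matrix: training-median
#' imputation of non-finite values, removal of constant columns, z-score
#' standardisation, F-test screening, LASSO selection with repeated
#' cross-validated penalty choice, an unpenalised logistic fit on the
#' survivors, and a Youden-optimal decision threshold on the training ROC.
#' Every statistic is derived from the training data only.
#'
#' @param X training samples x features matrix (SR: the 4 x 484 static
#'   columns; DR: the 9680 dynamic columns; DSR: the union of the SR- and
#'   DR-selected columns).
#' @param y binary training labels (0/1).
#' @param signature_type label stored on the model: "SR", "DR" or "DSR".
#' @param alpha F-test significance level.
#' @param cv_folds,cv_repeats cross-validation design for the LASSO penalty.
#' @return object of class \code{SignatureModel}.
#' @export
build_signature <- function(X, y, signature_type = c("SR", "DR", "DSR"),
                            alpha = 0.05, cv_folds = 5, cv_repeats = 5) {
  signature_type <- match.arg(signature_type)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), !is.null(colnames(X)))
  medians <- fit_imputer(X)
  Xi <- apply_imputer(X, medians)
  sds0 <- apply(Xi, 2, stats::sd)
  keep0 <- colnames(Xi)[sds0 > 0]
  Xi <- Xi[, keep0, drop = FALSE]
  Z <- standardize(Xi)
  screened <- f_test_screen(Z, y, alpha = alpha)
  if (length(screened) == 0) {
    p <- attr(screened, "p_values")
    screened <- names(which.min(p))
  }
  sel <- lasso_select(Z[, screened, drop = FALSE], y,
                      cv_folds = cv_folds, cv_repeats = cv_repeats)
  if (length(sel) == 0) sel <- screened[1]
  df <- as.data.frame(Z[, sel, drop = FALSE])
  names(df) <- paste0("f", seq_along(sel))
  glmfit <- suppressWarnings(stats::glm(y ~ ., data = cbind(y = y, df),
                                        family = stats::binomial()))
  scores <- stats::predict(glmfit, type = "response")
  thr <- youden_threshold(y, scores)
  structure(list(
    signature_type = signature_type,
    features = sel,
    impute_medians = medians[sel],
    means = attr(Z, "means")[sel],
    sds = attr(Z, "sds")[sel],
    coefficients = stats::setNames(stats::coef(glmfit)[-1], sel),
    intercept = unname(stats::coef(glmfit)[1]),
    threshold = thr,
    train_scores = scores
  ), class = "SignatureModel")
}

youden_threshold <- function(y, scores) {
  r <- pROC::roc(y, scores, direction = "<", quiet = TRUE)
  thr <- as.numeric(pROC::coords(r, "best", best.method = "youden",
                                 ret = "threshold", transpose = FALSE)$threshold)[1]
  if (!is.finite(thr) || thr <= 0 || thr >= 1) thr <- 0.5
  thr
}

#' @export
print.SignatureModel <- function(x, ...) {
  cat(x$signature_type, "signature:", length(x$features), "features, threshold",
      signif(x$threshold, 3), "\n")
  for (f in x$features)
    cat(sprintf("  %+.4f  %s\n", x$coefficients[f], f))
  invisible(x)
}

#' Predicted MVI probabilities from a fitted signature
#'
#' Applies the stored training-derived transforms (imputation medians,
#' z-score constants) and the logistic model to new data.
#'
#' @param object a \code{SignatureModel}.
#' @param newdata samples x features matrix containing the model's columns.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.SignatureModel <- function(object, newdata, ...) {
  X <- newdata[, object$features, drop = FALSE]
  X <- apply_imputer(X, object$impute_medians)
  Z <- sweep(sweep(X, 2, object$means), 2,
             ifelse(object$sds > 0, object$sds, 1), "/")
  eta <- object$intercept + as.numeric(Z %*% object$coefficients)
  stats::plogis(eta)
}

#' Evaluate a signature on labelled data
#'
#' AUC via the rank (Mann-Whitney) formulation with a DeLong 95\% CI,
#' accuracy / sensitivity / specificity at the model's training-derived
#' threshold, and the full ROC and precision-recall point sets.
#'
#' @param model a \code{SignatureModel}.
#' @param X samples x features matrix.
#' @param y binary labels (0/1); both classes must be present.
#' @return object of class \code{EvaluationReport}: list with auc, auc_ci,
#'   accuracy, sensitivity, specificity, roc (data.frame fpr/tpr),
#'   pr (data.frame recall/precision) and scores.
#' @export
evaluate <- function(model, X, y) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("undefined AUC: single-class labels")
  scores <- predict(model, X)
  r <- pROC::roc(y, scores, direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  pred <- as.integer(scores >= model$threshold)
  sens <- sum(pred == 1 & y == 1) / sum(y == 1)
  spec <- sum(pred == 0 & y == 0) / sum(y == 0)
  acc <- mean(pred == y)
  roc_df <- data.frame(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(y[ord] == 1)
  pr_df <- data.frame(recall = tp / sum(y == 1),
                      precision = tp / seq_along(tp))
  structure(list(auc = as.numeric(pROC::auc(r)),
                 auc_ci = c(lower = ci[1], upper = ci[3]),
                 accuracy = acc, sensitivity = sens, specificity = spec,
                 threshold = model$threshold,
                 roc = roc_df, pr = pr_df, scores = scores),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f)  accuracy %.3f  sensitivity %.3f  specificity %.3f\n",
              x$auc, x$auc_ci["lower"], x$auc_ci["upper"],
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' DeLong test comparing two paired AUCs
#'
#' Two-sided DeLong test for two correlated ROC curves evaluated on the
#' same subjects. Degenerate cases (identical scores, zero variance of the
#' AUC difference) return p = 1.
#'
#' @param scores_a,scores_b numeric score vectors on the same subjects.
#' @param y binary labels (0/1).
#' @return list with `p_value`, `statistic` (z; its sign flips when the two
#'   models are swapped) and the two AUCs.
#' @export
compare_auc <- function(scores_a, scores_b, y) {
  y <- as.integer(y)
  ra <- pROC::roc(y, scores_a, direction = "<", quiet = TRUE)
  rb <- pROC::roc(y, scores_b, direction = "<", quiet = TRUE)
  out <- tryCatch({
    tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    list(p_value = as.numeric(tst$p.value), statistic = as.numeric(tst$statistic))
  }, error = function(e) NULL)
  if (is.null(out) || !is.finite(out$p_value))
    out <- list(p_value = 1, statistic = 0)
  out$auc_a <- as.numeric(pROC::auc(ra))
  out$auc_b <- as.numeric(pROC::auc(rb))
  out
}

## feature-matrix assembly ----------------------------------------------------

#' Assemble the static (SR) design matrix from per-phase feature matrices
#'
#' Binds the four per-phase matrices column-wise with names
#' \code{"<phase>__<feature>"}; a 484-feature bank yields 1936 columns.
#'
#' @param phases named list of 4 samples x features matrices
#'   (plain, arterial, portal, equilibrium).
#' @return samples x (4 * features) matrix.
#' @export
static_matrix_from_phases <- function(phases) {
  stopifnot(length(phases) == 4)
  nm <- names(phases) %||% PHASE_NAMES
  do.call(cbind, lapply(seq_len(4), function(k) {
    m <- phases[[k]]
    colnames(m) <- paste(nm[k], colnames(m), sep = "__")
    m
  }))
}

#' Assemble the dynamic (DR) design matrix from per-phase feature matrices
#'
#' For every patient and static feature, the 4-phase trajectory is turned
#' into its 20 dynamic features; a 484-feature bank yields 9680 columns
#' named \code{"<family>__<type>__<feature>"}.
#'
#' @inheritParams static_matrix_from_phases
#' @inheritParams dynamic_feature_block
#' @return samples x (20 * features) matrix.
#' @export
dynamic_matrix_from_phases <- function(phases, time_grid = 1:4,
                                       racr_denominator = c("four-phase-mean", "segment-midpoint"),
                                       corrected_curvature = FALSE) {
  stopifnot(length(phases) == 4)
  n <- nrow(phases[[1]]); p <- ncol(phases[[1]])
  fn <- colnames(phases[[1]])
  ## columns = cells ordered feature-fastest within patient
  Y <- do.call(rbind, lapply(phases, function(m) as.numeric(t(m))))
  D <- dynamic_features_matrix(Y, time_grid,
                               racr_denominator = racr_denominator,
                               corrected_curvature = corrected_curvature)
  A <- array(D, c(20, p, n))
  out <- t(matrix(A, 20 * p, n))
  colnames(out) <- as.character(outer(dynamic_feature_names(), fn, paste, sep = "__"))
  out
}

#' Fit and evaluate the SR, DR and DSR signatures
#'
#' The three signature families of the analysis: SR on the static per-phase
#' columns, DR on the dynamic columns, and DSR on the union of the features
#' the SR and DR signatures selected, re-screened through the same
#' F-test + LASSO + logistic pipeline. The validation cohort is touched
#' exactly once, for final evaluation.
#'
#' @param train,validation lists as returned by
#'   \code{\link{generate_feature_series}} (elements `phases`, `labels`), or
#'   any named list with those elements.
#' @param alpha,cv_folds,cv_repeats passed to \code{\link{build_signature}}.
#' @inheritParams dynamic_feature_block
#' @return list with per-signature `model`, `train_eval`, `val_eval`, plus
#'   the DeLong comparisons `p_sr_dr` and `p_sr_dsr` on the validation set.
#' @export
fit_signature_suite <- function(train, validation, alpha = 0.05,
                                cv_folds = 5, cv_repeats = 5, time_grid = 1:4) {
  Xs_tr <- static_matrix_from_phases(train$phases)
  Xs_va <- static_matrix_from_phases(validation$phases)
  Xd_tr <- dynamic_matrix_from_phases(train$phases, time_grid)
  Xd_va <- dynamic_matrix_from_phases(validation$phases, time_grid)
  y_tr <- train$labels; y_va <- validation$labels

  sr <- build_signature(Xs_tr, y_tr, "SR", alpha, cv_folds, cv_repeats)
  dr <- build_signature(Xd_tr, y_tr, "DR", alpha, cv_folds, cv_repeats)
  u <- unique(c(sr$features, dr$features))
  Xu_tr <- cbind(Xs_tr, Xd_tr)[, u, drop = FALSE]
  Xu_va <- cbind(Xs_va, Xd_va)[, u, drop = FALSE]
  dsr <- build_signature(Xu_tr, y_tr, "DSR", alpha, cv_folds, cv_repeats)

  res <- list(
    SR = list(model = sr, train_eval = evaluate(sr, Xs_tr, y_tr),
              val_eval = evaluate(sr, Xs_va, y_va)),
    DR = list(model = dr, train_eval = evaluate(dr, Xd_tr, y_tr),
              val_eval = evaluate(dr, Xd_va, y_va)),
    DSR = list(model = dsr, train_eval = evaluate(dsr, Xu_tr, y_tr),
               val_eval = evaluate(dsr, Xu_va, y_va)))
  res$p_sr_dr <- compare_auc(res$SR$val_eval$scores, res$DR$val_eval$scores, y_va)$p_value
  res$p_sr_dsr <- compare_auc(res$SR$val_eval$scores, res$DSR$val_eval$scores, y_va)$p_value
  res
}
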