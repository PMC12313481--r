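# LASSO-logistic Radscore models for the binary subtype tasks, with
# univariate ROC for kinetic parameters, Youden operating metrics and
# decision-curve analysis. All selection (screening, standardization,
# lambda) happens on training rows only; the test set is touched exactly
# once, through the frozen model.

#' Stratified train/test split
#'
#' Training size is `round(n * train_fraction)` (124 patients at 7:3 gives
#' 87/37). With `stratified = TRUE` (default) the split samples within each
#' outcome class, so class fractions are preserved to within one patient and
#' small test sets keep both classes.
#'
#' @param labels 0/1 outcome vector.
#' @param train_fraction fraction assigned to training (default 0.7).
#' @param seed integer seed.
#' @param stratified stratify by outcome (default TRUE).
#' @return list with integer index vectors `train` and `test`.
#' @export
split_cohort <- function(labels, train_fraction = 0.7, seed = 1L,
                         stratified = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  if (any(table(labels) < 2L))
    stop("each class needs at least 2 patients to split", call. = FALSE)
  n <- length(labels)
  n_train <- round(n * train_fraction)
  set.seed(seed)
  if (stratified) {
    idx0 <- which(labels == 0); idx1 <- which(labels == 1)
    # per-class training counts: largest-remainder so totals hit n_train
    k1 <- round(length(idx1) * n_train / n)
    k0 <- n_train - k1
    k0 <- min(max(k0, 1L), length(idx0) - 1L)
    k1 <- min(max(n_train - k0, 1L), length(idx1) - 1L)
    train <- sort(c(sample(idx0, k0), sample(idx1, k1)))
  } else {
    train <- sort(sample(n, n_train))
  }
  list(train = train, test = sort(setdiff(seq_len(n), train)))
}

#' Pre-LASSO feature screening on training rows
#'
#' Removes zero-variance columns always; optionally (default on) also
#' removes columns whose two-sided Mann-Whitney test between outcome groups
#' has p >= `p_threshold`. Every removal is recorded.
#'
#' @param x training feature matrix (rows = patients).
#' @param labels 0/1 training outcomes.
#' @param rank_test apply the Mann-Whitney stage (default TRUE).
#' @param p_threshold keep features with p below this (default 0.05).
#' @return list with `x` (reduced matrix), `kept`, and `removed`
#'   (data.frame of column name + reason).
#' @export
screen_features <- function(x, labels, rank_test = TRUE, p_threshold = 0.05) {
  stopifnot(nrow(x) == length(labels))
  sds <- apply(x, 2, stats::sd)
  zv <- colnames(x)[sds == 0 | !is.finite(sds)]
  removed <- data.frame(feature = zv,
                        reason = rep("zero_variance", length(zv)),
                        stringsAsFactors = FALSE)
  keep <- which(sds > 0 & is.finite(sds))
  if (rank_test && length(keep)) {
    pvals <- vapply(keep, function(j)
      stats::wilcox.test(x[labels == 1, j], x[labels == 0, j],
                         exact = FALSE)$p.value, numeric(1))
    drop <- keep[pvals >= p_threshold]
    if (length(drop))
      removed <- rbind(removed,
                       data.frame(feature = colnames(x)[drop],
                                  reason = rep("rank_test_ns", length(drop)),
                                  stringsAsFactors = FALSE))
    keep <- keep[pvals < p_threshold]
  }
  if (!length(keep))
    stop("screening removed every feature", call. = FALSE)
  list(x = x[, keep, drop = FALSE], kept = colnames(x)[keep],
       removed = removed)
}

#' Fit a LASSO-logistic Radscore model with 10-fold cross-validation
#'
#' Columns are standardized to zero mean / unit variance on the training set
#' (the transform is stored for test-time application). The penalty lambda
#' minimizing the mean cross-validated binomial deviance over `folds` folds
#' is selected, the model refit on the full training set at that lambda, and
#' the features with nonzero coefficients form the signature.
#'
#' @param x training feature matrix.
#' @param labels 0/1 training outcomes (both classes required).
#' @param folds CV fold count (default 10).
#' @param seed integer seed (controls fold assignment).
#' @return object of class `radscore_model`: `selected`, `coefficients`,
#'   `intercept`, `lambda`, `center`, `scale`, `glmnet_fit`.
#' @export
fit_lasso_cv <- function(x, labels, folds = 10L, seed = 1L) {
  if (length(unique(labels)) < 2L)
    stop("labels must contain both classes", call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  set.seed(seed)
  cv <- glmnet::cv.glmnet(xs, labels, family = "binomial",
                          type.measure = "deviance", nfolds = folds,
                          standardize = FALSE)
  lam <- cv$lambda.min
  cf <- as.matrix(stats::coef(cv$glmnet.fit, s = lam))
  beta <- cf[-1L, 1L]
  sel <- names(beta)[beta != 0]
  structure(list(selected = sel,
                 coefficients = beta[beta != 0],
                 intercept = cf[1L, 1L],
                 lambda = lam,
                 center = ctr, scale = scl,
                 cv_deviance = min(cv$cvm),
                 glmnet_fit = cv),
            class = "radscore_model")
}

#' @export
print.radscore_model <- function(x, ...) {
  cat(sprintf("<radscore_model> %d selected features, lambda = %.5g\n",
              length(x$selected), x$lambda))
  invisible(x)
}

#' Compute Radscores for a feature table
#'
#' `score_i = intercept + sum_j beta_j x_ij` on training-standardized
#' columns — the selected features weighted by their LASSO coefficients.
#' The score is the logistic linear predictor, hence monotone in the
#' predicted probability.
#'
#' @param model a `radscore_model` from [fit_lasso_cv()].
#' @param x feature matrix containing every selected feature column.
#' @return numeric score vector.
#' @export
compute_radscore <- function(model, x) {
  missing_cols <- setdiff(model$selected, colnames(x))
  if (length(missing_cols))
    stop("feature table lacks selected columns: ",
         paste(utils::head(missing_cols, 5), collapse = ", "), call. = FALSE)
  if (!length(model$selected))
    return(rep(model$intercept, nrow(x)))
  xs <- sweep(x[, model$selected, drop = FALSE], 2,
              model$center[model$selected], `-`)
  xs <- sweep(xs, 2, model$scale[model$selected], `/`)
  drop(model$intercept + xs %*% model$coefficients)
}

# rank-based AUC: probability a random positive outscores a random
# negative, ties counted 1/2 (equivalent to the Wilcoxon statistic)
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong variance of the AUC (rank-based placement values)
auc_delong_var <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  v10 <- vapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)), numeric(1))
  v01 <- vapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)), numeric(1))
  stats::var(v10) / m + stats::var(v01) / n
}

#' ROC summary with Youden-optimal operating point
#'
#' AUC is the rank statistic; its 95% CI uses DeLong's asymptotic variance.
#' The cutoff maximizing the Youden index (sensitivity + specificity - 1) is
#' located by scanning every observed score as a candidate threshold
#' (predict positive when `score >= cutoff`), and sensitivity, specificity,
#' PPV, NPV and accuracy at that cutoff are reported.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 outcomes, both classes present.
#' @return object of class `roc_summary`: `auc`, `ci` (length 2), `cutoff`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`, `youden`.
#' @export
evaluate_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes are required for ROC analysis", call. = FALSE)
  auc <- auc_rank(scores, labels)
  se <- sqrt(auc_delong_var(scores, labels))
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  cand <- sort(unique(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  best <- list(youden = -Inf)
  for (cut in cand) {
    pred <- scores >= cut
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    sens <- tp / n1; spec <- 1 - fp / n0
    y <- sens + spec - 1
    if (y > best$youden)
      best <- list(cutoff = cut, youden = y, tp = tp, fp = fp,
                   sens = sens, spec = spec)
  }
  tn <- n0 - best$fp; fn <- n1 - best$tp
  structure(list(auc = auc, ci = ci, cutoff = best$cutoff,
                 sensitivity = best$sens, specificity = best$spec,
                 ppv = if (best$tp + best$fp > 0) best$tp / (best$tp + best$fp) else NA_real_,
                 npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
                 accuracy = (best$tp + tn) / length(labels),
                 youden = best$youden),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f); Youden cutoff %.4g: sens %.3f, spec %.3f, PPV %.3f, NPV %.3f, acc %.3f\n",
              x$auc, x$ci[1], x$ci[2], x$cutoff, x$sensitivity,
              x$specificity, x$ppv, x$npv, x$accuracy))
  invisible(x)
}

#' Univariate ROC for a single kinetic parameter
#'
#' As [evaluate_roc()] on one parameter column, with the direction
#' auto-oriented so the reported AUC is >= 0.5; the `flipped` field records
#' whether the parameter was negated. A constant parameter yields AUC 0.5
#' and is flagged `degenerate`.
#'
#' @param values per-patient kinetic parameter.
#' @param labels 0/1 outcomes.
#' @return `roc_summary` with extra fields `flipped` and `degenerate`.
#' @export
univariate_roc <- function(values, labels) {
  if (length(unique(values)) == 1L) {
    out <- list(auc = 0.5, ci = c(NA_real_, NA_real_), cutoff = values[1],
                sensitivity = NA_real_, specificity = NA_real_,
                ppv = NA_real_, npv = NA_real_, accuracy = NA_real_,
                youden = NA_real_, flipped = FALSE, degenerate = TRUE)
    class(out) <- "roc_summary"
    return(out)
  }
  flipped <- auc_rank(values, labels) < 0.5
  out <- evaluate_roc(if (flipped) -values else values, labels)
  out$flipped <- flipped
  out$degenerate <- FALSE
  out
}

#' Decision-curve analysis
#'
#' Net benefit of acting on `p >= p_t`:
#' `NB(p_t) = TP/n - FP/n * p_t/(1 - p_t)`, against the treat-all curve
#' `prevalence - (1 - prevalence) * p_t/(1 - p_t)` and treat-none (0).
#'
#' @param probs predicted probabilities in (0, 1).
#' @param labels 0/1 outcomes.
#' @param thresholds grid of threshold probabilities strictly inside (0, 1).
#' @return data.frame with `threshold`, `net_benefit`, `treat_all`,
#'   `treat_none`.
#' @export
decision_curve <- function(probs, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)", call. = FALSE)
  if (any(probs <= 0 | probs >= 1))
    stop("probs must lie strictly inside (0, 1)", call. = FALSE)
  n <- length(labels)
  prev <- mean(labels == 1)
  nb <- vapply(thresholds, function(pt) {
    pred <- probs >= pt
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    tp / n - fp / n * pt / (1 - pt)
  }, numeric(1))
  data.frame(threshold = thresholds,
             net_benefit = nb,
             treat_all = prev - (1 - prev) * thresholds / (1 - thresholds),
             treat_none = 0)
}

#' Run one Radscore modeling task end to end
#'
#' Splits the cohort, screens and standardizes on training rows, fits the
#' cross-validated LASSO, computes Radscores and logistic probabilities for
#' both splits, and evaluates ROC (train and test) plus the test-set
#' decision curve.
#'
#' @param x patients-by-features matrix.
#' @param labels 0/1 outcome vector.
#' @param train_fraction split fraction (default 0.7).
#' @param seed integer seed driving split, screening and CV folds.
#' @param rank_test enable the Mann-Whitney screening stage.
#' @return list: `model`, `split`, `screen`, `scores` (train/test),
#'   `roc_train`, `roc_test`, `dca_test`.
#' @export
run_radscore_task <- function(x, labels, train_fraction = 0.7, seed = 1L,
                              rank_test = TRUE) {
  sp <- split_cohort(labels, train_fraction, seed = seed)
  xtr <- x[sp$train, , drop = FALSE]; ytr <- labels[sp$train]
  xte <- x[sp$test, , drop = FALSE];  yte <- labels[sp$test]
  sc <- screen_features(xtr, ytr, rank_test = rank_test)
  model <- fit_lasso_cv(sc$x, ytr, seed = seed)
  s_tr <- compute_radscore(model, xtr[, sc$kept, drop = FALSE])
  s_te <- compute_radscore(model, xte[, sc$kept, drop = FALSE])
  p_te <- stats::plogis(s_te)
  list(model = model, split = sp, screen = sc,
       scores = list(train = s_tr, test = s_te),
       roc_train = evaluate_roc(s_tr, ytr),
       roc_test = evaluate_roc(s_te, yte),
       dca_test = decision_curve(pmin(pmax(p_te, 1e-8), 1 - 1e-8), yte))
}
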