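#' SMOTE: synthetic minority oversampling
#'
#' Each synthetic minority point is `x_i + u (x_nn - x_i)` with
#' `u ~ Uniform(0, 1)` and `x_nn` one of the `k` nearest minority
#' neighbours of `x_i` (Euclidean distance on the features as given; the
#' caller standardizes). The minority class is grown to
#' `ratio x majority`; majority rows are never touched and the original
#' minority rows are kept verbatim.
#'
#' @param features numeric matrix.
#' @param labels binary 0/1 vector; the rarer class is the minority.
#' @param k number of nearest minority neighbours (reduced with a
#'   warning when the minority is smaller than `k + 1`).
#' @param ratio target minority / majority size ratio (default 1).
#' @param seed integer seed.
#' @return list with augmented `features`, `labels`, and `synthetic`
#'   (logical marker for generated rows).
#' @export
smote <- function(features, labels, k = 5L, ratio = 1.0, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  tab <- table(factor(labels, levels = c(0L, 1L)))
  minority <- as.integer(names(tab)[which.min(tab)])
  n_min <- min(tab); n_maj <- max(tab)
  if (n_min < 2L) stopf("minority class needs >= 2 samples for SMOTE")
  if (k > n_min - 1L) {
    warning(sprintf("k reduced from %d to %d (minority size)", k, n_min - 1L))
    k <- n_min - 1L
  }
  n_new <- max(0L, round(ratio * n_maj) - n_min)
  if (n_new == 0L)
    return(list(features = features, labels = labels,
                synthetic = rep(FALSE, nrow(features))))
  idx_min <- which(labels == minority)
  Xm <- features[idx_min, , drop = FALSE]
  D <- as.matrix(stats::dist(Xm))
  diag(D) <- Inf
  nn <- matrix(apply(D, 1L, function(r) order(r)[seq_len(k)]),
               nrow = nrow(Xm), ncol = k, byrow = TRUE)
  set.seed(derive_seed(seed, 53L))
  base <- sample(rep_len(seq_len(nrow(Xm)), n_new))
  pickd <- nn[cbind(base, sample.int(k, n_new, replace = TRUE))]
  u <- runif(n_new)
  Xnew <- Xm[base, , drop = FALSE] +
    u * (Xm[pickd, , drop = FALSE] - Xm[base, , drop = FALSE])
  list(features = rbind(features, Xnew),
       labels = c(labels, rep(minority, n_new)),
       synthetic = c(rep(FALSE, nrow(features)), rep(TRUE, n_new)))
}

#' Logistic regression by ridge-stabilized IRLS
#'
#' Maximum penalized likelihood with a tiny L2 penalty (default 1e-6,
#' excluding the intercept) so that perfectly separable data still yield
#' finite coefficients with the correct score ordering. Iteratively
#' reweighted least squares, converged when the largest coefficient
#' change drops below 1e-8.
#'
#' @param features numeric matrix (columns named).
#' @param labels binary 0/1 vector.
#' @param l2 ridge penalty on the slopes.
#' @param max_iter iteration cap (error on non-convergence).
#' @return named coefficient vector, `(Intercept)` first.
#' @export
fit_logistic <- function(features, labels, l2 = 1e-6, max_iter = 100L) {
  X <- cbind("(Intercept)" = 1, as.matrix(features))
  y <- as.numeric(labels)
  if (min(table(y)) < 2L) stopf("need >= 2 samples per class")
  beta <- rep(0, ncol(X))
  pen <- c(0, rep(l2, ncol(X) - 1L))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    W <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / W
    XtW <- t(X * W)
    new_beta <- solve(XtW %*% X + diag(pen, ncol(X)), XtW %*% z)[, 1L]
    if (max(abs(new_beta - beta)) < 1e-8) {
      names(new_beta) <- colnames(X)
      return(new_beta)
    }
    beta <- new_beta
  }
  stopf("IRLS did not converge in %d iterations", max_iter)
}

#' ROC curve and AUC
#'
#' The curve walks the sorted unique score thresholds; the AUC is the
#' trapezoid area, which equals the Mann-Whitney concordance
#' `(#{case > control} + 0.5 #ties) / (n1 n0)`.
#'
#' @param scores numeric risk scores (higher = more case-like).
#' @param labels binary 0/1 vector (1 = case).
#' @return a `roc_result`: data.frame `curve` (`threshold`, `fpr`,
#'   `tpr`) from (0,0) to (1,1), and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0, numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  structure(list(curve = curve, auc = auc), class = "roc_result")
}

#' Stratified cross-validated logistic risk model with SMOTE
#'
#' Folds are stratified by class. Within each training partition —
#' and only there, so no synthetic point ever leaks information about
#' held-out samples — SMOTE balances the minority class before the
#' logistic fit; held-out probabilities are pooled across folds into a
#' single ROC. The deployable coefficients are refit on all data
#' (with SMOTE) at the end.
#'
#' @param features numeric matrix (samples x features, columns named).
#' @param labels binary 0/1 vector (1 = case).
#' @param folds number of CV folds (default 10; each class must have at
#'   least `folds` members).
#' @param seed integer seed (fold assignment, SMOTE draws).
#' @param smote_k,smote_ratio SMOTE parameters; `smote_ratio = 0`
#'   disables augmentation.
#' @param l2 ridge penalty passed to [fit_logistic()].
#' @return a `risk_model`: coefficients, feature names, per-fold and
#'   pooled held-out AUCs, pooled `roc_result`, held-out prediction
#'   data.frame, resubstitution AUC, and training metadata.
#' @export
cv_risk_model <- function(features, labels, folds = 10L, seed = 1L,
                          smote_k = 5L, smote_ratio = 1.0, l2 = 1e-6) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  labels <- as.integer(labels)
  n_by <- table(factor(labels, levels = c(0L, 1L)))
  if (any(n_by < folds))
    stopf("class sizes (%s) too small for %d folds; reduce folds",
          paste(n_by, collapse = "/"), folds)
  set.seed(derive_seed(seed, 61L))
  fold_id <- integer(length(labels))
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  pred <- rep(NA_real_, length(labels))
  fold_auc <- rep(NA_real_, folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    Xtr <- features[tr, , drop = FALSE]; ytr <- labels[tr]
    if (smote_ratio > 0) {
      aug <- smote(Xtr, ytr, k = min(smote_k, sum(ytr == 1L) - 1L,
                                     sum(ytr == 0L) - 1L),
                   ratio = smote_ratio, seed = derive_seed(seed, 100L + f))
      Xtr <- aug$features; ytr <- aug$labels
    }
    beta <- fit_logistic(Xtr, ytr, l2 = l2)
    te <- which(fold_id == f)
    pred[te] <- plogis(drop(cbind(1, features[te, , drop = FALSE]) %*% beta))
    if (length(unique(labels[te])) == 2L)
      fold_auc[f] <- roc_auc(pred[te], labels[te])$auc
  }
  pooled <- roc_auc(pred, labels)
  if (smote_ratio > 0) {
    aug <- smote(features, labels, k = min(smote_k, min(n_by) - 1L),
                 ratio = smote_ratio, seed = derive_seed(seed, 99L))
    beta <- fit_logistic(aug$features, aug$labels, l2 = l2)
  } else beta <- fit_logistic(features, labels, l2 = l2)
  resub <- roc_auc(plogis(drop(cbind(1, features) %*% beta)), labels)$auc
  structure(list(
    coefficients = beta, feature_names = colnames(features),
    cv_auc = pooled$auc, fold_auc = fold_auc, roc = pooled,
    predictions = data.frame(fold = fold_id, label = labels, prob = pred),
    resubstitution_auc = resub,
    meta = list(folds = folds, seed = seed, smote_k = smote_k,
                smote_ratio = smote_ratio, l2 = l2)),
    class = "risk_model")
}

#' Score new samples with a deployed risk model
#'
#' Standardizes the new CLR matrix with the measurement model's stored
#' constants, computes blinded factor scores, and applies the logistic
#' coefficients. No outcome information is needed or used.
#'
#' @param model a `risk_model` from [cv_risk_model()].
#' @param measurement a `measurement_model` from
#'   [measurement_submodel()].
#' @param clr_matrix samples x taxa CLR matrix containing every model
#'   taxon.
#' @return named vector of per-sample probabilities in (0, 1).
#' @export
estimate_risk <- function(model, measurement, clr_matrix) {
  stopifnot(inherits(model, "risk_model"),
            inherits(measurement, "measurement_model"))
  sc <- factor_scores(measurement, clr_matrix)
  missing_cols <- setdiff(model$feature_names, colnames(sc))
  if (length(missing_cols))
    stopf("scores lack model feature(s): %s",
          paste(missing_cols, collapse = ", "))
  X <- cbind(1, sc[, model$feature_names, drop = FALSE])
  p <- plogis(drop(X %*% model$coefficients))
  names(p) <- rownames(clr_matrix)
  p
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Logistic risk model on", length(x$feature_names), "feature(s):",
      paste(x$feature_names, collapse = ", "), "\n")
  cat("  pooled CV AUC =", round(x$cv_auc, 3),
      " resubstitution AUC =", round(x$resubstitution_auc, 3), "\n")
  invisible(x)
}
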