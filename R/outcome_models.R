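# Outcome classifiers: the five logistic-regression configurations (Basic,
# Clinical, Imaging, Robotic, Augmented) evaluated with stratified k-fold
# cross-validation, pooled out-of-fold metrics, AIC and coefficient
# importances.

#' The five canonical model configurations
#'
#' Feature lists for the Basic (demographics only), Clinical (+TLT, BIT,
#' FIM), Imaging (+VLSM mean Z, lesion volume), Robotic (+the eight APM
#' parameter z-scores) and Augmented (all features) models.
#'
#' @return named list of character feature vectors.
#' @export
model_specs <- function() {
  demo <- c("age", "sex", "affected_arm")
  clin <- c("tlt", "bit", "fim")
  imag <- c("vlsm_mean_z", "lesion_volume")
  robo <- apm_parameter_names()
  list(
    basic = demo,
    clinical = c(demo, clin),
    imaging = c(demo, imag),
    robotic = c(demo, robo),
    augmented = c(demo, clin, imag, robo)
  )
}

#' Stratified k-fold assignment
#'
#' Shuffles within each class and deals fold labels round-robin, so per-fold
#' class counts differ from perfect stratification by at most one
#' participant. Deterministic given the seed.
#'
#' @param labels binary vector (0/1 or logical).
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return integer fold assignment (1..k) per observation.
#' @export
stratified_kfold_indices <- function(labels, k = 10L, seed = 1L) {
  labels <- as.integer(as.logical(labels))
  stopifnot_scalar_count(k, "k")
  if (any(table(labels) < k)) {
    stop("each class must have at least k members", call. = FALSE)
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- ((seq_along(idx) - 1L) %% k) + 1L
    }
  })
  fold
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sig <- apply(X, 2, sd)
  if (any(sig == 0)) {
    stop("constant feature column: ", paste(colnames(X)[sig == 0], collapse = ", "),
         call. = FALSE)
  }
  list(mu = mu, sig = sig)
}

standardize_apply <- function(X, std) {
  sweep(sweep(X, 2, std$mu, "-"), 2, std$sig, "/")
}

#' Logistic fit on standardized features
#'
#' Features are z-standardized (mean 0, SD 1) before fitting, so the
#' coefficients are comparable across features. The default is plain
#' maximum likelihood; `ridge > 0` adds an L2 penalty
#' `ridge/2 * sum(beta^2)` on the non-intercept coefficients (penalized
#' Newton iterations), which keeps coefficients finite under separation.
#' AIC is only reported for the unpenalized fit. The design must be full
#' rank; separation or non-convergence is reported via the `converged` and
#' `separation` flags.
#'
#' @param X numeric matrix or data.frame of features.
#' @param y binary outcome (0/1 or logical).
#' @param standardize standardize the columns first (default TRUE).
#' @param ridge L2 penalty weight on the standardized coefficients
#'   (default 0 = maximum likelihood).
#' @return list: `coefficients` (intercept first), `aic` (NA when
#'   penalized), `converged`, `separation`, `std` (standardization
#'   parameters), `deviance`.
#' @export
fit_logistic <- function(X, y, standardize = TRUE, ridge = 0) {
  X <- as.matrix(X)
  y <- as.integer(as.logical(y))
  stopifnot(nrow(X) == length(y), length(ridge) == 1L, ridge >= 0)
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    stop("rank-deficient design (duplicated or collinear feature columns)",
         call. = FALSE)
  }
  std <- NULL
  if (standardize) {
    std <- standardize_fit(X)
    X <- standardize_apply(X, std)
  }
  if (ridge > 0) {
    return(c(ridge_logistic(X, y, ridge), list(std = std)))
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    glm.fit(cbind(`(intercept)` = 1, X), y, family = binomial(),
            control = list(maxit = 100L)),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      } else if (grepl("did not converge", msg)) {
        # recorded via the converged flag on the returned fit
        invokeRestart("muffleWarning")
      }
    }
  )
  list(coefficients = fit$coefficients, aic = fit$aic,
       deviance = fit$deviance, converged = fit$converged,
       separation = separation, std = std)
}

# Penalized Newton iterations for ridge logistic regression; the intercept
# is unpenalized.
ridge_logistic <- function(X, y, ridge, max_iter = 100L, tol = 1e-9) {
  Xd <- cbind(`(intercept)` = 1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(ridge, p - 1L)), nrow = p)
  beta <- numeric(p)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    grad <- drop(crossprod(Xd, y - mu)) - pen %*% beta
    hess <- crossprod(Xd * w, Xd) + pen
    step <- solve(hess, grad)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(Xd %*% beta)
  dev <- -2 * sum(y * eta - log1p(exp(eta)))
  list(coefficients = stats::setNames(drop(beta), colnames(Xd)),
       aic = NA_real_, deviance = dev, converged = converged,
       separation = FALSE)
}

predict_logistic <- function(fit, X) {
  X <- as.matrix(X)
  if (!is.null(fit$std)) X <- standardize_apply(X, fit$std)
  plogis(drop(cbind(1, X) %*% fit$coefficients))
}

#' ROC curve points
#'
#' Operating points of the pooled ROC, one per distinct score (plus the
#' endpoints), with tied scores grouped.
#'
#' @param scores numeric predicted scores (higher = more positive).
#' @param labels binary labels.
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & !labels), numeric(1))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fp / n0), tpr = c(0, tp / n1))
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the ROC curve with tied scores grouped, which
#' equals the pairwise-concordance probability with the midrank (half
#' credit) tie convention.
#'
#' @inheritParams roc_points
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
}

#' Constant-classifier baseline accuracies
#'
#' Accuracy of always predicting one class: the two class frequencies as
#' percentages.
#'
#' @param labels binary labels.
#' @return named numeric `c(minority = , majority = )`, percent.
#' @export
single_class_baseline <- function(labels) {
  labels <- as.logical(labels)
  f <- mean(labels)
  c(minority = min(f, 1 - f) * 100, majority = max(f, 1 - f) * 100)
}

#' Evaluate one model configuration with stratified cross-validation
#'
#' Fits the logistic configuration within each training fold (feature
#' standardization learned on the training data only), pools the
#' out-of-fold predicted probabilities, and computes the metric suite from
#' the pooled confusion matrix at threshold 0.5 (accuracy, positive-class
#' F1, class-weighted F1, sensitivity, specificity) and the pooled ROC
#' (AUC). AIC comes from one unpenalized full-data fit.
#'
#' @param table feature table: a data.frame containing the spec's feature
#'   columns and the binary `impaired_6mo` label.
#' @param features character vector of feature columns (one of
#'   [model_specs()], or any subset of the table's columns).
#' @param name model name for reporting.
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param ridge optional L2 penalty for the fold and coefficient fits; AIC
#'   always comes from the unpenalized full-data fit (default 0).
#' @return object of class `model_result`.
#' @export
evaluate_model <- function(table, features, name = "model", k = 10L, seed = 1L,
                           ridge = 0) {
  stopifnot(all(features %in% names(table)), "impaired_6mo" %in% names(table))
  y <- as.integer(as.logical(table$impaired_6mo))
  X <- as.matrix(as.data.frame(table)[features])
  if (any(!is.finite(X))) stop("missing values in model features", call. = FALSE)
  n <- length(y)
  fold <- stratified_kfold_indices(y, k = k, seed = seed)
  prob <- rep(NA_real_, n)
  fold_flags <- logical(k)
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- fit_logistic(X[!test, , drop = FALSE], y[!test], ridge = ridge)
    fold_flags[f] <- !fit$converged || fit$separation
    prob[test] <- predict_logistic(fit, X[test, , drop = FALSE])
  }
  pred <- as.integer(prob > 0.5)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  f1_pos <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  f1_neg <- if (2 * tn + fp + fn == 0) 0 else 2 * tn / (2 * tn + fp + fn)
  full <- fit_logistic(X, y)  # unpenalized: AIC semantics
  coef_fit <- if (ridge > 0) fit_logistic(X, y, ridge = ridge) else full
  metrics <- list(
    accuracy = (tp + tn) / n * 100,
    f1 = f1_pos,
    f1_weighted = (sum(y) * f1_pos + sum(1 - y) * f1_neg) / n,
    auc = auc(prob, y),
    sensitivity = tp / (tp + fn) * 100,
    specificity = tn / (tn + fp) * 100,
    aic = full$aic
  )
  structure(
    list(name = name, features = features, n = n, k = k, seed = seed,
         predictions = data.frame(row = seq_len(n), fold = fold,
                                  prob = prob, pred = pred, label = y),
         confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
         metrics = metrics,
         ridge = ridge,
         coefficients = coef_fit$coefficients,
         full_fit_flags = c(converged = full$converged,
                            separation = full$separation),
         fold_flags = fold_flags),
    class = "model_result"
  )
}

#' @export
print.model_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<model_result> %s (%d features, n = %d, %d-fold CV)\n",
              x$name, length(x$features), x$n, x$k))
  cat(sprintf("  accuracy %.2f%%  F1 %.2f  AUC %.2f  sens %.2f%%  spec %.2f%%  AIC %.2f\n",
              m$accuracy, m$f1, m$auc, m$sensitivity, m$specificity, m$aic))
  invisible(x)
}

#' Feature importance from standardized coefficients
#'
#' Coefficients of the full-data standardized logistic fit, ranked by
#' absolute value; signed values are reported.
#'
#' @param x a `model_result`, or a feature table (with `features` given).
#' @param features feature columns when `x` is a table.
#' @param ridge optional L2 penalty (table input only); useful when the
#'   unpenalized fit separates.
#' @return data.frame with `feature` and `coefficient`, most important
#'   first.
#' @export
feature_importance <- function(x, features = NULL, ridge = 0) {
  co <- if (inherits(x, "model_result")) {
    x$coefficients
  } else {
    fit_logistic(as.matrix(as.data.frame(x)[features]), x$impaired_6mo,
                 ridge = ridge)$coefficients
  }
  co <- co[names(co) != "(intercept)"]
  ord <- order(abs(co), decreasing = TRUE)
  data.frame(feature = names(co)[ord], coefficient = unname(co)[ord],
             row.names = NULL)
}

#' Evaluate all five canonical configurations
#'
#' @param table feature table (see [evaluate_model()]).
#' @param k folds.
#' @param seed fold seed shared by every configuration.
#' @param ridge optional L2 penalty shared by every configuration.
#' @return named list of `model_result`.
#' @export
evaluate_all_models <- function(table, k = 10L, seed = 1L, ridge = 0) {
  specs <- model_specs()
  lapply(stats::setNames(names(specs), names(specs)), function(nm) {
    evaluate_model(table, specs[[nm]], name = nm, k = k, seed = seed,
                   ridge = ridge)
  })
}

#' Summarise model results as a one-row-per-model table
#'
#' @param results list of `model_result` (e.g. [evaluate_all_models()]).
#' @return data.frame in the standard reporting layout.
#' @export
model_results_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    m <- r$metrics
    data.frame(model = r$name, accuracy = m$accuracy, f1 = m$f1,
               f1_weighted = m$f1_weighted, auc = m$auc,
               sensitivity = m$sensitivity, specificity = m$specificity,
               aic = m$aic, row.names = NULL)
  }))
}
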