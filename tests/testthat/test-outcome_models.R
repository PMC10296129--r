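test_that("stratified folds balance class counts and are deterministic", {
  y <- rep(c(1, 0), c(40, 60))
  f <- stratified_kfold_indices(y, k = 10, seed = 3)
  per_fold_pos <- tapply(y, f, sum)
  expect_true(all(per_fold_pos == 4))
  y2 <- rep(c(1, 0), c(48, 85))
  f2 <- stratified_kfold_indices(y2, k = 10, seed = 3)
  pos2 <- tapply(y2, f2, sum)
  expect_true(all(pos2 %in% c(4, 5)))
  expect_equal(sum(pos2), 48)
  expect_identical(f2, stratified_kfold_indices(y2, k = 10, seed = 3))
  expect_false(identical(f2, stratified_kfold_indices(y2, k = 10, seed = 4)))
  expect_error(stratified_kfold_indices(rep(c(1, 0), c(5, 95)), k = 10),
               "at least k")
})

test_that("logistic fit recovers null and known slopes", {
  withr::with_seed(10, {
    X <- matrix(rnorm(4000 * 2), ncol = 2, dimnames = list(NULL, c("a", "b")))
    y0 <- rbinom(4000, 1, 0.4)  # labels independent of features
    f0 <- fit_logistic(X, y0)
    expect_lt(max(abs(f0$coefficients[-1])), 0.12)
    # known log-odds slope on a standardized feature
    beta <- 0.8
    x <- rnorm(5000)
    y1 <- rbinom(5000, 1, plogis(-0.3 + beta * x))
    f1 <- fit_logistic(matrix(x, dimnames = list(NULL, "x")), y1)
    expect_equal(unname(f1$coefficients["x"]) / sd(x) * sd(x), beta,
                 tolerance = 0.10)
  })
  X2 <- cbind(a = rnorm(50), b = 0)  # constant column, collinear with intercept
  expect_error(fit_logistic(X2, rbinom(50, 1, 0.5)),
               "rank-deficient|constant")
  x <- rnorm(50)
  expect_error(fit_logistic(cbind(a = x, b = x), rbinom(50, 1, 0.5)),
               "rank-deficient")
})

test_that("AUC equals the pairwise-concordance oracle on exhaustive toy sets", {
  withr::with_seed(11, {
    for (i in 1:60) {
      n1 <- sample(1:8, 1); n0 <- sample(1:8, 1)
      scores <- if (i %% 2 == 0) {
        sample(1:4, n1 + n0, replace = TRUE)  # heavy ties
      } else {
        rnorm(n1 + n0)
      }
      labels <- rep(c(TRUE, FALSE), c(n1, n0))
      expect_equal(auc(scores, labels), concordance_auc(scores, labels),
                   tolerance = 1e-12)
    }
  })
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_error(auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(12, {
    scores <- rnorm(60)
    labels <- rbinom(60, 1, plogis(scores))
    ours <- auc(scores, labels)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-10)
  })
})

test_that("single-class baseline returns the class frequencies as percentages", {
  y <- rep(c(1, 0), c(48, 85))
  b <- single_class_baseline(y)
  expect_equal(round(unname(b["minority"]), 1), 36.1)
  expect_equal(round(unname(b["majority"]), 1), 63.9)
  expect_equal(unname(single_class_baseline(rep(c(1, 0), 50))), c(50, 50))
  expect_equal(unname(single_class_baseline(rep(1, 10))), c(0, 100))
})

test_that("evaluation metrics come exactly from the pooled confusion matrix", {
  withr::with_seed(13, {
    n <- 120L
    x <- rnorm(n)
    tab <- data.frame(x = x, noise = rnorm(n),
                      impaired_6mo = as.integer(x + 0.5 * rnorm(n) > 0.2))
    r <- evaluate_model(tab, c("x", "noise"), k = 10, seed = 1)
    cm <- r$confusion
    expect_identical(sum(cm), n)
    expect_equal(r$metrics$accuracy, (cm["tp"] + cm["tn"]) / n * 100,
                 ignore_attr = TRUE)
    expect_equal(r$metrics$sensitivity, cm["tp"] / (cm["tp"] + cm["fn"]) * 100,
                 ignore_attr = TRUE)
    expect_equal(r$metrics$specificity, cm["tn"] / (cm["tn"] + cm["fp"]) * 100,
                 ignore_attr = TRUE)
    expect_equal(r$metrics$f1,
                 2 * cm["tp"] / (2 * cm["tp"] + cm["fp"] + cm["fn"]),
                 ignore_attr = TRUE)
    # AIC matches an independent full-data glm on standardized features
    Xs <- scale(as.matrix(tab[c("x", "noise")]))
    ref <- glm(tab$impaired_6mo ~ Xs, family = binomial())
    expect_equal(r$metrics$aic, AIC(ref), tolerance = 1e-6)
  })
})

test_that("separable data yield perfect metrics and shuffled labels chance ones", {
  withr::with_seed(14, {
    n <- 100
    x <- c(rnorm(n / 2, -3), rnorm(n / 2, 3))
    tab <- data.frame(x = x, impaired_6mo = as.integer(x > 0))
    r <- evaluate_model(tab, "x", k = 5, seed = 2)
    expect_equal(r$metrics$accuracy, 100)
    expect_equal(r$metrics$auc, 1)
    shuf <- tab
    shuf$impaired_6mo <- sample(tab$impaired_6mo)
    r2 <- evaluate_model(shuf, "x", k = 5, seed = 2)
    expect_lt(abs(r2$metrics$auc - 0.5), 0.2)
  })
})

test_that("AIC moves in the right direction when features are added", {
  deltas <- withr::with_seed(15, {
    sapply(1:10, function(i) {
      n <- 800
      x <- rnorm(n)
      z <- rnorm(n)
      y <- rbinom(n, 1, plogis(x))
      tab <- data.frame(x = x, z = z, impaired_6mo = y)
      null_aic <- fit_logistic(matrix(z, dimnames = list(NULL, "z")), y)$aic
      info_aic <- fit_logistic(cbind(z = z, x = x), y)$aic
      base_aic <- fit_logistic(matrix(x, dimnames = list(NULL, "x")), y)$aic
      plus_noise <- fit_logistic(cbind(x = x, z = z), y)$aic
      c(info = info_aic - null_aic, noise = plus_noise - base_aic)
    })
  })
  expect_true(all(deltas["info", ] < 0))            # informative feature helps
  expect_gt(mean(deltas["noise", ] > 0), 0.5)       # pure noise usually hurts
})

test_that("feature importance ranks the informative feature first", {
  withr::with_seed(16, {
    top1 <- sapply(1:20, function(i) {
      n <- 400
      X <- matrix(rnorm(n * 4), ncol = 4,
                  dimnames = list(NULL, c("signal", "n1", "n2", "n3")))
      y <- rbinom(n, 1, plogis(1.2 * X[, "signal"]))
      tab <- data.frame(X, impaired_6mo = y)
      feature_importance(tab, c("signal", "n1", "n2", "n3"))$feature[1]
    })
    expect_gte(mean(top1 == "signal"), 0.9)
  })
  # two features with the same effect get near-equal coefficients
  withr::with_seed(17, {
    n <- 6000
    X <- matrix(rnorm(n * 2), ncol = 2, dimnames = list(NULL, c("a", "b")))
    y <- rbinom(n, 1, plogis(0.7 * X[, 1] + 0.7 * X[, 2]))
    imp <- feature_importance(data.frame(X, impaired_6mo = y), c("a", "b"))
    expect_equal(imp$coefficient[1], imp$coefficient[2], tolerance = 0.15)
  })
})

test_that("ridge fits shrink coefficients and stay finite under separation", {
  withr::with_seed(18, {
    n <- 300
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(1.5 * x))
    X <- matrix(x, dimnames = list(NULL, "x"))
    ml <- fit_logistic(X, y)
    r1 <- fit_logistic(X, y, ridge = 5)
    expect_true(r1$converged)
    expect_true(is.na(r1$aic))
    expect_lt(abs(r1$coefficients["x"]), abs(ml$coefficients["x"]))
    # ridge -> 0 recovers maximum likelihood
    r0 <- fit_logistic(X, y, ridge = 1e-8)
    expect_equal(r0$coefficients, ml$coefficients, tolerance = 1e-5)
    # separable data: ML coefficients blow up, ridge stays moderate
    ys <- as.integer(x > 0)
    rs <- fit_logistic(X, ys, ridge = 1)
    expect_true(rs$converged)
    expect_lt(abs(rs$coefficients["x"]), 20)
    # AIC still reported from the unpenalized full fit in evaluation
    tab <- data.frame(x = x, impaired_6mo = y)
    ev <- evaluate_model(tab, "x", k = 5, seed = 1, ridge = 1)
    expect_false(is.na(ev$metrics$aic))
    expect_identical(ev$ridge, 1)
  })
})

test_that("the five canonical specs match the published feature sets", {
  specs <- model_specs()
  expect_named(specs, c("basic", "clinical", "imaging", "robotic", "augmented"))
  expect_identical(specs$basic, c("age", "sex", "affected_arm"))
  expect_identical(specs$clinical, c(specs$basic, "tlt", "bit", "fim"))
  expect_identical(specs$imaging, c(specs$basic, "vlsm_mean_z", "lesion_volume"))
  expect_identical(specs$robotic, c(specs$basic, apm_parameter_names()))
  expect_identical(specs$augmented,
                   c(specs$basic, "tlt", "bit", "fim", "vlsm_mean_z",
                     "lesion_volume", apm_parameter_names()))
  expect_identical(length(specs$augmented), 16L)
})

test_that("the modality ordering of discrimination holds across seeds", {
  # demographics-only < imaging, with imaging at or below the best of the
  # clinical/robotic/augmented block, in >= 80% of 20 cohorts
  sweep <- fx_seed_sweep()
  ok <- vapply(sweep, function(s) {
    a <- s$aucs
    a["basic"] < a["imaging"] &&
      a["imaging"] <= max(a[c("clinical", "robotic", "augmented")]) + 0.02
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("on the default cohort the demographics-only model is the weakest", {
  ft <- fx_features()
  res <- evaluate_all_models(ft, k = 10, seed = 42)
  tab <- model_results_table(res)
  expect_identical(nrow(tab), 5L)
  aucs <- setNames(tab$auc, tab$model)
  expect_true(all(aucs["basic"] < aucs[c("clinical", "imaging", "robotic",
                                         "augmented")]))
  # demographics alone: low sensitivity, high specificity (majority-leaning)
  expect_lt(tab$sensitivity[tab$model == "basic"],
            tab$specificity[tab$model == "basic"])
})
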