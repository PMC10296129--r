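test_that("Box-Cox profile likelihood recovers known exponents", {
  y_ln <- withr::with_seed(1, rlnorm(10000, 0, 0.5))
  expect_equal(fit_boxcox(y_ln)$lambda, 0, tolerance = 0.1)
  y_n <- withr::with_seed(2, rnorm(20000, 10, 3))
  y_n <- y_n[y_n > 0.5]
  expect_equal(fit_boxcox(y_n)$lambda, 1, tolerance = 0.15)
  expect_error(fit_boxcox(rep(1, 30)), "constant")
  expect_error(fit_boxcox(rnorm(10)), ">= 20")
})

test_that("Box-Cox fit agrees with the MASS profile-likelihood implementation", {
  skip_if_not_installed("MASS")
  y <- withr::with_seed(3, rlnorm(500, 1, 0.4))
  ours <- fit_boxcox(y)
  bc <- MASS::boxcox(y ~ 1, lambda = seq(-2, 2, 0.01), plotit = FALSE)
  expect_equal(ours$lambda, bc$x[which.max(bc$y)], tolerance = 0.011)
})

test_that("exponent 1 with zero shift is the identity up to an affine constant", {
  y <- c(2, 3.5, 7)
  expect_equal(boxcox_transform(y, 1), y - 1)
})

test_that("negative and zero values are shifted positive before transforming", {
  y <- withr::with_seed(4, rnorm(100, 0, 1))
  f <- fit_boxcox(y)
  expect_equal(f$shift, 1 - min(y))
  expect_equal(f$domain_min, 1)  # min(y + shift) = 1 by construction
})

test_that("boxcox_apply flags values below the transform domain", {
  f <- fit_boxcox(withr::with_seed(5, rlnorm(100)))
  expect_identical(f$shift, 0)
  expect_warning(out <- boxcox_apply(c(1, -2), f), "domain")
  expect_true(attr(out, "clamped")[2])
  expect_false(attr(out, "clamped")[1])
  expect_equal(out[2], boxcox_transform(f$domain_min, f$lambda))
})

test_that("outlier trimming removes the expected normal tail mass", {
  z <- withr::with_seed(6, rnorm(1e6))
  tr <- trim_outliers(z)
  frac <- mean(!tr$keep)
  expect_gt(frac, 0.0008)  # 2*(1 - pnorm(3.29)) ~ 0.001
  expect_lt(frac, 0.0013)
  inside <- seq(-3, 3, length.out = 50)
  expect_identical(trim_outliers(inside)$values, inside)
  spiked <- c(rnorm(100), 10)
  expect_false(trim_outliers(spiked)$keep[101])
})

test_that("normative fit recovers null covariate effects and is deterministic", {
  cfg <- synthetic_config(n_controls = 250, effect_age = 0, effect_sex = 0,
                          effect_handedness = 0, seed = 8)
  ca <- control_assessments(generate_control_cohort(cfg))
  m1 <- fit_normative_model(ca)
  m2 <- fit_normative_model(ca)
  expect_identical(m1, m2)
  for (p in apm_parameter_names()) {
    f <- m1$parameters[[p]]
    # age slope over the 65-year span is small relative to the residual SD
    expect_lt(abs(f$coefficients["age"]) * 65, 0.5 * f$sigma)
  }
  expect_error(fit_normative_model(ca[1:40, ]), ">= 50")
})

test_that("held-out controls score as standard normal per parameter", {
  model <- fx_model()
  cfg <- synthetic_config(n_controls = 400, seed = 77)
  hold <- generate_control_cohort(cfg)
  ca <- control_assessments(hold)
  z <- parameter_z(ca[apm_parameter_names()],
                   ca[c("age", "sex", "handedness")], model)
  expect_gte(nrow(z), 1000)
  mz <- colMeans(z)
  sz <- apply(z, 2, sd)
  expect_true(all(mz > -0.1 & mz < 0.1))
  expect_true(all(sz > 0.9 & sz < 1.1))
})

test_that("scoring against the covariate model removes the age effect", {
  model <- fx_model()  # fitted on controls WITH an age effect on noise
  cfg <- synthetic_config(n_controls = 500, seed = 123)
  ca <- control_assessments(generate_control_cohort(cfg))
  z <- parameter_z(ca[apm_parameter_names()],
                   ca[c("age", "sex", "handedness")], model)
  young <- ca$age < 45
  old <- ca$age > 65
  # expected z equal for old and young once age is regressed out
  p <- t.test(rowMeans(z)[young], rowMeans(z)[old])$p.value
  expect_gt(p, 0.01)
})

test_that("z increases monotonically with raw absolute error", {
  model <- fx_model()
  demo <- data.frame(age = 60, sex = "male", handedness = "right")
  base <- as.list(setNames(rep(1, 8), apm_parameter_names()))
  raws <- seq(0.005, 0.08, length.out = 10)
  zs <- vapply(raws, function(r) {
    p <- base
    p$abs_error_x <- r
    parameter_z(as.data.frame(p), demo, model)[, "abs_error_x"]
  }, numeric(1))
  expect_true(all(diff(zs) > 0))
})

test_that("one-sided folding clamps good scores to zero and folds bad both ways", {
  expect_identical(one_sided_transform(0, "one_sided_high_bad"), 0)
  expect_identical(one_sided_transform(0, "two_sided"), 0)
  expect_identical(one_sided_transform(-2, "one_sided_high_bad"), 0)
  expect_identical(one_sided_transform(-2, "two_sided"), 2)
  expect_identical(one_sided_transform(1.5, "one_sided_high_bad"), 1.5)
})

test_that("zeta transform matches the normal-quantile oracle", {
  expect_equal(zeta_transform(1.645), qnorm((pnorm(1.645) + 1) / 2))
  expect_equal(zeta_transform(1.645), 1.96, tolerance = 1e-3)
  expect_equal(zeta_transform(0), qnorm(0.75))
  expect_equal(zeta_transform(0), 0.6745, tolerance = 1e-4)
  expect_equal(zeta_transform(-20), 0, tolerance = 1e-12)
  expect_true(is.finite(zeta_transform(12)))
  z <- seq(-5, 5, 0.25)
  expect_true(all(diff(zeta_transform(z)) > 0))
  expect_true(all(zeta_transform(z) >= 0))
})

test_that("task score is invariant to parameter column order and thresholds at 1.96", {
  model <- fx_model()
  z <- matrix(withr::with_seed(9, rnorm(80)), ncol = 8,
              dimnames = list(NULL, apm_parameter_names()))
  ts1 <- task_score(z, model)
  ts2 <- task_score(z[, sample(8)], model)
  expect_equal(ts1, ts2)
  expect_true(all(ts1$task_score >= 0))
  expect_identical(ts1$impaired, ts1$task_score > 1.96)
})

test_that("about 95% of held-out control task scores fall below 1.96", {
  model <- fx_model()
  hold <- generate_control_cohort(synthetic_config(n_controls = 400, seed = 77))
  demo <- hold$demographics
  names(demo)[names(demo) == "subject"] <- "participant"
  sc <- score_sessions(hold$trials, demo, model)
  expect_gt(nrow(sc), 1000)
  expect_equal(mean(sc$task_score < 1.96), 0.95, tolerance = 0.025)
})

test_that("scoring is bit-identical across repeated calls and JSON round-trip", {
  model <- fx_model()
  ca <- head(fx_assessments(), 20)
  z1 <- parameter_z(ca[apm_parameter_names()], ca, model)
  z2 <- parameter_z(ca[apm_parameter_names()], ca, model)
  expect_identical(z1, z2)
  path <- withr::local_tempfile(fileext = ".json")
  write_normative_model(model, path)
  model2 <- read_normative_model(path)
  z3 <- parameter_z(ca[apm_parameter_names()], ca, model2)
  expect_equal(z1, z3, tolerance = 1e-12)
  expect_equal(task_score(z1, model), task_score(z3, model2), tolerance = 1e-12)
})
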