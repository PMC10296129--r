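# Normative scoring: Box-Cox normalisation of each raw APM parameter,
# weighted covariate regression (age, sex, handedness) against a control
# population, one-sided folding of the parameter z-scores, and the composite
# zeta Task Score with its 1.96 impairment threshold.

BOXCOX_GRID <- seq(-5, 5, by = 0.01)

#' Fit a shifted Box-Cox transformation by profile maximum likelihood
#'
#' A location shift first makes all values positive (`shift = 1 - min(x)`
#' when `min(x) <= 0`, else 0); the exponent is then chosen by profile
#' log-likelihood on the fixed grid -5 to 5 in steps of 0.01.
#'
#' @param values numeric vector, length >= 20, non-constant.
#' @return list with `shift`, `lambda`, `transformed` (same length as
#'   input) and `domain_min` (smallest shifted training value, used as the
#'   scoring floor for out-of-domain values).
#' @export
fit_boxcox <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 20L) stop("need >= 20 values to fit Box-Cox", call. = FALSE)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  if (diff(range(values)) == 0) stop("constant input: Box-Cox undefined", call. = FALSE)
  shift <- if (min(values) <= 0) 1 - min(values) else 0
  y <- values + shift
  n <- length(y)
  logy <- log(y)
  slogy <- sum(logy)
  ll <- vapply(BOXCOX_GRID, function(lam) {
    t <- if (abs(lam) < 1e-12) logy else (y^lam - 1) / lam
    v <- mean((t - mean(t))^2)
    if (v <= 0) return(-Inf)
    -n / 2 * log(v) + (lam - 1) * slogy
  }, numeric(1))
  lambda <- BOXCOX_GRID[which.max(ll)]
  list(shift = shift, lambda = lambda,
       transformed = boxcox_transform(y, lambda),
       domain_min = min(y))
}

boxcox_transform <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

#' Apply a fitted Box-Cox transformation to new values
#'
#' Values whose shifted counterpart falls at or below zero lie outside the
#' transformation's domain; they are scored at the domain edge (the smallest
#' shifted value seen at fit time) and flagged via the `"clamped"` attribute
#' and a warning.
#'
#' @param values numeric vector of raw values.
#' @param fit a fit from [fit_boxcox()] (fields `shift`, `lambda`,
#'   `domain_min`).
#' @return transformed numeric vector with logical attribute `"clamped"`.
#' @export
boxcox_apply <- function(values, fit) {
  y <- as.numeric(values) + fit$shift
  clamped <- y <= 0
  if (any(clamped)) {
    warning(sprintf("%d value(s) below the Box-Cox domain; scored at the domain edge",
                    sum(clamped)), call. = FALSE)
    y[clamped] <- fit$domain_min
  }
  out <- boxcox_transform(y, fit$lambda)
  attr(out, "clamped") <- clamped
  out
}

#' Remove outliers beyond 3.29 standard deviations
#'
#' Standardises the input by its own mean and SD and removes values with
#' absolute standardised value above 3.29 (two-sided normal tail of about
#' 0.1%).
#'
#' @param values numeric vector, length >= 20.
#' @param limit cutoff in SD units (default 3.29).
#' @return list with `values` (retained) and `keep` (logical mask).
#' @export
trim_outliers <- function(values, limit = 3.29) {
  if (length(values) < 20L) stop("need >= 20 values", call. = FALSE)
  z <- (values - mean(values)) / sd(values)
  keep <- abs(z) <= limit
  list(values = values[keep], keep = keep)
}

param_directionality <- function() {
  c(abs_error_x = "one_sided_high_bad", abs_error_y = "one_sided_high_bad",
    variability_x = "one_sided_high_bad", variability_y = "one_sided_high_bad",
    contract_expand_x = "two_sided", contract_expand_y = "two_sided",
    shift_x = "two_sided", shift_y = "two_sided")
}

demographics_design <- function(demographics) {
  age <- as.numeric(demographics$age)
  if (any(!is.finite(age)) || any(age <= 0)) stop("age must be positive", call. = FALSE)
  sex_male <- as.numeric(demographics$sex == "male")
  hand_left <- as.numeric(demographics$handedness == "left")
  cbind(intercept = 1, age = age, sex_male = sex_male, hand_left = hand_left)
}

#' Fit the normative model from a control cohort
#'
#' For each of the eight APM parameters: fit a shifted Box-Cox
#' transformation, remove outliers beyond 3.29 SD of the transformed values,
#' then regress the transformed values on age, sex and handedness by
#' weighted least squares with per-observation weight 1/(number of sessions
#' contributed by that subject), so subjects with repeated assessments do
#' not dominate. The weighted residual SD completes the per-parameter
#' z-score map. All control observations are then scored, their one-sided
#' transformed z-scores combined into a root-sum-square (RSS), and the RSS's
#' own Box-Cox transformation and (trimmed, weighted) mean/SD are stored so
#' stroke assessments can be placed on the same composite scale.
#'
#' @param controls data.frame with one row per control assessment: columns
#'   `subject`, `age`, `sex` ("male"/"female"), `handedness`
#'   ("left"/"right") and the eight parameter columns of
#'   [apm_parameter_names()].
#' @return an object of class `normative_model`.
#' @export
fit_normative_model <- function(controls) {
  controls <- as.data.frame(controls)
  pnames <- apm_parameter_names()
  need <- c("subject", "age", "sex", "handedness", pnames)
  if (!all(need %in% names(controls))) {
    stop("controls lack columns: ",
         paste(setdiff(need, names(controls)), collapse = ", "), call. = FALSE)
  }
  if (nrow(controls) < 50L) {
    stop("need >= 50 control observations for a reliable calibration", call. = FALSE)
  }
  n_per_subject <- table(controls$subject)
  w <- 1 / as.numeric(n_per_subject[as.character(controls$subject)])
  X <- demographics_design(controls)
  dir <- param_directionality()

  fits <- lapply(pnames, function(p) {
    bc <- fit_boxcox(controls[[p]])
    tr <- trim_outliers(bc$transformed)
    keep <- tr$keep
    fit <- lm.wfit(x = X[keep, , drop = FALSE], y = bc$transformed[keep],
                   w = w[keep])
    r <- fit$residuals
    wk <- w[keep]
    sigma <- sqrt(sum(wk * r^2) / (sum(wk) - ncol(X)))
    if (!is.finite(sigma) || sigma <= 0) {
      stop("degenerate residual SD for parameter ", p, call. = FALSE)
    }
    list(shift = bc$shift, lambda = bc$lambda, domain_min = bc$domain_min,
         coefficients = fit$coefficients, sigma = sigma,
         directionality = unname(dir[p]), n_trimmed = sum(!keep))
  })
  names(fits) <- pnames

  model <- structure(
    list(parameters = fits, rss = NULL,
         n_obs = nrow(controls), n_subjects = length(n_per_subject),
         schema_version = 1L),
    class = "normative_model"
  )

  z <- parameter_z(controls[pnames], controls, model)
  folded <- fold_z(z, model)
  rss <- sqrt(rowSums(folded^2))
  rss_bc <- fit_boxcox(rss)
  tr <- trim_outliers(rss_bc$transformed)
  keep <- tr$keep
  wk <- w[keep]
  t_keep <- rss_bc$transformed[keep]
  m <- sum(wk * t_keep) / sum(wk)
  s <- sqrt(sum(wk * (t_keep - m)^2) / (sum(wk) - 1))
  model$rss <- list(shift = rss_bc$shift, lambda = rss_bc$lambda,
                    domain_min = rss_bc$domain_min, mean = m, sd = s)
  model
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("<normative_model> fitted on %d assessments from %d control subjects\n",
              x$n_obs, x$n_subjects))
  cat(sprintf("  RSS scale: Box-Cox lambda %.2f, mean %.3f, sd %.3f\n",
              x$rss$lambda, x$rss$mean, x$rss$sd))
  invisible(x)
}

#' Demographically adjusted parameter z-scores
#'
#' Converts raw APM parameters into z-scores relative to the control
#' population: `z = (boxcox(raw) - predicted control mean for these
#' demographics) / residual SD`. Zero equals mean control performance for a
#' person of the same age, sex and handedness.
#'
#' @param params named numeric vector of the eight raw parameters, or a
#'   data.frame with the eight parameter columns (one row per assessment).
#' @param demographics data.frame (or list) with `age`, `sex`,
#'   `handedness`, recycled/aligned to the rows of `params`.
#' @param model a fitted [fit_normative_model()] object.
#' @return matrix of z-scores, one column per parameter.
#' @export
parameter_z <- function(params, demographics, model) {
  pnames <- apm_parameter_names()
  if (is.numeric(params) && !is.matrix(params)) {
    params <- as.data.frame(as.list(params))
  }
  params <- as.data.frame(params)
  if (!all(pnames %in% names(params))) {
    stop("params lack columns: ",
         paste(setdiff(pnames, names(params)), collapse = ", "), call. = FALSE)
  }
  demographics <- as.data.frame(demographics)
  X <- demographics_design(demographics)
  if (nrow(X) == 1L && nrow(params) > 1L) {
    X <- X[rep(1L, nrow(params)), , drop = FALSE]
  }
  if (nrow(X) != nrow(params)) {
    stop("demographics and params row counts differ", call. = FALSE)
  }
  z <- sapply(pnames, function(p) {
    f <- model$parameters[[p]]
    t <- suppressWarnings(boxcox_apply(params[[p]], f))
    (as.numeric(t) - drop(X %*% f$coefficients)) / f$sigma
  })
  if (is.null(dim(z))) z <- matrix(z, nrow = 1, dimnames = list(NULL, pnames))
  z
}

#' Fold a z-score according to parameter directionality
#'
#' Best performance maps to 0 and worse performance to larger values. For
#' one-sided parameters (absolute error, variability: only high values are
#' bad) negative z clamps to 0; for two-sided parameters (shift,
#' contraction/expansion: deviation in either direction is bad) the absolute
#' value is taken.
#'
#' @param z numeric z-score(s).
#' @param directionality `"one_sided_high_bad"` or `"two_sided"`.
#' @return non-negative folded score(s).
#' @export
one_sided_transform <- function(z, directionality = c("one_sided_high_bad", "two_sided")) {
  directionality <- match.arg(directionality)
  if (directionality == "one_sided_high_bad") pmax(z, 0) else abs(z)
}

fold_z <- function(z, model) {
  pnames <- apm_parameter_names()
  folded <- z
  for (p in pnames) {
    folded[, p] <- one_sided_transform(z[, p], model$parameters[[p]]$directionality)
  }
  folded
}

#' Half-normal zeta transform
#'
#' Maps a normal z-score to the non-negative zeta scale via
#' `zeta = qnorm((pnorm(z) + 1) / 2)`: the control distribution of zeta is
#' the absolute value of a standard normal, so 95% of controls score below
#' 1.96 and 0 is the best attainable score.
#'
#' @param z numeric z-score(s).
#' @return non-negative zeta score(s).
#' @export
zeta_transform <- function(z) {
  # upper-tail formulation keeps precision (and finiteness) for large z
  qnorm(pnorm(z, lower.tail = FALSE) / 2, lower.tail = FALSE)
}

#' Composite APM Task Score
#'
#' Combines the eight parameter z-scores: fold each by its directionality,
#' take the root-sum-square (RSS), convert the RSS to a z-score through the
#' model's stored Box-Cox/mean/SD, and map it to the zeta scale. Scores
#' above 1.96 indicate impaired performance (5% of controls exceed it).
#'
#' @param z matrix (or single named vector) of the eight parameter z-scores.
#' @param model a fitted [fit_normative_model()] object.
#' @param threshold impairment threshold on the zeta scale (default 1.96).
#' @return data.frame with `task_score` and logical `impaired`.
#' @export
task_score <- function(z, model, threshold = 1.96) {
  if (is.numeric(z) && !is.matrix(z)) {
    z <- matrix(z, nrow = 1, dimnames = list(NULL, names(z)))
  }
  z <- z[, apm_parameter_names(), drop = FALSE]
  folded <- fold_z(z, model)
  rss <- sqrt(rowSums(folded^2))
  t <- suppressWarnings(boxcox_apply(rss, model$rss))
  z_rss <- (as.numeric(t) - model$rss$mean) / model$rss$sd
  zeta <- zeta_transform(z_rss)
  data.frame(task_score = zeta, impaired = zeta > threshold)
}

#' Serialize a normative model to JSON
#'
#' @param model a `normative_model`.
#' @param path file path to write.
#' @export
write_normative_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a normative model from JSON
#'
#' @param path file written by [write_normative_model()].
#' @return a `normative_model`.
#' @export
read_normative_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$parameters <- lapply(obj$parameters, function(p) {
    p$coefficients <- unlist(p$coefficients)
    p
  })
  structure(obj, class = "normative_model")
}
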