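# Univariate battery: feature-outcome associations (OLS, Spearman, t-test)
# and impaired-vs-unimpaired group comparisons (Mann-Whitney U) with
# Bonferroni correction.

association_result <- function(feature, method, statistic, effect, p,
                               alpha = 0.05, extra = list()) {
  structure(c(list(feature = feature, method = method,
                   statistic = unname(statistic), effect = unname(effect),
                   p = unname(p), alpha = alpha,
                   significant = unname(p) < alpha),
              extra),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s [%s]: statistic = %.4g, effect = %s, p = %.3g%s\n",
              x$feature, x$method, x$statistic,
              if (is.null(x$effect) || is.na(x$effect)) "NA" else sprintf("%.4g", x$effect),
              x$p, if (x$significant) " *" else ""))
  invisible(x)
}

#' Simple linear regression association
#'
#' Ordinary least squares of `y` on `x`; reports the slope t statistic, the
#' two-sided p-value and R-squared (adjusted R-squared in `adj_r_squared`).
#'
#' @param x,y numeric vectors, n >= 3.
#' @param feature label for the result.
#' @param alpha critical alpha for the significance flag.
#' @return an `association_result`.
#' @export
linear_assoc <- function(x, y, feature = deparse(substitute(x)), alpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (var(x) == 0) stop("predictor has zero variance", call. = FALSE)
  fit <- lm(y ~ x)
  sm <- summary(fit)
  association_result(feature, "linear_regression",
                     statistic = sm$coefficients[2, "t value"],
                     effect = sm$r.squared,
                     p = sm$coefficients[2, "Pr(>|t|)"],
                     alpha = alpha,
                     extra = list(adj_r_squared = sm$adj.r.squared,
                                  slope = unname(coef(fit)[2])))
}

#' Spearman rank correlation association
#'
#' Rank correlation with midrank ties; the p-value uses the t
#' approximation.
#'
#' @inheritParams linear_assoc
#' @return an `association_result` with `effect` = rho.
#' @export
spearman_assoc <- function(x, y, feature = deparse(substitute(x)), alpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (var(x) == 0 || var(y) == 0) stop("constant input", call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  association_result(feature, "spearman",
                     statistic = ct$statistic, effect = ct$estimate,
                     p = ct$p.value, alpha = alpha)
}

#' Student's pooled-variance two-sample t-test
#'
#' @param g1,g2 numeric vectors (each n >= 2).
#' @param feature label.
#' @param alpha critical alpha.
#' @return an `association_result` with `statistic` = t; positive when `g1`
#'   has the larger mean.
#' @export
two_sample_t <- function(g1, g2, feature = "group_difference", alpha = 0.05) {
  stopifnot(length(g1) >= 2, length(g2) >= 2)
  tt <- t.test(g1, g2, var.equal = TRUE)
  association_result(feature, "t_test",
                     statistic = tt$statistic,
                     effect = unname(diff(rev(tt$estimate))),
                     p = tt$p.value, alpha = alpha,
                     extra = list(df = unname(tt$parameter)))
}

#' Mann-Whitney U test (normal approximation)
#'
#' U statistic for the first group with the normal approximation, tie
#' correction and continuity correction, two-sided.
#'
#' @inheritParams two_sample_t
#' @return an `association_result` with `statistic` = U of `g1`.
#' @export
mann_whitney <- function(g1, g2, feature = "group_difference", alpha = 0.05) {
  stopifnot(length(g1) >= 2, length(g2) >= 2)
  wt <- suppressWarnings(wilcox.test(g1, g2, exact = FALSE, correct = TRUE))
  association_result(feature, "mann_whitney",
                     statistic = wt$statistic, effect = NA_real_,
                     p = wt$p.value, alpha = alpha)
}

#' Bonferroni-adjusted critical alpha
#'
#' @param family_alpha family-wise alpha (default 0.05).
#' @param m number of comparisons.
#' @return `family_alpha / m`.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, m) {
  stopifnot_scalar_count(m, "m")
  family_alpha / m
}

#' Hemispatial neglect flag from the BIT
#'
#' Behavioural Inattention Test scores below 130 indicate hemispatial
#' neglect.
#'
#' @param bit_score BIT score(s), 0-146.
#' @return logical vector.
#' @export
neglect_flag <- function(bit_score) {
  if (any(!is.finite(bit_score)) || any(bit_score < 0 | bit_score > 146)) {
    stop("BIT scores must lie in [0, 146]", call. = FALSE)
  }
  bit_score < 130
}

battery_features <- function() {
  c("age", "tlt", "bit", "fim", "lesion_volume", "vlsm_mean_z",
    apm_parameter_names())
}

results_to_df <- function(results) {
  data.frame(
    feature = vapply(results, `[[`, character(1), "feature"),
    method = vapply(results, `[[`, character(1), "method"),
    statistic = vapply(results, `[[`, numeric(1), "statistic"),
    effect = vapply(results, function(r) as.numeric(r$effect %||% NA), numeric(1)),
    p = vapply(results, `[[`, numeric(1), "p"),
    significant = vapply(results, `[[`, logical(1), "significant"),
    row.names = NULL
  )
}

#' Feature-outcome association battery
#'
#' Association of each two-week feature with the six-month Task Score:
#' simple linear regression for continuous features, Spearman rank
#' correlation for the ordinal TLT, and pooled two-sample t-tests for sex
#' and affected arm.
#'
#' @param features data.frame with the columns of [battery_features()] plus
#'   `sex` and `affected_arm`.
#' @param outcome numeric six-month Task Score per participant.
#' @param alpha critical alpha applied to every test (default 0.05).
#' @return data.frame, one row per feature.
#' @export
assoc_battery <- function(features, outcome, alpha = 0.05) {
  cont <- setdiff(battery_features(), "tlt")
  res <- lapply(cont, function(f) {
    linear_assoc(features[[f]], outcome, feature = f, alpha = alpha)
  })
  res <- c(res, list(spearman_assoc(features$tlt, outcome, feature = "tlt",
                                    alpha = alpha)))
  for (f in c("sex", "affected_arm")) {
    lev <- sort(unique(features[[f]]))
    g1 <- outcome[features[[f]] == lev[1]]
    g2 <- outcome[features[[f]] == lev[2]]
    res <- c(res, list(two_sample_t(g1, g2,
                                    feature = paste0(f, ":", lev[1], "-", lev[2]),
                                    alpha = alpha)))
  }
  results_to_df(res)
}

#' Impaired-vs-unimpaired group comparison battery
#'
#' Mann-Whitney U tests of each of the 14 features (age, TLT, BIT, FIM,
#' lesion volume, VLSM mean Z and the eight robotic parameters) between the
#' six-month impaired and unimpaired groups, at the Bonferroni-adjusted
#' critical alpha 0.05/14 = 0.00357.
#'
#' @param features data.frame with the columns of [battery_features()].
#' @param impaired logical six-month impairment label.
#' @param family_alpha family-wise alpha (default 0.05).
#' @return data.frame, one row per feature; `significant` uses the adjusted
#'   alpha.
#' @export
group_battery <- function(features, impaired, family_alpha = 0.05) {
  feats <- battery_features()
  alpha <- bonferroni_alpha(family_alpha, length(feats))
  res <- lapply(feats, function(f) {
    mann_whitney(features[[f]][impaired], features[[f]][!impaired],
                 feature = f, alpha = alpha)
  })
  out <- results_to_df(res)
  attr(out, "critical_alpha") <- alpha
  out
}
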