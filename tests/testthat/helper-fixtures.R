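# Shared fixtures, computed lazily once per test run and cached.

.fx <- new.env(parent = emptyenv())

# Normative model fitted on a moderate control cohort; shared by every test
# that only needs *a* fitted model (the acceptance calibration check fits
# its own full-size cohort).
fx_model <- function() {
  if (is.null(.fx$model)) {
    .fx$norm_config <- synthetic_config(seed = 42)  # full 799-subject default
    .fx$controls <- generate_control_cohort(.fx$norm_config)
    .fx$assessments <- control_assessments(.fx$controls)
    .fx$model <- fit_normative_model(.fx$assessments)
  }
  .fx$model
}

fx_assessments <- function() {
  fx_model()
  .fx$assessments
}

# Default-size stroke cohort (n = 133) with its feature table.
fx_stroke <- function() {
  if (is.null(.fx$stroke)) {
    model <- fx_model()
    cfg <- synthetic_config(n_controls = 300, seed = 42)
    .fx$stroke <- generate_stroke_cohort(cfg, model)
    .fx$features <- build_feature_table(.fx$stroke, model)
  }
  .fx$stroke
}

fx_features <- function() {
  fx_stroke()
  .fx$features
}

# Large stroke cohort (n = 500) for association-structure checks.
fx_stroke_500 <- function() {
  if (is.null(.fx$stroke500)) {
    model <- fx_model()
    cfg <- synthetic_config(n_controls = 300, n_stroke = 500, seed = 314)
    .fx$stroke500 <- generate_stroke_cohort(cfg, model)
    .fx$features500 <- build_feature_table(.fx$stroke500, model)
  }
  .fx$stroke500
}

fx_features_500 <- function() {
  fx_stroke_500()
  .fx$features500
}

# Multi-seed sweep at n = 200: per-seed mean Task Score improvement, VLSM
# peak-voxel recovery, and group difference in VLSM mean Z.
fx_seed_sweep <- function(n_seeds = 20L) {
  if (is.null(.fx$sweep)) {
    model <- fx_model()
    res <- lapply(seq_len(n_seeds), function(s) {
      cfg <- synthetic_config(n_controls = 300, n_stroke = 200,
                              seed = 1000L + s)
      st <- generate_stroke_cohort(cfg, model)
      ft <- build_feature_table(st, model)
      map <- attr(ft, "vlsm_map")
      peak <- arrayInd(which.max(ifelse(is.na(map$z), -Inf, map$z)),
                       dim(map$z))
      cr <- cfg$critical_region
      res_models <- evaluate_all_models(ft, k = 10, seed = 1000L + s)
      list(
        ts_improvement = mean(ft$task_score_2wk) - mean(ft$task_score_6mo),
        peak_in_region = all(peak >= cr$lower & peak <= cr$upper),
        mz_impaired = ft$vlsm_mean_z[ft$impaired_6mo == 1],
        mz_unimpaired = ft$vlsm_mean_z[ft$impaired_6mo == 0],
        aucs = vapply(res_models, function(r) r$metrics$auc, numeric(1))
      )
    })
    .fx$sweep <- res
  }
  .fx$sweep
}

# A hand-built session: perceived position = centre + scale*(target-centre)
# + offset + noise, recorded as its mirror image (midline x = 0).
make_session_trials <- function(arm = "right", offset = c(0, 0),
                                scale = c(1, 1), noise_sd = 0,
                                n_blocks = 6L, seed = NULL) {
  lay <- apm_target_layout(arm)
  cx <- if (arm == "right") 0.20 else -0.20
  cy <- 0.35
  build <- function() {
    tr <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      data.frame(block = b, target = 1:9,
                 robot_x = lay$x, robot_y = lay$y)
    }))
    perc_x <- cx + scale[1] * (tr$robot_x - cx) + offset[1] +
      rnorm(nrow(tr), 0, noise_sd)
    perc_y <- cy + scale[2] * (tr$robot_y - cy) + offset[2] +
      rnorm(nrow(tr), 0, noise_sd)
    tr$match_x <- -perc_x
    tr$match_y <- perc_y
    tr
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# Exhaustive-permutation two-sided Mann-Whitney p (symmetric-tail rule).
exact_mw_p <- function(g1, g2) {
  n1 <- length(g1)
  all_v <- c(g1, g2)
  n <- length(all_v)
  r <- rank(all_v)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  obs <- abs(u_of(seq_len(n1)) - mu)
  us <- combn(n, n1, u_of)
  mean(abs(us - mu) >= obs - 1e-9)
}

# Pairwise-concordance AUC oracle: P(score+ > score-) + 0.5 P(tie).
concordance_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}
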