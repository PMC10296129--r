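# Synthetic cohorts: a control population with demographic effects on
# matching performance, and a stroke cohort with a latent proprioceptive
# severity that drives the robotic, clinical and lesion modalities, with
# the six-month impairment prevalence calibrated against a fitted normative
# model.

#' Configuration for the synthetic cohort generator
#'
#' The defaults reproduce the study conditions downstream modules assume:
#' 799 control subjects contributing about 2.79 assessments each (~2229
#' sessions), a 133-participant stroke cohort with 36.1% six-month
#' impairment prevalence, 78/133 left-affected and 42/133 female, and a
#' coarse 40 x 48 x 40 lesion grid at 4 mm isotropic with an implanted
#' critical region in one hemisphere.
#'
#' @param n_controls number of control subjects.
#' @param assessments_per_control mean sessions per control subject
#'   (sessions are `1 + Poisson(assessments_per_control - 1)`).
#' @param n_stroke number of stroke participants.
#' @param prop_impaired_6mo target fraction impaired at six months.
#' @param prop_female fraction female (stroke cohort).
#' @param prop_left_affected fraction with the left arm affected.
#' @param effect_age relative increase in matching-noise SD per year of age
#'   (centred at 52.5 years).
#' @param effect_sex relative noise-SD increase for males vs females.
#' @param effect_handedness relative noise-SD increase for left- vs
#'   right-handers.
#' @param effect_left_affected log-odds shift toward six-month impairment
#'   for left-affected (right-hemisphere lesion) participants.
#' @param noise_sd baseline per-trial matching noise SD (metres).
#' @param bias_sd SD of the per-subject systematic workspace shift (metres);
#'   independent of severity, so the Shift parameter carries no outcome
#'   signal.
#' @param scale_sd SD of the per-subject workspace scale jitter around 1.
#' @param severity_noise_gain relative noise-SD increase per unit latent
#'   severity.
#' @param severity_contraction workspace contraction rate per unit severity
#'   (`scale ~ exp(-severity_contraction * s)`).
#' @param recovery_factor fraction by which severity shrinks from two weeks
#'   to six months in the recovering subgroup.
#' @param prop_recovering fraction of participants in the recovering
#'   subgroup.
#' @param lesion_grid integer vector of 3 voxel counts.
#' @param voxel_size numeric vector of 3 voxel dimensions (mm).
#' @param critical_region list with integer `lower` and `upper` voxel
#'   corners of the implanted critical box, strictly inside the grid.
#' @param lesion_base_voxels median lesion size (voxels) at zero severity.
#' @param lesion_severity_gain log-volume increase per unit severity.
#' @param lesion_log_sd log-normal SD of lesion volume.
#' @param seed integer seed; all generator randomness flows from it.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_controls = 799,
                             assessments_per_control = 2.79,
                             n_stroke = 133,
                             prop_impaired_6mo = 0.361,
                             prop_female = 42 / 133,
                             prop_left_affected = 78 / 133,
                             effect_age = 0.004,
                             effect_sex = 0.10,
                             effect_handedness = 0.10,
                             effect_left_affected = 0.8,
                             noise_sd = 0.015,
                             bias_sd = 0.008,
                             scale_sd = 0.05,
                             severity_noise_gain = 1.2,
                             severity_contraction = 0.12,
                             recovery_factor = 0.5,
                             prop_recovering = 0.5,
                             lesion_grid = c(40L, 48L, 40L),
                             voxel_size = c(4, 4, 4),
                             critical_region = list(lower = c(24L, 20L, 16L),
                                                    upper = c(32L, 28L, 24L)),
                             lesion_base_voxels = 120,
                             lesion_severity_gain = 0.45,
                             lesion_log_sd = 0.6,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot_scalar_count(cfg$n_controls, "n_controls")
  stopifnot_scalar_count(cfg$n_stroke, "n_stroke")
  if (cfg$assessments_per_control < 1) {
    stop("assessments_per_control must be >= 1", call. = FALSE)
  }
  stopifnot_fraction(cfg$prop_impaired_6mo, "prop_impaired_6mo")
  stopifnot_fraction(cfg$prop_female, "prop_female")
  stopifnot_fraction(cfg$prop_left_affected, "prop_left_affected")
  if (cfg$recovery_factor < 0 || cfg$recovery_factor >= 1) {
    stop("recovery_factor must lie in [0, 1)", call. = FALSE)
  }
  if (length(cfg$lesion_grid) != 3L || any(cfg$lesion_grid < 4)) {
    stop("lesion_grid must be 3 voxel counts >= 4", call. = FALSE)
  }
  if (length(cfg$voxel_size) != 3L || any(cfg$voxel_size <= 0)) {
    stop("voxel_size must be 3 positive lengths (mm)", call. = FALSE)
  }
  cr <- cfg$critical_region
  if (!all(cr$lower >= 2) || !all(cr$upper <= cfg$lesion_grid - 1) ||
      !all(cr$lower < cr$upper)) {
    stop("critical_region must lie strictly inside lesion_grid", call. = FALSE)
  }
  if (cfg$noise_sd < 0 || cfg$bias_sd < 0 || cfg$scale_sd < 0) {
    stop("noise/bias/scale SDs must be non-negative", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' Write / read a synthetic configuration as JSON
#' @param config a `synthetic_config`.
#' @param path file path.
#' @export
write_synthetic_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$lesion_grid <- as.integer(obj$lesion_grid)
  obj$critical_region <- lapply(obj$critical_region, as.integer)
  do.call(synthetic_config, obj)
}

#' Target layout of the APM task
#'
#' Nine targets on a 20 cm x 20 cm square (8 outer targets around a centre
#' target), placed in the workspace of the assessed arm; the mirror axis is
#' at x = 0.
#'
#' @param arm `"left"` or `"right"`: the robot-moved arm.
#' @return data.frame with `target`, `x`, `y` (metres).
#' @export
apm_target_layout <- function(arm = c("right", "left")) {
  arm <- match.arg(arm)
  cx <- if (arm == "right") 0.20 else -0.20
  cy <- 0.35
  off <- c(-0.10, 0, 0.10)
  grid <- expand.grid(dx = off, dy = off)
  data.frame(target = 1:9, x = cx + grid$dx, y = cy + grid$dy)
}

# Build a trial table for `ns` sessions with pre-drawn noise. All inputs are
# per-session vectors of length ns except eps_x/eps_y (ns x 54 matrices of
# standard normals) and orders (54 x ns matrix of targets).
build_trials <- function(ids, arm, sigma, scale_x, scale_y, bias_x, bias_y,
                         eps_x, eps_y, orders, midline_x = 0) {
  ns <- length(ids)
  lay_r <- apm_target_layout("right")
  lay_l <- apm_target_layout("left")
  target <- as.vector(orders)
  sess <- rep(seq_len(ns), each = 54L)
  is_right <- arm[sess] == "right"
  tx <- ifelse(is_right, lay_r$x[target], lay_l$x[target])
  ty <- ifelse(is_right, lay_r$y[target], lay_l$y[target])
  cx <- ifelse(is_right, 0.20, -0.20)
  cy <- 0.35
  perc_x <- cx + scale_x[sess] * (tx - cx) + bias_x[sess] +
    sigma[sess] * as.vector(t(eps_x))
  perc_y <- cy + scale_y[sess] * (ty - cy) + bias_y[sess] +
    sigma[sess] * as.vector(t(eps_y))
  data.table::data.table(
    .session = sess,
    participant = ids[sess],
    arm_assessed = arm[sess],
    block = rep(rep(1:6, each = 9L), ns),
    target = target,
    robot_x = tx, robot_y = ty,
    match_x = 2 * midline_x - perc_x, match_y = perc_y,
    midline_x = midline_x
  )
}

draw_orders <- function(n_sessions) {
  vapply(seq_len(n_sessions * 6L), function(i) sample.int(9L), integer(9L))
}

control_noise_sd <- function(config, age, sex, handedness) {
  sd <- config$noise_sd *
    pmax(0, 1 + config$effect_age * (age - 52.5)) *
    (1 + config$effect_sex * (sex == "male")) *
    (1 + config$effect_handedness * (handedness == "left"))
  pmax(sd, 0)
}

#' Generate a synthetic control population
#'
#' Control subjects with age uniform on 20-85 and balanced sex and
#' handedness, each contributing one or more APM sessions. Matched positions
#' mirror the robot positions up to a per-subject workspace bias and scale
#' jitter plus Gaussian trial noise whose SD grows linearly with age and
#' differs by sex and handedness by the configured effects.
#'
#' @param config a [synthetic_config()].
#' @return list of class `control_cohort` with `demographics` (one row per
#'   subject), `trials` (one row per trial, sessions keyed by
#'   `participant` + `session`), and the `config`.
#' @export
generate_control_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_controls
    demo <- data.frame(
      subject = sprintf("C%04d", seq_len(n)),
      age = runif(n, 20, 85),
      sex = ifelse(runif(n) < 0.5, "female", "male"),
      handedness = ifelse(runif(n) < 0.5, "left", "right"),
      stringsAsFactors = FALSE
    )
    demo$n_sessions <- 1L + rpois(n, config$assessments_per_control - 1)
    sigma_subj <- control_noise_sd(config, demo$age, demo$sex, demo$handedness)
    bias_x <- rnorm(n, 0, config$bias_sd)
    bias_y <- rnorm(n, 0, config$bias_sd)
    scale_x <- rnorm(n, 1, config$scale_sd)
    scale_y <- rnorm(n, 1, config$scale_sd)

    idx <- rep(seq_len(n), demo$n_sessions)
    ns <- length(idx)
    arm <- ifelse(runif(ns) < 0.5, "left", "right")
    orders <- draw_orders(ns)
    eps_x <- matrix(rnorm(ns * 54L), nrow = ns)
    eps_y <- matrix(rnorm(ns * 54L), nrow = ns)
    trials <- build_trials(demo$subject[idx], arm, sigma_subj[idx],
                           scale_x[idx], scale_y[idx],
                           bias_x[idx], bias_y[idx],
                           eps_x, eps_y, orders)
    # session index = running index of the session within the participant
    trials[, session := match(.session, unique(.session)), by = participant]
    trials[, .session := NULL]
    structure(list(demographics = demo, trials = trials[], config = config),
              class = "control_cohort")
  })
}

#' Control assessments with demographics, ready for normative fitting
#'
#' Computes the eight raw parameters for every control session and joins the
#' subject demographics, producing the one-row-per-assessment table
#' [fit_normative_model()] consumes.
#'
#' @param cohort a `control_cohort`.
#' @return data.frame with `subject`, demographics and parameter columns.
#' @export
control_assessments <- function(cohort) {
  stopifnot(inherits(cohort, "control_cohort"))
  params <- session_parameters(cohort$trials, by = c("participant", "session"))
  demo <- data.table::as.data.table(cohort$demographics)
  out <- merge(params, demo, by.x = "participant", by.y = "subject",
               sort = FALSE)
  data.table::setnames(out, "participant", "subject")
  as.data.frame(out)
}

#' Score sessions through a normative model
#'
#' Computes raw parameters per session, converts them to demographically
#' adjusted z-scores and the composite Task Score.
#'
#' @param trials trial table (one row per trial).
#' @param demographics data.frame keyed by `participant` with `age`, `sex`,
#'   `handedness`.
#' @param model a fitted `normative_model`.
#' @param by grouping columns identifying a session.
#' @return data.table: grouping columns, the eight z-score columns,
#'   `task_score`, `impaired`.
#' @export
score_sessions <- function(trials, demographics, model,
                           by = c("participant", "session")) {
  params <- session_parameters(trials, by = by)
  demo <- data.table::as.data.table(demographics)
  idcol <- if ("participant" %in% names(demo)) "participant" else "subject"
  m <- merge(params, demo[, c(idcol, "age", "sex", "handedness"), with = FALSE],
             by.x = "participant", by.y = idcol, sort = FALSE)
  z <- parameter_z(as.data.frame(m)[apm_parameter_names()],
                   as.data.frame(m)[c("age", "sex", "handedness")], model)
  ts <- task_score(z, model)
  out <- m[, c(by), with = FALSE]
  out <- cbind(out, data.table::as.data.table(z))
  out[, `:=`(task_score = ts$task_score, impaired = ts$impaired)]
  out[]
}

# Deterministic severity -> six-month session scorer used by the prevalence
# calibration: everything random is pre-drawn, only the scale factor moves.
stroke_session_frac <- function(scale_c, pre, config, model) {
  s6 <- scale_c * pre$s_base
  sigma <- pre$sigma0 * (1 + config$severity_noise_gain * s6)
  sc_x <- pre$scale_x * exp(-config$severity_contraction * s6)
  sc_y <- pre$scale_y * exp(-config$severity_contraction * s6)
  trials <- build_trials(pre$id, pre$arm, sigma, sc_x, sc_y,
                         pre$bias_x, pre$bias_y,
                         pre$eps6_x, pre$eps6_y, pre$orders6)
  scored <- score_sessions(trials, pre$demo, model, by = "participant")
  mean(scored$impaired)
}

#' Generate a synthetic stroke cohort
#'
#' Each participant carries a latent proprioceptive severity `s` drawn from
#' a two-component mixture (a near-zero component and a log-normal impaired
#' tail, with left-affected participants shifted toward the impaired
#' component by the configured log-odds). Severity scales the matching noise
#' and workspace contraction of the APM sessions, sets the clinical scores
#' (TLT, BIT, FIM) and biases lesion size and placement; the per-subject
#' workspace bias (the Shift parameter) and age are independent of `s`. A
#' global severity scale is calibrated by bisection against the supplied
#' normative model so the realized six-month impaired fraction matches
#' `prop_impaired_6mo`.
#'
#' @param config a [synthetic_config()].
#' @param model a fitted `normative_model` (needed to calibrate severity
#'   against the 1.96 threshold).
#' @param calibration_tol stop the calibration when the realized fraction is
#'   within this distance of the target (default 0.01).
#' @param max_iter bisection iteration cap; exceeding it with a realized
#'   fraction more than 5 percentage points from the target is an error.
#' @return list of class `stroke_cohort`: `demographics`, `latent`
#'   (severities, mixture component, recovery flag), `trials` (both
#'   timepoints, `timepoint` 2 or 26 weeks), `clinical`, `lesions` (list of
#'   `lesion_mask`), `calibration`, `config`.
#' @export
generate_stroke_cohort <- function(config, model, calibration_tol = 0.01,
                                   max_iter = 40L) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(model, "normative_model"))
  with_seed(config$seed + 1L, {
    n <- config$n_stroke
    id <- sprintf("S%04d", seq_len(n))
    demo <- data.frame(
      participant = id,
      age = runif(n, 20, 85),
      sex = ifelse(runif(n) < config$prop_female, "female", "male"),
      handedness = ifelse(runif(n) < 0.5, "left", "right"),
      affected_arm = ifelse(runif(n) < config$prop_left_affected,
                            "left", "right"),
      stringsAsFactors = FALSE
    )
    left <- demo$affected_arm == "left"
    p_imp <- plogis(qlogis(config$prop_impaired_6mo) +
                      config$effect_left_affected *
                        (left - config$prop_left_affected))
    in_tail <- runif(n) < p_imp
    s_base <- ifelse(in_tail, rlnorm(n, meanlog = 0, sdlog = 0.5),
                     abs(rnorm(n, 0, 0.05)))
    recovers <- runif(n) < config$prop_recovering

    pre <- list(
      id = id, arm = demo$affected_arm, s_base = s_base,
      demo = data.frame(demo, stringsAsFactors = FALSE),
      sigma0 = control_noise_sd(config, demo$age, demo$sex, demo$handedness),
      bias_x = rnorm(n, 0, config$bias_sd),
      bias_y = rnorm(n, 0, config$bias_sd),
      scale_x = rnorm(n, 1, config$scale_sd),
      scale_y = rnorm(n, 1, config$scale_sd),
      orders2 = draw_orders(n), orders6 = draw_orders(n),
      eps2_x = matrix(rnorm(n * 54L), nrow = n),
      eps2_y = matrix(rnorm(n * 54L), nrow = n),
      eps6_x = matrix(rnorm(n * 54L), nrow = n),
      eps6_y = matrix(rnorm(n * 54L), nrow = n)
    )

    # ---- calibrate the global severity scale by bisection ----------------
    target <- config$prop_impaired_6mo
    lo <- 1e-3; hi <- 1e3
    f_lo <- stroke_session_frac(lo, pre, config, model)
    f_hi <- stroke_session_frac(hi, pre, config, model)
    best <- list(c = 1, err = Inf, frac = NA_real_)
    iter <- 0L
    if (f_lo >= target) {
      best <- list(c = lo, err = abs(f_lo - target), frac = f_lo)
    } else if (f_hi <= target) {
      best <- list(c = hi, err = abs(f_hi - target), frac = f_hi)
    } else {
      repeat {
        iter <- iter + 1L
        mid <- sqrt(lo * hi)
        f_mid <- stroke_session_frac(mid, pre, config, model)
        if (abs(f_mid - target) < best$err) {
          best <- list(c = mid, err = abs(f_mid - target), frac = f_mid)
        }
        if (best$err <= calibration_tol || iter >= max_iter) break
        if (f_mid < target) lo <- mid else hi <- mid
      }
    }
    if (best$err > 0.05) {
      stop(sprintf(paste0("severity calibration failed after %d iterations: ",
                          "realized impaired fraction %.3f vs target %.3f"),
                   iter, best$frac, target), call. = FALSE)
    }

    s6 <- best$c * s_base
    s2 <- ifelse(recovers & config$recovery_factor > 0,
                 s6 / (1 - config$recovery_factor), s6)

    make_tp <- function(s, eps_x, eps_y, orders, weeks) {
      sigma <- pre$sigma0 * (1 + config$severity_noise_gain * s)
      tr <- build_trials(id, demo$affected_arm, sigma,
                         pre$scale_x * exp(-config$severity_contraction * s),
                         pre$scale_y * exp(-config$severity_contraction * s),
                         pre$bias_x, pre$bias_y, eps_x, eps_y, orders)
      tr[, `:=`(timepoint = weeks, .session = NULL)]
      tr
    }
    trials <- data.table::rbindlist(list(
      make_tp(s2, pre$eps2_x, pre$eps2_y, pre$orders2, 2),
      make_tp(s6, pre$eps6_x, pre$eps6_y, pre$orders6, 26)
    ))

    # ---- clinical scores -------------------------------------------------
    # driven by the unit-scale latent severity (the calibrated scale only
    # adapts severity to APM noise units, clinical instruments keep their own)
    u2 <- ifelse(recovers & config$recovery_factor > 0,
                 s_base / (1 - config$recovery_factor), s_base)
    tlt <- pmin(3L, findInterval(u2 + rnorm(n, 0, 0.3), c(0.4, 1.0, 1.8)))
    bit <- pmin(146, pmax(0, round(144 - 14 * u2 + rnorm(n, 0, 3))))
    fim <- pmin(126, pmax(18, round(112 - 20 * u2 + rnorm(n, 0, 8))))
    clinical <- data.frame(participant = id, tlt = tlt, bit = bit, fim = fim)

    # ---- lesion masks ----------------------------------------------------
    lesions <- generate_lesions(config, s_base, in_tail)
    names(lesions) <- id

    structure(
      list(demographics = demo,
           latent = data.frame(participant = id, s_2wk = s2, s_6mo = s6,
                               impaired_component = in_tail,
                               recovers = recovers),
           trials = trials[], clinical = clinical, lesions = lesions,
           calibration = list(scale = best$c, realized_frac = best$frac,
                              iterations = iter),
           config = config),
      class = "stroke_cohort"
    )
  })
}

# Random ellipsoidal lesions: impaired-component lesions are usually (not
# always) centred inside the critical region and unimpaired lesions
# occasionally fall there too, so lesion location is informative but not
# deterministic; volume grows log-linearly with severity.
generate_lesions <- function(config, s, in_tail) {
  grid <- config$lesion_grid
  cr <- config$critical_region
  n <- length(s)
  vol <- pmax(8, round(exp(log(config$lesion_base_voxels) +
                             config$lesion_severity_gain * s +
                             rnorm(n, 0, config$lesion_log_sd))))
  hit_region <- runif(n) < ifelse(in_tail, 0.75, 0.15)
  lapply(seq_len(n), function(i) {
    centre <- if (hit_region[i]) {
      round(runif(3, cr$lower, cr$upper))
    } else {
      round(runif(3, 4, grid - 3))
    }
    r0 <- (3 * vol[i] / (4 * pi))^(1 / 3)
    f <- exp(rnorm(3, 0, 0.2))
    r <- pmax(1, r0 * f / prod(f)^(1 / 3))
    arr <- array(0L, dim = grid)
    lo <- pmax(1, floor(centre - r)); hi <- pmin(grid, ceiling(centre + r))
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    dx2 <- ((ix - centre[1]) / r[1])^2
    dy2 <- ((iy - centre[2]) / r[2])^2
    dz2 <- ((iz - centre[3]) / r[3])^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
    arr[ix, iy, iz][inside] <- 1L
    arr[centre[1], centre[2], centre[3]] <- 1L
    lesion_mask(arr, voxel_size = config$voxel_size, space = "synthetic")
  })
}

#' Write a cohort to CSV interchange files
#'
#' Writes `demographics.csv`, `trials.csv` (one row per trial) and, for
#' stroke cohorts, `clinical.csv` and `latent.csv`, plus the configuration
#' as `config.json`.
#'
#' @param cohort a `control_cohort` or `stroke_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wr(cohort$demographics, "demographics.csv")
  wr(cohort$trials, "trials.csv")
  if (inherits(cohort, "stroke_cohort")) {
    wr(cohort$clinical, "clinical.csv")
    wr(cohort$latent, "latent.csv")
  }
  write_synthetic_config(cohort$config, file.path(dir, "config.json"))
  invisible(dir)
}
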