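# Arm position matching (APM) task: trial-level representation and the eight
# raw performance parameters (absolute error, variability,
# contraction/expansion, shift; each along x and y, in metres).

#' Construct an APM session
#'
#' One arm position matching assessment: the robot moves the affected arm to
#' 9 targets laid out on a 20 cm x 20 cm square (8 outer targets around a
#' centre target), once per block over 6 blocks, giving 54 trials. The
#' participant mirror-matches each position with the opposite arm, so matched
#' positions live in the contralateral workspace and are reflected about the
#' body midline before comparison.
#'
#' @param trials data.frame with columns `block` (1-6), `target` (1-9),
#'   `robot_x`, `robot_y`, `match_x`, `match_y` (metres).
#' @param participant participant identifier.
#' @param arm_assessed `"left"` or `"right"`: the robot-moved (affected) arm.
#' @param timepoint weeks post-stroke (NA for controls).
#' @param midline_x x-coordinate of the mirror axis in metres.
#' @return an object of class `apm_session`.
#' @export
apm_session <- function(trials, participant = NA_character_,
                        arm_assessed = c("left", "right"),
                        timepoint = NA_real_, midline_x = 0) {
  arm_assessed <- match.arg(arm_assessed)
  trials <- as.data.frame(trials)
  validate_apm_trials(trials, full = TRUE)
  structure(
    list(participant = participant, arm_assessed = arm_assessed,
         timepoint = timepoint, trials = trials, midline_x = midline_x),
    class = "apm_session"
  )
}

validate_apm_trials <- function(trials, full = TRUE) {
  need <- c("block", "target", "robot_x", "robot_y", "match_x", "match_y")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols)) {
    stop("trial table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  num <- trials[, c("robot_x", "robot_y", "match_x", "match_y")]
  if (!all(vapply(num, function(v) all(is.finite(v)), logical(1)))) {
    stop("trial coordinates must be finite", call. = FALSE)
  }
  if (!all(trials$block %in% 1:6) || !all(trials$target %in% 1:9)) {
    stop("blocks must lie in 1..6 and targets in 1..9", call. = FALSE)
  }
  if (full) {
    if (nrow(trials) != 54L) {
      stop("an APM session has exactly 54 trials (9 targets x 6 blocks), got ",
           nrow(trials), call. = FALSE)
    }
    tab <- table(trials$block, trials$target)
    if (!all(tab == 1L)) {
      stop("each target must appear exactly once per block", call. = FALSE)
    }
  }
  invisible(trials)
}

#' @export
print.apm_session <- function(x, ...) {
  cat(sprintf("<apm_session> participant %s, %s arm, %s trials, midline x = %g m\n",
              x$participant, x$arm_assessed, nrow(x$trials), x$midline_x))
  invisible(x)
}

#' Reflect a matched hand position across the body midline
#'
#' The participant matches with the opposite arm; reflecting the matched
#' position about the vertical midline brings it into the robot-moved arm's
#' workspace. The y-coordinate is unchanged. The map is an involution.
#'
#' @param match_pos numeric vector `c(x, y)` or a two-column matrix (metres).
#' @param midline_x mirror-axis x-coordinate (metres).
#' @return reflected coordinates, same shape as `match_pos`.
#' @export
mirror_match <- function(match_pos, midline_x = 0) {
  if (is.matrix(match_pos)) {
    stopifnot(ncol(match_pos) == 2, all(is.finite(match_pos)))
    out <- match_pos
    out[, 1] <- 2 * midline_x - match_pos[, 1]
    return(out)
  }
  stopifnot(length(match_pos) == 2, all(is.finite(match_pos)))
  c(2 * midline_x - match_pos[1], match_pos[2])
}

as_trials <- function(x) {
  if (inherits(x, "apm_session")) {
    list(trials = x$trials, midline_x = x$midline_x)
  } else {
    list(trials = validate_apm_trials(as.data.frame(x), full = FALSE),
         midline_x = attr(x, "midline_x") %||% 0)
  }
}

trial_errors <- function(x, midline_x = NULL) {
  parts <- as_trials(x)
  tr <- parts$trials
  mid <- midline_x %||% parts$midline_x
  mir_x <- 2 * mid - tr$match_x
  list(trials = tr,
       mir_x = mir_x, mir_y = tr$match_y,
       err_x = mir_x - tr$robot_x, err_y = tr$match_y - tr$robot_y)
}

#' Absolute Error parameter
#'
#' Mean absolute distance, per axis, between the mirrored matched position
#' and the robot position over all trials. Quantifies overall matching error;
#' 0 is perfect.
#'
#' @param x an `apm_session` or a trial data.frame.
#' @param midline_x mirror axis override (defaults to the session's).
#' @return named numeric `c(x = , y = )`, metres.
#' @export
absolute_error <- function(x, midline_x = NULL) {
  e <- trial_errors(x, midline_x)
  if (nrow(e$trials) < 1L) stop("no trials", call. = FALSE)
  c(x = mean(abs(e$err_x)), y = mean(abs(e$err_y)))
}

#' Shift parameter
#'
#' Mean signed difference (mirrored match minus robot) per axis: a systematic
#' displacement of the perceived workspace. Signed, 0 is unbiased.
#'
#' @inheritParams absolute_error
#' @return named numeric `c(x = , y = )`, metres (signed).
#' @export
position_shift <- function(x, midline_x = NULL) {
  e <- trial_errors(x, midline_x)
  c(x = mean(e$err_x), y = mean(e$err_y))
}

#' Variability parameter
#'
#' Trial-to-trial consistency: per axis, the sample standard deviation of the
#' mirrored matched positions across the repetitions of each target, averaged
#' over the targets.
#'
#' @inheritParams absolute_error
#' @return named numeric `c(x = , y = )`, metres.
#' @export
variability <- function(x, midline_x = NULL) {
  e <- trial_errors(x, midline_x)
  reps <- table(e$trials$target)
  if (any(reps < 2L)) {
    stop("variability needs >= 2 repetitions of every target", call. = FALSE)
  }
  sd_x <- tapply(e$mir_x, e$trials$target, sd)
  sd_y <- tapply(e$mir_y, e$trials$target, sd)
  c(x = mean(sd_x), y = mean(sd_y))
}

#' Contraction/Expansion parameter
#'
#' Perceived size of the matched workspace relative to the true one: per
#' axis, the range of the per-target mean mirrored matched positions across
#' the 8 outer targets divided by the range of the corresponding robot target
#' positions. 1 is veridical; values below 1 indicate contraction (a
#' shrunken percept), above 1 expansion.
#'
#' The centre target is identified as the target whose mean robot position is
#' closest to the centroid of all target positions and is excluded from the
#' ranges.
#'
#' @inheritParams absolute_error
#' @return named numeric `c(x = , y = )`, dimensionless ratios.
#' @export
contraction_expansion <- function(x, midline_x = NULL) {
  e <- trial_errors(x, midline_x)
  tr <- e$trials
  m_rx <- tapply(tr$robot_x, tr$target, mean)
  m_ry <- tapply(tr$robot_y, tr$target, mean)
  m_mx <- tapply(e$mir_x, tr$target, mean)
  m_my <- tapply(e$mir_y, tr$target, mean)
  d2 <- (m_rx - mean(m_rx))^2 + (m_ry - mean(m_ry))^2
  outer_t <- seq_along(m_rx)[-which.min(d2)]
  rng <- function(v) max(v) - min(v)
  den_x <- rng(m_rx[outer_t]); den_y <- rng(m_ry[outer_t])
  if (den_x <= 0 || den_y <= 0) {
    stop("degenerate robot target range; contraction/expansion undefined",
         call. = FALSE)
  }
  c(x = rng(m_mx[outer_t]) / den_x, y = rng(m_my[outer_t]) / den_y)
}

#' All eight APM parameters for one session
#'
#' @inheritParams absolute_error
#' @return named numeric vector with elements `abs_error_x`, `abs_error_y`,
#'   `variability_x`, `variability_y`, `contract_expand_x`,
#'   `contract_expand_y`, `shift_x`, `shift_y`.
#' @export
apm_parameters <- function(x, midline_x = NULL) {
  ae <- absolute_error(x, midline_x)
  vr <- variability(x, midline_x)
  ce <- contraction_expansion(x, midline_x)
  sh <- position_shift(x, midline_x)
  c(abs_error_x = unname(ae["x"]), abs_error_y = unname(ae["y"]),
    variability_x = unname(vr["x"]), variability_y = unname(vr["y"]),
    contract_expand_x = unname(ce["x"]), contract_expand_y = unname(ce["y"]),
    shift_x = unname(sh["x"]), shift_y = unname(sh["y"]))
}

#' Names of the eight APM parameters, in canonical order
#' @export
apm_parameter_names <- function() {
  c("abs_error_x", "abs_error_y", "variability_x", "variability_y",
    "contract_expand_x", "contract_expand_y", "shift_x", "shift_y")
}

#' Compute APM parameters for every session in a trial table
#'
#' Vectorised equivalent of [apm_parameters()] for cohort-scale trial tables
#' (the CSV dialect written by the synthetic-cohort generator: one row per
#' trial). Sessions are identified by the grouping columns.
#'
#' @param trials data.frame/data.table with the trial columns plus grouping
#'   columns and optionally `midline_x` (assumed 0 when absent).
#' @param by character vector of grouping columns identifying a session,
#'   e.g. `c("participant", "session")`.
#' @return data.table with one row per session: grouping columns plus the
#'   eight parameter columns.
#' @export
session_parameters <- function(trials, by = c("participant", "session")) {
  dt <- data.table::as.data.table(trials)
  if (!all(by %in% names(dt))) stop("missing grouping columns", call. = FALSE)
  if (!"midline_x" %in% names(dt)) dt[, midline_x := 0]
  validate_apm_trials(dt, full = FALSE)
  n_tr <- dt[, .N, by = by]
  if (any(n_tr$N != 54L)) {
    stop("every session must have exactly 54 trials", call. = FALSE)
  }
  dt[, `:=`(mir_x = 2 * midline_x - match_x, mir_y = match_y)]
  dt[, `:=`(err_x = mir_x - robot_x, err_y = mir_y - robot_y)]

  glob <- dt[, .(abs_error_x = mean(abs(err_x)), abs_error_y = mean(abs(err_y)),
                 shift_x = mean(err_x), shift_y = mean(err_y)), by = by]

  per_tgt <- dt[, .(sd_x = sd(mir_x), sd_y = sd(mir_y),
                    m_rx = mean(robot_x), m_ry = mean(robot_y),
                    m_mx = mean(mir_x), m_my = mean(mir_y)),
                by = c(by, "target")]
  vari <- per_tgt[, .(variability_x = mean(sd_x), variability_y = mean(sd_y)),
                  by = by]
  ce <- per_tgt[, {
    d2 <- (m_rx - mean(m_rx))^2 + (m_ry - mean(m_ry))^2
    keep <- seq_len(.N)[-which.min(d2)]
    den_x <- diff(range(m_rx[keep])); den_y <- diff(range(m_ry[keep]))
    if (den_x <= 0 || den_y <= 0) {
      stop("degenerate robot target range", call. = FALSE)
    }
    .(contract_expand_x = diff(range(m_mx[keep])) / den_x,
      contract_expand_y = diff(range(m_my[keep])) / den_y)
  }, by = by]

  out <- Reduce(function(a, b) merge(a, b, by = by, sort = FALSE),
                list(glob, vari, ce))
  data.table::setcolorder(out, c(by, apm_parameter_names()))
  out[]
}
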