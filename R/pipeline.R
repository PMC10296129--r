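# End-to-end orchestration: simulate -> fit normative model -> score ->
# lesion features -> univariate stats -> predictive models, with CSV/NIfTI/
# JSON interchange files and a hash manifest.

#' Extract one session as an `apm_session` object
#'
#' @param trials cohort trial table.
#' @param participant participant id.
#' @param session session index (control cohorts) or NULL.
#' @param timepoint timepoint in weeks (stroke cohorts) or NULL.
#' @return an [apm_session()].
#' @export
extract_session <- function(trials, participant, session = NULL,
                            timepoint = NULL) {
  dt <- data.table::as.data.table(trials)
  sel <- dt$participant == participant
  if (!is.null(session)) sel <- sel & dt$session == session
  if (!is.null(timepoint)) sel <- sel & dt$timepoint == timepoint
  tr <- dt[sel]
  if (nrow(tr) == 0L) stop("no matching trials", call. = FALSE)
  arm <- if ("arm_assessed" %in% names(tr)) tr$arm_assessed[1] else "right"
  apm_session(as.data.frame(tr), participant = participant,
              arm_assessed = arm,
              timepoint = if (is.null(timepoint)) NA_real_ else timepoint,
              midline_x = if ("midline_x" %in% names(tr)) tr$midline_x[1] else 0)
}

#' Build the per-participant feature table
#'
#' Two-week features (demographics, clinical scores, lesion volume, VLSM
#' mean Z, the eight robotic parameter z-scores) plus the six-month binary
#' impairment label derived from the six-month Task Score. Sex is encoded
#' male = 1, the affected arm left = 1 (the encoding is recorded in the
#' attributes).
#'
#' @param cohort a `stroke_cohort`.
#' @param model a fitted `normative_model`.
#' @param overlap_fraction VLSM minimum-overlap fraction (default 0.05).
#' @param vlsm_test voxel-wise test, `"t"` or `"ranksum"`.
#' @param leave_one_out if TRUE, each participant's VLSM mean Z is computed
#'   from a map fitted without that participant (slower; avoids scoring a
#'   lesion against a map it helped build). Default FALSE, matching the
#'   single-map design.
#' @return data.frame with one row per participant, attribute `"vlsm_map"`
#'   (the full-cohort map) and `"task_scores"`.
#' @export
build_feature_table <- function(cohort, model, overlap_fraction = 0.05,
                                vlsm_test = "t", leave_one_out = FALSE) {
  stopifnot(inherits(cohort, "stroke_cohort"),
            inherits(model, "normative_model"))
  demo <- cohort$demographics
  tr <- data.table::as.data.table(cohort$trials)
  s2 <- score_sessions(tr[timepoint == 2], demo, model, by = "participant")
  s6 <- score_sessions(tr[timepoint == 26], demo, model, by = "participant")
  ord <- match(demo$participant, s2$participant)
  s2 <- s2[ord]
  s6 <- s6[match(demo$participant, s6$participant)]

  masks <- cohort$lesions[demo$participant]
  map <- vlsm_zmap(masks, s2$task_score, fraction = overlap_fraction,
                   test = vlsm_test)
  mz <- if (leave_one_out) {
    vapply(seq_along(masks), function(i) {
      m_i <- vlsm_zmap(masks[-i], s2$task_score[-i],
                       fraction = overlap_fraction, test = vlsm_test)
      as.numeric(vlsm_mean_z(masks[[i]], m_i))
    }, numeric(1))
  } else {
    vlsm_mean_z_all(masks, map)
  }

  clin <- cohort$clinical[match(demo$participant, cohort$clinical$participant), ]
  out <- data.frame(
    participant = demo$participant,
    age = demo$age,
    sex = as.integer(demo$sex == "male"),
    affected_arm = as.integer(demo$affected_arm == "left"),
    tlt = clin$tlt, bit = clin$bit, fim = clin$fim,
    vlsm_mean_z = mz,
    lesion_volume = vapply(masks, lesion_volume, numeric(1)),
    as.data.frame(s2)[apm_parameter_names()],
    task_score_2wk = s2$task_score,
    task_score_6mo = s6$task_score,
    impaired_6mo = as.integer(s6$impaired),
    row.names = NULL
  )
  attr(out, "vlsm_map") <- map
  attr(out, "encoding") <- c(sex = "male=1", affected_arm = "left=1")
  out
}

pipeline_stage <- function(name, verbose, expr) {
  if (verbose) message("[", name, "] ...")
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> fit-normative -> score -> lesion-features -> stats
#' -> predict, writing every stage's outputs and a manifest with file
#' hashes to `out_dir`. All randomness flows from `config$seed` (plus the
#' fold seed), so rerunning with an identical configuration reproduces
#' identical outputs.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @param k cross-validation folds (default 10).
#' @param overlap_fraction VLSM minimum-overlap fraction.
#' @param vlsm_test voxel-wise test, `"t"` or `"ranksum"`.
#' @param verbose log stage progress (default TRUE).
#' @return (invisibly) a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, k = 10L, overlap_fraction = 0.05,
                         vlsm_test = "t", verbose = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  controls <- pipeline_stage("simulate-controls", verbose, {
    co <- generate_control_cohort(config)
    write_cohort_csv(co, file.path(out_dir, "controls"))
    co
  })

  model <- pipeline_stage("fit-norms", verbose, {
    m <- fit_normative_model(control_assessments(controls))
    write_normative_model(m, file.path(out_dir, "normative_model.json"))
    m
  })

  stroke <- pipeline_stage("simulate-stroke", verbose, {
    co <- generate_stroke_cohort(config, model)
    write_cohort_csv(co, file.path(out_dir, "stroke"))
    lesion_dir <- file.path(out_dir, "stroke", "lesions")
    dir.create(lesion_dir, showWarnings = FALSE)
    for (id in names(co$lesions)) {
      write_lesion_mask(co$lesions[[id]],
                        file.path(lesion_dir, paste0(id, ".nii.gz")))
    }
    co
  })

  features <- pipeline_stage("score+lesion-features", verbose, {
    ft <- build_feature_table(stroke, model,
                              overlap_fraction = overlap_fraction,
                              vlsm_test = vlsm_test)
    write.csv(ft, file.path(out_dir, "features.csv"), row.names = FALSE)
    write_vlsm_map(attr(ft, "vlsm_map"), file.path(out_dir, "vlsm_zmap.nii.gz"))
    ft
  })

  stats <- pipeline_stage("stats", verbose, {
    assoc <- assoc_battery(
      data.frame(features,
                 sex = ifelse(features$sex == 1, "male", "female"),
                 affected_arm = ifelse(features$affected_arm == 1,
                                       "left", "right")),
      features$task_score_6mo)
    grp <- group_battery(features, features$impaired_6mo == 1)
    write.csv(assoc, file.path(out_dir, "stats_associations.csv"),
              row.names = FALSE)
    write.csv(grp, file.path(out_dir, "stats_groups.csv"), row.names = FALSE)
    list(associations = assoc, groups = grp)
  })

  models <- pipeline_stage("predict", verbose, {
    res <- evaluate_all_models(features, k = k, seed = config$seed)
    tab <- model_results_table(res)
    write.csv(tab, file.path(out_dir, "models.csv"), row.names = FALSE)
    roc <- do.call(rbind, lapply(res, function(r) {
      cbind(model = r$name,
            roc_points(r$predictions$prob, r$predictions$label))
    }))
    write.csv(roc, file.path(out_dir, "roc_points.csv"), row.names = FALSE)
    preds <- lapply(res, function(r) {
      list(predictions = r$predictions, coefficients = as.list(r$coefficients))
    })
    jsonlite::write_json(preds, file.path(out_dir, "predictions.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    res
  })

  manifest <- pipeline_stage("manifest", verbose, {
    files <- sort(list.files(out_dir, recursive = TRUE, full.names = FALSE))
    files <- setdiff(files, "manifest.json")
    hashes <- tools::md5sum(file.path(out_dir, files))
    man <- list(
      files = stats::setNames(as.list(unname(hashes)), files),
      counts = list(
        n_controls = nrow(controls$demographics),
        n_control_assessments = nrow(controls$trials) / 54L,
        n_stroke = nrow(stroke$demographics),
        n_impaired_6mo = sum(features$impaired_6mo),
        voxels_tested = sum(attr(features, "vlsm_map")$tested),
        k_folds = k
      ),
      seed = config$seed
    )
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    man
  })

  if (verbose) {
    message(sprintf("[done] %d controls, %d stroke (%d impaired at 6mo), %d voxels tested",
                    manifest$counts$n_controls, manifest$counts$n_stroke,
                    manifest$counts$n_impaired_6mo,
                    manifest$counts$voxels_tested))
  }
  invisible(list(controls = controls, model = model, stroke = stroke,
                 features = features, stats = stats, models = models,
                 manifest = manifest))
}
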