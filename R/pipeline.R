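# Orchestration: simulate -> extract -> model -> evaluate, with on-disk
# CSV/WAV/JSON intermediates so each stage is idempotent and resumable.

#' Pipeline run configuration
#'
#' @param out_dir output directory (created if missing); intermediates are
#'   `audio/`, `participants.csv`, `truth_synthetic.csv`, `features.csv`,
#'   `exclusions.csv`, `predictions.csv`, `report.json`.
#' @param seed master seed stamped into every artifact.
#' @param fs sampling rate for synthesized audio (Hz).
#' @param mic a [microphone_model()].
#' @param filter_band,filter_order band-pass settings (Hz, even order).
#' @param segment_duration peak-segment length (s).
#' @param cps a [cps_params()] used both to synthesize target SPLs and to
#'   compute CPS at extraction (on real data, obtain one via
#'   [fit_cps_params()]).
#' @param lms an [lms_config()].
#' @param cohort a [cohort_params()] for the simulate stage (its own seed
#'   is overridden by `seed`).
#' @param hyper an [mlp_hyper()].
#' @param H_grid hidden-unit grid for nested CV.
#' @param feature_sets variants to run (`"CPS+VC_LMS"`, `"SPL+VC_LMS"`).
#' @param n_trials,trial_jitter_db,contamination synthesis settings
#'   (see [synthesize_cough_waveform()]).
#' @param full_scale_voltage PCM16 full-scale voltage for WAV files.
#' @return an object of class `coughvc_run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, fs = 20000,
                       mic = microphone_model(),
                       filter_band = c(140, 2000), filter_order = 4,
                       segment_duration = 5.0,
                       cps = cps_params(), lms = lms_config(),
                       cohort = cohort_params(lms = lms, cps = cps),
                       hyper = mlp_hyper(),
                       H_grid = 1:3,
                       feature_sets = c("CPS+VC_LMS", "SPL+VC_LMS"),
                       n_trials = 3, trial_jitter_db = 1,
                       contamination = contamination_spec(),
                       full_scale_voltage = 1.0) {
  cohort$seed <- seed
  structure(list(out_dir = out_dir, seed = as.integer(seed), fs = fs,
                 mic = mic, filter_band = filter_band,
                 filter_order = filter_order,
                 segment_duration = segment_duration, cps = cps, lms = lms,
                 cohort = cohort, hyper = hyper, H_grid = H_grid,
                 feature_sets = feature_sets, n_trials = n_trials,
                 trial_jitter_db = trial_jitter_db,
                 contamination = contamination,
                 full_scale_voltage = full_scale_voltage),
            class = "coughvc_run_config")
}

log_stage <- function(stage, event, participant = NA) {
  message(sprintf("[coughvc] stage=%s participant=%s event=%s",
                  stage, as.character(participant), event))
}

#' Simulate a cohort and its cough recordings to disk
#'
#' Writes `participants.csv` (the fields a real study would provide),
#' `truth_synthetic.csv` (generator ground truth, for recovery tests) and
#' one WAV per trial under `audio/` named `<participant_id>_trial<k>.wav`.
#'
#' @param cfg a [run_config()].
#' @return the cohort data.frame, invisibly.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "coughvc_run_config"))
  dir.create(file.path(cfg$out_dir, "audio"), recursive = TRUE,
             showWarnings = FALSE)
  cohort <- generate_cohort(cfg$cohort)
  write.csv(cohort[, c("participant_id", "group", "sex", "age", "height",
                       "weight", "measured_vc")],
            file.path(cfg$out_dir, "participants.csv"), row.names = FALSE)
  write.csv(cohort, file.path(cfg$out_dir, "truth_synthetic.csv"),
            row.names = FALSE)
  for (i in seq_len(nrow(cohort))) {
    trials <- synthesize_cough_waveform(
      cohort[i, ], mic = cfg$mic, fs = cfg$fs, n_trials = cfg$n_trials,
      trial_jitter_db = cfg$trial_jitter_db,
      contamination = cfg$contamination,
      seed = stream_seed(cfg$seed, "waveforms", i))
    for (k in seq_along(trials)) {
      write_wav(trials[[k]]$samples, cfg$fs,
                file.path(cfg$out_dir, "audio",
                          sprintf("%s_trial%d.wav",
                                  cohort$participant_id[i], k)),
                format = "pcm16",
                full_scale_voltage = cfg$full_scale_voltage)
    }
  }
  log_stage("simulate", sprintf("wrote %d participants", nrow(cohort)))
  invisible(cohort)
}

#' Extract per-participant features from recordings on disk
#'
#' For each participant with at least three trials: session SPL through
#' the filter/segment/SPL chain, CPS from SPL and age, the LMS reference
#' VC and the LLN. Participants with fewer than three trials are excluded
#' with a reason (mirroring failed-manoeuvre exclusion) and the run
#' continues.
#'
#' @param cfg a [run_config()].
#' @return list with `features` and `exclusions` data.frames; both are
#'   also written as CSV under `out_dir`.
#' @export
run_extract <- function(cfg) {
  stopifnot(inherits(cfg, "coughvc_run_config"))
  participants <- read.csv(file.path(cfg$out_dir, "participants.csv"),
                           stringsAsFactors = FALSE)
  rows <- list(); excl <- list()
  for (i in seq_len(nrow(participants))) {
    p <- participants[i, ]
    paths <- Sys.glob(file.path(cfg$out_dir, "audio",
                                paste0(p$participant_id, "_trial*.wav")))
    if (length(paths) < 3) {
      excl[[length(excl) + 1]] <- data.frame(
        participant_id = p$participant_id,
        reason = sprintf("only %d acceptable trials (3 required)",
                         length(paths)), stringsAsFactors = FALSE)
      log_stage("extract", "excluded: <3 trials", p$participant_id)
      next
    }
    trials <- lapply(seq_along(paths), function(k) {
      wv <- read_wav(paths[k], full_scale_voltage = cfg$full_scale_voltage)
      waveform(wv$samples, wv$fs, participant_id = p$participant_id,
               trial_index = k)
    })
    spl <- session_spl(trials, cfg$mic, low = cfg$filter_band[1],
                       high = cfg$filter_band[2], order = cfg$filter_order,
                       segment_duration = cfg$segment_duration)
    rows[[length(rows) + 1]] <- data.frame(
      participant_id = p$participant_id, group = p$group, sex = p$sex,
      age = p$age, height = p$height,
      measured_vc = p$measured_vc,
      spl = spl$session_spl_db,
      cps = compute_cps(spl$session_spl_db, p$age, cfg$cps),
      vc_lms = vc_lms(p$sex, p$height, p$age, cfg$lms),
      lln = lln(p$sex, p$height, p$age, cfg$lms),
      stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, rows)
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(participant_id = character(), reason = character())
  write.csv(features, file.path(cfg$out_dir, "features.csv"),
            row.names = FALSE)
  write.csv(exclusions, file.path(cfg$out_dir, "exclusions.csv"),
            row.names = FALSE)
  log_stage("extract", sprintf("%d feature rows, %d exclusions",
                               nrow(features), nrow(exclusions)))
  list(features = features, exclusions = exclusions)
}

#' Nested-CV predictions for the configured feature-set variants
#'
#' Runs nested leave-one-out cross-validation for each configured variant
#' (`NNVC_CPS` from `[CPS, VC_LMS]`, `NNVC_SPL` from `[SPL, VC_LMS]`) and
#' carries the `VC_LMS` baseline column through.
#'
#' @param cfg a [run_config()].
#' @param features features data.frame (from [run_extract()]); read from
#'   disk when `NULL`.
#' @return predictions data.frame (also written to `predictions.csv`).
#' @export
run_models <- function(cfg, features = NULL) {
  stopifnot(inherits(cfg, "coughvc_run_config"))
  if (is.null(features))
    features <- read.csv(file.path(cfg$out_dir, "features.csv"),
                         stringsAsFactors = FALSE)
  if (nrow(features) < 8) stop("need at least 8 participants to model")
  preds <- features[, c("participant_id", "group", "measured_vc", "vc_lms",
                        "lln")]
  names(preds)[names(preds) == "vc_lms"] <- "VC_LMS"
  for (fsname in cfg$feature_sets) {
    feat_col <- if (fsname == "CPS+VC_LMS") "cps" else "spl"
    X <- as.matrix(features[, c(feat_col, "vc_lms")])
    cv <- nested_cv(X, features$measured_vc, H_grid = cfg$H_grid,
                    seed = stream_seed(cfg$seed, fsname),
                    hyper = cfg$hyper, feature_set = fsname)
    col <- if (fsname == "CPS+VC_LMS") "NNVC_CPS" else "NNVC_SPL"
    preds[[col]] <- cv$predictions
    log_stage("model", sprintf("%s: RMSE %.3f L", col, cv$rmse))
  }
  write.csv(preds, file.path(cfg$out_dir, "predictions.csv"),
            row.names = FALSE)
  preds
}

method_cols <- function(preds)
  intersect(c("VC_LMS", "NNVC_SPL", "NNVC_CPS"), names(preds))

eval_block <- function(preds) {
  methods <- method_cols(preds)
  meas <- preds$measured_vc
  se <- squared_error_table(meas, as.list(preds[methods]))
  block <- list(
    n = nrow(preds),
    squared_error = se$summary,
    spearman = lapply(preds[methods], function(est) {
      s <- spearman(meas, est); s[c("rho", "p")]
    }),
    bland_altman = lapply(preds[methods], function(est) {
      ba <- bland_altman(meas, est)
      ba[c("mean_diff", "sd_diff", "limits", "fixed_bias_t",
           "proportional_bias_r", "orientation")]
    }))
  if (length(methods) >= 3) {
    semat <- sapply(methods, function(m) (preds[[m]] - meas)^2)
    fr <- friedman(semat)
    pairs <- utils::combn(methods, 2, simplify = FALSE)
    praw <- vapply(pairs, function(pr)
      wilcoxon_signed_rank((preds[[pr[1]]] - meas)^2,
                           (preds[[pr[2]]] - meas)^2)$p, numeric(1))
    block$friedman <- fr[c("statistic", "p", "df")]
    block$pairwise_holm <- data.frame(
      comparison = vapply(pairs, paste, character(1), collapse = " vs "),
      p_raw = praw, p_holm = holm_adjust(praw))
  }
  block
}

#' Evaluation report for a set of predictions
#'
#' Emits the full statistics battery overall and per generation, the
#' between-generation squared-error contrasts (unpaired by default: the
#' generations are independent groups), and the LLN screening section
#' (confusion rates, ROC/AUC per neural variant, DeLong comparison).
#' Written as `report.json` plus figure-data CSVs (`fig_scatter.csv`,
#' `fig_bland_altman.csv`, `fig_squared_error.csv`, `fig_roc.csv`).
#'
#' @param cfg a [run_config()].
#' @param preds predictions data.frame (from [run_models()]); read from
#'   disk when `NULL`.
#' @return the report as a list, invisibly.
#' @export
run_report <- function(cfg, preds = NULL) {
  stopifnot(inherits(cfg, "coughvc_run_config"))
  if (is.null(preds))
    preds <- read.csv(file.path(cfg$out_dir, "predictions.csv"),
                      stringsAsFactors = FALSE)
  methods <- method_cols(preds)
  report <- list(
    metadata = list(package = "coughvc",
                    version = as.character(utils::packageVersion("coughvc")),
                    seed = cfg$seed,
                    timestamp = format(Sys.time(), tz = "UTC")),
    overall = eval_block(preds))
  for (g in unique(preds$group))
    report[[paste0("generation_", g)]] <- eval_block(preds[preds$group == g, ])
  if (length(unique(preds$group)) == 2) {
    gs <- unique(preds$group)
    report$between_generations <- lapply(stats::setNames(methods, methods),
      function(m) {
        se1 <- (preds[[m]] - preds$measured_vc)[preds$group == gs[1]]^2
        se2 <- (preds[[m]] - preds$measured_vc)[preds$group == gs[2]]^2
        mw <- mann_whitney(se1, se2)
        list(groups = gs, median_se = c(median(se1), median(se2)),
             statistic = mw$statistic, p = mw$p, test = "Mann-Whitney")
      })
  }
  nn <- intersect(c("NNVC_CPS", "NNVC_SPL"), methods)
  truth <- preds$measured_vc < preds$lln
  if (length(unique(truth)) < 2) {
    report$screening <- list(available = FALSE,
                             reason = "single-class labels at the LLN")
    log_stage("evaluate", "screening unavailable: single-class labels")
  } else {
    scr <- list(available = TRUE,
                score_convention = "score = LLN - estimate; positive = measured VC < LLN")
    for (m in nn) {
      conf <- screening_confusion(preds[[m]], preds$measured_vc, preds$lln)
      roc <- screening_roc(preds[[m]], preds$measured_vc, preds$lln)
      scr[[m]] <- list(auc = roc$auc, tpr = conf$tpr, fnr = conf$fnr,
                       fpr = conf$fpr, tnr = conf$tnr)
    }
    if (length(nn) == 2) {
      dl <- delong_test(preds$lln - preds$NNVC_CPS,
                        preds$lln - preds$NNVC_SPL, truth)
      scr$delong <- dl[c("auc_a", "auc_b", "auc_diff", "z", "p",
                         "degenerate")]
    }
    report$screening <- scr
  }
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE,
                       dataframe = "rows")
  # figure-data exports
  scat <- do.call(rbind, lapply(methods, function(m)
    data.frame(method = m, measured = preds$measured_vc,
               estimated = preds[[m]])))
  write.csv(scat, file.path(cfg$out_dir, "fig_scatter.csv"),
            row.names = FALSE)
  ba <- do.call(rbind, lapply(methods, function(m)
    data.frame(method = m, mean = (preds$measured_vc + preds[[m]]) / 2,
               diff = preds$measured_vc - preds[[m]])))
  write.csv(ba, file.path(cfg$out_dir, "fig_bland_altman.csv"),
            row.names = FALSE)
  se <- squared_error_table(preds$measured_vc, as.list(preds[methods]))
  write.csv(se$errors, file.path(cfg$out_dir, "fig_squared_error.csv"),
            row.names = FALSE)
  if (isTRUE(report$screening$available)) {
    rocs <- do.call(rbind, lapply(nn, function(m) {
      r <- screening_roc(preds[[m]], preds$measured_vc, preds$lln)
      data.frame(method = m, threshold = r$thresholds, tpr = r$tpr,
                 fpr = r$fpr)
    }))
    write.csv(rocs, file.path(cfg$out_dir, "fig_roc.csv"),
              row.names = FALSE)
  }
  log_stage("evaluate", "report written")
  invisible(report)
}

#' Run the full pipeline
#'
#' `simulate -> extract -> model -> evaluate` under one configuration.
#'
#' @param cfg a [run_config()].
#' @return the report list, invisibly.
#' @export
run_all <- function(cfg) {
  run_simulate(cfg)
  ex <- run_extract(cfg)
  preds <- run_models(cfg, ex$features)
  run_report(cfg, preds)
}
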