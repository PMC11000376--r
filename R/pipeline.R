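## Stage-wise pipeline orchestration with a declarative config, provenance
## sidecars and content-hash caching. The thin command-line wrapper lives at
## inst/cli/dynrad.R; these functions are the real interface.

PIPELINE_STAGES <- c("simulate", "preprocess", "static", "dynamic", "model", "evaluate")

pipeline_schema <- function() {
  list(
    cohort = c("n_patients", "prevalence", "volume_shape", "lesion_radius_range",
               "noise_sigma", "noise_model", "background"),
    preprocess = c("target_spacing", "region", "n_levels", "time_grid",
                   "normalize_first"),
    features = c("wavelet", "racr_denominator", "corrected_curvature"),
    modeling = c("alpha", "cv_folds", "cv_repeats", "icc_threshold",
                 "train_fraction"),
    seed = NULL)
}

#' Validate a pipeline configuration
#'
#' Checks a (possibly nested) config list against the published schema;
#' unknown sections or keys are rejected with a "dynrad_schema_error".
#'
#' @param config named list, or path to a JSON/YAML config file.
#' @return the validated config list, with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  schema <- pipeline_schema()
  bad_sec <- setdiff(names(config), names(schema))
  if (length(bad_sec) > 0)
    stop(errorCondition(paste("unknown config section:", paste(bad_sec, collapse = ", ")),
                        class = c("dynrad_schema_error", "error")))
  for (sec in intersect(names(config), names(schema))) {
    if (sec == "seed") next
    bad <- setdiff(names(config[[sec]]), schema[[sec]])
    if (length(bad) > 0)
      stop(errorCondition(paste0("unknown config key in [", sec, "]: ",
                                 paste(bad, collapse = ", ")),
                          class = c("dynrad_schema_error", "error")))
  }
  defaults <- list(
    cohort = list(n_patients = 8, prevalence = 0.34, volume_shape = c(24, 24, 24),
                  lesion_radius_range = c(4, 6), noise_sigma = 5,
                  noise_model = "gaussian", background = 80),
    preprocess = list(target_spacing = c(1, 1, 1), region = "whole-volume",
                      n_levels = 64, time_grid = 1:4, normalize_first = FALSE),
    features = list(wavelet = "coif1", racr_denominator = "four-phase-mean",
                    corrected_curvature = FALSE),
    modeling = list(alpha = 0.05, cv_folds = 5, cv_repeats = 5,
                    icc_threshold = 0.8, train_fraction = 0.7),
    seed = 1L)
  out <- defaults
  for (sec in names(config)) {
    if (sec == "seed") { out$seed <- as.integer(config$seed); next }
    out[[sec]][names(config[[sec]])] <- config[[sec]]
  }
  out
}

config_hash <- function(config, extra = NULL) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(list(config = config, extra = extra), tmp,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

stage_cached <- function(out_dir, stage, hash, outputs) {
  prov <- file.path(out_dir, paste0(stage, "_provenance.json"))
  if (!file.exists(prov)) return(FALSE)
  rec <- jsonlite::read_json(prov)
  identical(rec$hash, as.character(hash)) && all(file.exists(file.path(out_dir, outputs)))
}

write_provenance <- function(out_dir, stage, hash, config) {
  jsonlite::write_json(
    list(stage = stage, hash = hash, seed = config$seed,
         package_version = as.character(utils::packageVersion("dynrad")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         config = config),
    file.path(out_dir, paste0(stage, "_provenance.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

read_cohort_features <- function(out_dir, file) {
  path <- file.path(out_dir, file)
  if (!file.exists(path))
    stop(errorCondition(paste("missing upstream artifact:", path),
                        class = c("dynrad_missing_artifact", "error")))
  utils::read.csv(path, check.names = FALSE)
}

#' Run one pipeline stage
#'
#' Stages: \code{simulate} (write a synthetic cohort), \code{preprocess}
#' (resample + normalise each stack, cache as NIfTI + sidecar),
#' \code{static} (484-feature vectors per patient and phase),
#' \code{dynamic} (9680-feature dynamic vectors), \code{model} (fit the SR,
#' DR and DSR signatures on the training split) and \code{evaluate}
#' (evaluation reports on the held-out split). Re-running a stage with an
#' unchanged config and inputs is skipped ("cached"). Each stage writes its
#' artifacts plus a provenance JSON into \code{out_dir}.
#'
#' @param stage one of the six stage names.
#' @param config config list or path (see \code{\link{validate_config}}).
#' @param out_dir run directory.
#' @param quiet suppress progress messages.
#' @return invisibly, a list of the stage's artifact paths.
#' @export
run_stage <- function(stage, config, out_dir, quiet = FALSE) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  hash <- config_hash(config[c("cohort", "preprocess", "features", "seed")])

  manifest_path <- file.path(out_dir, "manifest.csv")

  if (stage == "simulate") {
    outs <- "manifest.csv"
    if (stage_cached(out_dir, stage, hash, outs)) { say("simulate: cached"); return(invisible(outs)) }
    cc <- config$cohort
    cfg <- synthetic_cohort_config(
      n_patients = cc$n_patients, prevalence = cc$prevalence,
      volume_shape = cc$volume_shape, lesion_radius_range = cc$lesion_radius_range,
      noise_sigma = cc$noise_sigma, noise_model = cc$noise_model,
      background = cc$background, seed = config$seed)
    coh <- generate_cohort(cfg)
    paths <- lapply(seq_along(coh$stacks), function(i)
      save_phase_stack(coh$stacks[[i]], file.path(out_dir, "images"),
                       coh$manifest$patient_id[i]))
    man <- coh$manifest
    for (ph in PHASE_NAMES) {
      man[[paste0(ph, "_volume")]] <- file.path("images", paste0(man$patient_id, "_", ph, ".nii.gz"))
      man[[paste0(ph, "_mask")]] <- file.path("images", paste0(man$patient_id, "_", ph, "_mask.nii.gz"))
    }
    utils::write.csv(man, manifest_path, row.names = FALSE)
    write_provenance(out_dir, stage, hash, config)
    say("simulate: wrote ", nrow(man), " patients")
    return(invisible(outs))
  }

  if (!file.exists(manifest_path))
    stop(errorCondition("missing upstream artifact: manifest.csv (run simulate first or provide one)",
                        class = c("dynrad_missing_artifact", "error")))
  man <- utils::read.csv(manifest_path)

  load_patient <- function(i, dir = out_dir) {
    load_phase_stack(file.path(dir, unlist(man[i, paste0(PHASE_NAMES, "_volume")])),
                     file.path(dir, unlist(man[i, paste0(PHASE_NAMES, "_mask")])),
                     time_grid = config$preprocess$time_grid)
  }

  if (stage == "preprocess") {
    outs <- "preprocess_done.json"
    if (stage_cached(out_dir, stage, hash, outs)) { say("preprocess: cached"); return(invisible(outs)) }
    pdir <- file.path(out_dir, "preprocessed")
    for (i in seq_len(nrow(man))) {
      st <- preprocess_stack(load_patient(i),
                             target_spacing = config$preprocess$target_spacing,
                             region = config$preprocess$region,
                             normalize_first = config$preprocess$normalize_first)
      save_phase_stack(st, pdir, man$patient_id[i])
    }
    jsonlite::write_json(list(n = nrow(man)), file.path(out_dir, outs), auto_unbox = TRUE)
    write_provenance(out_dir, stage, hash, config)
    say("preprocess: ", nrow(man), " stacks")
    return(invisible(outs))
  }

  if (stage == "static") {
    outs <- "static_features.csv"
    if (stage_cached(out_dir, stage, hash, outs)) { say("static: cached"); return(invisible(outs)) }
    pdir <- file.path(out_dir, "preprocessed")
    if (!dir.exists(pdir))
      stop(errorCondition("missing upstream artifact: preprocessed/ (run preprocess first)",
                          class = c("dynrad_missing_artifact", "error")))
    rows <- lapply(seq_len(nrow(man)), function(i) {
      paths <- file.path(pdir, paste0(man$patient_id[i], "_", PHASE_NAMES, c(".nii.gz")))
      mpaths <- file.path(pdir, paste0(man$patient_id[i], "_", PHASE_NAMES, "_mask.nii.gz"))
      st <- load_phase_stack(paths, mpaths, time_grid = config$preprocess$time_grid)
      unlist(lapply(seq_len(4), function(k) {
        v <- extract_static_vector(st$volumes[[k]], st$masks[[k]],
                                   n_levels = config$preprocess$n_levels,
                                   wavelet = config$features$wavelet)
        stats::setNames(as.numeric(v), paste(PHASE_NAMES[k], names(v), sep = "__"))
      }))
    })
    df <- cbind(data.frame(patient_id = man$patient_id, label = man$label),
                as.data.frame(do.call(rbind, rows), check.names = FALSE))
    utils::write.csv(df, file.path(out_dir, outs), row.names = FALSE)
    write_provenance(out_dir, stage, hash, config)
    say("static: ", nrow(df), " x ", ncol(df) - 2, " features")
    return(invisible(outs))
  }

  if (stage == "dynamic") {
    df <- read_cohort_features(out_dir, "static_features.csv")
    outs <- "dynamic_features.csv"
    if (stage_cached(out_dir, stage, hash, outs)) { say("dynamic: cached"); return(invisible(outs)) }
    feat <- as.matrix(df[, -(1:2), drop = FALSE])
    phases <- lapply(PHASE_NAMES, function(ph) {
      cols <- grep(paste0("^", ph, "__"), colnames(feat))
      m <- feat[, cols, drop = FALSE]
      colnames(m) <- sub(paste0("^", ph, "__"), "", colnames(m))
      m
    })
    names(phases) <- PHASE_NAMES
    dyn <- dynamic_matrix_from_phases(phases, config$preprocess$time_grid,
                                      racr_denominator = config$features$racr_denominator,
                                      corrected_curvature = config$features$corrected_curvature)
    out <- cbind(df[, 1:2], as.data.frame(dyn, check.names = FALSE))
    utils::write.csv(out, file.path(out_dir, outs), row.names = FALSE)
    write_provenance(out_dir, stage, hash, config)
    say("dynamic: ", nrow(out), " x ", ncol(out) - 2, " features")
    return(invisible(outs))
  }

  if (stage %in% c("model", "evaluate")) {
    stat_df <- read_cohort_features(out_dir, "static_features.csv")
    dyn_df <- read_cohort_features(out_dir, "dynamic_features.csv")
    outs <- if (stage == "model") "models.json" else "evaluation.json"
    if (stage_cached(out_dir, stage, hash, outs)) { say(stage, ": cached"); return(invisible(outs)) }
    set.seed(config$seed)
    y <- stat_df$label
    idx <- sort(c(sample(which(y == 1), max(2, round(config$modeling$train_fraction * sum(y == 1)))),
                  sample(which(y == 0), max(2, round(config$modeling$train_fraction * sum(y == 0))))))
    split_phases <- function(df, rows) {
      feat <- as.matrix(df[rows, -(1:2), drop = FALSE])
      feat
    }
    tr <- list(static = split_phases(stat_df, idx), dynamic = split_phases(dyn_df, idx),
               labels = y[idx])
    va <- list(static = split_phases(stat_df, -idx), dynamic = split_phases(dyn_df, -idx),
               labels = y[-idx])
    md <- config$modeling
    sr <- build_signature(tr$static, tr$labels, "SR", md$alpha, md$cv_folds, md$cv_repeats)
    dr <- build_signature(tr$dynamic, tr$labels, "DR", md$alpha, md$cv_folds, md$cv_repeats)
    u <- unique(c(sr$features, dr$features))
    Xu_tr <- cbind(tr$static, tr$dynamic)[, u, drop = FALSE]
    Xu_va <- cbind(va$static, va$dynamic)[, u, drop = FALSE]
    dsr <- build_signature(Xu_tr, tr$labels, "DSR", md$alpha, md$cv_folds, md$cv_repeats)
    models <- list(SR = sr, DR = dr, DSR = dsr)
    if (stage == "model") {
      ser <- lapply(models, function(m)
        m[c("signature_type", "features", "impute_medians", "means", "sds",
            "coefficients", "intercept", "threshold")])
      jsonlite::write_json(ser, file.path(out_dir, outs), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      write_provenance(out_dir, stage, hash, config)
      say("model: SR/DR/DSR fitted (",
          paste(vapply(models, function(m) length(m$features), 1L), collapse = "/"),
          " features)")
      return(invisible(outs))
    }
    evs <- list(
      SR = evaluate(sr, va$static, va$labels),
      DR = evaluate(dr, va$dynamic, va$labels),
      DSR = evaluate(dsr, Xu_va, va$labels))
    rep_out <- lapply(evs, function(e)
      list(auc = e$auc, auc_ci = as.list(e$auc_ci), accuracy = e$accuracy,
           sensitivity = e$sensitivity, specificity = e$specificity))
    rep_out$p_sr_dr <- compare_auc(evs$SR$scores, evs$DR$scores, va$labels)$p_value
    rep_out$p_sr_dsr <- compare_auc(evs$SR$scores, evs$DSR$scores, va$labels)$p_value
    jsonlite::write_json(rep_out, file.path(out_dir, outs), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    for (s in names(evs)) {
      utils::write.csv(evs[[s]]$roc, file.path(out_dir, paste0("roc_", s, ".csv")), row.names = FALSE)
      utils::write.csv(evs[[s]]$pr, file.path(out_dir, paste0("pr_", s, ".csv")), row.names = FALSE)
    }
    write_provenance(out_dir, stage, hash, config)
    say("evaluate: validation AUC SR/DR/DSR = ",
        paste(vapply(evs, function(e) sprintf("%.3f", e$auc), ""), collapse = "/"))
    return(invisible(outs))
  }
}
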