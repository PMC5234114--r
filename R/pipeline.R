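#' Default pipeline configuration
#'
#' All tunable keys of the pipeline with their defaults. Unknown keys are
#' rejected on construction and on file round-trip.
#'
#' @param ... Named overrides of the default keys.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    denoise.enabled = TRUE, denoise.quantile = 0.1,
    denoise.oversubtraction = 2.0, denoise.floor = 0.01, denoise.nfft = 512L,
    stages.keep = c("N2", "N3"),
    temporal.window_s = 0.5, temporal.overlap = 0.8,
    temporal.normalization = "global",
    temporal.ratio_low = 2, temporal.ratio_high = 20,
    temporal.block_s = 60, temporal.smoothing = 0.9,
    temporal.min_gap_s = 20, temporal.proportion_threshold = 0.5,
    temporal.silence_floor_frac = 0.25,
    cyclo.window_s = 60, cyclo.n_f = 54L, cyclo.n_alpha = 889L,
    cyclo.rank = 45L, cyclo.otsu = TRUE, cyclo.include_mean = FALSE,
    model.k = 50L, model.folds = 5L, model.C = 100, model.nested = FALSE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    rlang::abort(sprintf("Unknown config key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Read / write a pipeline configuration file (YAML)
#'
#' @param path File path.
#' @param config A `pipeline_config`.
#' @return A `pipeline_config` (`read_config`); `path` invisibly
#'   (`write_config`).
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# normalize pipeline input into a list of (signal, stages, subject_id, ahi)
.as_subject_list <- function(subjects, ahi = NULL) {
  if (inherits(subjects, "osa_cohort")) {
    truth <- subjects$truth
    return(lapply(names(subjects$subjects), function(sid) {
      sub <- subjects$subjects[[sid]]
      list(signal = sub$signal, stages = sub$stages, subject_id = sid,
           ahi = truth$ahi[truth$subject_id == sid])
    }))
  }
  if (inherits(subjects, "synth_subject")) subjects <- list(subjects)
  lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    if (inherits(s, "synth_subject")) {
      list(signal = s$signal, stages = s$stages,
           subject_id = s$signal$subject_id %||% sprintf("s%03d", i),
           ahi = s$ahi)
    } else {
      list(signal = s$signal, stages = s$stages,
           subject_id = s$subject_id %||% s$signal$subject_id %||%
             sprintf("s%03d", i),
           ahi = s$ahi %||% ahi[i])
    }
  })
}

#' Extract the full 709-feature table for a cohort
#'
#' Runs the complete feature pipeline per subject — spectral-subtraction
#' denoising, N2/N3 stage extraction, the 16 temporal transition features and
#' the running-mean CSD — then fits one shared NMF basis across the cohort's
#' (Otsu-masked) mean-CSD grids, projects every subject onto it and computes
#' the 693 cyclostationary statistics.
#'
#' @param subjects An `osa_cohort`, a list of `synth_subject`s, or a list of
#'   `list(signal, stages, subject_id, ahi)` entries.
#' @param config A [pipeline_config()].
#' @param basis Optional pre-fitted `nmf_basis`; when NULL one is fitted from
#'   this cohort.
#' @param progress Print per-subject progress to stderr (default FALSE).
#'
#' @return A tibble with columns `subject_id`, `ahi`, `severity`, 16 `t_*`
#'   and 693 `c_*` feature columns, with the fitted `nmf_basis` attached as
#'   attribute `"basis"`.
#' @export
extract_features <- function(subjects, config = pipeline_config(),
                             basis = NULL, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  subs <- .as_subject_list(subjects)
  say <- function(...) if (progress) message(sprintf(...))

  temporal_rows <- list()
  masked <- list()
  meta <- list()
  for (s in subs) {
    say("features: %s", s$subject_id)
    sig <- s$signal
    if (isTRUE(config$denoise.enabled)) {
      sig <- denoise(sig,
                     quantile = config$denoise.quantile,
                     nfft = config$denoise.nfft,
                     oversubtraction = config$denoise.oversubtraction,
                     floor = config$denoise.floor)
    }
    seg <- extract_stage_segments(sig, s$stages, keep = config$stages.keep)
    tf <- temporal_features(
      seg,
      window_s = config$temporal.window_s, overlap = config$temporal.overlap,
      block_s = config$temporal.block_s, ratio_low = config$temporal.ratio_low,
      ratio_high = config$temporal.ratio_high,
      smoothing = config$temporal.smoothing,
      proportion_threshold = config$temporal.proportion_threshold,
      min_gap_s = config$temporal.min_gap_s,
      silence_floor_frac = config$temporal.silence_floor_frac,
      normalization = config$temporal.normalization
    )
    rms <- running_csd(seg, window_s = config$cyclo.window_s,
                       n_f = config$cyclo.n_f, n_alpha = config$cyclo.n_alpha)
    m <- rms$rms
    if (isTRUE(config$cyclo.otsu)) m <- otsu_mask(m)$masked
    temporal_rows[[s$subject_id]] <- tf$features
    masked[[s$subject_id]] <- m
    meta[[s$subject_id]] <- tibble::tibble(
      subject_id = s$subject_id, ahi = s$ahi,
      severity = as.character(ahi_to_severity(s$ahi))
    )
  }

  if (is.null(basis)) {
    say("fitting shared NMF basis (rank %d)", config$cyclo.rank)
    basis <- fit_shared_basis(masked, rank = config$cyclo.rank,
                              seed = config$seed)
  }
  rows <- lapply(names(masked), function(sid) {
    say("activations: %s", sid)
    H <- project_activations(basis, masked[[sid]])
    cf <- summarize_statistics(H, include_mean = config$cyclo.include_mean)
    dplyr::bind_cols(
      meta[[sid]],
      tibble::as_tibble(as.list(temporal_rows[[sid]])),
      tibble::as_tibble(as.list(cf))
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "basis") <- basis
  out
}

#' Select, train and evaluate the severity model on a feature table
#'
#' Wrapper feature selection, linear-SVM training and LOOCV evaluation in one
#' call (see [select_features()], [train_svm()], [loocv_evaluate()]).
#'
#' @param features Feature table from [extract_features()] (or any table with
#'   a `severity` column and numeric features).
#' @param config A [pipeline_config()]; `model.*` keys are used.
#' @return An `osa_eval` object.
#' @export
evaluate_severity <- function(features, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  loocv_evaluate(features, k = config$model.k, folds = config$model.folds,
                 seed = config$seed, C = config$model.C,
                 nested = config$model.nested)
}

#' Write evaluation reports
#'
#' Metrics and the binary summary as JSON (with the config snapshot and seed
#' embedded for reproducibility), the confusion matrix as CSV, and the
#' feature-selection audit (ranks and scores) as CSV.
#'
#' @param eval An `osa_eval`.
#' @param dir Output directory (created if needed).
#' @param config The [pipeline_config()] used (embedded in the JSON report).
#' @return `dir`, invisibly.
#' @export
write_report <- function(eval, dir, config = pipeline_config()) {
  stopifnot(inherits(eval, "osa_eval"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    accuracy = eval$metrics$accuracy,
    per_class = eval$metrics$per_class,
    weighted = eval$metrics$weighted,
    binary = if (!is.null(eval$binary)) {
      eval$binary[c("sensitivity", "specificity", "accuracy")]
    },
    config = unclass(config),
    loocv = eval$config
  )
  jsonlite::write_json(report, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(as.data.frame(unclass(eval$confusion)),
                   file.path(dir, "confusion.csv"))
  if (!is.null(eval$selection)) {
    utils::write.csv(tidy(eval$selection), file.path(dir, "selection.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(eval$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  invisible(dir)
}
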