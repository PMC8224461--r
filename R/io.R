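#' Write trial ensembles to a CSV table
#'
#' Long-format table with columns `sample_id`, `trial`, `speed_mps` — the
#' interchange format for repeated-measurement velocity tables.
#'
#' @param ensembles A list of [trial_ensemble()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(ensembles, path) {
  if (inherits(ensembles, "trial_ensemble")) ensembles <- list(ensembles)
  df <- do.call(rbind, lapply(ensembles, function(e)
    data.frame(sample_id = e$sample_id, trial = seq_len(e$n_trials),
               speed_mps = e$trials, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read trial ensembles from a CSV table
#'
#' Inverse of [write_trials_csv()]: rows are grouped by `sample_id` (trial
#' order preserved by the `trial` column).
#'
#' @param path CSV path with columns `sample_id`, `trial`, `speed_mps`.
#' @return A list of [trial_ensemble()] objects.
#' @export
read_trial_ensembles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "trial", "speed_mps")
  if (!all(req %in% names(df)))
    stop("CSV must have columns sample_id, trial, speed_mps")
  lapply(split(df, df$sample_id), function(d) {
    d <- d[order(d$trial), ]
    trial_ensemble(d$sample_id[1], d$speed_mps)
  })
}

#' Write an experiment report to a directory
#'
#' Emits `report.json` (config, hash, summaries), `trials.csv` (the
#' per-trial table every summary is recomputable from) and `ba_points.csv`
#' (Bland-Altman points, when present).
#'
#' @param report An `experiment_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  ba <- lapply(report$summaries, function(s) {
    if (!is.null(s$bland_altman)) s$bland_altman$points else NULL
  })
  ba <- ba[!vapply(ba, is.null, logical(1))]
  if (length(ba) > 0) {
    pts <- do.call(rbind, lapply(names(ba), function(m)
      cbind(modality = m, ba[[m]])))
    utils::write.csv(pts, file.path(dir, "ba_points.csv"), row.names = FALSE)
  }
  skim <- function(x) {
    if (inherits(x, c("bland_altman_result", "icc_result",
                      "trend_fit_result"))) {
      out <- unclass(x)
      out$points <- NULL
      out
    } else if (is.list(x)) lapply(x, skim) else x
  }
  body <- list(kind = report$kind, config = unclass(report$config),
               config_hash = report$config_hash,
               package_version = report$package_version,
               summaries = lapply(report$summaries, skim),
               failures = report$failures)
  jsonlite::write_json(body, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(dir)
}
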