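#' Experiment configuration
#'
#' Collects everything needed to reproduce a synthetic two-modality
#' elastography experiment: the sample set (labels and ground-truth Young's
#' moduli), modalities, trial structure, noise levels, processing options,
#' and the master seed. Ground-truth speeds are derived from the moduli as
#' `c = sqrt(E / (3 rho))`, so samples are specified in the same units as a
#' mechanical-testing reference.
#'
#' Defaults represent the phantom study design: eight gelatin phantoms (two
#' each of four stiffnesses spanning roughly 10-40 kPa, i.e. 1.8-3.7 m/s),
#' five removal/replacement trials per phantom with 1.5% inter-trial speed
#' jitter, OCE phase noise of 0.1 rad and 10% relative IQ noise.
#'
#' @param materials Data frame with columns `label` and `young_modulus` (Pa).
#' @param modalities Character subset of `c("OCE", "USE")`.
#' @param n_trials Trials per sample (>= 2).
#' @param intertrial_sd_frac Inter-trial speed SD as a fraction of the true
#'   speed (removal/replacement jitter).
#' @param oce_phase_noise_sd OCE phase noise SD (rad).
#' @param use_noise_sd USE relative IQ noise SD.
#' @param nu,rho Poisson's ratio and density used in modulus conversions.
#' @param correction Rayleigh-to-shear correction method
#'   (see [rayleigh_shear_ratio()]).
#' @param exclusion Near-field exclusion (m).
#' @param use_directional Apply f-k directional filtering in the USE chain.
#' @param depth_kernel,ensemble_kernel Loupas kernel sizes.
#' @param c_parallel,c_perpendicular,angles Anisotropy-experiment controls
#'   (speeds along/across the fiber axis, m/s, and angles in degrees).
#' @param seed Master integer seed; all per-trial seeds derive from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(materials = data.frame(
                                label = c("gel8-a", "gel8-b", "gel10-a", "gel10-b",
                                          "gel12-a", "gel12-b", "gel14-a", "gel14-b"),
                                young_modulus = rep(c(10e3, 17e3, 26e3, 40e3), each = 2)),
                              modalities = c("OCE", "USE"),
                              n_trials = 5,
                              intertrial_sd_frac = 0.015,
                              oce_phase_noise_sd = 0.1,
                              use_noise_sd = 0.1,
                              nu = 0.5, rho = 1000,
                              correction = "exact_secular",
                              exclusion = 0.5e-3,
                              use_directional = TRUE,
                              depth_kernel = 5, ensemble_kernel = 2,
                              c_parallel = 4.4, c_perpendicular = 2.4,
                              angles = c(0, 45, 90),
                              seed = 1) {
  stopifnot(is.data.frame(materials),
            all(c("label", "young_modulus") %in% names(materials)))
  if (nrow(materials) < 1) stop("need at least one material")
  if (any(materials$young_modulus <= 0)) stop("moduli must be positive")
  if (n_trials < 2) stop("n_trials must be >= 2")
  modalities <- match.arg(modalities, c("OCE", "USE"), several.ok = TRUE)
  if (is.null(seed)) stop("a seed is required for reproducibility")
  structure(list(materials = materials, modalities = modalities,
                 n_trials = n_trials, intertrial_sd_frac = intertrial_sd_frac,
                 oce_phase_noise_sd = oce_phase_noise_sd,
                 use_noise_sd = use_noise_sd, nu = nu, rho = rho,
                 correction = correction, exclusion = exclusion,
                 use_directional = use_directional,
                 depth_kernel = depth_kernel, ensemble_kernel = ensemble_kernel,
                 c_parallel = c_parallel, c_perpendicular = c_perpendicular,
                 angles = angles, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' Fields not present fall back to the [experiment_config()] defaults;
#' `materials` may be given as a list of `{label, young_modulus}` records.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(raw$materials) && !is.data.frame(raw$materials))
    raw$materials <- do.call(rbind, lapply(raw$materials, as.data.frame))
  do.call(experiment_config, raw)
}

# Deterministic md5 over the canonical JSON form of the config.
config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(js, tf)
  unname(tools::md5sum(tf))
}

# Simulate one trial at shear-scale speed `speed` and run the full
# modality-specific chain back to a shear-scale speed and a modulus.
measure_trial <- function(modality, speed, config, seed) {
  if (modality == "OCE") {
    ratio <- rayleigh_shear_ratio(config$nu, config$correction)
    geo <- oce_geometry()
    field <- make_displacement_field(geo, speed * ratio)
    frames <- encode_oce_frames(field, noise_sd_phase = config$oce_phase_noise_sd,
                                seed = seed)
    est <- oce_phase_to_displacement(frames)
    map <- depth_average(est)
    ve <- estimate_group_velocity(map, exclusion = config$exclusion,
                                  directional = FALSE)
    Eest <- ym_rayleigh(ve$speed, config$nu, config$rho)$young_modulus
    list(speed = rayleigh_to_shear_speed(ve$speed, config$nu, config$correction),
         young_modulus = Eest, r_squared = mean(vapply(ve$fits, `[[`,
                                                       numeric(1), "r_squared")))
  } else {
    geo <- use_geometry()
    field <- make_displacement_field(geo, speed)
    frames <- encode_us_iq(field, noise_sd = config$use_noise_sd, seed = seed)
    est <- loupas_displacement(frames, depth_kernel = config$depth_kernel,
                               ensemble_kernel = config$ensemble_kernel)
    map <- depth_average(est)
    ve <- estimate_group_velocity(map, exclusion = config$exclusion,
                                  directional = config$use_directional)
    list(speed = ve$speed,
         young_modulus = ym_shear(ve$speed, config$rho)$young_modulus,
         r_squared = mean(vapply(ve$fits, `[[`, numeric(1), "r_squared")))
  }
}

# Summary statistics (BA raw + normalized, ICC, MAPE, trend fits) for one
# modality's trials table.
summarize_modality <- function(tr, true_E) {
  samples <- unique(tr$sample)
  ens <- lapply(samples, function(s)
    trial_ensemble(s, tr$est_speed[tr$sample == s]))
  speed_mat <- do.call(rbind, lapply(samples, function(s)
    tr$est_speed[tr$sample == s]))
  ba_raw <- bland_altman(ens, normalized = FALSE)
  ba_norm <- bland_altman(ens, normalized = TRUE)
  mean_E <- vapply(samples, function(s)
    mean(tr$young_modulus_est[tr$sample == s]), numeric(1))
  list(bland_altman = ba_raw,
       bland_altman_normalized = ba_norm,
       icc = icc(speed_mat),
       mape_modulus = mape(mean_E, true_E),
       trend_raw = trend_fit(ba_raw),
       trend_normalized = trend_fit(ba_norm))
}

#' Run the synthetic phantom repeatability experiment
#'
#' For every material and trial, draws a removal/replacement trial speed,
#' simulates the wave field, encodes it for each modality, runs the full
#' displacement -> map -> velocity chain (the OCE chain applies the
#' Rayleigh-to-shear correction; the USE chain applies directional
#' filtering), converts speeds to Young's moduli, and summarizes
#' repeatability (Bland-Altman raw and normalized, ICC, trend fits) and
#' accuracy (MAPE of mean moduli against the configured ground truth).
#' Fully deterministic given the config seed.
#'
#' @param config An [experiment_config()].
#' @return An `experiment_report`: `config`, `config_hash`, `trials`
#'   (per-sample per-trial per-modality table), `summaries` (per modality),
#'   and `failures` (per-trial error messages, if any).
#' @export
run_phantom_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  mats <- config$materials
  rows <- list()
  failures <- list()
  for (i in seq_len(nrow(mats))) {
    E_true <- mats$young_modulus[i]
    c_true <- sqrt(E_true / (3 * config$rho))
    ens <- make_trial_ensemble(c_true, config$n_trials,
                               intertrial_sd = config$intertrial_sd_frac * c_true,
                               seed = config$seed + 101L * i,
                               sample_id = mats$label[i])
    for (j in seq_len(config$n_trials)) {
      c_trial <- ens$trials[j]
      for (mod in config$modalities) {
        seed_ij <- config$seed + 7919L * i + 613L * j +
          if (mod == "USE") 307L else 0L
        res <- tryCatch(measure_trial(mod, c_trial, config, seed_ij),
                        error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1]] <-
            list(sample = mats$label[i], trial = j, modality = mod,
                 message = conditionMessage(res))
          next
        }
        rows[[length(rows) + 1]] <- data.frame(
          sample = mats$label[i], modality = mod, trial = j,
          true_speed = c_trial, est_speed = res$speed,
          young_modulus_true = E_true, young_modulus_est = res$young_modulus,
          r_squared = res$r_squared, stringsAsFactors = FALSE)
      }
    }
  }
  trials <- do.call(rbind, rows)
  if (is.null(trials)) stop("every trial failed; no report can be produced")
  summaries <- lapply(stats::setNames(config$modalities, config$modalities),
                      function(mod) {
    tr <- trials[trials$modality == mod, ]
    true_E <- vapply(unique(tr$sample), function(s)
      tr$young_modulus_true[tr$sample == s][1], numeric(1))
    summarize_modality(tr, true_E)
  })
  structure(list(kind = "phantom", config = config,
                 config_hash = config_hash(config),
                 package_version = as.character(utils::packageVersion("elastowave")),
                 trials = trials, summaries = summaries, failures = failures),
            class = "experiment_report")
}

#' Run the synthetic anisotropic-tissue experiment
#'
#' Measures a transversely isotropic sample (fibrous tissue such as skeletal
#' muscle) at several angles to the fiber axis. Ground-truth speed per angle
#' follows the elliptical [anisotropic_speed_profile()]; each angle is
#' measured `n_trials` times per modality. The report carries per-angle
#' means and SDs, per-modality ICC with angles as subjects, and the
#' between-modality percent difference per angle.
#'
#' @param config An [experiment_config()]; `c_parallel`, `c_perpendicular`
#'   and `angles` define the sample.
#' @return An `experiment_report` with `kind = "anisotropy"`.
#' @export
run_anisotropy_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  angles <- config$angles
  rows <- list()
  failures <- list()
  for (i in seq_along(angles)) {
    c_true <- anisotropic_speed_profile(config$c_parallel,
                                        config$c_perpendicular, angles[i])
    label <- sprintf("angle_%g", angles[i])
    ens <- make_trial_ensemble(c_true, config$n_trials,
                               intertrial_sd = config$intertrial_sd_frac * c_true,
                               seed = config$seed + 271L * i, sample_id = label)
    for (j in seq_len(config$n_trials)) {
      for (mod in config$modalities) {
        seed_ij <- config$seed + 6101L * i + 433L * j +
          if (mod == "USE") 307L else 0L
        res <- tryCatch(measure_trial(mod, ens$trials[j], config, seed_ij),
                        error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1]] <-
            list(sample = label, trial = j, modality = mod,
                 message = conditionMessage(res))
          next
        }
        rows[[length(rows) + 1]] <- data.frame(
          sample = label, angle = angles[i], modality = mod, trial = j,
          true_speed = ens$trials[j], est_speed = res$speed,
          stringsAsFactors = FALSE)
      }
    }
  }
  trials <- do.call(rbind, rows)
  if (is.null(trials)) stop("every trial failed; no report can be produced")
  per_angle <- do.call(rbind, lapply(split(trials, trials[c("angle", "modality")]),
                                     function(d) data.frame(
    angle = d$angle[1], modality = d$modality[1],
    mean_speed = mean(d$est_speed), sd_speed = stats::sd(d$est_speed),
    stringsAsFactors = FALSE)))
  rownames(per_angle) <- NULL
  summaries <- lapply(stats::setNames(config$modalities, config$modalities),
                      function(mod) {
    tr <- trials[trials$modality == mod, ]
    m <- do.call(rbind, lapply(angles, function(a)
      tr$est_speed[tr$angle == a]))
    list(icc = icc(m),
         per_angle = per_angle[per_angle$modality == mod, ])
  })
  if (all(c("OCE", "USE") %in% config$modalities)) {
    oce_m <- per_angle$mean_speed[per_angle$modality == "OCE"]
    use_m <- per_angle$mean_speed[per_angle$modality == "USE"]
    summaries$cross_modality <- data.frame(
      angle = angles,
      pct_difference = abs(oce_m - use_m) / ((oce_m + use_m) / 2) * 100)
  }
  structure(list(kind = "anisotropy", config = config,
                 config_hash = config_hash(config),
                 package_version = as.character(utils::packageVersion("elastowave")),
                 trials = trials, summaries = summaries, failures = failures),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Experiment report (%s): %d trials rows, %d failure(s), hash %s\n",
              x$kind, nrow(x$trials), length(x$failures), x$config_hash))
  for (mod in names(x$summaries)) {
    s <- x$summaries[[mod]]
    if (!is.null(s$icc))
      cat(sprintf("  %s: ICC %.4f", mod, s$icc$icc))
    if (!is.null(s$mape_modulus))
      cat(sprintf(", modulus MAPE %.2f%%", s$mape_modulus))
    if (!is.null(s$bland_altman))
      cat(sprintf(", LOA [%.4g, %.4g] m/s",
                  s$bland_altman$loa_lower, s$bland_altman$loa_upper))
    cat("\n")
  }
  invisible(x)
}
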