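CONTAINER_FORMAT_VERSION <- 1L

as_plain_matrix <- function(x) {
  x <- as.matrix(x)
  dimnames(x) <- NULL
  x
}

#' Write a dataset container
#'
#' Serializes sensor data, lead-field and (optionally) simulation ground truth
#' to a single versioned JSON file with full-precision numbers, mirroring the
#' logical layout `/y`, `/leadfield`, `/truth/*` plus attributes (`fs`,
#' `seed`, `snr_db`, `format_version`). Floats round-trip to better than
#' 1e-15 relative.
#'
#' @param x a [simulate_scene()] scene, or a list with elements `data`
#'   ([sensor_dataset()]), `leadfield` ([leadfield()]) and optional `truth`.
#' @param path output file path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
write_container <- function(x, path) {
  stopifnot(inherits(x$data, "snc_dataset"), inherits(x$leadfield, "snc_leadfield"))
  obj <- list(
    format_version = CONTAINER_FORMAT_VERSION,
    attrs = list(fs = x$data$fs,
                 seed = x$truth$seed %||% NA,
                 snr_db = x$truth$snr_db %||% NA),
    y = as_plain_matrix(x$data$y),
    leadfield = list(gain = as_plain_matrix(x$leadfield$gain),
                     voxel_coords = as_plain_matrix(x$leadfield$voxel_coords),
                     normalized = x$leadfield$normalized)
  )
  if (!is.null(x$truth)) {
    tr <- x$truth
    obj$truth <- list(
      source_voxels = as.integer(tr$source_voxels),
      source_timecourses = as_plain_matrix(tr$source_timecourses),
      clean_sensor = as_plain_matrix(tr$clean_sensor),
      noise_sensor = as_plain_matrix(tr$noise_sensor),
      true_noise_covariance = as_plain_matrix(tr$true_noise_covariance),
      snr_db = tr$snr_db, noise_scale = tr$noise_scale,
      seed = tr$seed, q_noise = tr$q_noise, corr = tr$corr)
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = FALSE)
  invisible(path)
}

#' Read a dataset container
#'
#' @param path path written by [write_container()].
#' @return list with `data`, `leadfield`, `truth` (NULL when absent) and
#'   `attrs`.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop("container not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (is.null(obj$format_version) || obj$format_version != CONTAINER_FORMAT_VERSION)
    stop("unsupported container format_version: ", obj$format_version %||% "<missing>")
  lf <- leadfield(obj$leadfield$gain, obj$leadfield$voxel_coords,
                  normalized = isTRUE(obj$leadfield$normalized))
  data <- sensor_dataset(as_plain_matrix(obj$y), obj$attrs$fs)
  truth <- NULL
  if (!is.null(obj$truth)) {
    truth <- obj$truth
    truth$source_voxels <- as.integer(truth$source_voxels)
    for (f in c("source_timecourses", "clean_sensor", "noise_sensor",
                "true_noise_covariance"))
      truth[[f]] <- as_plain_matrix(truth[[f]])
  }
  list(data = data, leadfield = lf, truth = truth, attrs = obj$attrs)
}

#' Write / read a plain matrix as CSV
#'
#' Import path for users with plain matrices (no header, full precision).
#'
#' @param x numeric matrix.
#' @param path file path.
#' @return `path` / the matrix.
#' @export
write_matrix_csv <- function(x, path) {
  utils::write.table(format(as_plain_matrix(x), digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                              colClasses = "numeric"))
}

# ---- run configuration ------------------------------------------------------

default_run_config <- function() {
  list(
    # simulator
    m = 271L, n = 8196L, K = 480L, fs = 1200, n_sources = 5L, corr = 0.99,
    freq_min = 1, freq_max = 75, tau = 0.25, q_noise = 40L,
    noise_diag_scale = 1, snr_db = 3, geometry = "random-smooth",
    spacing_mm = 5, seed = 1L,
    # snc solver
    max_outer_iter = 100L, outer_tol = 1e-6, q = "auto",
    noise_kind = "structured", noise_update_every = 1L, noise_warmup = 3L,
    variance_update = "sqrt", noise_cov_mode = "fa_model",
    initial_noise_scale = 0.1, vbfa_max_iter = 50L, vbfa_tol = 1e-6,
    prune_tol = 1e-12,
    # baselines
    regularization = 0.05, mce_penalty = 0.1, mce_max_iter = 2000L,
    mce_tol = 1e-8, mce_temporal = "per-sample",
    # metrics
    aprime_mode = "corrected"
  )
}

#' Read / write a run configuration
#'
#' Flat JSON configuration covering the simulator, solver, baseline and metric
#' parameters. Unknown keys are rejected by name; missing keys take their
#' defaults; the round trip through disk is lossless.
#'
#' @param path JSON file path.
#' @param config named list (a complete or partial configuration).
#' @return the validated, completed configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(user)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  config <- validate_run_config(config)
  jsonlite::write_json(config, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

validate_run_config <- function(user) {
  def <- default_run_config()
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(def, user)
  for (k in c("m", "n", "K", "n_sources", "q_noise", "max_outer_iter",
              "noise_update_every", "noise_warmup", "vbfa_max_iter",
              "mce_max_iter", "seed"))
    cfg[[k]] <- as.integer(cfg[[k]])
  for (k in c("fs", "corr", "freq_min", "freq_max", "tau", "noise_diag_scale",
              "snr_db", "spacing_mm", "outer_tol", "vbfa_tol", "prune_tol",
              "initial_noise_scale", "regularization", "mce_penalty",
              "mce_tol"))
    cfg[[k]] <- as.numeric(cfg[[k]])
  if (!identical(cfg$q, "auto")) cfg$q <- as.integer(cfg$q)
  cfg
}

config_snc_options <- function(cfg) {
  snc_options(max_outer_iter = cfg$max_outer_iter, outer_tol = cfg$outer_tol,
              q = cfg$q, noise_kind = cfg$noise_kind,
              noise_update_every = cfg$noise_update_every,
              noise_warmup = cfg$noise_warmup, seed = cfg$seed,
              variance_update = cfg$variance_update,
              noise_cov_mode = cfg$noise_cov_mode,
              initial_noise_scale = cfg$initial_noise_scale,
              vbfa_max_iter = cfg$vbfa_max_iter, vbfa_tol = cfg$vbfa_tol,
              prune_tol = cfg$prune_tol)
}

config_baseline_options <- function(cfg) {
  baseline_options(regularization = cfg$regularization,
                   mce_penalty = cfg$mce_penalty,
                   mce_max_iter = cfg$mce_max_iter, mce_tol = cfg$mce_tol,
                   mce_temporal = cfg$mce_temporal)
}

# ---- metric reports ---------------------------------------------------------

metrics_row <- function(m, label = NA_character_) {
  data.frame(label = label, h_r = m$h_r, f_r = m$f_r, a_prime = m$a_prime,
             r_bar = m$r_bar, ap = m$ap, geodesic = m$geodesic,
             n_candidates = m$n_candidates, stringsAsFactors = FALSE)
}

#' Write metric reports as JSON and CSV
#'
#' One row per report; with more than one report a `summary` row holding the
#' mean and standard error of each metric is appended (sweep-style
#' aggregation).
#'
#' @param reports a single `snc_metrics` object or a (possibly named) list of
#'   them.
#' @param path_prefix output path without extension; writes
#'   `<path_prefix>.json` and `<path_prefix>.csv`.
#' @return the report data.frame, invisibly.
#' @export
write_metrics_report <- function(reports, path_prefix) {
  if (inherits(reports, "snc_metrics")) reports <- list(reports)
  labels <- names(reports) %||% paste0("run", seq_along(reports))
  df <- do.call(rbind, Map(metrics_row, reports, labels))
  if (length(reports) > 1L) {
    num <- c("h_r", "f_r", "a_prime", "r_bar", "ap", "geodesic")
    mean_row <- df[1, ]
    mean_row$label <- "mean"
    se_row <- df[1, ]
    se_row$label <- "stderr"
    for (cn in num) {
      vals <- df[[cn]]
      mean_row[[cn]] <- mean(vals, na.rm = TRUE)
      se_row[[cn]] <- sd(vals, na.rm = TRUE) / sqrt(sum(is.finite(vals)))
    }
    mean_row$n_candidates <- NA
    se_row$n_candidates <- NA
    df <- rbind(df, mean_row, se_row)
  }
  write.csv(df, paste0(path_prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(df, paste0(path_prefix, ".json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(df)
}
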