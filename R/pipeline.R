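# Reproducible end-to-end runs: simulate or load a trial table, analyse,
# and write a run directory (manifest + tables) that a config + seed fully
# determines.

#' Read and validate a per-trial table
#'
#' Reads the canonical CSV dialect (header row, comma-separated, empty
#' fields for missing values) and validates the schema: required columns
#' present, no unknown columns beyond the documented optional ones,
#' confidence in [0, 1], RT non-negative, directions/responses in
#' left/right. A column-mapping (old name -> canonical name) lets source
#' files with different headers be adopted without editing them.
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector renaming file columns
#'   to canonical names, e.g. \code{c(Conf = "confidence")}.
#' @return Validated trial data.frame.
#' @export
read_trial_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  if (!is.null(column_map)) {
    idx <- match(names(column_map), names(dat))
    names(dat)[idx[!is.na(idx)]] <- column_map[!is.na(idx)]
  }
  required <- c("subject_id", "group", "block", "mean_orientation_deg",
                "stimulus_direction", "response", "correct", "rt_ms",
                "confidence")
  optional <- c("trial", "variance_condition", "slider_start",
                "confidence_bin")
  miss <- setdiff(required, names(dat))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  unknown <- setdiff(names(dat), c(required, optional))
  if (length(unknown))
    stop("unknown column(s): ", paste(unknown, collapse = ", "),
         "; map them with column_map or drop them")
  if (is.character(dat$correct))
    dat$correct <- toupper(dat$correct) %in% c("TRUE", "T", "1")

  bad <- which(!is.na(dat$confidence) &
                 (dat$confidence < 0 | dat$confidence > 1))
  if (length(bad))
    stop("confidence outside [0,1] at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!is.na(dat$rt_ms) & dat$rt_ms < 0)
  if (length(bad))
    stop("negative rt_ms at row(s): ", paste(utils::head(bad, 5),
                                             collapse = ", "))
  bad <- which(!is.na(dat$response) & !dat$response %in% c("left", "right"))
  if (length(bad))
    stop("response not left/right at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!dat$stimulus_direction %in% c("left", "right"))
  if (length(bad))
    stop("stimulus_direction not left/right at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  dat
}

#' Run the full pipeline and write a run directory
#'
#' Either simulates a cohort (\code{input_mode = "simulate"}) or loads a
#' trial table (\code{input_mode = "table"}), runs [metacog()], and writes
#' \code{trials.csv} (simulate mode), \code{trials_filtered.csv},
#' \code{subjects.csv}, \code{results.csv}, \code{results.json},
#' \code{exclusions.json} and \code{manifest.json} into \code{output_dir}.
#' The same config and seed reproduce every output byte (the manifest
#' timestamp aside).
#'
#' @param config Named list, or path to a YAML/JSON config file, with
#'   fields \code{input_mode} ("simulate" or "table"), \code{cohort}
#'   (arguments for [cohort_spec()], simulate mode; per-group observer
#'   settings under \code{cohort$group_params} as argument lists for
#'   [observer_params()]), \code{input_path} and optional
#'   \code{column_map} (table mode), \code{output_dir}, and any [metacog()]
#'   arguments (\code{n_bins}, \code{rt_bounds}, \code{drop_first_block},
#'   \code{outlier_rule}, \code{mixed_pair}, \code{bf_pair},
#'   \code{bf_r_scale}).
#' @param seed Integer master seed (overrides \code{config$cohort$seed}).
#' @return The run manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config, seed = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  mode <- match.arg(config$input_mode, c("simulate", "table"))
  outdir <- config$output_dir %||% stop("config$output_dir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  if (mode == "simulate") {
    cargs <- config$cohort %||% list()
    if (!is.null(cargs$group_params))
      cargs$group_params <- lapply(cargs$group_params,
                                   function(p) do.call(observer_params, p))
    if (!is.null(seed)) cargs$seed <- seed
    cohort <- do.call(cohort_spec, cargs)
    trials <- simulate_cohort(cohort)
    write_trials(trials, file.path(outdir, "trials.csv"))
  } else {
    if (is.null(config$input_path)) stop("config$input_path is required")
    trials <- read_trial_table(config$input_path, config$column_map)
  }

  margs <- config[intersect(names(config),
                            c("n_bins", "rt_bounds", "drop_first_block",
                              "outlier_rule", "mixed_pair", "bf_pair",
                              "bf_r_scale"))]
  fit <- do.call(metacog, c(list(trials = trials), margs))

  write_trials(fit$trials, file.path(outdir, "trials_filtered.csv"))
  utils::write.csv(fit$subjects, file.path(outdir, "subjects.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(fit$tests, file.path(outdir, "results.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(fit$tests, file.path(outdir, "results.json"),
                       dataframe = "rows", na = "null", digits = NA)
  jsonlite::write_json(unclass(fit$exclusions),
                       file.path(outdir, "exclusions.json"),
                       auto_unbox = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("metacogsim")),
    timestamp = format(Sys.time(), tz = "UTC"),
    input_mode = mode,
    seed = if (mode == "simulate") cohort$seed else NULL,
    n_trials_in = nrow(trials),
    n_subjects = nrow(fit$subjects),
    config = config[setdiff(names(config), "cohort")],
    files = c("trials_filtered.csv", "subjects.csv", "results.csv",
              "results.json", "exclusions.json"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
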