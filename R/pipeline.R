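#' Configuration of a full analysis run
#'
#' Bundles the cohort design, quantification and statistics parameters, and
#' a master seed. Stage seeds (cohort generation, blinding) are derived
#' deterministically from the master seed by [derive_seed()], so each stage
#' is independently reproducible from the manifest.
#'
#' @param cohort A [cohort_spec()]; its own `seed` is replaced by the
#'   derived cohort seed at run time.
#' @param k Threshold multiplier for stain detection (default 5).
#' @param alpha Significance level for the report (default 0.05).
#' @param log_base Base of the activation log ratio (default 10).
#' @param adjust Multiple-testing adjustment, `"none"` (default) or `"BH"`.
#' @param seed Master seed (integer).
#' @return Object of class `ps6_run_config`.
#' @export
run_config <- function(cohort = cohort_spec(), k = 5, alpha = 0.05,
                       log_base = 10, adjust = "none", seed = 1L) {
  validate_cohort_spec(cohort)
  stopifnot(k > 0, alpha > 0, alpha < 1, log_base > 0,
            adjust %in% c("none", "BH"))
  structure(
    list(cohort = cohort, k = k, alpha = alpha, log_base = log_base,
         adjust = adjust, seed = as.integer(seed)),
    class = "ps6_run_config"
  )
}

#' Derive a stage seed from the master seed
#'
#' Multiplicative-congruential split: stage `i` gets
#' `(master * 48271 + 7919 * i) mod (2^31 - 1)`, mapped away from 0. The
#' same master seed always yields the same per-stage seeds, and distinct
#' stages get decorrelated streams.
#'
#' @param master Master seed (integer).
#' @param stage One of `"cohort"`, `"blind"`.
#' @return Integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(master, stage = c("cohort", "blind")) {
  stage <- match.arg(stage)
  idx <- match(stage, c("cohort", "blind"))
  m <- 2147483647
  s <- ((as.numeric(master) %% m) * 48271 + 7919 * idx) %% m
  as.integer(if (s == 0) 1 else s)
}

#' Read a run configuration from YAML
#'
#' Maps a YAML document onto [run_config()]. Recognized keys: `seed`, `k`,
#' `alpha`, `log_base`, `adjust`, and a `cohort` block with `regions`,
#' `groups`, `n_per_group`, `rois_per_region`, `multipliers` (list of
#' `{group, region, multiplier}`) and a `field` block of
#' [stain_field_spec()] arguments. Omitted keys take the package defaults.
#'
#' @param path Path to a YAML file.
#' @return Object of class `ps6_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cy <- y$cohort
  field_args <- cy$field
  if (!is.null(field_args$image_shape)) {
    field_args$image_shape <- as.integer(unlist(field_args$image_shape))
  }
  field <- do.call(stain_field_spec, field_args %||% list())
  mult <- NULL
  if (!is.null(cy$multipliers)) {
    mult <- do.call(rbind, lapply(cy$multipliers, function(m) {
      data.frame(group = m$group, region = m$region,
                 multiplier = as.numeric(m$multiplier),
                 stringsAsFactors = FALSE)
    }))
  }
  cohort_args <- list(
    base_field = field, multipliers = mult,
    seed = as.integer(y$seed %||% 1L)
  )
  for (f in c("regions", "groups")) {
    if (!is.null(cy[[f]])) cohort_args[[f]] <- unlist(cy[[f]])
  }
  for (f in c("n_per_group", "rois_per_region")) {
    if (!is.null(cy[[f]])) cohort_args[[f]] <- as.integer(unlist(cy[[f]]))
  }
  run_config(
    cohort = do.call(cohort_spec, cohort_args),
    k = y$k %||% 5, alpha = y$alpha %||% 0.05,
    log_base = y$log_base %||% 10, adjust = y$adjust %||% "none",
    seed = as.integer(y$seed %||% 1L)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthesize-quantify-test-report pipeline
#'
#' Executes the complete artifact chain into `out_dir`:
#' `cohort/` (section TIFFs, ROI JSONs, metadata, ground truth),
#' `blind_order.csv` + `blind_key.csv` (randomized presentation and sealed
#' unblinding key), `measurements_roi.csv`, `measurements_animal.csv`,
#' `report.csv` + `report.json`, and `manifest.json` (config, derived
#' seeds, versions, file checksums). Re-running with the same configuration
#' reproduces byte-identical measurement and report files.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param overwrite Overwrite an existing non-empty `out_dir`
#'   (default `FALSE`: refuse, to protect partial or previous output).
#' @return List of class `ps6_run`: `report`, `animal_measurements`,
#'   `roi_measurements`, `cohort`, `manifest`, `dir`.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "ps6_run_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite) {
    stop("output directory exists and is not empty; use overwrite = TRUE")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(cohort = derive_seed(config$seed, "cohort"),
                blind = derive_seed(config$seed, "blind"))

  spec <- config$cohort
  spec$seed <- seeds$cohort
  cohort <- generate_cohort(spec, out_dir = file.path(out_dir, "cohort"),
                            overwrite = overwrite)

  blind <- blind_order(cohort$metadata, seeds$blind)
  utils::write.csv(blind$presentation, file.path(out_dir, "blind_order.csv"),
                   row.names = FALSE)
  utils::write.csv(blind$key, file.path(out_dir, "blind_key.csv"),
                   row.names = FALSE)

  roi_meas <- measure_cohort(cohort, k = config$k)
  utils::write.csv(roi_meas, file.path(out_dir, "measurements_roi.csv"),
                   row.names = FALSE)
  animal <- aggregate_animals(roi_meas)
  utils::write.csv(animal, file.path(out_dir, "measurements_animal.csv"),
                   row.names = FALSE)

  report <- build_report(animal, control_group = config$cohort$groups[1],
                         alpha = config$alpha, log_base = config$log_base,
                         adjust = config$adjust)
  utils::write.csv(as.data.frame(report), file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(report = as.data.frame(report),
         group_means = attr(report, "group_means"),
         alpha = config$alpha, log_base = config$log_base),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )

  outputs <- c("blind_order.csv", "blind_key.csv", "measurements_roi.csv",
               "measurements_animal.csv", "report.csv", "report.json",
               file.path("cohort", "metadata.csv"),
               file.path("cohort", "ground_truth.csv"))
  manifest <- list(
    package = "ps6quant",
    package_version = as.character(utils::packageVersion("ps6quant")),
    r_version = R.version.string,
    created = format(Sys.time(), tz = "UTC"),
    master_seed = config$seed,
    stage_seeds = seeds,
    config = list(cohort = spec_to_list(config$cohort), k = config$k,
                  alpha = config$alpha, log_base = config$log_base,
                  adjust = config$adjust, seed = config$seed),
    file_md5 = as.list(tools::md5sum(file.path(out_dir, outputs)))
  )
  names(manifest$file_md5) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(
    list(report = report, animal_measurements = animal,
         roi_measurements = roi_meas, cohort = cohort,
         manifest = manifest, dir = out_dir),
    class = "ps6_run"
  )
}

#' @export
print.ps6_run <- function(x, ...) {
  cat("Pipeline run:", nrow(x$roi_measurements), "ROIs,",
      nrow(x$report), "comparisons ->", x$dir, "\n")
  nsig <- sum(x$report$significant)
  cat("  significant comparisons (p <", attr(x$report, "alpha"), "):",
      nsig, "\n")
  invisible(x)
}
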