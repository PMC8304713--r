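# Full-pipeline orchestration: data (synthetic or ingested) ->
# descriptors -> ensemble fit -> applicability-domain report -> ranked
# screen, with one JSON config, explicit seeds and a timestamped
# key=value run log.

#' Configuration for a full pipeline run
#'
#' @param output_dir Directory for run artifacts (created if absent).
#' @param components_csv,records_csv Optional input CSV paths; when
#'   `NULL` the synthetic generator supplies the data.
#' @param candidates How to build the screening candidate set:
#'   `"default"` enumerates neat, aqueous-binary and eutectic candidates
#'   from the component pool; or a path to a candidate component CSV
#'   screened as neat solvents.
#' @param n_networks Ensemble size target.
#' @param rmsd_max,max_outliers Acceptance thresholds (defaults 0.04 and
#'   4).
#' @param hidden_range Hidden-unit range, within `[1, 64]`.
#' @param seed Master seed.
#' @param noise_sd Synthetic noise level (log10 units).
#' @param max_attempts Cap on candidate network trainings.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(output_dir, components_csv = NULL, records_csv = NULL,
                       candidates = "default", n_networks = 40L,
                       rmsd_max = 0.04, max_outliers = 4L,
                       hidden_range = c(6L, 12L), seed = 1L,
                       noise_sd = 0.03, max_attempts = 20L * n_networks) {
  if (rmsd_max <= 0) stop("rmsd_max must be positive")
  if (hidden_range[1L] < 1L || hidden_range[2L] > 64L)
    stop("hidden range must lie within [1, 64]")
  structure(list(output_dir = output_dir, components_csv = components_csv,
                 records_csv = records_csv, candidates = candidates,
                 n_networks = as.integer(n_networks), rmsd_max = rmsd_max,
                 max_outliers = as.integer(max_outliers),
                 hidden_range = as.integer(hidden_range),
                 seed = as.integer(seed), noise_sd = noise_sd,
                 max_attempts = as.integer(max_attempts)),
            class = "run_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with [run_config()] fields.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- lapply(raw, function(v) if (is.list(v) && !length(v)) NULL else v)
  do.call(run_config, raw)
}

#' Run the full screening pipeline
#'
#' Stages: data (read CSVs or generate synthetic data), descriptor
#' construction, ensemble fit, Williams applicability-domain report,
#' candidate screening.  Writes `model.json`, `ad_report.csv`,
#' `ranked.csv` and `run.log` into the output directory; any stage
#' failure aborts with an error naming the stage.  Identical configs
#' (and seeds) reproduce identical artifacts.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the fitted ensemble, the AD report,
#'   the screening result and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ",
                            sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  stage <- function(name, expr) {
    logf("stage=%s status=start", name)
    out <- tryCatch(expr, error = function(e) {
      logf("stage=%s status=error message=%s", name, conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logf("stage=%s status=done", name)
    out
  }
  logf("seed=%d n_networks=%d rmsd_max=%g max_outliers=%d",
       config$seed, config$n_networks, config$rmsd_max, config$max_outliers)

  data <- stage("data", {
    if (!is.null(config$records_csv)) {
      comps <- read_components(config$components_csv)
      list(records = read_records(config$records_csv), components = comps,
           truth = NULL)
    } else {
      generate_records(generator_spec(noise_sd = config$noise_sd,
                                      seed = config$seed))
    }
  })
  fm <- stage("descriptors", build_feature_matrix(data$records,
                                                  data$components))
  ens <- stage("fit", build_ensemble(fm$x, fm$y,
                                     n_target = config$n_networks,
                                     max_attempts = config$max_attempts,
                                     seed = config$seed,
                                     rmsd_max = config$rmsd_max,
                                     max_outliers = config$max_outliers,
                                     hidden_range = config$hidden_range))
  logf("networks_trained=%d accepted=%d rejected_by_rmsd=%d rejected_by_outliers=%d",
       nrow(ens$log), sum(ens$log$accepted),
       sum(!ens$log$accepted & ens$log$rmsd >= config$rmsd_max),
       sum(!ens$log$accepted & ens$log$rmsd < config$rmsd_max))
  model_path <- file.path(config$output_dir, "model.json")
  stage("save_model", write_ensemble(ens, model_path))

  ad <- stage("ad_report", williams_report(ens))
  ad_path <- file.path(config$output_dir, "ad_report.csv")
  write.csv(cbind(ad, warning_leverage = attr(ad, "warning_leverage")),
            ad_path, row.names = FALSE)

  ranked <- stage("screen", {
    cand <- if (identical(config$candidates, "default")) {
      comps <- data$components
      neat <- enumerate_neat(comps[comps$role %in% c("solvent", "water"), ,
                                   drop = FALSE])
      bin <- enumerate_binary(comps[comps$role == "solvent", , drop = FALSE],
                              fractions = seq(0.1, 0.9, by = 0.1))
      nad <- enumerate_nades(comps$name[comps$role == "hbd"], comps)
      c(neat$systems, bin$systems, nad$systems)
    } else {
      enumerate_neat(read_components(config$candidates))$systems
    }
    screen(cand, ens, data$components)
  })
  logf("candidates=%d dropped=%d discarded_member_predictions=%d",
       nrow(ranked) + attr(ranked, "n_dropped"), attr(ranked, "n_dropped"),
       attr(ranked, "n_discarded_predictions"))
  ranked_path <- file.path(config$output_dir, "ranked.csv")
  write.csv(ranked, ranked_path, row.names = FALSE)

  logf("status=complete")
  invisible(list(ensemble = ens, ad_report = ad, ranked = ranked,
                 paths = list(model = model_path, ad_report = ad_path,
                              ranked = ranked_path, log = log_path)))
}
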