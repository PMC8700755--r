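# Pipeline orchestration: config-driven calibration and prediction runs
# with manifest-tracked provenance. A single seed in the config drives all
# randomness; reruns on identical inputs produce byte-identical model files.

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  config
}

config_preprocess <- function(cfg) {
  p <- cfg$preprocess
  if (is.null(p)) return(preprocess_options())
  preprocess_options(
    baseline_left = p$baseline_left, baseline_right = p$baseline_right,
    co2_region = if (is.null(p$co2_region)) wn_range(2280, 2400)
                 else if (isFALSE(p$co2_region)) NULL
                 else wn_range(p$co2_region[[1]], p$co2_region[[2]]),
    normalize = isTRUE(p$normalize),
    normalize_range = if (is.null(p$normalize_range)) NULL
                      else wn_range(p$normalize_range[[1]], p$normalize_range[[2]]))
}

config_search <- function(cfg) {
  s <- cfg$search
  if (is.null(s)) s <- list()
  defaults <- formals(search_config)
  args <- utils::modifyList(lapply(defaults, eval), s[names(s) %in% names(defaults)])
  if (!is.null(cfg$seed)) args$seed <- cfg$seed
  do.call(search_config, args)
}

stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[ftirserum] ", fmt), ...))
}

#' Run a full calibration from a config
#'
#' Executes preprocess -> band detection -> feature extraction -> term
#' search -> model fit, driven by a single config (list or YAML path), and
#' writes the model plus a provenance manifest to `output_dir`. The run is
#' deterministic for a fixed config and seed; on any stage error, partial
#' outputs are removed.
#'
#' Config fields: either `design` (a [study_design()] field list for a
#' synthetic study, simulated in-memory) or `spectra` (list with `files`
#' and parallel `samples` replicate grouping) plus `truth` (CSV path, first
#' column = sample id); optional `search` ([search_config()] fields),
#' `preprocess` ([preprocess_options()] fields), `reference_analyte`,
#' `detect` (`min_prominence`, `min_presence`), `seed`, `output_dir`.
#'
#' @param config List or YAML file path.
#' @param output_dir Output directory; overrides `config$output_dir`;
#'   `NULL` (and no config entry) skips writing.
#' @param quiet Suppress stage logging? Default `FALSE`.
#' @return The fitted `ftir_calibration`, with the manifest in attribute
#'   `"manifest"`.
#' @export
run_calibrate <- function(config, output_dir = NULL, quiet = FALSE) {
  cfg <- read_config(config)
  if (is.null(output_dir)) output_dir <- cfg$output_dir
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    t0 <<- proc.time()[["elapsed"]]
  }
  fingerprints <- list()

  if (!is.null(cfg$design)) {
    d <- cfg$design
    design <- study_design(
      stock = if (is.null(d$stock)) NULL else unlist(d$stock),
      dilution_factors = if (is.null(d$dilution_factors)) c(2, 3, 5, 7, 10)
                         else unlist(d$dilution_factors),
      replicates = if (is.null(d$replicates)) 3 else d$replicates,
      noise_sd = if (is.null(d$noise_sd)) 1e-4 else d$noise_sd,
      drift_amplitude = if (is.null(d$drift_amplitude)) 0 else d$drift_amplitude,
      jitter_sd = if (is.null(d$jitter_sd)) 0 else d$jitter_sd,
      seed = if (is.null(d$seed)) {
        if (is.null(cfg$seed)) 1L else cfg$seed
      } else d$seed)
    lib <- make_band_library(n_bands = if (is.null(d$n_bands)) 49 else d$n_bands,
                             seed = design$seed)
    study <- simulate_dilution_study(design, lib)
    spectra <- study$spectra
    truth <- study$truth
    fingerprints$design <- design[c("dilution_factors", "replicates",
                                    "noise_sd", "drift_amplitude",
                                    "jitter_sd", "seed")]
    stage_log(quiet, "simulated %d spectra (%d levels x %d replicates)",
              length(spectra), nrow(truth), design$replicates)
  } else if (!is.null(cfg$spectra)) {
    files <- unlist(cfg$spectra$files)
    samples <- unlist(cfg$spectra$samples)
    if (is.null(samples) || length(samples) != length(files))
      stop("config$spectra needs parallel 'files' and 'samples' fields")
    spectra <- lapply(seq_along(files), function(i)
      read_spectrum(files[i], meta = list(sample = samples[i])))
    if (is.null(cfg$truth)) stop("config is missing the 'truth' field")
    ttab <- utils::read.csv(cfg$truth, check.names = FALSE)
    truth <- as.matrix(ttab[, -1, drop = FALSE])
    rownames(truth) <- ttab[[1]]
    fingerprints$spectra <- as.list(tools::md5sum(files))
    fingerprints$truth <- unname(tools::md5sum(cfg$truth))
    stage_log(quiet, "read %d spectra (%d samples)", length(files),
              length(unique(samples)))
  } else {
    stop("config is missing the 'design' (or 'spectra' + 'truth') field")
  }
  tick("input")

  scfg <- config_search(cfg)
  popts <- config_preprocess(cfg)
  det <- cfg$detect
  model <- ftir_calibrate(
    spectra, truth, config = scfg, preprocess = popts,
    min_prominence = if (is.null(det$min_prominence)) 1e-3 else det$min_prominence,
    min_presence = if (is.null(det$min_presence)) 0.8 else det$min_presence,
    reference_analyte = cfg$reference_analyte)
  tick("calibrate")
  stage_log(quiet,
            "calibrated: %d bands, features {%s}, %d candidate terms, %d in model",
            nrow(model$bands),
            paste(model$training$screened_features, collapse = ", "),
            model$training$n_candidate_terms, length(model$composite$terms))

  manifest <- list(
    tool = "ftirserum", version = as.character(utils::packageVersion("ftirserum")),
    config = cfg, fingerprints = fingerprints,
    counts = list(spectra = length(spectra), samples = nrow(truth),
                  bands = nrow(model$bands),
                  screened_features = length(model$training$screened_features),
                  candidate_terms = model$training$n_candidate_terms,
                  model_terms = length(model$composite$terms)),
    outputs = list(), timings = as.list(timings))

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    model_path <- file.path(output_dir, "model.json")
    manifest_path <- file.path(output_dir, "manifest.json")
    tryCatch({
      save_model(model, model_path)
      manifest$outputs <- list(model = model_path, manifest = manifest_path)
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                           digits = I(17), pretty = TRUE, null = "null")
    }, error = function(e) {
      unlink(c(model_path, manifest_path))
      stop("output stage failed: ", conditionMessage(e))
    })
    stage_log(quiet, "wrote %s", model_path)
  }
  attr(model, "manifest") <- manifest
  model
}

#' Predict a panel report from spectra with a saved model
#'
#' Loads the model (path or object), preprocesses the spectra with its
#' recorded settings, and writes/returns a report mirroring the reference
#' table layout (analyte, name, units, predicted concentration, optional
#' truth and delta%). Predictions implying concentrations outside the
#' model's calibration ranges raise a warning.
#'
#' @param model `ftir_calibration` or path to a [save_model()] file.
#' @param spectra List of [ftir_spectrum()]s or character vector of
#'   spectrum file paths (each file one sample; replicates may share
#'   `meta$sample`).
#' @param truth Optional named true-concentration vector (single sample):
#'   adds `true` and `delta_pct` columns.
#' @param out Optional CSV output path.
#' @return A `data.frame` report (one row per analyte for a single sample;
#'   long format with a `sample` column otherwise).
#' @export
run_predict <- function(model, spectra, truth = NULL, out = NULL) {
  if (is.character(model)) model <- load_model(model)
  if (is.character(spectra))
    spectra <- lapply(spectra, function(f)
      read_spectrum(f, meta = list(sample = basename(f))))
  if (inherits(spectra, "ftir_spectrum")) spectra <- list(spectra)
  pred <- predict(model, spectra, warn_range = TRUE)
  if (!is.matrix(pred)) pred <- matrix(pred, nrow = 1,
                                       dimnames = list("sample1", names(pred)))
  long <- do.call(rbind, lapply(rownames(pred), function(sid) {
    df <- data.frame(sample = sid, analyte = colnames(pred),
                     found = unname(pred[sid, ]), row.names = NULL)
    df
  }))
  if (!is.null(model$panel)) {
    m <- match(long$analyte, model$panel$analyte)
    long$name <- model$panel$name[m]
    long$units <- model$panel$units[m]
    long <- long[, c("sample", "analyte", "name", "units", "found")]
  }
  if (!is.null(truth)) {
    if (nrow(pred) != 1) stop("truth scoring needs a single sample")
    long$true <- unname(truth[long$analyte])
    long$delta_pct <- round_half_away(100 * abs(long$true - long$found) / long$true, 2)
  }
  if (nrow(pred) == 1) long$sample <- NULL
  if (!is.null(out)) utils::write.csv(long, out, row.names = FALSE, quote = TRUE)
  long
}
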