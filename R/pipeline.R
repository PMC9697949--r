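# End-to-end orchestration: simulate -> compress -> train -> evaluate, each
# stage re-entrant from plain-text artifacts (CSV tables, JSON models) so a
# run can resume from any intermediate file. One master seed governs noise
# draws, the data split and network initializations.

#' Pipeline run configuration
#'
#' Collects every stage's settings with the study-design defaults: a 501
#' point 0--5 V ramp, the 13-level serial-dilution grid for both analytes in
#' triplicate, 0.02 V measurement noise, peak calibration at 4.65 V
#' (acetone) / 4.13 V (ethanol), 51-knot start eliminated to 6 knots with a
#' cubic spline, and a topology search over hidden sizes 2..9 with all four
#' activations. `restarts` defaults to 20; set 1000 to run the full
#' 32,000-network search.
#'
#' @param seed Master integer seed.
#' @param ramp_start,ramp_end,ramp_step Heater ramp in volts.
#' @param levels_eth,levels_ace Concentration ladders in percent.
#' @param replicates Replicate sweeps per concentration pair.
#' @param noise_sd Measurement noise sd in volts.
#' @param peak_acetone,peak_ethanol Calibration peak targets in volts.
#' @param spline_degree,initial_spacing,target_knots,shared_knots Spline
#'   compression settings.
#' @param hidden_sizes,activations,restarts,maxit,prefer_smallest_within
#'   Topology-search settings.
#' @param split_ratios Learning/test/validation proportions.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       ramp_start = 0, ramp_end = 5, ramp_step = 0.01,
                       levels_eth = concentration_levels(),
                       levels_ace = concentration_levels(),
                       replicates = 1L, noise_sd = 0.02,
                       peak_acetone = 4.65, peak_ethanol = 4.13,
                       spline_degree = 3L, initial_spacing = 0.1,
                       target_knots = 6L, shared_knots = FALSE,
                       hidden_sizes = 2:9,
                       activations = c("lin", "log", "exp", "tanh"),
                       restarts = 20L, maxit = 400L,
                       prefer_smallest_within = NULL,
                       split_ratios = c(0.70, 0.15, 0.15)) {
  cfg <- list(seed = as.integer(seed), ramp_start = ramp_start,
              ramp_end = ramp_end, ramp_step = ramp_step,
              levels_eth = levels_eth, levels_ace = levels_ace,
              replicates = as.integer(replicates), noise_sd = noise_sd,
              peak_acetone = peak_acetone, peak_ethanol = peak_ethanol,
              spline_degree = as.integer(spline_degree),
              initial_spacing = initial_spacing,
              target_knots = as.integer(target_knots),
              shared_knots = isTRUE(shared_knots),
              hidden_sizes = as.integer(hidden_sizes),
              activations = activations, restarts = as.integer(restarts),
              maxit = as.integer(maxit),
              prefer_smallest_within = prefer_smallest_within,
              split_ratios = split_ratios)
  heater_ramp(cfg$ramp_start, cfg$ramp_end, cfg$ramp_step)  # validate
  structure(cfg, class = "run_config")
}

config_ramp <- function(config) heater_ramp(config$ramp_start, config$ramp_end, config$ramp_step)

config_params <- function(config) {
  calibrate_amplitudes(c(acetone = config$peak_acetone, ethanol = config$peak_ethanol),
                       ramp = config_ramp(config))
}

stage_log <- function(stage, t0, ...) {
  message(sprintf("[%s] %s (%.1f s)", stage, paste0(...),
                  as.numeric(Sys.time()) - t0))
}

#' Write one sweep to a CSV file
#'
#' Plain two-column CSV (`heater_v`, `out_v`), one row per ramp sample.
#'
#' @param sweep A `sensor_sweep`.
#' @param path Output file path.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.csv(data.frame(heater_v = sweep$heater_v, out_v = sweep$out_v),
                   path, row.names = FALSE)
}

#' Read a sweep file written by [write_sweep()]
#'
#' @param path CSV file with columns `heater_v`, `out_v`.
#' @param mix,replicate Optional metadata to attach.
#' @return A `sensor_sweep` (with `noise_sd`/`seed` unknown, recorded as NA).
#' @export
read_sweep <- function(path, mix = analyte_mix(0, 0), replicate = 1L) {
  d <- utils::read.csv(path)
  if (!all(c("heater_v", "out_v") %in% names(d)))
    stop("read_sweep: ", path, " lacks heater_v/out_v columns")
  structure(list(heater_v = d$heater_v, out_v = d$out_v, mix = mix,
                 replicate = as.integer(replicate), seed = NA_integer_,
                 noise_sd = NA_real_),
            class = "sensor_sweep")
}

#' Simulation stage: write sweep files and a manifest
#'
#' Generates the factorial dataset and writes one CSV per sweep plus a
#' `manifest.csv` (file, concentrations, replicate, per-sweep seed) into
#' `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Writable output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
cmd_simulate <- function(config, out_dir) {
  t0 <- as.numeric(Sys.time())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sweeps <- generate_dataset(config$levels_eth, config$levels_ace,
                             config$replicates, config_ramp(config),
                             config_params(config), circuit_params(),
                             config$noise_sd, config$seed)
  man <- sweep_manifest(sweeps)
  for (i in seq_along(sweeps))
    write_sweep(sweeps[[i]], file.path(out_dir, man$file[i]))
  utils::write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  stage_log("simulate", t0, nrow(man), " sweeps -> ", out_dir)
  invisible(man)
}

#' Compression stage: sweeps to a feature table
#'
#' Reads every sweep listed in the manifest, runs knot elimination and
#' writes `features.csv`. Malformed sweep files are logged and skipped; the
#' run continues and the summary reports the failures.
#'
#' @param manifest_path Path to a `manifest.csv` (sweep files are resolved
#'   relative to its directory).
#' @param config A [run_config()].
#' @param out_path Output CSV path (default `features.csv` next to the
#'   manifest).
#' @return Invisibly, the feature table (with a `file` column prepended).
#' @export
cmd_compress <- function(manifest_path, config = run_config(),
                         out_path = file.path(dirname(manifest_path), "features.csv")) {
  t0 <- as.numeric(Sys.time())
  man <- utils::read.csv(manifest_path)
  dir <- dirname(manifest_path)
  sweeps <- list(); kept <- integer(); failed <- 0L
  for (i in seq_len(nrow(man))) {
    s <- tryCatch(
      read_sweep(file.path(dir, man$file[i]),
                 analyte_mix(man$c_ethanol_pct[i], man$c_acetone_pct[i]),
                 man$replicate[i]),
      error = function(e) { message("compress: skipping ", man$file[i], ": ",
                                    conditionMessage(e)); NULL })
    if (!is.null(s)) { sweeps[[length(sweeps) + 1]] <- s; kept <- c(kept, i) }
    else failed <- failed + 1L
  }
  if (length(sweeps) == 0) {
    warning("cmd_compress: no readable sweeps in manifest")
    tab <- data.frame()
  } else {
    tab <- compress_dataset(sweeps, config$initial_spacing, config$target_knots,
                            config$spline_degree, config$shared_knots)
    tab <- cbind(file = man$file[kept], tab)
  }
  utils::write.csv(tab, out_path, row.names = FALSE)
  stage_log("compress", t0, nrow(tab), " feature rows (", failed, " failed) -> ",
            out_path)
  invisible(tab)
}

#' Training stage: topology search on a feature table
#'
#' Splits the samples 70/15/15 from the master seed, runs the grid search
#' and writes the selected model (`model.json`) and the per-cell grid
#' report (`grid_report.csv`).
#'
#' @param features_path Path to a `features.csv` from [cmd_compress()].
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the `grid_search` result.
#' @export
cmd_train <- function(features_path, config = run_config(),
                      out_dir = dirname(features_path)) {
  t0 <- as.numeric(Sys.time())
  tab <- utils::read.csv(features_path)
  if (!all(c(paste0("f", 1:8), "c_ethanol_pct", "c_acetone_pct") %in% names(tab)))
    stop("cmd_train: feature table needs f1..f8 and both concentration columns")
  if (nrow(tab) < 3) stop("cmd_train: need at least 3 samples")
  X <- as_feature_matrix(tab)
  Y <- target_transform(tab$c_ethanol_pct, tab$c_acetone_pct)
  split <- split_dataset(nrow(tab), config$split_ratios, config$seed)
  gs <- grid_search(X, Y, split, config$hidden_sizes, config$activations,
                    config$restarts, config$seed, config$maxit,
                    config$prefer_smallest_within)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_mlp_model(gs$best_model, file.path(out_dir, "model.json"))
  utils::write.csv(gs$report, file.path(out_dir, "grid_report.csv"),
                   row.names = FALSE)
  stage_log("train", t0, nrow(gs$candidates), " candidates; selected 8-",
            gs$best_cell$hidden_size, "-2 ", gs$best_cell$activation,
            ", validation error ", signif(gs$best_cell$validation_err, 4))
  invisible(gs)
}

#' Evaluation stage: metrics per analyte and subset
#'
#' Recomputes the split from the master seed (so it matches training),
#' evaluates the stored model on the feature table and writes
#' `eval_report.csv` and `eval_report.json`.
#'
#' @param model_path Path to a `model.json`.
#' @param features_path Path to the `features.csv` the model was trained on.
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the `eval_report` data frame.
#' @export
cmd_evaluate <- function(model_path, features_path, config = run_config(),
                         out_dir = dirname(model_path)) {
  t0 <- as.numeric(Sys.time())
  model <- read_mlp_model(model_path)
  tab <- utils::read.csv(features_path)
  if (!all(c("c_ethanol_pct", "c_acetone_pct") %in% names(tab)))
    stop("cmd_evaluate: feature table lacks concentration columns")
  split <- split_dataset(nrow(tab), config$split_ratios, config$seed)
  rep <- evaluate_model(model, tab,
                        cbind(tab$c_ethanol_pct, tab$c_acetone_pct), split)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(rep, file.path(out_dir, "eval_report.csv"), row.names = FALSE)
  jsonlite::write_json(rep, file.path(out_dir, "eval_report.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  stage_log("evaluate", t0, "validation R^2: ethanol ",
            signif(rep$r_squared[rep$analyte == "ethanol" &
                                   rep$subset == "validation"], 4),
            ", acetone ",
            signif(rep$r_squared[rep$analyte == "acetone" &
                                   rep$subset == "validation"], 4))
  invisible(rep)
}

#' Run the full pipeline
#'
#' simulate -> compress -> train -> evaluate under one master seed, leaving
#' every intermediate artifact (sweep CSVs, manifest, feature table, model
#' JSON, grid report, evaluation report) in `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the feature table, grid-search result and
#'   evaluation report.
#' @export
cmd_run_all <- function(config, out_dir) {
  cmd_simulate(config, out_dir)
  tab <- cmd_compress(file.path(out_dir, "manifest.csv"), config)
  gs <- cmd_train(file.path(out_dir, "features.csv"), config, out_dir)
  rep <- cmd_evaluate(file.path(out_dir, "model.json"),
                      file.path(out_dir, "features.csv"), config, out_dir)
  invisible(list(features = tab, grid = gs, report = rep))
}

#' Serialize a trained network to JSON
#'
#' Layer sizes, activation, flattened weights, scaler parameters, seed and
#' the training errors, written as plain JSON so a model survives across
#' sessions and languages.
#'
#' @param model An `mlp_model`.
#' @param path Output path.
#' @export
write_mlp_model <- function(model, path) {
  obj <- list(
    input_dim = nrow(model$W1), hidden_size = model$hidden_size,
    output_dim = ncol(model$W2), activation = model$activation,
    W1 = as.vector(model$W1), b1 = model$b1,
    W2 = as.vector(model$W2), b2 = model$b2,
    x_center = unname(model$x_center), x_scale = unname(model$x_scale),
    y_center = unname(model$y_center), y_scale = unname(model$y_scale),
    errors = model$errors, seed = model$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
}

#' Read a network written by [write_mlp_model()]
#'
#' @param path JSON model file.
#' @return An `mlp_model`.
#' @export
read_mlp_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    hidden_size = as.integer(o$hidden_size), activation = o$activation,
    W1 = matrix(o$W1, o$input_dim, o$hidden_size),
    b1 = as.numeric(o$b1),
    W2 = matrix(o$W2, o$hidden_size, o$output_dim),
    b2 = as.numeric(o$b2),
    x_center = as.numeric(o$x_center), x_scale = as.numeric(o$x_scale),
    y_center = as.numeric(o$y_center), y_scale = as.numeric(o$y_scale),
    errors = o$errors, seed = as.integer(o$seed)
  ), class = "mlp_model")
}
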