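# YAML/JSON configuration with schema validation, run() stage dispatcher
# and per-run provenance manifest.

config_defaults <- function() {
  list(
    simulate = list(duration_s = 600, fs = 256, n_channels = 10,
                    n_recordings = 1, seizure_intervals = list(c(100, 160)),
                    sw_frequency = 3.0, sw_amplitude_gain = 2.0,
                    pink_noise_scale = 10, hf_burst_scale = 15, seed = 1),
    ingest = list(window_s = 30, overlap_frac = 0.30,
                  label_min_overlap_s = 0, channels = NULL,
                  resample_hz = NULL),
    features = list(profile = "compact19", wavelet = "db8", levels = 5,
                    entropy_bins = 100),
    graph = list(threshold = 0.2, export_fmt = "graphml"),
    resample = list(method = "smote", k_neighbors = 5, target_ratio = 1.0,
                    lambda_max = 0.5, safety_quantile = 0.5, seed = 1),
    train = list(model = "gcn_lstm", lr = 0.001, weight_decay = 5e-4,
                 epochs = 50, batch_size = 64, patience = 10,
                 split = c(0.60, 0.20, 0.20), seed = 1),
    io = list(input = NULL, out_dir = "seizgraph_out", model_path = NULL)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      sg_stop(paste0("unknown configuration key: ", full),
              "seizgraph_config_error")
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]]))
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    else defaults[key] <- list(user[[key]])   # keep explicit NULLs
  }
  defaults
}

#' Parse and validate a pipeline configuration file
#'
#' Accepts YAML or JSON; missing keys take the pipeline defaults (30 s
#' windows, 30% overlap, graph threshold 0.2, db8 wavelet, Adam lr 0.001 /
#' weight decay 5e-4, 50 epochs, batch 64, patience 10, 60/20/20 split).
#' Unknown keys raise an error naming the offending key.
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @return Validated configuration list (class `seizgraph_config`).
#' @export
parse_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    sg_assert(file.exists(path), paste0("no such config file: ", path),
              "seizgraph_io_error")
    user <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                             simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  cfg <- merge_config(config_defaults(), user)
  sg_assert(cfg$ingest$overlap_frac >= 0 && cfg$ingest$overlap_frac < 1,
            "overlap_frac must lie in [0, 1)")
  sg_assert(cfg$graph$threshold > 0, "graph threshold must be positive")
  sg_assert(cfg$resample$method %in% c("none", "smote", "knnor"),
            "resample method must be none/smote/knnor")
  sg_assert(cfg$train$model %in% c("gcn_lstm", "gcn_brf"),
            "train model must be gcn_lstm or gcn_brf")
  sg_assert(abs(sum(cfg$train$split) - 1) < 1e-8, "split must sum to 1")
  structure(cfg, class = c("seizgraph_config", "list"))
}

#' Write a configuration back to YAML
#'
#' @param cfg Configuration from [parse_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

as_train_config <- function(cfg) {
  rs <- cfg$resample
  train_config(
    lr = cfg$train$lr, weight_decay = cfg$train$weight_decay,
    epochs = cfg$train$epochs, batch_size = cfg$train$batch_size,
    patience = cfg$train$patience, split = cfg$train$split,
    seed = cfg$train$seed, threshold = cfg$graph$threshold,
    resample = resample_config(rs$method, rs$k_neighbors, rs$target_ratio,
                               rs$lambda_max, rs$safety_quantile,
                               seed = rs$seed))
}

as_feature_spec <- function(cfg) {
  feature_spec(profile = cfg$features$profile, wavelet = cfg$features$wavelet,
               levels = cfg$features$levels,
               entropy_bins = cfg$features$entropy_bins)
}

write_manifest <- function(cfg, stage, inputs, outputs, out_dir) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    stage = stage,
    package = "seizgraph",
    version = as.character(utils::packageVersion("seizgraph")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = list(simulate = cfg$simulate$seed, resample = cfg$resample$seed,
                 train = cfg$train$seed),
    config = unclass(cfg),
    input_digests = digests,
    outputs = outputs)
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  path
}

ingest_from_config <- function(cfg) {
  paths <- cfg$io$input
  sg_assert(length(paths) >= 1L, "io.input must list at least one EDF file",
            "seizgraph_config_error")
  fms <- lapply(paths, function(p) {
    rec <- read_edf(p)
    if (!is.null(cfg$ingest$channels))
      rec <- select_channels(rec, cfg$ingest$channels)
    if (!is.null(cfg$ingest$resample_hz))
      rec <- resample_recording(rec, cfg$ingest$resample_hz)
    ws <- segment_windows(rec, cfg$ingest$window_s, cfg$ingest$overlap_frac,
                          cfg$ingest$label_min_overlap_s)
    window_features(ws, as_feature_spec(cfg))
  })
  bind_feature_matrices(fms)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (write synthetic EDF recordings), `ingest`
#' (summarize windows/labels of the input EDFs), `features` (feature CSV),
#' `graph` (build + export the feature graph), `train` (fit the configured
#' model; writes the evaluation report, confusion CSV, model RDS and JSON
#' checkpoint), `evaluate` (re-score a saved model on input EDFs),
#' `predict` (per-second probability track and predicted intervals for an
#' input EDF).  Every stage writes a provenance manifest to the output
#' directory.
#'
#' @param subcommand Stage name.
#' @param config Configuration from [parse_config()].
#' @return Named list of written artifact paths, invisibly.
#' @export
run <- function(subcommand = c("simulate", "ingest", "features", "graph",
                               "train", "evaluate", "predict"),
                config = parse_config()) {
  subcommand <- tryCatch(match.arg(subcommand),
                         error = function(e) sg_stop(
                           paste0("unknown subcommand: ", subcommand[1]),
                           "seizgraph_usage_error"))
  cfg <- config
  out_dir <- cfg$io$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  inputs <- character(0)

  if (subcommand == "simulate") {
    for (k in seq_len(cfg$simulate$n_recordings)) {
      sc <- sim_config(
        duration_s = cfg$simulate$duration_s, fs = cfg$simulate$fs,
        n_channels = cfg$simulate$n_channels,
        seizure_intervals = cfg$simulate$seizure_intervals,
        sw_frequency = cfg$simulate$sw_frequency,
        sw_amplitude_gain = cfg$simulate$sw_amplitude_gain,
        pink_noise_scale = cfg$simulate$pink_noise_scale,
        hf_burst_scale = cfg$simulate$hf_burst_scale,
        seed = cfg$simulate$seed + k - 1L)
      p <- file.path(out_dir, sprintf("sim_%02d.edf", k))
      write_edf(simulate_recording(sc), p)
      outputs[[sprintf("edf_%02d", k)]] <- p
    }
  } else if (subcommand == "ingest") {
    inputs <- unlist(cfg$io$input)
    fm <- ingest_from_config(cfg)
    p <- file.path(out_dir, "ingest_summary.json")
    jsonlite::write_json(list(n_windows = nrow(fm$X),
                              n_ictal = sum(fm$y),
                              n_features = ncol(fm$X)),
                         p, auto_unbox = TRUE)
    outputs$summary <- p
  } else if (subcommand == "features") {
    inputs <- unlist(cfg$io$input)
    fm <- ingest_from_config(cfg)
    p <- file.path(out_dir, "features.csv")
    write_feature_csv(fm, p)
    outputs$features <- p
  } else if (subcommand == "graph") {
    inputs <- unlist(cfg$io$input)
    fm <- ingest_from_config(cfg)
    Xs <- apply_scaler(fm$X, fit_scaler(fm$X))
    g <- build_graph(Xs, fm$y, cfg$graph$threshold)
    ext <- if (cfg$graph$export_fmt == "graphml") "graphml" else "tsv"
    p <- file.path(out_dir, paste0("graph.", ext))
    export_graph(g, p, cfg$graph$export_fmt)
    pp <- file.path(out_dir, "graph_circular.png")
    plot_circular(g, pp)
    outputs$graph <- p; outputs$plot <- pp
  } else if (subcommand == "train") {
    inputs <- unlist(cfg$io$input)
    fm <- ingest_from_config(cfg)
    tc <- as_train_config(cfg)
    fit <- if (cfg$train$model == "gcn_lstm") train_gcn_lstm(fm, tc)
    else train_gcn_brf(fm, tc)
    pr <- file.path(out_dir, "eval_report.json")
    write_eval_report(fit$report, pr)
    pc <- file.path(out_dir, "confusion.csv")
    utils::write.csv(fit$report$confusion, pc)
    pm <- file.path(out_dir, "model.rds")
    saveRDS(fit, pm)
    pk <- file.path(out_dir, "checkpoint.json")
    save_checkpoint(fit, pk)
    outputs <- list(report = pr, confusion = pc, model = pm,
                    checkpoint = pk)
  } else if (subcommand %in% c("evaluate", "predict")) {
    sg_assert(!is.null(cfg$io$model_path) && file.exists(cfg$io$model_path),
              "io.model_path must point to a model.rds from `train`",
              "seizgraph_config_error")
    fit <- readRDS(cfg$io$model_path)
    inputs <- unlist(cfg$io$input)
    sg_assert(length(inputs) >= 1L, "io.input must list EDF file(s)",
              "seizgraph_config_error")
    if (subcommand == "evaluate") {
      fm <- ingest_from_config(cfg)
      score <- score_new_rows(fit, fm$X)
      rep <- compute_metrics(fm$y, as.integer(score > 0.5), score)
      p <- file.path(out_dir, "eval_report.json")
      write_eval_report(rep, p)
      outputs$report <- p
    } else {
      rec <- read_edf(inputs[[1L]])
      res <- classify_recording(fit, rec)
      pt <- file.path(out_dir, "probability_track.csv")
      utils::write.csv(res$track, pt, row.names = FALSE)
      pi_ <- file.path(out_dir, "predicted_intervals.tsv")
      utils::write.table(res$intervals, pi_, sep = "\t",
                         row.names = FALSE, col.names = FALSE)
      outputs$track <- pt; outputs$intervals <- pi_
    }
  }

  outputs$manifest <- write_manifest(cfg, subcommand, inputs, outputs,
                                     out_dir)
  invisible(outputs)
}
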