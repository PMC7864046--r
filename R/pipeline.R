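# Pipeline orchestration: run the stages generate -> preprocess -> segment
# -> features -> resample -> select -> evaluate from a single JSON/YAML
# config with per-stage derived seeds and a reproducibility manifest.

pipeline_stage_keys <- list(
  generate = c("n_classes", "epochs_per_class", "epoch_duration",
               "standing_duration", "channels", "class_params"),
  preprocess = c("emg_band", "emg_order", "emg_smooth_ms", "acc_lowpass",
                 "acc_order", "gyr_lowpass", "gyr_order", "normalize_standing"),
  segment = c("window_ms", "overlap"),
  features = c("delta_rel", "wavelet_mode"),
  resample = c("k", "k_nn"),
  select = c("method", "ninit", "population", "max_iterations", "folds",
             "relief_k", "corr_threshold", "max_features", "tol"),
  evaluate = c("classifiers", "folds"))

validate_pipeline_config <- function(config) {
  allowed_top <- c("seed", "output_dir", "stages", "input")
  unknown <- setdiff(names(config), allowed_top)
  if (length(unknown))
    stop_gfsfan("unknown config key: '", unknown[1], "'")
  st <- config$stages %||% list()
  bad <- setdiff(names(st), names(pipeline_stage_keys))
  if (length(bad)) stop_gfsfan("unknown pipeline stage: '", bad[1], "'")
  for (s in names(st)) {
    u <- setdiff(names(st[[s]]), pipeline_stage_keys[[s]])
    if (length(u))
      stop_gfsfan("unknown config key in stage '", s, "': '", u[1], "'")
  }
  invisible(config)
}

read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_gfsfan("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}

default_pipeline_channels <- function() {
  rbind(data.frame(name = "emg1", modality = "emg", rate = 2000,
                   sensor = NA_character_, axis = NA_character_,
                   stringsAsFactors = FALSE),
        data.frame(name = paste("imu1", rep(c("acc", "gyr"), each = 3),
                                c("x", "y", "z"), sep = "_"),
                   modality = rep(c("acc", "gyr"), each = 3), rate = 200,
                   sensor = "imu1", axis = rep(c("x", "y", "z"), 2),
                   stringsAsFactors = FALSE))
}

#' Run the activity-recognition pipeline from a config
#'
#' Executes the requested stages in order (generate or load a recording,
#' preprocess, segment, extract features, resample, select features,
#' evaluate), writing each artifact plus a manifest (config echo, derived
#' seeds, content hashes) into the output directory. Unknown config keys
#' are rejected by name; rerunning an identical config reproduces identical
#' artifacts.
#'
#' @param config a list, or path to a JSON/YAML file, with keys `seed`,
#'   `output_dir`, optional `input` (recording CSV to load instead of
#'   generating) and `stages` (named blocks; see the package vignette).
#' @param verbose print per-stage progress.
#' @return Invisibly, a list of in-memory stage results; side effect:
#'   artifacts and `manifest.json` under `output_dir`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  seed <- config$seed %||% 1
  out_dir <- config$output_dir %||% stop_gfsfan("config needs output_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- config$stages %||% list()
  res <- list()
  artifacts <- character(0)
  say <- function(...) if (verbose) message(sprintf(...))
  t_all <- Sys.time()

  rec <- NULL
  if (!is.null(config$input)) {
    rec <- read_recording(config$input)
    say("loaded recording: %d channels", length(rec$channels))
  } else if ("generate" %in% names(st)) {
    g <- st$generate
    ch <- if (is.null(g$channels)) default_pipeline_channels()
          else as.data.frame(g$channels, stringsAsFactors = FALSE)
    spec <- synthetic_signal_spec(
      n_classes = g$n_classes %||% 3, channels = ch,
      class_params = if (!is.null(g$class_params))
        as.data.frame(g$class_params, stringsAsFactors = FALSE),
      epoch_duration = g$epoch_duration %||% 4,
      epochs_per_class = g$epochs_per_class %||% 4,
      standing_duration = g$standing_duration %||% 2,
      seed = derive_seed(seed, "generate"))
    rec <- generate_signals(spec)
    f <- file.path(out_dir, "recording.csv")
    write_recording(rec, f)
    artifacts <- c(artifacts, list.files(out_dir, "^recording", full.names = TRUE))
    say("generated recording: %.1f s", recording_duration(rec))
  }

  if ("preprocess" %in% names(st)) {
    if (is.null(rec)) stop_gfsfan("stage 'preprocess' failed: no recording")
    rec <- preprocess(rec, st$preprocess)
    say("preprocessed")
  }

  ws <- NULL
  if ("segment" %in% names(st)) {
    if (is.null(rec)) stop_gfsfan("stage 'segment' failed: no recording")
    ws <- segment(rec, window_ms = st$segment$window_ms %||% 1040,
                  overlap = st$segment$overlap %||% 0.8)
    say("segmented: %d windows", length(ws$epochs))
  }

  ft <- NULL
  if ("features" %in% names(st)) {
    if (is.null(ws)) stop_gfsfan("stage 'features' failed: no window set")
    ft <- extract_features(ws, st$features)
    ft <- normalize_minmax(ft)
    df <- as.data.frame(ft$x)
    df$label <- as.character(ft$labels)
    f <- file.path(out_dir, "features.csv")
    write.csv(df, f, row.names = FALSE)
    artifacts <- c(artifacts, f)
    say("features: %d x %d", nrow(ft$x), ncol(ft$x))
  }

  ens <- NULL
  if ("resample" %in% names(st)) {
    if (is.null(ft)) stop_gfsfan("stage 'resample' failed: no feature table")
    ens <- build_ensemble(ft, k = st$resample$k %||% 10,
                          seed = derive_seed(seed, "resample"),
                          k_nn = st$resample$k_nn %||% 5)
    say("resampled: %d groups at %d per class", ens$k, ens$target)
  }

  sel <- NULL
  if ("select" %in% names(st)) {
    dat <- ens %||% ft
    if (is.null(dat)) stop_gfsfan("stage 'select' failed: no features")
    s <- st$select
    method <- s$method %||% "gfsfan"
    sel <- switch(method,
      gfsfan = run_gfsfan(dat, ga_config(
        ninit = s$ninit %||% 10, population = s$population %||% 80,
        max_iterations = s$max_iterations %||% 100,
        folds = s$folds %||% 10, seed = derive_seed(seed, "select"))),
      relief = list(selected = relief_filter(
        if (inherits(dat, "ResampledEnsemble")) dat$groups[[1]] else dat,
        relief_k = s$relief_k %||% 10,
        corr_threshold = s$corr_threshold %||% 0.95)),
      sfs = sfs(dat, max_features = s$max_features,
                tol = s$tol %||% 1e-4, folds = s$folds %||% 10,
                seed = derive_seed(seed, "select")),
      stop_gfsfan("unknown selection method '", method, "'"))
    f <- file.path(out_dir, "subset.json")
    jsonlite::write_json(list(method = method, selected = sel$selected,
                              fitness = sel$fitness %||% NULL),
                         f, auto_unbox = TRUE, digits = NA, null = "null")
    artifacts <- c(artifacts, f)
    say("selected %d features (%s)", length(sel$selected), method)
  }

  if ("evaluate" %in% names(st)) {
    if (is.null(ft)) stop_gfsfan("stage 'evaluate' failed: no feature table")
    cls <- st$evaluate$classifiers %||% c("knn", "lda", "nb")
    subset <- if (!is.null(sel)) sel$selected else NULL
    ev <- do.call(rbind, lapply(cls, function(cl) {
      r <- evaluate_subset(ft, subset, classifier = cl,
                           folds = st$evaluate$folds %||% 10,
                           seed = derive_seed(seed, "evaluate"))
      data.frame(classifier = cl, fn = length(r$subset), fm = r$fm_all,
                 fm_min = r$fm_min, stringsAsFactors = FALSE)
    }))
    f <- file.path(out_dir, "evaluation.csv")
    write.csv(ev, f, row.names = FALSE)
    artifacts <- c(artifacts, f)
    res$evaluation <- ev
    say("evaluated %d classifiers", nrow(ev))
  }

  manifest <- list(
    config = config,
    seeds = lapply(stats::setNames(nm = names(st)),
                   function(s) derive_seed(seed, s)),
    artifacts = lapply(stats::setNames(nm = basename(artifacts)), function(a)
      unname(tools::md5sum(file.path(out_dir, a)))),
    elapsed_s = as.numeric(difftime(Sys.time(), t_all, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$recording <- rec; res$windows <- ws; res$features <- ft
  res$ensemble <- ens; res$selection <- sel
  invisible(res)
}
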