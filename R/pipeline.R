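# End-to-end orchestration: one config drives
#   simulate -> (train detector + detect | corrupt ground truth)
#   -> encode -> train classifiers -> classify -> report
# with a single master seed and a per-stage log.

defaultPipelineConfig_ <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    synthgen = list(n_episodes = 60L, n_train = 40L, balance = 0.5,
                    duration_s = 20, fps = 12.5),
    detection = list(mode = "oracle_noise",
                     noise = list(dropout_prob = 0.1, clutter_rate = 0.5,
                                  jitter_sd = 2),
                     detector = list(score_min = 0.5, nms_iou = 0.3,
                                     max_frames_per_episode = 10L)),
    takeseq = list(T_fixed = 64L),
    actionclf = list(hidden = 16L, epochs = 200L, lr = 0.05, batch_size = 32L,
                     rule = list(k_consecutive = 3L, proximity_min = 0.8,
                                 pill_confidence_min = 0.5)),
    eval = list(positive_class = "medication")
  )
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills unspecified keys with the
#' package defaults, and validates it. Exactly one detection mode must be
#' selected (`detection$mode` is `"oracle_noise"` -- corrupt ground truth
#' with the noise model -- or `"pixel"` -- render frames, train the
#' detector and run it).
#'
#' @param config Path to a YAML file or a config list.
#' @return The validated, completed config list.
#' @export
readPipelineConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(defaultPipelineConfig_(), config)
  mode <- cfg$detection$mode
  if (length(mode) != 1L || !mode %in% c("oracle_noise", "pixel")) {
    stop("config key 'detection.mode' must select exactly one of ",
         "'oracle_noise' or 'pixel'", call. = FALSE)
  }
  sg <- cfg$synthgen
  for (key in c("n_episodes", "n_train", "balance")) {
    if (is.null(sg[[key]])) {
      stop("missing config key 'synthgen.", key, "'", call. = FALSE)
    }
  }
  cfg
}

configHash_ <- function(cfg) {
  cfg$output_dir <- NULL  # the run location is not part of the experiment
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null"), tf)
  unname(tools::md5sum(tf))
}

#' Run the full recognition pipeline
#'
#' Simulates a labeled episode dataset, produces per-episode detection
#' streams (oracle-noise or pixel mode), encodes take sequences, trains
#' the LSTM classifier and the four baselines on the training partition,
#' classifies the test partition (including the rule-based recognizer),
#' and writes a comparison report, the LSTM confusion matrix, predictions
#' and a machine-readable summary. Rerunning with the same config
#' reproduces identical summary values.
#'
#' @param config Config list or YAML path (see [readPipelineConfig()]).
#' @param output_dir Run directory; overrides the config's `output_dir`;
#'   `NULL` keeps everything in memory.
#' @return Invisibly, a list with `summary` (metrics per model), `report`
#'   (data frame), `confusion` (LSTM confusion matrix), `predictions`,
#'   and when in pixel mode `detector_eval`.
#' @export
runPipeline <- function(config = list(), output_dir = NULL) {
  cfg <- readPipelineConfig(config)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  out <- cfg$output_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    message(line)
    log_lines <<- c(log_lines, line)
  }
  hash <- configHash_(cfg)
  seeds <- derive_seeds_(cfg$seed, 4L)

  # stage 1: simulate ---------------------------------------------------
  sg <- cfg$synthgen
  grammar <- defaultGrammar()
  ds <- makeDataset(grammar, n_episodes = sg$n_episodes, balance = sg$balance,
                    n_train = sg$n_train, seed = seeds[1],
                    duration_s = sg$duration_s, fps = sg$fps,
                    output_dir = out)
  n_frames_total <- sum(vapply(ds$episodes, nFrames, numeric(1)))
  logf("simulate: %d episodes (%d train / %d test), %d frames",
       nrow(ds$manifest), sum(ds$manifest$partition == "train"),
       sum(ds$manifest$partition == "test"), n_frames_total)

  # stage 2: detection streams ------------------------------------------
  mode <- cfg$detection$mode
  detector_eval <- NULL
  ep_seeds <- derive_seeds_(seeds[2], length(ds$episodes))
  if (mode == "oracle_noise") {
    np <- do.call(noiseParams, cfg$detection$noise)
    streams <- lapply(seq_along(ds$episodes), function(i) {
      ep <- ds$episodes[[i]]
      sz <- frameSize(ep)
      corruptDetections(groundTruth(ep), np, seed = ep_seeds[i],
                        n_frames = nFrames(ep),
                        frame_width = sz[1], frame_height = sz[2])
    })
  } else {
    model <- trainDetector(ds, config = cfg$detection$detector,
                           seed = seeds[2])
    if (!is.null(out)) saveDetectorModel(model, file.path(out, "detector.json"))
    streams <- lapply(ds$episodes, detectEpisode, model = model)
    test_ids <- ds$manifest$episode_id[ds$manifest$partition == "test"]
    all_gt <- do.call(rbind, lapply(test_ids, function(id) {
      g <- groundTruth(ds$episodes[[id]])
      g$frame <- g$frame + 1e6 * match(id, test_ids)  # disambiguate episodes
      g
    }))
    all_dt <- do.call(rbind, lapply(test_ids, function(id) {
      d <- streams[[match(id, names(ds$episodes))]]
      if (nrow(d)) d$frame <- d$frame + 1e6 * match(id, test_ids)
      d
    }))
    detector_eval <- evalDetections(all_dt, all_gt)
    if (!is.null(out)) {
      write.csv(detector_eval, file.path(out, "detector_eval.csv"),
                row.names = FALSE)
    }
  }
  names(streams) <- names(ds$episodes)
  logf("detect (%s): %d detections over %d episodes", mode,
       sum(vapply(streams, nrow, numeric(1))), length(streams))

  # stage 3: encode -----------------------------------------------------
  seqs <- lapply(names(streams), function(id) {
    ep <- ds$episodes[[id]]
    sz <- frameSize(ep)
    detectionsToSequence(streams[[id]], nFrames(ep), sz[1], sz[2],
                         T_fixed = cfg$takeseq$T_fixed, episode_id = id,
                         label = episodeLabel(ep))
  })
  names(seqs) <- names(streams)
  agg <- t(vapply(seqs, aggregateFeatures,
                  numeric(2L * length(channelNames_()))))
  logf("encode: %d sequences of length %d x %d channels", length(seqs),
       cfg$takeseq$T_fixed, length(channelNames_()))

  # stage 4: train ------------------------------------------------------
  is_train <- ds$manifest$partition == "train"
  train_ids <- ds$manifest$episode_id[is_train]
  test_ids <- ds$manifest$episode_id[!is_train]
  ac <- cfg$actionclf
  lstm <- trainActionClassifier(seqs[train_ids],
                                config = list(hidden = ac$hidden,
                                              epochs = ac$epochs, lr = ac$lr,
                                              batch_size = ac$batch_size,
                                              seed = seeds[3]))
  baselines <- fitBaselines(agg[train_ids, , drop = FALSE],
                            ds$manifest$label[is_train], seed = seeds[4])
  if (!is.null(out)) saveLSTMModel(lstm, file.path(out, "lstm.json"))
  logf("train: LSTM %d epochs (final loss %.4f) + %d baselines on %d episodes",
       ac$epochs, tail(lstm@history, 1), length(baselines), length(train_ids))

  # stage 5: classify ---------------------------------------------------
  y_true <- ds$manifest$label[!is_train]
  lstm_pred <- classifySequences(lstm, seqs[test_ids])
  predictions <- list(lstm = lstm_pred$label)
  for (nm in names(baselines)) {
    predictions[[nm]] <- predictBaseline(baselines[[nm]],
                                         agg[test_ids, , drop = FALSE])$label
  }
  rule <- do.call(ruleParams, ac$rule)
  predictions$rule_based <- vapply(test_ids, function(id) {
    ep <- ds$episodes[[id]]
    sz <- frameSize(ep)
    ruleBasedClassify(streams[[id]], nFrames(ep), rule, sz[1], sz[2])
  }, character(1))
  logf("classify: %d test episodes x %d models", length(test_ids),
       length(predictions))

  # stage 6: report -----------------------------------------------------
  report <- comparisonReport(predictions, y_true,
                             positive_class = cfg$eval$positive_class)
  cm <- confusion(y_true, predictions$lstm, cfg$eval$positive_class)
  summary <- list(
    format_version = MODEL_FORMAT_VERSION_,
    config_hash = hash,
    seed = cfg$seed,
    detection_mode = mode,
    n_train = length(train_ids), n_test = length(test_ids),
    metrics = setNames(lapply(names(predictions), function(nm) {
      classMetrics(confusion(y_true, predictions[[nm]],
                             cfg$eval$positive_class))
    }), names(predictions))
  )
  if (!is.null(detector_eval)) {
    summary$detector_map <- detector_eval$ap[detector_eval$category == "Average"]
  }
  if (!is.null(out)) {
    write.csv(report, file.path(out, "report.csv"), row.names = FALSE)
    writeConfusionCSV(cm, file.path(out, "confusion.csv"))
    pred_df <- data.frame(episode_id = test_ids, truth = y_true,
                          lstm_score = lstm_pred$score,
                          as.data.frame(predictions))
    write.csv(pred_df, file.path(out, "predictions.csv"), row.names = FALSE)
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA),
               file.path(out, "summary.json"))
    writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                                null = "null"),
               file.path(out, "config.json"))
  }
  logf("report: %d model rows, LSTM accuracy %.3f", nrow(report),
       summary$metrics$lstm$accuracy)
  if (!is.null(out)) writeLines(log_lines, file.path(out, "run.log"))
  invisible(list(summary = summary, report = report, confusion = cm,
                 predictions = predictions, detector_eval = detector_eval,
                 lstm = lstm))
}
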