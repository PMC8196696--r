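# Plain-text interchange formats: JSON-lines detection/ground-truth
# streams (one record per frame) and JSON model serializations.

#' Write boxes as a JSON-lines detection stream
#'
#' One JSON object per frame:
#' `{"episode_id":..., "frame":..., "boxes":[{"category":..., "x_min":...,
#' ..., "score":...}]}`. The `score` field is present only when the input
#' has one (ground truth has none). Frames without boxes are written with
#' an empty `boxes` array so the stream records the episode length.
#'
#' @param boxes Data frame with `frame`, `category`, corner columns and
#'   optionally `score`.
#' @param path Output file.
#' @param episode_id Identifier written into every record.
#' @param n_frames Total frame count (records are emitted for frames
#'   `0..n_frames-1`); defaults to `max(boxes$frame) + 1`.
#' @return Invisibly, `path`.
#' @export
writeDetectionsJSONL <- function(boxes, path, episode_id = "episode",
                                 n_frames = if (nrow(boxes)) max(boxes$frame) + 1L else 0L) {
  has_score <- "score" %in% names(boxes)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(n_frames) - 1L) {
    rows <- boxes[boxes$frame == f, , drop = FALSE]
    bx <- lapply(seq_len(nrow(rows)), function(k) {
      b <- list(category = rows$category[k],
                x_min = rows$x_min[k], y_min = rows$y_min[k],
                x_max = rows$x_max[k], y_max = rows$y_max[k])
      if (has_score) b$score <- rows$score[k]
      b
    })
    rec <- list(episode_id = episode_id, frame = f, boxes = bx)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read a JSON-lines detection stream
#'
#' @param path File written by [writeDetectionsJSONL()].
#' @return A list with `boxes` (data frame; includes `score` if present
#'   in the stream), `episode_id`, and `n_frames`.
#' @export
readDetectionsJSONL <- function(path) {
  lines <- readLines(path)
  rows <- list()
  episode_id <- NA_character_
  n_frames <- 0L
  for (ln in lines) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    episode_id <- rec$episode_id
    n_frames <- max(n_frames, rec$frame + 1L)
    for (b in rec$boxes) {
      b$frame <- rec$frame
      rows[[length(rows) + 1L]] <- as.data.frame(b, stringsAsFactors = FALSE)
    }
  }
  boxes <- if (length(rows)) do.call(rbind, rows) else emptyDetections_()
  cols <- intersect(c("frame", "category", "x_min", "y_min", "x_max", "y_max",
                      "score"), names(boxes))
  list(boxes = boxes[, cols, drop = FALSE], episode_id = episode_id,
       n_frames = n_frames)
}

MODEL_FORMAT_VERSION_ <- "1.0"

#' Serialize a detector model to JSON
#'
#' Weights are written as nested numeric arrays together with a
#' `format_version` field.
#'
#' @param model A [DetectorModel-class].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
saveDetectorModel <- function(model, path) {
  obj <- list(
    format_version = MODEL_FORMAT_VERSION_,
    type = "detector",
    categories = model@categories,
    feature_spec = model@featureSpec,
    weights = model@weights,
    biases = model@biases,
    regressors = model@regressors,
    score_min = model@scoreMin,
    nms_iou = model@nmsIoU
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' Read a detector model from JSON
#' @param path File written by [saveDetectorModel()].
#' @return A [DetectorModel-class].
#' @export
readDetectorModel <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  regs <- lapply(obj$regressors, function(R) {
    if (is.null(R)) NULL else as.matrix(R)
  })
  new("DetectorModel", categories = obj$categories,
      featureSpec = obj$feature_spec,
      weights = as.matrix(obj$weights), biases = as.numeric(obj$biases),
      regressors = regs, scoreMin = obj$score_min, nmsIoU = obj$nms_iou)
}

#' Serialize an LSTM sequence classifier to JSON
#' @param model An [LSTMModel-class].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
saveLSTMModel <- function(model, path) {
  obj <- list(format_version = MODEL_FORMAT_VERSION_, type = "lstm",
              input_size = model@inputSize, hidden_size = model@hiddenSize,
              params = model@params, history = model@history)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read an LSTM sequence classifier from JSON
#' @param path File written by [saveLSTMModel()].
#' @return An [LSTMModel-class].
#' @export
readLSTMModel <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  p <- obj$params
  for (nm in names(p)) {
    p[[nm]] <- if (is.matrix(p[[nm]])) p[[nm]] else as.numeric(p[[nm]])
  }
  new("LSTMModel", inputSize = as.integer(obj$input_size),
      hiddenSize = as.integer(obj$hidden_size), params = p,
      history = as.numeric(obj$history))
}
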