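# "Sequence of takes": per-frame detection streams converted into
# fixed-width feature vectors for the temporal classifier, plus
# aggregate features for the non-sequential baselines.
#
# Channel layout (20 channels, fixed order):
#   1-9   per-category max detection confidence
#   10-18 area fraction of that max-confidence box
#   19    pill-to-open-mouth proximity
#   20    pill-in-hand indicator

channelNames_ <- function() {
  c(paste0("conf_", objectCategories()),
    paste0("area_", objectCategories()),
    "pill_mouth_proximity", "pill_in_hand")
}

#' Encode one frame's detections as a feature vector
#'
#' For each category the confidence channel is the maximum confidence
#' among that category's detections (0 if absent) and the area channel is
#' the frame-area fraction of that max-confidence box. The proximity
#' channel is 1.0 when the pill center lies inside the open-mouth box and
#' otherwise decays as `max(0, 1 - d/D)` with `d` the pill-to-open-mouth
#' center distance and `D` the open-mouth box diagonal. The pill-in-hand
#' indicator is 1 when the (max-confidence) pill box overlaps any hand
#' box. Encoding is purely local to the frame.
#'
#' @param dets Detections of a single frame (`category`, corners, `score`;
#'   a missing `score` column is treated as confidence 1).
#' @param frame_width,frame_height Frame size in pixels.
#' @return Named numeric vector of length 20 (all zero for an empty
#'   detection list).
#' @export
encodeFrame <- function(dets, frame_width = 128, frame_height = 128) {
  v <- setNames(numeric(length(channelNames_())), channelNames_())
  if (is.null(dets) || nrow(dets) == 0L) return(v)
  if (any(dets$x_max > frame_width) || any(dets$y_max > frame_height) ||
      any(dets$x_min < 0) || any(dets$y_min < 0)) {
    stop("detection box exceeds frame bounds", call. = FALSE)
  }
  if (!"score" %in% names(dets)) dets$score <- 1
  cats <- objectCategories()
  best <- list()
  for (cc in unique(dets$category)) {
    rows <- dets[dets$category == cc, , drop = FALSE]
    k <- which.max(rows$score)
    best[[cc]] <- rows[k, , drop = FALSE]
    ci <- match(cc, cats)
    v[ci] <- rows$score[k]
    v[9 + ci] <- boxArea(rows[k, , drop = FALSE]) / (frame_width * frame_height)
  }
  pill <- best[["pill"]]
  om <- best[["open_mouth"]]
  if (!is.null(pill) && !is.null(om)) {
    pcx <- (pill$x_min + pill$x_max) / 2
    pcy <- (pill$y_min + pill$y_max) / 2
    if (pcx >= om$x_min && pcx < om$x_max && pcy >= om$y_min && pcy < om$y_max) {
      v["pill_mouth_proximity"] <- 1
    } else {
      d <- sqrt((pcx - (om$x_min + om$x_max) / 2)^2 +
                (pcy - (om$y_min + om$y_max) / 2)^2)
      D <- sqrt((om$x_max - om$x_min)^2 + (om$y_max - om$y_min)^2)
      v["pill_mouth_proximity"] <- max(0, 1 - d / D)
    }
  }
  if (!is.null(pill)) {
    hands <- dets[dets$category == "hand", , drop = FALSE]
    if (nrow(hands) && any(iouMany_(pill, hands) > 0)) v["pill_in_hand"] <- 1
  }
  v
}

#' Build a fixed-length take sequence from per-frame features
#'
#' Longer inputs are uniformly subsampled: row `i` (0-based) of the
#' output is input row `floor(i * L / T_fixed)`, so selected original
#' indices are strictly increasing and late events survive. Shorter
#' inputs are zero-padded at the tail with `mask = FALSE`.
#'
#' @param frames Matrix (rows = frames, 20 columns) or list of
#'   [encodeFrame()] vectors; must be non-empty.
#' @param T_fixed Output length, >= 1; default 64.
#' @param episode_id,label Metadata stored on the sequence.
#' @return A [TakeSequence-class].
#' @export
buildSequence <- function(frames, T_fixed = 64L, episode_id = "episode",
                          label = NA_character_) {
  if (is.list(frames) && !is.data.frame(frames)) {
    frames <- do.call(rbind, frames)
  }
  frames <- as.matrix(frames)
  L <- nrow(frames)
  if (is.null(L) || L == 0L) stop("empty frame list", call. = FALSE)
  if (T_fixed < 1L) stop("T_fixed must be >= 1", call. = FALSE)
  if (ncol(frames) != length(channelNames_())) {
    stop("frame features must have the ", length(channelNames_()),
         "-channel layout", call. = FALSE)
  }
  if (L > T_fixed) {
    idx <- floor((seq_len(T_fixed) - 1L) * L / T_fixed) + 1L
    ch <- frames[idx, , drop = FALSE]
    mask <- rep(TRUE, T_fixed)
  } else {
    ch <- rbind(frames, matrix(0, nrow = T_fixed - L, ncol = ncol(frames)))
    mask <- c(rep(TRUE, L), rep(FALSE, T_fixed - L))
  }
  colnames(ch) <- channelNames_()
  rownames(ch) <- NULL
  new("TakeSequence", episodeId = episode_id, channels = ch, mask = mask,
      label = label)
}

#' Aggregate a take sequence for non-sequential classifiers
#'
#' Per-channel maximum and mean over the unmasked (real) rows; padding
#' rows never contribute.
#'
#' @param seq A [TakeSequence-class] with at least one unmasked row.
#' @return Named numeric vector of length 40 (`max_*` then `mean_*`).
#' @export
aggregateFeatures <- function(seq) {
  rows <- seq@channels[seq@mask, , drop = FALSE]
  if (nrow(rows) == 0L) stop("all rows masked", call. = FALSE)
  mx <- apply(rows, 2, max)
  mn <- colMeans(rows)
  setNames(c(mx, mn), c(paste0("max_", channelNames_()),
                        paste0("mean_", channelNames_())))
}

#' Encode a detection stream into a take sequence
#'
#' Convenience wrapper: per-frame [encodeFrame()] over `0..n_frames-1`
#' followed by [buildSequence()].
#'
#' @param dets Detection data frame spanning one episode.
#' @param n_frames Episode length in frames.
#' @param frame_width,frame_height Frame size.
#' @param T_fixed Sequence length after resampling.
#' @param episode_id,label Metadata.
#' @return A [TakeSequence-class].
#' @export
detectionsToSequence <- function(dets, n_frames, frame_width = 128,
                                 frame_height = 128, T_fixed = 64L,
                                 episode_id = "episode",
                                 label = NA_character_) {
  mat <- matrix(0, nrow = n_frames, ncol = length(channelNames_()))
  if (nrow(dets)) {
    byf <- split(dets, factor(dets$frame, levels = seq_len(n_frames) - 1L))
    nonempty <- which(vapply(byf, nrow, integer(1)) > 0L)
    for (f in nonempty) {
      mat[f, ] <- encodeFrame(byf[[f]], frame_width, frame_height)
    }
  }
  buildSequence(mat, T_fixed = T_fixed, episode_id = episode_id, label = label)
}

#' @describeIn TakeSequence-class Channel matrix (`T x 20`).
#' @param x A `TakeSequence`.
#' @export
seqChannels <- function(x) x@channels

#' @describeIn TakeSequence-class Padding mask (`TRUE` = real frame).
#' @export
seqMask <- function(x) x@mask

#' @describeIn TakeSequence-class Stored class label (may be `NA`).
#' @export
seqLabel <- function(x) x@label

#' @name TakeSequence-class
#' @aliases TakeSequence
#' @title Sequence of takes
#' @description Fixed-length per-frame feature matrix ("sequence of
#'   takes") extracted from an episode's detection stream, with a padding
#'   mask and optional label. Built by [buildSequence()] /
#'   [detectionsToSequence()].
NULL

setMethod("show", "TakeSequence", function(object) {
  cat(sprintf("TakeSequence '%s': T=%d (%d real), %d channels, label=%s\n",
              object@episodeId, nrow(object@channels), sum(object@mask),
              ncol(object@channels), object@label))
})

#' Write a take sequence as CSV
#'
#' Columns: `frame_slot` (0-based), `mask`, then the 20 named channels.
#' A sidecar JSON (same path + `.meta.json`) records the layout name,
#' version and label.
#'
#' @param seq A [TakeSequence-class].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
writeSequenceCSV <- function(seq, path) {
  df <- data.frame(frame_slot = seq_len(nrow(seq@channels)) - 1L,
                   mask = seq@mask)
  df <- cbind(df, as.data.frame(seq@channels))
  write.csv(df, path, row.names = FALSE)
  meta <- list(layout = "conf9_area9_prox_hand", layout_version = "1.0",
               episode_id = seq@episodeId, label = seq@label)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE),
             paste0(path, ".meta.json"))
  invisible(path)
}
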