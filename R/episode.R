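# Accessors and display for Episode objects.

#' @name Episode-class
#' @aliases Episode
#' @title Synthetic wrist-camera episode
#' @description A labeled synthetic clip: per-frame scenes (object
#'   placements), ground-truth boxes, and the step timeline that
#'   generated them. Created by [sampleEpisode()].
NULL

setGeneric("episodeId", function(x) standardGeneric("episodeId"))
setGeneric("episodeLabel", function(x) standardGeneric("episodeLabel"))
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
setGeneric("stepTimeline", function(x) standardGeneric("stepTimeline"))
setGeneric("frameScene", function(x, i) standardGeneric("frameScene"))

#' @describeIn Episode-class Episode identifier.
#' @param x An `Episode`.
#' @export
setMethod("episodeId", "Episode", function(x) x@episodeId)

#' @describeIn Episode-class Class label (`"medication"`/`"non_medication"`).
#' @export
setMethod("episodeLabel", "Episode", function(x) x@label)

#' @describeIn Episode-class Number of frames.
#' @export
setMethod("nFrames", "Episode", function(x) length(x@frames))

#' @describeIn Episode-class Ground-truth boxes as a data frame with
#'   columns `frame` (0-based), `category`, `x_min`, `y_min`, `x_max`,
#'   `y_max`.
#' @export
setMethod("groundTruth", "Episode", function(x) x@groundTruth)

#' @describeIn Episode-class Step timeline: `state`, `start_frame`,
#'   `end_frame` (half-open frame intervals tiling the episode).
#' @export
setMethod("stepTimeline", "Episode", function(x) x@stepTimeline)

#' @describeIn Episode-class Scene of frame `i` (1-based): a list with
#'   `placements` and `background_seed`.
#' @param i Frame number, 1-based.
#' @export
setMethod("frameScene", "Episode", function(x, i) x@frames[[i]])

setMethod("show", "Episode", function(object) {
  cat(sprintf("Episode '%s' (%s): %d frames @ %.3g fps, %dx%d px\n",
              object@episodeId, object@label, length(object@frames),
              object@fps, as.integer(object@frameWidth),
              as.integer(object@frameHeight)))
  cat(sprintf("  %d ground-truth boxes over %d steps: %s\n",
              nrow(object@groundTruth), nrow(object@stepTimeline),
              paste(object@stepTimeline$state, collapse = " -> ")))
})

#' Frame dimensions of an episode
#' @param x An `Episode`.
#' @return `c(width, height)` in pixels.
#' @export
frameSize <- function(x) c(x@frameWidth, x@frameHeight)
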