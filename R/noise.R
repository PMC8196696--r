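# Detector-noise model: corrupts ground-truth boxes into realistic
# detection streams so the sequence classifier can be trained and tested
# without running (or even having) a pixel detector. The noise channels
# mimic what an imperfect per-frame detector produces: missed objects
# (dropout), spurious boxes (clutter), localization error (jitter) and
# graded confidences.

#' Detector-noise parameters
#'
#' @param dropout_prob Probability that a true box is missed, in `[0, 1]`.
#' @param clutter_rate Expected number of spurious (false-positive) boxes
#'   per frame; Poisson mean, >= 0.
#' @param jitter_sd Gaussian localization noise per box coordinate, in
#'   pixels, >= 0.
#' @param conf_true Beta shape parameters `c(shape1, shape2)` of the
#'   confidence law for surviving true boxes, or `NULL` for a
#'   deterministic confidence of 1.0.
#' @param conf_clutter Beta shape parameters of the clutter confidence law.
#' @return A list of class `"NoiseParams"`.
#' @seealso [noiseFree()], [corruptDetections()]
#' @export
noiseParams <- function(dropout_prob = 0.1, clutter_rate = 0.5, jitter_sd = 2,
                        conf_true = c(8, 2), conf_clutter = c(2, 5)) {
  if (dropout_prob < 0 || dropout_prob > 1) {
    stop("dropout_prob must be in [0,1]", call. = FALSE)
  }
  if (clutter_rate < 0) stop("clutter_rate must be >= 0", call. = FALSE)
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  structure(list(dropout_prob = dropout_prob, clutter_rate = clutter_rate,
                 jitter_sd = jitter_sd, conf_true = conf_true,
                 conf_clutter = conf_clutter),
            class = "NoiseParams")
}

#' Zero-noise parameters
#'
#' No dropout, no clutter, no jitter, confidence exactly 1.0: the output
#' of [corruptDetections()] equals its input.
#' @return A `"NoiseParams"` list.
#' @export
noiseFree <- function() {
  noiseParams(dropout_prob = 0, clutter_rate = 0, jitter_sd = 0,
              conf_true = NULL)
}

#' Corrupt ground-truth boxes into a simulated detection stream
#'
#' Applies the noise model to per-frame ground truth: each true box
#' survives with probability `1 - dropout_prob`, keeps its category, has
#' its coordinates jittered, and gets a confidence drawn from the
#' true-box law; each frame additionally receives `Poisson(clutter_rate)`
#' clutter boxes with uniform random category, random geometry and the
#' clutter confidence law. Confidences are always clamped to `[0, 1]`.
#'
#' @param gt Ground-truth data frame (`frame`, `category`, `x_min`,
#'   `y_min`, `x_max`, `y_max`), e.g. from [groundTruth()].
#' @param noise A [noiseParams()] object.
#' @param seed Integer seed; identical inputs and seed give identical
#'   output.
#' @param n_frames Number of frames the stream spans (clutter is drawn
#'   for every frame, including ones with no true boxes). Defaults to
#'   `max(gt$frame) + 1`.
#' @param frame_width,frame_height Frame bounds for jitter clipping and
#'   clutter placement.
#' @return Detection data frame with an added `score` column.
#' @examples
#' ep <- sampleEpisode(defaultGrammar(), "medication", seed = 1)
#' dets <- corruptDetections(groundTruth(ep), noiseParams(), seed = 2)
#' head(dets)
#' @export
corruptDetections <- function(gt, noise = noiseParams(), seed = 1L,
                              n_frames = if (nrow(gt)) max(gt$frame) + 1L else 0L,
                              frame_width = 128, frame_height = 128) {
  stopifnot(inherits(noise, "NoiseParams"))
  with_seed_(seed, {
    keep <- if (nrow(gt)) runif(nrow(gt)) >= noise$dropout_prob else logical(0)
    out <- gt[keep, , drop = FALSE]
    if (nrow(out)) {
      if (noise$jitter_sd > 0) {
        jit <- matrix(round(rnorm(4L * nrow(out), 0, noise$jitter_sd)), ncol = 4)
        out$x_min <- out$x_min + jit[, 1]
        out$y_min <- out$y_min + jit[, 2]
        out$x_max <- out$x_max + jit[, 3]
        out$y_max <- out$y_max + jit[, 4]
        out <- clipBox_(out, frame_width, frame_height)
      }
      out$score <- if (is.null(noise$conf_true)) {
        rep(1.0, nrow(out))
      } else {
        pmin(pmax(rbeta(nrow(out), noise$conf_true[1], noise$conf_true[2]), 0), 1)
      }
    } else {
      out$score <- numeric(0)
    }
    clutter <- NULL
    if (noise$clutter_rate > 0 && n_frames > 0L) {
      n_cl <- rpois(n_frames, noise$clutter_rate)
      total <- sum(n_cl)
      if (total > 0L) {
        w <- round(runif(total, 8, 40))
        h <- round(runif(total, 8, 40))
        x0 <- round(runif(total, 0, frame_width - w))
        y0 <- round(runif(total, 0, frame_height - h))
        clutter <- data.frame(
          frame = rep(seq_len(n_frames) - 1L, n_cl),
          category = sample(objectCategories(), total, replace = TRUE),
          x_min = x0, y_min = y0, x_max = x0 + w, y_max = y0 + h,
          score = pmin(pmax(rbeta(total, noise$conf_clutter[1],
                                  noise$conf_clutter[2]), 0), 1))
        clutter <- clipBox_(clutter, frame_width, frame_height)
      }
    }
    res <- rbind(out, clutter)
    if (is.null(res) || nrow(res) == 0L) return(emptyDetections_())
    res <- res[order(res$frame, -res$score, res$x_min, res$y_min), , drop = FALSE]
    rownames(res) <- NULL
    res
  })
}
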