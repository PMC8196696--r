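# Rule-based pill-to-mouth recognizer: an episode counts as medication
# taking only if a pill is confirmed inside the open mouth over a series
# of consecutive shots; a pill merely held in the hand is not taking it.

#' Rule-recognizer parameters
#'
#' @param k_consecutive Number of consecutive qualifying frames required
#'   (>= 1); default 3.
#' @param proximity_min Minimum pill-to-open-mouth proximity, `[0, 1]`;
#'   default 0.8.
#' @param pill_confidence_min Minimum pill detection confidence; default
#'   0.5.
#' @return A list of class `"RuleParams"`.
#' @export
ruleParams <- function(k_consecutive = 3L, proximity_min = 0.8,
                       pill_confidence_min = 0.5) {
  if (k_consecutive < 1L) stop("k_consecutive must be >= 1", call. = FALSE)
  if (proximity_min < 0 || proximity_min > 1 ||
      pill_confidence_min < 0 || pill_confidence_min > 1) {
    stop("thresholds must be in [0,1]", call. = FALSE)
  }
  structure(list(k_consecutive = as.integer(k_consecutive),
                 proximity_min = proximity_min,
                 pill_confidence_min = pill_confidence_min),
            class = "RuleParams")
}

#' Rule-based episode classification
#'
#' Classifies an episode as `"medication"` iff at least `k_consecutive`
#' consecutive frames each contain a pill detection with confidence >=
#' `pill_confidence_min` whose pill-to-open-mouth proximity (see
#' [encodeFrame()]) is >= `proximity_min`; otherwise `"non_medication"`.
#' An empty detection stream is `"non_medication"`.
#'
#' @param dets Detection data frame for one episode (`frame`, `category`,
#'   corners, `score`).
#' @param n_frames Episode length in frames.
#' @param rule A [ruleParams()] object.
#' @param frame_width,frame_height Frame size.
#' @return `"medication"` or `"non_medication"`.
#' @export
ruleBasedClassify <- function(dets, n_frames, rule = ruleParams(),
                              frame_width = 128, frame_height = 128) {
  stopifnot(inherits(rule, "RuleParams"))
  if (is.null(dets) || nrow(dets) == 0L || n_frames == 0L) {
    return("non_medication")
  }
  run <- 0L
  byf <- split(dets, factor(dets$frame, levels = seq_len(n_frames) - 1L))
  for (f in seq_len(n_frames)) {
    v <- encodeFrame(byf[[f]], frame_width, frame_height)
    hit <- v[["conf_pill"]] >= rule$pill_confidence_min &&
      v[["pill_mouth_proximity"]] >= rule$proximity_min
    run <- if (hit) run + 1L else 0L
    if (run >= rule$k_consecutive) return("medication")
  }
  "non_medication"
}
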