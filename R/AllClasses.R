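# S4 class definitions and validity methods for the package's central
# data objects.

#' @rdname EpisodeGrammar-class
#' @exportClass EpisodeGrammar
setClass("EpisodeGrammar",
  representation(
    states      = "list",     # per-state: name, dur_range, emissions, classes
    frameWidth  = "numeric",
    frameHeight = "numeric",
    anchors     = "list",     # category -> base placement box
    pillAnchors = "list",     # state-specific pill placement overrides
    jitterSd    = "numeric",  # per-frame placement jitter (px)
    contactStates = "character"  # states implying pill-to-mouth contact
  )
)

setValidity("EpisodeGrammar", function(object) {
  msgs <- character(0)
  cats <- objectCategories()
  nm <- vapply(object@states, function(s) s$name, character(1))
  if (anyDuplicated(nm)) msgs <- c(msgs, "duplicate state names")
  for (s in object@states) {
    if (s$dur_range[1] < 1) {
      msgs <- c(msgs, sprintf("state '%s': minimum duration must be >= 1", s$name))
    }
    if (s$dur_range[2] < s$dur_range[1]) {
      msgs <- c(msgs, sprintf("state '%s': duration range reversed", s$name))
    }
    p <- s$emissions
    if (any(p < 0 | p > 1)) {
      msgs <- c(msgs, sprintf("state '%s': emission probabilities outside [0,1]", s$name))
    }
    if (length(setdiff(names(p), cats)) > 0L) {
      msgs <- c(msgs, sprintf("state '%s': unknown emission category", s$name))
    }
    for (pair in exclusivePairs_()) {
      pr <- p[intersect(pair, names(p))]
      if (sum(pr > 0) > 1L) {
        msgs <- c(msgs, sprintf(
          "state '%s': mutually exclusive categories %s both emitted",
          s$name, paste(pair, collapse = "/")))
      }
    }
  }
  for (cs in object@contactStates) {
    s <- object@states[[match(cs, nm)]]
    if (is.null(s)) {
      msgs <- c(msgs, sprintf("contact state '%s' not in grammar", cs))
    } else if ("non_medication" %in% s$classes) {
      msgs <- c(msgs, sprintf("contact state '%s' must be medication-only", cs))
    }
  }
  if (object@frameWidth < 32 || object@frameHeight < 32) {
    msgs <- c(msgs, "frame must be at least 32x32")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname Episode-class
#' @exportClass Episode
setClass("Episode",
  representation(
    episodeId    = "character",
    label        = "character",   # "medication" | "non_medication"
    fps          = "numeric",
    frames       = "list",        # per-frame scenes: placements + background_seed
    groundTruth  = "data.frame",  # frame, category, x_min..y_max (frame 0-based)
    stepTimeline = "data.frame",  # state, start_frame, end_frame (half-open)
    frameWidth   = "numeric",
    frameHeight  = "numeric"
  )
)

setValidity("Episode", function(object) {
  msgs <- character(0)
  if (!object@label %in% c("medication", "non_medication")) {
    msgs <- c(msgs, "label must be 'medication' or 'non_medication'")
  }
  n <- length(object@frames)
  tl <- object@stepTimeline
  if (nrow(tl) > 0L) {
    if (tl$start_frame[1] != 0L || tl$end_frame[nrow(tl)] != n ||
        (nrow(tl) > 1L && any(tl$start_frame[-1] != tl$end_frame[-nrow(tl)]))) {
      msgs <- c(msgs, "step timeline must tile [0, frame_count) without gaps")
    }
  }
  gt <- object@groundTruth
  if (nrow(gt) > 0L) {
    if (any(gt$frame < 0L) || any(gt$frame >= n)) {
      msgs <- c(msgs, "ground-truth frame index outside episode")
    }
    if (any(gt$x_max > object@frameWidth) || any(gt$y_max > object@frameHeight)) {
      msgs <- c(msgs, "ground-truth box outside frame bounds")
    }
  }
  msgs <- c(msgs, character(0))
  if (length(msgs)) msgs else TRUE
})

#' @rdname DetectorModel-class
#' @exportClass DetectorModel
setClass("DetectorModel",
  representation(
    categories  = "character",
    featureSpec = "list",     # crop side, hist bins, feature length
    weights     = "matrix",   # n_category x D feature weights
    biases      = "numeric",  # n_category
    regressors  = "list",     # category -> (D+1) x 4 coefficient matrix (or NULL)
    scoreMin    = "numeric",
    nmsIoU      = "numeric"
  )
)

setValidity("DetectorModel", function(object) {
  msgs <- character(0)
  D <- object@featureSpec$length
  if (ncol(object@weights) != D) msgs <- c(msgs, "weight length != feature length")
  if (nrow(object@weights) != length(object@categories)) {
    msgs <- c(msgs, "one weight row per category required")
  }
  if (length(object@biases) != length(object@categories)) {
    msgs <- c(msgs, "one bias per category required")
  }
  if (object@scoreMin < 0 || object@scoreMin > 1) {
    msgs <- c(msgs, "score_min must be in [0,1]")
  }
  if (object@nmsIoU <= 0 || object@nmsIoU >= 1) {
    msgs <- c(msgs, "nms_iou must be in (0,1)")
  }
  for (nm in names(object@regressors)) {
    R <- object@regressors[[nm]]
    if (!is.null(R) && (nrow(R) != D + 1L || ncol(R) != 4L)) {
      msgs <- c(msgs, sprintf("regressor for '%s' must be (D+1) x 4", nm))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname TakeSequence-class
#' @exportClass TakeSequence
setClass("TakeSequence",
  representation(
    episodeId = "character",
    channels  = "matrix",    # T x 20
    mask      = "logical",   # TRUE = real frame, FALSE = padding
    label     = "character"  # class label or NA
  )
)

setValidity("TakeSequence", function(object) {
  msgs <- character(0)
  if (ncol(object@channels) != length(channelNames_())) {
    msgs <- c(msgs, sprintf("channel matrix must have %d columns",
                            length(channelNames_())))
  }
  if (nrow(object@channels) != length(object@mask)) {
    msgs <- c(msgs, "mask length must equal sequence length")
  }
  if (any(!object@mask) && any(object@channels[!object@mask, ] != 0)) {
    msgs <- c(msgs, "padding rows must be all-zero")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname LSTMModel-class
#' @exportClass LSTMModel
setClass("LSTMModel",
  representation(
    inputSize  = "integer",
    hiddenSize = "integer",
    params     = "list",   # Wx/Wh/b per gate (f,i,o,g) + w_out, b_out
    history    = "numeric" # per-epoch training loss (empty before training)
  )
)

setValidity("LSTMModel", function(object) {
  msgs <- character(0)
  D <- object@inputSize; H <- object@hiddenSize
  p <- object@params
  need <- c(paste0("Wx", c("f", "i", "o", "g")),
            paste0("Wh", c("f", "i", "o", "g")),
            paste0("b", c("f", "i", "o", "g")), "w_out", "b_out")
  if (!all(need %in% names(p))) {
    return("missing LSTM parameter fields")
  }
  for (g in c("f", "i", "o", "g")) {
    if (!all(dim(p[[paste0("Wx", g)]]) == c(H, D))) {
      msgs <- c(msgs, sprintf("Wx%s must be H x D", g))
    }
    if (!all(dim(p[[paste0("Wh", g)]]) == c(H, H))) {
      msgs <- c(msgs, sprintf("Wh%s must be H x H", g))
    }
    if (length(p[[paste0("b", g)]]) != H) {
      msgs <- c(msgs, sprintf("b%s must have length H", g))
    }
  }
  if (length(p$w_out) != H) msgs <- c(msgs, "w_out must have length H")
  if (length(p$b_out) != 1L) msgs <- c(msgs, "b_out must be scalar")
  if (!all(vapply(p, function(x) all(is.finite(unlist(x))), logical(1)))) {
    msgs <- c(msgs, "all parameters must be finite")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname ConfusionMatrix-class
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(
    tp = "numeric", fn = "numeric", fp = "numeric", tn = "numeric",
    positiveClass = "character",
    negativeClass = "character"
  )
)

setValidity("ConfusionMatrix", function(object) {
  counts <- c(object@tp, object@fn, object@fp, object@tn)
  if (any(counts < 0)) return("confusion counts must be non-negative")
  TRUE
})
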