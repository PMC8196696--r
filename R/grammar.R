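# Step grammar for synthetic medication episodes.
#
# An episode walks through an ordered sequence of hand/object states
# (reach for the bottle, open it, pour a pill, ...). Each state has a
# duration range (frames), an emission table (probability that each
# object category is visible while the state is active) and placement
# anchors giving where each category sits in the 128x128 wrist-camera
# view. Medication and non-medication episodes share all states except
# the pill-to-mouth contact phase, which only the medication class may
# enter, so the two classes differ exactly in whether the pill ever
# reaches an open mouth.

state_ <- function(name, dur_range, emissions, classes = c("medication", "non_medication")) {
  list(name = name, dur_range = as.numeric(dur_range),
       emissions = emissions, classes = classes)
}

# base placement anchors in a 128x128 frame (x_min, y_min, x_max, y_max):
# face top-center, hand bottom-center (the camera looks up the forearm),
# bottle left, cup right.
defaultAnchors_ <- function() {
  list(
    bottle      = c(6, 60, 30, 110),
    open_bottle = c(6, 60, 30, 110),
    cap         = c(32, 96, 44, 108),
    cup         = c(96, 62, 124, 112),
    face        = c(34, 6, 94, 60),
    hand        = c(44, 86, 92, 122),
    mouth       = c(54, 38, 74, 52),
    open_mouth  = c(52, 36, 76, 56),
    pill        = c(60, 96, 70, 106)   # default: resting in the hand
  )
}

# where the pill sits while each state is active (overrides the anchor)
defaultPillAnchors_ <- function() {
  list(
    pour_pill          = c(20, 78, 30, 88),   # at the bottle opening
    hold_pill          = c(60, 96, 70, 106),  # in the palm
    pill_to_mouth      = c(58, 66, 68, 76),   # travelling upwards
    open_mouth_contact = c(59, 41, 69, 51)    # centered in the open mouth
  )
}

#' Default episode grammar
#'
#' The built-in step grammar for ~15-20 s medication-taking episodes:
#' idle, reach for the bottle, open it, pour and hold a pill, bring the
#' pill to the mouth, pill-in-open-mouth contact, drink from the cup and
#' lower the hand. Non-medication episodes traverse the same steps except
#' the two pill-to-mouth states, so they still open the bottle and hold
#' the pill ("holding the pill in the hand" is explicitly not taking it).
#'
#' Duration ranges are in frames at the default 12.5 frames/s. Emission
#' probabilities encode which objects are typically visible during each
#' step; `bottle`/`open_bottle` and `mouth`/`open_mouth` are mutually
#' exclusive within any state.
#'
#' @param frame_width,frame_height Frame size in pixels (default 128).
#' @param jitter_sd Per-frame placement jitter in pixels.
#' @return An [EpisodeGrammar-class] object.
#' @examples
#' g <- defaultGrammar()
#' g
#' @export
defaultGrammar <- function(frame_width = 128, frame_height = 128, jitter_sd = 1.5) {
  med <- c("medication")
  states <- list(
    state_("idle", c(8, 25),
           c(face = 0.8, hand = 0.9, mouth = 0.6, cup = 0.3, bottle = 0.5)),
    state_("reach_bottle", c(12, 30),
           c(bottle = 1, hand = 1, face = 0.7, mouth = 0.5)),
    state_("open_bottle", c(15, 35),
           c(open_bottle = 1, cap = 0.9, hand = 1, face = 0.6, mouth = 0.5)),
    state_("pour_pill", c(12, 30),
           c(open_bottle = 1, cap = 0.6, hand = 1, pill = 0.9, face = 0.6, mouth = 0.5)),
    state_("hold_pill", c(18, 45),
           c(pill = 1, hand = 1, open_bottle = 0.7, cap = 0.4, face = 0.7, mouth = 0.6)),
    state_("pill_to_mouth", c(8, 20),
           c(pill = 1, hand = 1, face = 0.9, mouth = 0.8), classes = med),
    state_("open_mouth_contact", c(6, 14),
           c(pill = 1, open_mouth = 1, face = 1, hand = 0.9), classes = med),
    state_("drink_cup", c(20, 50),
           c(cup = 1, hand = 1, face = 0.9, mouth = 0.5)),
    state_("lower_hand", c(8, 20),
           c(hand = 1, face = 0.8, mouth = 0.7, cup = 0.4))
  )
  new("EpisodeGrammar",
      states = states,
      frameWidth = frame_width, frameHeight = frame_height,
      anchors = defaultAnchors_(),
      pillAnchors = defaultPillAnchors_(),
      jitterSd = jitter_sd,
      contactStates = "open_mouth_contact")
}

#' @describeIn defaultGrammar Names of the grammar's states, in order.
#' @param grammar An `EpisodeGrammar`.
#' @export
grammarStates <- function(grammar) {
  vapply(grammar@states, function(s) s$name, character(1))
}

setMethod("show", "EpisodeGrammar", function(object) {
  nm <- grammarStates(object)
  cat("EpisodeGrammar with", length(nm), "states:",
      paste(nm, collapse = " -> "), "\n")
  cat(sprintf("  frame %dx%d px, contact state(s): %s\n",
              as.integer(object@frameWidth), as.integer(object@frameHeight),
              paste(object@contactStates, collapse = ", ")))
})

# allocate `total` frames across sampled state durations: proportional
# scaling with largest-remainder rounding, every state >= 1 frame, and
# contact states >= 3 frames so brief mouth contact is never lost.
allocateDurations_ <- function(raw, total, contact_idx) {
  n <- length(raw)
  if (total < n) stop("episode too short for the grammar's states", call. = FALSE)
  scaled <- raw * total / sum(raw)
  base <- pmax(floor(scaled), 1)
  # largest-remainder distribution of the leftover frames
  while (sum(base) < total) {
    rem <- scaled - base
    k <- which.max(rem)
    base[k] <- base[k] + 1
  }
  while (sum(base) > total) {
    k <- which.max(base)
    base[k] <- base[k] - 1
  }
  min_contact <- 3
  for (ci in contact_idx) {
    while (base[ci] < min_contact) {
      k <- which.max(replace(base, ci, -Inf))
      if (base[k] <= 1) break
      base[k] <- base[k] - 1
      base[ci] <- base[ci] + 1
    }
  }
  base
}

# jittered integer placement of `anchor` clamped inside the frame
placeBox_ <- function(anchor, offset, width, height) {
  w <- anchor[3] - anchor[1]
  h <- anchor[4] - anchor[2]
  x0 <- round(anchor[1] + offset[1])
  y0 <- round(anchor[2] + offset[2])
  x0 <- min(max(x0, 0), width - w)
  y0 <- min(max(y0, 0), height - h)
  c(x0, y0, x0 + w, y0 + h)
}

#' Sample a synthetic medication episode
#'
#' Draws one labeled episode from a step grammar: a state timeline whose
#' durations fill exactly `round(duration_s * fps)` frames, and for each
#' frame the set of visible objects with their ground-truth boxes. The
#' same arguments and seed always yield an identical episode.
#'
#' During the pill-to-mouth contact state the pill box is centered on the
#' open-mouth box (they share the per-frame jitter offset), which is the
#' geometric signature separating the two classes.
#'
#' @param grammar An [EpisodeGrammar-class], e.g. [defaultGrammar()].
#' @param label `"medication"` or `"non_medication"`.
#' @param duration_s Episode length in seconds (> 0).
#' @param fps Frame rate in frames/second (> 0); default 12.5 so a 20 s
#'   episode has 250 frames.
#' @param seed Integer seed.
#' @param episode_id Identifier stored in the episode.
#' @return An [Episode-class] object.
#' @examples
#' ep <- sampleEpisode(defaultGrammar(), "medication", seed = 1)
#' nFrames(ep)
#' @export
sampleEpisode <- function(grammar, label = c("medication", "non_medication"),
                          duration_s = 20, fps = 12.5, seed = 1L,
                          episode_id = sprintf("ep_%s_%d", label[1], seed)) {
  label <- match.arg(label)
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be positive", call. = FALSE)
  }
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive", call. = FALSE)
  validObject(grammar)
  frame_count <- round(duration_s * fps)

  snames <- grammarStates(grammar)
  keep <- vapply(grammar@states, function(s) label %in% s$classes, logical(1))
  states <- grammar@states[keep]
  snames <- snames[keep]
  contact_idx <- which(snames %in% grammar@contactStates)

  W <- grammar@frameWidth
  H <- grammar@frameHeight

  with_seed_(seed, {
    raw <- vapply(states, function(s) {
      r <- s$dur_range
      if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1L)
    }, numeric(1))
    dur <- allocateDurations_(raw, frame_count, contact_idx)
    end <- cumsum(dur)
    start <- c(0, end[-length(end)])
    timeline <- data.frame(state = snames, start_frame = as.integer(start),
                           end_frame = as.integer(end))

    frames <- vector("list", frame_count)
    gt_rows <- vector("list", frame_count)
    state_of_frame <- rep(seq_along(snames), dur)
    for (f in seq_len(frame_count)) {
      st <- states[[state_of_frame[f]]]
      p <- st$emissions
      visible <- names(p)[runif(length(p)) < p]
      # defensive: never co-emit an exclusive pair
      for (pair in exclusivePairs_()) {
        if (all(pair %in% visible)) visible <- setdiff(visible, pair[1])
      }
      # draw jitter for every category up-front so RNG use is stable
      off <- matrix(round(rnorm(2 * length(visible), 0, grammar@jitterSd)),
                    ncol = 2)
      nv <- length(visible)
      bx <- matrix(0, nrow = nv, ncol = 4)
      if (nv > 0L) {
        mouth_off <- off[match("open_mouth", visible), , drop = TRUE]
        for (j in seq_len(nv)) {
          cat_j <- visible[j]
          anchor <- grammar@anchors[[cat_j]]
          o <- off[j, ]
          if (cat_j == "pill") {
            pa <- grammar@pillAnchors[[st$name]]
            if (!is.null(pa)) anchor <- pa
            # during contact the pill rides with the mouth so its center
            # stays inside the open-mouth box
            if (st$name %in% grammar@contactStates && "open_mouth" %in% visible) {
              o <- mouth_off
            }
          }
          bx[j, ] <- placeBox_(anchor, o, W, H)
        }
      }
      placements <- data.frame(category = visible, x_min = bx[, 1],
                               y_min = bx[, 2], x_max = bx[, 3],
                               y_max = bx[, 4], stringsAsFactors = FALSE)
      frames[[f]] <- list(placements = placements, background_seed = f)
      gt_rows[[f]] <- list(cats = visible, boxes = bx)
    }
    all_cats <- unlist(lapply(gt_rows, `[[`, "cats"))
    all_boxes <- do.call(rbind, lapply(gt_rows, `[[`, "boxes"))
    n_per <- vapply(gt_rows, function(r) length(r$cats), integer(1))
    gt <- data.frame(frame = rep(seq_len(frame_count) - 1L, n_per),
                     category = all_cats,
                     x_min = all_boxes[, 1], y_min = all_boxes[, 2],
                     x_max = all_boxes[, 3], y_max = all_boxes[, 4],
                     stringsAsFactors = FALSE)

    new("Episode", episodeId = episode_id, label = label, fps = fps,
        frames = frames, groundTruth = gt, stepTimeline = timeline,
        frameWidth = W, frameHeight = H)
  })
}
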