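#' The nine medication-related object categories
#'
#' Fixed, case-stable category vocabulary of the detector: the objects a
#' wrist camera sees during a medication-taking episode. The order is
#' fixed and used everywhere an index order matters (feature channel
#' layout, classifier tie-breaks).
#'
#' @return Character vector of length 9.
#' @examples
#' objectCategories()
#' @export
objectCategories <- function() {
  c("bottle", "cap", "cup", "face", "hand", "mouth",
    "open_bottle", "open_mouth", "pill")
}

# mutually exclusive category pairs: an object is either open or closed
exclusivePairs_ <- function() {
  list(c("bottle", "open_bottle"), c("mouth", "open_mouth"))
}

assertCategory_ <- function(category) {
  bad <- setdiff(category, objectCategories())
  if (length(bad) > 0L) {
    stop("unknown object category: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(category)
}

#' Construct a bounding box
#'
#' Boxes are axis-aligned, integer-valued, origin at the image top-left,
#' and half-open: the box covers pixel columns `[x_min, x_max)` and rows
#' `[y_min, y_max)`, so its area is `(x_max - x_min) * (y_max - y_min)`.
#'
#' @param x_min,y_min,x_max,y_max Box corners in pixels.
#' @return A one-row `data.frame` with columns `x_min`, `y_min`, `x_max`,
#'   `y_max`.
#' @examples
#' bbox(0, 0, 10, 10)
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  b <- data.frame(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                  x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  validateBoxes_(b)
  b
}

validateBoxes_ <- function(boxes) {
  if (nrow(boxes) == 0L) return(invisible(boxes))
  stopifnot(all(c("x_min", "y_min", "x_max", "y_max") %in% names(boxes)))
  if (any(boxes$x_max <= boxes$x_min) || any(boxes$y_max <= boxes$y_min)) {
    stop("degenerate box: x_max must exceed x_min and y_max must exceed y_min",
         call. = FALSE)
  }
  if (any(boxes$x_min < 0) || any(boxes$y_min < 0)) {
    stop("box coordinates must be non-negative", call. = FALSE)
  }
  invisible(boxes)
}

#' Box area under the half-open pixel convention
#'
#' @param boxes Data frame with `x_min`, `y_min`, `x_max`, `y_max` columns.
#' @return Numeric vector of pixel areas.
#' @export
boxArea <- function(boxes) {
  (boxes$x_max - boxes$x_min) * (boxes$y_max - boxes$y_min)
}

# clip boxes to [0, width) x [0, height), preserving at least 1 px extent
clipBox_ <- function(boxes, width, height) {
  boxes$x_min <- pmin(pmax(boxes$x_min, 0), width - 1)
  boxes$y_min <- pmin(pmax(boxes$y_min, 0), height - 1)
  boxes$x_max <- pmax(pmin(boxes$x_max, width), boxes$x_min + 1)
  boxes$y_max <- pmax(pmin(boxes$y_max, height), boxes$y_min + 1)
  boxes
}

#' Intersection over union of two boxes
#'
#' Overlap ratio `|a intersect b| / |a union b|` under the half-open pixel
#' convention. Symmetric, bounded in `[0, 1]`, and equal to 1 exactly for
#' identical boxes.
#'
#' @param a,b One-row box data frames (or any objects with `x_min`,
#'   `y_min`, `x_max`, `y_max` fields).
#' @return A number in `[0, 1]`.
#' @examples
#' boxIoU(bbox(0, 0, 10, 10), bbox(5, 0, 15, 10))  # 50/150
#' @export
boxIoU <- function(a, b) {
  iw <- min(a$x_max, b$x_max) - max(a$x_min, b$x_min)
  ih <- min(a$y_max, b$y_max) - max(a$y_min, b$y_min)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a$x_max - a$x_min) * (a$y_max - a$y_min) +
    (b$x_max - b$x_min) * (b$y_max - b$y_min) - inter
  inter / union
}

# vectorized IoU of one box against each row of `boxes`
iouMany_ <- function(box, boxes) {
  if (nrow(boxes) == 0L) return(numeric(0))
  iw <- pmin(box$x_max, boxes$x_max) - pmax(box$x_min, boxes$x_min)
  ih <- pmin(box$y_max, boxes$y_max) - pmax(box$y_min, boxes$y_min)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  union <- (box$x_max - box$x_min) * (box$y_max - box$y_min) +
    (boxes$x_max - boxes$x_min) * (boxes$y_max - boxes$y_min) - inter
  ifelse(inter > 0, inter / union, 0)
}

# empty detection table with the canonical column layout
emptyDetections_ <- function(score = TRUE) {
  d <- data.frame(frame = integer(0), category = character(0),
                  x_min = numeric(0), y_min = numeric(0),
                  x_max = numeric(0), y_max = numeric(0))
  if (score) d$score <- numeric(0)
  d
}
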