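# Detection-quality evaluation: per-category precision-recall and
# average precision at IoU 0.5, and their unweighted mean.

#' Per-category average precision at an IoU threshold
#'
#' Standard greedy evaluation: detections of the category are sorted by
#' descending confidence (ties broken by `frame`, `x_min`, `y_min` for
#' reproducibility) and matched greedily to the highest-IoU unmatched
#' ground-truth box of the same category and frame at IoU >= `iou_min`;
#' a detection matching an already-matched ground truth counts as a
#' false positive. AP is the area under the precision envelope over
#' recall (all-point interpolation).
#'
#' @param dets Detection data frame (`frame`, `category`, corners, `score`).
#' @param gts Ground-truth data frame (`frame`, `category`, corners).
#' @param category Category to evaluate.
#' @param iou_min Match threshold, default 0.5.
#' @return List of class `"APResult"`: `category`, `ap`, `pr_points`
#'   (data frame `recall`, `precision`, non-decreasing in recall) and
#'   `n_gt`. With detections but no ground truth, AP is 0 with a warning.
#' @export
averagePrecision <- function(dets, gts, category, iou_min = 0.5) {
  assertCategory_(category)
  d <- dets[dets$category == category, , drop = FALSE]
  g <- gts[gts$category == category, , drop = FALSE]
  n_gt <- nrow(g)
  if (n_gt == 0L) {
    if (nrow(d) > 0L) {
      warning("detections present for category '", category,
              "' but no ground truth; AP = 0", call. = FALSE)
    }
    return(structure(list(category = category, ap = 0,
                          pr_points = data.frame(recall = numeric(0),
                                                 precision = numeric(0)),
                          n_gt = 0L), class = "APResult"))
  }
  if (nrow(d) == 0L) {
    return(structure(list(category = category, ap = 0,
                          pr_points = data.frame(recall = 0, precision = 1),
                          n_gt = n_gt), class = "APResult"))
  }
  d <- d[order(-d$score, d$frame, d$x_min, d$y_min), , drop = FALSE]
  matched <- logical(n_gt)
  tp <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    cand <- which(g$frame == d$frame[i])
    if (length(cand) == 0L) next
    ious <- iouMany_(d[i, ], g[cand, , drop = FALSE])
    ord <- order(-ious)
    for (j in ord) {
      if (ious[j] < iou_min) break
      if (!matched[cand[j]]) {
        matched[cand[j]] <- TRUE
        tp[i] <- TRUE
        break
      }
    }
  }
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  recall <- ctp / n_gt
  precision <- ctp / (ctp + cfp)
  # all-point interpolation: integrate the precision envelope over recall
  env <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  ap <- sum((recall - r_prev) * env)
  structure(list(category = category, ap = ap,
                 pr_points = data.frame(recall = recall, precision = precision),
                 n_gt = n_gt), class = "APResult")
}

#' Mean average precision
#'
#' Unweighted arithmetic mean of per-category AP values.
#'
#' @param results List of `"APResult"` objects (or a bare numeric vector
#'   of AP values).
#' @return A number in `[0, 1]`.
#' @examples
#' meanAP(c(0.9, 0.8))
#' @export
meanAP <- function(results) {
  if (length(results) == 0L) stop("empty AP list", call. = FALSE)
  aps <- if (is.numeric(results)) results
         else vapply(results, function(r) r$ap, numeric(1))
  mean(aps)
}

#' Evaluate a detection stream against ground truth
#'
#' Computes AP@`iou_min` for every category present in the ground truth
#' plus the mean AP, in the shape of a per-category results table.
#'
#' @param dets Detection data frame.
#' @param gts Ground-truth data frame.
#' @param categories Categories to evaluate (default: all nine).
#' @param iou_min Match threshold.
#' @return Data frame with columns `category` and `ap`, with a final
#'   `Average` row.
#' @export
evalDetections <- function(dets, gts, categories = objectCategories(),
                           iou_min = 0.5) {
  res <- lapply(categories, function(cc) averagePrecision(dets, gts, cc, iou_min))
  aps <- vapply(res, function(r) r$ap, numeric(1))
  rbind(data.frame(category = categories, ap = aps),
        data.frame(category = "Average", ap = meanAP(res)))
}
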