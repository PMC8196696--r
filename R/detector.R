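# Desk-scale region-based detector, structured as the four classic
# modules: (1) category-agnostic region proposal, (2) fixed-size
# warp/crop feature extraction, (3) linear SVM region classification,
# (4) bounding-box regression; plus NMS and frame-level inference.
#
# The region proposer segments connected components of uniform color on
# the background-subtracted image -- a stand-in for selective search that
# is adequate for flat-shaded synthetic scenes and interchangeable behind
# the operation contract. The feature extractor (mean-centered grayscale
# crop + per-channel color histograms) is the declared plug-point that
# replaces a pretrained CNN backbone.

defaultFeatureSpec_ <- function(crop_side = 24L, hist_bins = 8L) {
  list(crop_side = as.integer(crop_side), hist_bins = as.integer(hist_bins),
       length = as.integer(crop_side^2 + 3L * hist_bins))
}

#' Propose candidate object regions in an image
#'
#' Category-agnostic region proposal by connected-component segmentation:
#' pixels are quantized to flat colors, the dominant (background) color
#' is removed, and each connected component of each remaining color
#' becomes one candidate box. Components smaller than `min_area` pixels
#' are dropped and at most `max_proposals` boxes (largest first) are
#' returned.
#'
#' @param image Numeric array `height x width x 3`, values in `[0, 1]`.
#' @param min_area Minimum component area in pixels.
#' @param max_proposals Upper bound on the number of proposals.
#' @return Box data frame (`x_min`, `y_min`, `x_max`, `y_max`); zero rows
#'   for a uniform image.
#' @export
proposeRegions <- function(image, min_area = 12L, max_proposals = 100L) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  h <- dim(image)[1]; w <- dim(image)[2]
  q <- round(image * 50) / 50  # quantize to flat colors
  key <- q[, , 1] * 1e6 + q[, , 2] * 1e3 + q[, , 3]
  tab <- table(key)
  bg <- as.numeric(names(tab)[which.max(tab)])
  colors <- setdiff(as.numeric(names(tab)), bg)
  if (length(colors) > 60L) {
    # fall back to a single foreground mask if the image is not flat-shaded
    colors <- NA_real_
  }
  boxes <- list()
  for (cv in colors) {
    mask <- if (is.na(cv)) abs(key - bg) > 1e-9 else abs(key - cv) < 1e-9
    if (!any(mask)) next
    lab <- EBImage::bwlabel(EBImage::Image(t(mask * 1)))  # dims [x, y]
    labm <- EBImage::imageData(lab)
    for (k in seq_len(max(labm))) {
      px <- which(labm == k, arr.ind = TRUE)
      if (nrow(px) < min_area) next
      boxes[[length(boxes) + 1L]] <- data.frame(
        x_min = min(px[, 1]) - 1L, y_min = min(px[, 2]) - 1L,
        x_max = max(px[, 1]), y_max = max(px[, 2]))
    }
  }
  if (length(boxes) == 0L) {
    return(data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0)))
  }
  out <- do.call(rbind, boxes)
  out <- out[order(-boxArea(out)), , drop = FALSE]
  out <- head(out, max_proposals)
  rownames(out) <- NULL
  out
}

#' Warp/crop a region to a fixed-length feature vector
#'
#' Crops the box, resizes it to `crop_side x crop_side`, and concatenates
#' the mean-centered grayscale pixels with per-channel color histograms
#' (`hist_bins` equal-width bins on `[0, 1]`, normalized to sum 1 per
#' channel). The output length is fixed by the feature spec regardless of
#' the box size.
#'
#' @param image Numeric array `height x width x 3`.
#' @param box One-row box data frame, within the image.
#' @param feature_spec Feature recipe from the detector model (crop side,
#'   histogram bins).
#' @return Numeric feature vector of length
#'   `crop_side^2 + 3 * hist_bins`.
#' @export
warpCrop <- function(image, box, feature_spec = defaultFeatureSpec_()) {
  h <- dim(image)[1]; w <- dim(image)[2]
  validateBoxes_(box)
  if (box$x_max > w || box$y_max > h) {
    stop("box outside image bounds", call. = FALSE)
  }
  crop <- image[(box$y_min + 1):box$y_max, (box$x_min + 1):box$x_max, ,
                drop = FALSE]
  side <- feature_spec$crop_side
  # EBImage works in [x, y] order
  img <- EBImage::Image(aperm(crop, c(2, 1, 3)), colormode = "Color")
  rs <- EBImage::imageData(EBImage::resize(img, w = side, h = side))
  if (length(dim(rs)) == 2L) rs <- array(rs, dim = c(side, side, 3))
  gray <- (rs[, , 1] + rs[, , 2] + rs[, , 3]) / 3
  gray <- as.numeric(gray) - mean(gray)
  brk <- seq(0, 1, length.out = feature_spec$hist_bins + 1L)
  hists <- unlist(lapply(1:3, function(ch) {
    v <- pmin(pmax(as.numeric(rs[, , ch]), 0), 1)
    counts <- tabulate(pmin(findInterval(v, brk, rightmost.closed = TRUE),
                            feature_spec$hist_bins),
                       nbins = feature_spec$hist_bins)
    counts / length(v)
  }))
  c(gray, hists)
}

# calibrated score from the winning SVM margin
marginScore_ <- function(margin) 1 / (1 + exp(-margin))

#' Classify a region feature vector
#'
#' Computes the per-category linear margins `w . f + b`; the predicted
#' category is the argmax if the best margin is positive, otherwise the
#' region is background (`NA` category). Ties break to the lowest
#' category index in the fixed category order. The score is the logistic
#' map of the winning margin, so it increases strictly with the margin.
#'
#' @param feature Feature vector (length must match the model).
#' @param model A [DetectorModel-class].
#' @return List with `category` (or `NA` for background), `score`, and
#'   the full `margins` vector.
#' @export
classifyRegion <- function(feature, model) {
  if (length(feature) != model@featureSpec$length) {
    stop("feature length does not match the model", call. = FALSE)
  }
  margins <- as.numeric(model@weights %*% feature) + model@biases
  best <- which.max(margins)  # which.max takes the first (lowest index) on ties
  if (margins[best] <= 0) {
    list(category = NA_character_, score = marginScore_(max(margins)),
         margins = margins)
  } else {
    list(category = model@categories[best], score = marginScore_(margins[best]),
         margins = margins)
  }
}

# standard box-regression parameterization: targets relative to proposal
regressionTargets_ <- function(prop, gt) {
  pw <- prop$x_max - prop$x_min; ph <- prop$y_max - prop$y_min
  gw <- gt$x_max - gt$x_min; gh <- gt$y_max - gt$y_min
  c((gt$x_min + gw / 2 - (prop$x_min + pw / 2)) / pw,
    (gt$y_min + gh / 2 - (prop$y_min + ph / 2)) / ph,
    log(gw / pw), log(gh / ph))
}

applyRegression_ <- function(box, t, width, height) {
  w <- box$x_max - box$x_min; h <- box$y_max - box$y_min
  cx <- box$x_min + w / 2 + t[1] * w
  cy <- box$y_min + h / 2 + t[2] * h
  nw <- w * exp(t[3]); nh <- h * exp(t[4])
  out <- data.frame(x_min = round(cx - nw / 2), y_min = round(cy - nh / 2),
                    x_max = round(cx + nw / 2), y_max = round(cy + nh / 2))
  clipBox_(out, width, height)
}

#' Refine a candidate box with the learned regressor
#'
#' Applies the per-category regressor's predicted offsets
#' `(dx/w, dy/h, log dw, log dh)` to the box center and size, then clips
#' to the frame. A missing or all-zero regressor returns the input box.
#'
#' @param feature Region feature vector.
#' @param box One-row box data frame.
#' @param model A [DetectorModel-class].
#' @param category Category whose regressor to use.
#' @param width,height Frame bounds for clipping.
#' @return Refined one-row box data frame (valid, in-bounds).
#' @export
refineBox <- function(feature, box, model, category, width, height) {
  R <- model@regressors[[category]]
  if (is.null(R)) return(box)
  t <- as.numeric(c(1, feature) %*% R)
  applyRegression_(box, t, width, height)
}

#' Non-maximum suppression
#'
#' Greedy per-category suppression: detections are visited in order of
#' descending score; any same-category detection with IoU above
#' `nms_iou` against an already-kept detection is discarded.
#'
#' @param dets Detection data frame with `category`, corner columns, `score`.
#' @param nms_iou Suppression threshold in `(0, 1)`.
#' @return The kept subset, sorted by descending score.
#' @export
nonMaxSuppression <- function(dets, nms_iou = 0.3) {
  if (nrow(dets) <= 1L) return(dets)
  dets <- dets[order(-dets$score, dets$x_min, dets$y_min), , drop = FALSE]
  keep <- logical(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    ok <- TRUE
    kept <- which(keep & dets$category == dets$category[i])
    for (j in kept) {
      if (boxIoU(dets[i, ], dets[j, ]) > nms_iou) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Train the region-based detector
#'
#' Runs region proposal over the training frames, assigns proposals to
#' categories (positive at IoU >= 0.5 against ground truth, negative
#' below 0.3, ignored between), adds the ground-truth boxes themselves as
#' positives, extracts warp/crop features, and fits one linear SVM per
#' category (one-vs-rest) plus a per-category ridge box regressor on
#' matches at IoU >= 0.6.
#'
#' @param dataset Dataset from [makeDataset()] (episodes are rendered on
#'   the fly), or a named list of [Episode-class] objects.
#' @param config List of tunables: `svm_cost` (default 1), `score_min`
#'   (0.5), `nms_iou` (0.3), `max_frames_per_episode` (frames sampled per
#'   episode for training), `ridge_lambda` (box-regressor penalty),
#'   `neg_per_frame` (cap on negatives kept per frame).
#' @param seed Integer seed (frame subsampling and negative selection).
#' @return A [DetectorModel-class]. Categories with no positive examples
#'   are skipped with a warning (zero weights, never predicted).
#' @export
trainDetector <- function(dataset, config = list(), seed = 1L) {
  cfg <- modifyList(list(svm_cost = 1, score_min = 0.5, nms_iou = 0.3,
                         max_frames_per_episode = 10L, ridge_lambda = 1e-3,
                         neg_per_frame = 6L, gt_crops_per_category = 8L),
                    config)
  episodes <- if (!is.null(dataset$episodes)) {
    ids <- dataset$manifest$episode_id[dataset$manifest$partition == "train"]
    if (length(ids) == 0L) ids <- dataset$manifest$episode_id
    dataset$episodes[ids]
  } else dataset
  if (length(episodes) == 0L) stop("no training episodes", call. = FALSE)

  spec <- defaultFeatureSpec_()
  cats <- objectCategories()
  feats <- list(); labs <- character(0)
  reg_feats <- list(); reg_targets <- list(); reg_cats <- character(0)

  seeds <- derive_seeds_(seed, 2L * length(episodes))
  for (e in seq_along(episodes)) {
    ep <- episodes[[e]]
    gt <- groundTruth(ep)
    sz <- frameSize(ep)
    n <- nFrames(ep)
    pick <- with_seed_(seeds[e],
                       sort(sample.int(n, min(n, cfg$max_frames_per_episode))))
    for (f in pick) {
      img <- renderFrame(frameScene(ep, f), sz[1], sz[2])
      gtf <- gt[gt$frame == f - 1L, , drop = FALSE]
      props <- proposeRegions(img)
      cand <- rbind(props,
                    gtf[, c("x_min", "y_min", "x_max", "y_max"), drop = FALSE])
      if (nrow(cand) == 0L) next
      neg_kept <- 0L
      for (k in seq_len(nrow(cand))) {
        box <- cand[k, , drop = FALSE]
        ious <- iouMany_(box, gtf)
        best <- if (length(ious)) which.max(ious) else integer(0)
        lab <- NA_character_
        if (length(best) && ious[best] >= 0.5) {
          lab <- gtf$category[best]
        } else if (!length(best) || max(ious) < 0.3) {
          if (neg_kept >= cfg$neg_per_frame) next
          neg_kept <- neg_kept + 1L
          lab <- "__background__"
        } else next  # ignore band
        fv <- warpCrop(img, box, spec)
        feats[[length(feats) + 1L]] <- fv
        labs <- c(labs, lab)
        if (length(best) && ious[best] >= 0.6) {
          reg_feats[[length(reg_feats) + 1L]] <- fv
          reg_targets[[length(reg_targets) + 1L]] <-
            regressionTargets_(box, gtf[best, , drop = FALSE])
          reg_cats <- c(reg_cats, gtf$category[best])
        }
      }
    }
    # balance positives across appearance contexts: extra ground-truth
    # crops per category, drawn from the episode's full frame range
    extra <- with_seed_(seeds[length(episodes) + e], {
      idx <- unlist(lapply(split(seq_len(nrow(gt)), gt$category), function(rows) {
        rows[sample.int(length(rows), min(length(rows),
                                          cfg$gt_crops_per_category))]
      }))
      sort(idx)
    })
    for (k in extra) {
      img <- renderFrame(frameScene(ep, gt$frame[k] + 1L), sz[1], sz[2])
      fv <- warpCrop(img, gt[k, c("x_min", "y_min", "x_max", "y_max")], spec)
      feats[[length(feats) + 1L]] <- fv
      labs <- c(labs, gt$category[k])
    }
  }
  if (length(feats) == 0L) stop("no training regions extracted", call. = FALSE)
  X <- do.call(rbind, feats)

  W <- matrix(0, nrow = length(cats), ncol = spec$length)
  b <- rep(-1, length(cats))  # never-predicted default for skipped categories
  for (ci in seq_along(cats)) {
    y <- labs == cats[ci]
    if (!any(y)) {
      warning("no positive examples for category '", cats[ci], "'; skipped",
              call. = FALSE)
      next
    }
    fit <- e1071::svm(x = X, y = factor(ifelse(y, "pos", "neg"),
                                        levels = c("pos", "neg")),
                      kernel = "linear", cost = cfg$svm_cost,
                      scale = FALSE, type = "C-classification")
    wv <- as.numeric(t(fit$coefs) %*% fit$SV)
    bv <- -fit$rho
    # libsvm orients the decision value toward the class it saw first;
    # flip so positive margins always mean "this category"
    m <- X %*% wv + bv
    if (mean(m[y]) < mean(m[!y])) { wv <- -wv; bv <- -bv }
    W[ci, ] <- wv
    b[ci] <- bv
  }

  regs <- setNames(vector("list", length(cats)), cats)
  for (ci in seq_along(cats)) {
    sel <- reg_cats == cats[ci]
    if (sum(sel) >= 5L) {
      Xr <- cbind(1, do.call(rbind, reg_feats[sel]))
      Yr <- do.call(rbind, reg_targets[sel])
      A <- crossprod(Xr) + cfg$ridge_lambda * diag(ncol(Xr))
      regs[[cats[ci]]] <- solve(A, crossprod(Xr, Yr))
    }
  }

  new("DetectorModel", categories = cats, featureSpec = spec,
      weights = W, biases = b, regressors = regs,
      scoreMin = cfg$score_min, nmsIoU = cfg$nms_iou)
}

#' Detect objects in one frame
#'
#' Full inference pipeline: propose regions, extract warp/crop features,
#' classify each region, refine the box with the winning category's
#' regressor, drop detections below `score_min`, apply per-category NMS,
#' and return the survivors sorted by descending confidence.
#'
#' @param image Numeric array `height x width x 3`.
#' @param model A [DetectorModel-class].
#' @param frame Frame index recorded in the output (0-based).
#' @return Detection data frame (`frame`, `category`, corners, `score`).
#' @export
detectFrame <- function(image, model, frame = 0L) {
  h <- dim(image)[1]; w <- dim(image)[2]
  props <- proposeRegions(image)
  if (nrow(props) == 0L) return(emptyDetections_())
  rows <- list()
  for (k in seq_len(nrow(props))) {
    box <- props[k, , drop = FALSE]
    fv <- warpCrop(image, box, model@featureSpec)
    cl <- classifyRegion(fv, model)
    if (is.na(cl$category) || cl$score < model@scoreMin) next
    rb <- refineBox(fv, box, model, cl$category, w, h)
    rows[[length(rows) + 1L]] <- data.frame(
      frame = as.integer(frame), category = cl$category,
      x_min = rb$x_min, y_min = rb$y_min, x_max = rb$x_max, y_max = rb$y_max,
      score = cl$score)
  }
  if (length(rows) == 0L) return(emptyDetections_())
  dets <- do.call(rbind, rows)
  out <- nonMaxSuppression(dets, model@nmsIoU)
  rownames(out) <- NULL
  out
}

#' Detect objects in every frame of an episode
#'
#' @param episode An [Episode-class].
#' @param model A [DetectorModel-class].
#' @return Detection data frame over all frames.
#' @export
detectEpisode <- function(episode, model) {
  sz <- frameSize(episode)
  out <- lapply(seq_len(nFrames(episode)), function(i) {
    img <- renderFrame(frameScene(episode, i), sz[1], sz[2])
    detectFrame(img, model, frame = i - 1L)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) emptyDetections_() else res
}

setMethod("show", "DetectorModel", function(object) {
  trained <- sum(rowSums(object@weights != 0) > 0)
  cat(sprintf(
    "DetectorModel: %d/%d categories trained, %d features, score_min=%.2f, nms_iou=%.2f\n",
    trained, length(object@categories), object@featureSpec$length,
    object@scoreMin, object@nmsIoU))
})
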