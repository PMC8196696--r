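test_that("region proposal finds isolated glyphs and nothing on background", {
  uni <- glyphImage(bbox(0, 0, 1, 1))  # drawn over, then reset below
  uni[] <- 0.5
  expect_equal(nrow(proposeRegions(uni)), 0L)

  b <- bbox(5, 5, 25, 15)  # 20x10 glyph at (5,5)
  img <- glyphImage(b)
  props <- proposeRegions(img)
  expect_gte(nrow(props), 1L)
  ious <- vapply(seq_len(nrow(props)),
                 function(k) boxIoU(props[k, ], b), numeric(1))
  expect_gte(max(ious), 0.9)

  img3 <- glyphImage(bbox(2, 2, 12, 12))
  img3[30:40, 30:40, 1] <- 0.1; img3[30:40, 30:40, 2] <- 0.9
  img3[50:60, 5:15, 3] <- 0.1
  expect_gte(nrow(proposeRegions(img3)), 3L)
})

test_that("warp/crop features have fixed length and center to zero on uniform crops", {
  spec <- pillcam:::defaultFeatureSpec_()
  img <- glyphImage(bbox(5, 5, 25, 15))
  f1 <- warpCrop(img, bbox(0, 0, 10, 10), spec)
  f2 <- warpCrop(img, bbox(3, 3, 60, 50), spec)
  expect_equal(length(f1), spec$length)
  expect_equal(length(f2), spec$length)
  # uniform region: the mean-centered pixel block vanishes
  f3 <- warpCrop(img, bbox(40, 40, 60, 60), spec)
  expect_equal(f3[seq_len(spec$crop_side^2)], rep(0, spec$crop_side^2))
  expect_identical(warpCrop(img, bbox(0, 0, 10, 10), spec), f1)
  expect_error(warpCrop(img, bbox(60, 60, 80, 80), spec), "bounds")
})

test_that("region classification follows the margin rules", {
  spec <- list(crop_side = 2L, hist_bins = 1L, length = 7L)
  W <- rbind(c(1, 0, 0, 0, 0, 0, 0),
             c(-1, 0, 0, 0, 0, 0, 0))
  model <- new("DetectorModel", categories = c("pill", "cup"),
               featureSpec = spec, weights = W, biases = c(1, 0),
               regressors = list(), scoreMin = 0.5, nmsIoU = 0.3)
  f <- c(1, 0, 0, 0, 0, 0, 0)  # margins: (+2, -1)
  r <- classifyRegion(f, model)
  expect_equal(r$category, "pill")
  expect_gt(r$score, 0.5)
  expect_equal(r$margins, c(2, -1))

  zero <- new("DetectorModel", categories = c("pill", "cup"),
              featureSpec = spec, weights = W * 0, biases = c(0, 0),
              regressors = list(), scoreMin = 0.5, nmsIoU = 0.3)
  expect_true(is.na(classifyRegion(f, zero)$category))

  s1 <- classifyRegion(c(1, rep(0, 6)), model)$score
  s2 <- classifyRegion(c(2, rep(0, 6)), model)$score
  expect_gt(s2, s1)
  expect_error(classifyRegion(c(1, 2), model), "length")
})

test_that("box regression applies the documented offset parameterization", {
  spec <- list(crop_side = 2L, hist_bins = 1L, length = 7L)
  zeroR <- matrix(0, nrow = 8, ncol = 4)
  shiftR <- zeroR; shiftR[1, 1] <- 0.5  # dx = 0.5 * box width
  model <- new("DetectorModel", categories = "pill", featureSpec = spec,
               weights = matrix(0, 1, 7), biases = 0,
               regressors = list(pill = shiftR, cup = zeroR),
               scoreMin = 0.5, nmsIoU = 0.3)
  box <- bbox(20, 20, 30, 40)
  f <- rep(0, 7)
  expect_equal(refineBox(f, box, model, "cup", 128, 128), box)
  shifted <- refineBox(f, box, model, "pill", 128, 128)
  expect_equal(shifted, bbox(25, 20, 35, 40))
  # refinement never leaves the frame
  edge <- refineBox(f, bbox(120, 20, 127, 40), model, "pill", 128, 128)
  expect_lte(edge$x_max, 128)
  expect_gt(edge$x_max, edge$x_min)
})

test_that("NMS keeps one of a duplicate pair and respects the IoU bound", {
  d <- data.frame(frame = 0L, category = "pill",
                  x_min = c(10, 10), y_min = c(10, 10),
                  x_max = c(30, 30), y_max = c(30, 30),
                  score = c(0.9, 0.8))
  expect_equal(nrow(nonMaxSuppression(d, 0.3)), 1L)
  # different categories are never suppressed against each other
  d$category <- c("pill", "cup")
  expect_equal(nrow(nonMaxSuppression(d, 0.3)), 2L)
})

test_that("a fixture-trained detector localizes objects and repeats itself", {
  fx <- getDetectorFixture()
  model <- fx$model
  # training-set region classification accuracy on ground-truth crops
  ep <- fx$ds$episodes[[fx$ds$manifest$episode_id[
    fx$ds$manifest$partition == "train"][1]]]
  gt <- groundTruth(ep)
  pick <- which(gt$frame %in% unique(gt$frame)[1:6])
  correct <- 0
  for (k in pick) {
    img <- renderFrame(frameScene(ep, gt$frame[k] + 1L), 128, 128)
    f <- warpCrop(img, gt[k, c("x_min", "y_min", "x_max", "y_max")],
                  model@featureSpec)
    r <- classifyRegion(f, model)
    if (!is.na(r$category) && r$category == gt$category[k]) {
      correct <- correct + 1
    }
  }
  expect_gte(correct / length(pick), 0.9)

  # single-pill frame: exactly one pill detection overlapping ground truth
  scene <- list(placements = data.frame(category = "pill", x_min = 50,
                                        y_min = 50, x_max = 62, y_max = 62))
  img <- renderFrame(scene, 128, 128)
  det <- detectFrame(img, model)
  pill <- det[det$category == "pill", ]
  expect_equal(nrow(pill), 1L)
  expect_gte(boxIoU(pill[1, ], bbox(50, 50, 62, 62)), 0.5)
  # idempotence
  expect_identical(detectFrame(img, model), det)
  # uniform background yields nothing
  expect_equal(nrow(detectFrame(array(0.5, c(64, 64, 3)), model)), 0L)
})

test_that("raising the score threshold never adds detections", {
  fx <- getDetectorFixture()
  ep <- fx$ds$episodes[[1]]
  img <- renderFrame(frameScene(ep, 10), 128, 128)
  m_lo <- fx$model; m_lo@scoreMin <- 0.3
  m_hi <- fx$model; m_hi@scoreMin <- 0.8
  expect_lte(nrow(detectFrame(img, m_hi)), nrow(detectFrame(img, m_lo)))
})

test_that("same-category survivors never exceed the NMS IoU bound", {
  fx <- getDetectorFixture()
  ep <- fx$ds$episodes[[2]]
  total <- 0L
  for (fr in c(5, 50, 90)) {
    det <- detectFrame(renderFrame(frameScene(ep, fr), 128, 128), fx$model)
    total <- total + nrow(det)
    if (nrow(det) < 2) next
    for (i in seq_len(nrow(det) - 1)) {
      for (j in (i + 1):nrow(det)) {
        if (det$category[i] == det$category[j]) {
          expect_lte(boxIoU(det[i, ], det[j, ]), fx$model@nmsIoU)
        }
      }
    }
  }
  expect_gt(total, 0L)
})

test_that("detector training is deterministic and serializes losslessly", {
  fx <- getDetectorFixture()
  m2 <- trainDetector(fx$ds, config = list(max_frames_per_episode = 8),
                      seed = 1)
  expect_equal(fx$model@weights, m2@weights)
  expect_equal(fx$model@biases, m2@biases)
  tf <- tempfile(fileext = ".json")
  saveDetectorModel(fx$model, tf)
  back <- readDetectorModel(tf)
  expect_equal(back@weights, fx$model@weights, tolerance = 1e-12)
  expect_equal(back@biases, fx$model@biases, tolerance = 1e-12)
  img <- renderFrame(frameScene(fx$ds$episodes[[1]], 20), 128, 128)
  expect_equal(detectFrame(img, back), detectFrame(img, fx$model))
  expect_error(trainDetector(list(), seed = 1), "episodes")
})
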