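test_that("frame count follows round(duration * fps) and labels shape the timeline", {
  g <- defaultGrammar()
  for (case in list(c(20, 12.5, 250), c(16, 12.5, 200), c(15.3, 10, 153))) {
    ep <- sampleEpisode(g, "medication", duration_s = case[1], fps = case[2],
                        seed = 3)
    expect_equal(nFrames(ep), round(case[1] * case[2]))
    tl <- stepTimeline(ep)
    expect_equal(tl$start_frame[1], 0L)
    expect_equal(tl$end_frame[nrow(tl)], nFrames(ep))
    expect_true(all(tl$start_frame[-1] == tl$end_frame[-nrow(tl)]))
  }
  med <- sampleEpisode(g, "medication", seed = 1)
  non <- sampleEpisode(g, "non_medication", seed = 1)
  expect_true("open_mouth_contact" %in% stepTimeline(med)$state)
  expect_false(any(c("pill_to_mouth", "open_mouth_contact") %in%
                     stepTimeline(non)$state))
})

test_that("episode generation is a pure function of its seed", {
  g <- defaultGrammar()
  a <- sampleEpisode(g, "medication", seed = 42)
  b <- sampleEpisode(g, "medication", seed = 42)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- sampleEpisode(g, "medication", seed = 43)
  expect_false(identical(groundTruth(a), groundTruth(c)))
})

test_that("invalid episode arguments are rejected", {
  g <- defaultGrammar()
  expect_error(sampleEpisode(g, "medication", duration_s = 0), "positive")
  expect_error(sampleEpisode(g, "medication", fps = -1), "positive")
  expect_error(sampleEpisode(g, "swallow"))
})

test_that("per-state emission frequencies match the grammar probabilities", {
  # a single-state grammar makes every frame a draw from one emission table
  probs <- c(face = 0.8, hand = 0.9, mouth = 0.6, cup = 0.3, bottle = 0.5)
  g <- defaultGrammar()
  g@states <- list(list(name = "idle", dur_range = c(1, 1), emissions = probs,
                        classes = c("medication", "non_medication")))
  g@contactStates <- character(0)
  n <- 1200
  ep <- sampleEpisode(g, "non_medication", duration_s = n / 12.5, fps = 12.5,
                      seed = 9)
  gt <- groundTruth(ep)
  for (cat in names(probs)) {
    obs <- sum(gt$category == cat)
    lo <- qbinom(0.005, n, probs[[cat]])
    hi <- qbinom(0.995, n, probs[[cat]])
    expect_gte(obs, lo)
    expect_lte(obs, hi)
  }
})

test_that("mutual exclusions hold in every generated frame", {
  ep <- sampleEpisode(defaultGrammar(), "medication", seed = 5)
  gt <- groundTruth(ep)
  per_frame <- split(gt$category, gt$frame)
  for (cats in per_frame) {
    expect_false(all(c("bottle", "open_bottle") %in% cats))
    expect_false(all(c("mouth", "open_mouth") %in% cats))
  }
})

test_that("zero noise passes ground truth through with confidence 1", {
  ep <- sampleEpisode(defaultGrammar(), "medication", seed = 2)
  gt <- groundTruth(ep)
  d <- corruptDetections(gt, noiseFree(), seed = 1, n_frames = nFrames(ep))
  expect_equal(nrow(d), nrow(gt))
  expect_true(all(d$score == 1))
  key <- function(x) {
    o <- order(x$frame, x$category, x$x_min, x$y_min)
    x[o, c("frame", "category", "x_min", "y_min", "x_max", "y_max")]
  }
  expect_equal(unname(as.matrix(key(d)[, -2])), unname(as.matrix(key(gt)[, -2])))
  expect_equal(key(d)$category, key(gt)$category)
})

test_that("total dropout with no clutter yields an empty stream", {
  ep <- sampleEpisode(defaultGrammar(), "medication", seed = 2)
  np <- noiseParams(dropout_prob = 1, clutter_rate = 0, jitter_sd = 0)
  d <- corruptDetections(groundTruth(ep), np, seed = 1, n_frames = nFrames(ep))
  expect_equal(nrow(d), 0L)
})

test_that("dropout survival counts match the binomial law", {
  n <- 1000
  gt <- data.frame(frame = rep(0:9, each = 100), category = "pill",
                   x_min = 10, y_min = 10, x_max = 20, y_max = 20)
  np <- noiseParams(dropout_prob = 0.3, clutter_rate = 0, jitter_sd = 0,
                    conf_true = NULL)
  d <- corruptDetections(gt, np, seed = 77, n_frames = 10)
  expect_gte(nrow(d), qbinom(0.005, n, 0.7))
  expect_lte(nrow(d), qbinom(0.995, n, 0.7))
})

test_that("clutter and jitter stay within frame bounds with clamped scores", {
  ep <- sampleEpisode(defaultGrammar(), "medication", seed = 2)
  np <- noiseParams(dropout_prob = 0.2, clutter_rate = 2, jitter_sd = 4)
  d <- corruptDetections(groundTruth(ep), np, seed = 5, n_frames = nFrames(ep))
  expect_true(all(d$score >= 0 & d$score <= 1))
  expect_true(all(d$x_min >= 0 & d$y_min >= 0))
  expect_true(all(d$x_max <= 128 & d$y_max <= 128))
  expect_true(all(d$x_max > d$x_min & d$y_max > d$y_min))
  expect_true(all(d$category %in% objectCategories()))
})

test_that("dataset split honors exact counts and per-partition balance", {
  ds <- makeDataset(defaultGrammar(), n_episodes = 10, balance = 0.5,
                    n_train = 6, seed = 1, duration_s = 2.4)
  m <- ds$manifest
  expect_equal(sum(m$label == "medication"), 5L)
  expect_equal(sum(m$partition == "train"), 6L)
  tab <- table(m$partition, m$label)
  expect_true(all(abs(tab[, "medication"] -
                        rowSums(tab) * 0.5) <= 1))
  expect_error(makeDataset(defaultGrammar(), n_episodes = 10, n_train = 10),
               "n_train")
})

test_that("frame-level manifest split is exact at the requested fraction", {
  part <- splitFrameManifest(50, 0.8, seed = 3)
  expect_equal(sum(part == "train"), 40L)
  expect_equal(length(part), 50L)
})

test_that("rendering is deterministic and confined to placement boxes", {
  g <- defaultGrammar()
  empty <- renderFrame(list(placements = NULL), 64, 64)
  expect_equal(dim(empty), c(64, 64, 3))
  for (ch in 1:3) expect_equal(length(unique(as.numeric(empty[, , ch]))), 1L)

  scene <- list(placements = data.frame(category = "pill", x_min = 10,
                                        y_min = 20, x_max = 30, y_max = 40))
  img <- renderFrame(scene, 64, 64)
  bgmask <- img[, , 1] == empty[1, 1, 1] & img[, , 2] == empty[1, 1, 2] &
    img[, , 3] == empty[1, 1, 3]
  fg <- which(!bgmask, arr.ind = TRUE)
  expect_gt(nrow(fg), 0)
  expect_true(all(fg[, "col"] >= 11 & fg[, "col"] <= 30))
  expect_true(all(fg[, "row"] >= 21 & fg[, "row"] <= 40))
  expect_identical(renderFrame(scene, 64, 64), img)
  bad <- list(placements = data.frame(category = "pill", x_min = 50,
                                      y_min = 50, x_max = 70, y_max = 70))
  expect_error(renderFrame(bad, 64, 64), "bounds")
})

test_that("JSON-lines detection streams round-trip", {
  ep <- sampleEpisode(defaultGrammar(), "medication", duration_s = 2.4, seed = 4)
  d <- corruptDetections(groundTruth(ep), noiseParams(0.1, 0.5, 1), seed = 1,
                         n_frames = nFrames(ep))
  tf <- tempfile(fileext = ".jsonl")
  writeDetectionsJSONL(d, tf, episode_id = "ep1", n_frames = nFrames(ep))
  back <- readDetectionsJSONL(tf)
  expect_equal(back$episode_id, "ep1")
  expect_equal(back$n_frames, nFrames(ep))
  o1 <- d[order(d$frame, d$x_min, d$y_min), ]
  o2 <- back$boxes[order(back$boxes$frame, back$boxes$x_min, back$boxes$y_min), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o2[, names(o1)], o1)
})
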