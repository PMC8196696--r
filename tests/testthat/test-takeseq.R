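test_that("frame encoding computes confidences, areas and geometry channels", {
  empty <- encodeFrame(NULL, 128, 128)
  expect_equal(sum(empty), 0)
  expect_equal(length(empty), 20L)

  one <- data.frame(frame = 0L, category = "pill", x_min = 0, y_min = 0,
                    x_max = 16, y_max = 10.24, score = 0.9)  # 1% of 128^2
  v <- encodeFrame(one, 128, 128)
  expect_equal(v[["conf_pill"]], 0.9)
  expect_equal(v[["area_pill"]], 16 * 10.24 / 128^2)
  expect_equal(sum(v) - v[["conf_pill"]] - v[["area_pill"]], 0)

  # pill center inside the open mouth: proximity exactly 1
  d <- data.frame(frame = 0L,
                  category = c("pill", "open_mouth"),
                  x_min = c(60, 52), y_min = c(42, 36),
                  x_max = c(70, 76), y_max = c(52, 56),
                  score = c(0.8, 0.9))
  expect_equal(encodeFrame(d, 128, 128)[["pill_mouth_proximity"]], 1.0)

  # outside: the documented linear decay in center distance
  d2 <- d; d2$x_min[1] <- 90; d2$x_max[1] <- 100
  v2 <- encodeFrame(d2, 128, 128)
  dd <- sqrt((95 - 64)^2 + (47 - 46)^2)
  D <- sqrt(24^2 + 20^2)
  expect_equal(v2[["pill_mouth_proximity"]], max(0, 1 - dd / D))

  # pill overlapping a hand raises the indicator
  d3 <- data.frame(frame = 0L, category = c("pill", "hand"),
                   x_min = c(60, 55), y_min = c(60, 55),
                   x_max = c(70, 90), y_max = c(70, 95),
                   score = c(0.8, 0.9))
  expect_equal(encodeFrame(d3, 128, 128)[["pill_in_hand"]], 1)

  bad <- data.frame(frame = 0L, category = "pill", x_min = 120, y_min = 120,
                    x_max = 140, y_max = 140, score = 0.5)
  expect_error(encodeFrame(bad, 128, 128), "bounds")
})

test_that("per-category channels use the maximum-confidence detection", {
  d <- data.frame(frame = 0L, category = "cup",
                  x_min = c(0, 50), y_min = c(0, 50),
                  x_max = c(10, 80), y_max = c(10, 80),
                  score = c(0.4, 0.7))
  v <- encodeFrame(d, 128, 128)
  expect_equal(v[["conf_cup"]], 0.7)
  expect_equal(v[["area_cup"]], 30 * 30 / 128^2)
})

test_that("sequence building subsamples by the floor-index rule and pads short input", {
  L <- 250; Tf <- 64
  mat <- matrix(0, L, 20)
  mat[, 1] <- seq_len(L)  # row fingerprint
  s <- buildSequence(mat, T_fixed = Tf)
  expect_equal(nrow(seqChannels(s)), Tf)
  picked <- seqChannels(s)[, 1]
  expected <- floor((0:(Tf - 1)) * L / Tf) + 1
  expect_equal(picked, expected)
  expect_true(all(diff(picked) > 0))  # original order preserved, strictly
  expect_true(all(seqMask(s)))

  short <- matrix(1, 10, 20)
  s2 <- buildSequence(short, T_fixed = Tf)
  expect_equal(sum(seqMask(s2)), 10L)
  expect_equal(seqChannels(s2)[11:64, ], matrix(0, 54, 20),
               ignore_attr = TRUE)
  expect_identical(buildSequence(short, T_fixed = Tf), s2)
  expect_error(buildSequence(matrix(0, 0, 20), 64), "empty")
})

test_that("aggregate features pool only unmasked rows", {
  z <- buildSequence(matrix(0, 5, 20), T_fixed = 8)
  expect_equal(sum(aggregateFeatures(z)), 0)

  mat <- matrix(0.25, 6, 20)
  s <- buildSequence(mat, T_fixed = 10)
  a <- aggregateFeatures(s)
  expect_equal(length(a), 40L)
  expect_true(all(a == 0.25))

  # corrupting padding rows (mask FALSE) must not change aggregates
  tampered <- s
  ch <- seqChannels(s)
  ch[7:10, ] <- 99
  tampered@channels <- ch
  expect_equal(suppressWarnings(aggregateFeatures(tampered)), a)

  allpad <- s
  allpad@mask <- rep(FALSE, 10)
  allpad@channels <- matrix(0, 10, 20)
  expect_error(aggregateFeatures(allpad), "masked")
})

test_that("channel ranges hold for fuzzed random detection streams", {
  set.seed(31)
  for (trial in 1:25) {
    n <- sample(1:12, 1)
    x0 <- sample(0:100, n, replace = TRUE)
    y0 <- sample(0:100, n, replace = TRUE)
    d <- data.frame(frame = 0L,
                    category = sample(objectCategories(), n, replace = TRUE),
                    x_min = x0, y_min = y0,
                    x_max = x0 + sample(1:27, n, replace = TRUE),
                    y_max = y0 + sample(1:27, n, replace = TRUE),
                    score = runif(n))
    v <- encodeFrame(d, 128, 128)
    expect_true(all(v >= 0 & v <= 1))
    expect_true(v[["pill_in_hand"]] %in% c(0, 1))
  }
})

test_that("sequence CSV export writes the layout and sidecar metadata", {
  s <- buildSequence(matrix(runif(40), 2, 20), T_fixed = 4,
                     episode_id = "epX", label = "medication")
  tf <- tempfile(fileext = ".csv")
  writeSequenceCSV(s, tf)
  back <- read.csv(tf)
  expect_equal(nrow(back), 4L)
  expect_equal(names(back)[1:2], c("frame_slot", "mask"))
  meta <- jsonlite::fromJSON(paste0(tf, ".meta.json"))
  expect_equal(meta$episode_id, "epX")
  expect_equal(meta$label, "medication")
})
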