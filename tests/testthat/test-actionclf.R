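zeroParams <- function(D, H) {
  p <- list()
  for (g in c("f", "i", "o", "g")) {
    p[[paste0("Wx", g)]] <- matrix(0, H, D)
    p[[paste0("Wh", g)]] <- matrix(0, H, H)
    p[[paste0("b", g)]] <- rep(0, H)
  }
  p$w_out <- rep(0, H); p$b_out <- 0
  p
}

test_that("the gate recurrence has its closed forms at zero parameters", {
  p <- zeroParams(3, 4)
  st <- lstmStep(c(1, -2, 3), rep(0, 4), rep(0, 4), p)
  expect_equal(st$h, rep(0, 4))
  expect_equal(st$c, rep(0, 4))

  cc <- c(2, -1, 0.5, 0)
  st2 <- lstmStep(c(1, -2, 3), rep(0, 4), cc, p)
  expect_equal(st2$c, 0.5 * cc)                 # f = sigma(0) = 0.5
  expect_equal(st2$h, 0.5 * tanh(0.5 * cc))     # o = 0.5

  expect_error(lstmStep(c(1, 2), rep(0, 4), rep(0, 4), p), "shape")
})

test_that("gate activations stay in their ranges for random inputs", {
  set.seed(8)
  for (trial in 1:20) {
    m <- lstmInit(5, 3, seed = trial, init_scale = 1)
    st <- lstmStep(rnorm(5), rnorm(3), rnorm(3), m)
    expect_true(all(st$i > 0 & st$i < 1))
    expect_true(all(st$f > 0 & st$f < 1))
    expect_true(all(st$o > 0 & st$o < 1))
    expect_true(all(st$g > -1 & st$g < 1))
  }
})

test_that("lstmStep matches a straight-line transcription of the equations", {
  set.seed(17)
  for (trial in 1:100) {
    D <- sample(2:6, 1); H <- sample(2:5, 1)
    m <- lstmInit(D, H, seed = trial, init_scale = 1.5, forget_bias = 0)
    x <- rnorm(D); h0 <- rnorm(H); c0 <- rnorm(H)
    got <- lstmStep(x, h0, c0, m)
    want <- oracleLstmStep(x, h0, c0, m@params)
    expect_equal(got$h, want$h, tolerance = 1e-10)
    expect_equal(got$c, want$c, tolerance = 1e-10)
  }
})

test_that("sequence forward pass respects the head, mask and range contracts", {
  D <- 20; H <- 4
  zero <- new("LSTMModel", inputSize = as.integer(D), hiddenSize = as.integer(H),
              params = zeroParams(D, H), history = numeric(0))
  s <- buildSequence(matrix(runif(5 * D), 5, D), T_fixed = 8)
  expect_equal(forwardSequence(s, zero), 0.5)

  m <- lstmInit(D, H, seed = 2)
  s_nopad <- buildSequence(matrix(0.3, 6, D), T_fixed = 6)
  s_pad <- buildSequence(matrix(0.3, 6, D), T_fixed = 12)
  expect_equal(forwardSequence(s_pad, m), forwardSequence(s_nopad, m))
  p <- forwardSequence(s_pad, m)
  expect_gt(p, 0); expect_lt(p, 1)
  expect_error(buildSequence(matrix(0.3, 6, D + 1), T_fixed = 6),
               "channel layout")
  expect_error(forwardSequence(matrix(0.3, 6, D + 1), m), "input size")
})

test_that("analytic BPTT gradients match central finite differences", {
  set.seed(5)
  D <- 3; H <- 2; Tl <- 4; N <- 2
  m <- lstmInit(D, H, seed = 3)
  p <- m@params
  Xl <- lapply(seq_len(Tl), function(t) matrix(rnorm(D * N), D, N))
  M <- matrix(1, Tl, N); M[4, 2] <- 0
  y <- c(1, 0)
  lg <- pillcam:::lstmLossGrad_(p, Xl, M, y)
  eps <- 1e-5
  for (nm in names(p)) {
    for (k in seq_along(p[[nm]])) {
      pp <- p
      pp[[nm]][k] <- pp[[nm]][k] + eps
      lp <- pillcam:::lstmLossGrad_(pp, Xl, M, y)$loss
      pp[[nm]][k] <- pp[[nm]][k] - 2 * eps
      lm <- pillcam:::lstmLossGrad_(pp, Xl, M, y)$loss
      num <- (lp - lm) / (2 * eps)
      ana <- lg$grads[[nm]][k]
      expect_lte(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("training reduces the loss monotonically in full batch and repeats itself", {
  fx <- getSequenceFixture()
  tr_ids <- fx$ds$manifest$episode_id[fx$ds$manifest$partition == "train"]
  cfg <- list(hidden = 8L, epochs = 30L, lr = 0.02,
              batch_size = length(tr_ids), seed = 4)
  m1 <- trainActionClassifier(fx$seqs[tr_ids], config = cfg)
  expect_true(all(diff(m1@history) <= 1e-8))
  m2 <- trainActionClassifier(fx$seqs[tr_ids], config = cfg)
  expect_identical(m1@params, m2@params)

  one_class <- fx$seqs[fx$ds$manifest$episode_id[
    fx$ds$manifest$label == "medication"]]
  expect_error(trainActionClassifier(one_class), "both classes")
})

test_that("a trained LSTM separates held-out noisy episodes", {
  fx <- getSequenceFixture()
  m <- fx$ds$manifest
  tr_ids <- m$episode_id[m$partition == "train"]
  te_ids <- m$episode_id[m$partition == "test"]
  # the small fixture has far fewer gradient updates per epoch than the
  # full study, so give it a proportionally longer training run
  lstm <- trainActionClassifier(fx$seqs[tr_ids],
                                config = list(seed = 5, epochs = 400))
  pred <- classifySequences(lstm, fx$seqs[te_ids])
  acc <- mean(pred$label == m$label[m$partition == "test"])
  expect_gte(acc, 0.9)
  # serialization round-trip preserves predictions
  tf <- tempfile(fileext = ".json")
  saveLSTMModel(lstm, tf)
  back <- readLSTMModel(tf)
  expect_equal(classifySequences(back, fx$seqs[te_ids])$score, pred$score,
               tolerance = 1e-12)
})

test_that("the rule recognizer implements the consecutive-contact decision", {
  mk <- function(frames_with_contact, n_frames = 12) {
    rows <- lapply(frames_with_contact, function(f) {
      data.frame(frame = f,
                 category = c("pill", "open_mouth"),
                 x_min = c(60, 52), y_min = c(42, 36),
                 x_max = c(70, 76), y_max = c(52, 56),
                 score = c(0.9, 0.9))
    })
    do.call(rbind, rows)
  }
  expect_equal(ruleBasedClassify(mk(3:7), 12), "medication")
  expect_equal(ruleBasedClassify(mk(c(2, 4, 6, 8)), 12), "non_medication")
  expect_equal(ruleBasedClassify(mk(3:7), 12, ruleParams(k_consecutive = 6)),
               "non_medication")

  # a pill only ever overlapping the hand is not taking it
  hand_only <- do.call(rbind, lapply(0:11, function(f) {
    data.frame(frame = f, category = c("pill", "hand"),
               x_min = c(60, 50), y_min = c(96, 90),
               x_max = c(70, 92), y_max = c(106, 122),
               score = c(0.9, 0.9))
  }))
  expect_equal(ruleBasedClassify(hand_only, 12), "non_medication")
  expect_equal(ruleBasedClassify(emptyDets <- NULL, 12), "non_medication")
  # low-confidence pills are ignored
  weak <- mk(3:7); weak$score[weak$category == "pill"] <- 0.2
  expect_equal(ruleBasedClassify(weak, 12), "non_medication")
})

test_that("the rule recognizer is exact on noise-free datasets of any seed", {
  for (seed in c(2, 13)) {
    ds <- makeDataset(defaultGrammar(), n_episodes = 8, n_train = 4,
                      seed = seed, duration_s = 20)
    pred <- vapply(ds$episodes, function(ep) {
      d <- corruptDetections(groundTruth(ep), noiseFree(), seed = 1,
                             n_frames = nFrames(ep))
      ruleBasedClassify(d, nFrames(ep))
    }, character(1))
    expect_equal(unname(pred), ds$manifest$label)
  }
})

test_that("baselines train, repeat themselves and handle degenerate data", {
  set.seed(60)
  n <- 40
  X <- cbind(sig = c(rnorm(n / 2, 2), rnorm(n / 2, -2)),
             noise = rnorm(n))
  y <- rep(c("medication", "non_medication"), each = n / 2)
  models <- fitBaselines(X, y, seed = 1)
  expect_named(models, c("logistic_regression", "boosted_decision_tree",
                         "support_vector_machine", "decision_forest"))
  lr_acc <- mean(predictBaseline(models$logistic_regression, X)$label == y)
  expect_equal(lr_acc, 1.0)

  probe <- X[c(1, 2, n), , drop = FALSE]
  again <- fitBaselines(X, y, seed = 1)
  for (nm in names(models)) {
    expect_equal(predictBaseline(again[[nm]], probe)$label,
                 predictBaseline(models[[nm]], probe)$label)
  }

  # constant features: every model falls back to the majority class
  Xc <- matrix(1, 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  yc <- c(rep("medication", 6), rep("non_medication", 14))
  mc <- fitBaselines(Xc, yc, seed = 1)
  for (nm in names(mc)) {
    expect_equal(unique(predictBaseline(mc[[nm]], Xc[1:4, ])$label),
                 "non_medication")
  }
  expect_error(fitBaselines(X, rep("medication", n)), "both classes")
})
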