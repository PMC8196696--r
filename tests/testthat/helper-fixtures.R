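# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# small rendered dataset + trained detector (the expensive fixture)
getDetectorFixture <- function() {
  if (is.null(.fixtures$detector)) {
    ds <- makeDataset(defaultGrammar(), n_episodes = 6, n_train = 4,
                      seed = 7, duration_s = 8)
    model <- trainDetector(ds, config = list(max_frames_per_episode = 8),
                           seed = 1)
    .fixtures$detector <- list(ds = ds, model = model)
  }
  .fixtures$detector
}

# moderate-noise take sequences for classifier tests (smaller than the
# full study-size dataset; the acceptance suite runs the full one)
getSequenceFixture <- function() {
  if (is.null(.fixtures$seqs)) {
    ds <- makeDataset(defaultGrammar(), n_episodes = 40, n_train = 28,
                      seed = 21, duration_s = 20)
    np <- noiseParams(0.1, 0.5, 2)
    seeds <- pillcam:::derive_seeds_(22, length(ds$episodes))
    seqs <- lapply(seq_along(ds$episodes), function(i) {
      ep <- ds$episodes[[i]]
      d <- corruptDetections(groundTruth(ep), np, seed = seeds[i],
                             n_frames = nFrames(ep))
      detectionsToSequence(d, nFrames(ep), T_fixed = 64,
                           episode_id = episodeId(ep),
                           label = episodeLabel(ep))
    })
    names(seqs) <- names(ds$episodes)
    .fixtures$seqs <- list(ds = ds, seqs = seqs)
  }
  .fixtures$seqs
}

# one-glyph image helper
glyphImage <- function(box, color = c(0.2, 0.6, 0.9), width = 64, height = 64) {
  img <- array(rep(c(0.82, 0.82, 0.80), each = height * width),
               dim = c(height, width, 3))
  for (ch in 1:3) {
    img[(box$y_min + 1):box$y_max, (box$x_min + 1):box$x_max, ch] <- color[ch]
  }
  img
}
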